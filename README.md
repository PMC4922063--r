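# semiRecMap

Mapping an autosomal semi-recessive trait in a case/control cohort and
prioritizing its causal variant — from segregation analysis to a de-novo
transcription-factor-binding-site prediction — as one tested R pipeline.

The package is aimed at geneticists working with closed animal
populations (livestock strains, laboratory colonies) in which a
recessive or semi-recessive phenotype segregates and the causal mutation
is expected to descend from a single ancestral haplotype. It implements
the full chain of desk analyses such a study needs, with the real-data
formats (VCF, PLINK-style PED/MAP, BED, FASTA, TSV count tables) at the
boundaries and synthetic-data generators with planted truth for
verification.

## The statistical core

* **Segregation**: χ² goodness of fit of observed (unaffected, affected)
  offspring counts against candidate Mendelian ratios u:a
  (χ² = Σ(O−E)²/E, df = 1), ratio selection by maximal p, and per-class
  penetrance estimates with Wilson 95% intervals.
* **Association**: marker QC (MAF > 0.05, call rate > 0.75), allelic χ²
  on the 2×2 allele-count table (Fisher exact when an expected cell
  < 5), and genome-wide empirical significance by single-step max-T
  phenotype permutation with the add-one estimator
  p_genome = (#{max ≥ observed} + 1)/(n_perm + 1).
* **Haplotype concordance**: windows of 2–10 markers whose
  window-homozygote classes perfectly separate phenotype (all risk-
  haplotype homozygotes affected, all other homozygotes unaffected, read
  without phasing), merged into maximal blocks, scored by a 3×2 Fisher
  exact test and a chromosome-wide permutation p, and a candidate
  interval bounded by the nearest informative recombinant markers
  (1-based inclusive, length truncated to whole kb).
* **Variant cascade**: recessive co-segregation classification
  (CONSISTENT / AMBIGUOUS with missing data / INCONSISTENT), absolute
  population-panel privacy filtering, source merging, region and
  coding-effect annotation (protein labels such as N106K), and
  deterministic candidate ranking with promoter-focus first.
* **Expression**: exon-level RPKM
  (count / (library/10⁶) / (length/10³)), pseudocounted fold changes,
  and an isoform-specific-loss caller that separates loss of one
  promoter's first exon from a gene-level shift.
* **Motif gain**: strand-aware IUPAC/PWM scanning (default SOX HMG-box
  core `WWCAAWG`), indel-aware coordinate projection between promoter
  alleles, gained/lost site sets in no-zero TSS-relative coordinates,
  and an in-silico region-deletion test for predicted restoration.

See `vignettes/semi-recessive-mapping.Rmd` for the models, conventions
and design decisions in detail.

## Worked example

`runDemo()` simulates a full study — 74 offspring in 11 carrier×carrier
litters, a 28-case/73-control cohort typed at 2,000 SNPs in founder-
haplotype LD around a semi-recessive locus (penetrances 1.0 and 4/51),
a 3+3 resequencing panel against 103 wild-type genomes, a 3v3 exon count
table with an 11.5-fold planted loss of the M first exon, and a promoter
allele pair carrying a 9-bp insertion, a GC>TT substitution and a 14-bp
insertion with a SOX consensus payload — then runs every stage and
checks it against the planted truth:

```r
library(semiRecMap)
report <- runDemo()
#> [segregation] 11 litters, 74 offspring (14 affected); selected ratio 3:1
#> [assoc] 2000 markers -> 1879 after MAF/call-rate QC
#> [assoc] top marker M01000 (pos 59990000, p_genome 0.0004998), r2 with causal 1.00
#> [hapmap] 2 concordant block(s); best: 26 risk-hom / 56 het (2 affected) / 17 prot-hom, fisher p 7.3e-22, p_chr 0.0005
#> [hapmap] interval 13:59940000-60050000 (110 kb), contains causal: TRUE
#> [prioritize] 65 variants -> 65 co-segregated (0 ambiguous) -> 15 private -> 15 retained
#> [prioritize] causal variant rank: 1
#> [exonfc] planted 11.5-fold loss on exon M; estimated 12.7; flagged isoform(s): M
#> [motifscan] gained sites: 1 (TSS-relative -7550); lost: 0; 96-bp deletion restores: TRUE
report$ok
#> [1] TRUE
```

Reading the log: the 3:1 unaffected:affected ratio is the single-locus
recessive expectation; the top association marker is the planted causal
SNP (r² = 1); the concordant haplotype block separates 26 risk
homozygotes from 17 protective homozygotes with 2 affected carriers
among 56 heterozygotes, and the recombinant-bounded interval contains
the causal position; the variant cascade strips the 50 panel-shared
variants and ranks the planted promoter insertion first among the 15
private ones; the exon caller flags only the M isoform; and the motif
scan finds exactly one gained SOX site, inside the 14-bp insertion,
which disappears when the 96-bp mutation cluster is deleted in silico.

The worked example on the printed cohort numbers alone:

```r
gofChisq(c(49, 25), c(3, 1))
#> GOF vs 3:1  observed (49 unaffected, 25 affected)  chi2 = 3.0450 (df = 1), p = 0.08098
selectMendelianRatio(c(49, 25))$selected
#> [1] 3 1
lengthKb(candidateInterval("13", 56170062, 56933573))
#> [1] 763
```

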