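---
title: "Mapping a semi-recessive trait and prioritizing its causal variant"
author: "semiRecMap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a semi-recessive trait and prioritizing its causal variant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semiRecMap)
```

# The analysis problem

semiRecMap implements the chain of analyses used to take an autosomal
recessive (or semi-recessive) trait in a closed animal population from
"it is heritable" to "this is the candidate mutation":

1. **Segregation analysis** on litters from carrier x carrier matings
   (chi-square goodness of fit against candidate Mendelian ratios,
   penetrance estimation per genotype class).
2. **Case/control association mapping** on SNP-array genotypes (MAF and
   call-rate QC, allelic tests, genome-wide empirical significance by
   max-T phenotype permutation).
3. **Haplotype-concordance mapping**: finding marker windows whose two
   homozygote classes perfectly separate affected from unaffected
   animals, and bounding the candidate interval by the nearest
   informative recombinants.
4. **Variant prioritization**: a co-segregation filter under the
   recessive model (with explicit handling of missing calls), exclusion
   of alleles carried by a wild-type population panel, merging of
   screening sources, and region/coding-effect annotation with
   deterministic ranking.
5. **Isoform-resolved expression analysis**: exon-level RPKM so that
   loss of one promoter's isoform is visible even when gene-level
   quantification is flat across isoforms.
6. **Regulatory interpretation**: strand-aware motif scanning of the
   two promoter alleles with indel-aware coordinate projection, to ask
   whether an insertion created a transcription-factor binding site de
   novo — a candidate silencer — and whether deleting the mutated
   region is predicted to restore the reference behaviour.

The package is written for the common situation where the real cohort
is not redistributable: every stage is exercised end to end on
synthetic data whose generators plant a known truth and return it, so
the pipeline's operating characteristics (recovery rates, calibration)
are measurable.

# Statistical models and conventions

## Segregation

For observed (unaffected, affected) counts and a candidate u:a ratio,
`gofChisq` uses the classical df = 1 Pearson statistic
\(\chi^2 = \sum_c (O_c - E_c)^2 / E_c\) without continuity correction
(a `yates` flag is available). `selectMendelianRatio` scores candidates
{1:1, 3:1, 15:1} by goodness-of-fit p and ties break toward the simpler
ratio. The ratio convention is unaffected:affected, so 3:1 is the
single-locus recessive expectation. Note that at realistic litter
totals the exact multinomial tail can sit a couple of percentage points
away from the chi-square approximation; the test suite checks the
statistic against both a Monte-Carlo resample and the exact binomial
tail with a band wide enough for that discreteness.

Penetrance per genotype class is estimated as affected/total with a
Wilson 95% interval (z = 1.959964); an empty class is reported as
undefined rather than zero.

## Association and genome-wide significance

Markers pass QC when MAF > 0.05 and call rate > 0.75 (strict
inequalities, computed on non-missing alleles). The single-marker test
is the allelic chi-square on the 2x2 allele-count table (two alleles
per non-missing genotype); when any expected cell is below 5 the
two-sided Fisher exact p replaces the chi-square p. Family-wise
significance is single-step max-T: phenotype labels are permuted with
genotypes fixed, the maximum allelic chi-square across markers is
recorded per permutation, and each marker's genome-wide empirical p is
the add-one estimator \((b + 1)/(n_{perm} + 1)\), which never returns
zero and is conservative by construction. The permutation statistic is
always the allelic chi-square — even for markers whose per-marker p
came from the Fisher branch — so that one comparable statistic ranks
all markers. Missing genotypes are dropped per marker, never imputed.

## Haplotype concordance and the candidate interval

No statistical phasing is attempted. A sample is a *window-homozygote*
when it is homozygous at every marker of a window with no missing
call; its haplotype is then read directly off the genotypes. A window
is *concordant* when all affected window-homozygotes share a single
(risk) haplotype, no unaffected animal is homozygous for that
haplotype, and both homozygote classes are non-empty. Heterozygous
animals do not enter the concordance condition — under a
semi-recessive model a few of them are expected to be affected, and
they are reported as `het_affected` (penetrance data) instead.
Overlapping concordant windows merge into maximal blocks; each block is
summarized by its strongest window (most phenotype-explaining
homozygotes, ties to the widest then leftmost).

A block is scored two ways. `fisher_p` is the two-sided Fisher exact p
of the 3x2 table (risk-homozygote / heterozygote /
protective-homozygote by phenotype). `p_chr` asks how often a phenotype
permutation produces an equally-or-more concordant window anywhere on
the chromosome. To keep that comparison exchangeable and free of ties,
the per-window statistic is the Pearson chi-square of phenotype
against a *phenotype-free* partition of the samples (most common
window-homozygote haplotype / other window-homozygotes /
heterozygotes); the add-one estimator is used as above. The suite
verifies this p is uniform under label-shuffled phenotypes.

The candidate interval walks outward from the block: the boundary on
each side is the position of the nearest flanking marker at which any
affected risk-homozygote stops being consistent with homozygosity for
an extended risk haplotype — a heterozygous call, or affected animals
homozygous for different alleles. Boundaries are the recombinant
markers themselves (not midpoints), the interval is 1-based inclusive,
and its length is truncated to whole kb — the convention under which
boundaries 56,170,062 and 56,933,573 span 763 kb. When a chromosome
end is reached first, the interval is flagged `open`.

## The variant cascade

Under the recessive model a variant is **CONSISTENT** when every case
is homozygous-alternate and no control is (controls may be carrier
heterozygotes; a strict mode requires homozygous-reference controls);
**AMBIGUOUS** when at least one call is missing and every observed call
is still consistent; **INCONSISTENT** otherwise. Ambiguous variants are
retained through the cascade but flagged, matching the practice of
keeping missing-data SNPs in the co-segregating set. Panel exclusion is
absolute: any panel individual carrying one alternate allele removes
the variant, so "private to the cases" means private. The filter is
monotone in the panel: adding individuals can only exclude more.

Annotation assigns promoter (a strand-aware window upstream of the
TSS, 10 kb by default), coding, splice boundary (within 2 bp of an exon
edge), intron or intergenic, with coding SNPs translated through the
standard genetic code into labels such as N106K, and coding indels
labelled frameshift or in-frame by length modulo 3. Ranking is a
deterministic total order: focus-region (promoter) variants first, then
non-silent coding > splice > promoter > intron > silent coding >
intergenic, then position.

## Exon-level expression

Normalization is exon-level RPKM:
\(\mathrm{value} = c / (L/10^6) / (\ell/10^3)\) for count c, library
size L and exon length \(\ell\). Fold change between groups is the
ratio of arithmetic means of normalized values with a pseudocount of
0.5 reads (expressed on the normalized scale using the median library
size and the exon's own length), which keeps near-silenced exons
finite without distorting well-expressed ones; direction is reported
explicitly. An isoform is called *specifically lost* when its own
first exon reaches the fold threshold (default 2) while no shared exon
does — a gene-level shift moves the shared exons too and is therefore
not called.

## Promoter allele comparison

Motif models are IUPAC consensus strings (default SOX HMG-box core
`WWCAAWG`) or position weight matrices with a score threshold.
Scanning is strand-aware; minus-strand hits are reported at their
forward-strand start with the site sequence as read on the minus
strand. The two promoter alleles are compared through the edit list
(insertions, substitutions, deletions in reference coordinates):
positions project between alleles with shifts accumulated over edits,
and positions inside a span that exists in only one allele project to
nothing. A hit is *gained* when the alternate allele has it and the
reference has no hit at the projected position on the same strand —
which includes sites created inside insertions and at insertion
junctions. TSS-relative coordinates use the no-zero convention (…, −2,
−1, +1, …). `deletionTest` removes a region from the alternate allele
and re-runs the comparison; an empty gained set is reported as
predicted restoration.

# What the generators emulate — and what they do not

`simCohort` builds genotypes as founder-haplotype mosaics: each
transmitted haplotype copies one of 8 founders and switches founder
with probability 0.01 per marker. This produces the two features the
mapping stages need — linkage disequilibrium around every locus and a
single ancestral risk haplotype — without a recombination map. The
risk founder is drawn with weight 0.5, emulating a closed breeding
population in which the mutant allele has drifted to intermediate
frequency: with penetrances 1.0 (hom) and 4/51 (het), a 28-case /
73-control cohort then contains roughly 24 risk homozygotes, 51
heterozygotes with about 4 affected, and 26 protective homozygotes —
the structure the haplotype-concordance model expects. Phenotypes come
from the causal genotype alone; individuals are rejection-sampled to
the case/control quotas; 2% of calls are masked missing.

`simLitters` draws 74 offspring in 11 litters of 1:2:1 carrier-mating
genotypes. `simVariantCalls` plants 15 private-linked variants
(homozygous-alternate in all 3 cases, absent from 3 controls and a
103-animal panel, one of them the designated causal insertion) among
shared-common variants that co-segregate in the small panel but are
carried in the population. `simExonCounts` draws negative-binomial
counts with mean proportional to exon length x library size x a
per-exon abundance (uniform 50–500 RPKM-equivalents), variance
\(m + \phi m^2\) with dispersion \(\phi = 0.1\), mean depth 1e6, and
divides the mutant-group mean of flagged exons by the planted fold
change. `simPromoterPair` draws a uniform-composition reference
sequence and rejects it until it is motif-free *and* the edited allele
carries exactly the payload's single motif hit inside the 14-bp
insertion — so the expected gained-site count is exactly one; the
default edit structure is a 9-bp insertion, a GC>TT dinucleotide
substitution and the 14-bp payload insertion within a ~100-bp cluster.

Not emulated: realistic demography or a recombination map, genotyping
error (only missingness), sequencing error or read-level simulation,
multi-gene regional annotation, and chromatin context for motif hits.
Passing recovery tests on these generators therefore shows the
*inference machinery* is correct and calibrated at the study's sample
sizes; it does not show robustness to artifacts the generators do not
produce.

Two sampling facts about the expression conditions are worth knowing.
At 3 vs 3 samples with dispersion 0.1 the per-group mean of an exon's
normalized values has a coefficient of variation near
\(\sqrt{1/m + 0.1}/\sqrt{3} \approx 0.19\), so a fold-change ratio
carries a log-scale sd of roughly 0.27: the median relative error of
the estimate is then expected near 17–19% whatever the estimator, and
with 8 shared exons about one dataset in ten shows some shared exon
crossing the 2-fold threshold by chance. The isoform-loss caller's
"only the planted isoform" behaviour is therefore a typical-dataset
property at these conditions, not a per-dataset certainty, and the
acceptance checks treat it accordingly.

# Numerical and design choices

- Internal coordinates are 1-based inclusive everywhere (VCF
  convention); the only 0-based half-open conversion is in the BED
  writer/reader.
- Missing genotypes are `NA`, never conflated with homozygous
  reference; the ambiguity logic of the cascade depends on the
  distinction.
- Multi-allelic VCF records are split into biallelic records at read
  time; indels use the anchored-base convention.
- Empirical p-values use the add-one estimator throughout, with a
  1e-9 tolerance when comparing permuted statistics to the observed
  one to absorb floating-point ties.
- The allelic chi-square for permutation is computed in a reduced
  closed form from the case alt-allele and call counts, evaluated as
  two matrix products per permutation block; blocks of 1000–2000
  permutations bound memory.
- Degenerate tables (empty strata, zero margins) yield statistic 0 or
  a flagged result, never an error, so permutation never aborts.
- Rejection sampling (cohort quotas, motif-free references) is bounded
  and fails with an explicit message when a quota is unreachable.
- All generators take one integer seed and restore the RNG state
  (`withr::with_seed`); equal seeds give byte-identical output.

Problem sizes in the shipped tests and acceptance script were chosen
to exercise the study-scale designs (28/73 cohorts on 2000 markers;
3+3+103 resequencing panels; 3 vs 3 expression) with permutation
counts of a few hundred to a few thousand and 50–200 simulation
replicates per property — enough for the binomial error of a recovery
rate to be a few percent. The full-scale permutation counts
(100,000 genome-wide, 25,000 chromosome-wide) remain the defaults of
the corresponding functions.

# A worked demonstration

```{r demo, eval = FALSE}
cfg <- pipelineConfig()
cfg$cohort$n_markers <- 300      # demonstration scale
cfg$association$n_perm <- 300
cfg$haplotype$n_perm <- 300
report <- runDemo(cfg)
report$ok
```

`runDemo` chains all six stages on simulated data, logs the record
counts of the variant cascade (total, co-segregated, ambiguous,
private, retained), and compares every stage's result with the planted
truth. Setting `cfg$variants$panel_carries_causal <- TRUE` runs the
designed negative control: the causal insertion is then carried by one
panel animal, the privacy filter removes it, and the report flags the
(expected) recovery failure.

# Known limitations

- The concordance scan is exhaustive over windows of 2–10 markers;
  very long risk haplotypes are found as merged blocks rather than as
  one wide window.
- `p_chr` measures concordance through a phenotype-free three-class
  partition; in datasets where more than two homozygote haplotypes are
  common in one window, the partition lumps the minor ones together.
- Coding annotation handles SNPs and simple indels against a single
  gene model; it is not a general-purpose variant-effect predictor
  (no UTR model, no multi-transcript resolution beyond the declared
  first exons).
- The motif component predicts candidate binding sites from sequence
  alone; it cannot say whether a site is bound in vivo.
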