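---
title: "Homozygosity mapping with rohtrait: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homozygosity mapping with rohtrait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohtrait)
```

## The problem

Runs of homozygosity (ROH) are contiguous stretches of a diploid genome where
both haplotypes are identical, usually because they descend from a common
ancestor. In livestock, the genome-wide ROH burden measures inbreeding (the
genomic inbreeding coefficient FROH), and regions where many animals carry
overlapping ROH — consensus ROH and ROH islands — can mark selection
footprints linked to production traits. `rohtrait` implements the full
analysis chain for SNP-array genotypes: quality control, ROH detection,
summaries, consensus/island construction, and two complementary association
stages (extreme-group Fisher enrichment, then a GRM-based mixed-model
validation), plus a seeded simulator that makes every stage testable against
planted truth.

## ROH detection

Detection follows the PLINK-style two-phase design. A sliding window of
`window_snps = 50` SNPs passes over each individual and chromosome; a window
is *homozygous* if it contains at most `window_max_het = 1` heterozygous and
`window_max_missing = 5` missing calls. Each SNP's *hit rate* is the fraction
of windows covering it that are homozygous, and SNPs with hit rate at least
`window_hit_threshold = 0.05` become run candidates. Final segments must then
satisfy six criteria: minimum length 500 kb, minimum 100 SNPs, average
density at most 50 kb/SNP, no inter-SNP gap above 100 kb, and at most 1
heterozygous and 2 missing calls per segment. Size classes are Small
(0.5 to <1 Mb), Medium (1 to 5 Mb inclusive) and Large (>5 Mb); the published
class ranges share their endpoints, so we assign 1 Mb and 5 Mb to Medium and
document the choice here.

Two details of run construction are deliberately fixed because no published
definition settles them:

* **Run selection is greedy left-to-right.** Within each gap-split stretch of
  candidate SNPs, a run starts at the first homozygous non-missing SNP,
  extends as far as the segment het/missing allowances permit, is trimmed to
  end on a homozygous non-missing SNP, and the scan resumes after it. This is
  deterministic and matched exactly by the brute-force oracle used in the
  test suite.
* **Window missing allowance.** The window heterozygote cap is published (1)
  but the missing cap is not; we use 5, the screening tool's default, and
  expose it in `roh_params()`.

Segment length is `end_bp - start_bp + 1` (1-based inclusive coordinates, as
in PLINK text formats). A consequence of window screening worth knowing:
when an autozygous segment ends, flanking genotypes drawn from
Hardy-Weinberg proportions are still homozygous with probability around
0.6 per SNP, so a called segment typically overruns the true breakpoint by a
few SNPs (geometric overshoot, occasionally extended across one flanking
heterozygote by the segment allowance). Called boundaries are therefore
accurate to a few SNPs, not to one.

## FROH, summaries and consensus regions

FROH is an individual's summed ROH length divided by the SNP-covered
autosome length (per-chromosome first-to-last SNP span). Using the covered
span rather than an assembly length keeps the coefficient self-contained:
un-genotyped chromosome ends neither inflate nor deflate it. Zero-ROH
individuals stay in all averages.

Consensus ROH pool overlapping segments across individuals by transitive
(single-linkage) positional overlap; each pool's consensus is the
intersection interval of its members, and pools with an empty intersection
are split greedily left-to-right into sub-pools with non-empty
intersections. Regions with fewer than 5 SNPs are dropped. A region's
carriers are all samples with an ROH fully covering its interval — pool
members always qualify (the interval is their intersection), and after a
pool split a neighbouring sub-pool's member may too; defining carriers this
way keeps the region frequency identical to the population mean of
`carrier_status()`. ROH islands are maximal runs of SNPs whose carrier rate
strictly exceeds 0.2, merged across gaps of at most 100 kb (the same gap
constant as the scanner, configurable).

## Phenotype adjustment and association

Production traits (net meat weight, carcass weight, average daily gain =
weight gain / fattening days, live weight) are adjusted by ordinary least
squares on farm, year and sex (categorical) plus weight before fattening and
fattening days (covariates); the residuals are the adjusted phenotypes. Any
full-rank factor coding yields identical residuals, which is all downstream
stages use.

For each trait the top and bottom `n = 300` animals by adjusted value form
extreme groups (ties broken by sample id for determinism). Each consensus
region contributes a 2x2 table of carrier status against group and is tested
with the two-sided Fisher exact test (p = sum of hypergeometric
probabilities no larger than the observed table's). The odds ratio is the
sample OR with a Haldane-Anscombe 0.5 correction when a cell is zero. No
multiplicity correction is applied by default — matching the study design
this mirrors, which reports raw p < 0.05 counts — and Benjamini-Hochberg is
available via `p_adjust = "BH"`. Because the test is exact and the tables
discrete, its attained size is below the nominal level for small groups;
calibration checks should expect rejection rates under, not at, 5%.

Regions passing the Fisher screen are validated with the mixed model
`y = Xb + Zu + e`, with the region's carrier indicator among the fixed
effects, `u ~ N(0, G sigma_g2)` for the VanRaden method-1 GRM `G`
(dosages centred by twice the observed allele frequency, scaled by
`2*sum(p(1-p))`; missing calls mean-imputed for this step only), `Z = I`
(one record per animal) and `e ~ N(0, I sigma_e2)`. REML is profiled down to
the variance ratio `lambda = sigma_g2/sigma_e2` via the eigendecomposition
of `G` and maximised by bounded one-dimensional search on `log10(lambda)`
(interval `[-6, 6]`, tolerance 1e-9), which is deterministic and free of
starting-value sensitivity; `lambda = 0` is compared explicitly so boundary
estimates are exact and flagged. The carrier coefficient is tested with a
two-sided Wald test against a normal reference. With a normal (rather than
t) reference the test is slightly anti-conservative at small n (measured
type-I error ~0.06-0.08 at n = 60, nominal at n = 600); the model validates
regions in populations of several hundred animals, where the approximation
is good. The mixed model uses raw traits with the fixed effects in `X`;
the carrier-vs-non-carrier boxplot contrast (`compare_carriers()`) uses
adjusted traits. Both pathways exist and are labelled.

## Linkage disequilibrium

Pairwise LD around candidate regions is computed from unphased genotypes by
the standard two-locus EM (convergence 1e-10, cap 1000 iterations; only the
double-heterozygote class has ambiguous phase), giving `r2 = D^2/(pA pa pB pb)`
and `|D'| = |D|/Dmax`, with pairwise-complete observations for missing data.
The signed D' is reported alongside the matrix of absolute values.

## The simulator and what it does (not) emulate

`sim_config()`/`simulate_genotypes()` build array-density genotypes
(exponential spacings, mean 4 kb; allele frequencies Uniform(0.05, 0.5)).
Outside planted segments, genotypes are independent Hardy-Weinberg draws.
Each individual receives a Poisson number (mean 4) of background autozygous
segments with a short/long log-normal length mixture (medians ~0.7 Mb and
~6 Mb, long weight 0.15) — the short-dominated spectrum array studies
report — in which both haplotypes are the individual's own ancestral draw
(allele chosen once per SNP by frequency). Planted *association regions*
instead make each carrier homozygous for a single ancestral haplotype shared
by all carriers: a selection footprint. That choice matters twice — it
produces the elevated LD that the LD stage is supposed to measure (with
independent per-carrier draws, region r2 would be ~0), and it interacts
realistically with the Hardy-Weinberg QC filter, which genuinely penalises
high-frequency autozygosity regions (at carrier frequency 0.3 and n in the
hundreds, a fraction of region SNPs sits near the HWE removal threshold).
Genotyping error (heterozygous mis-calls inside segments) and missingness
are overlaid last. Phenotypes follow the generative mixed model: fixed
effects + region effects for carriers + a polygenic draw through the
factorised realized GRM (negative eigenvalues clipped) + Gaussian noise.

What the simulator does **not** emulate: background LD between SNPs (no
coalescent machinery — segments are planted directly so the detection oracle
stays exact), allele-frequency spectra of real arrays, genotype-calling
artefacts beyond uniform error/missingness, and pedigree structure. Passing
tests therefore demonstrate correctness of the algorithms under the stated
generative model, not calibration on any particular real population. The
small synthetic genomes (tens of Mb) also make simulated FROH values large
(~0.1-0.3) relative to real cattle (~0.05): the planted segment load is
spread over far less genome, which is a scale effect, not a model
difference.

## Problem sizes used in validation

The test suite validates the scanner against a brute-force oracle on 200
fuzzed chromosomes (up to 2,000 SNPs, up to 5 samples each); planted-segment
recovery on a 600-individual, 5 x 10,000-SNP study; Fisher p-values
exhaustively for all 2x2 tables with total at most 40; null calibration over
500 simulated traits on the 60-individual study; and variance-component
recovery over 200 replicates at n = 600 with true
`sigma_g2 = sigma_e2 = 1` and a 0.5-SD region effect. The acceptance script
runs the full pipeline on a 400-individual, 3 x 6,000-SNP study with one
planted region (carrier frequency 0.3, effect 0.5). These sizes were chosen
to exercise every code path at array-realistic density while completing in
minutes on a single core.

## Known limitations

* The scanner reproduces a window-screen dialect; likelihood/HMM-based ROH
  callers can be more sensitive for short segments and are out of scope.
* Called ROH boundaries overrun true breakpoints by a few SNPs (see above).
* The exact Fisher stage is conservative on small groups; with 300-animal
  groups, as in the intended design, discreteness is mild.
* One random effect only; no dominance or epistatic relationship matrices,
  no repeated records.
* PED allele inference is data-driven: at monomorphic variants the single
  observed allele is taken as `allele_a` (dosage 0). Binary BED/BIM round
  trips preserve allele roles exactly and are preferred for interchange.
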