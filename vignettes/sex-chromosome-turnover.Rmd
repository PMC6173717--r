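---
title: "Detecting sex-linked markers and quantifying sex-chromosome turnover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sex-linked markers and quantifying sex-chromosome turnover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexturn)
```

## The problem

In many poikilothermic vertebrates — frogs especially — sex chromosomes are
homomorphic: X and Y (or Z and W) look alike and recombine recently enough
that no large diverged region exists. One explanation is frequent
*sex-chromosome turnover*: the chromosome pair carrying the sex-determining
locus is swapped for another faster than differentiation can accumulate.
Detecting which chromosome determines sex in such species, and how often
lineages swap it, requires (i) finding sex-linked markers in population
genotype data, (ii) convincing oneself they are not artifacts, (iii)
locating them on a chromosome-level reference, and (iv) placing the
per-species sex-chromosome identities on a dated phylogeny and counting
transitions. `sexturn` implements that chain, together with a
synthetic-data module that generates inputs with known truth so that every
stage can be calibrated.

## Sex-linkage screens

Three rule-based screens are applied to each dataset, in both XY
(male-heterogametic) and ZW orientation; rules below are stated for XY and
the ZW orientation swaps the sex roles.

* **Allele frequency** (`screen_allele_freq`). A fully penetrant Y-specific
  SNP segregates at frequency 0.5 in males and 0 in females. Allowing for a
  few miscalls or mis-sexed individuals, a locus is flagged when the X
  allele — operationalized as the major allele among female calls, ties
  broken towards the reference allele — has frequency at least 0.95 in
  females and within [0.4, 0.6] in males. All fractions use non-missing
  calls only.
* **Heterozygosity** (`screen_heterozygosity`). Flagged when homozygous in
  *every* female call and heterozygous in at least half the male calls.
  This is the stricter screen: a 0.5 frequency can arise by chance in small
  samples or from structure among males, but ubiquitous male-only
  heterozygosity cannot.
* **Sex-limited tags** (`screen_sex_limited`). RADtags present in no female
  and in at least half of the males — produced by Y-specific restriction
  sites, X null alleles, or under-merged highly diverged gametologs.

"At least half" is evaluated as a fraction of the observed denominator
(so 10 of 20 males passes, 9 of 20 does not). Loci with no calls in one
sex are unevaluable and counted, never flagged.

Upstream of the screens, `filter_loci()` applies the standard RADseq
population filters: call rate of at least 75% within each sex, pooled
minor-allele frequency of at least 0.05, and observed heterozygosity at
most 0.75 (removing over-merged paralogous stacks). MAF is pooled across
sexes — the convention of running a single population through a Stacks-style
`populations` step; it is configurable. The heterozygosity ceiling has a
documented side effect that the tests reproduce: when the heterogametic
sex exceeds 75% of samples, fully sex-linked loci are themselves removed.

```{r screens}
sim <- simulate_population(pop_sim_params(
  n_males = 20, n_females = 20, n_loci = 2000, system = "XY",
  prop_sexlinked = 0.1, prop_y_snp = 0.5, prop_sex_limited = 0.25,
  prop_x_hemizygous = 0.25, seed = 1))
report <- run_all_screens(sim$genotypes, sim$tags, sim$sheet)
report
```

Note the ZW sets: they are exactly the simulated X-hemizygous loci. Loci
present on the X but hemizygous in males (or carrying a paternal-X-specific
allele) are heterozygous in every female and homozygous in every male —
the mirror image of a W-specific SNP. This pseudo-ZW confound is why a ZW
signal co-locating with an XY signal on the same chromosome is interpreted
as male hemizygosity rather than as a coexisting ZW system.

## The permutation null

Every screen flags *something* in every dataset, sex-linked or not, so the
observed count must be compared with what random sex assignments produce.
`build_null()` permutes the M/F labels across samples (sex counts
preserved) `n_permutations` times — 1000 by default — and re-runs all six
screens on each shuffle; the same shuffles are shared by the six screens,
and each shuffle draws from a sub-seed derived from the master seed by a
counter. A screen PASSes when its observed count strictly exceeds the
99th percentile (linear-interpolation definition) of its null series; ties
fail. The strict reading matches "probability below 0.01 of occurring by
chance"; both the percentile and the tie rule are configurable. When the
permutation count cannot resolve the requested percentile the exact rank
rule is used and a warning raised.

`subsample_experiment()` re-runs the whole screen-and-validate procedure on
reduced designs — a balanced series from 19M/19F down to 5M/5F, an 18M/9F
male skew, a 9M/18F female skew, and a 6+6 males / 12 females two-Y-haplotype
design (`scenario_catalog()`) — to probe which dataset properties drive
yield and validation. The two-haplotype design matters because a Y-specific
allele private to one Y lineage is heterozygous in only a fraction of
males: with two balanced haplotypes the carrier fraction sits exactly at
the 0.5 screening boundary and any dropout pushes loci below it, so the
heterozygosity screen loses markers relative to a single-haplotype dataset
of the same size.

## Identifying the sex chromosome

Validated markers are located by their alignment hits against
chromosome-assigned scaffolds (`filter_alignment_hits()` keeps a query's
best hit only when its e-value is below 1e-20 and at least five orders of
magnitude better than the runner-up, guarding against repetitive
multi-mappings). Observed per-chromosome counts are then compared against
a null built from 1000 random same-size subsets of the whole marker
catalogue (`random_subset_null()`), which absorbs chromosome-specific
mapping-rate biases. A chromosome is identified when at least ten
sex-linked markers align to it *and* the count strictly exceeds the null's
99th percentile (`identify_sex_chromosome()`). The ten-marker floor
applies to the observed set only, not to null replicates. If several
chromosomes pass, all are reported and flagged rather than forced to a
single winner — the criterion does not define a tie-break, and silently
choosing one would hide exactly the situation a user must inspect.

## Mk models, stochastic mapping and turnover counting

Per-species sex-chromosome states are analysed on a dated ultrametric tree
under a K-state Mk model (default K = 5: the chromosomes observed as
sex-linked). Tips are probability rows: a species polymorphic between two
chromosomes gets 0.5/0.5, a species with unknown system the uniform row.
`mk_loglik()` implements Felsenstein pruning with per-branch rescaling;
transition matrices come from an eigendecomposition of the generator
computed once per likelihood evaluation (with a `Matrix::expm` fallback
when the decomposition is ill-conditioned), and every transition matrix is
checked to have unit row sums within 1e-10. Because probability rows enter
directly as tip partial likelihoods, a fully uninformative (uniform) tip
contributes a constant factor 1/K; this shifts the log-likelihood by a
constant that cancels in every rate estimate, model comparison and
posterior.

`fit_mk()` maximizes rates on the log scale within [1e-8, 1e3] per Myr
(golden-section for the one-parameter ER model; multi-start L-BFGS-B, 10
log-spaced starts by default, for SYM and ARD). `fit_mk_models()` fits the
three constraints in nesting order with warm starts — SYM starts from the
ER optimum, ARD from SYM — which guarantees lnL(ER) ≤ lnL(SYM) ≤ lnL(ARD)
and makes the AIC comparison meaningful even when the ARD surface is flat.
The root prior is uniform by default (the equilibrium distribution of the
fitted generator is available as an option).

`stochastic_map()` samples full histories conditional on the tips: node
states by a pruning pass followed by root-to-tip sampling, branch paths by
endpoint-conditioned CTMC simulation — forward rejection first (50
attempts), then an exact uniformization sampler, so no history is ever
discarded. `summarize_node_states()` gives the per-node state frequencies
(the node pie charts of the usual figures), which converge on the pruning
marginal posteriors; the test suite checks this against
`mk_node_marginals()` within Monte-Carlo error, and checks the pruning
likelihood itself against exhaustive enumeration on small trees.

`count_turnovers()` calls a turnover on every branch whose two endpoint
consensus states (majority across maps) differ; ties are unresolved and
reported, mirroring genuinely ambiguous regions such as a poorly resolved
root. Intraspecific and homologous (XY↔ZW on the same chromosome) events,
which branch-level interspecific mapping cannot see, are supplied as extra
events and combined into the same summary. The turnover rate is events
divided by the summed branch length of the dated tree — Myr of independent
evolutionary time — so 13 events on 650 Myr give 0.02 per Myr, one
turnover per 50 Myr.

Two tests ask whether the pattern of turnovers is random:

* `heterogamety_binomial()` — an exact binomial tail (direct enumeration of
  terms) for the number of transitions preserving the heterogametic sex,
  against p0 = 0.5 (direction-indifferent) or p0 = 3/4 (drift-driven
  fixation, where the twice-as-frequent X/Z is the likelier chromosome to
  fix). For 11 of 13 preserving transitions the exact upper tail at
  p0 = 0.5 is 92/8192 ≈ 0.0112; published analyses of the same counts
  sometimes quote smaller values, whose construction is not specified —
  this package reports only the exact enumeration.
* `recruitment_null_test()` — each replicate samples as many genes as there
  are recruitment events, uniformly without replacement from the pooled
  genome, and tallies chromosomes; the per-chromosome upper-tail
  probability uses the (r+1)/(n+1) correction with the raw fraction also
  reported. 1000 replicates by default (100 is in common use and
  available). `recruitment_regression()` is the companion OLS of
  recruitment counts on gene counts.

```{r fixture}
fx <- load_fig1_fixture()
count_turnovers(fx$events)
heterogamety_binomial(11, 13, 0.5)
```

## The synthetic-data generator

`simulate_population()` emulates the structure of a RADseq dataset from a
phenotypically sexed population sample: fully penetrant Y- (or W-) specific
SNPs (heterogametic sex het, homogametic hom), sex-limited tags (present
only in the heterogametic sex), X-hemizygous loci (homogametic sex het,
heterogametic hom — the pseudo-ZW confound), and Hardy–Weinberg autosomal
loci at minor-allele frequencies drawn uniformly on [0.05, 0.5] (the real
spectrum of any particular dataset is unknown; the distribution is a
pluggable function, not a claim about data). Multiple Y haplotypes make
each Y-specific SNP private to one lineage. Noise is applied after the
clean construction: miscalls first (a wrong genotype chosen uniformly from
the two alternatives), then missingness. Locus-class counts use floor
rounding with the remainder autosomal, so truth labels are deterministic.
Fixed default noise levels are deliberately zero: each experiment states
its own error and missingness.

What the generator does *not* emulate — linkage between loci, population
structure, allele-frequency clines, read-level error models, reference
bias — bounds what passing tests show: the pipeline is correct and
calibrated for data matching its own assumptions, not validated against
every pathology of real RADseq data. Population structure in particular is
known to inflate false positives of the frequency screen, which is exactly
why the permutation validation exists.

`simulate_tree()` draws a pure-birth tree rescaled to a chosen root age
(ultrametric by construction); `simulate_states_on_tree()` runs the exact
CTMC along branches and emits the true event list, the ground truth for
the mapping machinery; `simulate_alignment_hits()` builds a 13-chromosome
toy reference with scaffold map, concentrated sex-linked placement, and a
controllable fraction of ambiguous second hits.

## Numerical and design choices

* Genotypes are coded 0/1/2 copies of the alternate allele; the Y-specific
  allele is always the alternate. Missing is NA in memory, "NA" in the TSV
  dialect, "./." in VCF.
* Thresholds stated as "at least"/"below" are read literally: retention
  minima are ≥, the e-value bound is strict <, null exceedance is strict >.
* Empirical percentiles use the linear-interpolation (type 7) definition,
  with the exact rank rule as small-sample fallback.
* Monte-Carlo p-values use the (r+1)/(n+1) add-one correction; raw
  fractions are reported alongside.
* Optimization bounds [1e-8, 1e3] per Myr; non-convergence is flagged and
  the best point returned.
* All randomness flows from user-supplied seeds; permutations use
  master-seed-plus-counter sub-seeds recorded in the output, and pipeline
  stages derive their seeds from the master seed by fixed offsets.

## Problem sizes in the checks

The shipped tests and the acceptance script exercise: screens and truth
recovery at 20M/20F with 2000 loci; permutation calibration over 200
no-signal datasets (10M/10F, 2000 loci, 1000 permutations each); power
over 50 noise-free 19M/19F replicates; ER-rate recovery over 50 replicates
of 200-tip trees with profile intervals; 1000 stochastic maps on a 20-tip
tree against pruning marginals; and 25–50 end-to-end identification
replicates against a 13-chromosome toy reference. These sizes were chosen
as the smallest that make the calibration statements statistically sharp.

## Known limitations

* Screens are population screens; family-based linkage mapping of
  extremely undifferentiated sex chromosomes is out of scope.
* The consensus turnover rule cannot see multiple turnovers on one branch,
  nor homologous turnovers without a heterogamety change; counts are
  minima, as the rate interpretation requires.
* The recruitment null conditions on the per-chromosome gene counts
  supplied; the packaged gene-count table is synthetic and
  size-proportional, suitable for demonstrations and calibration, not for
  inference about any real genome.
* The packaged turnover fixture encodes a published figure's most
  parsimonious event placement; two root-region events have unknown
  chromosome identities and are excluded from per-chromosome tallies.
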