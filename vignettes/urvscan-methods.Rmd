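---
title: "Rare-variant discovery with urvscan: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant discovery with urvscan: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urvscan)
```

# The problem

Large case--control exome studies of rare disease variants face three
coupled difficulties. First, the designs are heavily unbalanced (often
five to ten controls per case, assembled from many sequencing cohorts),
so standard maximum-likelihood logistic regression is anti-conservative
for rare alleles and diverges entirely under separation. Second, most
interesting variants are *ultrarare* -- carried by five or fewer people --
so single-variant tests are powerless and evidence must be aggregated
over functional units (genes, protein domains, genesets) under several
defensible filtering rules at once. Third, multi-cohort assembly leaves
technical structure (batch-specific genotyping artifacts, duplicated and
related samples, per-technology call-rate differences) that mimics
association if not screened out.

`urvscan` implements this whole workflow: a Firth-penalized statistical
engine, sample- and variant-level quality control including a
control--control batch scan and greedy unrelated-set selection, exome-wide
and targeted single-variant scans, ultrarare-variant (URV) burden tests
with Cauchy omnibus combination, oligogenic co-occurrence analyses,
replication-stage meta-analysis with winner's-curse correction, power
simulation, and onset/survival models for carriers. A synthetic-cohort
generator with recorded ground truth makes every stage testable without
access to protected genotype data.

# The statistical engine

## Firth-penalized logistic regression

All case--control tests maximize the Jeffreys-prior penalized
log-likelihood
$$ l^*(\beta) = l(\beta) + \tfrac12 \log \det I(\beta), $$
where $I(\beta) = X^\top W X$ is the Fisher information and
$W = \mathrm{diag}\{\pi_i(1-\pi_i)\}$. The penalty removes the
$O(n^{-1})$ bias of the MLE, guarantees finite estimates under complete
separation, and -- crucially for rare variants in unbalanced designs --
gives tests whose type-I error stays near nominal where Wald and
unpenalized likelihood-ratio tests do not.

The maximizer is found by modified-score Newton iteration
$U^*(\beta) = X^\top\{y - \pi + h\,(\tfrac12 - \pi)\}$ with the
leverages $h_i$ taken from the weighted hat matrix, with step-halving
(up to 25 halvings), a per-iteration step cap of 5 on the log-odds
scale, a tolerance of $10^{-8}$ on the maximum absolute modified score,
and a default iteration cap of 100. The hot loop is compiled
(RcppArmadillo); collapsed designs with replicated rows are supported
through observation weights, which makes the pure-genotype power
simulations essentially free (six weighted rows instead of thousands of
samples).

## Inference: profile intervals and penalized LRT

Reported p-values are penalized likelihood-ratio tests, not Wald tests:
the tested coefficient is constrained to zero and all other coefficients
are re-maximized, with the penalty always evaluated on the full-design
information. Confidence intervals are profile penalized-likelihood
intervals: the two points where the profile drops by
$\chi^2_1(0.95)/2 = 1.92$, located by monotone bisection (default
tolerance $10^{-6}$ on the coefficient; scans expose `ci_tol` because
coverage experiments do not need endpoint precision beyond $10^{-3}$).
Constraining within the full design rather than deleting the column
keeps the LRT and the profile interval mutually consistent: the LRT
statistic at an interval endpoint equals the $\chi^2_1$ critical value
by construction, which the test suite asserts directly.

## Cauchy (ACAT) combination

Burden evidence across the four filtering strategies is combined with
the Cauchy method: $T = \sum_i w_i\tan\{(0.5-p_i)\pi\}/\sum_i w_i$ and
$p = 0.5 - \arctan(T)/\pi$. The transform is exact for a single input,
monotone in each input, and approximately valid under arbitrary
dependence, which is what makes it usable across overlapping variant
sets. Weights default to equal; inputs below $10^{-15}$ use the stable
tail form $1/(p\pi)$.

# Association scans

**Single-variant scan.** Every HIGH or MODERATE impact variant whose
minor allele frequency (computed over non-missing genotypes of the used
samples, hemizygous males contributing one allele) lies strictly inside
the testable window -- default $(5\times10^{-5}, 0.05)$ -- is tested for
association between case status and dosage, adjusting for sex, ten
principal components and the per-sample count of rare synonymous
variants (a per-person proxy for residual sequencing/ancestry
background). Monomorphic and out-of-window variants are reported with an
explicit status. Inflation is summarized by $\lambda_{1000}$, the
median-based genomic inflation factor rescaled to a 1,000-case /
1,000-control study, and multiplicity by Bonferroni over the tested
count. A targeted panel scan relaxes only the per-supercohort call-rate
filter (panel genes with poor call rates in individual subcohorts remain
assessable) and carries its own Bonferroni threshold.

**URV burden scan.** The four filtering strategies cross a carrier rule
(ultrarare: at most five carriers; singleton: exactly one) with an
impact rule (HIGH only; HIGH+MODERATE). A carrier is anyone with at
least one minor allele; heterozygous and homozygous genotypes both
qualify, and the per-sample burden score is the dosage sum over
qualifying unit members (missing genotypes contribute zero -- call-rate
filters already bound missingness). The synonymous covariate is
re-qualified under the same carrier rule so that exposure and covariate
live in the same frequency stratum. A unit-strategy test is retained
only with at least ten carriers; retained p-values are ACAT-combined per
unit. Domains are intervals in coding-sequence (CDS) coordinates; a
genomic-to-CDS mapper handles toy transcripts, attributing positions up
to 12 bp outside a CDS border to that border, and domains spanning more
than 90% of the CDS are dropped as indistinguishable from the gene.
Genesets come from GMT files, intersected with the analysis gene
universe and size-filtered to 5--1,000 genes. A conditional variant of
the unit test adds a second unit's burden score as a covariate, which is
how nested genesets are disentangled.

# Quality control

Sample metrics (call rate, inbreeding $F$ from pooled-frequency expected
heterozygosity over autosomal sites, SNV/INDEL/singleton counts, Ti/Tv)
feed rule-based exclusion with per-sample reason lists; exact per-cohort
count thresholds are study-specific, so the count metrics use
configurable robust z-score bands (off by default). Relatedness is
resolved greedily: all samples with five or more relations are removed
first, then the highest-degree sample repeatedly, breaking ties by
removing controls before cases, then WXS before WGS, then the smallest
id -- preserving cases and the richer genotype data. Variant QC flags
per-supercohort call rate below 0.9, exact-test Hardy--Weinberg failure
in controls at $P < 10^{-4}$ (chromosome X among female controls only),
INDELs longer than 50 bp (strictly), spanning-deletion alleles, and a
batch metric: within controls, each variant's dosage is tested against
each cohort membership indicator (cohorts under 100 controls merged),
adjusting for sex and four PCs, and the minimum p over contrasts flags
batch-driven calling bias (default threshold $10^{-4}$, configurable --
the corresponding full-study filter stringencies are tuned per cohort
and are not reproducible from the publication). The exact conditional
HWE test is used rather than the chi-square because rare-variant cell
counts make the asymptotic test unreliable. Duplicate-pair concordance
is the fraction of agreeing non-missing pairs; exactly 0.9 passes, since
the exclusion rule is stated strictly as "below 0.9". A case--case
variant screen reuses the control--control machinery: a candidate fails
when batch structure among cases explains it better than phenotype does.

# Replication machinery

Meta-analysis uses Stouffer's method with weights
$w_i = \sqrt{n_{eff,i}}$, $n_{eff} = 4/(1/n_{cases} + 1/n_{controls})$.
This effective-sample-size form is the standard weight base for
unbalanced designs; recomputing the published meta p-values of the four
replicated risk variants from their printed discovery/replication
p-values and cohort sizes reproduces all four within the rounding of
3-significant-figure inputs, which both validates the implementation and
pins down the weighting convention. Effect directions come from the
odds ratio side (OR exactly 1 is treated as positive with a warning).

Winner's-curse correction inverts the selection-conditional mean by
parametric bootstrap: for a candidate true effect $\mu$, replicates are
drawn from $N(\mu, se^2)$ truncated to the two-sided selection region
$|\hat\beta| > z_c\,se$ (inverse-CDF sampling, common random numbers
across candidates), and $\mu$ is solved by monotone bisection so the
conditional mean matches the observed estimate; the result is clamped to
$[0, |\hat\beta|]$ on the observed sign. A one-step plug-in bias
subtraction was rejected at design time: when the true effect is null,
the bias evaluated *at the observed estimate* is only a fraction of the
actual selection bias, so a plug-in correction cannot remove most of the
curse, whereas the inversion recovers essentially all of it (the
acceptance suite requires at least half). For estimates far above the
threshold the selection probability approaches one and the adjustment
vanishes, as it should.

Replication power is simulated exactly as an idealized design: control
genotypes binomial at the MAF, case genotypes at the odds-shifted
frequency, a covariate-free Firth LRT per replicate; covariate
adjustment in a real analysis can only reduce realized power.
Co-occurrence power draws joint carrier tables from the multinomial
implied by two carrier frequencies and a co-occurrence odds ratio (the
Plackett 2x2 cell solution) and applies the two-sided Fisher exact test.

# Co-occurrence analyses

The dose--response scan counts distinct qualifying variants carried
(homozygotes count once; at gene level, several variants in one gene
count once) and fits each count category against the zero-variant
reference with the standard covariates -- a progressively increasing OR
is the signature of additive oligogenic risk. The pairwise permutation
test shuffles one carrier vector relative to the other within cases
(only samples non-missing for both variants), with add-one empirical
p-values, so p is never zero and excess and depletion are reported
separately along with a doubled two-sided value; the add-one convention
is the standard unbiased-conservative choice and the publication does
not state its formula. The interaction model is the fixed
16-coefficient design (intercept, two main effects, product, sex,
synonymous count, ten PCs) with a penalized LRT on the product term.

# Phenotype models

Age-at-onset is ordinary least squares of onset on exposure (variant MAC
or gene burden) with sex, PCs and synonymous count; cohort indicators
can be supplied as additional covariates. Survival uses the Cox
proportional-hazards partial likelihood with Efron tie handling (the
publication does not state its tie method; Efron is the standard default
and behaves better under heavy ties), with a partial likelihood-ratio
p-value. The survival-shift summary for carriers is reported as the
difference in Kaplan--Meier median survival, explicitly labelled as such
because the headline "survival difference in months" statistic of such
studies is not otherwise defined.

# The synthetic-cohort generator

The generator is first-class, tested code, not a fixture. It emulates an
unbalanced multi-cohort exome study: samples are assigned to cohorts
(each with a supercohort and sequencing technology) by configured
fractions; PCs are standard normal with cohort-dependent shifts on
PC1/PC2; sex is drawn at a configurable ratio. Variants sit in genes
with Poisson(+1) counts and log-uniform MAFs on a configurable window of
$(0, 0.05]$ -- a heavy-tailed spectrum dominated by very rare alleles --
with impact classes, SNV/INDEL types with geometric INDEL lengths, and
optional chromosome X genes where males are hemizygous (0/1). Genotypes
are two independent Bernoulli alleles (Hardy--Weinberg by construction;
HWE violations enter only via explicit error injection). Disease status
is drawn prospectively from a logistic liability whose intercept is the
logit of the requested case fraction and whose linear predictor adds
log(OR) times dosage over implanted effect variants plus small sex and
PC1 effects; realized case counts are therefore binomial around the
requested sizes, which downstream code never assumes to be exact. The
per-sample synonymous count is the realized synonymous dosage sum plus a
cohort-specific Poisson background (default means 35/40/45), so the
covariate has both genuine and batch structure. Case onset is
$N(65, 10^2)$ years plus per-allele shifts; survival is exponential with
baseline median 30 months, per-allele log-hazard shifts and uniform
censoring over 12--120 months -- magnitudes chosen to match a rapidly
progressive neurodegenerative disease. Duplicates copy genotype rows
(optionally with a discordance rate); second-degree pairs are recorded
in the relation table only, since kinship estimation is out of scope and
relations are pipeline inputs. Batch artifacts (cohort-specific
missingness and spurious heterozygous calls) are injected on demand and
recorded in the truth table, providing positive controls for the batch
scan and call-rate filters.

What the generator does *not* emulate: linkage disequilibrium (variants
are independent), sequence context, read-level error processes, and
non-European population structure beyond cohort PC shifts. Passing
calibration on these cohorts therefore demonstrates correctness of the
statistical machinery under the stated model, not robustness to LD
confounding or fine-scale stratification.

# Simulation sizes and numerical choices

The test suite and acceptance script size their experiments so the whole
battery runs on a single CPU in well under half an hour, while keeping
every asserted property at the scale where it is statistically sharp:

* Null calibration pools 10 cohorts of 1,000 cases / 5,000 controls with
  roughly 600 testable variants each (about 5,000--6,000 null p-values).
  For these runs the simulated MAF window starts at $2\times10^{-3}$ so
  that the rarest testable variant has an expected minor-allele count
  near 20 -- mirroring the full-scale study, where the
  $5\times10^{-5}$ window floor corresponds to a minor-allele count of
  about 8 in 83,000 samples. Testing far rarer variants at desk scale
  would measure the discreteness of tiny-MAC tests, not scan
  calibration. Burden calibration uses 150-gene cohorts with dense
  panels ($\sim$25 variants per gene) over the ultrarare spectrum, so
  that a typical gene clears the ten-carrier retention rule with a few
  dozen qualifying carriers, as genes do at full study scale.
* Interval coverage implants a single OR = 5 variant at MAF 0.005 in
  cohorts of 2,000 / 20,000 and checks 95% profile-interval coverage of
  log 5 over 100 seeds (at least 93 must cover).
* Winner's-curse recovery draws null effects conditioned on passing the
  exome-wide threshold and requires at least a 50% reduction in mean
  absolute bias after correction.

Other numerical choices: genotype dosage matrices are dense integer
matrices (the tool targets cohort slices and simulation studies, not
biobank-scale storage); probabilities inside the engine are clamped to
$[e^{-30}/(1+e^{-30}),\ 1/(1+e^{-30})]$ on the linear predictor to keep
the log-likelihood finite; the ACAT transform clips inputs at
$1 - 10^{-15}$; permutation p-values carry the $+1$ correction;
monomorphic predictors are reported with a status upstream rather than
fitted.

# Known limitations

* The engine targets designs with tens of covariates, not
  mixed-model-scale random effects; there is no SKAT-type
  variance-component test, by design.
* The batch-scan flag threshold is a single configurable value; the
  original full-study procedure retunes several standard QC filters
  around the batch metric in a way that is not reproducible from the
  publication.
* The read-support screen for candidate variants requires raw
  alignments and is supported only as an externally computed table.
* Winner's-curse inversion assumes a normal sampling distribution of
  the estimate; for extremely rare variants with strongly asymmetric
  profiles this is an approximation.
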