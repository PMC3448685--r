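---
title: "Scanning for pri-miRNA SNP effects and miSNP x 3'UTR-SNP interactions on gene expression"
author: "misnpscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning for pri-miRNA SNP effects and miSNP x 3'UTR-SNP interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific problem

MicroRNAs repress their target mRNAs by binding complementary sites that
sit mostly in 3'UTRs. Two kinds of common variants can perturb this
regulation: SNPs inside the primary miRNA transcript (*miSNPs*), which can
change miRNA abundance or processing, and SNPs inside a gene's 3'UTR
(*3utrSNPs*), which can create or destroy binding sites. A miSNP can act
*marginally* on expression — in *cis* on a nearby gene or in *trans* on
remote targets — or *epistatically*: the effect of a 3'UTR variant on its
own gene's expression may depend on which miRNA allele is present. The
package implements a genome-wide version of both analyses for
cohort-scale genotype + expression data (array-style normalized log
intensities), plus the supporting genetics (QC, two-locus haplotype EM,
LD, proxy selection) and a synthetic-data generator with known truth so
every stage is testable without access to individual-level cohort data.

## Models

**Marginal scan.** For each (miSNP, probe) pair, ordinary least squares of
expression $y$ on dosage $g \in \{0,1,2\}$ (count of the minor allele,
additive coding) with age and sex as covariates:
$y = \mu + \beta g + \gamma' c + \varepsilon$. The reported $R^2$ is the
increment attributable to the SNP term (full-model $R^2$ minus the
covariate-only $R^2$ on the same samples), since the marginal table's
per-SNP $R^2$ is not otherwise well defined. An association is *cis* when
the SNP lies on the probe's chromosome within 1 Mb of the nearest edge of
its annotated span (closed boundary: exactly 1 Mb is cis), *trans*
otherwise. Follow-up models append adjusters to the covariates: the best
cis eSNP of the probe (the cis SNP with minimal $p$ among those with
$p < 5.5\times10^{-5}$, a flag), to ask whether a miSNP signal is mere LD
with a local regulatory variant; or a mediator gene's expression, to ask
whether a trans cluster acts through a cis-regulated gene.

**Interaction scan.** For each (3utrSNP proxy, probe) unit and each miSNP:
$y = \mu + \beta_u g_u + \beta_m g_m + \beta_{int}\, g_u g_m + \gamma' c +
\varepsilon$, with the two-sided $t$-test on the product term. Tests with
a degenerate design (constant dosage or product, rank deficiency such as
perfect LD between the two SNPs) are skipped with a recorded reason and
excluded from the test count $N$.

**Variance-prioritized weighted Bonferroni.** A genuine interaction makes
the phenotypic variance differ across the 3utrSNP's genotype classes, so
units with heterogeneous variance are promising. Each unit gets a Levene
test: expression is residualized on the covariates (matching the
regression's covariate set; the package also offers median centering,
i.e. Brown–Forsythe), deviations $z_{ij} = |r_{ij} - \bar r_j|$ are
compared by one-way ANOVA with $(k-1, n-k)$ df, giving $q_u$. Weights are
$w_u \propto -\log q_u$, standardized to mean 1 over the $N$ executed
tests (the log base cancels), and each interaction $p$-value is divided
by its unit's weight: $P^* = P / w_u$, declared genome-wide significant
when $P^* < \alpha/N$. With all $q_u$ equal the procedure reduces exactly
to standard Bonferroni; if every $q_u = 1$ the weights are 0/0 and the
implementation falls back to uniform weights. The functional form was
validated against a published 51-row interaction-hit table: calibrating
the single normalization constant on one row reproduces every other
internally consistent row's printed weighted $p$ within 2% (one printed
row is excluded: its value is off by exactly a factor of 10 *and* breaks
the table's own ascending sort order — a printed-exponent typo).

**Replication.** Significant discovery interactions are refit in an
independent cohort (same model, disease status appended to the
covariates) with plain Bonferroni over the $k$ replicable hits and a
sign-consistency requirement (configurable).

**Haplotype effects.** A detected pair is illustrated on the haplotype
scale. Two-locus haplotype frequencies come from an EM on unphased
dosages: only double heterozygotes are ambiguous, the EM starts at
linkage equilibrium (the two-locus likelihood is well behaved; a grid
oracle over the one free parameter guards the tests against local
optima) and stops when the largest frequency change is below $10^{-10}$
or after 1000 iterations. From the frequencies we report
$D = f_{AB} - p_A p_B$, $D' = |D|/D_{max}$ and
$r^2 = D^2/(p_A p_a p_B p_b)$; proxy selection picks the candidate with
maximal EM $r^2 \ge 0.90$ (ties by genomic distance, then id).
Per-sample expected haplotype dosages (posterior phase split for double
heterozygotes, integer counts otherwise; always summing to 2) enter an
OLS with the most frequent haplotype as reference, giving per-copy
effects with $t$-based CIs and a global F-test. The homogeneity test is
a Wald contrast $[\beta_{AB} - \beta_{aB}] - [\beta_{Ab} - \beta_{ab}]$
on the coefficient covariance — the haplotype-scale analogue of the
product-term test (their $p$-values rank simulated scenarios nearly
identically; expected-dosage regression replaces stochastic-EM multiple
imputation deliberately: it is deterministic and testable, at the cost
of slightly understating uncertainty when double heterozygotes are
common).

## Quality control and selection

SNPs pass QC when MAF > 0.01, call rate > 0.98 and the exact
Hardy–Weinberg test (full enumeration of heterozygote counts conditional
on allele counts) gives $p > 10^{-4}$, applied in that order with a
per-filter removal report; a replication-style set (call rate > 0.95,
HWE $p > 10^{-5}$) is available through the same thresholds object.
Probes enter only when annotated "perfect" quality and free of SNPs in
their sequence. A SNP belongs to every containing interval (strand
ignored; internal coordinates are 0-based half-open, everything
user-facing is 1-based inclusive, and the two conversions are exact
inverses). One genotyped proxy may tag several 3utrSNPs, so the per-gene
histogram counts distinct 3utrSNPs while the scan runs on distinct
proxies; both totals are reported.

## The synthetic generator

`scenario_config()` + `simulate_scenario()` produce genotypes (HWE at
given MAF; LD pairs drawn as two haplotypes per sample from explicit
four-haplotype frequencies), covariates (age uniform 35–74 years, sex
Bernoulli(0.5), optional disease status Bernoulli(0.48), matching a
case-enriched replication cohort), and expression built from an effect
plan: additive terms, interaction product terms, mediator chains
(generated in topological order; cycles are errors), covariate effects,
and Gaussian noise whose sd can depend on a SNP's genotype — the
variance-heterogeneity plan that gives the Levene prioritization genuine
signal. Defaults: intercept 7 and residual sd 0.3 on the log scale,
typical of normalized array intensities; per-genotype sds 0.3/0.45/0.6
(ratio 1:1.5:2) where heterogeneity is planted. One master seed expands
into per-component substreams through a fixed documented scheme, so
bundles are bit-reproducible. `make_miniature_study()` assembles a
miniature study — 30 miSNPs in 28 pri-miRNAs, ~110 3utrSNPs over 60
genes with a realistic per-gene histogram, 195 probes including
quality-flagged and SNP-containing ones, six ungenotyped targets tagged
by LD proxies (two sharing one proxy), two planted interactions, one
mediation chain and two heteroskedastic null units — whose truth ledger
the pipeline must recover exactly.

What the generator does *not* emulate: genome-scale LD maps, probe-level
array noise, population structure, non-Gaussian expression tails.
Passing tests therefore show the statistics are implemented correctly
and behave as designed under the stated model, not that real-cohort
results would be free of those additional complications.

## What the FWER simulations show — and a genuine caveat

Under a homoskedastic global null the weighted procedure controls the
family-wise error at $\alpha$ (weights have mean 1, so per-test levels
sum to $\alpha$); the suite verifies this. But when residual variance
genuinely depends on the 3utrSNP genotype *without* any interaction, the
OLS $t$-test on the product term is anticonservative (high-variance
samples carry high product-term leverage, so the homoskedastic SE is an
underestimate — about five-fold excess at the $10^{-3}$ level for sd
ratio 1:1.5:2 at $n = 300$), and the Levene weights concentrate the
$\alpha$ budget on precisely those miscalibrated units. The measured
family-wise error of the weighted scan under such a null is therefore
well above $\alpha$ (about 0.18 under the simulation conditions above),
and the corresponding acceptance check is left failing by design rather
than softened. The same mechanism produces non-replicating sibling hits
at a true unit: the interaction itself induces variance heterogeneity,
so the unit's other miSNP tests are both upweighted and miscalibrated.
Practical consequence: treat weighted hits at extreme-Levene units as
prioritized candidates requiring replication, not as calibrated
discoveries — replication with plain Bonferroni, as implemented, is the
appropriate gate.

## Numerical choices

All regressions share one QR-based least-squares core, cross-checked in
the tests against `stats::lm` and an explicit normal-equations solve at
$10^{-8}$ relative tolerance; the Levene ANOVA is cross-checked against
`car::leveneTest`. Ties: minor allele at frequency 0.5 is the
alphabetically first allele; proxy ties break by distance then id; best
cis eSNP ties by larger $|\beta|$ then id; reference haplotype ties
lexicographically. Scan output is ordered by weighted $p$, then (probe,
3utrSNP, miSNP), so reruns are byte-identical. Complete cases are used
per test; a dosage constant after missing-data drop is an error (marginal
scan) or a recorded skip (interaction scan).

## Problem sizes

The shipped workflow and checks run at deliberately small scale: the
miniature study uses 800 discovery / 700 replication samples, ~3,800
interaction tests and ~5,100 marginal tests; the FWER simulation uses
500 replicate scans of 200 tests at $n = 300$; coverage checks use
1,000 replicates. These sizes make every result reproducible on a
laptop in minutes while leaving all statistical structure intact.

## Limitations

Expected-dosage haplotype regression understates uncertainty for high
double-heterozygote fractions; proxies are computed from supplied
genotypes rather than external reference panels; only two-locus
haplotypes are supported; the weighted procedure's FWER guarantee is
conditional on test calibration, as discussed above; and microarray
preprocessing (normalization, probe re-annotation) is out of scope — the
pipeline consumes already-normalized expression and annotation flags.
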