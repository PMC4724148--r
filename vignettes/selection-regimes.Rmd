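---
title: "Inferring selection regimes on protamine-like genes with codonsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring selection regimes on protamine-like genes with codonsel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Protamines are small arginine-rich nuclear proteins that repackage sperm
DNA during spermiogenesis.  Protamine 2 is translated as a precursor whose
N-terminal *cleaved* domain is proteolytically removed while the C-terminal
*mature* domain stays bound to DNA.  The two domains are structurally and
functionally different, so they may evolve under different selective
constraints, and the strength of constraint may in turn respond to
post-copulatory sexual selection (sperm competition) and correlate with
sperm head shape.

`codonsel` implements the full analysis chain this question requires:

1. codon substitution models that measure selective pressure as
   $\omega = d_N/d_S$;
2. likelihood ratio tests (LRTs) between nested branch models, plus a
   decision table that turns them into regime labels (*conserved*,
   *positive*, *relaxed*);
3. branch-site model A with Bayes empirical Bayes (BEB) identification of
   positively selected sites;
4. a per-species *root-to-tip* $\omega$ statistic from a free-ratio fit;
5. sequence statistics (domain lengths, arginine content, Welch tests);
6. phylogenetic generalized least squares (PGLS) with maximum-likelihood
   Pagel's $\lambda$, regressing evolutionary rate against body and testes
   mass (the sperm-competition proxies) and sperm head dimensions against
   evolutionary rate.

## The codon model

The substitution process acts on the 61 sense codons of the standard
genetic code (the code table is injectable).  Instantaneous rates between
codons $i \ne j$ are

$$ q_{ij} = \begin{cases}
  0 & \text{more than one nucleotide changes} \\
  \pi_j & \text{synonymous transversion} \\
  \kappa \pi_j & \text{synonymous transition} \\
  \omega \pi_j & \text{nonsynonymous transversion} \\
  \omega \kappa \pi_j & \text{nonsynonymous transition,}
\end{cases} $$

normalized so one unit of branch length is one expected substitution per
codon.  Equilibrium frequencies $\pi$ come from one of four schemes
(`equal`, `F1x4`, `F3x4`, `F61`); `F3x4` — products of position-specific
nucleotide frequencies with stop-codon mass renormalized over the sense
codons — is the default, the conventional choice when the data themselves
do not dictate a scheme; `compare_freq_schemes()` fits all four under M0
and ranks them by AIC when the choice should be data-driven.  Frequencies are floored at $10^{-6}$ and
renormalized so the likelihood stays finite for codons a scheme would
otherwise zero out (relevant to `F61` with unobserved codons).

Transition matrices $P(t) = e^{Qt}$ are computed from the symmetric
eigendecomposition of the $\pi$-symmetrized generator
$D^{1/2} Q D^{-1/2}$ (with $D = \mathrm{diag}(\pi)$), which exists because
the process is reversible and $\pi$ is strictly positive after flooring.
One decomposition is shared by all branches with the same $(\kappa,
\omega, \pi)$, which is what makes the quasi-Newton fits cheap; the
alternative scaling-and-squaring exponential would repeat the full matrix
work on every branch.

Per-branch $d_N$ and $d_S$ use the mutational-opportunity decomposition:
with $\rho_N^{(1)}$ the nonsynonymous fraction of equilibrium flux at
$\omega = 1$, a codon exposes $N = 3\rho_N^{(1)}$ nonsynonymous and
$S = 3 - N$ synonymous sites, and a branch of length $t$ under its own
$\omega$ decomposes as $d_N = t\,\rho_N/N$, $d_S = t\,\rho_S/S$, so that
$d_N N + d_S S = t$ exactly.

## Likelihood and the model ladder

Likelihoods are computed by Felsenstein pruning over compressed site
patterns in a compiled kernel; gap and ambiguous codons are missing data
(summed over all sense codons).  Rooted trees are accepted; because the
model is reversible only the sum of the two root-child branch lengths is
identifiable, so during optimization the second root branch is held at
zero and the first carries the pair (the unrooted equivalent), while the
rooted shape is kept for root-to-tip paths.

The ladder reproduces the standard branch/branch-site analysis:

* **M0** (one ratio): single $\omega$, $\kappa$ and all branch lengths
  estimated jointly.  The M0 branch lengths are reused, fixed, by every
  model below — the convention of the analysis this package reproduces.
* **MC** (two ratio): separate background/foreground $\omega$ on marked
  branches; **MCfixed** constrains the foreground $\omega$ to 1.
* **FREE** (free ratio): one $\omega$ per branch, branch lengths
  re-optimized jointly; branches whose $\hat\omega$ runs to the ceiling
  (no synonymous change) are flagged rather than trusted.
* **BS / BSfixed** (branch-site model A): four site classes —
  0 ($\omega_0 < 1$ everywhere), 1 (neutral), 2a ($\omega_0$ background,
  $\omega_2$ foreground) and 2b (neutral background, $\omega_2$
  foreground) — with the class-proportion identities
  $p_{2a} = (1 - p_0 - p_1)\,p_0/(p_0+p_1)$ and its $p_{2b}$ twin.  BS
  frees $\omega_2 \ge 1$; BSfixed pins $\omega_2 = 1$.  The published
  description of the null is worded unusually; the standard model-A null
  ($\omega_2 = 1$) is implemented here.

Optimization is bounded L-BFGS-B on transformed parameters ($\log\kappa$,
$\log\omega$, $\log t$, logit proportions) with $\omega \in [10^{-4},
999]$ and a deterministic multi-start schedule for the branch-site models
(default 5 starts; these likelihoods have well-known local optima).  When
an alternative model is fitted right after its null, the null's solution
seeds an extra start, which enforces the nesting inequality up to
optimizer tolerance.  Everything is deterministic: the same data and
settings give bit-identical likelihoods.

Foreground marks follow the `#1` Newick tag dialect: a tag on an internal
node marks the whole clade **up to and including** its stem branch; a tag
on a tip marks that terminal branch.  `mark_clade()` does the same
programmatically and refuses non-monophyletic tip sets.

## Tests, regimes and sites

LRTs compare nested fits with $2\Delta = 2(\ell_1 - \ell_0)$ against
$\chi^2_{df}$, with $df = 1$ for M0-vs-MC, MCfixed-vs-MC and BSfixed-vs-BS
(each frees exactly one parameter).  The 50:50 point-mass/$\chi^2_1$
boundary mixture is available as an option for the branch-site test, but
the plain $\chi^2_1$ is the default because it is what the reproduced
analysis reports.

The regime decision table (with sig meaning $p \le \alpha$):

| M0 vs MC | MCfixed vs MC | effective $\omega$ | label |
|---|---|---|---|
| sig | sig | MC foreground $> 1$ | positive |
| sig | sig | MC foreground $< 1$ | conserved |
| sig | ns  | — | relaxed |
| ns  | sig | M0 $> 1$ | positive |
| ns  | sig | M0 $< 1$ | conserved |
| ns  | ns  | — | relaxed |

When M0-vs-MC is not significant the M0 $\omega$ is the reported
(effective) rate, otherwise the MC foreground $\omega$ — the reporting
rule of the original tables.  Note one deliberate asymmetry: a
double-non-significant outcome is labelled *relaxed*, which reproduces
the realized calls of the source analysis even though its verbal rule
asks for a significant M0-vs-MC test before claiming relaxation; the
published tables themselves contain such a row, so the table above
follows the tables.  At the site level, a significant BSfixed-vs-BS test
yields *positive*, otherwise *no_signal*.

Positively selected sites are reported from the BS fit as the posterior
probability of the positive classes (2a + 2b).  The default is a BEB
computation: $\kappa$ and branch lengths stay at their MLEs while
$(p_0, p_1)$, $\omega_0$ and $\omega_2$ are integrated over a uniform
grid — 45 simplex points for the proportions, 10 points each for
$\omega_0 \in (0,1)$ and $\omega_2 \in (1, 11)$ — weighting each grid
point by its posterior given the whole alignment.  Naive empirical Bayes
(posterior at the MLE) is available as `method = "NEB"`.  Sites meeting
the threshold (default 0.95, the "$p < 0.05$" convention) are printed as
1-based alignment coordinates plus the reference taxon's residue, e.g.
`64R`; alignment coordinates and the reference projection are both kept
because reported positions are otherwise ambiguous.

The root-to-tip statistic for a species sums free-ratio $d_N$ and $d_S$
over the path from the clade root **including its stem branch** (clades
are marked up to and including their ancestor; `include_stem = FALSE`
switches this off) down to the terminal branch, and takes the ratio of
sums.  A zero synonymous path sum leaves the statistic undefined; such
species are excluded pairwise from regressions, never imputed.

## PGLS with Pagel's lambda

Trait covariance is the Brownian matrix $C$ of shared path lengths, with
Pagel's $\lambda$ multiplying the off-diagonal.  For a fixed $\lambda$
the GLS estimate is $\hat\beta = (X^\top C_\lambda^{-1} X)^{-1} X^\top
C_\lambda^{-1} y$; $\lambda$ is profiled over $[0,1]$ by golden-section
search (with both endpoints checked) on the REML criterion by default
(ML is a switch; the original report does not say which it used).
Coefficient $t$-tests use $n - p$ degrees of freedom, $R^2$ compares
whitened residual sums of squares against an intercept-only GLS fit at
the same $\lambda$, and $\lambda$ is tested against the fixed values 0
and 1 by LRT with the 50:50 boundary mixture by default (plain
$\chi^2_1$ optional).  At $\lambda = 0$ the fit reproduces OLS exactly;
the test suite asserts this to $10^{-10}$ and cross-checks the ML
$\hat\lambda$ against `nlme::gls` with `ape::corPagel`.

The regression suite runs, per clade and domain: $\omega_{rtt}$ against
log body + log testes mass (testes mass conditioned on body mass is the
sperm-competition proxy); mature-domain arginine percentage against the
same; and relative head length, relative head width and elongation
(HL/HW) each against $\omega_{rtt}$.  Mass logarithms are base 10 (the
comparative-methods convention; configurable).  Missing data are deleted
listwise per model, which is why `n` varies across rows; models left
with $n < p + 2$ are reported as skipped rows with a reason rather than
aborting the suite.  Residual testes mass (OLS of log testes on log body
mass) is computed for plotting only and never enters a regression.
No multiple-testing correction is applied by default, matching the
reproduced analysis; a Benjamini–Hochberg adjustment can be applied to
the returned table with `p.adjust` if desired.

## The synthetic study

`make_toy_study()` builds the bundled end-to-end dataset: two clades of 8
species (coalescent shapes scaled to 0.35 expected substitutions per
codon of depth, 0.15 stems), a 300-codon precursor split 150/150 into
cleaved and mature domains, and a phenotype table.  Generating
conditions, chosen once as a realistic miniature of a two-clade
protamine study:

* cleaved domain: per-branch $\omega$ lognormal around 0.3 with sdlog
  1.2 in all branches — purifying selection with the strong among-branch
  rate heterogeneity protamines show.  The heterogeneity is load-bearing:
  within a clade most of the root-to-tip path is shared, so only
  branch-to-branch rate variation gives the per-species $\omega_{rtt}$
  the within-clade variance a per-clade regression needs;
* mature domain: lognormal around 4 in clade A (positive selection),
  around 1 in clade B (relaxation), around 0.5 on the stems; the
  contrast is deliberately stronger than a large real study would show
  because a 16-taxon miniature carries proportionally less information
  per test;
* $\kappa = 2.5$, codon frequencies from a fixed Dirichlet draw;
* clade-biased terminal truncations (gap tails) make the cleaved domain
  longer in clade A and the mature domain longer in clade B, giving the
  Welch length comparisons real signal and exercising missing-data
  handling;
* relative head width $= 0.04 + 0.3\,\omega_{rtt}^{\text{cleaved,true}} +
  \varepsilon$ with $\lambda = 0.9$, $\sigma = 0.006$ — the planted
  rate–morphology association (elongation inherits it with opposite
  sign); relative head length, body mass and testes mass are pure
  Brownian controls with no planted association.  Because the regression
  uses the *estimated* $\omega_{rtt}$, attenuation by estimation noise
  is expected, and whether both clades or only one reach significance
  depends on each clade's realized rate spread — just as the source
  analyses detect such associations in one clade and not the other;
* one species per clade has a missing head width, mirroring the patchy
  phenotype coverage such compilations always have.

What the simulator deliberately does **not** emulate: indels beyond the
terminal truncations, alignment error, among-site rate variation within a
class, non-stationary composition, and correlated evolution between the
domains.  Passing tests therefore demonstrate correctness of the
inference machinery under the model's own assumptions, not robustness of
the biological conclusions to alignment or model violations.

Simulation sizes elsewhere in the test suite (8 taxa × 500 codons for
recovery, 6 taxa × 200 codons × 200 replicates for test calibration,
150-codon branch-site replicates) were picked so the whole suite runs in
well under half an hour on a single core while leaving the Monte Carlo
noise small relative to the tolerances being asserted.

## Numerical choices and limitations

* Optimizer tolerance is `factr = 1e7` (about $2\times10^{-9}$ in lnL);
  nesting assertions allow $10^{-6}$ slack.
* $\omega$ is bounded in $[10^{-4}, 999]$; a free-ratio branch at the
  ceiling is flagged `omega_undefined` (no synonymous change to anchor
  the denominator) and its $d_N$, $d_S$ are still reported.
* Zero-length branches are admitted ($P(0) = I$); an invariant alignment
  is refused with an explicit error since branch lengths would be
  unidentifiable.
* The LRT of M0 against MC inherits a mild conservativeness from holding
  branch lengths at their M0 estimates in MC — the cost of reproducing
  the original procedure exactly; the calibration test bounds the
  realized size against the nominal 5% band.
* Domain boundaries are taken in alignment coordinates and must agree
  across species after alignment; per-species unaligned boundaries can be
  mapped through each row's gap pattern before the pipeline is invoked.
* The branch-site BEB grid is coarser than a full adaptive quadrature;
  with 61-state likelihoods this keeps site detection to seconds while
  the posterior ordering of sites — the quantity the tests assert — is
  insensitive to the grid resolution.
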