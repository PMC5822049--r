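---
title: "Quantifying DNA shape readout: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DNA shape readout: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapeproj)
```

# The scientific problem

Transcription factors (TFs) read DNA both through direct contacts with
bases ("base readout") and through sensitivity to the local three-
dimensional conformation of the double helix ("shape readout"): minor
groove width (MGW, Ångström), propeller twist (ProT), roll and helix
twist (Roll/HelT, degrees). Because the shape of DNA is itself a function
of the base sequence, shape readout leaves a sequence signature — the
challenge is to decompose a measured sequence-to-affinity relationship
into the two mechanisms, with honest statistical uncertainty.

`shapeproj` implements a complete desk-scale pipeline for this
decomposition:

1. **Sequence-to-shape regression** (`fit_seq2shape`, `loo_cv_r2`,
   `count_dof`): parsimonious linear models predicting a k-mer shape
   table from mononucleotide and adjacent-dinucleotide indicators.
2. **Free-energy binding models** (`agn_model`, `partition_sum`): a
   mechanism-agnostic mono+dinucleotide model of binding free energy,
   with partition sums and gradients computed by a transfer-matrix
   recursion in log space.
3. **Shape projection** (`project`): the core post hoc analysis — given a
   mechanism-agnostic model, find the base-readout scoring matrix plus
   position-specific shape-sensitivity profiles whose implied model best
   approximates it under a penalized, normalized objective.
4. **Complexity-matched significance** (`random_matched_table`,
   `null_bands`, `position_fdr`): empirical per-position p-values from
   random shape tables whose positional dependence structure matches the
   real one, with Benjamini–Hochberg correction across binding-site
   positions.
5. **A desk-scale SELEX fitter** (`simulate_selex`, `fit_bias`,
   `fit_selection`, `kmer_performance`): biophysical multinomial
   inference of binding models directly from two-round SELEX read sets.
6. **Energy-stratified shape profiling** (`sample_by_bin`,
   `mean_shape_by_bin`, `align_high_affinity_probes`): what shape
   preferences a scoring matrix already encodes.

# Sequence-to-shape models

A base-centered shape table assigns one value $\phi(s)$ to every pentamer
$s$ (window offsets $-2..+2$ around the central base pair); step
parameters live on tetramers centered on the base-pair step (offsets
$-1..+2$; `center_step_table` recenters the raw per-pentamer pair of step
values by marginalizing over the outer bases and averaging). All tables
are reverse-complement (RC) symmetrized, reflecting the equivalence of
the two strands.

The regression model is
$$\hat\phi(s) = \gamma^{(0)} + \sum_{\delta} \gamma^{(1)}_{\delta, s_\delta}
 + \sum_{\delta} \gamma^{(2)}_{\delta, s_{\delta:\delta+1}},$$
fit by minimum-norm least squares (the indicator design is deliberately
redundant; the pseudoinverse uses a relative singular-value cutoff of
$10^{-9}$, far below the clean gap between exact-zero redundancy
directions and signal). The number of independent parameters of the
RC-symmetric designs is obtained by counting nonzero eigenvalues of
$X^\top P_{RC} X$, where $P_{RC}$ projects onto RC-symmetric value
vectors; closed forms are $\lceil (3k+1)/2 \rceil$ (mono) and
$4\lfloor 3k/2 \rfloor - 2$ (dinucleotide):

```{r dof}
c(step_mono = count_dof(4, "mono"), base_mono = count_dof(5, "mono"),
  base_di = count_dof(5, "mono+di"), step_di = count_dof(4, "mono+di"))
```

Cross-validation leaves out each RC pair of k-mers together
(`loo_cv_r2`), computed with the exact block leave-out identity on the
projection hat matrix — removing one class never changes the design's
column space, so the shortcut is exact (verified against explicit refits
in the test suite). Reported $R^2$ values are cross-validated by default;
in-sample values are available from `fit_seq2shape`. Coefficient *logos*
use a display gauge (`logo_coefficients`): per-position mono blocks
centered, dinucleotide blocks doubly centered — predictions are
gauge-invariant.

# Binding models and the partition sum

The mechanism-agnostic model scores a k-bp footprint as
$$-\Delta\Delta G(s)/RT = \beta^{(0)} + \sum_i \beta^{(1)}_{i,s_i} +
  \sum_i \beta^{(2)}_{i,s_{i:i+1}},$$
with larger scores meaning stronger binding. The partition sum
$\sigma(\beta) = \sum_s e^{score(s)}$ over all $4^k$ footprints and its
gradient (single-position and adjacent-pair Boltzmann marginals) are
computed by a forward–backward transfer recursion in $O(k)$, entirely in
log space — footprints of 20 bp with coefficients of several $RT$ would
overflow a direct evaluation. Enumeration oracles at $k \le 6$ pin the
implementation to relative error below $10^{-10}$.

# Shape projection

A shape-readout model replaces part of the dinucleotide structure with
physically interpretable terms:
$$-\Delta\Delta G(s)/RT = \beta^{(0)} + \sum_i \beta^{(1)}_{i,s_i} +
  \sum_i \beta^{(\phi)}_i\, \hat\phi(s_{i-2:i+2}),$$
where $\beta^{(\phi)}_i$ is the shape sensitivity at position $i$ in
$RT$ per unit shape. Substituting the mono+di sequence-to-shape model
for $\hat\phi$ turns this into an exactly equivalent mechanism-agnostic
model (`to_sequence_representation`); sensitivities at the two outermost
base positions (one outermost step) are constrained to zero because
readout there would require sequence preferences outside the footprint.

`project` inverts this map. Stage 1 minimizes a loss between the target
model and the candidate's sequence-only representation with no
penalties; the default loss is the Kullback–Leibler divergence between
the Boltzmann sequence distributions the two models imply (convex in the
candidate parameters; intercepts cancel and are dropped as a gauge). An
alternative summed-squared-affinity loss is provided; it is evaluated
from three partition sums. Stage 2 minimizes the combined objective
$$\frac{V}{V_{ref}}
 + \lambda_{shape}\frac{\|\beta^{(\phi)}\|_p}{\|\beta^{(\phi),ref}\|_p}
 + \lambda_{mono}\frac{\|\beta^{(1)}\|_p}{\|\beta^{(1),ref}\|_p/4},$$
with $\|x\|_p = \sum_i |x_i|^p$, reference norms from stage 1, and
$\lambda_{shape} = \lambda_{mono} = 1$ by default. The division of the
mono reference norm by 4 follows the printed form of the objective; a
flag (`mono_ref_quarter = FALSE`) disables it. For $p = 1$ the
non-smooth penalty is reformulated exactly by positive/negative variable
splitting with box constraints. Optimization uses L-BFGS-B with analytic
gradients; both stages start deterministically (zeros, then the stage-1
solution). When the unpenalized reference loss or a reference norm is
numerically zero (an exactly representable model), the corresponding
normalization is floored ($10^{-10}$ of the trivial-model loss;
$10^{-8}$ per parameter for norms) and, for norms, the penalty term is
dropped with a warning.

Why penalize at all? The mononucleotide part of shape readout is exactly
collinear with base readout, so the unpenalized problem is
ill-conditioned: profiles from perturbed starts differ along near-null
directions even though the implied scores agree (a property the test
suite asserts). The normalized penalties make base and shape readout
compete for the same structure and select the parsimonious attribution.

The KL and affinity losses are positively but not perfectly associated:
near a base model both reduce to quadratic forms, one weighted by
squared affinity and one by Boltzmann probability. Measured over random
small perturbations their correlation is roughly 0.7 — enough for the
two losses to agree on strong signals (the robustness the defaults rely
on) but not interchangeable in fine ranking.

# Complexity-matched significance

A sensitivity coefficient is only meaningful against the distribution
obtained when the real shape table is replaced by a random sequence
feature *of the same complexity*. Naive permutation of the table
destroys its mono+di structure: the permuted table's fitted
sequence-to-shape coefficients are near zero, so reproducing any
dinucleotide structure in the binding model requires mechanically
inflated sensitivity coefficients, and the permutation null is
miscalibrated on the coefficient scale. Instead, `random_matched_table`
draws uniform random mono/di coefficient blocks, RC-symmetrizes, and
scales per-position blocks (tied across RC-mirrored positions,
nonnegative) to match the reference table's expected conditional
variance matrix
$$C_{ij} = E_{c,d}\,\mathrm{Var}_s[\phi(s) \mid s_i = c, s_j = d],$$
minimizing $D = \sum_{i\le j}(C_{ij}(\phi) - C_{ij}(\hat\phi))^2$.
Because the candidate table is linear in the scaled blocks, each
$C_{ij}$ is an exact quadratic form in the scale vector, so the matching
problem is smooth, fast and has an analytic gradient. Population
variances and exact enumeration are used throughout.

`null_bands` reruns the projection with `N` matched tables under the
identical configuration and records percentile bands (2.5/25/75/97.5).
`position_fdr` computes two-sided add-one empirical p-values per interior
position, $p_i = (1 + \#\{|\beta^{null}_{n,i}| \ge |\beta^{obs}_i|\})/(N+1)$,
and applies Benjamini–Hochberg step-up across the interior positions
within each feature (features are corrected separately; the magnitude
$|\beta|$ is the null statistic). The default ensemble size is
$N = 200$; published analyses of this kind use thousands, and `N` scales
linearly in cost. When many binding models are screened against one
reference table, `make_null_models` builds the table bank once and
shares it across screens.

# Desk-scale SELEX inference

The SELEX model: round-zero probe frequencies
$p_{i,0} = w_i / Z_0$ with $w_i = \exp(\sum_\phi \beta^{(0)}_\phi
X_{i\phi})$ summing k-mer bias features over the full probe (flanks
included); round-one frequencies $p_{i,1} \propto p_{i,0} \kappa_i$ with
$$\kappa_i = e^{\beta_{NS}} + \sum_v e^{score_{iv}}$$
summed over all footprint placements (offsets and both strands) within
flank+variable+flank. Both rounds are multinomial; `fit_bias` and
`fit_selection` maximize the corresponding likelihoods with analytic
gradients. The partition sums over the $4^L$ probe space and their
gradients use a clamped transfer-matrix DP whose state is the last $m$
probe bases ($m$ = 1 for mono/dinucleotide features, 4 when direct
shape-regression features are active, larger for wide bias features);
flank positions are clamped to their fixed base. Enumeration oracles at
$L \le 8$ verify $Z_0$ and $Z_1$ exactly.

Direct shape regression (`features = "mono+shape"`) adds per-position
sensitivities multiplying mean-centered table values evaluated in probe
context; windows without complete context contribute zero (centering
decorrelates the shape predictors from the intercept). The likelihood is
exactly invariant under strand-flipping the binding parameters, with two
consequences: a fitted matrix is defined only up to reverse
complementation (`strand_align` resolves the orientation against a
reference), and an exactly symmetric start would trap the optimizer in
the flip-symmetric saddle — the default initialization is therefore a
tiny seed-controlled perturbation ($\mathcal{N}(0, 10^{-2})$),
deterministic given the seed. `rc_symmetric = TRUE` instead *projects*
the start and gradient onto the symmetric subspace, the correct target
for homodimers. Reported matrices are gauge-fixed to per-position zero
mean (`gauge_fix_scoring`).

Model quality is quantified as in k-mer fingerprinting: observed m-mer
counts from held-out round-one reads (sliding windows within the
variable region; `split_holdout` thins counts binomially, equivalent to
a per-read split), expected counts from the model by clamped DP (with a
closed-form fast path when the window spans the whole variable region),
and the Pearson correlation of log counts. `compare_r_fisher` tests
differences of correlations by the Fisher z-transformation; the
effective sample size (retained m-mers vs reads) is an explicit argument
because the appropriate choice depends on the application.

Simulation (`simulate_selex`) enumerates the probe space exactly
($L \le 12$) and draws multinomial counts; all study-condition defaults
live in `fixture_spec`: L = 10 variable bases between 5-bp flanks,
$2\times 10^5$ reads per round, dimer bias of scale 0.1, negligible
non-specific binding ($\beta_{NS} = -10$), footprint k = 8 with
base-readout scale 0.5 $RT$ and planted MGW sensitivity $-1\ RT$/Å.

# Energy-stratified shape profiles

`sample_by_bin` stratifies footprint-length sequences into 10 uniform
bins of the free-energy score $W(s) = \sum_j w_{j,s_j}$ (shifted so the
best sequence scores zero). Uniform sampling cannot reach extreme bins,
so Metropolis–Hastings chains target Boltzmann distributions
$p(s) \propto e^{\beta_T W(s)}$ on a 13-point inverse-temperature grid
spanning $\log(4^k)/(-W_{min}) \cdot [-2, 2]$ — the printed form of this
grid in the source literature is typographically ambiguous; this scaling
makes the Boltzmann tilt comparable to the sequence entropy and is our
documented reading. Chains use single-base-substitution proposals and
run as many short parallel vectorized chains rather than one long chain
(same stationary distribution, far better R throughput). Each (bin,
temperature) stratum is rejection-filtered back to uniformity using the
analytic supremum of $e^{-\beta_T W}$ at the bin edge — exact, unlike a
running-maximum scheme, which is only asymptotically uniform. Empty bins
are flagged with a warning, not an error. `mean_shape_by_bin` then
averages per-position table values per bin.

`align_high_affinity_probes` mirrors the standard high-affinity-probe
analysis: retain m-mers with count $\ge 100$ and relative affinity
$\ge 0.1$, align them to the top m-mer by maximizing base matches over
shifts and strands, build a count-weighted frequency matrix, and place
each probe containing a retained m-mer at its best log-score offset and
strand. The relative-affinity estimator (`affinity_kmer_table`) is the
simple round-1/round-0 frequency ratio normalized to the top m-mer — a
documented simplification of model-based affinity estimators.

# Synthetic data: what it does and does not emulate

`make_table` constructs tables as exact variance-weighted sums of three
orthogonal unit-variance components inside the RC-symmetric subspace
(mononucleotide; dinucleotide orthogonalized against mono; unstructured
remainder), so requested variance fractions are realized exactly. The
default split 0.65/0.30/0.05 reproduces the structure of the published
decomposition of real shape tables (two-thirds mono, nearly all of the
rest dinucleotide). What passing tests on such tables shows: the
estimators recover known structure at realistic signal-to-noise. What
they do not show: behavior under the real tables' specific coefficient
patterns (A-tract narrowing, pyrimidine–purine roll), platform-specific
artifacts (PBM spatial bias, sequencing error), or data at full
experimental scale (hundreds of millions of reads; the full-scale
streaming fitter is out of scope). The test suite's problem sizes — null
ensembles of 200 tables, SELEX at $L = 10$ with $2\times10^5$ reads,
screens of 100 null models sharing one table bank — were chosen as the
smallest sizes at which the calibration and recovery claims are
statistically meaningful.

# Numerical choices, degenerate inputs, known limitations

* Pseudoinverse cutoff $10^{-9}$ (relative); eigenvalue counting uses the
  same cutoff. Numerically constant tables report $R^2 = 1$.
* Palindromic k-mers form singleton RC classes; `permute_table` permutes
  them among themselves so symmetry is preserved exactly.
* Projection convergence: relative objective change below
  `factr * .Machine$double.eps` (default `factr = 1e6`, i.e. ~$10^{-10}$);
  constraint handling for $p=1$ is exact via variable splitting.
* `conditional_variance` uses population variances; any consistent
  convention works, but reference and candidate must match.
* Degenerate SELEX data (a single unique probe) is rejected; bins that
  attract no Metropolis–Hastings draw are flagged empty.
* Non-specific binding far below the specific signal is essentially
  unidentifiable from round-one data (the likelihood is flat in
  $\beta_{NS}$); fits leave it at its initial value in that regime.
* The eigen-decomposition "soft-direction" diagnostic of unpenalized
  projections, electrostatic-potential tables, and multi-round
  ($r \ge 2$) SELEX are not implemented (extension points only).

# Reproducibility

Every stochastic function takes an explicit seed; `fixture_spec` fans a
single master seed out to labelled per-component streams, so adding a
fixture never perturbs existing ones. `scripts/acceptance.R` recomputes
the package's reference quantities from scratch;
`scripts/external_validation.R` reproduces the real-table regression
numbers when a user supplies the DNAshape-derived pentamer tables (not
shipped).
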