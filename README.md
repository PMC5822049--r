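# shapeproj

Decomposing transcription factor (TF) binding models into DNA **base
readout** and **shape readout**.

TFs recognize DNA through direct base contacts and through sensitivity to
the local helix conformation — minor groove width (MGW, Å), propeller
twist (ProT), roll and helix twist (Roll/HelT, degrees). Shape is itself a
function of sequence, so the two mechanisms leave overlapping sequence
signatures. `shapeproj` is for researchers in regulatory genomics who have
a quantitative binding model (or SELEX reads to fit one from) and want to
know *where* in the binding site, *for which* shape parameter, and *how
significantly* the model encodes shape readout.

## The models at the package's core

**Sequence-to-shape regression.** A k-mer shape table φ(s) (pentamers for
base-pair parameters, recentered tetramers for step parameters) is modeled
as

    φ̂(s) = γ⁰ + Σ_δ γ¹[δ, s_δ] + Σ_δ γ²[δ, s_δ:δ+1]

with reverse-complement symmetry. The RC-symmetric designs have
⌈(3k+1)/2⌉ (mono) and 4⌊3k/2⌋−2 (dinucleotide) independent parameters;
mono features alone explain about two-thirds of real shape-table variance
and the dinucleotide model nearly all of it.

**Mechanism-agnostic binding model.** Binding free energy of a k-bp
footprint: −ΔΔG(s)/RT = β⁰ + Σ β¹[i, s_i] + Σ β²[i, s_i:i+1]. Partition
sums over all 4^k footprints and their gradients are computed by a
transfer-matrix recursion in log space.

**Shape projection.** Given a mechanism-agnostic model, `project()` finds
the base-readout scoring matrix β^proj,(1) and shape-sensitivity profiles
β^proj,(φ) (ΔΔG/RT per unit shape; zero at footprint boundaries) whose
sequence-only representation best approximates it, minimizing

    V/V_ref + λ_shape ‖β^(φ)‖_p/‖β^(φ),ref‖_p + λ_mono ‖β^(1)‖_p/(‖β^(1),ref‖_p/4)

with V the Kullback–Leibler divergence between the models' Boltzmann
sequence distributions (default) or a squared-affinity error, and
λ_shape = λ_mono = 1 by default.

**Significance.** Sensitivities are compared to those obtained from random
shape tables with *matched complexity*: random mono+di coefficients scaled
so the expected conditional variance matrix C_ij = E Var[φ | s_i, s_j]
matches the real table's. Per-position empirical p-values get
Benjamini–Hochberg correction across binding-site positions.

**SELEX inference.** A desk-scale biophysical fitter for two-round SELEX:
round-zero k-mer bias model, round-one selection model
κ_i = e^βNS + Σ_views e^score with mono, mono+di or mono+shape features,
multinomial likelihoods maximized with analytic gradients and clamped
transfer-matrix partition sums over the 4^L probe space.

## Worked example

Plant a known MGW readout in a synthetic binding model, recover it by
penalized shape projection, and test its significance:

```r
library(shapeproj)

spec <- fixture_spec(seed = 42)          # study conditions: k = 8 footprint,
                                         # planted MGW sensitivity -1 RT/A at
                                         # position 5, pentamer table with
                                         # 0.65/0.30/0.05 variance split
pm <- make_planted_model(spec)
res <- project(pm$agn, pm$shape_models)  # KL loss, p = 2, lambda = 1
round(res$model$profiles$MGW, 3)
#> [1]  0  0  0  0 -1  0  0  0

ens <- null_bands(pm$agn, pm$tables, N = 200, seed = 7)
position_fdr(res, ens)
#>   feature position          beta           p         q
#> 1     MGW        3 -4.916265e-08 1.000000000 1.0000000
#> 2     MGW        4  3.259042e-08 1.000000000 1.0000000
#> 3     MGW        5 -1.000000e+00 0.004975124 0.0199005
#> 4     MGW        6  4.807409e-08 1.000000000 1.0000000
```

The projection recovers the planted sensitivity exactly (−1 RT/Å at
position 5, zero elsewhere — the planted model is noise-free, so the
penalized optimum coincides with it), and position 5 is the only
significant position after multiple-testing correction (q ≈ 0.02 from
200 complexity-matched null tables; the smallest attainable p with
N = 200 is 1/201 ≈ 0.005).

Degrees-of-freedom bookkeeping for the regression designs:

```r
c(count_dof(4, "mono"), count_dof(5, "mono"),
  count_dof(5, "mono+di"), count_dof(4, "mono+di"))
#> [1]  7  8 26 22
```

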