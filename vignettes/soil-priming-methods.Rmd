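---
title: "Methods: isotope partitioning, priming statistics, and community shift analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotope partitioning, priming statistics, and community shift analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilpriming)
```

soilpriming analyzes soil incubation experiments in which ¹³C-enriched
organic matter (OM) or pyrogenic organic matter (PyOM, "biochar") is added
to soil and the fate of native soil organic carbon (nSOC) is tracked
through the δ¹³C signature of respired CO₂. This vignette is the package's
account of the models it implements, the defaults it ships, and the limits
of what its synthetic-data checks demonstrate.

## The two end-member mixing model

Each gas measurement gives a total CO₂-C flux and the δ¹³C of the respired
CO₂. Because the amendment is strongly ¹³C-enriched relative to the soil,
respiration can be partitioned between the two sources by isotope mass
balance:

$$\delta_{measured} = \delta_{soil} \, f_{soil} +
  \delta_{amendment} \, f_{amendment}, \qquad
  f_{soil} + f_{amendment} = 1,$$

so that

$$f_{soil} = \frac{\delta_{measured} - \delta_{amendment}}
                   {\delta_{soil} - \delta_{amendment}},$$

and the component fluxes are `flux_soil = f_soil * flux` with
`flux_amendment` defined as the exact remainder, so the two components add
back to the measured total at machine precision.

**End-members.** The amendment end-member is the bulk δ¹³C of the OM or
PyOM (a constant per amendment). The soil end-member is estimated *daily*
as the mean δ¹³C measured that calendar day (`floor(time_h / 24)`) in the
same soil's unamended control jars; days without a control measurement are
filled by linear interpolation (endpoint extension at the edges). Controls
are never pooled across soils. Unamended jars themselves are assigned
`f_soil = 1` by construction.

**Numerical safeguards.** Partitioning is ill-conditioned when the
end-members approach each other; `min_separation` (default 50‰) rejects
such configurations up front. With measurement noise, `delta_measured` can
fall outside the end-member interval, making `f_soil` leave [0, 1]; it is
then clipped and the clip *counted* (attribute `n_clipped`), never silent.
On noise-free input the clip count is zero.

## Cumulative emissions and the priming statistic

Component fluxes are integrated per jar by the trapezoid rule. The first
measurement typically happens up to a day after wet-up, so integration
starts at $t = 0$ with the first measured flux extended backward. This
back-extension is the dominant quadrature error: for a pool with rate $k$
it contributes roughly $c_0 k^2/2$, i.e. ~0.02% of the 26-day cumulative
at $k = 0.01\,\mathrm{d^{-1}}$ and ~0.15% at $k = 0.05\,\mathrm{d^{-1}}$
under daily sampling. When priming decays quickly (small $\tau$, below),
the unobserved early peak inflates this to order one percentage point on
the priming *percent*; the error falls quadratically with finer sampling,
which the test suite verifies directly.

Treatment summaries average cumulative nSOC-derived CO₂-C across replicate
jars per (soil, amendment, time) and report mean ± 1.96 SE, the
convention of incubation figure legends. The **priming estimate** for an
amended treatment against its control is

$$\Delta(t) = \bar{x}_A(t) - \bar{x}_C(t), \qquad
  se_\Delta = \sqrt{se_A^2 + se_C^2}, \qquad
  \%\Delta = 100\,\Delta / \bar{x}_C .$$

**Interval and significance choices.** Two decisions here were genuinely
open:

* *Critical value.* With n = 4 jars per arm, a 1.96 normal quantile on
  `se_diff` gives ~10% type-I error for the "CI excludes zero" call. The
  default therefore uses a Welch–Satterthwaite t quantile
  (`conf = "welch"`); `conf = "z"` reproduces the 1.96 figure convention.
  The stricter rule — the two treatments' own 95% CIs do not overlap — is
  also reported (`significant_nonoverlap`).
* *Percent-scale uncertainty.* `recover_truth()` judges coverage on the
  percent scale, where the control mean appears in the denominator. The
  delta method for $\bar{x}_A/\bar{x}_C$ gives
  $se_{\%} = 100\sqrt{se_A^2/\bar{x}_C^2 +
  \bar{x}_A^2 se_C^2/\bar{x}_C^4}$, which propagates control-mean
  uncertainty that the naive rescaling of the difference CI omits.

The SE of the difference is formed by quadrature of the two arms' SEs
(pooling was the alternative; quadrature requires no equal-variance
assumption). Percent change is computed from treatment means, not per-jar
ratios, matching how such figures are constructed, and is invariant to
per-g-soil versus per-g-initial-C normalization.

## The synthetic incubation generator

The generator exists so every downstream stage can be tested against known
ground truth. It emulates the design of multi-soil amendment incubations:
several soils, three treatments (unamended control, OM at 3% by mass, PyOM
at 0.99% by mass — a pre-pyrolysis mass basis), n = 4 replicate jars per
treatment and harvest, harvests at days 1/10/26, ~daily gas measurement
over 26 days.

**Flux model.** Each carbon pool mineralizes first-order: flux
$c_0 k e^{-kt}$, summed over two nSOC pools (fast/slow) and two amendment
pools, each pool with a fixed δ¹³C (soil default −27‰; amendment default
+500‰ — only the separation matters for partitioning). Priming multiplies
the nSOC pool fluxes in amended jars by $1 + a\,e^{-t/\tau}$ (default
$\tau$ = 5 d): stimulation is strongest right after amendment and decays,
reproducing the early-peaking effects seen in such incubations.
`amplitude_for_percent()` inverts the (linear-in-$a$) closed form of the
primed cumulative to hit a requested percent increase exactly — truth is
analytic, not simulated.

Measurement noise: additive Gaussian on δ (default sd 2‰) and
multiplicative `1 + N(0, cv)` on flux (default cv 5%), truncated at zero
so fluxes stay non-negative.

Two structural points deserve note. First, the multiplier acts on the
*flux* without depleting the pool, so the design constructor proves, in
closed form, that no pool's cumulative CO₂-C can exceed its $c_0$ over the
experiment and rejects designs that would violate this. Second, the
default fast-pool rate is $k = 0.02\,\mathrm{d^{-1}}$: with a much faster
pool (nearly exhausted by day 26) the mass-balance proof correctly fails
for the large early multipliers needed for strong (>50%) priming, so the
shipped defaults keep both pools only partially consumed within the
incubation window.

**What the flux generator does not emulate:** headspace-concentration
dynamics and the concentration-to-flux conversion (fluxes are emitted
directly in µg C g⁻¹ h⁻¹), instrument drift, sorption, pH or nutrient
feedbacks, and any coupling between jars.

## The synthetic community generator

OTU tables are coupled to the priming magnitude so that the
"community shift tracks priming" analysis can be exercised with known
truth. Baseline log-abundances are drawn per soil (`base_logmean_sd` =
1.5); each OTU has a home soil and occurs elsewhere with probability
`otu_soil_overlap` = 0.3, echoing the strong soil-specificity of real OTU
inventories. A planted responder set (present in all soils) has true log₂
fold changes drawn from [2, 4]; in an amended sample the responders'
expected abundances are multiplied by $2^{\mathrm{lfc} \cdot g}$ with
$g = \min(1, \kappa \cdot \%\Delta/100)$, so the compositional shift
scales with that treatment's true priming percent (κ default 1). Per-OTU
log-scale day offsets (sd 0.25) emulate community drift over the
incubation, shared across treatments. Counts are Dirichlet-multinomial:
Dirichlet(θ·p) then multinomial at the read depth.

θ (default 1000) sets overdispersion: the per-OTU marginal is
beta-binomial with φ ≈ 1/(1+θ) ≈ 10⁻³, the order reported for real 16S
data sets. This is a consequential choice: at depth 3·10⁴ a taxon at 0.24%
relative abundance then varies ~±60% between replicate jars. That is
realistic burstiness, and it bounds what any detector can do — taxa near
the 0.01–0.05% filter boundary carry Wald statistics around 3–5 that
BH correction at ~10³ tests often cannot admit at n = 8 samples per
group, and mean Bray–Curtis shifts induced by weak coupling (g ≤ 0.2) sit
below replicate noise at n = 4. Passing tests therefore demonstrate
correctness of the machinery and calibration of its error rates, not that
every planted effect of this size is recoverable at these sample sizes —
with real data the same power limits apply.

**What the community generator does not emulate:** sequencing reads and
their error profiles (counts only), taxonomy, phylogenetic correlation
among OTUs, blank contamination, and compositional effects beyond
renormalization (note that renormalization alone means a planted absolute
fold change of 2³ realizes as slightly less on the relative-abundance
scale).

## Community analyses

**Dissimilarity.** Counts are Hellinger-transformed
($h_{ij} = \sqrt{x_{ij}/x_{i\cdot}}$) and compared by Bray–Curtis
dissimilarity — applied to the transformed values exactly as stated, with
no renormalization after the transform (this is not classical abundance
Bray–Curtis). The shift of an amended treatment is each amended
replicate's mean dissimilarity to all control replicates of the same soil
and day (all cross pairs; a centroid distance was the alternative), then
mean ± SE across amended replicates.

**PERMANOVA.** Implemented from the Gower-centered inner-product
formulation: $G = C(-\tfrac12 D^2)C$, sequential (Type-I) sums of squares
from incremental projectors of the nested model matrices,
pseudo-F per term, and p-values by free permutation of sample rows,
$p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})$. Term order follows the
design listing (soil, day, amendment, interactions). For ≤ 8 samples the
permutation null can be enumerated exactly (`exact = TRUE`); the sampled
p converges to the enumerated value, and the implementation matches
vegan's `adonis2` (the reference implementation of the procedure) on
sums of squares, F, and R² to 10⁻¹⁰.

**Differential abundance.** Per OTU, counts given library size follow a
beta-binomial with $\mathrm{logit}(\mu) = \beta_0 + \beta_{amend} +
\beta_{day}$ and $\mathrm{logit}(\phi) = \gamma_0 + \gamma_{amend}$ — the
minimal model that both adjusts for time point and allows differential
variance between amended and control groups. Fitting is maximum
likelihood by bounded L-BFGS-B from moment-based starting values
(smoothed group logits; Pearson overdispersion), with the observed
information supplying Wald SEs. The Wald statistic for
$\beta_{amend}$ is referred to a t distribution with $n - p$ degrees of
freedom — the small-sample convention of beta-binomial
differential-abundance tools; a normal reference is visibly
anticonservative for rare, bursty taxa. With the dispersion pinned near
zero (`fixed_phi`) the model reduces to binomial logistic regression and
reproduces `glm` coefficients, which the tests use as an independent
oracle.

Responder calling within one soil and amendment analyzes days 10 and 26
jointly: a prevalence filter first (mean relative abundance across all of
the soil's samples ≥ 0.01%), then per-OTU fits, BH adjustment of Wald
p-values within the (soil, amendment) family, and the responder rule
q < 0.05 with |log₂FC| ≥ 2 (positive responders: ≥ +2, inclusive). The
log₂ fold change is defined on *fitted mean relative abundances*, averaged
at equal weight over the two days, not on the logit coefficient.
Non-converged fits are excluded from calls and counted, never silently
dropped.

**Linking shift to priming.** Per (soil, amendment) cell the estimated
percent change at the final day is paired with the mean dissimilarity to
control; association across cells is Spearman rank correlation (average
ranks for ties) with a seeded permutation p-value, preferred over the
asymptotic approximation at a handful of cells. OM-vs-PyOM response
agreement is an ordinary least-squares regression of the per-OTU OM
response on the PyOM response for OTUs significant for at least one
amendment.

## Problem sizes used by the checks

The package's own verification runs at sizes a laptop handles in minutes,
chosen as the smallest that make the Monte-Carlo bands informative:
parameter-recovery at 100 coupled + 200 null incubations (n = 4 jars,
2-pool soil, δ sd 2‰, flux cv 5%); PERMANOVA size at 500 null data sets of
8 samples with 999 permutations; responder operating characteristics on
one 2000-OTU table with 40 planted responders at depth 3·10⁴; and the
five-soil linkage (true priming 0/5/20/60/130%) over 50 seeds at a
500-OTU scale. All randomness is seeded; identical seeds give identical
tables, files, and p-values.

## Known limitations

* Two end-members only; no Keeling-plot or multi-source partitioning, and
  all nSOC pools of a soil must share one δ¹³C (isotopically distinct
  native pools would bias partitioning and are not modeled).
* The cumulative series integrates across harvest gaps without adjustment.
* Beta-binomial Wald inference at n ≤ 8 per group is power-limited for
  taxa near the prevalence floor under realistic overdispersion (see
  above); the FDR side is controlled, the sensitivity side is not
  guaranteed.
* Mean Bray–Curtis shift at n = 4 replicates cannot rank-order treatments
  whose induced shift is below replicate noise; rank correlations across
  treatment cells should be read with their permutation p, not as point
  values.
* The CLI is a thin convenience over the R functions; the functions are
  the contract.
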