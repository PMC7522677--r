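---
title: "Searchable-area geometry of microTESE: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Searchable-area geometry of microTESE: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microtese)
```

## The model and its assumptions

The testis is idealized as a triaxial ellipsoid. We work with dimensionless
integer semi-axis ratios $a \ge b \ge c$ and a physical slice width $l$
(mm), so the semi-axes are $A = al$, $B = bl$, $C = cl$ and the surface is
$x^2/A^2 + y^2/B^2 + z^2/C^2 = 1$, long axis along X. Two conventions
deserve emphasis because they are easy to get wrong:

* **$al$, $bl$, $cl$ are *semi*-axes, not full axial lengths.** Anatomical
  descriptions often quote full lengths; the cross-section formulas below
  are only consistent with the semi-axis reading, which is the one this
  package uses everywhere. A "40 × 25 × 20 mm" input to `recommend()` means
  semi-axes, i.e. an 80 mm-long organ; measure accordingly (or halve
  caliper lengths).
* **Plane names follow the organ's frame**: transverse planes have the long
  (X) axis as normal, sagittal the middle (Y), coronal the short (Z).

A tunical incision bivalves the testis and exposes the two faces of a
central cross-section ($2\pi a b l^2$ longitudinal, $2\pi b c l^2$
transverse). The parenchyma is then serially sliced at integer multiples of
$l$ along the slicing normal. Each cut at $x = lx$ exposes **four** half
cross-sections — two bivalved halves times two faces per cut — of half-area
$S_x = \pi b c l^2 (a^2 - x^2)/(2a^2)$ (and analogously $S_y$, $S_z$). The
factor 4 is encoded once as the named constant `FACES_PER_CUT`. Cuts run
over $x = -(a-1), \dots, a-1$: strictly inside the poles, whose tangent
planes have zero area and are never counted. The closed-form sum is
$\sum 4 S_x = 2 b c l^2 (2a+1)(2a-1)/(3a)\,\pi$, with $b$ or $c$ along the
normal for sagittal/coronal slicing.

Slicing parallel to the bivalve exposure plane would detach the slices from
the tunica albuginea, so feasibility is coded as a geometric predicate
(slicing normal differs from the exposure-plane normal), not a hard-coded
pair list; a test pins the predicate to the two excluded combinations
(longitudinal + coronal, transverse + transverse). The four feasible
strategies are labelled 1–4. For strictly ordered testes ($a > b > c$) the
three adjacent total-area differences reduce to
$2cl^2(a^2-b^2)/(3ab)\,\pi$, $2bl^2(a-c)\,\pi$ and
$2al^2(b^2-c^2)/(3bc)\,\pi$, all positive, so method 1 (longitudinal +
transverse slices) is always the maximizer. `rank_strategies()` verifies
this numerically rather than assuming it, and reports ties: $a = b$
collapses the 1–2 difference, $b = c$ the 3–4 difference, and a sphere
makes all four totals equal; ties are broken by ascending method label.

What the model ignores: the convex outer surface of each slice (only cut
faces are searchable area), any occlusion of the face strip at the tunical
hinge, vasculature, tubule distribution and tissue deformation. These are
modelling choices, not omissions to be fixed: the comparison between
strategies is what matters, and all strategies are treated identically.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `a, b, c` | — | none (user) | integer ratios; integers make the closed-form sums exact and the ranking provable |
| `l` | mm | 1 (clinically 2–3) | slice width; thinner slices expose more area (total scales as $l^2$ for fixed ratios, and slice count grows as ratios grow) |
| `resolution` | intervals | 1024 | quadrature oracle accuracy $\mathcal{O}(n^{-3/2})$; 1024 gives ~1e-5 relative error against the 1e-4 test tolerance |
| `alpha` | — | 0.05 | per-row significance level of the cohort comparison; no multiplicity adjustment (deliberately, matching the published analysis style) |

## Numerical choices

* **Strict vs generalized mode.** Nothing in the anatomy forces integer
  ratios; the closed forms do. Strict mode (default) requires integers and
  unlocks `slice_face_sum_closed()`. Generalized mode accepts any positive
  reals and sums $4S$ over the integer cut lattice $|x| < a$ directly; the
  closed form is refused with a pointer to the direct sum, and results are
  flagged (`closed_form = FALSE`) in area breakdowns.
* **Rounding in `recommend()`.** Measured semi-axes rarely sit on the
  lattice; ratios are rounded to the nearest integer (minimum 1) and the
  residuals are reported, keeping the closed forms applicable while making
  the approximation visible.
* **Quadrature oracle.** `plane_section_area_quadrature()` exists to check
  the closed forms, so it must not share code with them: it midpoint-
  integrates the section's width function $2 Q \sqrt{k - u^2/P^2}$ obtained
  directly from the implicit surface equation. The square-root edge limits
  midpoint convergence to $\mathcal{O}(n^{-3/2})$ — ample for the 1e-4
  relative tolerance at $n = 1024$.
* **Tolerances.** Closed form vs direct summation: relative $10^{-9}$
  (pure double arithmetic on a handful of terms; passes with orders of
  magnitude to spare). Quadrature vs closed form: relative $10^{-4}$.
  Continuum limit: with the physical organ fixed and $l = A/a \to 0$,
  slice-face sum × $l$ converges to twice the volume (each cut exposes two
  faces) with relative error exactly $1/(4a^2)$, checked as a monotone
  refinement over $a = 10, 20, 40, 80$ on a 20 × 10 × 4 mm organ (ratio
  10:5:2, so every refinement keeps integer ratios).
* **Degenerate inputs.** Pole-plane sections return area 0; cut indices
  beyond the pole raise a domain error naming the valid range; `recommend()`
  rejects slice widths not smaller than the shortest semi-axis.

## The cohort statistics

The clinical component reproduces the published comparison of 56
previous-method and 102 new-method patients. Three choices matter:

* **Uncorrected Pearson chi-square, no exact-test fallback.** The published
  subgroup p-value of .011 for uniform maturation arrest (0/2 vs 8/9) is
  only reproduced by the *uncorrected* Pearson statistic ($X^2 = 6.52$);
  Yates correction or Fisher's exact test give ~.05 or larger. The
  implementation therefore fixes the uncorrected variant (the tests verify
  this derivation), with the usual small-expected-count caveat documented
  on `pearson_chi2()`. The overall comparison gives $X^2 = 4.14$,
  $p = .042$, consistent with the published "<.05".
* **Half-up rounding** at the printed precision (0 decimals overall, 1
  decimal for subgroups). One printed cell is internally inconsistent:
  13/24 = 54.17% prints as 54.1%. The reproduction test excludes that
  single cell; everything else matches exactly.
* **Not-computable rows.** Rows with an empty cohort side *or* a
  single-outcome margin (e.g. 0/4 vs 0/3) cannot be chi-square tested and
  are reported as `NA` / "-", matching the dashes of the published table.

Only marginal counts are published, never individual patients. The bundled
`reconstruct_cohort()` therefore commits exactly to the printed margins and
fills the unpublished joint etiology × histopathology structure by a
deterministic northwest-corner allocation — a synthetic choice that cannot
affect any reproduced statistic, all of which are marginal.

## What the synthetic generator emulates — and does not

`synth_cohort()` draws one independent Bernoulli outcome per patient within
each (cohort, subgroup) stratum at a configurable true rate, with exact
stratum sizes and a fixed seed (the caller's RNG state is preserved). That
is the statistical structure the cohort analysis assumes; it deliberately
does *not* emulate within-surgeon learning curves, temporal drift across
the 2011–2018 accrual, correlation between etiology and histopathology, or
patient-level covariates (hormones, age). A green test on synthetic data
therefore establishes that the arithmetic and the test behave correctly
under the assumed model — not that the published cohorts themselves are
reproducible, which they are not (criterion-level tests only ever assert
arithmetic on the printed counts).

`power_sim()` uses the same generator marginally to calibrate the
uncorrected test: at the published group sizes (56 vs 102) and a common
rate of 0.29, the Monte-Carlo type-I error over $10^4$ replicates sits
within [0.03, 0.07] — slightly liberal behaviour is expected from the
uncorrected statistic at these sizes, and that is the point of reporting
it. Degenerate replicates (single-outcome margins) count as non-rejections.

## Design decisions that were genuinely open

* **JSON-only configuration.** Reports and configs are JSON (machine-
  diffable, `jsonlite`); no YAML parser is available as a dependency, and
  JSON loses nothing here.
* **Ties reported, not hidden.** Degenerate ratio equalities are clinically
  plausible (near-spherical testes); the ranking object carries tie groups
  explicitly instead of pretending a strict order.
* **Verification as a first-class command.** `verify_invariants()` re-runs
  the identity/ranking/limit grids on demand (CLI `verify`, exit code 2 on
  failure) and has a `tamper` hook that perturbs the closed forms so the
  harness itself can be shown to detect breakage.
* **S3 model-object idiom.** The central computation returns a classed
  object (`strategy_ranking`) with `print`/`summary`/`plot` methods, like
  R's fitting functions; `coef`/`predict`/`residuals` have no meaning for a
  deterministic geometric ranking and are intentionally absent.

## Known limitations

Integer-ratio strictness is an idealization; the generalized mode relaxes
it but loses the closed forms. The ellipsoid ignores the epididymis and
hilum, where slicing is constrained in practice. The area-maximization
argument assumes retrieval probability is monotone in searched area — a
modelling premise supported, not proven, by the cohort comparison. And the
chi-square subgroup analyses inherit all the usual caveats of small,
unadjusted, retrospective-vs-prospective comparisons; this package
reproduces them, it does not endorse them as confirmatory.
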