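---
title: "Methods: two-level fuzzy periodontitis risk scoring and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-level fuzzy periodontitis risk scoring and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periorisk)
```

## The clinical problem

Periodontitis risk in type 2 diabetes patients is driven by metabolic
factors that are measured routinely: adiposity (BMI), glycemic control
(fasting glucose), and the lipid profile (total cholesterol,
triglycerides). `periorisk` encodes the clinical reasoning "the worse these
biomarkers, the higher the periodontal risk" as a two-level fuzzy inference
system and scores each patient on a 1–10 risk scale (PCRisk). The score is
then validated against the number of periodontal pockets (nrPP), the
clinical severity outcome, by simple linear regression.

## Model structure

### Linguistic variables

Every variable — the four biomarkers and the three risk outputs — carries
five ordered linguistic terms (Vs, s, Md, B, VB) with triangular membership
functions. Peaks are placed evenly across the variable's universe and each
triangle's feet sit at the adjacent peaks; the two end terms have a
degenerate outer limb (shoulder). This makes the five degrees sum to one at
every point (a Ruspini partition), which has three consequences we rely on
throughout: fuzzification never loses mass, at most two terms are active at
any crisp value, and the inference cascade can never encounter an empty
firing set for clamped inputs.

The default biomarker universes are the observed cohort ranges: BMI
[22.03, 44.08] kg/m², glucose [83, 237] mg/dL, cholesterol [112, 290]
mg/dL, triglycerides [63, 320] mg/dL. The risk scale is [1, 10] for all
three outputs, the conventional range for decision-support scores of this
kind. All universes, the resolution and the rule matrices are overridable
through a strict YAML configuration (`read_config()` /`write_config()`).

### Rule bases and their completion

Each subsystem has 25 if-then rules over the 5×5 grid of input-term pairs.
Twelve rules per subsystem are fixed by the published clinical rule lists
(rows Vs, Md and VB of the matrix); the remaining rows are completed as the
unique symmetric, row/column-monotone matrix with identity diagonal that
extends them, pinned by (s,s)→s, (s,B)→Md and (B,B)→B. The completed
matrix (rows = input 1, Vs→VB) is

```{r rules}
default_rule_matrix()
```

Symmetry says the two risk factors in a level are interchangeable;
monotonicity says a worse biomarker can never lower the risk; the identity
diagonal says concordant inputs map to the concordant grade. The same
matrix serves all three subsystems because the published rule lists are
identical across them. Custom matrices supplied by configuration must
satisfy the same three structural invariants — they are validated, not
trusted.

### Inference operators

The operator set is the product–sum–gravity Mamdani variant:

* **AND** (antecedent combination): product. For Ruspini inputs the 25 rule
  strengths then sum to exactly 1.
* **Implication**: product — each rule scales its consequent term by its
  strength.
* **Aggregation**: sum — the scaled consequents add.
* **Defuzzification**: centroid of the aggregated curve over the discretised
  output universe.

This choice is deliberate and load-bearing. The more common min/min/max
(clipping) configuration is *not* monotone here: between adjacent term
peaks the clipped-maximum envelope first shrinks and then regrows, which
produces dips of up to ≈0.035 risk units in the response surfaces, and
replacing only the aggregation by sum while keeping min-AND still dips by
up to ≈0.077. Since the defining qualitative property of the system is
that risk rises with every biomarker, we use the product/sum operators,
under which each inter-peak segment of the surface is a ratio of functions
linear in the interpolation parameter; combined with the monotone rule
matrix this makes the surfaces non-decreasing along both axes to machine
precision (verified on 201×201 grids in the test suite at tolerance 1e-6).
Because aggregation is linear in the per-term weights, batch evaluation
also reduces to two cached dot products per record.

Both operator sets agree wherever a single rule fires at full strength, so
the anchor values below are unaffected by the choice.

### Numerical choices

* **Discretisation**: the output universe is sampled at 1001 evenly spaced
  points including both endpoints. Tests check convergence against 2001
  points (difference < 1e-3) and against a 100,001-point oracle
  (difference < 0.01).
* **Quadrature**: the centroid uses trapezoid weights (half weight at the
  two endpoints). With flat weights the corner-case centroid at resolution
  1001 is 1.747 instead of the analytic 1.75; trapezoid weights give
  1.749988. The analytic anchors are the centroids of the end/middle
  triangles of the [1, 10] partition: 1.75, 5.5 and 9.25.
* **Out-of-range inputs** are clamped to the universe bounds rather than
  rejected — a screening tool must still score a patient more extreme than
  the reference cohort — and clamping is counted and reported per patient
  in the batch run log.
* **Degenerate firing** (all strengths zero) cannot occur after clamping
  with Ruspini partitions; the defensive error in `defuzzify_centroid()`
  remains for direct engine use.

The score of a patient at all four biomarker minima is 1.75 at the first
level; the second level then sees (1.75, 1.75), fires Vs with weight 8/9
and s with weight 1/9, and lands at 2.05. The mirrored maximum is 8.95.
Mid-range patients score exactly 5.5 at every level.

## The validation stage

`fit_simple_ols()` regresses nrPP on PCRisk and reports the coefficient
table (estimates, SEs, t, two-sided p from the central t distribution with
n − 2 df), the ANOVA decomposition, the standardized slope
(b₁·sd(x)/sd(y), the Pearson correlation in simple regression) and R². The
reference clinical fit, nrPP = 0.399 + 1.881 × PCRisk with n = 37, is
internally consistent to the printed 3 decimals (1.881/0.781 = 2.408;
p(t = 2.408, df = 35) = 0.021; 1313.647/35 = 37.533; F = 5.799 = t²;
β = 0.377 = √(SSreg/SStot)) and the test suite re-derives every one of
those identities. The underlying fit is delegated to `stats::lm`; the test
oracle is an independent closed-form normal-equations solution plus a
grid minimisation of the SSE.

## The synthetic cohort generator

No per-patient data are published, so the generator emulates the study
conditions:

* **n = 37** by default — the regression's total degrees of freedom (36)
  imply 37 analysed patients, although 87 were enrolled; the subset
  criterion is not stated, so n is a parameter.
* **Biomarkers**: independent truncated normals with mean at mid-range and
  sd = range/6, truncated to the universe bounds (a uniform alternative is
  available by configuration). The true biomarker distributions are
  unknown; these defaults keep every draw in range and concentrate mass
  centrally, as clinical cohorts do.
* **Outcome**: nrPP = round(clamp(0.399 + 1.881·PCRisk + ε)), ε ~
  N(0, √37.533) — the residual mean square of the reference fit — clamped
  to [0, 28] (one pocket per tooth of a full dentition minus third molars;
  the observed maximum was 20). Note 0.399 + 1.881·5.5 = 10.7445, which
  rounds to 11.
* **Seeding**: biomarkers and outcome noise use separate streams, so either
  can be held fixed; everything is reproducible from (seed, model, config).

What the generator does *not* emulate: biomarker correlations (hooks exist
but default to independence), measurement error, missingness, and any
relationship between the biomarkers and nrPP beyond the PCRisk pathway. A
passing parameter-recovery study therefore demonstrates that the pipeline
is statistically sound under its own generating assumptions — not that the
fuzzy score is clinically valid; that evidence must come from real
cohorts.

## Simulation results the tests compute

The acceptance suite runs a 200-replicate study at n = 37 (sizes chosen to
keep the whole suite under a minute on one core): the mean refitted slope
must fall within 3 standard errors of the generating 1.881 — integer
rounding and the floor clamp attenuate it mildly, by about 5% — the 95%
CI coverage must lie in [90%, 99%], and on null cohorts (slope 0,
intercept at the observed nrPP mean 10.73 so the floor clamp rarely
censors) the slope test must reject at a rate in [2%, 9%] at α = 0.05.

## Known limitations

* The rule-base completion, though minimal and structure-preserving, is not
  the only monotone completion; the matrices are configurable precisely so
  sensitivity to the completion can be studied.
* The membership placement is uniform; the original system may have used
  hand-tuned placements, which the configuration can express but which
  cannot be recovered from the published material.
* PCRisk's empirical distribution under the generator (mean ≈ 6.5 with
  default settings) sits above the observed cohort mean of 5.49 — the
  published medium-row rules are asymmetric upward (Md row = s,Md,Md,B,B),
  and the real biomarker distribution is unknown — so observed-cohort
  descriptive statistics are not reproduction targets.
* The regression stage is deliberately minimal (simple OLS, no robust SEs,
  no multivariable adjustment), matching the reference analysis.
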