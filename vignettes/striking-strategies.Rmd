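---
title: "Methods: spatio-temporal strategies for a striking gesture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatio-temporal strategies for a striking gesture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strikekin)
```

This vignette is the package's account of its models and the design choices
behind them: what is assumed, what is tunable, what the synthetic generator
does and does not emulate, and where numerical conventions matter.

## 1. The sliding model and the task-demand axis

A cube launched at speed $v_0$ along a gutter of slope $\alpha$ (degrees,
positive uphill from the strike point) and kinetic friction $\mu_K$
decelerates at the constant magnitude

$$a \;=\; g\,[\sin\alpha + \mu_K\cos\alpha], \qquad g = 9.81\ \mathrm{m/s^2},$$

and stops after $v_0^2/(2a)$ metres. Inverting gives the *optimal cube
speed* $v_\mathrm{opt}(d,\alpha,\mu_K)=\sqrt{2\,g\,d\,[\sin\alpha +
\mu_K\cos\alpha]}$ — the launch speed that parks the cube's front edge
exactly at the target distance $d$. The model assumes pure translational
sliding: no static-friction sticking, no tumbling, no wall contact, no
restitution beyond the scalar speed-transfer ratio described below.

The experimental design crosses $d \in \{0.25, 0.50\}$ m, surfaces
$\{\text{aluminum } \mu_K = 0.37,\ \text{balsa } \mu_K = 0.47\}$ and slopes
$\{-10°, 0°, +10°\}$. `build_condition_grid()` ranks these 12 conditions by
$v_\mathrm{opt}$, which spans 0.97–2.50 m/s with $g = 9.81$; this value of
$g$ (standard gravity to 2 dp) reproduces both printed endpoints at 2 dp.
Ties in the ranking cannot occur with these constants; they would be broken
lexicographically by $(d, \mu_K, \alpha)$.

```{r}
build_condition_grid()[c(1, 12), ]
```

## 2. The synthetic cohort generator

The generator exists so that every downstream stage is testable end-to-end
without recordings. It emulates the study's structure — cohorts of
participants × 12 conditions × 10 repetitions, 250 Hz fingertip (3D) and
cube (1D) positions, arming/strike/collision/slide phases — and the
statistical signature the analysis looks for: three archetypes
distinguished by the sign of the duration–impact-speed coupling.

**Generation order per trial** (impact speed is the controlled variable):

1. intended impact speed $IS = v_\mathrm{opt}/\kappa + \varepsilon_{IS}$,
   where $\kappa$ is the participant's speed-transfer ratio (cube launch
   speed / fingertip impact speed) and $\varepsilon_{IS}$ is Gaussian
   planning noise;
2. duration $D = D_0 + \beta_D (IS - IS_\mathrm{ref}) + \varepsilon_D$ and
   amplitude $A = A_0 + \beta_A (IS - IS_\mathrm{ref}) + \varepsilon_A$
   from the archetype's affine rules;
3. the strike speed profile $v(u) = IS\,u^{s}$, $u \in [0,1]$, whose
   exponent makes the displacement integral equal $A$.

**Defaults and why.** $IS_\mathrm{ref} = 1.8$ m/s is roughly the
cohort-mean intended impact speed (grid-mean $v_\mathrm{opt} \approx 1.66$
over a typical $\kappa \approx 0.92$). Archetype duration slopes $\beta_D$
are $-0.030 / 0 / +0.023$ s per m/s and amplitude slopes $\beta_A$ are
$0.030 / 0.063 / 0.071$ m per m/s — the cluster-mean regression slopes
reported for this task — with baselines of 125–145 mm and 150–170 ms,
typical strike scales. $\kappa$ is drawn once per participant from
$[0.85, 0.98]$. Trial noise defaults ($\varepsilon_{IS}$: SD 0.15 m/s;
$\varepsilon_D, \varepsilon_A$: SD 18% of the baselines) were chosen once
so that per-participant correlations over 120 trials land in the reported
ranges (negative couplings around $-0.3$ to $-0.6$, positive around $+0.2$
to $+0.45$, and $r(A,IS)$ positive throughout) rather than at the
deterministic extremes $|r| \to 1$.

**The sampled trajectory.** Phases are: 0.1 s rest at the cube face; a
0.4 s cosine arming excursion of amplitude $A$ away from the cube (arming
equals the strike amplitude — the fingertip starts at the cube face; its
duration is a free choice excluded from all analyses); a 48 ms hold; the
strike; a 16 ms (4-sample) linear fingertip deceleration at the collision;
and the cube's slide. The strike profile is solved in *discrete* form: the
per-interval speeds $w_j = IS\,(j/n)^{s}$ are given the exponent $s$ that
makes $\sum_j w_j \Delta t = A$ exactly (a one-dimensional root solve,
tolerance $10^{-13}$), so the sampled trajectory's chord amplitude and
terminal finite-difference speed equal the ground truth to machine
precision rather than to $O(s/2n)$ discretization error. The exponent is
kept in $[\sim 0.08, 6]$; infeasible draws are resampled (bounded retries),
which also rejects profiles so flat at onset that the first samples move by
less than machine precision.

**The collision.** The fingertip decelerates linearly to rest over 4
samples. The cube waits one sample (contact lag) and then follows the exact
constant-deceleration parabola with launch speed $\kappa\,IS$ from the
impact point, held at its vertex once stopped. Two properties motivated
this over a multi-sample cube speed ramp: (i) the cube's total travel
equals `stopping_distance(kappa * IS)` *exactly*, so a noise-free,
perfectly calibrated trial has spatial error exactly 0%; (ii) the
contact-detection window (below) stays non-degenerate on clean data,
because the minimal pre-motion cube speed falls on the lag sample between
impact and cube motion.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: measurement noise and marker dropout on the
positions themselves (trajectories are smooth; only the *parameters* are
noisy), joint-level arm dynamics, 3D cube motion, trial-to-trial learning,
and the demand-dependent undershoot visible in the study's spatial errors
(a `kappa` decrement with demand could inject it; it is off by default
because no generative mechanism is reported).

## 3. Kinematic event detection

All kinematics are first-order forward finite differences of *raw*
positions; no smoothing is ever applied, because a 10–15 Hz low-pass would
erase the ~15 ms collision transient that contact detection relies on (a
regression test filters a trajectory and shows the recovered impact speed
is corrupted).

**Index convention.** The speed attributed to sample $i$ is the difference
over the interval *arriving* at $i$; acceleration likewise. Under this
convention an impact between samples $c$ and $c+1$ first registers in the
acceleration at $c+1$, and the contact rule's trailing $-\Delta t$ lands on
$c$ — the last frame before impact, which is what the contact time means
here.

**Events.** The cube counts as moving at the first sample whose speed
strictly exceeds 0.04 m/s; $t_\mathrm{minCS}$ is the *latest* sample
attaining the minimal cube speed between the fingertip speed peak
($t_\mathrm{maxFS}$) and that onset (latest, so that the zero-speed
plateau before impact resolves to the sample adjacent to motion). Within
$[t_\mathrm{maxFS}, t_\mathrm{minCS}]$ the fingertip acceleration is
normalized by the window's most negative value (which normalizes to 1, so
a crossing always exists when any deceleration is present) and contact is
one sample before the first value strictly above 0.4. Both 0.04 and 0.4
are strict inequalities; both thresholds are `kinematic_config()` fields,
and the cube-stop threshold reuses 0.04 m/s symmetrically.

**Strike onset** has no published definition, so the rule is this module's
own: locate the strike as the first sample after the last toward-cube
direction reversal whose speed exceeds 5% of the strike-segment peak, then
walk back to the sample preceding that contiguous run of toward-cube
motion (the reversal extremum, where the fingertip is still stationary).
The threshold alone would bias onset late by $n \cdot 0.05^{1/s}$ samples —
2 samples for a linear ramp ($s = 1$) but ~9 for a late-impulse profile
($s \approx 1.8$) — breaking the round-trip guarantee; the walk-back makes
noise-free recovery exact to ≤ 1 sample while the threshold still guards
against slow drift on real recordings. The fraction is configurable and is
recorded in the run metadata.

**Derived variables.** $D$ = onset→contact; $A$ = 3D chord between the
fingertip positions at onset and contact (path length would differ only
for curved strikes; the chord matches the variable's definition as a
distance between two positions); $IS$ = fingertip speed at contact;
spatial error = $100\,(x_\mathrm{stop} - d)/d$ with $x_\mathrm{stop}$ the
front-edge travel (for a rigid cube, front-edge and marker displacement
are identical, so the 60 mm cube length cancels against an origin at the
front edge's start). Trials failing any detection are excluded with a
reason code and counted, mirroring the study's exclusion bookkeeping.

## 4. Strategy classification

Per participant, Pearson correlations $r(D,IS)$, $r(D,A)$, $r(A,IS)$ over
all trials; p-values via the t transform; CIs via Fisher-Z. Regulation
modes split at the two-tailed critical correlation
(`critical_r(120) = 0.179`), with $|r|$ exactly at the criterion counted
as not significant.

Clustering operates on the *unstandardized* Fisher-Z triplets (the
transform already puts the three coordinates on a comparable scale, and no
further scaling is reported); Hartigan–Wong K-means with 100 seeded random
restarts by default, best solution by minimal total WCSS, ties resolved by
first occurrence. `stats::kmeans` rejects $k = n$, so the singleton
partition (WCSS 0) is special-cased to let the elbow profile reach 100%.
For $k = 3$ the cluster with the most negative centroid $z(D,IS)$ is
labelled Inverse Duration-Amplitude, the most positive Late-Impulse, the
remainder Temporal Invariance. Validation uses the elbow profile
($100\,\mathrm{BSS/TSS}$ and marginal gains) and the Calinski–Harabasz
pseudo-F.

Because the shipped correlation table is printed to 2 dp, fixture-based
checks use absolute tolerances (±1 point on percentages, ±1 on the CH
index, ±0.05 on WCSS values) rather than exactness; residual discrepancies
beyond those tolerances are reported by the tests, not absorbed.

## 5. Scaling analysis

Slopes are fitted per participant by OLS on all trials, with
$v_\mathrm{opt}$ as a continuous regressor (not on 12 condition means —
the per-trial fit is what the study's regression figures show; switching
to condition means only changes the weighting of the noise). Z-scoring of
the slope columns is pooled across *all* participants (sample-SD
convention): comparing Z-slopes between clusters presumes a common scale.
The between-cluster comparison is a classical one-way ANOVA; partial
$\eta^2 = SSB/(SSB+SSW)$ with a 95% CI by noncentral-F inversion; Tukey
HSD for the pairs; Cohen's d with the pooled SD of the two groups and a
noncentral-t CI. The strategy-by-coordination table is tested with
Pearson's chi-square (no continuity correction) and Cramér's V. No
multiple-testing correction beyond Tukey is applied.

## 6. Hierarchical multiple factor analysis

Continuous inputs are the participant × 12-condition means of $A$, $D$,
$IS$ (one row per participant); trial-level HMFA is out of scope. Each
continuous block is centered, unit-scaled, and divided by $\sqrt{\lambda_1}$
of its correlation-matrix PCA; the categorical cluster block is coded as a
complete disjunctive table with MCA-standard column processing — category
$j$ with relative frequency $p_j$ becomes $(\mathbb{1}_j - p_j)/\sqrt{p_j}$
— and weighted the same way. After weighting, every block's own first
eigenvalue is exactly 1 (a unit test).

The hierarchy is fixed as two levels: {Cluster} and {Kinematics = A, D,
IS}. This is the natural reading of "one categorical variable and three
continuous blocks": the three kinematic blocks are siblings under one
node, so the re-weighting at the Kinematics node prevents the three
(correlated) kinematic blocks from jointly outweighing the single cluster
block. The tree is an argument of `hmfa_fit()`, so other placements can be
tried. Weighting is applied bottom-up: leaves first, then each internal
node's assembled table is re-weighted by its own $\lambda_1$; a node with
a single child is a no-op (its child's $\lambda_1$ is already 1).

The merged table gets one global PCA (SVD; eigenvalues
$d_k^2/(n-1)$, near-zero eigenvalues below $10^{-10}$ of the largest are
dropped). Contributions of a column to a dimension are the squared loading
in percent; block, group and kind (categorical vs quantitative) shares are
column sums, so each partition level sums to 100% per dimension by
construction. No rotation is offered — rotation would redistribute
variance and invalidate the $\lambda_1$ bookkeeping. Reports default to
95% cumulative inertia and never fewer than 4 dimensions.

## 7. Problem sizes, determinism, and limitations

Every random stage takes an explicit integer seed and restores the
caller's RNG state; identical configs give byte-identical outputs. The
test suite exercises: zero-noise round trips per archetype at the demand
extremes; a 6-participant default-noise cohort for extraction and
classification checks; a 33-participant cohort (11 per archetype, the
study's size) for the strategy-recovery check; exhaustive-enumeration
K-means oracles at $n \le 8$; and 1000-replicate null calibration of the
ANOVA stage. These sizes were chosen as the smallest that make the
respective statistical property sharp.

Known limitations: the generator's parameter noise model is Gaussian and
trial-independent (no serial correlation, no block effects from the nested
design); event detection presumes a single strike per trial and a cube
that starts at rest; the MCA column convention is one of several in use —
it is pinned by the first-eigenvalue-equals-one and single-block tests,
and alternative conventions would rescale category coordinates without
changing the balanced-block logic; and the per-cluster WCSS of a k-means
solution is only identified up to the label-matching of near-equal
clusters when the input correlations are rounded to 2 dp.
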