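---
title: "Methods: kinematics, clustering and dynamics of infant mobile-paradigm learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinematics, clustering and dynamics of infant mobile-paradigm learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobilekin)
```

## The paradigm and the measures

In the mobile paradigm an infant lies supine with reflective markers on
both wrists and ankles while an overhead mobile hangs in view. After a
2-min baseline in which limb movements have no consequence, a ribbon
connects one wrist to the mobile for a 10-min play phase, so movements of
that arm move the mobile. Learning shows up as a change in the amount of
limb movement relative to baseline.

`mobilekin` quantifies "amount of movement" in three steps, each a small
pure function on a tagged data frame:

1. **Instantaneous speed** (`instantaneous_speed()`): the central
   difference of the 3D marker position over one sampling period
   (default 60 Hz), dropping the two endpoint samples. Central
   differences are exact on linear motion and second-order accurate
   otherwise.
2. **Displacement rate** (`displacement_rate()`): the mean speed over a
   centred window $[t-\tau, t+\tau]$ with $\tau = 30$ s, i.e. movement
   per 1-min window, in mm/s. Near the recording edges the window is
   truncated to the available support and normalised by the actual
   sample count, so curves are defined over the full session; the
   alternative (dropping partial windows) would discard the first and
   last 30 s that full-session figures need.
3. **Baseline ratio** (`baseline_ratio()`): the displacement rate
   divided by its baseline-phase mean. The divisor uses only window
   centres whose full $\pm\tau$ window lies inside the baseline
   interval ($t \in [30, 90]$ s for a 120-s baseline), so the play
   phase cannot leak into the normaliser through straddling windows.
   By construction the ratio averages to exactly 1 over those centres;
   this is asserted on every generated session in the test suite. A
   motionless baseline (divisor zero) is an error, not a NaN.

Limbs are analysed by *role* relative to the tethered wrist — connected
arm (ConA), unconnected arm (UncA), ipsilateral and contralateral leg —
so left- and right-connected infants are comparable. Block summaries
average a series over half-open 2-min intervals: B = [0, 120) s,
P1–P5 = [120, 720) s in 120-s steps. All intervals in the package are
half-open and timestamps are seconds from recording start.

Units: coordinates in millimetres, time in seconds, displacement rate in
mm/s. The ratio is dimensionless, which is also why the generator's gain
calibration (below) cannot distort it.

## Time-series clustering

Individual learning curves are heterogeneous, so infants are partitioned
by K-means over their four-limb baseline-ratio series down-sampled to
1 Hz (decimation at integer seconds; no additional z-scaling, since the
ratio is already normalised per infant). The feature vector concatenates
the four limb roles in fixed order, and the objective is the plain
Euclidean sum of squares

$$D = \sum_{i=1}^{k}\sum_{j=1}^{n}\sum_t \delta_{i,j}\,(x_{j,t}-v_{i,t})^2 .$$

`kmeans_timeseries()` implements the Lloyd scheme from a *random initial
assignment*, iterating centre updates and nearest-centre reassignment
until the assignment stabilises, with `restarts = 10` independent
initialisations by default and the best final $D$ kept. Design choices
where the algorithm sketch leaves room:

- **Empty clusters** are reseeded at the subject farthest from its own
  centre (deterministic given the seed); a clustering that still ends
  with empty clusters (e.g. all-identical subjects) warns and breaks
  ties toward the lowest cluster index.
- **Convergence** is declared when assignments stop changing; $D$ is
  tracked every iteration and asserted non-increasing.
- **Determinism**: every restart derives its RNG stream from the user
  seed, so runs are exactly reproducible.
- Random-assignment initialisation has small basins of attraction on
  small unstructured instances; the oracle-equality tests therefore use
  thousands of cheap restarts, while realistic curve data (which is
  strongly structured) separates with the default ten.

`label_clusters()` names fitted clusters from their centres: a centre
whose connected-arm play mean stays below 1.5 is *no increase*; the
centre with the largest final-block connected-arm ratio above 2.5 is
*arm more increase*; both legs above 1.5 in play is *all-limb increase*;
anything else is *arm increase*. The 1.5 threshold is the conventional
learning criterion; both thresholds are arguments.

## The infant–mobile dynamical system

The modelling layer asks whether differences in *spontaneous* movement
alone can explain the different learning curves. The limb is a van der
Pol oscillator with a Duffing frequency-modulation term, the mobile a
damped harmonic oscillator forced by the limb, and a slow variable
$\delta$ closes the sensorimotor loop:

$$\ddot x + \dot x(\gamma + \alpha x^2) + x(\omega_0^2 + \delta x^2) = 0$$
$$\ddot y + \varepsilon\dot y + \Omega_0^2 y = c\,x$$
$$\dot\delta = a y^2 - \kappa\,\delta$$

With $\gamma < 0 < \alpha$ the limb sits on a limit cycle of amplitude
$\approx 2\sqrt{-\gamma/\alpha} = 1$ — spontaneous periodic movement.
During play ($c = 2$) mobile motion pumps $\delta$, which raises the
limb's effective frequency and hence its speed; the loop is the model's
account of learning. Defaults are $\gamma = -0.25$, $\alpha = 1$,
$\varepsilon = 1$, $\Omega_0 = 2.2$, $a = 0.13$, $\kappa = 0.007$,
$c = 0$ in baseline and $2$ in play, integration step $dt = 0.01$. Only
$\omega_0$, the natural frequency of spontaneous movement, varies across
infants: it is drawn per infant from a uniform distribution of width 0.5
whose mean characterises a cluster — (2.8, 3.3), (0.9, 1.4), (1.4, 1.9)
and (0.3, 0.8) for the no-increase, arm-increase, all-limb and
arm-more-increase archetypes respectively. Slow intrinsic oscillators
have the most frequency headroom, so they show the largest relative
increases; this ordering is asserted numerically in the tests.

Numerical choices:

- **Integrator**: fixed-step classical RK4 at $dt = 0.01$, implemented
  in C++ for cohort-scale ensembles. Halving the step changes final-block
  simulated ratios by far less than 1% (asserted), and the trajectories
  agree with an independent adaptive solver (deSolve's lsoda at
  tolerance $10^{-10}$) in the tests.
- **Time map**: one model time unit = one second, so a simulated session
  is 120 + 600 units and simulated curves align with experimental ones.
  This mapping is a package convention, configurable through the
  schedule argument.
- **Initial conditions and burn-in**: $x(0)=1$, $\dot x(0)=0$, mobile
  and $\delta$ at rest, preceded by a discarded 60-unit baseline-coupling
  burn-in so the limb starts on its limit cycle and transients cannot
  contaminate the baseline mean.
- **Speed proxy**: the simulated "instantaneous speed" is $|\dot x(t)|$,
  fed through the *same* displacement-rate and baseline-ratio code as
  the motion-capture data. $|\dot x|$ is the model's velocity magnitude,
  the natural analogue of the 3D speed; $|x|$ would be blind to the
  frequency increase that constitutes the effect.
- $\delta$ stays non-negative whenever $\delta(0) \ge 0$ and $a \ge 0$
  (its derivative at $\delta = 0$ is $a y^2 \ge 0$); blow-ups abort with
  the failure time, and ensemble runs exclude failed members, erroring
  if more than 10% fail.

`fit_omega0()` recovers a cluster-mean $\omega_0$ by grid search:
each candidate mean $m$ spawns an ensemble with
$\omega_0 \sim U(m - 0.25, m + 0.25)$, scored by the mean squared
deviation of the ensemble-mean curve from the target over play-phase
points, ties toward smaller $m$. On self-generated targets the true mean
is recovered within one grid step (0.25).

## Synthetic sessions and cohorts

The generator exists so every downstream stage is testable without
motion-capture recordings; it produces data with the statistical
structure the analysis assumes, not a biomechanical simulation.

- Each limb runs its own independent model oscillator with its own
  $\omega_0$ draw from the archetype range. The connected arm couples at
  full play strength; other limbs couple through a per-role attenuation
  of $c$ (`c_gain`): 1 for both arms, 0.5 for the legs in the all-limb
  archetype, 0 for legs elsewhere. The attenuation scheme is a package
  choice — the paradigm offers no mechanism for unconnected-limb
  increases — and is fully configurable.
- The 1-D model coordinate is linearly interpolated from the 100 Hz
  integration grid to the 60 Hz capture grid and embedded in 3D as
  *rest point + gain · x(t) · fixed unit direction*, plus isotropic
  Gaussian jitter. Only the speed magnitude matters downstream, so the
  embedding direction is immaterial.
- **Gain calibration**: when an archetype specifies a target baseline
  displacement rate, the per-limb gain is scaled by (target / model
  baseline mean speed), so generated sessions land on prescribed
  baseline levels. Defaults of 30, 15, 20 and 10 mm/s for archetypes
  1–4 encode the observed pattern that the no-increase group moves most
  at baseline while the strong-increase groups move least.
- **Noise**: default positional jitter SD is 0.02 mm, the residual
  noise of smoothed optical-capture trajectories. Central differencing
  at 60 Hz multiplies white positional noise by ~65 s⁻¹, so raw-marker
  noise levels (0.1–1 mm) would add a speed floor comparable to the
  signal itself; the generator therefore emulates post-smoothing data,
  and tests that need exact structural fidelity set the jitter to zero.
- Cohort defaults mirror the study scale: cluster sizes
  (102, 47, 27, 9), ages (90, 95), 60 Hz, 120 + 600 s. Ages and
  connected sides are assigned in a deterministic counterbalanced
  round-robin honouring the age totals, and per-session seeds derive
  from the master seed, so cohorts are bit-reproducible.

What passing tests on generated data do **not** show: real infant
movement is intermittent, posture-dependent and non-stationary, markers
drop out, and unconnected-limb changes arise from neural coupling rather
than an attenuated mechanical link. The generator shares none of these
features, so green tests certify the *pipeline*, not claims about real
recordings.

## Statistics

The group layer follows the conventions of mixed-design behavioural
analyses with a global $\alpha = 0.01$:

- `mixed_anova()` computes the classical split-plot partition through
  `stats::aov` with an `Error(subject)` stratum: the between factor
  (age or cluster) is tested against the between-subjects error
  ($df = n - g$), phase and the interaction against the
  subject-by-phase residual ($df = (p-1)(n-g)$). **No sphericity
  correction** is applied by design, matching the uncorrected-df
  reporting convention; under iid errors the within test is exact, and
  the null-simulation test verifies the type-I rate at $\alpha = 0.01$
  stays in [0.005, 0.02] over 2000 replicates.
- **Partial $\eta^2$** is $SS_e/(SS_e + SS_{err})$ with a 95% CI from
  inverting the noncentral-F distribution
  ($\eta_p^2 = \lambda/(\lambda + df_1 + df_2 + 1)$, lower bound clamped
  at 0). The inversion is the package's documented choice among the
  several CI constructions in use.
- `simple_main_effects()` tests one factor within slices of the other,
  reusing the omnibus error terms, with Bonferroni-corrected per-slice
  thresholds ($\alpha$ / number of slices).
- `tukey_hsd()` computes studentised-range comparisons (Tukey–Kramer
  for unequal n). For the repeated-measures phase factor the caller
  passes the omnibus within-subject error term and df — the reason the
  function is built on `stats::ptukey` rather than `TukeyHSD()`, which
  cannot take an external error term. For two groups it collapses to
  the pooled t-test ($q = \sqrt{2}\,|t|$), which the tests verify.
- `origin_regression()` fits $y = \beta x$ through the origin
  ($\hat\beta = \sum xy / \sum x^2$), one line per age group in the
  baseline-vs-play scatter; `learner_flag()` applies the conventional
  criterion — any play block with connected-arm ratio $\ge 1.5$ — with
  the boundary counting as learned.

## Problem sizes and reproducibility

The test suite exercises the pipeline at sizes chosen to keep a full run
around a minute while preserving every scientific property: ensembles of
9–47 simulated infants, cohorts of 8–20 sessions at 10–60 Hz (the full
185-session default cohort is generated once at reduced sampling rate to
check the counting and counterbalancing), exhaustive K-means oracles at
$n \le 8$, and 2000-replicate null calibration for the ANOVA layer.
`run_full()` writes every intermediate artifact plus a summary JSON and
is byte-identical when rerun from the same configuration and seed; all
randomness flows from user-supplied seeds through a documented sub-seed
derivation.

## Known limitations

- The dynamical model is one-dimensional per limb and deterministic;
  it reproduces cluster-level curve shapes, not individual fluctuation
  patterns (real individual curves show rhythmic rises and falls that
  the smooth model cannot produce).
- K-means with Euclidean distance on smooth synthetic curves tends to
  split high-variance archetypes before separating nearby low-variance
  ones, so ground-truth recovery tests use well-separated narrow
  frequency ranges; with overlapping default ranges the partition is
  only approximately aligned with the generating archetypes — as in any
  K-means analysis, cluster boundaries on continuous variation are
  descriptive.
- The phase-factor Tukey test inherits the no-sphericity convention;
  with strongly non-spherical real data its p-values are approximate.
- Gap interpolation for dropped markers is limited to 0.5 s; longer
  gaps reject the session rather than imputing.
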