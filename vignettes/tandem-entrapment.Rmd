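---
title: "Reading tandem running out of trapped and fossilised pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reading tandem running out of trapped and fossilised pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Termite mating pairs run in tandem: a follower keeps its head in contact
with the tip of the leader's abdomen while the pair searches for a nest
site. A pair preserved in amber, however, is not a frame from that movie.
Tree resin traps animals gradually; a pair can keep responding to each
other while being caught, and the posture that fossilises is the end state
of that process — in the motivating specimen, two termites side-by-side
rather than single file, with one head still at the other's abdomen tip.

`tandemtrap` operationalises three questions about such a snapshot:

1. **Does entrapment reshape spatial organisation in a specific way?**
   Compare distance, relative direction and heading difference between
   natural tandems and sticky-trapped pairs.
2. **Is the trapped pair still interacting?** Break the pairing with a
   randomised-pairing null that preserves each individual's movement but
   destroys the coupling, and ask whether real pairs are closer than
   re-paired ones.
3. **Who was leading?** Train a leader/follower classifier on posture
   features of live pairs with known roles, and score the fossil snapshot.

## The pair-metrics model

All analyses work on per-frame centroid tracks (mm, y-up, headings in
radians CCW from +x) downsampled to 1 FPS. Distances are normalised by the
pair's mean body length $\bar{L}$; the *interaction filter* keeps frames
with raw distance below $L_F + L_M$ (the conservative "twice a body
length" reach of tandem contact), using a strict inequality since the
boundary case carries no information. Relative direction is the unsigned
angle in $[0, \pi]$ between the focal heading and the bearing to the
partner; heading difference is the unsigned difference of headings in
$[0, \pi]$. Headings missing from a tracker are estimated from forward
displacements, carrying the last reliable heading across steps shorter
than `min_step_mm` and back-filling the leading gap.

One measurement choice deserves emphasis: **speeds are computed at the
acquisition frame rate**, not at the 1-FPS analysis rate used for spatial
organisation. A trapped animal's centroid wiggles in place; sampled at
1 FPS most of that motion cancels, and the resulting number measures the
displacement model rather than the animal's activity. At the native rate
the step lengths are the activity level, and the trapped/natural speed
ratio recovers the trap's slowing factor directly. Forward differences are
used throughout and the last frame is dropped.

## The randomised-pairing null

Under the null of no interaction, a trapped female's trajectory should
look the same no matter which trapped male is placed next to her. Each
replicate draws a *derangement* (a permutation with no fixed points, by
rejection sampling from uniform permutations, so no male is re-paired with
his own female), rigidly realigns each swapped male — the unique
rotation-then-translation taking his first position and initial heading
onto the original male's — and truncates each randomised pair to the
shorter trajectory. Rigid realignment preserves every within-trajectory
distance, so individual movement statistics are untouched; only the
coupling is broken.

Two summaries are kept per replicate: means over all common frames and
means over interaction frames only; a seeded subsample of pooled per-frame
values (capped per replicate to bound memory) supports distribution-level
comparisons. `compare_real_null()` reports both routes:

- the placement (`real_quantile`, two-sided `p_perm`) of the real mean in
  the null distribution of replicate means — exchangeable under the null,
  hence calibrated, and the recommended test;
- a pooled two-sample KS (or rank-sum) of per-frame values — useful for
  distribution shape (e.g. the bimodal heading differences of trapped
  pairs), but anticonservative as a test because frames autocorrelate.

The package's calibration check runs the null on independently generated
walks and verifies that `real_quantile` is uniform; its power check
verifies that coordinated trapped pairs fall below the null mean distance
in essentially every seeded ensemble.

## Posture features and role inference

Six points are tracked per pair: head middle, head–pronotum border and
abdomen tip for each sex (`fHead`, `fPro`, `fTip`, `mHead`, `mPro`,
`mTip`). Pose-estimation exports are read with a likelihood cutoff
(default 0.9) below which coordinates are masked, never silently kept.

The classifier's feature vector for a focal animal is the distance from
its head to the partner's head, pronotum and abdomen tip, divided by a
normalising body length — by default the pair's mean, so that pairs of
different species and sizes are comparable (for the packaged fossil
stand-in, the mean of 6.5 and 5.5 mm). Features are centred and scaled to
unit variance before both the PCA (correlation-style; the three distances
have unequal spreads) and the unregularised logistic fit of
leader-vs-follower. Each snapshot individual is scored independently as
focal; the two probabilities are deliberately not constrained to be
complementary, since each uses different features. Perfect separation of
training classes — expected when training on clean synthetic tandems — is
tolerated with a warning: coefficients stop at the glm convergence
tolerance, and predicted probabilities saturate accordingly.

## What the generator emulates (and what it does not)

`synth_params()` fixes the study conditions; the defaults are chosen once:

| parameter | default | rationale |
|---|---|---|
| `leader_speed_mean_bl_s`, `leader_speed_sd` | 2.0, 0.5 BL/s | natural tandem speeds of the reference termite |
| `turn_sd_rad` | 0.3 rad/√s | tortuous but persistent search paths |
| `contact_dist_bl` | 1.0 BL | centroid-to-centroid formation offset; places the follower's head at the leader's abdomen tip given the landmark proportions |
| `follower_gain` | 0.8 /step | stable pursuit without oscillation |
| `trap_speed_factor` | 0.03 | trapped speed ≈ 3% of natural (0.06 BL/s) |
| `escape_hazard_per_min` | 0.0212 | two independent exponentials give a both-trapped fraction of ≈0.65 at 10 min |
| `heading_mix_w` | 0.5 | settled partners parallel or antiparallel with equal odds |
| `pos_noise_sd_mm` | 0 | centroid trackers are smooth at this scale; opt-in |
| `posture_noise_sd_mm` | 0.4 mm | landmark error of pose estimation plus within-body posture variation |
| `body_length_f_mm`, `body_length_m_mm` | 8.0, 7.5 | typical dealate sizes of the reference species |
| `proportions` | head 0.1, pronotum 0.3, tip 1.0 | landmark positions along the body axis; centroid at 0.5 |
| `fps`, `duration_s` | 30, 1800 | entrapment recordings: 30 FPS, ≥20–30 min (natural recordings use 25 FPS) |

The natural tandem is a correlated random walk (truncated-normal step
speeds, Gaussian heading increments) pursued by a follower with
proportional gain toward the formation point one body length behind the
leader's centroid. The pursuit is deliberately uncapped: real followers
briefly sprint to re-establish contact, and the discrete pursuit corner-cuts
a swinging target, so the sex-pooled natural speed sits a little above the
leader's mean (the leader's own speed recovers the configured parameter
exactly). Simulation must run at a native rate (tens of FPS): the pursuit
lag scales with step size, so "simulating at 1 FPS" is degenerate by
design — simulate at native rate, then `downsample()`.

Entrapment adds an 80 mm sticky patch centred in a 221×114 mm arena. The
approach steers the leader's heading weakly toward the patch so every
simulated event reaches it (an event-selection device, not a behavioural
claim). An animal entering the patch is not held instantly: the leader
advances 12 mm past the boundary — enough to drag the follower onto the
patch — before sticking for good. Stuck animals keep their body
orientation (turning damped by the trap factor) while their centroid
jitters at the trapped speed around the sticking point, with slowly mixing
jitter direction. The follower, once the leader is stuck, makes for a
settling slot displaced 0.45 BL rearward and 0.15 BL sideways (about half
a body width) from the leader: bodies side-by-side, follower head next to
the leader's abdomen region. This geometry is what preserves the
head-to-tip asymmetry (`d_fTip_mHead` ≪ `d_fHead_mTip` for a female-led
pair) that survives entrapment, while collapsing the centroid distance
well below the 1-BL tandem formation. Escapes are independent
exponentials per individual; the recording is truncated at the first
escape and survivors are right-censored.

Skeleton postures place head/pronotum/tip collinearly on each animal's
heading axis at the configured proportions, plus isotropic landmark noise.

What the generator does **not** emulate: wall-following and arena boundary
effects in natural recordings, pausing/re-pairing dynamics of interrupted
tandems, gradual (rather than threshold) adhesion, body bending (real
trapped termites writhe; our skeletons stay straight apart from noise),
and any sensory mechanism. Passing tests therefore show that the analysis
recovers the statistical signatures the generator encodes — not that real
termites obey the generator.

## Numerical and interface choices

- Frame indices are 0-based; `downsample()` keeps every `fps/target`-th
  frame and renumbers them consecutively so the frame/fps clock stays
  consistent; entry/escape frames map to the next kept frame.
- `trapped_counts()` treats an observed escape as settling an event's
  status at all later times, drops events whose censored recording is
  shorter than the query time, and allows two frames of slack so a
  recording of exactly *t* minutes is not lost to resampling round-off.
- The exact rank-sum enumerates assignments when $n_1+n_2 \le 20$ and
  there are no ties; tied data in exact mode is a refusal unless midrank
  enumeration is requested explicitly; otherwise a normal approximation
  with continuity correction. Two-sided p doubles the smaller tail, capped
  at 1. The Mann–Whitney count is computed via midranks in
  $O(n \log n)$.
- Derangements are drawn by rejection (acceptance probability
  $\to e^{-1}$); ensembles, simulations and the pipeline are fully
  deterministic given their seeds, with sub-seeds derived from the
  configuration seed by fixed offsets.
- Degenerate inputs are hard errors, not silent repairs: one-sex events,
  non-monotone frames, zero-variance paired differences, unresolvable
  headings, empty density maps, single-event nulls.

## Problem sizes

The test suite exercises the calibration study at 100 seeded runs of 10
independent pairs × 120 s and the direction-of-effect study at 20 seeded
ensembles of 20 trapped events × 300 s, both at 5 FPS; classifier recovery
uses 8 events × 120 s. `scripts/acceptance.R` runs the full pipeline at
the study scale (27 natural events at 25 FPS, 26 trapped events at 30 FPS,
30 min each, 1,000 null replicates). These sizes are the package's own
choices balancing Monte-Carlo error against run time; all reported
quantities are computed fresh at run time.

## Known limitations

The null realigns males only (females are the reference frame), scopes to
one condition, and truncates unequal lengths to the shorter series;
time-shuffling or rotation nulls are out of scope. The classifier is a
three-feature logistic model — adequate for the strongly structured
geometry of tandems, but probabilities saturate when training classes
separate, so extreme scores for far-from-cloud snapshots should be read as
"outside the training cloud", not as calibrated certainty. Real-data
conclusions require the real trajectories and postures; the packaged
snapshot is a clearly labelled synthetic stand-in.
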