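---
title: "Methods: geometry, rater models and design choices in shapecat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometry, rater models and design choices in shapecat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapecat)
```

`shapecat` measures how people generalize object categories from a single
exemplar drawing. This vignette documents the package's models and the
decisions behind them: the contour conventions, each analysis stage's
procedure and assumptions, the rater noise models in the synthetic-data
generator, and the numerical choices (tolerances, tie-breaks, degenerate
cases) that a user extending the package needs to know.

## Contour conventions

A drawing is a **closed contour**: an ordered circular list of 2D points in
screen coordinates with the y axis pointing down, first point not repeated.
On construction the order is normalized so traversal is clockwise as seen
on screen (equivalently, the mathematical y-up shoelace area of the stored
order is positive). All cross-shape analyses operate on contours resampled
to a standard **360 points** by linear arc-length interpolation; 360 gives
roughly one point per degree of a typical blob and keeps the quadratic
geometry checks (self-intersection, pairwise clearance) affordable.
Resampling starts at the original first point, so repeated resampling is
idempotent. Zero-perimeter input is an error, not a silent NaN.

Segments of a contour are **half-open circular index ranges**
(`start`, `length`): two complementary chord-cut segments partition the
point set exactly, and the polygon belonging to a segment adds the chord's
far endpoint. A chord is admissible only if the straight line between its
endpoints stays inside the polygon — checked by edge-intersection tests
plus interior probes at three points along the chord, mirroring the rule
the part-picking interface enforced.

### Straightness

Two notions of "drawn straight" exist and the package keeps them separate.
When a contour carries **stroke metadata** (the drawing app recorded
whether each segment was made in freehand or straight-line mode), the
straight fraction is the arc-length share of straight-mode edges. Without
metadata, a **geometric classifier** is used: a point is straight when the
total absolute turning angle over a ±k window (default `window = 3`,
i.e. 7 vertices) is below `theta_deg` = 1 degree per vertex, strictly.
Neither is asserted to be the "true" definition; the recorded mode takes
precedence when present.

Two caveats are worth recording. First, at 360 points every *convex* shape
has a mean turn of exactly 1°/vertex, so the default threshold sits exactly
at the knife edge for a circle; the comparison subtracts a relative guard
of 1e-9 so an exact 360-gon circle classifies as fully curved rather than
flipping on round-off. Second, each sharp corner excludes a full window of
2k+1 points, so a polygon with m corners cannot score above 1 − 7m/360 at
the defaults; a square resampled to 360 points scores ≈ 0.92 (and ≥ 0.95
only with `window = 1`). This is why the synthetic generator's class
contract (polygonal ≥ 0.9, curved ≤ 0.1) is carried by stroke metadata —
see below — while the geometric classifier is validated on canonical
fixtures (square, circle, stadium) where the analytic answer is known.

## Synthetic-data generator

The generator is first-class, tested code: it emulates the *structure* of
the drawing study so every analysis stage can be exercised against known
ground truth.

**Shapes are radial functions.** An exemplar is a main body — a convex
polygon (polygonal class) or a low-frequency radial Fourier blob (curved
class) of base radius 100 drawing units — with 0–5 **parts** added as
radial bumps (positive) or notches (negative) over disjoint angular spans.
Because the radius stays positive and single-valued, every generated shape
(including its radially warped variations) is star-shaped and therefore
guaranteed simple; no rejection sampling is needed on the hot path, and
part spans map exactly to index ranges on the resampled contour via the
polar angle. The cost is a restricted shape family: no bent limbs, spirals
or occluding parts (see Limitations). Each part carries a ground-truth
distinctiveness weight in [0, 1], increasing with bump height — the
assumption being that taller protrusions are more salient.

**Stroke metadata by class.** Drawers of polygonal categories are modelled
as using the interface's straight-line mode throughout, curved categories
as freehand. This is a statement about recorded drawing *mode*, not local
geometry, which is exactly the distinction the straightness analysis
preserves.

**Variations.** A variation spec holds a drawer id, a strategy subset of
{warp, shuffle, add, omit, substitute}, a warp magnitude in [0, 1], a
cyclic permutation for shuffles, and its own seed. Assembly edits the
exemplar's construction table (drop / replace / insert / permute parts
across the clockwise slot order), then applies a smooth radial warp
`r(θ) ← r(θ)(1 + 0.35·m·g(θ))` with `g` a normalized 3-harmonic field —
order-preserving, as a warp should be. A zero-magnitude, empty-strategy
spec reproduces the exemplar bit for bit. Ground truth recorded per
variation: retained label spans, the permutation, omitted / added /
substituted label lists, and a scalar **deviation magnitude** = normalized
mean point displacement after optimal rigid (Kabsch) alignment, plus 0.15
per part change, capped at 1. The default cohort is the study layout:
8 exemplars × 17 drawers × 12 variations = 1632 drawings, with drawer warp
levels laddered over [0.12, 0.72] so a stable creativity ordering exists to
recover.

**Rater models** (all parameters surfaced as arguments):

- *Similarity placements*: `x = x_exemplar + scale_r · max(m + ε, 0.001)`
  with rater-specific axis scale and offset and Gaussian noise ε
  (sd = `noise`, default 0.05 magnitude units). Monotone in the true
  magnitude at zero noise, affine-invariant after normalization.
- *Classification*: correct with probability 1 − `confusability`
  (default 0.1), otherwise uniform over the other categories.
- *Correspondence picks*: for each part label retained in both shapes, a
  chord bracketing the ground-truth span, widened minimally until
  admissible; adjacent parts merge into one pick with probability
  `bundling`; same-category trials close with a rest-of-shape (body to
  body) pair with probability `rest_pick_rate` (default 0.4); spurious
  cross-category picks occur at `cross_pick_rate` (default 0.15). Deep
  notches can have no admissible bracketing chord (the chord would cross
  the notch mouth); such parts are skipped, exactly as the real interface
  would have prevented the pick.
- *Paintings*: tier 1 on the highest-weight span with boundary jitter
  (sd = `jitter` × span length), tiers 2–3 on the next-ranked spans with
  probabilities `tier_p`; tiers never overlap and tier 1 is always present.
  Shapes without parts get tier 1 at the highest-curvature stretch
  (smoothed turning angle), modelling the observation that raters agree on
  *something* even for part-less shapes — without this, part-less
  categories would have no consensus distinctive region and the swap
  design could not fill.

What the generator does **not** emulate: visual resemblance to the study's
hand-crafted exemplars, human drawing kinematics, semantic associations,
or any quantitative model of drawer behaviour (none is published). Passing
tests therefore show that the *analysis chain* is correct and recovers
planted structure; they do not validate claims about human data.

## Similarity space

Per rater and category, placements normalize to
`|x − x_exemplar| / max |x − x_exemplar|`, i.e. 0 at the exemplar and 1 at
the rater's most-distant shape, which removes the rater's private axis
scale. Normalization is per full session (the alternative, per trial, is
not implemented). Scores average across raters with unbiased between-rater
variance; missing shapes average over the raters that placed them. The
**creativity index** is a drawer's mean score; the **order trend** is OLS
of score on drawing index 1–12 (fewer than 3 points is flagged degenerate,
constant response reports slope 0 and R² = 0 rather than NaN).

**Spanning subsets** divide [0, 1] into `n_bins` *equal-width* bins —
"equally sized" read as equal width, since the goal is spanning the
similarity space — and pick per bin the unused shape with minimal
between-rater variance (ties: lexicographically smallest id). Empty bins
search neighbours at distance +1, −1, +2, −2, … (above before below, an
arbitrary but fixed choice the tests pin down) and may remain unfilled.

## Correspondence and part order

Picks resolve to segments via chord cuts; side 1 is the segment starting
at the chord's first index. The **per-point field** assigns each variation
point the exemplar segment that included it most often across raters
(modal vote over identical segments; the first-counted wins ties) and
colours it by that segment's *circular median* point — the point at half
the segment's length, resolved toward the lower index for even lengths.
Support is the number of distinct raters covering the point.

**Area fractions** sum picked part polygons per rater and trial (picks are
non-overlapping by the interface rule, so the union is the sum; a
rest-of-shape pick covers everything remaining, giving fraction 1), then
average raters within trial and trials within condition — rater-then-trial
averaging, one of two orders the procedure leaves open. Trials with
unresolvable picks are excluded and reported, never silently dropped.

**Part circles** scan the contour clockwise from the left-most point
(ties: minimum x, then minimum y, then lowest index) and run-length merge
labels and gaps, cyclically. Rest-of-shape picks are excluded from circles:
they are not localized parts, and a catch-all pick would otherwise
fabricate order information. Order comparison drops gaps, requires unique
shared labels, and is undefined at ≤ 2 shared labels (the circle `[A,B]`
equals `[B,A]`); otherwise the variation's shared-label sequence is tested
against all rotations of the exemplar's (identical), of its reversal
(reversed), else shuffled.

**Gap changes**: for each interval between consecutive shared labels in
the exemplar's cyclic order, "a gap at the same spot" is operationalized
as *any non-shared entry (gap marker or unshared label) in the interval
following the same shared label on both circles* — exemplar-only gap =
omission, variation-only = addition, both = substitution. Two consequences
are deliberate and documented: non-shared labels count as gaps (an
unmatched part *is* non-corresponding material), and circles that include
body gaps between every pair of parts (as pick-derived circles do when
raters never pick the body) classify every interval as substitution. For
part-change recovery against generator ground truth the package therefore
offers `ground_truth_circle(..., include_body_gaps = FALSE)`, the
idealized circle holding only part labels, in which planted omissions,
additions and substitutions come back exactly.

## Distinctiveness

Painting tiers 1/2/3 carry weights 3/2/1; point scores sum over raters and
normalize to 0–100 with "highest possible score" read literally as
3 × n_raters — so 100 is attained iff every rater paints the point tier 1,
not merely at the observed maximum. Threshold comparisons are strict
(score > 75, "higher than 75"). The headline perimeter statistic uses the
**largest** consecutive high region per shape by default ("mean
consecutive area" being ambiguous between largest and total); both modes
are exposed. On equally resampled contours the arc-length share equals the
point-count share, which is what is computed.

The **randomized null** estimates, per tier and category, the empirical
distributions of tier usage, consecutive run lengths, and number of
non-consecutive areas per painting, then samples paintings with those
extents but uniformly random placement, rejecting overlaps (50 retries per
run, then fresh lengths, with exhaustions counted). Tier 1 is always
present, mirroring the interface. Tiers are treated independently except
for the within-rater non-overlap constraint. Human-versus-null agreement
compares per-shape high-region fractions with `stats::ks.test` (exact p
for small samples, asymptotic otherwise).

## Part-swap synthesis

The **distinctive part** is the longest maximal run strictly above 75
(ties: higher mean score, then lower start). The **indistinctive window**
has exactly the distinctive part's point count — hence, on equally spaced
contours, the same perimeter share, the study's control — and minimal mean
score among windows avoiding the distinctive part (ties: lowest start).
Donor parts for insertion come from the donor *exemplar's* field.

Transplantation solves the two-point similarity transform (in complex
form, `z ↦ a·z + b`) mapping the donor part's endpoints *exactly* onto the
recipient points flanking the gap; an exact endpoint fit is one reading of
"fit the gap as best as possible" (a least-squares fit over all part
points is the other; exactness was chosen for its invertibility and
testability). Of the two mirror solutions the one pointing outward is
kept, chosen as the candidate maximizing the resulting polygon's area —
chirality handling the original procedure leaves unstated. All recipient
points outside the gap are preserved exactly before the final resampling
back to 360 points.

Screening replaces the study's manual curation with a deterministic proxy:
a stimulus passes iff it is a simple polygon and no two non-adjacent
points come closer than half the mean point spacing. Candidate bases are
consumed in seeded order until each of the 8 × 7 × 2 cells holds 5
passing stimuli; shortfalls are reported per cell, never padded.

The simulated observer for swap stimuli is a cue mixture keyed to ground
truth: lapse (uniform guess, p = 0.12), else follow the distinctive-part
cue with probability 0.55 (which points to the donor category when the
distinctive part was swapped), else the body cue (misread with p = 0.25
when an indistinctive swap altered the body). These defaults were chosen
once to place unswapped accuracy near the high-80s and enforce, by
construction, the qualitative ordering unswapped > indistinctive-swapped >
distinctive-swapped that the swap logic is meant to produce; the tests
check the ordering, not the absolute values.

## Statistics

Exact one-sided binomial tests use the upper tail `P(X ≥ K)` (lower tail
for below-chance cells); confusion matrices test every cell against 1/8,
upper or lower according to the observed direction, at a per-cell alpha
defaulting to the family alpha divided by the number of outcomes per row
(0.05/8 = 0.00625). A differently adjusted alpha (such as 0.015) can be
supplied explicitly but is never silently substituted. The binomial
sample-size calculator reports the normal-approximation formula
`n = ⌈((z₁₋α√(p₀q₀) + z₁₋β√(p₁q₁))/(p₁−p₀))²⌉` as the headline value —
this is the arithmetic that yields 3197 for detecting 15% over a 12.5%
chance level at α = 0.00625, power 0.95 — alongside an exact-binomial
search reported for comparison, never substituted. The *t* calculator
iterates noncentral-*t* power over the per-group size; 1084 for d = 0.2,
α = 0.05, power 0.95 is consistent only with a *two-sample* equal-group
reading (542 per group), which is therefore the default design.
`power.t.test` serves as an independent cross-check in the tests, not as
the implementation.

## Pipeline and reproducibility

`run_experiment()` chains the stages for each simulated experiment from a
single `run_config`. One master seed fans out to per-stage child seeds
through a fixed linear scheme (`child_seed`), so stages are independently
reproducible and identical configs give identical reports; all derived
seeds stay below 2³¹. Datasets serialize to a directory of contour JSON
files plus CSV response tables, with 1-based in-memory indices converted
to 0-based on disk at the I/O boundary, and `validate_dataset()` checks
contour well-formedness, referential integrity and the tier-1 painting
rule, reporting findings rather than raising. The exported functions,
this vignette and `scripts/acceptance.R` are the package's interface; no
separate command-line binary is shipped.

The test suite runs the full default cohort (1632 drawings) and the full
560-stimulus swap design once, in the acceptance tests; unit tests use
scaled-down cohorts (3–4 categories, 3–6 drawers) chosen to keep each
property readable and the whole suite quick, while the property sizes the
acceptance tests use (500 order-recovery trials, 100 oracle instances,
10,000 Monte-Carlo and null-painting replicates) were fixed in advance as
the package's standard evidence levels.

## Known limitations

- The shape family is star-shaped by construction; analyses accept
  arbitrary simple polygons, but the generator cannot plant ground truth
  in non-radial geometry (bent parts, occlusions).
- The geometric straightness classifier is scale-coupled: at 360 points
  its 1°/vertex threshold coincides with the mean turning of any convex
  contour, so it separates polygons from curves only when curvature is
  concentrated (corners) or sustained (arcs), not for near-circular blobs.
- Gap-change classification is interval-based; it cannot distinguish a
  substitution from an omission plus a nearby addition within the same
  interval.
- The randomized painting null matches run extents per tier independently;
  it does not preserve cross-tier adjacency patterns of human paintings.
- Simulated raters are independent given the ground truth; there is no
  shared bias structure across raters.
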