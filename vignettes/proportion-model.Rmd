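---
title: "The proportion model: quantifying indel and substitution variants from mixed Sanger traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The proportion model: quantifying indel and substitution variants from mixed Sanger traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracemix)
```

## The problem

A eukaryotic genome carries tens to thousands of rDNA repeat units, and
concerted evolution does not fully homogenize them.  When the internal
transcribed spacers (ITS1, ITS2) of such a multicopy gene are PCR-amplified
from one individual and Sanger-sequenced directly — without cloning — the
electropherogram superposes every template variant present in the genome.
Substitution variants show up as double peaks at single positions.  Length
variants are worse: an indel shifts *every* downstream peak of that
molecule's trace out of frame, so from the indel site onward the trace is a
mixture of frame-shifted copies of nearly the same sequence.

`tracemix` quantifies both kinds of variant from a single direct trace, and
assembles the results into a per-individual **ITS profile** — the table of
length-variant percentages, substitution percentages and per-site deletion
fractions that characterizes an individual's rDNA pool and can be compared
across individuals (for the freshwater sponge system the package is built
around, specimens of the same strain have near-identical profiles).

## The model

### Intrinsic intensities

The peak height of a base in a Sanger trace is not arbitrary: it depends
reproducibly on the bases that precede it.  Sequencing a modest number of
clones of the (nearly identical) template therefore measures, per aligned
position $i$, an **intrinsic (expected) intensity** $E_i$: the mean of the
clones' called-channel intensities at $i$ after each run is normalized to a
common scale.  Runs are normalized so the mean called-channel intensity
over the read is 1000 units (clone reads), or so the mean per-position sum
of the four channel *window maxima* is 1000 units (direct reads — in a
mixture, minor peaks need not crest exactly at the call point, so each
channel is represented by its maximum over a 5-scan window around the call
point, and all four channels carry real signal).

With 48 clones the relative standard deviation of the normalized
intensities is about 5% per position; this spread is the error floor of the
method and motivates its permitted error rates (5 percentage points for
length variants, which pool hundreds of positions, and 10 for
substitutions, which use a single position).

### Superposition of shifted frames

Let a homopolymer track start at position $a$, and let variant $v$ change
the track length by $s_v$ (deletion negative).  At observed position
$i \ge a$, variant $v$ displays the reference base of position $i - s_v$:
a deletion pulls the downstream sequence forward, an insertion pushes it
back.  A mixture with proportions $p_v$ therefore produces the expected
signal

$$M_{i,b}(p) \;=\; \sum_v p_v \, E_{i - s_v}\,
  \mathbf{1}\!\left[ b = b^{\mathrm{ref}}_{\,i - s_v} \right],
  \qquad i \ge a,$$

with all variants contributing identically upstream of the track.  This is
`simulate_mixture()`, and it is linear in $p$.

### Fitting

`fit_proportions()` searches the simplex of proportions exhaustively on a
grid (1% by default; coarse-to-fine 5% → 1% above three variants) and
scores each candidate against the observed direct read by least squares
over all (position, base) pairs of a window that starts at the indel site
and spans at least 200 positions:

$$\hat p \;=\; \arg\min_p \sum_{i \in W}\sum_{b}
  \left( I_{i,b} - c(p)\, M_{i,b}(p) \right)^2 ,$$

where $c(p)$ rescales the simulated signal so its mean per-position sum
over $W$ matches the observed one (both sides are then on the same
1000-unit scale).  Ties break toward fewer nonzero variants, then
lexicographically.  For two-variant fits the minimum is additionally
refined by parabolic interpolation between adjacent grid points and
reported to 0.01% (`percent_interpolated`); the long window is what makes
this sub-grid precision meaningful.

The objective is a design choice: the base-resolved residuals are what
distinguish frames from one another, while position sums are already
consumed by normalization.  A least-squares score over window intensities
is the simplest objective with the right invariances; it is exact for
noiseless grid-aligned mixtures (verified exhaustively in the tests) and
its recovery error shrinks monotonically with window length.

### Substitutions

At a clean (unshifted) position, the fraction of molecules carrying base
$X$ rather than $Y$ is estimated from the two peak heights corrected by
their intrinsic expectations,

$$f_X = \frac{I_X / E_X}{I_X/E_X + I_Y/E_Y},$$

which reduces to the raw peak-height ratio when $E_X = E_Y$.  Results are
always rounded to integer percentages — one position's signal does not
support more precision.  When no clone carries the minor base, its
intrinsic expectation falls back to the consensus base's value at that
position (channel equivalence), which is the exact correction's
first-order surrogate.

Inside a frame-shifted mixed region (`quantify_substitution_mixed()`), the
substituted reference coordinate $q$ is displayed at the observed
coordinates $q + s_v$ of the fitted variants.  The expected background at
those coordinates is simulated from the fitted mixture; the substitution
candidate is the base with the largest positive total excess over
background, and its fraction is that excess divided by the total expected
signal mass of coordinate $q$, i.e. $c \, E_q$ (the $p_v$ sum to one).
Summing the excess over all frames' coordinates makes the estimate
independent of how the substitution is distributed across the length
variants.

### Two deletion sites: the joint-length identity

When a region carries two single-nucleotide deletion sites more than a
window apart, each site is fitted from the read direction that reaches it
first, and the total-length distribution ties the two together exactly:
a molecule of length $L-2$ is deleted at both sites and one of length
$L-1$ at exactly one, so the expected per-site deletion fractions satisfy
$d_1 + d_2 = 2P(L-2) + P(L-1)$.  `infer_joint_site_proportions()` uses
this identity to recover the unmeasured site from the measured one.

### Thresholds and profiles

Length variants below 5% and substitutions below 10% are reported as 0
(`apply_thresholds()`); these thresholds come from the acceptable
electropherogram noise level.  Surviving values are *not* renormalized —
they are estimates, and published profiles of this kind visibly report raw
rounded values whose totals can fall just short of 100.  Reads whose noise
fraction (largest non-called channel over called channel, averaged across
a designated clean region) exceeds 10% are excluded from quantitative
analysis altogether (`assess_noise()`).

Profiles are compared feature-by-feature over the union of features
(absent = 0).  Two criteria for a "distinguishing feature" are
implemented: `"any"` (any nonzero difference after thresholding; the
default) and `"margin"` (the difference must exceed the permitted error
rate of the feature class — 5 points for length and deletion features, 10
for substitutions).  The two agree on strongly distinct profiles; the
margin criterion is the right reading when deciding whether two profiles
are *the same up to measurement error*, and it is what makes same-strain
profiles differ only in their genuinely different ITS2 length proportions.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| normalization target | 1000 | signal units | common scale across runs |
| call-point window | 5 | scan points | minor peaks crest off the call point |
| noise QC threshold | 0.10 | fraction | above it, quantification is unreliable |
| length detection threshold | 5 | percent | noise floor for length variants |
| substitution detection threshold | 10 | percent | single-position estimates are noisier |
| fit window | ≥ 200 (min 50) | positions | averages per-position 5% spread down to <1% |
| grid step | 0.01 (coarse 0.05) | proportion | matches reporting precision |
| calibration minimum | 3 | clones/position | below it a position is not fitted |
| clone divergence cap | 0.05 | fraction | outlier clones are rejected |

## Numerical choices and degenerate inputs

* Proportion vectors must sum to 1 within $10^{-6}$; grid compositions are
  exact rationals so sums are exact.
* Window positions whose shifted coordinate leaves the calibrated profile
  are dropped from the objective, never extrapolated; fewer than 50 usable
  positions is refused, fewer than 200 flagged.
* All-zero observed windows and zero-mean normalization regions raise
  degenerate-signal errors rather than producing NaNs.
* Population (not sample) SD is used for the intrinsic profile: it is a
  descriptive statistic of the full clone set.
* Clone alignment is exact under the package's constraint that indels
  occur only inside declared homopolymer tracks; gaps are canonically
  placed at the 3′ end of a track, and tie-broken substitution columns are
  assigned to the majority base (reference base on ties).
* Substitution percentages round half away from zero; the pair always
  sums to 100.
* Normalization warns below 30 region positions (the scale estimate gets
  noisy) instead of refusing, since tiny regions are legitimate in tests
  and toy analyses.
* User-facing coordinates are 1-based inclusive throughout ("position
  169" style); reverse-primer reads are complement-reversed onto the
  forward strand before any analysis.

Design points that were genuinely open, and the package's resolution:

* **Objective function.**  Nothing in the trace physics dictates a score;
  least squares on base-resolved window intensities was chosen for its
  exactness and monotonicity properties (above), with the position-sum
  variant available in principle but not exposed.
* **Per-direction profiles.**  Forward- and reverse-primer clone reads are
  calibrated into separate intrinsic profiles and each direct read is
  fitted against its own direction's profile; pooling directions would
  mix unrelated context effects.
* **Noise numerator.**  The QC noise fraction uses the maximum non-called
  channel (conservative) rather than the mean of the three, and window
  maxima rather than call-point values, since minor-peak displacement is
  precisely the phenomenon being guarded against.
* **Interpolated minima.**  Sub-grid precision is reported via parabolic
  interpolation rather than a finer grid; at 0.01 grid resolution the two
  are indistinguishable in practice and interpolation is 100× cheaper.

## The synthetic generator

Every stage of the package is testable without external data because the
generator (`generator_config()`, `make_reference()`,
`simulate_clone_read()`, `simulate_direct_read()`) produces traces with
known ground truth under a fixed seed:

* a ~0.9 kb amplicon with the four region-boundary motifs placed verbatim,
  a 254-nt ITS1 with a homopolymer T track at positions 177–179, and a
  323-nt ITS2 with T tracks at 10–13 and 246–247 — the geometry of the
  sponge system;
* a context model mapping each preceding 3-mer to a repeatable intensity
  in 600–1400 units (a deterministic hash — it reproduces
  *position-specific repeatable intensities* without modelling dye
  chemistry);
* 5% per-position multiplicative (lognormal) noise on clone reads, a
  configurable baseline channel noise floor, and direct reads built as the
  proportion-weighted superposition of each variant's own trace, with
  substitution truths splitting the called channel at their positions.

What it deliberately does **not** emulate: scan-level peak shapes (peaks
are rendered as isolated spikes when files are written, so window
extraction is exercised but mobility artefacts are not), Phred quality,
dye blobs, and polymerase slippage noise after long homopolymers.  One
realism feature it *does* include: intensities are computed from each
molecule's own sequence, so within $k-1 = 2$ bases downstream of a track
the generator and the reference-frame model disagree slightly.  The
induced bias on fitted proportions is of order $10^{-3}$ — far below the
grid — so noiseless recovery remains exact; it is also why a noiseless
end-to-end fit has a small nonzero objective.  Passing synthetic tests
therefore demonstrates the statistical machinery, not robustness to every
chromatogram artefact of real data; the noise-QC gate is the package's
defence against the latter.

Problem sizes used by the test-suite and the acceptance script, chosen to
mirror a realistic calibration while keeping runs quick: 48 clones at 5%
noise for calibration, a 917-nt amplicon, 100 seeded noisy fitting trials,
an exhaustive sweep of the 5% proportion grid (231 three-variant truths;
the test suite also sweeps all 1771 four-variant truths), and 20-seed
Monte-Carlo checks for the window- and noise-monotonicity properties.

## Known limitations

* Two indel sites per region at most, tied together by the joint-length
  identity; denser indel clusters would need a joint fit over composite
  shift states.
* Substitutions and length variants are quantified separately, not in one
  joint objective; a substitution falling exactly on a track edge is out
  of scope.
* Three-allele substitution positions are not modelled.
* Intrinsic profiles do not transfer across sequencing chemistries or
  machines; clones must be sequenced under the conditions of the direct
  reads they calibrate.
* Real AB1 direct reads must already be base-called against the dominant
  frame; the package does not re-call bases.

## A worked example

```{r example, eval = FALSE}
cfg <- generator_config(seed = 7, noise_sd = 0.05, baseline = 0, n_clones = 48)
ref <- make_reference(cfg)

clones <- lapply(1:48, function(i) simulate_clone_read(ref$amplicon, cfg,
                                                       seed = 100 + i))
names(clones) <- sprintf("c%02d", 1:48)
aln <- align_clones(vapply(clones, function(x) paste(x$call, collapse = ""),
                           character(1)),
                    ref$amplicon, indel_sites = unname(ref$tracks))
prof <- build_intrinsic_profile(lapply(clones, normalize_clone_read), aln)
profile_qc(prof)$mean_relative_sd   # ~0.05

mix <- list(shifts = list(c(ITS1 = -1L), c(ITS1 = 0L)),
            proportions = c(0.25, 0.75))
obs <- normalize_direct_read(
  simulate_direct_read(ref$amplicon, ref$tracks, mix, cfg, seed = 1))
v <- enumerate_variants(ref$amplicon, ref$tracks$ITS1, max_indel = 1)
fit_proportions(obs, prof, v,
                window = c(ref$tracks$ITS1[1], ref$tracks$ITS1[1] + 249))
```
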