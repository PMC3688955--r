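# tracemix

Quantifying length (indel) and substitution variants of a multicopy gene
from a single direct-Sanger electropherogram of the mixed amplicon.

## The problem

rDNA occurs in tens to thousands of copies per genome, and the copies are
not perfectly homogenized: the internal transcribed spacers (ITS1, ITS2)
of one individual typically exist as several sequence variants in
different proportions.  Direct Sanger sequencing of the uncloned PCR
amplicon superposes all of them into one trace.  Substitution variants
appear as double peaks; *length* variants are harder, because an indel
shifts every downstream peak of that molecule out of frame, turning the
rest of the trace into a mixture of frame-shifted copies of nearly the
same sequence.

`tracemix` is for anyone who needs the relative abundances of those
variants — e.g. to build per-individual **ITS profiles** and decide which
specimens are genetically similar enough to pool — without sequencing
hundreds of clones.

## The method

1. **Calibration.**  A set of clone reads, each normalized so its mean
   called-channel intensity is 1000 units, yields the *intrinsic
   (expected) intensity* `E[i]` of every position: peak heights are
   reproducible functions of the preceding sequence context (relative SD
   about 5% across 48 clones).
2. **The proportion model.**  A variant whose homopolymer track is changed
   by `s` nucleotides displays, at observed position `i` after the track,
   the reference base of position `i − s`.  A hypothesized mixture with
   proportions `p_v` therefore predicts the signal

   ```
   M[i, b](p) = Σ_v  p_v · E[i − s_v] · 1{ b = ref_base[i − s_v] }
   ```

   `fit_proportions()` grid-searches the simplex of proportions (1% grid,
   parabolic sub-grid refinement) minimizing the squared difference
   between `M(p)` and the observed window intensities over ≥ 200
   positions downstream of the indel site.
3. **Substitutions.**  At clean positions,
   `f_X = (I_X/E_X) / (I_X/E_X + I_Y/E_Y)` — peak heights corrected by
   intrinsic expectations.  Inside mixed regions, the residual of the
   observed trace over the fitted mixture background, summed across the
   frames' coordinates, quantifies the substitution.
4. **Profiles.**  Detection thresholds (5% for length variants, 10% for
   substitutions), a 10% noise QC gate, per-site deletion fractions via an
   exact two-site length identity, and feature-aligned profile comparison.

A synthetic-data module generates chromatograms with known ground truth
(context-dependent intensities, configurable noise, mixtures and
substitution truths), so the whole pipeline is testable end to end.

## A worked example

Calibrate from 48 synthetic clones, then deconvolve a direct read that
mixes a 1-nt-deletion variant (25%) with the reference (75%) under 5%
per-position noise:

```r
library(tracemix)
cfg <- generator_config(seed = 7, noise_sd = 0.05, baseline = 0, n_clones = 48)
ref <- make_reference(cfg)

clones <- lapply(1:48, function(i)
  simulate_clone_read(ref$amplicon, cfg, seed = 100 + i))
names(clones) <- sprintf("c%02d", 1:48)
aln <- align_clones(vapply(clones, function(x) paste(x$call, collapse = ""),
                           character(1)),
                    ref$amplicon, indel_sites = unname(ref$tracks))
prof <- build_intrinsic_profile(lapply(clones, normalize_clone_read), aln)
profile_qc(prof)$mean_relative_sd
#> [1] 0.049

mix <- list(shifts = list(c(ITS1 = -1L), c(ITS1 = 0L)),
            proportions = c(0.25, 0.75))
obs <- normalize_direct_read(
  simulate_direct_read(ref$amplicon, ref$tracks, mix, cfg, seed = 1))
v <- enumerate_variants(ref$amplicon, ref$tracks$ITS1, max_indel = 1)
fit_proportions(obs, prof, v,
                window = c(ref$tracks$ITS1[1], ref$tracks$ITS1[1] + 249))
#> <mixture_estimate>
#>   916 nt:  25.00%
#>   917 nt:  75.00%
#>   918 nt:   0.00%
#>   objective 5.839e+05 over positions 217-466 (grid 0.01)
```

The labels are total variant lengths (reference amplicon 917 nt); the
25/75 truth is recovered on the 1% grid.  A 35% substitution planted at
ITS1 position 169 (amplicon position 209) is recovered the same way:

```r
pos <- 40 + 169  # ITS1 position 169 in amplicon coordinates
obs2 <- normalize_direct_read(
  simulate_direct_read(ref$amplicon, ref$tracks,
                       list(shifts = list(c(ITS1 = 0L)), proportions = 1),
                       cfg,
                       substitutions = list(list(pos = pos, to = "A",
                                                 fraction = 0.35)),
                       seed = 2))
quantify_substitution(obs2, prof$mean[pos], prof$mean[pos], pos, c("A", "C"))
#> <substitution_call> position 209: A 36% / C 64% (clean)
```

integer-rounded, as single-position estimates warrant.  The package also
ships the published run tables of the sponge study system under
`tracemix_example()` — replicate PCR conditions, within-individual site
samples, and the ITS1/ITS2 profiles of the strain-comparison specimens —
which the profiling statistics (`replicate_stats()`,
`infer_joint_site_proportions()`, `count_distinguishing_features()`)
operate on directly.

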