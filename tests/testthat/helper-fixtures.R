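# Shared fixtures, built in code and memoized per test run.

`%||%` <- function(a, b) if (is.null(a)) b else a

.tm_cache <- new.env(parent = emptyenv())

# noiseless reference world: amplicon, clone alignment, exact profile
tm_clean_world <- function() {
  if (!is.null(.tm_cache$clean)) return(.tm_cache$clean)
  cfg <- generator_config(seed = 7, noise_sd = 0, baseline = 0,
                          n_clones = 8)
  ref <- make_reference(cfg)
  clones <- lapply(seq_len(cfg$n_clones), function(i)
    simulate_clone_read(ref$amplicon, cfg, seed = 100 + i))
  names(clones) <- sprintf("c%02d", seq_along(clones))
  reads <- lapply(clones, normalize_clone_read)
  seqs <- vapply(clones, function(x) paste(x$call, collapse = ""),
                 character(1))
  aln <- align_clones(seqs, ref$amplicon, indel_sites = unname(ref$tracks))
  prof <- build_intrinsic_profile(reads, aln)
  .tm_cache$clean <- list(cfg = cfg, ref = ref, prof = prof, aln = aln,
                          reads = reads)
  .tm_cache$clean
}

# 48 clones with 5% multiplicative noise, as in a real calibration set
tm_noisy_world <- function() {
  if (!is.null(.tm_cache$noisy)) return(.tm_cache$noisy)
  cfg <- generator_config(seed = 11, noise_sd = 0.05, baseline = 0,
                          n_clones = 48)
  ref <- make_reference(generator_config(seed = 7))  # same amplicon as clean
  clones <- lapply(seq_len(cfg$n_clones), function(i)
    simulate_clone_read(ref$amplicon, cfg, seed = 2000 + i))
  names(clones) <- sprintf("c%02d", seq_along(clones))
  reads <- lapply(clones, normalize_clone_read)
  seqs <- vapply(clones, function(x) paste(x$call, collapse = ""),
                 character(1))
  aln <- align_clones(seqs, ref$amplicon, indel_sites = unname(ref$tracks))
  prof <- build_intrinsic_profile(reads, aln)
  .tm_cache$noisy <- list(cfg = cfg, ref = ref, prof = prof)
  .tm_cache$noisy
}

# hand-constructable containers for toy arithmetic tests ---------------------

toy_profile <- function(means, bases) {
  stopifnot(length(means) == length(bases))
  structure(data.frame(ref_pos = seq_along(means), base = bases,
                       mean = means, sd = 0, n = 3L, calibrated = TRUE),
            class = c("intrinsic_profile", "data.frame"), min_clones = 3L)
}

toy_table <- function(point, win = point, call = NULL) {
  stopifnot(identical(colnames(point), c("A", "C", "G", "T")))
  n <- nrow(point)
  call <- call %||% rep("A", n)
  data.frame(call = call,
             point_A = point[, "A"], point_C = point[, "C"],
             point_G = point[, "G"], point_T = point[, "T"],
             win_A = win[, "A"], win_C = win[, "C"],
             win_G = win[, "G"], win_T = win[, "T"])
}

toy_observed <- function(win, call = NULL, read_type = "direct") {
  tab <- toy_table(win, win, call)
  structure(tab,
            class = c("normalized_signals", "call_point_table",
                      "data.frame"),
            scale_factor = 1, read_type = read_type,
            direction_normalized = TRUE)
}

toy_norm_clone <- function(called_values, call) {
  win <- matrix(0, length(call), 4L,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  win[cbind(seq_along(call), match(call, c("A", "C", "G", "T")))] <-
    called_values
  toy_observed(win, call, read_type = "clone")
}

# independent brute-force superposition oracle for simulate_mixture
oracle_mixture <- function(profile, shifts, p, positions, track_start) {
  m <- matrix(0, length(positions), 4L,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  for (k in seq_along(shifts)) {
    for (ii in seq_along(positions)) {
      i <- positions[ii]
      j <- if (i < track_start) i else i - shifts[k]
      if (j >= 1 && j <= nrow(profile)) {
        b <- profile$base[j]
        m[ii, b] <- m[ii, b] + p[k] * profile$mean[j]
      }
    }
  }
  m
}

# observed direct read ready for fitting, from the generator
tm_direct_obs <- function(world, mixture, substitutions = list(),
                          seed = 1, noise_sd = NULL, baseline = NULL) {
  cfg <- world$cfg
  if (!is.null(noise_sd)) cfg$noise_sd <- noise_sd
  if (!is.null(baseline)) cfg$baseline <- baseline
  rd <- simulate_direct_read(world$ref$amplicon, world$ref$tracks, mixture,
                             cfg, substitutions = substitutions,
                             seed = seed)
  normalize_direct_read(rd)
}
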