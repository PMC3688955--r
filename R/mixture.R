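# The proportion model: simulate expected direct-read signals for
# hypothesized mixtures of length variants and fit their proportions to an
# observed direct read.
#
# A variant whose homopolymer track is shortened by s nucleotides (shift
# s < 0) displays, at observed position i at/after the track start, the
# reference base at position i - s (a deletion pulls the downstream
# sequence forward; an insertion pushes it back).  The observed mixed trace
# is the proportion-weighted superposition of these shifted copies of the
# intrinsic profile.

#' Enumerate length variants around a homopolymer indel site
#'
#' @param reference reference sequence of the region being analysed (its
#'   length labels the shift-0 variant).
#' @param indel_site `c(start, end)` coordinates of the homopolymer track
#'   within `reference`.
#' @param max_indel largest insertion/deletion size to enumerate.
#' @param region_label optional label (e.g. `"ITS1"`).
#' @return a `length_variant_set`: list with `indel_site`, `track_base`,
#'   `shifts` (every shift in `-max_indel:max_indel` keeping the track
#'   length non-negative), `labels` (resulting region length, as character),
#'   `ref_length`, `region_label`.
#' @export
enumerate_variants <- function(reference, indel_site, max_indel,
                               region_label = NA_character_) {
  ref <- seq_chars(reference)
  a <- as.integer(indel_site[1]); b <- as.integer(indel_site[2])
  if (a < 1L || b > length(ref) || a > b)
    stop_tm("indel_site outside the reference",
            class = "tracemix_parameter_error")
  base <- unique(ref[a:b])
  if (length(base) != 1L) {
    warning("indel site is not a homopolymer run; enumerating anyway")
    base <- ref[a]
  } else {
    maximal <- (a == 1L || ref[a - 1L] != base) &&
      (b == length(ref) || ref[b + 1L] != base)
    if (!maximal)
      warning("indel site is not a maximal homopolymer run")
  }
  run <- b - a + 1L
  if (max_indel > run)
    warning("max_indel exceeds the track length; deletions capped")
  shifts <- seq.int(-max_indel, max_indel)
  shifts <- shifts[shifts >= -run]
  structure(list(indel_site = c(a, b), track_base = base, shifts = shifts,
                 labels = as.character(length(ref) + shifts),
                 ref_length = length(ref), region_label = region_label),
            class = "length_variant_set")
}

#' @export
print.length_variant_set <- function(x, ...) {
  cat(sprintf("<length_variant_set> %s-track at %d-%d, shifts %s (labels %s)\n",
              x$track_base, x$indel_site[1], x$indel_site[2],
              paste(x$shifts, collapse = ","),
              paste(x$labels, collapse = ",")))
  invisible(x)
}

# shifted reference coordinate displayed at observed position i by a
# variant with shift s: identity before the track, i - s from its start on
shifted_coord <- function(i, s, track_start) {
  ifelse(i < track_start, i, i - s)
}

# pure (single-variant) expected signal matrix over observed positions:
# value profile$mean[j], routed to channel profile$base[j], j = shifted coord.
# Positions whose shifted coordinate is uncalibrated get all-NA rows.
variant_signal <- function(profile, variants, shift, positions) {
  j <- shifted_coord(positions, shift, variants$indel_site[1])
  ok <- j >= 1L & j <= nrow(profile)
  m <- matrix(NA_real_, length(positions), 4L,
              dimnames = list(NULL, BASES))
  jo <- j[ok]
  good <- profile$calibrated[jo]
  rows <- which(ok)[good]
  jg <- jo[good]
  m[rows, ] <- 0
  m[cbind(rows, match(profile$base[jg], BASES))] <- profile$mean[jg]
  m
}

#' Simulate the expected direct-read signal of a variant mixture
#'
#' Superposes shifted copies of the intrinsic profile: each variant with
#' shift s contributes, at observed position i at/after the track start,
#' proportion x expected intensity of reference position i - s, on that
#' position's base; upstream of the track all variants contribute
#' identically.  Linear in the proportions.
#'
#' @param profile an `intrinsic_profile` of the reference.
#' @param variants a [enumerate_variants()] set.
#' @param proportions numeric vector over `variants$shifts` (optionally
#'   named by `variants$labels`), summing to 1 within 1e-6.
#' @param positions observed positions to simulate (default: the whole
#'   profile range); positions whose shifted coordinates leave the
#'   calibrated profile are returned as NA rows, never extrapolated.
#' @return a `mixture_signal`: list with `positions`, `signal` (positions x
#'   4 base channels), `position_sum`.
#' @export
simulate_mixture <- function(profile, variants, proportions,
                             positions = NULL) {
  p <- check_proportions(proportions, variants)
  positions <- as.integer(positions %||% seq_len(nrow(profile)))
  sig <- matrix(0, length(positions), 4L, dimnames = list(NULL, BASES))
  na_mask <- logical(length(positions))
  for (k in seq_along(variants$shifts)) {
    if (p[k] == 0) next
    m <- variant_signal(profile, variants, variants$shifts[k], positions)
    na_mask <- na_mask | is.na(m[, 1L])
    m[is.na(m)] <- 0
    sig <- sig + p[k] * m
  }
  sig[na_mask, ] <- NA_real_
  structure(list(positions = positions, signal = sig,
                 position_sum = rowSums(sig), proportions = p),
            class = "mixture_signal")
}

check_proportions <- function(proportions, variants) {
  if (!is.null(names(proportions))) {
    if (!setequal(names(proportions), variants$labels))
      stop_tm("proportion names must match the variant labels",
              class = "tracemix_parameter_error")
    proportions <- proportions[variants$labels]
  }
  p <- as.numeric(proportions)
  if (length(p) != length(variants$shifts))
    stop_tm("proportions must have one entry per variant",
            class = "tracemix_parameter_error")
  if (abs(sum(p) - 1) > 1e-6)
    stop_tm("proportions must sum to 1 (got ", format(sum(p)), ")",
            class = "tracemix_parameter_error")
  if (any(p < 0))
    stop_tm("proportions must be non-negative",
            class = "tracemix_parameter_error")
  p
}

# all k-part compositions of n (columns), as a k x choose(n+k-1, k-1) matrix
simplex_grid <- function(k, n) {
  if (k == 1L) return(matrix(n, 1L, 1L))
  cols <- lapply(0:n, function(i) rbind(i, simplex_grid(k - 1L, n - i),
                                        deparse.level = 0))
  m <- do.call(cbind, cols)
  dimnames(m) <- NULL
  m
}

#' Fit length-variant proportions to an observed direct read
#'
#' Exhaustive simplex grid search over the variant proportions: each
#' candidate mixture is simulated from the intrinsic profile, rescaled so
#' its mean per-position channel sum over the window matches the observed
#' one, and scored by the sum over window positions and bases of squared
#' differences against the observed window intensities.  For more than
#' three variants the search is coarse-to-fine (step 0.05, then
#' `grid_step` in a +/-0.05 box around the incumbent).  Ties break toward
#' fewer nonzero variants, then lexicographically by label.  For
#' two-variant fits the minimum is additionally refined by parabolic
#' interpolation between adjacent grid points (reported as
#' `percent_interpolated` to 0.01).
#'
#' @param observed a `normalized_signals` direct read (positions aligned to
#'   reference coordinates).
#' @param profile an `intrinsic_profile` of the reference.
#' @param variants a [enumerate_variants()] set.
#' @param window `c(start, end)` observed position range used for fitting;
#'   defaults to 200 positions (or the read end) from the track start.
#'   Fewer than 50 usable positions is refused; fewer than 200 is flagged.
#' @param grid_step grid resolution on the proportions (default 0.01).
#' @param coarse_step coarse stage resolution for > 3 variants.
#' @return a `mixture_estimate`: list with `proportions` (named fractions),
#'   `percent`, `percent_interpolated`, `objective`, `scale`, `window`,
#'   `positions` (those actually used), `grid_step`, `short_window` flag.
#' @export
fit_proportions <- function(observed, profile, variants, window = NULL,
                            grid_step = 0.01, coarse_step = 0.05) {
  a <- variants$indel_site[1]
  if (is.null(window)) window <- c(a, min(a + 199L, nrow(observed)))
  window <- as.integer(window)
  positions <- window[1]:window[2]
  positions <- positions[positions >= 1L & positions <= nrow(observed)]
  # drop positions any variant cannot be simulated at (uncalibrated /
  # outside the profile)
  usable <- rep(TRUE, length(positions))
  for (s in variants$shifts) {
    j <- shifted_coord(positions, s, a)
    usable <- usable & j >= 1L & j <= nrow(profile) & profile$calibrated[pmax(j, 1L)]
  }
  if (any(!usable))
    warning(sprintf("%d window position(s) outside the calibrated profile dropped",
                    sum(!usable)))
  positions <- positions[usable]
  if (length(positions) < 50L)
    stop_tm("fitting window has ", length(positions),
            " usable positions (< 50): insufficient signal",
            class = "tracemix_parameter_error")
  short <- length(positions) < 200L
  if (short)
    warning("fitting window shorter than 200 positions; estimate flagged")

  obs <- win_matrix(observed)[positions, , drop = FALSE]
  if (all(obs == 0))
    stop_tm("observed window is all zero", class = "tracemix_degenerate_signal_error")
  target <- mean(rowSums(obs))

  k <- length(variants$shifts)
  # per-variant pure signals, flattened to one column each
  S <- vapply(variants$shifts, function(s) {
    m <- variant_signal(profile, variants, s, positions)
    as.numeric(m)
  }, numeric(length(positions) * 4L))
  o <- as.numeric(obs)

  eval_grid <- function(P) {
    # P: k x m proportion candidates; returns objective per column
    M <- S %*% P
    msum <- colSums(M) / length(positions)  # mean position sum per candidate
    cs <- target / msum
    cross <- as.numeric(crossprod(o, M))
    nn <- colSums(M * M)
    sum(o * o) - 2 * cs * cross + cs^2 * nn
  }

  search <- function(step_n, P) {
    obj <- eval_grid(P)
    best <- min(obj)
    cand <- which(obj <= best + 1e-9 * max(1, best))
    if (length(cand) > 1L) {
      nz <- colSums(P[, cand, drop = FALSE] > 0)
      cand <- cand[nz == min(nz)]
      if (length(cand) > 1L) {
        key <- apply(P[, cand, drop = FALSE], 2, paste, collapse = ",")
        cand <- cand[order(key)][1]
      }
    }
    list(p = P[, cand[1]], objective = obj[cand[1]], obj = obj, P = P)
  }

  steps_fine <- round(1 / grid_step)
  if (k <= 3L) {
    P <- simplex_grid(k, steps_fine) / steps_fine
    res <- search(steps_fine, P)
  } else {
    steps_coarse <- round(1 / coarse_step)
    Pc <- simplex_grid(k, steps_coarse) / steps_coarse
    inc <- search(steps_coarse, Pc)$p
    Pf <- simplex_grid(k, steps_fine) / steps_fine
    box <- colSums(abs(Pf - inc) > coarse_step + 1e-9) == 0
    res <- search(steps_fine, Pf[, box, drop = FALSE])
  }

  p <- setNames(res$p, variants$labels)
  pint <- p
  if (k == 2L) {
    # parabolic interpolation on the first proportion
    h <- grid_step
    p1 <- p[1]
    if (p1 - h >= 0 && p1 + h <= 1) {
      f <- function(x) eval_grid(matrix(c(x, 1 - x), 2L))
      y0 <- f(p1 - h); y1 <- res$objective; y2 <- f(p1 + h)
      den <- y0 - 2 * y1 + y2
      if (den > 0) {
        d <- 0.5 * h * (y0 - y2) / den
        pi1 <- min(max(p1 + d, 0), 1)
        pint <- setNames(c(pi1, 1 - pi1), variants$labels)
      }
    }
  }
  M <- S %*% matrix(res$p, ncol = 1L)
  scale <- target / (sum(M) / length(positions))
  structure(list(proportions = p, percent = 100 * p,
                 percent_interpolated = round(100 * pint, 2),
                 objective = res$objective, scale = scale,
                 window = range(positions), positions = positions,
                 grid_step = grid_step, short_window = short,
                 variants = variants),
            class = "mixture_estimate")
}

#' @export
print.mixture_estimate <- function(x, ...) {
  cat("<mixture_estimate>\n")
  for (i in seq_along(x$proportions))
    cat(sprintf("  %s nt: %6.2f%%\n", names(x$proportions)[i],
                x$percent_interpolated[i]))
  cat(sprintf("  objective %.4g over positions %d-%d (grid %.2f%s)\n",
              x$objective, x$window[1], x$window[2], x$grid_step,
              if (x$short_window) ", SHORT WINDOW" else ""))
  invisible(x)
}

#' Infer one deletion site's fraction from the total-length distribution
#'
#' With two single-nucleotide deletion sites, the total length of a
#' molecule determines the number of deletions it carries: a molecule of
#' length L-2 is deleted at both sites, L-1 at exactly one.  The expected
#' per-site deletion fractions therefore satisfy
#' d1 + d2 = 2 P(L-2) + P(L-1) exactly, so measuring one site gives the
#' other: d_other = 2 P(L-2) + P(L-1) - d_measured (clamped to \[0, 100\]).
#'
#' @param length_dist named numeric percentages over the total lengths
#'   (names are the lengths, e.g. `c("321" = 54, "322" = 19, "323" = 27)`);
#'   must sum to 100 within 2 (rounding slack).
#' @param measured_site measured deletion percentage at one site.
#' @return inferred deletion percentage at the other site.
#' @export
infer_joint_site_proportions <- function(length_dist, measured_site) {
  if (any(length_dist < 0 | length_dist > 100) ||
      measured_site < 0 || measured_site > 100)
    stop_tm("percentages must lie in [0, 100]",
            class = "tracemix_validation_error")
  if (abs(sum(length_dist) - 100) > 2)
    stop_tm("length distribution sums to ", sum(length_dist),
            ", not 100 +/- 2", class = "tracemix_validation_error")
  lens <- as.integer(names(length_dist))
  if (any(is.na(lens)))
    stop_tm("length_dist must be named by total lengths",
            class = "tracemix_validation_error")
  L <- max(lens)
  p1 <- if ((L - 1L) %in% lens) length_dist[[as.character(L - 1L)]] else 0
  p2 <- if ((L - 2L) %in% lens) length_dist[[as.character(L - 2L)]] else 0
  min(max(2 * p2 + p1 - measured_site, 0), 100)
}
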