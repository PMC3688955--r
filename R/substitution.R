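# Quantifying two-base substitution mixtures from direct-read peak heights,
# corrected by intrinsic expected intensities.  Substitution results are
# always integer percentages: only one position's signal informs them,
# unlike length fits which pool hundreds of downstream positions.

new_substitution_call <- function(position, bases, percent, method,
                                  threshold, region_label = NA_character_) {
  pass <- !any(is.na(percent)) && min(percent) >= threshold
  structure(list(region_label = region_label, position = position,
                 bases = bases, percent = percent, method = method,
                 threshold = threshold, passed_threshold = pass,
                 no_call = any(is.na(percent))),
            class = "substitution_call")
}

#' @export
print.substitution_call <- function(x, ...) {
  if (x$no_call) {
    cat(sprintf("<substitution_call> position %d: no call (%s)\n",
                x$position, x$method))
  } else {
    cat(sprintf("<substitution_call> position %d: %s %d%% / %s %d%% (%s)%s\n",
                x$position, x$bases[1], x$percent[1], x$bases[2],
                x$percent[2], x$method,
                if (x$passed_threshold) "" else " [below threshold]"))
  }
  invisible(x)
}

#' Quantify a substitution at a clean (unshifted) position
#'
#' The fraction of molecules carrying base X is estimated from the observed
#' window intensities of the two channels, each first divided by its
#' intrinsic expected intensity (so context-dependent peak-height
#' differences between the two bases cancel):
#' `fraction_X = (I_X/E_X) / (I_X/E_X + I_Y/E_Y)`.
#' With equal expectations this reduces to the raw peak-height ratio.
#'
#' @param observed a `normalized_signals` direct read.
#' @param expected_x,expected_y intrinsic expected intensities (on the
#'   normalized 1000-unit scale) for the two bases at the position; both
#'   must be positive.
#' @param position 1-based observed position.
#' @param bases length-2 character, the two bases `c(X, Y)`.
#' @param threshold reporting threshold on the minor percentage
#'   (default 10).
#' @param noise_floor intensities (both channels) below this are a no-call
#'   (default 50 units, i.e. 5% of the position scale).
#' @param region_label carried through to the call.
#' @return a `substitution_call` with integer `percent` named by base
#'   (half rounded away from zero; the pair sums to 100), `method =
#'   "clean"`, and `passed_threshold` flag.
#' @export
quantify_substitution <- function(observed, expected_x, expected_y, position,
                                  bases, threshold = 10, noise_floor = 50,
                                  region_label = NA_character_) {
  stopifnot(length(bases) == 2L, all(bases %in% BASES))
  if (expected_x <= 0 || expected_y <= 0)
    stop_tm("expected intensities must be positive",
            class = "tracemix_parameter_error")
  wm <- win_matrix(observed)
  ix <- wm[position, bases[1]]
  iy <- wm[position, bases[2]]
  if (ix < noise_floor && iy < noise_floor)
    return(new_substitution_call(position, bases, c(NA_real_, NA_real_),
                                 "no_call", threshold, region_label))
  rx <- ix / expected_x
  ry <- iy / expected_y
  px <- round_half_up(100 * rx / (rx + ry))
  new_substitution_call(position, bases,
                        setNames(c(px, 100 - px), bases),
                        "clean", threshold, region_label)
}

#' Quantify a substitution inside a frame-shifted mixed region
#'
#' Downstream of an indel site the trace is a fitted mixture of shifted
#' copies, so a substitution's signal is spread over the observed
#' coordinates at which the different frames display the substituted
#' reference position.  The expected background at those coordinates is
#' simulated from the fitted mixture; the substitution candidate is the
#' base with the largest positive total excess over background, and its
#' fraction is that excess divided by the total expected signal mass of
#' the substituted reference coordinate.
#'
#' @param observed a `normalized_signals` direct read.
#' @param mixture a fitted [fit_proportions()] estimate covering the
#'   position.
#' @param profile the `intrinsic_profile` the mixture was fitted with.
#' @param position substituted position in reference coordinates.
#' @param threshold reporting threshold (default 10).
#' @param noise_floor_frac minimum excess, as a fraction of the
#'   coordinate's expected mass, below which no call is made
#'   (default 0.05).
#' @param region_label carried through to the call.
#' @return a `substitution_call` with `method = "mixed_region"`; `percent`
#'   is named `c(substitute base, consensus base)`.
#' @export
quantify_substitution_mixed <- function(observed, mixture, profile, position,
                                        threshold = 10,
                                        noise_floor_frac = 0.05,
                                        region_label = NA_character_) {
  variants <- mixture$variants
  a <- variants$indel_site[1]
  p <- mixture$proportions
  cons <- profile$base[position]
  if (!profile$calibrated[position])
    stop_tm("position ", position, " is not calibrated in the profile",
            class = "tracemix_parameter_error")
  # observed coordinates at which each frame displays `position`
  coords <- if (position < a) position
            else unique(position + variants$shifts)
  coords <- coords[coords >= 1L & coords <= nrow(observed)]
  bg <- simulate_mixture(profile, variants, p, positions = coords)
  ok <- !is.na(bg$signal[, 1L])
  coords <- coords[ok]
  if (length(coords) == 0L)
    stop_tm("no usable observed coordinates for position ", position,
            class = "tracemix_parameter_error")
  B <- mixture$scale * bg$signal[ok, , drop = FALSE]
  I <- win_matrix(observed)[coords, , drop = FALSE]
  excess <- colSums(I - B)
  excess[cons] <- -Inf  # the consensus channel only loses signal
  cand <- names(which.max(excess))
  denom <- mixture$scale * profile$mean[position]  # full mass of the coordinate
  if (excess[cand] <= noise_floor_frac * denom)
    return(new_substitution_call(position, c(NA_character_, cons),
                                 c(NA_real_, NA_real_), "no_call",
                                 threshold, region_label))
  px <- round_half_up(100 * min(excess[cand] / denom, 1))
  new_substitution_call(position, c(cand, cons),
                        setNames(c(px, 100 - px), c(cand, cons)),
                        "mixed_region", threshold, region_label)
}
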