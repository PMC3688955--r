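# Normalization to the common 1000-unit intensity scale and noise gating.
#
# Every sequencing run has its own overall signal level, so intensities from
# different runs are made comparable by scaling each read so that its mean
# intensity over a reference region is 1000 units.  Clone reads are scaled
# on the called-channel point values; direct (mixed) reads on the
# per-position sums of the four channel window maxima, because in a mixture
# every channel at a position carries signal from some variant.

check_region <- function(table, region, min_region) {
  region <- as.integer(region)
  if (length(region) == 2L) region <- region[1]:region[2]
  if (min(region) < 1L || max(region) > nrow(table))
    stop_tm("region outside the read", class = "tracemix_parameter_error")
  if (length(region) < min_region)
    warning(sprintf("normalization region has %d positions (< %d)",
                    length(region), min_region))
  region
}

new_normalized_signals <- function(table, scale_factor, read_type, region) {
  structure(table, class = c("normalized_signals", class(table)),
            scale_factor = scale_factor, read_type = read_type,
            region = range(region))
}

#' Normalize a clone read to the 1000-unit scale
#'
#' Scales all channels so that the mean called-channel point intensity over
#' `region` equals 1000 units.  N calls are excluded from the mean.
#'
#' @param table a `call_point_table` (see [extract_call_points()]),
#'   direction-normalized.
#' @param region positions (a `c(start, end)` pair or an index vector) used
#'   to compute the scale; defaults to the whole read.
#' @param min_region minimum number of positions expected in `region`;
#'   fewer positions gives a warning (the scale estimate is then noisy).
#' @return a `normalized_signals` object: the table with all intensities
#'   scaled, with attributes `scale_factor` and `read_type = "clone"`.
#' @export
normalize_clone_read <- function(table, region = NULL, min_region = 30L) {
  region <- check_region(table, region %||% c(1L, nrow(table)), min_region)
  cc <- called_channel(point_matrix(table), table$call)
  m <- mean(cc[region], na.rm = TRUE)
  if (!is.finite(m) || m <= 0)
    stop_tm("degenerate signal: zero mean called-channel intensity",
            class = "tracemix_degenerate_signal_error")
  scale_table(table, 1000 / m, "clone", region)
}

#' Normalize a direct (mixed) read to the 1000-unit scale
#'
#' Per position, the four channel window maxima are summed (minor peaks do
#' not always crest at the call point, so window maxima, not point values,
#' capture them); all channels are scaled so the mean per-position sum over
#' `region` is 1000 units.
#'
#' @inheritParams normalize_clone_read
#' @return a `normalized_signals` object with `read_type = "direct"`.
#' @export
normalize_direct_read <- function(table, region = NULL, min_region = 30L) {
  region <- check_region(table, region %||% c(1L, nrow(table)), min_region)
  sums <- rowSums(win_matrix(table))
  m <- mean(sums[region])
  if (!is.finite(m) || m <= 0)
    stop_tm("degenerate signal: zero mean position sum",
            class = "tracemix_degenerate_signal_error")
  scale_table(table, 1000 / m, "direct", region)
}

scale_table <- function(table, k, read_type, region) {
  cols <- c(paste0("point_", BASES), paste0("win_", BASES))
  for (cl in cols) table[[cl]] <- table[[cl]] * k
  out <- new_normalized_signals(table, k, read_type, region)
  out$sum <- rowSums(win_matrix(out))
  out
}

#' Noise assessment of a read
#'
#' The noise fraction is the mean (over a clean, known-homogeneous region)
#' of the largest non-called-channel window intensity, divided by the mean
#' called-channel intensity.  Reads whose noise fraction exceeds the
#' threshold (default 10%) are not eligible for quantitative analysis.
#'
#' @param table a `call_point_table` or `normalized_signals`.
#' @param clean_region positions known to be free of heterogeneity
#'   (typically the invariant sequence upstream of the first heterogeneous
#'   position).
#' @param threshold pass/fail boundary on the noise fraction (default 0.10).
#' @return a `noise_report` list: `noise_fraction`, `clean_region`,
#'   `threshold`, `pass`.
#' @export
assess_noise <- function(table, clean_region, threshold = 0.10) {
  if (missing(clean_region) || length(clean_region) == 0L)
    stop_tm("clean_region must be a non-empty position range",
            class = "tracemix_parameter_error")
  region <- check_region(table, clean_region, 1L)
  wm <- win_matrix(table)[region, , drop = FALSE]
  call <- table$call[region]
  keep <- call %in% BASES
  wm <- wm[keep, , drop = FALSE]; call <- call[keep]
  if (nrow(wm) == 0L)
    stop_tm("clean_region contains no A/C/G/T basecalls",
            class = "tracemix_parameter_error")
  idx <- match(call, BASES)
  called <- wm[cbind(seq_len(nrow(wm)), idx)]
  off <- vapply(seq_len(nrow(wm)),
                function(i) max(wm[i, -idx[i]]), numeric(1))
  nf <- mean(off) / mean(called)
  structure(list(noise_fraction = nf, clean_region = range(region),
                 threshold = threshold, pass = nf <= threshold),
            class = "noise_report")
}

#' @export
print.noise_report <- function(x, ...) {
  cat(sprintf("<noise_report> noise %.1f%% over positions %d-%d: %s (threshold %.0f%%)\n",
              100 * x$noise_fraction, x$clean_region[1], x$clean_region[2],
              if (x$pass) "PASS" else "FAIL", 100 * x$threshold))
  invisible(x)
}
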