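# Learning intrinsic (expected) per-position signal intensities from clones.
#
# Each nucleotide has a repeatable, sequence-context-dependent intensity at
# each position; the mean over normalized clone reads of the called-channel
# intensity at an aligned position is its intrinsic value, and the spread
# across clones (about 5% relative SD in practice) sets the error floor of
# everything downstream.

#' Align clone sequences to a reference with declared indel sites
#'
#' Clones of a multicopy-gene amplicon are expected to be nearly identical
#' to the reference, differing only by substitutions and by indels inside
#' declared homopolymer tracks.  Under that constraint the alignment is
#' exact and linear-time: segments between tracks pair up one-to-one and
#' each track's length difference gives the clone's shift there.  Gaps are
#' canonically placed at the 3' end of the track.
#'
#' @param clone_seqs named character vector of clone sequences.
#' @param reference reference sequence (forward-oriented amplicon).
#' @param indel_sites list of `c(start, end)` reference coordinate ranges,
#'   each a homopolymer track, in increasing order.
#' @param max_divergence maximum tolerated mismatch fraction per clone
#'   (default 0.05); beyond it the clone is rejected as an outlier.
#' @return a `clone_alignment`: list with `reference`, `indel_sites`, and
#'   per clone a `map` (reference position -> clone read position, NA at
#'   deleted positions), `shifts` (per track), `gapped` sequence over
#'   reference coordinates, and `substitutions` (reference positions whose
#'   aligned clone base differs).  `substitution_cols` is the union.
#' @export
align_clones <- function(clone_seqs, reference, indel_sites = list(),
                         max_divergence = 0.05) {
  ref <- seq_chars(reference)
  L <- length(ref)
  sites <- lapply(indel_sites, as.integer)
  if (length(sites) > 1L &&
      any(diff(vapply(sites, `[`, integer(1), 1L)) <= 0))
    stop_tm("indel_sites must be in increasing order",
            class = "tracemix_parameter_error")
  for (s in sites) {
    b <- unique(ref[s[1]:s[2]])
    if (length(b) != 1L)
      stop_tm("indel site ", s[1], "-", s[2],
              " is not a homopolymer in the reference",
              class = "tracemix_parameter_error")
  }
  clone_names <- names(clone_seqs) %||% paste0("clone", seq_along(clone_seqs))
  clones <- lapply(seq_along(clone_seqs), function(ci) {
    cl <- seq_chars(clone_seqs[[ci]])
    map <- rep(NA_integer_, L)
    shifts <- integer(length(sites))
    offset <- 0L
    prev <- 0L
    for (si in seq_along(sites)) {
      a <- sites[[si]][1]; b <- sites[[si]][2]
      base <- ref[a]
      if (a - 1L >= prev + 1L)
        map[(prev + 1L):(a - 1L)] <- (prev + 1L):(a - 1L) + offset
      r <- b - a + 1L
      # clone's homopolymer run at the track
      j <- a + offset
      clen <- 0L
      while (j + clen <= length(cl) && cl[j + clen] == base) clen <- clen + 1L
      shifts[si] <- clen - r
      nmap <- min(r, clen)
      if (nmap > 0L) map[a:(a + nmap - 1L)] <- (a:(a + nmap - 1L)) + offset
      # deletions leave the 3'-most reference track positions unmapped
      offset <- offset + shifts[si]
      prev <- b
    }
    if (prev + 1L <= L)
      map[(prev + 1L):L] <- ((prev + 1L):L) + offset
    map[!is.na(map) & (map < 1L | map > length(cl))] <- NA_integer_
    expected_len <- L + offset
    if (length(cl) != expected_len)
      stop_tm("clone ", clone_names[ci], " length ", length(cl),
              " does not match reference plus track shifts (",
              expected_len, "); indels outside declared sites?",
              class = "tracemix_outlier_error")
    aligned <- ifelse(is.na(map), "-", cl[pmax(map, 1L)])
    aligned[is.na(map)] <- "-"
    subs <- which(!is.na(map) & cl[replace(map, is.na(map), 1L)] != ref)
    div <- length(subs) / L
    if (div > max_divergence)
      stop_tm("clone ", clone_names[ci], " diverges from the reference by ",
              sprintf("%.1f%%", 100 * div), " (> ",
              sprintf("%.0f%%", 100 * max_divergence), ")",
              class = "tracemix_outlier_error")
    list(name = clone_names[ci], seq = clone_seqs[[ci]], map = map,
         shifts = setNames(shifts,
                           vapply(sites, function(s)
                             paste0(s[1], "-", s[2]), character(1))),
         gapped = paste(aligned, collapse = ""), substitutions = subs)
  })
  names(clones) <- clone_names
  structure(list(reference = toupper(reference), indel_sites = sites,
                 clones = clones,
                 substitution_cols = sort(unique(unlist(
                   lapply(clones, `[[`, "substitutions"))))),
            class = "clone_alignment")
}

#' Build the intrinsic intensity profile from normalized clone reads
#'
#' For every reference position, the expected intensity is the mean (and
#' `sd` the population standard deviation) of the normalized called-channel
#' point intensities of the clones mapping to it.  Where clones disagree on
#' the base, only clones carrying the majority base contribute.
#'
#' @param clone_reads named list of `normalized_signals` clone reads (names
#'   matching the alignment's clones); read positions are clone sequence
#'   positions.
#' @param alignment a [align_clones()] result.
#' @param min_clones minimum clone count for a position to count as
#'   calibrated (default 3); uncalibrated positions are excluded from
#'   fitting windows.
#' @return an `intrinsic_profile`: data frame `ref_pos`, `base` (majority
#'   base), `mean`, `sd`, `n`, `calibrated`.
#' @export
build_intrinsic_profile <- function(clone_reads, alignment, min_clones = 3L) {
  nm <- intersect(names(alignment$clones), names(clone_reads))
  if (length(nm) == 0L)
    stop_tm("no clone reads match the alignment's clones",
            class = "tracemix_parameter_error")
  for (r in clone_reads[nm])
    if (!inherits(r, "normalized_signals") ||
        !identical(attr(r, "read_type"), "clone"))
      stop_tm("clone_reads must be clone-normalized (normalize_clone_read)",
              class = "tracemix_parameter_error")
  L <- nchar(alignment$reference)
  ref <- seq_chars(alignment$reference)
  # per clone: value and base at each reference position
  vals <- matrix(NA_real_, nrow = L, ncol = length(nm))
  bss <- matrix(NA_character_, nrow = L, ncol = length(nm))
  for (k in seq_along(nm)) {
    cl <- alignment$clones[[nm[k]]]
    rd <- clone_reads[[nm[k]]]
    cc <- called_channel(point_matrix(rd), rd$call)
    ok <- !is.na(cl$map) & cl$map <= nrow(rd)
    vals[ok, k] <- cc[cl$map[ok]]
    bss[ok, k] <- rd$call[cl$map[ok]]
  }
  out <- data.frame(ref_pos = seq_len(L), base = ref,
                    mean = NA_real_, sd = NA_real_, n = 0L)
  for (i in seq_len(L)) {
    b <- bss[i, ]
    v <- vals[i, ]
    ok <- !is.na(b) & b %in% BASES & !is.na(v)
    if (!any(ok)) next
    tab <- table(b[ok])
    maj <- names(tab)[order(-tab, names(tab))][1]
    # prefer the reference base on ties
    if (ref[i] %in% names(tab) && tab[[ref[i]]] == max(tab)) maj <- ref[i]
    use <- ok & b == maj
    x <- v[use]
    out$base[i] <- maj
    out$mean[i] <- mean(x)
    out$sd[i] <- sqrt(mean((x - mean(x))^2))  # population SD
    out$n[i] <- length(x)
  }
  out$calibrated <- out$n >= min_clones & !is.na(out$mean) & out$mean > 0
  structure(out, class = c("intrinsic_profile", "data.frame"),
            min_clones = min_clones)
}

#' Quality summary of an intrinsic profile
#'
#' @param profile an `intrinsic_profile`.
#' @return list with `mean_relative_sd` (mean over covered positions of
#'   sd/mean; around 0.05 for good clone sets), `coverage` (fraction of
#'   positions calibrated), and `flagged` (positions whose relative SD
#'   exceeds 3x the mean relative SD).
#' @export
profile_qc <- function(profile) {
  if (nrow(profile) == 0L)
    stop_tm("empty profile", class = "tracemix_parameter_error")
  cov <- profile$n >= 1L & !is.na(profile$mean) & profile$mean > 0
  rel <- profile$sd[cov] / profile$mean[cov]
  mrs <- mean(rel)
  flagged <- profile$ref_pos[cov][rel > 3 * mrs]
  list(mean_relative_sd = mrs,
       coverage = mean(profile$calibrated),
       flagged = flagged)
}

#' Serialize / read an intrinsic profile as TSV
#'
#' Columns: `ref_pos` (1-based), `base`, `mean`, `sd`, `n`.
#'
#' @param profile an `intrinsic_profile`.
#' @param path TSV path.
#' @return `path` (write) or the profile (read).
#' @export
write_intrinsic_profile <- function(profile, path) {
  write.table(profile[c("ref_pos", "base", "mean", "sd", "n")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_intrinsic_profile
#' @param min_clones calibration threshold restored on read.
#' @export
read_intrinsic_profile <- function(path, min_clones = 3L) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  out$calibrated <- out$n >= min_clones & !is.na(out$mean) & out$mean > 0
  structure(out, class = c("intrinsic_profile", "data.frame"),
            min_clones = min_clones)
}
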