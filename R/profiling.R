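# Region annotation, detection thresholds, ITS profile assembly and the
# replicate/comparison statistics.
#
# Feature naming convention inside a profile:
#   ITS1_len_253   percentage of region length variant 253 nt
#   ITS1_sub_169_A percentage of base A at region position 169
#   ITS2_del_13    percentage of molecules deleted at region position 13

MOTIF_18S_END <- "GATCATTA"
MOTIF_58S_START <- "ACAACTTC"
MOTIF_58S_END <- "TCTGAGCG"
MOTIF_28S_START <- "CGCTGAAT"

#' Locate the ITS regions in an amplicon by boundary motifs
#'
#' ITS1 lies between the last 8 nucleotides of 18S (`GATCATTA`) and the
#' first 8 of 5.8S (`ACAACTTC`); ITS2 between the end of 5.8S
#' (`TCTGAGCG`) and the beginning of 28S (`CGCTGAAT`).  Each motif must
#' occur exactly once, in order; regions exclude the motifs.
#'
#' @param amplicon amplicon sequence (forward strand).
#' @return a `region_annotation`: list with 1-based inclusive `its1`,
#'   `r58s` (5.8S including its boundary motifs), `its2` coordinate pairs
#'   and per-region lengths.
#' @export
locate_regions <- function(amplicon) {
  amplicon <- toupper(amplicon)
  find1 <- function(motif) {
    hits <- gregexpr(motif, amplicon, fixed = TRUE)[[1]]
    if (hits[1] == -1L)
      stop_tm("boundary motif ", motif, " not found",
              class = "tracemix_annotation_error")
    if (length(hits) > 1L)
      stop_tm("boundary motif ", motif, " occurs ", length(hits), " times",
              class = "tracemix_annotation_error")
    as.integer(hits[1])
  }
  p18 <- find1(MOTIF_18S_END)
  p58a <- find1(MOTIF_58S_START)
  p58b <- find1(MOTIF_58S_END)
  p28 <- find1(MOTIF_28S_START)
  if (!(p18 < p58a && p58a < p58b && p58b < p28))
    stop_tm("boundary motifs are out of order",
            class = "tracemix_annotation_error")
  its1 <- c(p18 + 8L, p58a - 1L)
  its2 <- c(p58b + 8L, p28 - 1L)
  structure(list(its1 = its1, r58s = c(p58a, p58b + 7L), its2 = its2,
                 lengths = c(ITS1 = its1[2] - its1[1] + 1L,
                             ITS2 = its2[2] - its2[1] + 1L)),
            class = "region_annotation")
}

#' @export
print.region_annotation <- function(x, ...) {
  cat(sprintf("<region_annotation> ITS1 %d-%d (%d nt), 5.8S %d-%d, ITS2 %d-%d (%d nt)\n",
              x$its1[1], x$its1[2], x$lengths["ITS1"],
              x$r58s[1], x$r58s[2],
              x$its2[1], x$its2[2], x$lengths["ITS2"]))
  invisible(x)
}

#' Construct an ITS profile
#'
#' @param sample_id sample identifier.
#' @param features named numeric vector of percentages; names follow the
#'   `<region>_len_<nt>`, `<region>_sub_<pos>_<base>`, `<region>_del_<pos>`
#'   convention.
#' @param qc optional list of QC information (noise reports etc.).
#' @return an `its_profile`.
#' @export
its_profile <- function(sample_id, features, qc = list()) {
  stopifnot(is.numeric(features), !is.null(names(features)))
  structure(list(sample_id = sample_id, features = features, qc = qc),
            class = "its_profile")
}

#' @export
print.its_profile <- function(x, ...) {
  cat(sprintf("<its_profile> %s\n", x$sample_id))
  for (nm in names(x$features))
    cat(sprintf("  %-16s %6.2f\n", nm, x$features[nm]))
  invisible(x)
}

feature_type <- function(nm) {
  ifelse(grepl("_len_", nm), "len",
         ifelse(grepl("_sub_", nm), "sub",
                ifelse(grepl("_del_", nm), "del", "other")))
}

#' Apply detection thresholds to a raw profile
#'
#' Length-variant percentages below the length threshold (default 5%,
#' established from the acceptable electropherogram noise level) are set
#' to 0; substitution percentages below the substitution threshold
#' (default 10%) are set to 0.  Surviving values are NOT renormalized:
#' they are estimates, so totals may fall short of 100.  Idempotent.
#'
#' @param profile an `its_profile` (or bare named numeric vector).
#' @param length_threshold detection threshold for length/deletion
#'   features, in percent.
#' @param substitution_threshold detection threshold for substitution
#'   features, in percent.
#' @return the thresholded profile, same class as the input.
#' @export
apply_thresholds <- function(profile, length_threshold = 5,
                             substitution_threshold = 10) {
  f <- if (inherits(profile, "its_profile")) profile$features else profile
  ty <- feature_type(names(f))
  thr <- ifelse(ty == "sub", substitution_threshold, length_threshold)
  f[f < thr] <- 0
  if (inherits(profile, "its_profile")) {
    profile$features <- f
    profile$qc$thresholds <- c(length = length_threshold,
                               substitution = substitution_threshold)
    profile
  } else f
}

#' Replicate statistics: reference mean, absolute deviations, range
#'
#' Used to summarize repeatability across replicate PCR/sequencing runs:
#' the mean over a designated reference subset (e.g. the standard-input
#' replicates), each queried value's absolute deviation from that mean,
#' and the range (max - min) over the queried subset.
#'
#' @param values numeric vector of percentages (one per run/sample).
#' @param reference_idx indices of the reference subset (>= 2 values).
#' @param query_idx indices of the queried subset (default: all values).
#' @return list with `mean`, `deviation` (per queried value), `range`.
#' @export
replicate_stats <- function(values, reference_idx,
                            query_idx = seq_along(values)) {
  if (length(reference_idx) < 2L)
    stop_tm("reference subset needs at least 2 values",
            class = "tracemix_parameter_error")
  if (length(query_idx) == 0L)
    stop_tm("query subset is empty", class = "tracemix_parameter_error")
  m <- mean(values[reference_idx])
  dev <- abs(values[query_idx] - m)
  names(dev) <- names(values)[query_idx]
  list(mean = m, deviation = dev,
       range = max(values[query_idx]) - min(values[query_idx]))
}

#' Compare two ITS profiles feature by feature
#'
#' The feature universe is the union of both profiles' features, absent
#' values treated as 0.  A feature is distinguishing under criterion
#' `"any"` if the (thresholded) values differ at all, or under `"margin"`
#' if they differ by more than the permitted error rate for the feature
#' class (5 points for length and per-site deletion features, 10 for
#' substitutions).
#'
#' @param a,b `its_profile` objects (or bare named numeric vectors).
#' @param criterion `"any"` (default) or `"margin"`.
#' @param margins named permitted error rates for the `"margin"` criterion.
#' @return `compare_profiles`: data frame with `feature`, `value_a`,
#'   `value_b`, `diff`, `distinguishing`.  `count_distinguishing_features`:
#'   the number of distinguishing features (symmetric in `a`, `b`).
#' @export
compare_profiles <- function(a, b, criterion = c("any", "margin"),
                             margins = c(len = 5, sub = 10, del = 5)) {
  criterion <- match.arg(criterion)
  fa <- if (inherits(a, "its_profile")) a$features else a
  fb <- if (inherits(b, "its_profile")) b$features else b
  feats <- union(names(fa), names(fb))
  va <- setNames(rep(0, length(feats)), feats); va[names(fa)] <- fa
  vb <- setNames(rep(0, length(feats)), feats); vb[names(fb)] <- fb
  d <- abs(va - vb)
  if (criterion == "any") {
    dist <- d > 1e-9
  } else {
    ty <- feature_type(feats)
    lim <- margins[ifelse(ty %in% names(margins), ty, "len")]
    dist <- d > lim + 1e-9
  }
  data.frame(feature = feats, value_a = va, value_b = vb, diff = d,
             distinguishing = dist, row.names = NULL)
}

#' @rdname compare_profiles
#' @export
count_distinguishing_features <- function(a, b, criterion = c("any", "margin"),
                                          margins = c(len = 5, sub = 10,
                                                      del = 5)) {
  sum(compare_profiles(a, b, criterion, margins)$distinguishing)
}

#' Read / write ITS profile tables
#'
#' One row per sample; a `sample` column plus one column per feature.
#'
#' @param path TSV path.
#' @return named list of `its_profile` objects (read); `path` (write).
#' @export
read_its_profiles <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  feats <- setdiff(names(tab), "sample")
  out <- lapply(seq_len(nrow(tab)), function(i)
    its_profile(tab$sample[i],
                setNames(as.numeric(tab[i, feats]), feats)))
  setNames(out, tab$sample)
}

#' @rdname read_its_profiles
#' @param profiles named list of `its_profile` objects.
#' @export
write_its_profiles <- function(profiles, path) {
  feats <- unique(unlist(lapply(profiles, function(p) names(p$features))))
  rows <- lapply(profiles, function(p) {
    v <- setNames(rep(0, length(feats)), feats)
    v[names(p$features)] <- p$features
    v
  })
  tab <- cbind(data.frame(sample = vapply(profiles, `[[`, character(1),
                                          "sample_id")),
               as.data.frame(do.call(rbind, rows), check.names = FALSE))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
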