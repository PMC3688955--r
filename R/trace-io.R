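# Reading chromatograms and reducing them to per-basecall intensity tables.
#
# Two on-disk forms are supported:
#  * the tabular trace dialect: TSV with columns scan, call, A, C, G, T;
#    one row per scan point, basecalls are rows where call != "."
#  * AB1 (ABIF) files, via a minimal big-endian ABIF reader covering the
#    analyzed channels (DATA 9-12), basecall scan positions (PLOC.2),
#    basecalls (PBAS.2) and the dye order (FWO_.1).

#' Construct a chromatogram object
#'
#' A chromatogram holds the four analyzed channel traces over scan index
#' plus the basecalls (called base, scan position) placed by the basecaller.
#'
#' @param channels named list `A`, `C`, `G`, `T` of equal-length non-negative
#'   numeric vectors (fluorescence over scan index).
#' @param basecalls data frame with columns `base` (A/C/G/T/N) and `scan`
#'   (strictly increasing scan positions within the trace).
#' @param sample_id,primer_name,direction read metadata; `direction` is
#'   `"forward"` or `"reverse"`.
#' @return an object of class `chromatogram`.
#' @export
chromatogram <- function(channels, basecalls, sample_id = NA_character_,
                         primer_name = NA_character_, direction = "forward") {
  stopifnot(is.list(channels), all(BASES %in% names(channels)))
  channels <- lapply(channels[BASES], as.numeric)
  n <- unique(lengths(channels))
  if (length(n) != 1L)
    stop_tm("all four channel series must have equal length",
            class = "tracemix_format_error")
  if (any(vapply(channels, function(x) any(x < 0), logical(1))))
    stop_tm("channel intensities must be non-negative",
            class = "tracemix_format_error")
  if (nrow(basecalls) == 0L)
    stop_tm("chromatogram contains zero basecalls",
            class = "tracemix_empty_read_error")
  if (!all(basecalls$base %in% c(BASES, "N")))
    stop_tm("called bases must be one of A, C, G, T, N",
            class = "tracemix_format_error")
  if (any(diff(basecalls$scan) <= 0))
    stop_tm("basecall scan positions must be strictly increasing",
            class = "tracemix_format_error")
  if (min(basecalls$scan) < 1 || max(basecalls$scan) > n)
    stop_tm("basecall scan positions fall outside the scan range",
            class = "tracemix_format_error")
  direction <- match.arg(direction, c("forward", "reverse"))
  structure(list(sample_id = sample_id, primer_name = primer_name,
                 direction = direction, channels = channels,
                 basecalls = data.frame(base = basecalls$base,
                                        scan = as.integer(basecalls$scan))),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram> %s (%s, %s): %d scans, %d basecalls\n",
              x$sample_id, x$primer_name, x$direction,
              length(x$channels$A), nrow(x$basecalls)))
  invisible(x)
}

#' Read a chromatogram from disk
#'
#' @param path path to the trace file.
#' @param format `"tabular"` for the TSV trace dialect (columns `scan`,
#'   `call`, `A`, `C`, `G`, `T`; basecalls are rows where `call != "."`),
#'   or `"ab1"` for an ABIF file.
#' @param sample_id,primer_name,direction metadata, normally supplied from
#'   the run manifest.
#' @return a [chromatogram()] object.
#' @export
read_chromatogram <- function(path, format = c("tabular", "ab1"),
                              sample_id = NA_character_,
                              primer_name = NA_character_,
                              direction = "forward") {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_tm("trace file not found: ", path, class = "tracemix_format_error")
  if (format == "tabular") {
    tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    need <- c("scan", "call", BASES)
    miss <- setdiff(need, names(tab))
    if (length(miss))
      stop_tm("tabular trace is missing column(s): ",
              paste(miss, collapse = ", "), class = "tracemix_format_error")
    if (any(diff(tab$scan) <= 0))
      stop_tm("tabular trace scan column is not strictly increasing",
              class = "tracemix_format_error")
    calls <- tab$call != "."
    chromatogram(channels = as.list(tab[BASES]),
                 basecalls = data.frame(base = tab$call[calls],
                                        scan = seq_len(nrow(tab))[calls]),
                 sample_id = sample_id, primer_name = primer_name,
                 direction = direction)
  } else {
    read_abif(path, sample_id = sample_id, primer_name = primer_name,
              direction = direction)
  }
}

#' Write a chromatogram in the tabular trace dialect
#'
#' @param chrom a [chromatogram()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_trace_tsv <- function(chrom, path) {
  n <- length(chrom$channels$A)
  call <- rep(".", n)
  call[chrom$basecalls$scan] <- chrom$basecalls$base
  tab <- data.frame(scan = seq_len(n), call = call,
                    A = chrom$channels$A, C = chrom$channels$C,
                    G = chrom$channels$G, T = chrom$channels$T)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reduce a chromatogram to a per-basecall intensity table
#'
#' For every basecall, the point intensity of each channel is its value at
#' the basecall's scan position, and the window intensity is the channel
#' maximum over a centered window of `window` scan points (truncated at the
#' trace ends).  Window maxima matter for direct (mixed) reads, where minor
#' peaks need not crest exactly at the call point.
#'
#' @param chrom a [chromatogram()].
#' @param window odd positive integer, window width in scan points
#'   (default 5, i.e. call point +/- 2 scans).
#' @return a `call_point_table`: data frame with columns `call`,
#'   `point_A` ... `point_T`, `win_A` ... `win_T`, carrying the read
#'   metadata and a `direction_normalized` flag as attributes.
#' @export
extract_call_points <- function(chrom, window = 5L) {
  if (length(window) != 1L || window < 1L || window %% 2L == 0L)
    stop_tm("window must be an odd positive integer",
            class = "tracemix_parameter_error")
  half <- (window - 1L) %/% 2L
  n <- length(chrom$channels$A)
  scans <- chrom$basecalls$scan
  lo <- pmax(scans - half, 1L)
  hi <- pmin(scans + half, n)
  point <- vapply(BASES, function(b) chrom$channels[[b]][scans],
                  numeric(length(scans)))
  win <- vapply(BASES, function(b) {
    ch <- chrom$channels[[b]]
    vapply(seq_along(scans), function(i) max(ch[lo[i]:hi[i]]), numeric(1))
  }, numeric(length(scans)))
  point <- matrix(point, ncol = 4L, dimnames = list(NULL, BASES))
  win <- matrix(win, ncol = 4L, dimnames = list(NULL, BASES))
  new_call_point_table(chrom$basecalls$base, point, win,
                       sample_id = chrom$sample_id,
                       primer_name = chrom$primer_name,
                       direction = chrom$direction,
                       direction_normalized = (chrom$direction == "forward"),
                       window = as.integer(window))
}

new_call_point_table <- function(call, point, win, sample_id = NA,
                                 primer_name = NA, direction = "forward",
                                 direction_normalized = TRUE, window = 5L) {
  tab <- data.frame(call = call,
                    point_A = point[, "A"], point_C = point[, "C"],
                    point_G = point[, "G"], point_T = point[, "T"],
                    win_A = win[, "A"], win_C = win[, "C"],
                    win_G = win[, "G"], win_T = win[, "T"])
  structure(tab, class = c("call_point_table", "data.frame"),
            sample_id = sample_id, primer_name = primer_name,
            direction = direction,
            direction_normalized = direction_normalized, window = window)
}

# matrix accessors for the two intensity representations
point_matrix <- function(table) {
  m <- as.matrix(table[paste0("point_", BASES)])
  colnames(m) <- BASES
  m
}
win_matrix <- function(table) {
  m <- as.matrix(table[paste0("win_", BASES)])
  colnames(m) <- BASES
  m
}

# intensity of the called channel per position (NA for N calls)
called_channel <- function(m, call) {
  idx <- match(call, BASES)
  out <- rep(NA_real_, length(call))
  ok <- !is.na(idx)
  out[ok] <- m[cbind(which(ok), idx[ok])]
  out
}

#' Orient a call-point table to the forward strand
#'
#' Reverse-primer reads run 3' to 5' on the amplicon's forward strand; to
#' compare them with forward reads the position order is reversed and the
#' channels (and called bases) complemented (A with T, C with G).
#'
#' @param table a `call_point_table`.
#' @param direction direction the read was sequenced in.
#' @return the table in forward-strand orientation, with the
#'   `direction_normalized` attribute set.
#' @export
orient_read <- function(table, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  if (direction == "forward") {
    attr(table, "direction_normalized") <- TRUE
    return(table)
  }
  idx <- rev(seq_len(nrow(table)))
  pm <- point_matrix(table); wm <- win_matrix(table)
  # reverse position order; relabel channels with their complements
  pm2 <- pm[idx, c("T", "G", "C", "A"), drop = FALSE]; colnames(pm2) <- BASES
  wm2 <- wm[idx, c("T", "G", "C", "A"), drop = FALSE]; colnames(wm2) <- BASES
  out <- new_call_point_table(complement_base(table$call[idx]), pm2, wm2,
                              sample_id = attr(table, "sample_id"),
                              primer_name = attr(table, "primer_name"),
                              direction = attr(table, "direction"),
                              direction_normalized = TRUE,
                              window = attr(table, "window"))
  out
}

# ---- minimal ABIF (AB1) support -------------------------------------------

abif_read_entry <- function(con) {
  name <- rawToChar(readBin(con, "raw", 4L))
  number <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  etype <- readBin(con, "integer", 1L, size = 2L, endian = "big")
  esize <- readBin(con, "integer", 1L, size = 2L, endian = "big")
  nelem <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  dsize <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  draw <- readBin(con, "raw", 4L)
  readBin(con, "raw", 4L)  # data handle, unused
  list(name = name, number = number, etype = etype, esize = esize,
       nelem = nelem, dsize = dsize, draw = draw)
}

abif_entry_data <- function(con, e) {
  raw <- if (e$dsize <= 4L) e$draw[seq_len(e$dsize)] else {
    off <- readBin(e$draw, "integer", 1L, size = 4L, endian = "big")
    seek(con, off)
    readBin(con, "raw", e$dsize)
  }
  switch(as.character(e$etype),
         "2" = rawToChar(raw),                                     # char
         "4" = readBin(raw, "integer", e$nelem, 2L, endian = "big"), # short
         "5" = readBin(raw, "integer", e$nelem, 4L, endian = "big"), # long
         raw)
}

read_abif <- function(path, sample_id = NA_character_,
                      primer_name = NA_character_, direction = "forward") {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(magic, "ABIF"))
    stop_tm("not an ABIF file (bad magic): ", path,
            class = "tracemix_format_error")
  readBin(con, "integer", 1L, size = 2L, endian = "big")  # version
  tdir <- abif_read_entry(con)
  diroff <- readBin(tdir$draw, "integer", 1L, size = 4L, endian = "big")
  seek(con, diroff)
  entries <- lapply(seq_len(tdir$nelem), function(i) abif_read_entry(con))
  find <- function(name, number) {
    for (e in entries) if (e$name == name && e$number == number) return(e)
    NULL
  }
  get <- function(name, number) {
    e <- find(name, number)
    if (is.null(e))
      stop_tm("ABIF file is missing required tag ", name, ".", number,
              class = "tracemix_format_error")
    abif_entry_data(con, e)
  }
  fwo <- seq_chars(get("FWO_", 1L))  # dye order: base of DATA.9..12 in turn
  channels <- setNames(vector("list", 4L), BASES)
  for (i in 1:4) channels[[fwo[i]]] <- get("DATA", 8L + i)
  ploc <- get("PLOC", 2L) + 1L  # ABIF scan positions are 0-based
  pbas <- seq_chars(get("PBAS", 2L))
  if (length(pbas) == 0L)
    stop_tm("ABIF file contains zero basecalls",
            class = "tracemix_empty_read_error")
  chromatogram(channels, data.frame(base = pbas, scan = ploc),
               sample_id = sample_id, primer_name = primer_name,
               direction = direction)
}

#' Write a chromatogram as a minimal ABIF (AB1) file
#'
#' Writes the subset of ABIF tags this package reads back: analyzed
#' channels DATA.9-12 (16-bit), basecall scan positions PLOC.2, basecalls
#' PBAS.2, and the dye order FWO_.1 (written as GATC).  Intended for
#' round-trip testing of [read_chromatogram()]; not a full trace file.
#'
#' @param chrom a [chromatogram()]; channel values are truncated to
#'   integers and must fit in a signed 16-bit range.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_abif <- function(chrom, path) {
  fwo <- c("G", "A", "T", "C")
  blobs <- list()
  entry <- function(name, number, etype, esize, nelem, data_raw) {
    list(name = name, number = number, etype = etype, esize = esize,
         nelem = nelem, data = data_raw)
  }
  int_raw <- function(x, size) writeBin(as.integer(x), raw(), size = size,
                                        endian = "big")
  for (i in 1:4) {
    v <- chrom$channels[[fwo[i]]]
    if (any(v > 32767))
      stop_tm("channel values exceed the 16-bit ABIF range",
              class = "tracemix_format_error")
    blobs[[length(blobs) + 1L]] <-
      entry("DATA", 8L + i, 4L, 2L, length(v), int_raw(round(v), 2L))
  }
  blobs[[length(blobs) + 1L]] <-
    entry("PLOC", 2L, 4L, 2L, nrow(chrom$basecalls),
          int_raw(chrom$basecalls$scan - 1L, 2L))
  blobs[[length(blobs) + 1L]] <-
    entry("PBAS", 2L, 2L, 1L, nrow(chrom$basecalls),
          charToRaw(paste(chrom$basecalls$base, collapse = "")))
  blobs[[length(blobs) + 1L]] <-
    entry("FWO_", 1L, 2L, 1L, 4L, charToRaw(paste(fwo, collapse = "")))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("ABIF"), con)
  writeBin(101L, con, size = 2L, endian = "big")
  # layout: 128-byte header, then data blobs, then the directory
  offset <- 128L
  offsets <- integer(length(blobs))
  for (i in seq_along(blobs)) {
    offsets[i] <- offset
    offset <- offset + length(blobs[[i]]$data)
  }
  dir_offset <- offset
  write_entry <- function(name, number, etype, esize, nelem, dsize, dword) {
    writeBin(charToRaw(name), con)
    writeBin(as.integer(number), con, size = 4L, endian = "big")
    writeBin(as.integer(etype), con, size = 2L, endian = "big")
    writeBin(as.integer(esize), con, size = 2L, endian = "big")
    writeBin(as.integer(nelem), con, size = 4L, endian = "big")
    writeBin(as.integer(dsize), con, size = 4L, endian = "big")
    writeBin(dword, con)
    writeBin(raw(4L), con)
  }
  # header tdir entry pointing at the directory
  write_entry("tdir", 1L, 1023L, 28L, length(blobs), 28L * length(blobs),
              int_raw(dir_offset, 4L))
  writeBin(raw(128L - 6L - 28L), con)  # pad header to 128 bytes
  for (b in blobs) writeBin(b$data, con)
  for (i in seq_along(blobs)) {
    b <- blobs[[i]]
    dsize <- length(b$data)
    dword <- if (dsize <= 4L) c(b$data, raw(4L - dsize)) else
      int_raw(offsets[i], 4L)
    write_entry(b$name, b$number, b$etype, b$esize, b$nelem, dsize, dword)
  }
  invisible(path)
}

#' Read and write run manifests
#'
#' A run manifest is a TSV with columns `file`, `sample_id`, `primer`,
#' `direction` (forward/reverse) and `read_type` (clone/direct) describing
#' the traces of a sequencing run.
#'
#' @param path manifest path.
#' @return data frame with the manifest columns.
#' @export
read_manifest <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("file", "sample_id", "primer", "direction", "read_type")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop_tm("manifest is missing column(s): ", paste(miss, collapse = ", "),
            class = "tracemix_format_error")
  m
}

#' @rdname read_manifest
#' @param manifest data frame with the manifest columns.
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
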