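# Synthetic chromatogram generator with known ground truth.
#
# Emulates the statistical structure the method relies on: every base has a
# repeatable intensity determined by its preceding k-mer context (modelled
# as a deterministic hash into 600..1400 units), clone reads add ~5%
# per-position multiplicative noise, direct reads superpose the length
# variants of the mixture in their shifted frames, and all channels carry a
# configurable baseline noise floor.  Intensities are computed from each
# molecule's own sequence, so within k-1 bases downstream of a track the
# true context differs slightly between variants -- a realism feature the
# reference-frame proportion model does not capture (second-order; see the
# methods vignette).

# run code with a local, restored RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generator configuration
#'
#' Defaults mirror the study system: a ~0.9 kb amplicon with a 254-nt ITS1
#' carrying a homopolymer T track at positions 177-179, a 323-nt ITS2 with
#' T tracks at 10-13 and 246-247, context order 3, 5% per-position
#' multiplicative noise, 2% baseline channel noise, 48 clones.
#'
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param its1_length,its2_length region lengths in nt.
#' @param len18,len58,len28 lengths of the 18S tail, 5.8S and 28S head.
#' @param its1_track,its2_track1,its2_track2 `c(start, end)` homopolymer
#'   T-track coordinates within their regions.
#' @param context_k context order (preceding k-mer size).
#' @param noise_sd per-position multiplicative (lognormal) noise SD.
#' @param baseline baseline channel noise as a fraction of the position's
#'   total signal.
#' @param n_clones number of clone reads for profile building.
#' @return a `generator_config` list.
#' @export
generator_config <- function(seed = 1L, its1_length = 254L,
                             its2_length = 323L, len18 = 40L, len58 = 160L,
                             len28 = 140L, its1_track = c(177L, 179L),
                             its2_track1 = c(10L, 13L),
                             its2_track2 = c(246L, 247L),
                             context_k = 3L, noise_sd = 0.05,
                             baseline = 0.02, n_clones = 48L) {
  stopifnot(noise_sd >= 0, baseline >= 0, context_k >= 1L)
  structure(list(seed = as.integer(seed), its1_length = its1_length,
                 its2_length = its2_length, len18 = len18, len58 = len58,
                 len28 = len28, its1_track = its1_track,
                 its2_track1 = its2_track1, its2_track2 = its2_track2,
                 context_k = context_k, noise_sd = noise_sd,
                 baseline = baseline, n_clones = n_clones),
            class = "generator_config")
}

# deterministic context model: preceding k-mer + base -> units in [600, 1400]
context_value <- function(kmer, base) {
  s <- paste0(kmer, base)
  codes <- utf8ToInt(s)
  h <- 7
  for (c in codes) h <- (h * 31 + c) %% 100003
  600 + (h %% 8001) / 8000 * 800
}

# vectorized context values over a whole sequence (positions 1..n); the
# sequence is padded upstream with A for the first k positions
context_values_seq <- function(seq, k) {
  ch <- seq_chars(seq)
  padded <- c(rep("A", k), ch)
  vapply(seq_along(ch), function(i)
    context_value(paste(padded[i:(i + k - 1L)], collapse = ""), ch[i]),
    numeric(1))
}

#' Construct the synthetic reference amplicon
#'
#' Builds 18S tail + ITS1 + 5.8S + ITS2 + 28S head with the four boundary
#' motifs placed verbatim, the configured homopolymer T tracks (flanked by
#' non-T bases so the tracks are maximal runs), and seed-determined random
#' filler guaranteed not to duplicate any boundary motif.
#'
#' @param config a [generator_config()].
#' @return list with `amplicon` (character sequence), `annotation` (truth,
#'   comparable to [locate_regions()] output), and `tracks` (named list of
#'   `c(start, end)` amplicon coordinates: `ITS1`, `ITS2_a`, `ITS2_b`).
#' @export
make_reference <- function(config) {
  with_seed(config$seed, {
    motifs <- c(MOTIF_18S_END, MOTIF_58S_START, MOTIF_58S_END,
                MOTIF_28S_START)
    for (try in 1:100) {
      filler <- function(n) paste(sample(BASES, n, replace = TRUE),
                                  collapse = "")
      stamp_track <- function(region, track) {
        ch <- seq_chars(region)
        ch[track[1]:track[2]] <- "T"
        if (track[1] > 1L && ch[track[1] - 1L] == "T")
          ch[track[1] - 1L] <- "C"
        if (track[2] < length(ch) && ch[track[2] + 1L] == "T")
          ch[track[2] + 1L] <- "C"
        paste(ch, collapse = "")
      }
      s18 <- paste0(filler(config$len18 - 8L), MOTIF_18S_END)
      its1 <- stamp_track(filler(config$its1_length), config$its1_track)
      s58 <- paste0(MOTIF_58S_START, filler(config$len58 - 16L),
                    MOTIF_58S_END)
      its2 <- stamp_track(stamp_track(filler(config$its2_length),
                                      config$its2_track1),
                          config$its2_track2)
      s28 <- paste0(MOTIF_28S_START, filler(config$len28 - 8L))
      amplicon <- paste0(s18, its1, s58, its2, s28)
      counts <- vapply(motifs, function(m)
        length(gregexpr(m, amplicon, fixed = TRUE)[[1]]) *
          (regexpr(m, amplicon, fixed = TRUE) != -1L), integer(1))
      if (all(counts == 1L)) break
      if (try == 100L)
        stop_tm("could not place boundary motifs uniquely",
                class = "tracemix_config_error")
    }
    o1 <- config$len18                      # ITS1 starts at o1 + 1
    o2 <- config$len18 + config$its1_length + config$len58
    list(amplicon = amplicon,
         annotation = list(its1 = c(o1 + 1L, o1 + config$its1_length),
                           its2 = c(o2 + 1L, o2 + config$its2_length)),
         tracks = list(ITS1 = o1 + config$its1_track,
                       ITS2_a = o2 + config$its2_track1,
                       ITS2_b = o2 + config$its2_track2))
  })
}

#' Build a variant of the reference amplicon
#'
#' @param reference reference amplicon sequence.
#' @param tracks named list of `c(start, end)` track coordinates (amplicon
#'   frame), as returned by [make_reference()].
#' @param shifts named integer vector (names among `names(tracks)`) of
#'   signed track length changes; omitted tracks keep their length.
#' @return list with `seq` (the variant sequence) and `map_ref` function
#'   mapping reference coordinates to variant coordinates.
#' @export
variant_sequence <- function(reference, tracks, shifts = integer()) {
  ch <- seq_chars(reference)
  use <- tracks[names(shifts)]
  ord <- order(-vapply(use, `[`, integer(1), 1L))  # edit right to left
  for (i in ord) {
    tr <- use[[i]]; s <- shifts[[i]]
    base <- ch[tr[1]]
    run <- tr[2] - tr[1] + 1L
    if (run + s < 0L)
      stop_tm("shift ", s, " deletes more than the track",
              class = "tracemix_config_error")
    ch <- append(ch[-(tr[1]:tr[2])], rep(base, run + s), after = tr[1] - 1L)
  }
  starts <- vapply(tracks, `[`, integer(1), 1L)
  sh <- setNames(rep(0L, length(tracks)), names(tracks))
  sh[names(shifts)] <- as.integer(shifts)
  map_ref <- function(q)
    q + vapply(q, function(x) sum(sh[starts <= x]), numeric(1))
  list(seq = paste(ch, collapse = ""), map_ref = map_ref)
}

finish_table <- function(signal, call, sample_id, primer_name) {
  new_call_point_table(call, signal, signal, sample_id = sample_id,
                       primer_name = primer_name, direction = "forward",
                       direction_normalized = TRUE)
}

add_baseline <- function(signal, baseline) {
  if (baseline <= 0) return(signal)
  tot <- rowSums(signal)
  signal + baseline * tot *
    matrix(runif(length(signal), 0.5, 1.5), nrow(signal), 4L)
}

#' Simulate a clone read
#'
#' Called-channel intensity at position i is the context model value of the
#' clone's own preceding k-mer, times lognormal multiplicative noise; the
#' other channels carry the baseline noise floor.  Deterministic under
#' `seed`.
#'
#' @param seq the clone's sequence.
#' @param config a [generator_config()].
#' @param seed read-level seed (default `config$seed`).
#' @param sample_id,primer_name metadata.
#' @return a `call_point_table` (window intensities equal point
#'   intensities: clone peaks crest at the call point).
#' @export
simulate_clone_read <- function(seq, config, seed = config$seed,
                                sample_id = "clone",
                                primer_name = "fw") {
  with_seed(seed, {
    ch <- seq_chars(seq)
    ev <- context_values_seq(seq, config$context_k)
    point <- ev * exp(rnorm(length(ev), 0, config$noise_sd))
    signal <- matrix(0, length(ch), 4L, dimnames = list(NULL, BASES))
    signal[cbind(seq_along(ch), match(ch, BASES))] <- point
    signal <- add_baseline(signal, config$baseline)
    finish_table(signal, ch, sample_id, primer_name)
  })
}

#' Simulate a direct (mixed-amplicon) read
#'
#' Per (position, base), the signal is the proportion-weighted sum over the
#' mixture's variants of each variant's own context-model intensity at that
#' position, on that variant's own base there.  Substitution truths move
#' the configured fraction of each variant's called-channel signal at the
#' substituted (reference-frame) position onto the substitute base.
#' Multiplicative noise and the baseline floor are then applied.
#'
#' @param reference reference amplicon (from [make_reference()]).
#' @param tracks track coordinates (from [make_reference()]).
#' @param mixture named list: `shifts` a list of per-variant named shift
#'   vectors, `proportions` numeric summing to 1.
#' @param config a [generator_config()].
#' @param substitutions optional list of `list(pos =, to =, fraction =)`
#'   with `pos` in reference amplicon coordinates.
#' @param seed read-level seed (default `config$seed`).
#' @param sample_id,primer_name metadata.
#' @return a `call_point_table` whose `call` column follows the
#'   highest-proportion variant, with a `truth` attribute recording the
#'   mixture.
#' @export
simulate_direct_read <- function(reference, tracks, mixture, config,
                                 substitutions = list(),
                                 seed = config$seed, sample_id = "direct",
                                 primer_name = "fw") {
  p <- mixture$proportions
  if (abs(sum(p) - 1) > 1e-6)
    stop_tm("mixture proportions must sum to 1",
            class = "tracemix_config_error")
  vs <- lapply(mixture$shifts, function(s)
    variant_sequence(reference, tracks, s))
  n <- min(vapply(vs, function(v) nchar(v$seq), integer(1)))
  with_seed(seed, {
    signal <- matrix(0, n, 4L, dimnames = list(NULL, BASES))
    for (k in seq_along(vs)) {
      ch <- seq_chars(vs[[k]]$seq)[seq_len(n)]
      ev <- context_values_seq(vs[[k]]$seq, config$context_k)[seq_len(n)]
      contrib <- p[k] * ev
      for (sub in substitutions) {
        i <- vs[[k]]$map_ref(sub$pos)
        if (i >= 1L && i <= n) {
          moved <- sub$fraction * contrib[i]
          contrib[i] <- contrib[i] - moved
          signal[i, sub$to] <- signal[i, sub$to] + moved
        }
      }
      idx <- cbind(seq_len(n), match(ch, BASES))
      signal[idx] <- signal[idx] + contrib
    }
    if (config$noise_sd > 0)
      signal <- signal * exp(matrix(rnorm(length(signal), 0,
                                          config$noise_sd), n, 4L))
    signal <- add_baseline(signal, config$baseline)
    dominant <- seq_chars(vs[[which.max(p)]]$seq)[seq_len(n)]
    out <- finish_table(signal, dominant, sample_id, primer_name)
    attr(out, "truth") <- mixture
    out
  })
}

#' Render a call-point table as a scan-level chromatogram
#'
#' Places each basecall's per-channel point intensities as isolated peaks
#' `spacing` scans apart (zero signal between peaks), so that
#' [extract_call_points()] with the default 5-scan window recovers the
#' original table exactly.  Used to exercise the trace file formats.
#'
#' @param table a `call_point_table`.
#' @param spacing scans between consecutive basecalls (>= 3 keeps a 5-scan
#'   window from touching the neighbouring peak).
#' @return a [chromatogram()].
#' @export
render_chromatogram <- function(table, spacing = 4L) {
  stopifnot(spacing >= 3L)
  n <- nrow(table)
  scans <- spacing * (seq_len(n) - 1L) + 3L
  total <- scans[n] + 2L
  channels <- setNames(lapply(BASES, function(b) {
    v <- numeric(total)
    v[scans] <- table[[paste0("point_", b)]]
    v
  }), BASES)
  chromatogram(channels, data.frame(base = table$call, scan = scans),
               sample_id = attr(table, "sample_id"),
               primer_name = attr(table, "primer_name"),
               direction = attr(table, "direction"))
}

#' Write a complete synthetic dataset to a directory
#'
#' Emits the reference FASTA, clone and direct reads in the tabular trace
#' dialect, a run manifest, and a ground-truth manifest (JSON), so
#' pipeline commands can be exercised end to end without external data.
#'
#' @param dir output directory (created if needed).
#' @param config a [generator_config()].
#' @param mixture mixture truth as for [simulate_direct_read()].
#' @param substitutions substitution truths as for
#'   [simulate_direct_read()].
#' @param sample_id sample identifier used in the manifest.
#' @return the manifest data frame, invisibly; files are written under
#'   `dir`.
#' @export
simulate_dataset <- function(dir, config, mixture,
                             substitutions = list(),
                             sample_id = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- make_reference(config)
  write_fasta(c(reference = ref$amplicon), file.path(dir, "reference.fasta"))
  rows <- list()
  for (i in seq_len(config$n_clones)) {
    rd <- simulate_clone_read(ref$amplicon, config,
                              seed = config$seed + i,
                              sample_id = sample_id)
    f <- sprintf("clone_%02d.tsv", i)
    write_trace_tsv(render_chromatogram(rd), file.path(dir, f))
    rows[[length(rows) + 1L]] <-
      data.frame(file = f, sample_id = sample_id, primer = "fw",
                 direction = "forward", read_type = "clone")
  }
  rd <- simulate_direct_read(ref$amplicon, ref$tracks, mixture, config,
                             substitutions = substitutions,
                             seed = config$seed + 1000L,
                             sample_id = sample_id)
  write_trace_tsv(render_chromatogram(rd), file.path(dir, "direct_fw.tsv"))
  rows[[length(rows) + 1L]] <-
    data.frame(file = "direct_fw.tsv", sample_id = sample_id,
               primer = "fw", direction = "forward", read_type = "direct")
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(dir, "manifest.tsv"))
  jsonlite::write_json(list(seed = config$seed, mixture = mixture,
                            substitutions = substitutions,
                            tracks = ref$tracks,
                            annotation = ref$annotation),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
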