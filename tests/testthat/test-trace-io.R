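# Chromatogram reading, call-point extraction, orientation.

test_that("tabular trace dialect round-trips", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("scan\tcall\tA\tC\tG\tT",
               "1\t.\t0\t0\t0\t0",
               "10\tA\t120\t5\t0\t0",
               "20\tC\t0\t200\t0\t10",
               "30\tG\t0\t0\t90\t0",
               "31\t.\t0\t0\t0\t0"), tsv)
  chrom <- read_chromatogram(tsv, "tabular", sample_id = "s1")
  expect_s3_class(chrom, "chromatogram")
  expect_equal(nrow(chrom$basecalls), 3L)
  expect_equal(length(chrom$channels$A), 5L)
  expect_equal(chrom$basecalls$base, c("A", "C", "G"))

  # full round trip through the writer on a generated read
  w <- tm_clean_world()
  rd <- simulate_clone_read(substr(w$ref$amplicon, 1, 60), w$cfg, seed = 3)
  chrom2 <- render_chromatogram(rd)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_trace_tsv(chrom2, out)
  back <- read_chromatogram(out, "tabular")
  expect_equal(back$channels, chrom2$channels)
  expect_equal(back$basecalls$base, chrom2$basecalls$base)
})

test_that("a non-monotonic scan column is rejected", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("scan\tcall\tA\tC\tG\tT",
               "1\tA\t10\t0\t0\t0",
               "3\tC\t0\t10\t0\t0",
               "2\tG\t0\t0\t10\t0"), tsv)
  expect_error(read_chromatogram(tsv, "tabular"),
               class = "tracemix_format_error")
})

test_that("ABIF files written by the generator read back bit-for-bit", {
  channels <- list(A = c(0, 5, 100, 3, 0, 0, 40, 0),
                   C = c(1, 0, 0, 0, 90, 0, 0, 0),
                   G = c(0, 0, 2, 0, 0, 0, 0, 7),
                   T = c(0, 80, 0, 0, 0, 60, 0, 0))
  chrom <- chromatogram(channels,
                        data.frame(base = c("T", "A", "C", "T"),
                                   scan = c(2L, 3L, 5L, 6L)),
                        sample_id = "ab1test")
  f <- withr::local_tempfile(fileext = ".ab1")
  write_abif(chrom, f)
  back <- read_chromatogram(f, "ab1")
  expect_identical(lapply(back$channels, as.numeric), channels)
  expect_equal(back$basecalls, chrom$basecalls)
  # a corrupt file is refused with a named-field error
  g <- withr::local_tempfile(fileext = ".ab1")
  writeBin(charToRaw("NOTABIF!"), g)
  expect_error(read_chromatogram(g, "ab1"), "magic",
               class = "tracemix_format_error")
})

test_that("extract_call_points equals a brute-force sliding maximum", {
  set.seed(41)
  nscan <- 200
  channels <- setNames(lapply(1:4, function(i) runif(nscan, 0, 1000)),
                       c("A", "C", "G", "T"))
  scans <- sort(sample(3:(nscan - 2), 30))
  calls <- sample(c("A", "C", "G", "T"), 30, replace = TRUE)
  chrom <- chromatogram(channels, data.frame(base = calls, scan = scans))
  for (w in c(1L, 3L, 5L, 7L)) {
    tab <- extract_call_points(chrom, window = w)
    half <- (w - 1) %/% 2
    for (b in c("A", "C", "G", "T")) {
      brute <- vapply(scans, function(s)
        max(channels[[b]][max(1, s - half):min(nscan, s + half)]),
        numeric(1))
      expect_equal(tab[[paste0("win_", b)]], brute)
      expect_equal(tab[[paste0("point_", b)]], channels[[b]][scans])
    }
  }
  # degenerate window: maxima collapse onto the call points
  t1 <- extract_call_points(chrom, window = 1L)
  expect_equal(tracemix:::win_matrix(t1), tracemix:::point_matrix(t1))
  expect_error(extract_call_points(chrom, window = 4L),
               class = "tracemix_parameter_error")
})

test_that("window maxima capture off-center minor peaks", {
  # called peak 80 at the call scan; a minor peak of 90 two scans away on
  # another channel must appear in the window but not the point value
  A <- c(0, 0, 50, 80, 60, 0, 0)
  C <- c(0, 90, 0, 20, 0, 0, 0)
  chrom <- chromatogram(list(A = A, C = C, G = numeric(7), T = numeric(7)),
                        data.frame(base = "A", scan = 4L))
  tab <- extract_call_points(chrom, window = 5L)
  expect_equal(tab$point_A, 80)
  expect_equal(tab$win_A, 80)
  expect_equal(tab$point_C, 20)
  expect_equal(tab$win_C, 90)
})

test_that("orient_read complements and reverses, and is an involution", {
  # reverse read called TGCA with the A-channel peak on its first position:
  # forward-oriented it must read TGCA -> complement ACGT reversed = ACGT?
  # worked by hand: reverse of complement(T,G,C,A)=(A,C,G,T) is (T,G,C,A)
  # read backwards = A at the end on the T channel
  point <- matrix(0, 4, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  point[1, "T"] <- 500  # called T at position 1
  point[2, "G"] <- 400
  point[3, "C"] <- 300
  point[4, "A"] <- 200
  tab <- toy_observed(point, call = c("T", "G", "C", "A"))
  fwd <- orient_read(tab, "reverse")
  expect_equal(fwd$call, c("T", "G", "C", "A"))  # revcomp of TGCA is TGCA
  # the original first-position T peak is now the last position, channel A
  expect_equal(fwd$win_A[4], 500)
  expect_equal(fwd$win_C[3], 400)  # G 400 at pos 2 -> C 400 at new pos 3
  # involution: applying the reverse transform twice restores the data
  twice <- orient_read(fwd, "reverse")
  expect_equal(tracemix:::win_matrix(twice), tracemix:::win_matrix(tab),
               ignore_attr = TRUE)
  expect_equal(twice$call, tab$call)
  # multiset of intensities is preserved
  expect_equal(sort(as.numeric(tracemix:::win_matrix(fwd))),
               sort(as.numeric(point)))
  # forward orientation is the identity apart from the flag
  f2 <- orient_read(tab, "forward")
  expect_true(attr(f2, "direction_normalized"))
  expect_equal(f2$call, tab$call)
})
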