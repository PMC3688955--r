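# Region annotation, thresholds, replicate statistics, profile comparison.

test_that("boundary motifs delimit the ITS regions", {
  amp <- paste0("GG", "GATCATTA", strrep("N", 254), "ACAACTTC",
                strrep("R", 30), "TCTGAGCG", strrep("N", 323),
                "CGCTGAAT", "GG")
  ann <- locate_regions(amp)
  expect_equal(unname(ann$lengths["ITS1"]), 254L)
  expect_equal(unname(ann$lengths["ITS2"]), 323L)
  # a missing border motif is named in the error
  expect_error(locate_regions(sub("CGCTGAAT", "CGCTCAAT", amp)),
               "CGCTGAAT", class = "tracemix_annotation_error")
  # a duplicated motif is refused too
  expect_error(locate_regions(paste0(amp, "GATCATTA")),
               class = "tracemix_annotation_error")
  # annotation inverts the synthetic amplicon constructor for any seed
  for (s in c(1, 7, 23)) {
    ref <- make_reference(generator_config(seed = s))
    a <- locate_regions(ref$amplicon)
    expect_equal(unname(a$its1), ref$annotation$its1)
    expect_equal(unname(a$its2), ref$annotation$its2)
    expect_equal(unname(a$lengths), c(254L, 323L))
  }
})

test_that("detection thresholds zero out sub-threshold features", {
  raw <- c(ITS1_len_252 = 3, ITS1_len_253 = 25, ITS1_len_254 = 72,
           ITS1_sub_169_A = 17, ITS1_sub_173_A = 8)
  thr <- apply_thresholds(raw)
  expect_equal(unname(thr), c(0, 25, 72, 17, 0))
  # idempotent
  expect_equal(apply_thresholds(thr), thr)
  # monotone: raising a threshold never adds features
  support <- function(x) names(x)[x > 0]
  thr2 <- apply_thresholds(raw, length_threshold = 30,
                           substitution_threshold = 20)
  expect_true(all(support(thr2) %in% support(thr)))
  # no renormalization: surviving totals may fall short of 100
  lens <- thr[grepl("_len_", names(thr))]
  expect_lt(sum(lens), 100)
  # works on its_profile objects too
  p <- apply_thresholds(its_profile("s", raw))
  expect_equal(p$features, thr)
})

test_that("replicate statistics reproduce the published run table", {
  tab <- read.delim(tracemix_example("efluviatilis_its1_replicates.tsv"))
  v253 <- setNames(tab$ITS1_len_253, tab$condition)
  st <- replicate_stats(v253, reference_idx = 1:3)
  expect_equal(st$mean, 25.03)
  # three-replicate range below the 5% permitted error, in fact below 1
  expect_lt(replicate_stats(v253, 1:3, 1:3)$range, 1)
  expect_equal(replicate_stats(v253, 1:3, 1:3)$range, 0.73)
  # primer-ratio robustness: deviations 0.38 and 0.35
  expect_equal(unname(st$deviation[c("primers_2to1", "primers_1to2")]),
               c(0.38, 0.35))
  # template titration: 1.14 (10 ng) and 2.26 (1 ng)
  expect_equal(unname(st$deviation[c("10ng", "1ng")]), c(1.14, 2.26))
  # substitution analysis across the three replicates has range 2
  subs <- setNames(tab$ITS1_sub_169_A, tab$condition)
  expect_equal(replicate_stats(subs, 1:3, 1:3)$range, 2)
  # degenerate cases
  expect_equal(replicate_stats(c(5, 5, 5), 1:3)$deviation,
               c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(replicate_stats(c(5, 5, 5), 1:3)$range, 0)
  expect_error(replicate_stats(c(1, 2), reference_idx = 1),
               class = "tracemix_parameter_error")
})

test_that("distinguishing-feature counts form a symmetric premetric", {
  p1 <- its_profile("a", c(ITS1_len_253 = 25, ITS1_len_254 = 75,
                           ITS1_sub_169_A = 35))
  expect_equal(count_distinguishing_features(p1, p1), 0L)
  p2 <- its_profile("b", c(ITS1_len_253 = 82, ITS1_len_254 = 10,
                           ITS1_len_255 = 8, ITS1_sub_169_A = 79))
  expect_equal(count_distinguishing_features(p1, p2),
               count_distinguishing_features(p2, p1))
  # absent features are 0: the 255-nt variant counts once
  cmp <- compare_profiles(p1, p2)
  expect_equal(cmp$value_a[cmp$feature == "ITS1_len_255"], 0)
  expect_equal(sum(cmp$distinguishing), 4L)
  # margin criterion ignores differences within the permitted error
  p3 <- its_profile("c", c(ITS1_len_253 = 27, ITS1_len_254 = 73,
                           ITS1_sub_169_A = 41))
  expect_equal(count_distinguishing_features(p1, p3), 3L)
  expect_equal(count_distinguishing_features(p1, p3, criterion = "margin"),
               0L)
})

test_that("published strain profiles separate as reported", {
  its1 <- read_its_profiles(tracemix_example("efluviatilis_its1_profiles.tsv"))
  its2 <- read_its_profiles(tracemix_example("efluviatilis_its2_profiles.tsv"))
  full <- lapply(names(its1), function(s)
    its_profile(s, c(its1[[s]]$features, its2[[s]]$features)))
  names(full) <- names(its1)
  # different strains from one site: 10 distinguishing features
  expect_equal(count_distinguishing_features(full$V1, full$V2), 10L)
  expect_equal(count_distinguishing_features(full$V1, full$V2,
                                             criterion = "margin"), 10L)
  # same strain: differences confined to the ITS2 length proportions
  cmp <- compare_profiles(full$Pe1, full$Pe2, criterion = "margin")
  diffs <- cmp$feature[cmp$distinguishing]
  expect_gt(length(diffs), 0L)
  expect_true(all(grepl("^ITS2_len_", diffs)))
})

test_that("profile tables round-trip through the TSV layout", {
  ps <- list(A = its_profile("A", c(ITS1_len_253 = 25, ITS1_len_254 = 75)),
             B = its_profile("B", c(ITS1_len_253 = 80,
                                    ITS1_sub_169_A = 40)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_its_profiles(ps, f)
  back <- read_its_profiles(f)
  expect_equal(names(back), c("A", "B"))
  expect_equal(back$A$features[["ITS1_len_253"]], 25)
  # absent features materialize as 0 in the aligned table
  expect_equal(back$A$features[["ITS1_sub_169_A"]], 0)
  expect_equal(back$B$features[["ITS1_len_254"]], 0)
})
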