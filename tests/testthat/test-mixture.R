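# The proportion model: variant enumeration, mixture simulation, fitting,
# and the two-site joint-deletion identity.

test_that("variant enumeration spans the shift range of the track", {
  v1 <- enumerate_variants("AATTTTCC", c(3, 6), 1)
  expect_equal(v1$shifts, -1:1)
  expect_equal(v1$labels, c("7", "8", "9"))
  v2 <- enumerate_variants("AATTCC", c(3, 4), 2)
  expect_equal(v2$shifts, -2:2)
  # deletions larger than the track are dropped
  v3 <- suppressWarnings(enumerate_variants("AATTCC", c(3, 4), 3))
  expect_equal(min(v3$shifts), -2L)
  # ITS1-like reference of length 254 with the track at 177-179
  ref254 <- paste0(substr(strrep("ACGACG", 50), 1, 176), "TTT",
                   substr(strrep("CAGCAG", 50), 1, 75))
  expect_equal(nchar(ref254), 254L)
  v4 <- enumerate_variants(ref254, c(177, 179), 2)
  expect_equal(v4$labels, as.character(252:256))
  # non-homopolymer site warns but still enumerates
  expect_warning(enumerate_variants("AACGTT", c(2, 3), 1), "homopolymer")
})

test_that("mixture simulation equals the brute-force superposition oracle", {
  set.seed(9)
  bases <- c("A", "C", "G", "T", "T", "T", "A", "C", "G", "A", "C", "G")
  prof <- toy_profile(100 * 1:12, bases)   # distinct values per position
  v <- enumerate_variants(paste(bases, collapse = ""), c(4, 6), 1)
  for (p in list(c(1, 0, 0), c(0, 1, 0), c(0.5, 0.5, 0),
                 c(0.25, 0.5, 0.25))) {
    sim <- simulate_mixture(prof, v, p, positions = 1:10)
    orc <- oracle_mixture(prof, v$shifts, p, 1:10, 4)
    expect_equal(sim$signal, orc)
  }
  # a single variant at 100% is exactly the shifted profile
  pure <- simulate_mixture(prof, v, c(0, 1, 0), positions = 1:10)
  expect_equal(unname(pure$signal[1, "A"]), 100)
  expect_equal(unname(pure$position_sum), unname(prof$mean[1:10]))
})

test_that("mixture simulation is linear in the proportions", {
  set.seed(10)
  n <- 40
  bases <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  bases[10:12] <- "T"; bases[c(9, 13)] <- "A"
  prof <- toy_profile(runif(n, 600, 1400), bases)
  v <- enumerate_variants(paste(bases, collapse = ""), c(10, 12), 1)
  p1 <- c(0.6, 0.3, 0.1); p2 <- c(0.1, 0.2, 0.7)
  for (a in c(0, 0.25, 0.5, 1)) {
    mix <- simulate_mixture(prof, v, a * p1 + (1 - a) * p2,
                            positions = 1:(n - 2))
    lin <- a * simulate_mixture(prof, v, p1, positions = 1:(n - 2))$signal +
      (1 - a) * simulate_mixture(prof, v, p2, positions = 1:(n - 2))$signal
    expect_equal(mix$signal, lin)
  }
  # proportions must sum to one
  expect_error(simulate_mixture(prof, v, c(0.5, 0.4, 0.2)),
               class = "tracemix_parameter_error")
})

test_that("noiseless fits are exact for grid-aligned truths", {
  w <- tm_clean_world()
  v <- enumerate_variants(w$ref$amplicon, w$ref$tracks$ITS1, 1)
  mk_obs <- function(p) {
    sim <- simulate_mixture(w$prof, v, p)
    ok <- !is.na(sim$signal[, 1])
    toy_observed(sim$signal[ok, , drop = FALSE])
  }
  # self-consistency at (0.25, 0.75): exact grid recovery, zero objective
  obs <- mk_obs(c(0, 0.25, 0.75))
  fit <- fit_proportions(obs, w$prof, v,
                         window = c(w$ref$tracks$ITS1[1],
                                    w$ref$tracks$ITS1[1] + 199))
  expect_equal(unname(fit$proportions), c(0, 0.25, 0.75))
  expect_equal(fit$objective, 0, tolerance = 1e-6)
  # pure reference
  fit0 <- fit_proportions(mk_obs(c(0, 1, 0)), w$prof, v,
                          window = c(w$ref$tracks$ITS1[1],
                                     w$ref$tracks$ITS1[1] + 199))
  expect_equal(unname(fit0$proportions), c(0, 1, 0))
  # exhaustive oracle equivalence over the full 5% simplex grid (3 variants)
  grid <- tracemix:::simplex_grid(3L, 20L) / 20
  for (j in seq_len(ncol(grid))) {
    f <- fit_proportions(mk_obs(grid[, j]), w$prof, v, grid_step = 0.05,
                         window = c(w$ref$tracks$ITS1[1],
                                    w$ref$tracks$ITS1[1] + 199))
    expect_equal(unname(f$proportions), grid[, j])
  }
})

test_that("window guards are enforced", {
  w <- tm_clean_world()
  v <- enumerate_variants(w$ref$amplicon, w$ref$tracks$ITS1, 1)
  sim <- simulate_mixture(w$prof, v, c(0, 0.5, 0.5))
  ok <- !is.na(sim$signal[, 1])
  obs <- toy_observed(sim$signal[ok, , drop = FALSE])
  a <- w$ref$tracks$ITS1[1]
  expect_error(fit_proportions(obs, w$prof, v, window = c(a, a + 39)),
               class = "tracemix_parameter_error")
  expect_warning(fit_proportions(obs, w$prof, v, window = c(a, a + 99)),
                 "shorter than 200")
  zero <- toy_observed(matrix(0, nrow(obs), 4,
                              dimnames = list(NULL, c("A", "C", "G", "T"))))
  expect_error(suppressWarnings(
    fit_proportions(zero, w$prof, v, window = c(a, a + 210))),
    class = "tracemix_degenerate_signal_error")
})

test_that("recovery under 5% noise stays within the permitted error", {
  w <- tm_noisy_world()
  cw <- tm_clean_world()
  v <- enumerate_variants(w$ref$amplicon, w$ref$tracks$ITS1, 1)
  a <- w$ref$tracks$ITS1[1]
  mix <- list(shifts = list(c(ITS1 = -1L), c(ITS1 = 0L)),
              proportions = c(0.25, 0.75))
  errs <- vapply(1:10, function(s) {
    obs <- tm_direct_obs(cw, mix, seed = 7000 + s, noise_sd = 0.05)
    fit <- fit_proportions(obs, w$prof, v, window = c(a, a + 249))
    abs(fit$proportions[["916"]] - 0.25)
  }, numeric(1))
  expect_true(all(errs <= 0.05))
})

test_that("recovery error shrinks as the window grows", {
  w <- tm_noisy_world()
  cw <- tm_clean_world()
  v <- enumerate_variants(w$ref$amplicon, w$ref$tracks$ITS1, 1)
  a <- w$ref$tracks$ITS1[1]
  mix <- list(shifts = list(c(ITS1 = -1L), c(ITS1 = 0L)),
              proportions = c(0.25, 0.75))
  rmse <- function(len) {
    e <- vapply(1:20, function(s) {
      obs <- tm_direct_obs(cw, mix, seed = 900 + s, noise_sd = 0.05)
      fit <- suppressWarnings(
        fit_proportions(obs, w$prof, v, window = c(a, a + len - 1)))
      fit$proportions[["916"]] - 0.25
    }, numeric(1))
    sqrt(mean(e^2))
  }
  r <- c(rmse(50), rmse(100), rmse(200))
  expect_true(r[3] <= r[2] && r[2] <= r[1])
})

test_that("joint-deletion inference reproduces the two-site identity", {
  # published two-site rows: length distribution + one measured site give
  # the other site exactly
  expect_equal(infer_joint_site_proportions(
    c("321" = 54, "322" = 19, "323" = 27), 62), 65)
  expect_equal(infer_joint_site_proportions(
    c("321" = 87, "322" = 8, "323" = 5), 87), 95)
  expect_equal(infer_joint_site_proportions(
    c("321" = 48, "322" = 38, "323" = 13), 64), 70)
  expect_equal(infer_joint_site_proportions(
    c("321" = 20, "322" = 25, "323" = 55), 33), 32)
  expect_equal(infer_joint_site_proportions(c("323" = 100), 0), 0)
  expect_error(infer_joint_site_proportions(c("321" = 60, "322" = 50), 10),
               class = "tracemix_validation_error")
  expect_error(infer_joint_site_proportions(c("321" = 150, "322" = -50), 10),
               class = "tracemix_validation_error")

  # conservation property on random two-site pools: d1 + d2 always equals
  # 2 P(L-2) + P(L-1), so inferring one site from the other is exact
  set.seed(33)
  for (i in 1:20) {
    pj <- runif(4); pj <- 100 * pj / sum(pj)     # (none, d1 only, d2 only, both)
    lens <- c("323" = pj[1], "322" = pj[2] + pj[3], "321" = pj[4])
    d1 <- pj[2] + pj[4]; d2 <- pj[3] + pj[4]
    expect_equal(infer_joint_site_proportions(lens, d1), d2,
                 tolerance = 1e-9)
  }
})
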