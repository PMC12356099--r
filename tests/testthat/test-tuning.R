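test_that("site information matches closed forms", {
  # uniform rate carries no information
  expect_equal(site_information(rep(3, 4), rep(0.25, 4)), 0)
  # one-hot rate under uniform visits carries log2(4) = 2 bits/spike
  expect_equal(site_information(c(5, 0, 0, 0), rep(0.25, 4)), 2)
  # direct evaluation of the formula for a graded curve
  expect_equal(site_information(c(2, 1, 1, 1), rep(0.25, 4)), 0.07807,
               tolerance = 1e-4)
  # zero overall rate is flagged undefined
  r <- site_information(c(0, 0, 0, 0), rep(0.25, 4))
  expect_true(is.na(r))
  expect_true(attr(r, "uninformative"))
})

test_that("site information agrees with a term-by-term oracle and is scale invariant", {
  set.seed(21)
  brute <- function(lambda, p) {
    lbar <- 0
    for (x in seq_along(lambda)) lbar <- lbar + lambda[x] * p[x]
    acc <- 0
    for (x in seq_along(lambda)) {
      if (lambda[x] > 0)
        acc <- acc + (lambda[x] / lbar) * log2(lambda[x] / lbar) * p[x]
    }
    acc
  }
  for (rep in 1:1000) {
    lambda <- runif(4, 0, 20)
    if (rep %% 7 == 0) lambda[sample(4, 1)] <- 0
    p <- runif(4); p <- p / sum(p)
    expect_lt(abs(site_information(lambda, p) - brute(lambda, p)), 1e-12)
    k <- runif(1, 0.1, 10)
    expect_equal(site_information(k * lambda, p),
                 site_information(lambda, p), tolerance = 1e-12)
  }
})

test_that("selectivity index follows the normalized-difference definition", {
  expect_equal(selectivity_index(c(5, 0, 0, 0))$index, 1)
  s <- selectivity_index(c(4, 2, 1, 0))
  expect_equal(s$index, 0.5)
  expect_equal(s$preferred, 1)
  expect_equal(selectivity_index(c(3, 3, 0, 0))$index, 0)
  expect_true(selectivity_index(c(0, 0, 0, 0))$undefined)
})

test_that("shuffle test behaves at the extremes", {
  set.seed(8)
  # identical rates at every event: zero information, not significant
  flat <- data.frame(site = rep(1:4, each = 25), rate = 2)
  r0 <- shuffle_significance(flat, 1:4, n_shuffles = 100)
  expect_equal(r0$information, 0)
  expect_false(r0$significant)
  # strong tuning: significant with normalized information > 1
  strong <- data.frame(site = rep(1:4, each = 25),
                       rate = rpois(100, rep(c(20, 1, 1, 1), each = 25)))
  r1 <- shuffle_significance(strong, 1:4, n_shuffles = 200)
  expect_true(r1$significant)
  expect_gt(r1$normalized_information, 1)
  expect_lt(r1$p_value, 0.01)
  # fewer than two sites represented is an error
  expect_error(shuffle_significance(data.frame(site = rep(1, 10),
                                               rate = rpois(10, 3)), 1:4),
               "2 distinct sites")
})

test_that("preferred-site match and chance level behave as expected", {
  set.seed(9)
  pref <- sample(1:4, 200, replace = TRUE)
  r <- preferred_match_stats(pref, pref, n_scrambles = 200)
  expect_equal(r$match_fraction, 1)
  pg <- sample(1:4, 200, replace = TRUE)
  r2 <- preferred_match_stats(pref, pg, n_scrambles = 500)
  expect_lt(abs(r2$chance_mean - 0.25), 0.03)
  expect_error(preferred_match_stats(integer(0), integer(0)))
})

test_that("tuning-curve correlations and the scramble null behave correctly", {
  set.seed(10)
  a <- matrix(runif(40), 10, 4)
  r <- tuning_correlation(a, a, n_scrambles = 10)
  expect_equal(r$r, rep(1, 10))
  # a curve against its reversal correlates negatively
  x <- c(4, 3, 1, 0)
  rr <- tuning_correlation(matrix(x, 1, byrow = TRUE),
                           matrix(rev(x), 1, byrow = TRUE),
                           n_scrambles = 0)
  expect_lt(rr$r, 0)
  # independent curves: null centered near zero
  b <- matrix(runif(400), 100, 4)
  cc <- matrix(runif(400), 100, 4)
  rn <- tuning_correlation(b, cc, n_scrambles = 20)
  expect_lt(abs(mean(rn$null)), 0.05)
  # zero-variance curves are excluded and counted
  bz <- b; bz[1, ] <- 1
  rz <- tuning_correlation(bz, cc, n_scrambles = 0)
  expect_equal(rz$n_excluded, 1)
})

test_that("place maps localize synthetic fields and stay flat for untuned cells", {
  fx <- fixture_session()
  s <- fx$session
  pop <- fixture_population()
  # a place cell's map peaks in the bin set containing its field center
  j <- 1  # preferred site 1
  m <- place_rate_map(pop$spikes[[j]], s$trace, fx$segments, s$arena,
                      offsets = 0)
  pk <- which(m$rate == max(m$rate), arr.ind = TRUE)[1, ]
  half <- s$arena$arena_side / 2
  ctr <- seq(-half, half, length.out = 41)
  ctr <- (ctr[-1] + ctr[-41]) / 2
  site <- s$arena$site_positions[1, ]
  expect_lt(sqrt((ctr[pk[1]] - site[1])^2 + (ctr[pk[2]] - site[2])^2), 100)
  # no spikes: all-zero rate on visited bins
  m0 <- place_rate_map(numeric(0), s$trace, fx$segments, s$arena,
                       offsets = 0)
  expect_equal(max(m0$rate), 0)
  # a homogeneous Poisson cell yields a map whose occupancy-weighted mean
  # rate is near its true rate
  set.seed(2)
  flat_spec <- neuron_spec(baseline_rate = 8, place_gain = 0, gaze_gain = 0)
  fp <- generate_spike_population(list(flat_spec), s, rng_seed = 31)
  mf <- place_rate_map(fp$spikes[[1]], s$trace, fx$segments, s$arena,
                       offsets = 0)
  wmean <- sum(mf$rate[mf$mask] * mf$occupancy[mf$mask]) /
    sum(mf$occupancy[mf$mask])
  expect_lt(abs(wmean - 8) / 8, 0.1)
})

test_that("Hamming smoothing conserves total mass over a full mask", {
  set.seed(12)
  K <- remotegaze:::hamming_kernel2d(11)
  expect_equal(sum(K), 1, tolerance = 1e-12)
  M <- matrix(0, 40, 40)
  # mass concentrated in the interior
  M[12:28, 12:28] <- rpois(17 * 17, 3)
  full_mask <- matrix(TRUE, 40, 40)
  S <- remotegaze:::conv2d_masked(M, K, full_mask)
  expect_equal(sum(S), sum(M), tolerance = 1e-9)
  # with mass near the edge, renormalization keeps totals within
  # kernel-edge tolerance
  M2 <- matrix(rpois(1600, 3), 40, 40)
  S2 <- remotegaze:::conv2d_masked(M2, K, full_mask)
  expect_lt(abs(sum(S2) - sum(M2)) / sum(M2), 0.05)
})

test_that("gaze maps separate tuned from untuned cells", {
  fx <- fixture_session()
  s <- fx$session
  pop <- fixture_population()
  # tuned cell (preferred site 1), contra eye = right
  mt <- gaze_rate_map(pop$spikes[[1]], s$trace, fx$segments, s$arena,
                      s$calib, eye = "right", stride = 4)
  set.seed(3)
  flat <- generate_spike_population(
    list(neuron_spec(baseline_rate = 4, place_gain = 0, gaze_gain = 0)),
    s, rng_seed = 17)
  mu <- gaze_rate_map(flat$spikes[[1]], s$trace, fx$segments, s$arena,
                      s$calib, eye = "right", stride = 4)
  cv <- function(m) {
    v <- m$rate[m$mask & m$occupancy > stats::quantile(m$occupancy[m$mask], 0.5)]
    sd(v) / mean(v)
  }
  expect_gt(cv(mt), cv(mu))
  # argmax of the tuned map lies closer to the preferred site than to
  # any other site (cone footprints elongate along the gaze line)
  pk <- which(mt$rate == max(mt$rate), arr.ind = TRUE)[1, ]
  half <- s$arena$arena_side / 2
  ctr <- seq(-half, half, length.out = 41)
  ctr <- (ctr[-1] + ctr[-41]) / 2
  d_site <- sqrt((ctr[pk[1]] - s$arena$site_positions[, 1])^2 +
                   (ctr[pk[2]] - s$arena$site_positions[, 2])^2)
  expect_equal(which.min(d_site[1:4]), 1)
  # no center fixations is an error
  empty <- fx$segments[fx$segments$state == "dash", ]
  expect_error(gaze_rate_map(pop$spikes[[1]], s$trace, empty, s$arena,
                             s$calib), "fixations")
})

test_that("population tuning summary recovers generator preferences", {
  fx <- fixture_session()
  pop <- fixture_population()
  tun <- tuning_summary(pop, fx$segments, fx$session$arena,
                        n_shuffles = 200)
  truth <- rep(1:4, 3)
  expect_gte(mean(tun$preferred_place == truth), 0.9)
  expect_gte(mean(tun$preferred_gaze == truth), 0.9)
  expect_gte(mean(tun$sig_place), 0.9)
  expect_gte(mean(tun$sig_gaze), 0.9)
  expect_true(all(tun$norm_I_place[tun$sig_place] > 1))
})
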