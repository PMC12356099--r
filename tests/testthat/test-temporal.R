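test_that("PSTHs behave at the degenerate ends", {
  expect_error(event_aligned_rate(c(1, 2), numeric(0)), "at least one")
  # no spikes: zero everywhere
  p0 <- event_aligned_rate(numeric(0), c(1, 2, 3))
  expect_true(all(p0$rate == 0))
  # one spike exactly at each event: peak at lag zero
  ev <- seq(10, 100, by = 5)
  p1 <- event_aligned_rate(ev, ev, window = c(-0.2, 0.2), sigma = 0.03)
  expect_lt(abs(p1$t[which.max(p1$rate)]), 0.01)
})

test_that("a homogeneous Poisson train gives a flat PSTH at its rate", {
  set.seed(31)
  r <- 20
  st <- sort(runif(r * 500, 0, 500))
  ev <- seq(10, 490, by = 2)
  p <- event_aligned_rate(st, ev, window = c(-0.5, 0.5), sigma = 0.03)
  sem <- mean(p$sem)
  expect_lt(abs(mean(p$rate) - r), 2 * sem)
  expect_lt(sd(p$rate), 3 * sem)
})

test_that("PSTH counts and smoothing conserve area", {
  set.seed(32)
  ev <- seq(5, 95, by = 1)
  st <- sort(runif(3000, 0, 100))
  win <- c(-0.4, 0.4)
  praw <- event_aligned_rate(st, ev, window = win, sigma = 0)
  # integral of the raw PSTH times n_events equals the total in-window
  # spike count, exactly
  total <- sum(vapply(ev, function(e)
    sum(st >= e + win[1] & st < e + win[1] + praw$bin * length(praw$t)), 0))
  expect_equal(sum(praw$raw) * praw$bin * praw$n_events, total)
  # Gaussian smoothing preserves the area to numerical precision when the
  # response mass sits away from the window edges (elsewhere the
  # truncated-kernel renormalization trades exact conservation for
  # unbiased edge rates)
  bump <- sort(unlist(lapply(ev, function(e) rnorm(4, e + 0.05, 0.02))))
  pb <- event_aligned_rate(bump, ev, window = win, sigma = 0.03)
  expect_lt(abs(sum(pb$rate) - sum(pb$raw)) / sum(pb$raw), 1e-9)
})

# place spikes as Gaussian bumps at given latencies after each event
bump_train <- function(events, latency, sd, n_per = 3) {
  sort(unlist(lapply(events, function(e)
    rnorm(n_per, e + latency, sd))))
}

test_that("early/late peaks separate biphasic response profiles", {
  set.seed(33)
  ev <- seq(5, 600, by = 1.5)
  # late-only cell
  late_cell <- bump_train(ev, 0.187, 0.03)
  pl <- event_aligned_rate(late_cell, ev, window = c(-0.3, 0.5),
                           sigma = 0.03)
  el <- early_late_peaks(pl)
  expect_gt(el$late_peak, 3 * el$early_peak)
  expect_lt(el$difference, 0)
  # symmetric kernels of equal amplitude: difference near zero
  sym <- sort(c(bump_train(ev, 0.017, 0.02), bump_train(ev, 0.187, 0.02)))
  ps <- event_aligned_rate(sym, ev, window = c(-0.3, 0.5), sigma = 0.03)
  es <- early_late_peaks(ps)
  expect_lt(abs(es$difference) / max(es$early_peak, es$late_peak), 0.25)
  # insufficient coverage errors
  short <- event_aligned_rate(late_cell, ev, window = c(0, 0.1))
  expect_error(early_late_peaks(short), "window")
})

test_that("population sorting recovers graded early/late weights", {
  set.seed(34)
  ev <- seq(5, 900, by = 1.5)
  w_early <- seq(0, 1, length.out = 12)
  psths <- lapply(w_early, function(w) {
    st <- sort(c(bump_train(ev, 0.017, 0.02, n_per = round(8 * w)),
                 bump_train(ev, 0.187, 0.03, n_per = round(8 * (1 - w)))))
    event_aligned_rate(st, ev, window = c(-0.3, 0.5), sigma = 0.03)
  })
  res <- early_late_population(psths)
  expect_gt(cor(res$difference, w_early, method = "spearman"), 0.9)
  M <- attr(res, "normalized")
  expect_true(all(apply(M, 1, max) <= 1 + 1e-12))
})

test_that("bivariate early matrices expose prev/next dependence patterns", {
  set.seed(35)
  n <- 5000
  prev_d <- runif(n, 0, 90)
  next_d <- runif(n, 0, 90)
  noise <- function() rnorm(n, 0, 0.05)
  m_next <- bivariate_early_matrix(exp(-next_d^2 / (2 * 30^2)) + noise(),
                                   prev_d, next_d)
  m_prev <- bivariate_early_matrix(exp(-prev_d^2 / (2 * 30^2)) + noise(),
                                   prev_d, next_d)
  m_both <- bivariate_early_matrix(exp(-(next_d^2 + prev_d^2) / (2 * 30^2))
                                   + noise(), prev_d, next_d)
  spread <- function(x) diff(range(x, na.rm = TRUE))
  # next-only dependence: strong variation along columns, little along rows
  expect_gt(spread(m_next$next_marginal), 4 * spread(m_next$prev_marginal))
  expect_gt(spread(m_prev$prev_marginal), 4 * spread(m_prev$next_marginal))
  expect_gt(spread(m_both$next_marginal), 0.2)
  expect_gt(spread(m_both$prev_marginal), 0.2)
  # conditional slice (prev in [30, 40)) follows the next-distance profile
  expect_gt(m_next$conditional[1], m_next$conditional[length(m_next$conditional)])
})

test_that("condition-split PSTHs diverge only where the generator modulates them", {
  set.seed(36)
  ev_on <- seq(5, 600, by = 3)
  ev_off <- seq(6.5, 600, by = 3)
  # light scales the late component only
  on_cell <- sort(c(bump_train(ev_on, 0.017, 0.02, 3),
                    bump_train(ev_on, 0.187, 0.03, 6),
                    bump_train(ev_off, 0.017, 0.02, 3),
                    bump_train(ev_off, 0.187, 0.03, 2)))
  ev <- c(ev_on, ev_off)
  lab <- rep(c("on", "off"), c(length(ev_on), length(ev_off)))
  ps <- condition_psth(on_cell, ev, lab, reference = "off",
                       window = c(-0.3, 0.5), sigma = 0.03)
  tt <- ps$on$t
  early_win <- tt >= -0.01 & tt <= 0.06
  late_win <- tt >= 0.14 & tt <= 0.24
  rel_diff <- function(w) {
    a <- mean(ps$on$rate[w]); b <- mean(ps$off$rate[w])
    abs(a - b) / max(a, b)
  }
  expect_lt(rel_diff(early_win), 0.2)
  expect_gt(rel_diff(late_win), 0.5)
  expect_true(!is.null(ps$off$norm_rate))
  expect_equal(max(ps$off$norm_rate), 1)
  expect_warning(condition_psth(on_cell, ev,
                                factor(lab, levels = c("on", "off", "catch")),
                                window = c(-0.1, 0.1)),
                 NA)  # unused factor levels are simply absent, no warning
})

test_that("the early-response linear model recovers sparse structure", {
  set.seed(37)
  n <- 3000
  cells <- rep(1:5, each = n / 5)
  cov <- data.frame(h_prev = rnorm(n), v_prev = rnorm(n))
  cov$h_prev2 <- cov$h_prev^2
  cov$v_prev2 <- cov$v_prev^2
  cov$h_next <- rnorm(n); cov$v_next <- rnorm(n)
  cov$h_next2 <- cov$h_next^2
  cov$v_next2 <- cov$v_next^2
  base <- c(1, 3, 5, 7, 9)[cells]
  y <- base - 0.8 * cov$v_next2 + rnorm(n, 0, 0.8)
  res <- early_response_model(y, cov, cells)
  expect_true(res$significant[res$term == "v_next2"])
  expect_equal(res$estimate[res$term == "v_next2"], -0.8, tolerance = 0.1)
  expect_false(any(res$significant[res$term %in%
                                     c("h_prev", "v_prev", "h_prev2")]))
  # per-cell intercepts absorb baselines: shared coefficients unchanged
  y2 <- y + 10 * (cells == 3)
  res2 <- early_response_model(y2, cov, cells)
  expect_equal(res2$estimate[res2$term == "v_next2"],
               res$estimate[res$term == "v_next2"], tolerance = 1e-9)
  # pure-noise rates: about zero significant coefficients
  hits <- replicate(30, {
    yn <- rnorm(n)
    sum(early_response_model(yn, cov, cells)$significant)
  })
  expect_lt(mean(hits), 0.3)
  expect_error(early_response_model(y[cells == 1], cov[cells == 1, ],
                                    cells[cells == 1]), "two cells")
})
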