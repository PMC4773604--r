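test_that("weight profiles average synapses by generator state", {
  net <- build_network(case_config("A"))
  p <- weight_profile(net, "pfpc", complex = 0)
  expect_length(p, 500)
  expect_true(all(p == 5))
  # one depressed state shows as a single dip at its index
  gc_ids <- 4 * (42 - 1) + 1:4       # cells of state 42
  net$w_pfpc[gc_ids, 1:10] <- 1
  p <- weight_profile(net, "pfpc", complex = 0)
  expect_equal(which(p < 5), 42)
  expect_equal(p[42], 1)
  # untouched complex stays flat
  expect_true(all(weight_profile(net, "pfpc", complex = 1) == 5))
  m <- weight_profile(net, "mfdcn", complex = 0)
  expect_length(m, 25)
})

test_that("counter-phase score behaves like a signed correlation", {
  x <- sin(seq(0, 2 * pi, length.out = 500))
  xb <- vapply(1:25, function(i) mean(x[(i - 1) * 20 + 1:20]), numeric(1))
  expect_equal(counter_phase_score(x, -xb), -1)
  expect_equal(counter_phase_score(x, xb), 1)
  # sign-flip symmetries
  y <- xb + rnorm(25, sd = 0.1)
  expect_equal(counter_phase_score(x, y), counter_phase_score(-x, -y))
  expect_equal(counter_phase_score(x, y), -counter_phase_score(-x, y))
  expect_warning(s <- counter_phase_score(rep(1, 500), rep(2, 25)),
                 "zero-variance")
  expect_true(is.na(s))
})

test_that("reverse cross-correlation summarizes anti-correlation magnitude", {
  set.seed(31)
  x <- rpois(200, 2)
  anti <- max(x) - x                    # binwise complement
  r <- reverse_cross_correlation(x, anti, binned = TRUE, bin = 0.01)
  expect_equal(r$summary, 1, tolerance = 1e-9)
  expect_true(all(abs(r$correlation) <= 1 + 1e-12, na.rm = TRUE))
  # identical trains are maximally correlated, hence minimally anti-correlated
  same <- reverse_cross_correlation(x, x, binned = TRUE, bin = 0.01)
  expect_lt(same$summary, r$summary - 0.5)
  # independent trains: summary within the permutation null
  a <- rpois(500, 1.5); b <- rpois(500, 1.5)
  obs <- reverse_cross_correlation(a, b, binned = TRUE, bin = 0.01)$summary
  null <- replicate(60, reverse_cross_correlation(sample(a), b,
                                                  binned = TRUE,
                                                  bin = 0.01)$summary)
  expect_lt(obs, mean(null) + 3 * sd(null))
  # spike-time interface and empty-train handling
  expect_warning(e <- reverse_cross_correlation(numeric(0), c(1, 2)),
                 "empty")
  expect_true(is.na(e$summary))
})

test_that("averaged gain is the microcomplex mean weight", {
  net <- build_network(case_config("A", pcdcn_init_mode = "zero"))
  expect_equal(averaged_gain(net, "pcdcn", 0), 0)
  net$w_pcdcn[1:10] <- 4
  expect_equal(averaged_gain(net, "pcdcn", 0), 4)
  net$w_pcdcn[11:15] <- 6
  expect_equal(averaged_gain(net, "pcdcn", 1), 3)
  net$w_mfdcn[, 1] <- 2.5
  expect_equal(averaged_gain(net, "mfdcn", 0), 2.5)
})

test_that("convergence detection finds settling of step and exponential series", {
  expect_equal(convergence_trial(rep(3, 400)), 1)
  step <- c(rep(0, 300), rep(10, 700))
  ct <- convergence_trial(step)
  expect_lt(abs(ct - 300), 55)               # within the smoothing window
  tau <- 150
  expo <- 10 * (1 - exp(-(1:2000) / tau))
  ct <- convergence_trial(expo, fraction = 0.05)
  expect_gt(ct, 2 * tau)
  expect_lt(ct, 4 * tau)                     # ~3 tau settling
  # a series still rising at the end is only "converged" near the end
  expect_gt(convergence_trial(seq(0, 1, length.out = 400)), 300)
})

test_that("error reduction percentage is plain window arithmetic", {
  mae <- c(rep(2, 10), rep(0.5, 10))
  expect_equal(error_reduction_pct(mae, 1:10, 11:20), 75)
  expect_equal(error_reduction_pct(mae, 1:10, 1:10), 0)
  expect_equal(error_reduction_pct(c(1, 0), 1, 2), 100)
  expect_error(error_reduction_pct(c(0, 1), 1, 2), "zero baseline")
})

test_that("two-timescale ordering holds for constructed exponentials", {
  n <- 4000
  f <- function(tau) 5 * (1 - exp(-(1:n) / tau))
  res <- two_timescale_check(f(100), f(500), f(1000))
  expect_true(res$pass)
  expect_true(res$pfpc < res$mfdcn && res$mfdcn <= res$pcdcn)
  tie <- two_timescale_check(rep(1, n), rep(1, n), rep(1, n))
  expect_false(tie$pass)
  expect_true(tie$tie)
})
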