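test_that("eligibility-trace depression matches the brute-force double loop", {
  set.seed(5)
  cfg <- pfpc_rule_config(truncation_window = 100)  # effectively untruncated
  for (rep in 1:5) {
    pf <- lapply(1:8, function(i) sort(runif(sample(0:30, 1), 0, 2)))
    t_cf <- 2 + runif(1)
    dw <- pfpc_on_cf_spike(pf, t_cf, cfg)
    oracle <- vapply(pf, function(ts)
      oracle_pfpc_ltd(ts, t_cf, cfg$tau_ltd, cfg$ltd_scale), numeric(1))
    expect_equal(dw, oracle, tolerance = 1e-9)
  }
})

test_that("depression peaks for parallel-fiber spikes one delay earlier", {
  cfg <- pfpc_rule_config()      # tau_ltd calibrated for 100 ms
  peak <- pfpc_ltd_kernel(atan(20))
  dw <- pfpc_on_cf_spike(list(0.9), 1.0, cfg)
  expect_equal(dw, -cfg$ltd_scale * peak, tolerance = 1e-9)
  # coincident spike contributes nothing; empty buffer likewise
  expect_equal(pfpc_on_cf_spike(list(1.0), 1.0, cfg), 0)
  expect_equal(pfpc_on_cf_spike(list(numeric(0)), 1.0, cfg), 0)
  expect_error(pfpc_on_cf_spike(list(1.2), 1.0, cfg), "future")
})

test_that("fixed potentiation is additive in the spike count", {
  cfg <- pfpc_rule_config(alpha_ltp = 0.002)
  expect_equal(pfpc_on_pf_spike(cfg), 0.002)
  expect_equal(pfpc_on_pf_spike(cfg, 7), 7 * 0.002)
  expect_equal(pfpc_on_pf_spike(pfpc_rule_config(alpha_ltp = 0), 5), 0)
  expect_equal(mfdcn_on_mf_spike(mfdcn_rule_config(alpha_ltp = 0.01), 3),
               0.03)
})

test_that("two-sided mossy depression equals the double loop via both event views", {
  set.seed(6)
  cfg <- mfdcn_rule_config()
  for (rep in 1:5) {
    mf <- sort(runif(40, 0, 2))
    pc <- sort(runif(60, 0, 2))
    # past view on each Purkinje spike + deferred view on each mossy spike
    dw <- sum(vapply(pc, function(tp)
      mfdcn_on_pc_spike(list(mf), tp, cfg), numeric(1))) +
      sum(vapply(mf, function(tm)
        mfdcn_on_mf_spike_ltd(pc, tm, cfg), numeric(1)))
    oracle <- oracle_mfdcn_ltd(mf, pc, cfg$sigma, cfg$beta, cfg$ltd_scale,
                               cfg$truncation_window)
    expect_equal(dw, oracle, tolerance = 1e-9)
  }
  # single coincident pair depresses by the kernel peak
  expect_equal(mfdcn_on_pc_spike(list(1), 1, cfg), -cfg$ltd_scale)
  # quarter-period offset contributes nothing
  expect_equal(mfdcn_on_pc_spike(list(1 - cfg$sigma * pi / 2), 1, cfg), 0,
               tolerance = 1e-12)
  expect_equal(mfdcn_on_pc_spike(list(numeric(0)), 1, cfg), 0)
})

test_that("symmetric inhibitory rule equals the brute-force double loop", {
  set.seed(7)
  cfg <- pcdcn_rule_config("symmetric")
  for (rep in 1:5) {
    pre <- sort(runif(80, 0, 2))
    post <- sort(runif(50, 0, 2))
    expect_equal(apply_pcdcn_stdp(pre, post, cfg),
                 oracle_pcdcn_symmetric(pre, post, cfg), tolerance = 1e-9)
  }
})

test_that("Hebbian pairing follows nearest-neighbour semantics", {
  cfg <- pcdcn_rule_config("hebbian", scale = 1, tau1 = 0.02, tau2 = 0.02,
                           pre_decay = 0)
  # single causal pair potentiates, single anti-causal pair depresses
  expect_equal(apply_pcdcn_stdp(0.1, 0.12, cfg), exp(-0.02 / 0.02))
  expect_equal(apply_pcdcn_stdp(0.12, 0.1, cfg), -exp(-0.02 / 0.02))
  # nearest neighbour only: a post spike pairs with the latest pre spike
  dw <- apply_pcdcn_stdp(c(0.08, 0.1), 0.12, cfg)
  expect_equal(dw, exp(-0.02 / 0.02))
  # coincident pre/post: potentiation only (tie-break)
  expect_equal(apply_pcdcn_stdp(0.1, 0.1, cfg), 1)
  # pre_decay adds constant decay per presynaptic spike
  cfg2 <- pcdcn_rule_config("hebbian", scale = 1, pre_decay = 0.5)
  expect_equal(apply_pcdcn_stdp(c(1, 2, 3), numeric(0), cfg2), -1.5)
})

test_that("inhibitory rules decay without postsynaptic spikes and potentiate with them", {
  set.seed(8)
  pre <- sort(runif(200, 0, 2))
  for (k in c("hebbian", "symmetric")) {
    cfg <- pcdcn_rule_config(k)
    expect_lte(apply_pcdcn_stdp(pre, numeric(0), cfg), 0)
  }
  # forced near-coincident post activity potentiates under both kernels
  post <- pre + 0.001
  for (k in c("hebbian", "symmetric")) {
    cfg <- pcdcn_rule_config(k)
    expect_gt(apply_pcdcn_stdp(pre, post, cfg), 0)
  }
})

test_that("weights never go negative under any update sequence", {
  # run the full engine briefly from near-zero weights with strong LTD
  net <- build_network(case_config("A", pcdcn_init_mode = "random",
                                   pcdcn_init_scale = 0.05))
  net$w_pfpc[] <- 0.02
  r <- run_case_a(10, seed = 1, net = net,
                  pfpc = pfpc_rule_config(ltd_scale = 5, alpha_ltp = 0),
                  mfdcn = mfdcn_rule_config(ltd_scale = 1, alpha_ltp = 1e-4))
  expect_true(all(r$net$w_pfpc >= 0))
  expect_true(all(r$net$w_mfdcn >= 0))
  expect_true(all(r$net$w_pcdcn >= 0))
})
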