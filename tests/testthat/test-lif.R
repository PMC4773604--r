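test_that("a silent neuron stays at rest and a perturbed one relaxes back", {
  p <- lif_params()
  st <- population_state(1, p)
  res <- step_population(st, p, 0.002)
  expect_equal(res$state$membrane_potential, p$resting_potential)
  expect_equal(sum(res$spikes), 0)

  st$membrane_potential <- p$resting_potential + 5
  v <- numeric(1000)
  for (i in 1:1000) {
    res <- step_population(st, p, 0.002)
    st <- res$state
    v[i] <- st$membrane_potential
  }
  d <- diff(c(p$resting_potential + 5, v))
  expect_true(all(d <= 0))
  expect_true(all(d[1:100] < 0))
  expect_equal(v[1000], p$resting_potential, tolerance = 1e-6)
})

test_that("one strong excitatory spike gives one spike then refractory silence", {
  p <- lif_params(refractory_period = 5)
  st <- population_state(1, p)
  exc <- matrix(0, 10, 1)
  exc[1, 1] <- 500  # way super-threshold
  res <- step_population(st, p, 0.002, exc)
  expect_equal(res$spikes[1, 1], 1)
  # refractory (5 ms) spans steps 2-3 even though conductance persists
  expect_equal(sum(res$spikes[2:3, ]), 0)
})

test_that("conductance traces decay exactly exponentially", {
  p <- lif_params(tau_exc = 0.5, tau_inh = 10)
  st <- population_state(1, p)
  w <- 3.7
  res <- step_population(st, p, 0.002, exc_weights = w, inh_weights = w / 2)
  g1e <- res$state$g_exc
  g1i <- res$state$g_inh
  expect_equal(g1e, w * exp(-2 / 0.5), tolerance = 1e-9)
  expect_equal(g1i, w / 2 * exp(-2 / 10), tolerance = 1e-9)
  # n further silent steps: g multiplied by exp(-n*dt/tau)
  res <- step_population(res$state, p, 0.002, matrix(0, 7, 1), matrix(0, 7, 1))
  expect_equal(res$state$g_exc / g1e, exp(-7 * 2 / 0.5), tolerance = 1e-9)
  expect_equal(res$state$g_inh / g1i, exp(-7 * 2 / 10), tolerance = 1e-9)
})

test_that("no neuron ever fires twice within its refractory period", {
  set.seed(42)
  p <- lif_params(refractory_period = 5)
  st <- population_state(5, p)
  exc <- matrix(runif(500 * 5, 0, 30), 500, 5)
  res <- step_population(st, p, 0.002, exc)
  for (i in 1:5) {
    tms <- rep((which(res$spikes[, i] > 0) - 1) * 2, # step onset, ms
               res$spikes[which(res$spikes[, i] > 0), i])
    # spike times are only known to step resolution (2 ms)
    if (length(tms) > 1) expect_true(all(diff(tms) >= 5 - 2))
  }
})

test_that("identical seeds and configs give identical runs", {
  net <- build_network(case_config("A", pcdcn_init_mode = "fixed"))
  r1 <- run_case_a(5, seed = 7, net = net)
  net2 <- build_network(case_config("A", pcdcn_init_mode = "fixed"))
  r2 <- run_case_a(5, seed = 7, net = net2)
  expect_identical(r1$log, r2$log)
  expect_identical(r1$net$w_pfpc, r2$net$w_pfpc)
  expect_identical(r1$final$y, r2$final$y)
})

test_that("the generic router delivers spikes with a one-step delay", {
  # two-neuron chain: stimulating neuron 1 at step n fires neuron 2 at n+1
  p <- lif_params(refractory_period = 2)
  net <- list(populations = list(A = list(size = 1, params = p),
                                 B = list(size = 1, params = p)),
              projections = list(list(pre = "A", post = "B", type = "exc",
                                      synapses = data.frame(pre_id = 1,
                                                            post_id = 1,
                                                            weight = 500))))
  st <- network_state(net)
  st <- run_network_step(net, st, external = list(A = 500), dt = 0.002)
  expect_equal(st$pending$A, 1)   # A fired at step n
  expect_equal(st$pending$B, 0)
  st <- run_network_step(net, st, dt = 0.002)
  expect_equal(st$pending$B, 1)   # B fires at step n+1

  # empty network step produces no spikes
  st0 <- network_state(net)
  st0 <- run_network_step(net, st0, dt = 0.002)
  expect_true(all(unlist(st0$pending) == 0))

  # dangling projection index is a configuration error
  bad <- net
  bad$projections[[1]]$synapses$post_id <- 99
  expect_error(run_network_step(bad, network_state(bad),
                                external = list(A = 500)),
               "dangling")
})
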