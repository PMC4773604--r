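test_that("static torques match the hand-derived gravity moments", {
  # horizontal-zero variant so the closed form is easy to write down
  arm <- planar_arm(payload = 6, base_angle = 0)
  tau <- arm_inverse_dynamics(arm, c(0, 0, 0), c(0, 0, 0), c(0, 0, 0))
  g <- 9.81
  m <- arm$masses; L <- arm$lengths; lc <- arm$coms
  t1 <- g * (m[1] * lc[1] + m[2] * (L[1] + lc[2]) +
               m[3] * (L[1] + L[2] + lc[3]) + 6 * sum(L))
  t2 <- g * (m[2] * lc[2] + m[3] * (L[2] + lc[3]) + 6 * (L[2] + L[3]))
  t3 <- g * (m[3] * lc[3] + 6 * L[3])
  expect_equal(tau, c(t1, t2, t3), tolerance = 1e-10)
  # hanging home pose carries no static load at rest
  hang <- planar_arm(payload = 6)
  expect_equal(arm_inverse_dynamics(hang, c(0, 0, 0), c(0, 0, 0), c(0, 0, 0)),
               c(0, 0, 0), tolerance = 1e-10)
})

test_that("torques are linear in the inertial parameters", {
  q <- c(0.3, -0.2, 0.5); qd <- c(1, -0.5, 0.2); qdd <- c(2, 1, -1)
  a1 <- planar_arm(masses = c(2, 1.5, 1), inertias = c(0.03, 0.02, 0.01),
                   payload = 3)
  a2 <- planar_arm(masses = 2 * c(2, 1.5, 1),
                   inertias = 2 * c(0.03, 0.02, 0.01), payload = 6)
  expect_equal(arm_inverse_dynamics(a2, q, qd, qdd),
               2 * arm_inverse_dynamics(a1, q, qd, qdd), tolerance = 1e-9)
})

test_that("heavier payloads need monotonically more holding torque", {
  taus <- vapply(c(0, 2, 4, 6, 8), function(m) {
    arm <- planar_arm(payload = m, base_angle = 0)
    arm_inverse_dynamics(arm, c(0, 0, 0), c(0, 0, 0), c(0, 0, 0))[2]
  }, numeric(1))
  expect_true(all(diff(taus) > 0))
})

test_that("the passive frictionless arm conserves mechanical energy", {
  arm <- planar_arm(payload = 2)
  st <- list(q = c(0.4, -0.3, 0.2), qd = c(0, 0, 0))
  e0 <- arm_energy(arm, st$q, st$qd)$total
  drift <- 0
  for (s in 1:500) {
    st <- step_plant(arm, st, c(0, 0, 0), dt = 0.002, friction = 0,
                     n_substeps = 20)
    e <- arm_energy(arm, st$q, st$qd)$total
    drift <- max(drift, abs(e - e0))
  }
  # scale by the energy actually exchanged (KE+|PE swing|)
  expect_lt(drift / (abs(e0) + 1), 0.001)
  # zero torque, zero gravity, at rest: state unchanged
  ng <- planar_arm(gravity = 0)
  st0 <- step_plant(ng, list(q = c(0.1, 0.2, 0.3), qd = c(0, 0, 0)),
                    c(0, 0, 0), friction = 0)
  expect_equal(st0$q, c(0.1, 0.2, 0.3))
  expect_equal(st0$qd, c(0, 0, 0))
})

test_that("the benchmark trajectory is a closed loop with zero end velocities", {
  tc <- trajectory_config(amplitudes = c(0.4, 0.3, 0.2), duration = 1)
  d0 <- desired_joint_state(0, tc)
  d1 <- desired_joint_state(1, tc)
  expect_equal(d0$q[1, 1], 0.4 * sin(pi / 4), tolerance = 1e-12)
  expect_equal(d1$q, d0$q, tolerance = 1e-9)       # phi(1) = 2*pi
  expect_equal(as.vector(d0$qd), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(as.vector(d1$qd), c(0, 0, 0), tolerance = 1e-9)
  expect_error(desired_joint_state(1.5, tc), "outside")
})

test_that("the set-point reference is an antisymmetric twin-Gaussian", {
  cfg <- reference_config(sigma_ref = 0.1, period = 1)
  expect_equal(reference_variable(0.5, cfg), 0)
  expect_equal(reference_variable(0.25, cfg), 1 - exp(-25), tolerance = 1e-12)
  t <- seq(0, 1, by = 0.01)
  expect_equal(reference_variable(t, cfg), -reference_variable(1 - t, cfg),
               tolerance = 1e-12)
})

test_that("a payload-matched crude controller tracks almost perfectly", {
  net <- build_network(case_config("B", pcdcn_init_mode = "zero"))
  r <- run_case_b(1, 1, net, arm = planar_arm(payload = 0),
                  freeze = c("pfpc", "mfdcn", "pcdcn"))
  expect_lt(r$log$mae[1], 0.01)
  # with the payload the frozen baseline error is substantial
  net2 <- build_network(case_config("B", pcdcn_init_mode = "zero"))
  rb <- run_case_b(1, 1, net2, freeze = c("pfpc", "mfdcn", "pcdcn"))
  expect_gt(rb$log$mae[1], 0.02)
})
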