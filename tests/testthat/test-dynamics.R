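test_that("assembled right-hand side matches the relaxation law", {
  sa <- make_fixture("self-activator")
  f <- assemble_rhs(sa, fz_env())
  # at q = 0 the derivative is the gated zero-proposition
  expect_equal(unname(f(c(A = 0), 0)), 1 / (1 + exp(5)), tolerance = 1e-12)
  # at q = mu(v)/alpha with v frozen the derivative vanishes
  qstar <- fz_gate(0.8)
  expect_equal(unname(f(c(A = 0.8), 0)), qstar - 0.8, tolerance = 1e-12)
  # clamped inputs contribute zero derivative
  bt <- biased_toggle()
  env <- fz_env(levels = c(BIAS = 0.3))
  g <- assemble_rhs(bt, env)
  d <- g(c(BIAS = 0.3, A = 0.2, B = 0.9), 0)
  expect_equal(unname(d["BIAS"]), 0)
  expect_equal(unname(d["A"]),
               fz_gate(fz_eval(bt$nodes$A$rule, c(B = 0.9, BIAS = 0.3))) - 0.2)
  # an environment that misses an input is a configuration error
  expect_error(assemble_rhs(bt, fz_env()), class = "fuzzynet_config_error")
})

test_that("integration is deterministic and respects the unit hypercube", {
  net <- make_fixture("toggle")
  t1 <- simulate_network(net, fz_env(), t_end = 30, q0 = c(A = 0.8, B = 0.1))
  t2 <- simulate_network(net, fz_env(), t_end = 30, q0 = c(A = 0.8, B = 0.1))
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_true(all(t1$time == sort(t1$time)))
  for (nm in c("A", "B")) {
    expect_true(all(t1[[nm]] >= -1e-7 & t1[[nm]] <= 1 + 1e-7))
  }
  # t_end = 0: single-sample trajectory equal to the initial state
  t0 <- simulate_network(net, fz_env(), t_end = 0, q0 = c(A = 0.25, B = 0.5))
  expect_equal(nrow(t0), 1)
  expect_equal(unname(unlist(t0[1, c("A", "B")])), c(0.25, 0.5))
})

test_that("the CD4 trajectory stays in [0,1] under unit decay rates", {
  net <- cd4_net_cached()
  traj <- simulate_network(net, preset_env("all_type", cl = 0.75,
                                           manifest = cd4_man_cached()),
                           t_end = 30)
  vals <- as.matrix(as.data.frame(traj)[, -1])
  expect_true(all(vals >= -1e-6 & vals <= 1 + 1e-6))
})

test_that("the fixed-point oracle finds the complete attractor set", {
  # toggle: two asymmetric stable points and the unstable symmetric one
  fp <- fixed_point_oracle(make_fixture("toggle"), grid_step = 0.25)
  expect_equal(nrow(fp), 3)
  expect_true(any(abs(fp$A - 0.5) < 1e-6 & abs(fp$B - 0.5) < 1e-6))
  hi <- fp[which.max(fp$A), ]
  expect_gt(hi$A, 0.99); expect_lt(hi$B, 0.01)
  expect_equal(hi$A + hi$B, 1, tolerance = 1e-6)  # symmetry of the pair
  expect_true(all(fp$residual < 1e-9))

  # self-activator: roots of q = gate(q); cross-check with 1-D bisection
  fp1 <- fixed_point_oracle(make_fixture("self-activator"), grid_step = 0.1)
  expect_equal(nrow(fp1), 3)
  g <- function(q) fz_gate(q) - q
  for (r in sort(fp1$A)) expect_equal(g(r), 0, tolerance = 1e-9)
  lo <- stats::uniroot(g, c(0, 0.2), tol = 1e-12)$root
  expect_equal(min(fp1$A), lo, tolerance = 1e-6)

  # constant network: unique fixed point mu(const)/alpha
  cn <- fz_network(list(fz_node("A", "activation-core", rule = "0.7")))
  fpc <- fixed_point_oracle(cn, grid_step = 0.5)
  expect_equal(nrow(fpc), 1)
  expect_equal(fpc$A, fz_gate(0.7), tolerance = 1e-9)

  # refusal on too many free nodes
  expect_error(fixed_point_oracle(cd4_net_cached(), grid_step = 0.5),
               class = "fuzzynet_refusal_error")
})

test_that("integration endpoints agree with brute-force fixed points", {
  set.seed(421)
  for (kind in c("toggle", "self-activator", "negative-feedback-loop")) {
    net <- make_fixture(kind)
    fp <- fixed_point_oracle(net, grid_step = 0.2)
    fpm <- as.matrix(fp[, internal_cols <- setdiff(names(fp), "residual")])
    for (i in 1:10) {
      q0 <- stats::setNames(stats::runif(length(internal_cols)), internal_cols)
      traj <- simulate_network(net, fz_env(), t_end = 60, q0 = q0)
      endpoint <- unlist(traj[nrow(traj), internal_cols])
      d <- apply(fpm, 1, function(r) max(abs(r - endpoint)))
      expect_lt(min(d), 1e-3)
    }
  }
})

test_that("nodes classified fixed satisfy the steady-state residual bound", {
  net <- make_fixture("toggle")
  traj <- simulate_network(net, fz_env(), t_end = 40, q0 = c(A = 1, B = 0))
  rep <- steady_state(traj)
  expect_true(all(rep$class == "fixed"))
  expect_true(all(rep$residual < 1e-4))
  expect_error(steady_state(traj, window = 100),
               class = "fuzzynet_validation_error")
})

test_that("oscillatory attractors are classified with amplitude and period", {
  net <- cd4_net_cached()
  traj <- simulate_network(net, preset_env("TFH", manifest = cd4_man_cached()),
                           t_end = 120)
  rep <- steady_state(traj)
  b <- rep[rep$node == "BCL6", ]
  expect_identical(b$class, "periodic")
  expect_gt(b$amplitude, 0.05)
  expect_gt(b$period, 1)
  expect_lt(b$period, 30)
  g <- glance(rep)
  expect_gt(g$n_periodic, 3)
  expect_true(all(rep$residual[rep$class == "fixed"] < 1e-4, na.rm = TRUE))
})

test_that("halving the integrator tolerances leaves steady states unchanged", {
  net <- cd4_net_cached()
  env <- preset_env("Th1", manifest = cd4_man_cached())
  a <- simulate_network(net, env, t_end = 30, rtol = 1e-8, atol = 1e-10)
  b <- simulate_network(net, env, t_end = 30, rtol = 5e-9, atol = 5e-11)
  ia <- unlist(a[nrow(a), -1]); ib <- unlist(b[nrow(b), -1])
  expect_lt(max(abs(ia - ib)), 1e-5)
})

test_that("trajectories accumulate decay-limited levels above one when tau > 1", {
  # a held-high node with alpha = 1/4 relaxes to mu/alpha ~ 4
  net <- fz_network(list(fz_node("S", "cytokine-input"),
                         fz_node("X", "regulatory", rule = "S", alpha = 0.25)))
  env <- fz_env(levels = c(S = 1))
  traj <- simulate_network(net, env, t_end = 40)
  expect_equal(traj$X[nrow(traj)], fz_gate(1) / 0.25, tolerance = 1e-4)
})
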