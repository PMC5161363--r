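make_traj <- function(times, y) {
  list(times = times, states = matrix(y, ncol = 1))
}

test_that("steady-state detection applies the 1% band on the window", {
  tm <- 9000:10000
  # constant trajectory: steady at its value
  st <- detect_steady_state(make_traj(tm, rep(3.2, length(tm))), 1)
  expect_true(st$steady)
  expect_equal(st$value, 3.2)
  # 10% ramp across the window: violates the band
  ramp <- seq(1, 1.1, length.out = length(tm))
  expect_false(detect_steady_state(make_traj(tm, ramp), 1)$steady)
  # decayed-to-zero output: steady at 0
  st0 <- detect_steady_state(make_traj(tm, rep(0, length(tm))), 1)
  expect_true(st0$steady)
  expect_equal(st0$value, 0)
  # an output below the integration noise floor is steady at ~0 ...
  stn <- detect_steady_state(make_traj(tm, 1e-20 * exp(-0.01 * (tm - 9000))),
                             1)
  expect_true(stn$steady)
  expect_lt(stn$value, 1e-19)
  # ... but a drift above the floor is not
  expect_false(detect_steady_state(
    make_traj(tm, c(rep(0, 500), rep(1e-6, 501))), 1)$steady)
  expect_error(detect_steady_state(make_traj(0:100, rep(1, 101)), 1),
               "window")
})

test_that("point mode accepts a slow ramp that band mode rejects", {
  tm <- 9000:10000
  ramp <- seq(1, 1.1, length.out = length(tm))
  tr <- make_traj(tm, ramp)
  expect_false(detect_steady_state(tr, 1, mode = "band")$steady)
  # the mid-window sample of a linear ramp equals the window mean
  expect_true(detect_steady_state(tr, 1, mode = "point",
                                  point_frac = 0.5)$steady)
  expect_false(detect_steady_state(tr, 1, mode = "point",
                                   point_frac = 0.99)$steady)
})

test_that("output classification uses the off/on ratio thresholds", {
  expect_equal(output_state(1, 1), "off")          # ratio 1
  expect_equal(output_state(20, 1), "on")          # 20 > 15
  expect_equal(output_state(10, 1), "indeterminate")
  expect_equal(output_state(10, 1, thr = c(off_max = 5, on_min = 10)),
               "indeterminate")
  expect_equal(output_state(11, 1, thr = c(off_max = 5, on_min = 10)),
               "on")
  # decayed baseline: floored denominator keeps any production "on"
  expect_equal(output_state(1e-3, 0), "on")
  expect_equal(output_state(0, 0), "off")
})

test_that("an empty network converges to a unique zero baseline", {
  t <- topology(3, roles = learning_roles())
  p <- make_params(t, eta = c(0.05, 0.05, 0.01))
  out <- converged_unique_state(t, p, input_schedule(input_phase(10000)),
                                n_inits = 5, seed = 3)
  expect_equal(out$status, "ok")
  expect_lt(out$value, 1e-6)
})

test_that("a bistable toggle is rejected as multistable", {
  # mutual inhibition between nodes 1 and 2; node 3 reads node 1.
  t <- topology(3, roles = learning_roles(),
                edges = data.frame(from = c(1, 2, 1), to = c(2, 1, 3),
                                   sign = c("-", "-", "+")))
  p <- make_params(t, eta = c(0.01, 0.01, 0.01),
                   V = 1, k = 1, K = 0.1, alpha = 1, n = 3)
  # 1-D fixed-point oracle: at steady state A1 = g(A2)/eta, A2 = g(A1)/eta
  # with g the inhibition term; roots of f(x) = g(g(x)/eta)/eta - x
  g <- function(x) inhibition_term(x, list(k = 1, K = 0.1, alpha = 1, n = 3))
  f <- function(x) g(g(x) / 0.01) / 0.01 - x
  grid <- c(seq(0, 5, by = 0.01), seq(5, 110, by = 0.5))
  sgn <- sign(f(grid))
  roots <- grid[which(diff(sgn) != 0)]
  expect_gte(length(roots), 3)  # two stable states + the separatrix
  out <- converged_unique_state(t, p, input_schedule(input_phase(10000)),
                                n_inits = 10, seed = 11)
  expect_equal(out$status, "multistable")
})

test_that("n_inits = 1 reduces to plain steady-state detection", {
  t <- topology(3, roles = learning_roles())
  p <- make_params(t, eta = c(0.05, 0.05, 0.01))
  out <- converged_unique_state(t, p, input_schedule(input_phase(10000)),
                                n_inits = 1, seed = 3)
  expect_equal(out$status, "ok")
  expect_lt(out$value, 1e-6)
})

# hand-built learning fixture: R -> M (+), F -> M (+), fast input turnover,
# near-frozen memory node. The trained plateau is a slow linear ramp, so it
# is steady under the mid-window sample rule but not under the full band.
learning_fixture <- function() {
  t <- topology(3, roles = learning_roles(),
                edges = data.frame(from = c(1, 2), to = c(3, 3),
                                   sign = c("+", "+")))
  p <- make_params(t, eta = c(0.05, 0.05, 1e-8), V = 1, k = 0.1, n = 2)
  list(t = t, p = p)
}

test_that("the direct learning motif passes under the survey rules", {
  fx <- learning_fixture()
  cfg <- run_config(n_inits = 4)  # defaults: point + class agreement
  v <- test_learning(fx$t, fx$p, cfg, point_frac = 0.5)
  expect_true(v$passed)
  expect_equal(v$failure_stage, "none")
  # trained plateau dominates the off state by the derived margin:
  # y_on ~ c*(t_wash + t_mid), y_off ~ c*t_wash, c = V_R*V_F
  expect_gt(v$y_on / v$y_off, 15)
  # under the strict band the trained ramp is not a steady plateau
  vb <- test_learning(fx$t, fx$p,
                      run_config(n_inits = 4, steady_mode = "band"),
                      point_frac = 0.5)
  expect_false(vb$passed)
  expect_equal(vb$failure_stage, "no-steady-state")
  # under 1%-value agreement the IC-dependent baseline is multistable
  vv <- test_learning(fx$t, fx$p,
                      run_config(n_inits = 4, ic_agreement = "value"),
                      point_frac = 0.5)
  expect_false(vv$passed)
  expect_equal(vv$failure_stage, "multistable")
})

test_that("food alone must not switch the memory on", {
  # F -> M only: the food signal drives the single activator, so the
  # output follows food alone and the truth table fails at that stage
  t <- topology(3, roles = learning_roles(),
                edges = data.frame(from = 2, to = 3, sign = "+"))
  p <- make_params(t, eta = c(0.05, 0.05, 1e-8), V = 1, k = 0.1, n = 2)
  cfg <- run_config(n_inits = 4)
  v <- test_learning(t, p, cfg, point_frac = 0.5)
  expect_false(v$passed)
  expect_equal(v$failure_stage, "truth-table")
})

test_that("an empty topology fails the learning truth table", {
  t <- topology(3, roles = learning_roles())
  p <- make_params(t, eta = c(0.05, 0.05, 0.01))
  v <- test_learning(t, p, run_config(n_inits = 4))
  expect_false(v$passed)
  expect_equal(v$failure_stage, "truth-table")
})

test_that("the direct recall motif realises the recall truth table", {
  # M -> F&S (+) and R -> F&S (+): multiplicative AND of memory and ring,
  # additive food at the output
  t <- topology(3, roles = recall_roles(),
                edges = data.frame(from = c(1, 2), to = c(3, 3),
                                   sign = c("+", "+")))
  p <- make_params(t, eta = c(0.05, 0.05, 0.01), V = 5, k = 0.1, n = 2)
  v <- test_recall(t, p, run_config(n_inits = 4))
  expect_true(v$passed)
  expect_equal(v$failure_stage, "none")
  # fixed-point oracle: food-only output = V_s*hill(1,k_s,n_s)/eta_S
  fx_on <- 10 * hill(1, 0.1, 2) / 0.01
  expect_equal(v$y_on, 5 * hill(10 * hill(1, 0.1, 2) / 0.05, 0.1, 2) *
                 5 * hill(10 * hill(1, 0.1, 2) / 0.05, 0.1, 2) / 0.01,
               tolerance = 1e-3)
  expect_gt(fx_on, 15 * max(v$y_off, 1e-12))
})

test_that("an empty recall network fails at the memory+ring stage", {
  # the additive food source alone turns the output on, but memory+ring
  # cannot (no production path), so the last truth-table stage fails
  t <- topology(3, roles = recall_roles())
  p <- make_params(t, eta = c(0.05, 0.05, 0.01))
  v <- test_recall(t, p, run_config(n_inits = 4))
  expect_false(v$passed)
  expect_equal(v$failure_stage, "truth-table")
})

test_that("Q of the empty topology is zero for both module functions", {
  t <- topology(3, roles = learning_roles())
  q <- compute_q(t, "learning", n_sets = 25, seed = 4,
                 run_config(n_inits = 3))
  expect_equal(q$q, 0)
  expect_equal(q$n_pass, 0L)
  tr <- topology(3, roles = recall_roles())
  qr <- compute_q(tr, "recall", n_sets = 25, seed = 4,
                  run_config(n_inits = 3))
  expect_equal(qr$q, 0)
})

test_that("compute_q is deterministic given the seed", {
  t <- topology(3, roles = recall_roles(),
                edges = data.frame(from = c(1, 2), to = c(3, 3),
                                   sign = c("+", "+")))
  cfg <- run_config(n_inits = 3)
  a <- compute_q(t, "recall", n_sets = 30, seed = 7, cfg)
  b <- compute_q(t, "recall", n_sets = 30, seed = 7, cfg)
  expect_identical(a, b)
  expect_equal(a$q * a$n_sets, a$n_pass)
})

test_that("select_pool ranks by Q and breaks ties by ID", {
  res <- data.frame(topology_id = c(10, 3, 7, 1),
                    n_sets = 100, n_pass = c(5, 0, 9, 5),
                    q = c(0.05, 0, 0.09, 0.05))
  pool <- select_pool(res, 0.0)
  expect_equal(pool$topology_id, c(7, 1, 10))
  expect_equal(select_pool(res, 0.05)$topology_id, 7)
  expect_equal(nrow(select_pool(res, 1)), 0)
  # monotone: a higher threshold yields a subset
  lo <- select_pool(res, 0.01)$topology_id
  hi <- select_pool(res, 0.06)$topology_id
  expect_true(all(hi %in% lo))
})

test_that("screening results order deterministically by canonical ID", {
  ids <- c(5, 1, 3)
  df <- screen_topologies(ids, "recall", n_sets = 5, seed = 2,
                          run_config(n_inits = 2))
  expect_equal(df$topology_id, sort(ids))
  expect_true(all(df$q == 0))
})
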