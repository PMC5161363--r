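#' Steady-state detection on a trajectory window
#'
#' The reference output value `y0` is the mean of the node's unit-grid
#' samples over the window. In `"band"` mode (default) the trajectory is
#' steady iff every sample in the window satisfies
#' `|y - y0| < rel_tol * y0`; a window that is identically zero is steady
#' at value 0. In `"point"` mode a single test sample (uniformly drawn
#' from the window by the caller, `point_frac`) replaces "every sample".
#'
#' @param traj a trajectory from [simulate()], or any list with `times`
#'   and `states`.
#' @param node node index to test.
#' @param window time window, default `c(9000, 10000)`.
#' @param rel_tol relative band, default 0.01.
#' @param mode `"band"` or `"point"`.
#' @param point_frac position of the test sample within the window
#'   (fraction in `[0, 1]`), used in `"point"` mode.
#' @param atol absolute noise floor added to the band: deviations below
#'   `atol` (default the integrator's absolute tolerance, `1e-9`) are
#'   numerical noise, so an output that has decayed to that level counts
#'   as steady at (numerically) zero.
#' @return list with `steady` (logical) and `value` (`y0`, or `NA` when
#'   not steady).
#' @export
detect_steady_state <- function(traj, node, window = c(9000, 10000),
                                rel_tol = 0.01, mode = "band",
                                point_frac = 0.5, atol = 1e-9) {
  sel <- traj$times >= window[1] & traj$times <= window[2]
  if (!any(sel)) stop("trajectory does not span the window", call. = FALSE)
  y <- traj$states[sel, node]
  steady_window(y, rel_tol, mode, point_frac, atol)
}

steady_window <- function(y, rel_tol, mode, point_frac, atol = 1e-9) {
  y0 <- mean(y)
  ok <- if (mode == "band") {
    all(abs(y - y0) < rel_tol * y0 + atol)
  } else {
    i <- 1L + as.integer(floor(point_frac * (length(y) - 1L)))
    abs(y[i] - y0) < rel_tol * y0 + atol
  }
  # below the integrator's absolute tolerance the value is numerical
  # noise, indistinguishable from zero; snap it so downstream ratios of
  # two noise levels cannot fabricate an on state
  if (ok && y0 < atol) y0 <- 0
  list(steady = ok, value = if (ok) y0 else NA)
}

#' Classify an output as on/off from its signal-on/signal-off ratio
#'
#' The state of the output is the ratio of its steady value when the input
#' condition is applied over its steady value at baseline:
#' below `off_max` the output is off, above `on_min` it is on, and a ratio
#' between the two thresholds is not switch-like and fails the parameter
#' set (`"indeterminate"`). The baseline is floored at `eps` to keep the
#' ratio finite when the off state decays to numerical zero.
#'
#' @param y_on,y_off steady output values (>= 0).
#' @param thr named vector `c(off_max = , on_min = )`; defaults 5/15.
#' @param eps denominator floor.
#' @return `"on"`, `"off"` or `"indeterminate"`.
#' @export
output_state <- function(y_on, y_off, thr = c(off_max = 5, on_min = 15),
                         eps = 1e-12) {
  ratio <- y_on / max(y_off, eps)
  if (ratio < thr[["off_max"]]) "off"
  else if (ratio > thr[["on_min"]]) "on"
  else "indeterminate"
}

# ---- internal machinery -------------------------------------------------

draw_ics <- function(n_nodes, output_nodes, config) {
  ics <- matrix(stats::runif(config$n_inits * n_nodes,
                             config$init_range[1], config$init_range[2]),
                nrow = config$n_inits)
  ics[, output_nodes] <- config$init_output
  ics
}

# Integrate one constant-signal condition for all replicates and check
# per-replicate steadiness of each requested output node. Returns
# list(status, values (n_rep x out_nodes matrix, columns named by node),
# finals (n_rep x n)). Cross-replicate agreement is judged by the caller
# (by value or by classification, per config$ic_agreement).
eval_condition <- function(sys, levels, ics, out_nodes, config,
                           point_frac = 0.5) {
  # unit grid on the evaluation window; elsewhere only the points the
  # verdict needs (the integrator's accuracy is set by rtol/atol, not by
  # the output grid)
  times <- unique(c(0, seq(config$window[1], config$window[2], by = 1),
                    config$t_end))
  res <- integrate_phase(sys, levels, ics, times, config$rtol, config$atol)
  if (!res$ok) return(list(status = "sim-failed"))
  sel <- res$times >= config$window[1] & res$times <= config$window[2]
  values <- matrix(NA_real_, nrow(ics), length(out_nodes),
                   dimnames = list(NULL, as.character(out_nodes)))
  for (node in out_nodes) {
    for (r in seq_len(nrow(ics))) {
      st <- steady_window(res$states[sel, r, node], config$rel_tol,
                          config$steady_mode, point_frac,
                          config$atol_steady)
      if (!st$steady) return(list(status = "no-steady-state"))
      values[r, as.character(node)] <- st$value
    }
  }
  finals <- matrix(res$states[length(res$times), , ], nrow = nrow(ics))
  list(status = "ok", values = values, finals = finals)
}

# 1% relative value agreement across replicates (with the noise floor).
values_agree <- function(vals, config) {
  m <- mean(vals)
  (max(vals) - min(vals)) <= config$agree_tol * abs(m) + config$atol_steady
}

# Classify one condition against the baseline across replicates.
# Returns the unanimous class ("on"/"off") or a failure stage label.
condition_class <- function(cond_vals, base_vals, thr, config) {
  if (config$ic_agreement == "value") {
    if (!values_agree(cond_vals, config)) return("multistable")
    st <- output_state(mean(cond_vals), mean(base_vals), thr,
                       config$eps_ratio)
    if (st == "indeterminate") return("indeterminate-ratio")
    return(st)
  }
  cls <- vapply(seq_along(cond_vals), function(r) {
    output_state(cond_vals[r], base_vals[r], thr, config$eps_ratio)
  }, character(1))
  if (any(cls == "indeterminate")) return("indeterminate-ratio")
  if (length(unique(cls)) > 1) return("multistable")
  cls[1]
}

# Continue all replicates from `finals` under new signal levels.
continue_condition <- function(sys, levels, finals, duration, config,
                               sample_dt = NULL) {
  dt <- if (is.null(sample_dt)) 1 else sample_dt
  times <- seq(0, duration, by = dt)
  if (times[length(times)] < duration) times <- c(times, duration)
  res <- integrate_phase(sys, levels, finals, times, config$rtol,
                         config$atol)
  res
}

fail_verdict <- function(stage) list(passed = FALSE, failure_stage = stage)

signal_levels <- function(config, food = FALSE, ring = FALSE,
                          memory = FALSE) {
  s <- config$signal_on
  c(food = if (food) s else 0, ring = if (ring) s else 0,
    memory = if (memory) s else 0)
}

#' Unique converged steady state across random initial conditions
#'
#' Simulates a topology from `n_inits` random initial conditions
#' (non-output nodes uniform on the configured range, output nodes fixed
#' at 0.1) under the final phase of `schedule`, requiring every run to
#' reach a steady output and all runs to agree on its value within the
#' configured relative tolerance.
#'
#' @param t a [topology()].
#' @param params a parameter set.
#' @param schedule an [input_schedule()]; the last phase must span the
#'   steady-state window.
#' @param n_inits number of initial conditions.
#' @param seed RNG seed for the initial-condition draw.
#' @param config a [run_config()].
#' @param output_node node to read out; defaults to the role-designated
#'   output.
#' @param mode steadiness mode for this op (default the strict
#'   deterministic `"band"`, independent of the screening default).
#' @return list with `status` (`"ok"`, `"no-steady-state"`,
#'   `"multistable"`, `"sim-failed"`) and `value` (the common steady
#'   output when `status == "ok"`).
#' @export
converged_unique_state <- function(t, params, schedule, n_inits = 10,
                                   seed = 1, config = run_config(),
                                   output_node = NULL, mode = "band") {
  config$n_inits <- n_inits
  config$steady_mode <- mode
  if (is.null(output_node)) output_node <- default_output_nodes(t)
  wiring <- signal_wiring(t)
  sys <- build_system(t, params, wiring)
  set.seed(as.integer(seed))
  ics <- draw_ics(t$n_nodes, output_node, config)
  phases <- schedule$phases
  y <- ics
  for (ph in phases[-length(phases)]) {
    res <- continue_condition(sys, ph$levels, y, ph$duration, config)
    if (!res$ok) return(list(status = "sim-failed"))
    y <- matrix(res$states[dim(res$states)[1], , ], nrow = nrow(ics))
  }
  last <- phases[[length(phases)]]
  cfg <- config
  cfg$t_end <- last$duration
  out <- eval_condition(sys, last$levels, y, output_node[1], cfg)
  if (out$status != "ok") return(list(status = out$status, value = NA))
  vals <- out$values[, 1]
  if (!values_agree(vals, cfg)) {
    return(list(status = "multistable", value = NA))
  }
  list(status = "ok", value = mean(vals))
}

default_output_nodes <- function(t) {
  r <- t$roles
  nodes <- unname(r[names(r) %in% c("memory_output", "output_fs")])
  if (!length(nodes)) stop("topology has no output role", call. = FALSE)
  sort(unique(nodes))
}

#' Test the learning function on one parameter set
#'
#' The learning module must behave as a conditioned memory switch: with no
#' signal the memory output settles to a unique low baseline from every
#' initial condition; food alone and ring alone must leave it off (ratio
#' to baseline below `off_max`); food and ring together must switch it on
#' (ratio above `on_min`) to a steady plateau; and after the signals are
#' removed the output must still hold at least `retain_frac` of the
#' plateau at the persistence checkpoint. Stages run in order with early
#' exit on the first failure.
#'
#' @param t a [topology()] with learning roles.
#' @param params a parameter set for `t`.
#' @param config a [run_config()].
#' @param ics optional initial-condition matrix (`n_inits x n_nodes`);
#'   drawn from `config$seed` when omitted.
#' @param point_frac steady-test sample position for
#'   `steady_mode = "point"`.
#' @return a verdict: list with `passed` and `failure_stage` (one of
#'   `none`, `no-steady-state`, `multistable`, `indeterminate-ratio`,
#'   `truth-table`, `persistence`, `sim-failed`), plus `y_off`/`y_on`
#'   when reached.
#' @export
test_learning <- function(t, params, config = run_config(), ics = NULL,
                          point_frac = 0.5) {
  out_node <- t$roles[["memory_output"]]
  wiring <- signal_wiring(t)
  sys <- build_system(t, params, wiring)
  if (is.null(ics)) {
    set.seed(as.integer(config$seed))
    ics <- draw_ics(t$n_nodes, out_node, config)
  }
  thr <- config$ratio_submodule

  base <- eval_condition(sys, signal_levels(config), ics, out_node, config,
                         point_frac)
  if (base$status != "ok") return(fail_verdict(base$status))
  y_off <- base$values[, 1]
  if (config$ic_agreement == "value" && !values_agree(y_off, config)) {
    return(fail_verdict("multistable"))
  }

  for (cond in list(signal_levels(config, food = TRUE),
                    signal_levels(config, ring = TRUE))) {
    res <- eval_condition(sys, cond, ics, out_node, config, point_frac)
    if (res$status != "ok") return(fail_verdict(res$status))
    cls <- condition_class(res$values[, 1], y_off, thr, config)
    if (cls %in% c("multistable", "indeterminate-ratio")) {
      return(fail_verdict(cls))
    }
    if (cls != "off") return(fail_verdict("truth-table"))
  }

  both <- eval_condition(sys, signal_levels(config, food = TRUE,
                                            ring = TRUE),
                         ics, out_node, config, point_frac)
  if (both$status != "ok") return(fail_verdict(both$status))
  cls <- condition_class(both$values[, 1], y_off, thr, config)
  if (cls %in% c("multistable", "indeterminate-ratio")) {
    return(fail_verdict(cls))
  }
  if (cls != "on") return(fail_verdict("truth-table"))
  y_on <- both$values[, 1]

  hold <- continue_condition(sys, signal_levels(config), both$finals,
                             config$t_check - config$t_end, config,
                             sample_dt = config$t_check - config$t_end)
  if (!hold$ok) return(fail_verdict("sim-failed"))
  held <- hold$states[dim(hold$states)[1], , out_node]
  if (any(held < config$retain_frac * y_on)) {
    return(fail_verdict("persistence"))
  }

  list(passed = TRUE, failure_stage = "none", y_off = mean(y_off),
       y_on = mean(y_on))
}

#' Test the recall function on one parameter set
#'
#' The recall module must salivate for food alone (food enters the output
#' node additively), stay quiet for memory alone or ring alone, and
#' salivate when memory and ring co-occur (their terms compose
#' multiplicatively). All conditions are judged against the shared no-signal
#' baseline; there is no persistence requirement.
#'
#' @inheritParams test_learning
#' @param t a [topology()] with recall roles.
#' @return a verdict, as for [test_learning()].
#' @export
test_recall <- function(t, params, config = run_config(), ics = NULL,
                        point_frac = 0.5) {
  out_node <- t$roles[["output_fs"]]
  wiring <- signal_wiring(t)
  sys <- build_system(t, params, wiring)
  if (is.null(ics)) {
    set.seed(as.integer(config$seed))
    ics <- draw_ics(t$n_nodes, out_node, config)
  }
  thr <- config$ratio_submodule

  base <- eval_condition(sys, signal_levels(config), ics, out_node, config,
                         point_frac)
  if (base$status != "ok") return(fail_verdict(base$status))
  y_off <- base$values[, 1]
  if (config$ic_agreement == "value" && !values_agree(y_off, config)) {
    return(fail_verdict("multistable"))
  }

  conds <- list(list(signal_levels(config, food = TRUE), "on"),
                list(signal_levels(config, memory = TRUE), "off"),
                list(signal_levels(config, ring = TRUE), "off"),
                list(signal_levels(config, memory = TRUE, ring = TRUE),
                     "on"))
  y_on <- NA_real_
  for (cd in conds) {
    res <- eval_condition(sys, cd[[1]], ics, out_node, config, point_frac)
    if (res$status != "ok") return(fail_verdict(res$status))
    cls <- condition_class(res$values[, 1], y_off, thr, config)
    if (cls %in% c("multistable", "indeterminate-ratio")) {
      return(fail_verdict(cls))
    }
    if (cls != cd[[2]]) return(fail_verdict("truth-table"))
    if (cd[[2]] == "on") y_on <- mean(res$values[, 1])
  }
  list(passed = TRUE, failure_stage = "none", y_off = mean(y_off),
       y_on = y_on)
}

#' Q-value of a topology: fraction of parameter sets that realise a function
#'
#' Draws `n_sets` Latin hypercube parameter sets for the topology (seeded
#' by the run seed XOR the canonical topology ID, so topologies are
#' independent and reproducible) and evaluates the requested function test
#' on each. The Q-value is the pass fraction — the robustness of the
#' topology with respect to its kinetic parameters.
#'
#' @param t a [topology()] (learning or recall roles) or a
#'   [combine_networks()] result (tested with [test_pavlovian()]).
#' @param test `"learning"`, `"recall"`, `"pavlovian"`, or a function
#'   `(t, params, config, ics, point_frac) -> verdict`.
#' @param n_sets parameter sets to draw (>= 1).
#' @param seed run seed.
#' @param config a [run_config()].
#' @return list of class `q_result`: `topology_id`, `n_sets`, `n_pass`,
#'   `q`.
#' @export
compute_q <- function(t, test, n_sets = 1000, seed = 1,
                      config = run_config()) {
  combined <- inherits(t, "combined_network")
  topo <- if (combined) t$topology else t
  id <- encode_id(topo)
  test_fun <- if (is.function(test)) {
    test
  } else {
    switch(test,
           learning = test_learning,
           recall = test_recall,
           pavlovian = test_pavlovian,
           stop("unknown test: ", test, call. = FALSE))
  }
  target <- if (combined || identical(test, "pavlovian")) t else topo
  wiring <- if (combined) combined_wiring(t) else signal_wiring(topo)
  base_seed <- topology_seed(seed, id)
  psets <- sample_parameters(topo, n_sets, base_seed, config$ranges,
                             wiring, config$integer_hill)
  out_nodes <- default_output_nodes(topo)
  n_pass <- 0L
  for (i in seq_len(n_sets)) {
    set.seed((base_seed + 7919L * i) %% 2147483647L)
    ics <- draw_ics(topo$n_nodes, out_nodes, config)
    pf <- stats::runif(1)
    v <- try(test_fun(target, psets[[i]], config, ics = ics,
                      point_frac = pf), silent = TRUE)
    if (!inherits(v, "try-error") && isTRUE(v$passed)) n_pass <- n_pass + 1L
  }
  structure(list(topology_id = id, n_sets = n_sets, n_pass = n_pass,
                 q = n_pass / n_sets), class = "q_result")
}

#' Screen a set of topologies and collect Q-values
#'
#' @param ids canonical topology IDs to screen.
#' @param test `"learning"` or `"recall"` (or a test function).
#' @param n_sets,seed,config as in [compute_q()].
#' @param roles role map for decoded topologies; defaults to the role set
#'   matching `test`.
#' @param workers forked parallel workers (requires the `parallel`
#'   package; results are merged in canonical-ID order either way).
#' @return data frame `topology_id`, `n_sets`, `n_pass`, `q`.
#' @export
screen_topologies <- function(ids, test, n_sets = 1000, seed = 1,
                              config = run_config(), roles = NULL,
                              workers = 1L) {
  if (is.null(roles)) {
    roles <- if (identical(test, "recall")) recall_roles() else
      learning_roles()
  }
  ids <- sort(ids)
  one <- function(id) {
    t <- decode_id(id, 3, roles)
    q <- compute_q(t, test, n_sets, seed, config)
    data.frame(topology_id = id, n_sets = q$n_sets, n_pass = q$n_pass,
               q = q$q)
  }
  rows <- if (workers > 1L && requireNamespace("parallel", quietly = TRUE)) {
    parallel::mclapply(ids, one, mc.cores = workers)
  } else {
    lapply(ids, one)
  }
  out <- do.call(rbind, rows)
  out[order(out$topology_id), , drop = FALSE]
}

#' Select the robust pool from screening results
#'
#' Keeps topologies with Q strictly above the threshold, ranked by
#' descending Q with ties broken by ascending canonical ID.
#'
#' @param results data frame from [screen_topologies()] (or a list of
#'   `q_result`s).
#' @param q_threshold selection cutoff (e.g. 0.007 for learning, 0.008
#'   for recall).
#' @return data frame `topology_id`, `q`, sorted.
#' @export
select_pool <- function(results, q_threshold) {
  if (!is.data.frame(results)) {
    results <- do.call(rbind, lapply(results, function(r) {
      data.frame(topology_id = r$topology_id, n_sets = r$n_sets,
                 n_pass = r$n_pass, q = r$q)
    }))
  }
  keep <- results[results$q > q_threshold, , drop = FALSE]
  keep <- keep[order(-keep$q, keep$topology_id), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}

#' Materialise the topologies of a pool
#'
#' @param pool data frame with a `topology_id` column.
#' @param n_nodes,roles decoding parameters.
#' @return list of [topology()] objects in pool order.
#' @export
pool_topologies <- function(pool, n_nodes = 3, roles = learning_roles()) {
  lapply(pool$topology_id, decode_id, n_nodes = n_nodes, roles = roles)
}
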