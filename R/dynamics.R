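#' Hill activation function
#'
#' `hill(x, T, n) = x^n / (x^n + T^n)`: the saturating occupancy of a
#' transcription-factor binding site, with half-maximal response at `x = T`
#' and steepness `n`.
#'
#' @param x regulator concentration (>= 0).
#' @param T half-maximal concentration (> 0).
#' @param n Hill coefficient (>= 1).
#' @return fraction in `[0, 1)`.
#' @export
hill <- function(x, T, n) {
  if (any(T <= 0)) stop("Hill half-max T must be positive", call. = FALSE)
  xn <- x^n
  xn / (xn + T^n)
}

#' Regulation production terms
#'
#' `activation_term()` is the production rate contributed by a positive
#' regulation: `V * hill(A, k, n)`, bounded by the maximal rate `V`.
#' `inhibition_term()` is the production rate under a negative regulation:
#' `k * K^n / (K^n + alpha * A^n)`; it equals the basal rate `k` when the
#' inhibitor is absent (`A = 0`) or unweighted (`alpha = 0`) and decreases
#' monotonically with `A`.
#'
#' @param A regulator concentration (>= 0).
#' @param p parameter list: `V`, `k`, `n` for activation; `k`, `K`,
#'   `alpha`, `n` for inhibition.
#' @return production rate.
#' @export
activation_term <- function(A, p) p$V * hill(A, p$k, p$n)

#' @rdname activation_term
#' @export
inhibition_term <- function(A, p) {
  Kn <- p$K^p$n
  p$k * Kn / (Kn + p$alpha * A^p$n)
}

#' External-signal wiring implied by a topology's roles
#'
#' Signals are clamped species, at level `S_on` when on and 0 when off,
#' acting through their own activation term on the receiving node. For the
#' learning module the ring and food signals compose multiplicatively with
#' the receiving node's activation product; for the recall module the
#' memory and ring signals compose multiplicatively while the food signal
#' adds to the regulation of the output node. Combined networks use
#' [combined_wiring()].
#'
#' @param t a [topology()] carrying learning or recall roles.
#' @return data frame with columns `signal`, `node`, `mode`
#'   (`"mult"`/`"add"`).
#' @export
signal_wiring <- function(t) {
  r <- t$roles
  nm <- names(r)
  if (all(c("ring_input", "food_input", "memory_output") %in% nm)) {
    data.frame(signal = c("ring", "food"),
               node = c(r[["ring_input"]], r[["food_input"]]),
               mode = c("mult", "mult"), stringsAsFactors = FALSE)
  } else if (all(c("memory_input", "ring_input", "output_fs") %in% nm)) {
    data.frame(signal = c("memory", "ring", "food"),
               node = c(r[["memory_input"]], r[["ring_input"]],
                        r[["output_fs"]]),
               mode = c("mult", "mult", "add"), stringsAsFactors = FALSE)
  } else {
    stop("topology roles identify neither a learning nor a recall module",
         call. = FALSE)
  }
}

#' Production rate of one node (reference implementation)
#'
#' Computes the instantaneous production of `node` given the full network
#' state: the product over incoming activation edges and multiplicative
#' signal terms, plus the sum over incoming inhibition edges, plus any
#' additive signal terms. A node with no activation edge, no multiplicative
#' signal, no inhibition edge and no additive signal produces nothing (an
#' unregulated promoter has no transcription source here; basal production
#' only arises through the inhibition term's `k`).
#'
#' This pure-R version defines the model; the integrator uses an equivalent
#' compiled routine, and the two are cross-checked in the test suite.
#'
#' @param t a [topology()].
#' @param params a parameter set (see [sample_parameters()]).
#' @param node node index.
#' @param state numeric vector of node concentrations.
#' @param signals named numeric vector of current signal levels
#'   (`food`/`ring`/`memory`), missing entries = 0.
#' @param wiring signal wiring table (defaults to [signal_wiring()]).
#' @return production rate (scalar).
#' @export
build_production <- function(t, params, node, state,
                             signals = c(food = 0, ring = 0, memory = 0),
                             wiring = signal_wiring(t)) {
  edges <- params$edges
  inc <- edges[edges$to == node, , drop = FALSE]
  act <- inc[inc$sign == REG_ACT, , drop = FALSE]
  inh <- inc[inc$sign == REG_INH, , drop = FALSE]
  sw <- wiring[wiring$node == node, , drop = FALSE]
  sp <- params$signals

  prod_val <- 1
  n_fac <- 0
  if (nrow(act)) {
    for (r in seq_len(nrow(act))) {
      prod_val <- prod_val * activation_term(max(state[act$from[r]], 0),
                                             as.list(act[r, ]))
      n_fac <- n_fac + 1
    }
  }
  add_val <- 0
  if (nrow(sw)) {
    for (r in seq_len(nrow(sw))) {
      lev <- signals[[sw$signal[r]]]
      if (is.null(lev) || is.na(lev)) lev <- 0
      pr <- sp[sp$signal == sw$signal[r] & sp$node == sw$node[r] &
                 sp$mode == sw$mode[r], , drop = FALSE]
      term <- activation_term(lev, as.list(pr[1, ]))
      if (sw$mode[r] == "mult") {
        prod_val <- prod_val * term
        n_fac <- n_fac + 1
      } else {
        add_val <- add_val + term
      }
    }
  }
  inh_val <- 0
  if (nrow(inh)) {
    for (r in seq_len(nrow(inh))) {
      inh_val <- inh_val + inhibition_term(max(state[inh$from[r]], 0),
                                           as.list(inh[r, ]))
    }
  }
  (if (n_fac > 0) prod_val else 0) + inh_val + add_val
}

# ---- compiled-system plumbing ------------------------------------------

PARMS_LEN <- 512L

# Precompute the structure shared by all phases of a simulation.
build_system <- function(t, params, wiring) {
  n <- t$n_nodes
  edges <- params$edges
  act <- vector("list", n)
  inh <- vector("list", n)
  for (j in seq_len(n)) {
    aj <- edges[edges$to == j & edges$sign == REG_ACT, , drop = FALSE]
    ij <- edges[edges$to == j & edges$sign == REG_INH, , drop = FALSE]
    act[[j]] <- if (nrow(aj)) as.vector(t(cbind(aj$from - 1, aj$V, aj$k,
                                                aj$n))) else numeric(0)
    inh[[j]] <- if (nrow(ij)) as.vector(t(cbind(ij$from - 1, ij$k, ij$K,
                                                ij$alpha, ij$n))) else numeric(0)
  }
  list(n = n, act = act, inh = inh, eta = params$eta,
       wiring = wiring, signals = params$signals)
}

# Flatten system + signal levels for one phase into the padded parms vector.
phase_parms <- function(sys, levels, n_rep) {
  n <- sys$n
  hdr <- numeric(5 * n)
  blocks <- numeric(0)
  sw <- sys$wiring
  sp <- sys$signals
  for (j in seq_len(n)) {
    na <- length(sys$act[[j]]) / 4
    ni <- length(sys$inh[[j]]) / 5
    mult_const <- 1
    add_const <- 0
    nms <- 0L
    if (!is.null(sw) && nrow(sw)) {
      rows <- which(sw$node == j)
      for (r in rows) {
        lev <- levels[[sw$signal[r]]]
        if (is.null(lev) || is.na(lev)) lev <- 0
        pr <- sp[sp$signal == sw$signal[r] & sp$node == j &
                   sp$mode == sw$mode[r], , drop = FALSE]
        term <- pr$V[1] * hill(lev, pr$k[1], pr$n[1])
        if (sw$mode[r] == "mult") {
          mult_const <- mult_const * term
          nms <- nms + 1L
        } else {
          add_const <- add_const + term
        }
      }
    }
    hdr[5 * (j - 1) + 1:5] <- c(na, ni, nms, mult_const, add_const)
    blocks <- c(blocks, sys$act[[j]], sys$inh[[j]])
  }
  p <- c(n, n_rep, sys$eta, hdr, blocks)
  if (length(p) > PARMS_LEN) stop("network too large for compiled RHS")
  c(p, numeric(PARMS_LEN - length(p)))
}

# Integrate one constant-signal phase for a stack of replicates.
# y0: n_rep x n matrix. Returns list(ok, states [time x rep x node], times).
integrate_phase <- function(sys, levels, y0, times, rtol, atol) {
  n_rep <- nrow(y0)
  p <- phase_parms(sys, levels, n_rep)
  out <- try(suppressWarnings(
    deSolve::lsoda(y = as.vector(t(y0)), times = times,
                   func = "pavnet_derivs", parms = p, dllname = "pavnet",
                   initfunc = "pavnet_init", rtol = rtol, atol = atol)
  ), silent = TRUE)
  if (inherits(out, "try-error")) return(list(ok = FALSE))
  istate <- attr(out, "istate")
  if (is.null(istate) || istate[1] < 0 || nrow(out) < length(times) ||
      anyNA(out) || any(!is.finite(out))) {
    return(list(ok = FALSE))
  }
  # columns of out are rep-major: rep1 node1..n, rep2 node1..n, ...
  states <- aperm(array(out[, -1, drop = FALSE],
                        dim = c(nrow(out), sys$n, n_rep)), c(1, 3, 2))
  min_state <- min(states)
  if (min_state < -1e-6) return(list(ok = FALSE))
  states[states < 0] <- 0
  list(ok = TRUE, times = out[, 1], states = states, min_state = min_state)
}

#' Simulate a topology under a piecewise-constant signal schedule
#'
#' Integrates `dA_j/dt = production_j(A, signals) - eta_j * A_j` phase by
#' phase with `deSolve::lsoda` (adaptive, stiff-capable; dense output on a
#' unit time grid). State is continuous across phase boundaries. Small
#' negative numerical excursions are clipped at zero; excursions beyond
#' `-1e-6`, non-finite states or integrator failure raise a
#' `pavnet_sim_failed` condition, which the screening layer treats as a
#' failed parameter set.
#'
#' @param t a [topology()].
#' @param params parameter set (see [sample_parameters()]).
#' @param schedule an [input_schedule()].
#' @param init nonnegative initial concentrations (length `n_nodes`).
#' @param config a [run_config()] (integrator tolerances).
#' @param wiring signal wiring table; defaults to [signal_wiring()].
#' @return list of class `trajectory`: `times`, `states`
#'   (time x node matrix), `min_state` (most negative pre-clip value).
#' @export
simulate <- function(t, params, schedule, init,
                     config = run_config(), wiring = signal_wiring(t)) {
  stopifnot(length(init) == t$n_nodes, all(init >= 0))
  sys <- build_system(t, params, wiring)
  y <- matrix(init, nrow = 1)
  all_times <- numeric(0)
  all_states <- NULL
  t0 <- 0
  min_state <- 0
  for (ph in schedule$phases) {
    times <- seq(0, ph$duration, by = schedule$dt)
    res <- integrate_phase(sys, ph$levels, y, times,
                           config$rtol, config$atol)
    if (!res$ok) {
      stop(structure(class = c("pavnet_sim_failed", "error", "condition"),
                     list(message = "integration failed", call = NULL)))
    }
    states <- res$states[, 1, , drop = TRUE]
    if (is.null(dim(states))) states <- matrix(states, ncol = sys$n)
    keep <- if (is.null(all_states)) seq_len(nrow(states)) else -1L
    all_times <- c(all_times, (res$times + t0)[keep])
    all_states <- rbind(all_states, states[keep, , drop = FALSE])
    min_state <- min(min_state, res$min_state)
    y <- matrix(states[nrow(states), ], nrow = 1)
    t0 <- t0 + ph$duration
  }
  structure(list(times = all_times, states = all_states,
                 min_state = min_state), class = "trajectory")
}

#' Build a signal schedule
#'
#' An input schedule is an ordered list of constant-signal phases; each
#' phase fixes the levels of the `food`, `ring` and `memory` signals for a
#' given duration (time units are arbitrary but shared with all rate
#' parameters).
#'
#' @param ... phases created by [input_phase()].
#' @param dt output sampling interval (default 1 time unit).
#' @return an `input_schedule` object.
#' @export
input_schedule <- function(..., dt = 1) {
  phases <- list(...)
  stopifnot(length(phases) > 0)
  structure(list(phases = phases, dt = dt), class = "input_schedule")
}

#' @rdname input_schedule
#' @param duration phase length in time units (> 0).
#' @param food,ring,memory signal levels during the phase.
#' @export
input_phase <- function(duration, food = 0, ring = 0, memory = 0) {
  stopifnot(duration > 0)
  list(duration = duration,
       levels = c(food = food, ring = ring, memory = memory))
}

#' Export a trajectory as TSV
#'
#' @param traj a trajectory from [simulate()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(traj, path) {
  df <- data.frame(time = traj$times, traj$states)
  names(df) <- c("time", paste0("node", seq_len(ncol(traj$states))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
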