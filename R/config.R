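#' Screening run configuration
#'
#' Collects every tunable of the screening pipeline with the defaults used
#' throughout: 10^4 parameter sets per topology, output ratio thresholds
#' 5/15 for sub-module screens and 5/10 for combined networks, Q-value
#' selection thresholds 0.007 (learning) and 0.008 (recall), a 10000-unit
#' simulation span with the steady-state window `[9000, 10000]` and a 1%
#' band, persistence checked at T = 50000 with 80% retention, and 10 random
#' initial conditions drawn from `[0, 50]` per non-output node with output
#' nodes started at 0.1.
#'
#' @param n_sets parameter sets per topology.
#' @param seed run seed.
#' @param t_end simulated span per signal condition (time units).
#' @param window steady-state evaluation window (time units).
#' @param rel_tol steady-state relative band.
#' @param steady_mode `"point"` (default): one test sample, drawn
#'   uniformly from the window per parameter set, must lie within
#'   `rel_tol` of the window mean — the literal "arbitrary value" rule;
#'   `"band"`: every unit-grid sample must (strict, deterministic; it
#'   rejects the slowly drifting plateaus that near-frozen memory nodes
#'   produce, and with it no three-node network can hold a persistent
#'   memory — see the methods vignette).
#' @param atol_steady absolute noise floor added to the steadiness band
#'   and agreement checks; outputs that have decayed below integration
#'   accuracy count as steady at zero.
#' @param ic_agreement how runs from different initial conditions must
#'   agree: `"class"` (default) — all must yield the same on/off
#'   classification; `"value"` — steady values must agree to `agree_tol`.
#' @param ratio_submodule,ratio_combined `c(off_max, on_min)` output-ratio
#'   thresholds.
#' @param q_threshold_learning,q_threshold_recall pool selection cutoffs.
#' @param t_check absolute time of the persistence check (the trained
#'   plateau is held from `t_end` to `t_check` with signals removed).
#' @param retain_frac minimal retained fraction of the trained plateau.
#' @param n_inits random initial conditions per parameter set.
#' @param init_range range of non-output initial concentrations.
#' @param init_output fixed initial concentration of output nodes.
#' @param signal_on level of a signal that is on.
#' @param agree_tol relative tolerance for "same steady state" across
#'   initial conditions.
#' @param eps_ratio floor on the off-state denominator in output ratios.
#' @param rtol,atol integrator tolerances.
#' @param ranges parameter ranges ([parameter_ranges()]).
#' @param integer_hill sample integer Hill coefficients.
#' @param workers parallel workers for full-scale drivers (forked; 1 = serial).
#' @return a named list of class `run_config`.
#' @export
run_config <- function(n_sets = 10000, seed = 1, t_end = 10000,
                       window = c(9000, 10000), rel_tol = 0.01,
                       steady_mode = c("point", "band"),
                       atol_steady = 1e-9,
                       ic_agreement = c("class", "value"),
                       ratio_submodule = c(off_max = 5, on_min = 15),
                       ratio_combined = c(off_max = 5, on_min = 10),
                       q_threshold_learning = 0.007,
                       q_threshold_recall = 0.008,
                       t_check = 50000, retain_frac = 0.8,
                       n_inits = 10, init_range = c(0, 50),
                       init_output = 0.1, signal_on = 1.0,
                       agree_tol = 0.01, eps_ratio = 1e-12,
                       rtol = 1e-6, atol = 1e-9,
                       ranges = parameter_ranges(),
                       integer_hill = FALSE, workers = 1L) {
  steady_mode <- match.arg(steady_mode)
  ic_agreement <- match.arg(ic_agreement)
  stopifnot(rel_tol > 0, retain_frac > 0, retain_frac <= 1,
            n_inits >= 1, t_check > t_end,
            ratio_submodule[["off_max"]] < ratio_submodule[["on_min"]],
            ratio_combined[["off_max"]] <= ratio_combined[["on_min"]])
  structure(list(n_sets = n_sets, seed = seed, t_end = t_end,
                 window = window, rel_tol = rel_tol,
                 steady_mode = steady_mode, atol_steady = atol_steady,
                 ic_agreement = ic_agreement,
                 ratio_submodule = ratio_submodule,
                 ratio_combined = ratio_combined,
                 q_threshold_learning = q_threshold_learning,
                 q_threshold_recall = q_threshold_recall,
                 t_check = t_check, retain_frac = retain_frac,
                 n_inits = n_inits, init_range = init_range,
                 init_output = init_output, signal_on = signal_on,
                 agree_tol = agree_tol, eps_ratio = eps_ratio,
                 rtol = rtol, atol = atol, ranges = ranges,
                 integer_hill = integer_hill, workers = workers),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; parameter ranges may be
#' overridden as `ranges: {V: [1e-3, 1e2, log], ...}`.
#'
#' @param path YAML file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$ranges)) {
    base <- parameter_ranges()
    for (nm in names(y$ranges)) {
      v <- y$ranges[[nm]]
      base[[nm]] <- list(low = as.numeric(v[[1]]), high = as.numeric(v[[2]]),
                         scale = as.character(v[[3]]))
    }
    y$ranges <- base
  }
  for (nm in c("ratio_submodule", "ratio_combined")) {
    if (!is.null(y[[nm]])) {
      y[[nm]] <- c(off_max = as.numeric(y[[nm]][[1]]),
                   on_min = as.numeric(y[[nm]][[2]]))
    }
  }
  do.call(run_config, y)
}
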