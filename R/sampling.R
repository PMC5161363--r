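#' Default kinetic parameter ranges
#'
#' Each entry is `(low, high, scale)` with `scale` either `"log"`
#' (stratified uniformly in `log10`) or `"linear"`. Defaults: maximal
#' production rate `V` in `[1e-3, 1e2]` (log), activation half-max /
#' inhibition basal rate `k` in `[1e-6, 1]` (log), inhibition coefficient
#' `K` in `[1e-3, 10]` (log), inhibition weight `alpha` in `[0, 1]`
#' (linear; a log scale is impossible at 0), degradation `eta` in
#' `[1e-12, 1]` (log), Hill coefficient `n` in `[1, 3]` (linear and
#' continuous; an integer mode is available via
#' `run_config(integer_hill = TRUE)`).
#'
#' @return named list of `list(low, high, scale)`.
#' @export
parameter_ranges <- function() {
  list(V = list(low = 1e-3, high = 1e2, scale = "log"),
       k = list(low = 1e-6, high = 1, scale = "log"),
       K = list(low = 1e-3, high = 10, scale = "log"),
       alpha = list(low = 0, high = 1, scale = "linear"),
       eta = list(low = 1e-12, high = 1, scale = "log"),
       n = list(low = 1, high = 3, scale = "linear"))
}

range_transform <- function(u, rng) {
  if (rng$scale == "log") {
    10^(log10(rng$low) + u * (log10(rng$high) - log10(rng$low)))
  } else {
    rng$low + u * (rng$high - rng$low)
  }
}

# One row per scalar dimension of the Latin hypercube for this topology.
sampling_dims <- function(t, wiring) {
  edges <- topology_edges(t)
  dims <- list()
  add <- function(kind, what, from = NA, to = NA, signal = NA, mode = NA) {
    dims[[length(dims) + 1]] <<- data.frame(
      kind = kind, what = what, from = from, to = to,
      signal = signal, mode = mode, stringsAsFactors = FALSE)
  }
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      if (edges$sign[r] == REG_ACT) {
        for (w in c("V", "k", "n")) add("edge", w, edges$from[r], edges$to[r])
      } else {
        for (w in c("k", "K", "alpha", "n")) {
          add("edge", w, edges$from[r], edges$to[r])
        }
      }
    }
  }
  for (j in seq_len(t$n_nodes)) add("eta", "eta", to = j)
  if (!is.null(wiring) && nrow(wiring)) {
    for (r in seq_len(nrow(wiring))) {
      for (w in c("V", "k", "n")) {
        add("signal", w, to = wiring$node[r], signal = wiring$signal[r],
            mode = wiring$mode[r])
      }
    }
  }
  do.call(rbind, dims)
}

#' Draw Latin hypercube parameter sets for a topology
#'
#' Every scalar dimension of the model — `(V, k, n)` per activation edge,
#' `(k, K, alpha, n)` per inhibition edge, one degradation rate `eta` per
#' node, and `(V, k, n)` per external-signal term — is stratified into
#' `n_sets` equal-probability bins, each hit exactly once across the draws
#' (the Latin hypercube property), on the log scale for log-scale
#' parameters. Fully reproducible from `seed`.
#'
#' @param t a [topology()].
#' @param n_sets number of parameter sets (>= 1).
#' @param seed integer RNG seed.
#' @param ranges parameter ranges, see [parameter_ranges()].
#' @param wiring signal wiring table (defaults to [signal_wiring()];
#'   pass `NULL` for a closed system).
#' @param integer_hill round Hill coefficients to integers.
#' @return list of `n_sets` parameter sets; each is a list with `edges`
#'   (data frame `from, to, sign, V, k, K, alpha, n`), `eta` (numeric per
#'   node) and `signals` (data frame `signal, node, mode, V, k, n`).
#' @export
sample_parameters <- function(t, n_sets, seed, ranges = parameter_ranges(),
                              wiring = signal_wiring(t),
                              integer_hill = FALSE) {
  stopifnot(n_sets >= 1)
  dims <- sampling_dims(t, wiring)
  set.seed(as.integer(seed))
  cube <- lhs::randomLHS(n_sets, nrow(dims))
  edges <- topology_edges(t)
  lapply(seq_len(n_sets), function(s) {
    u <- cube[s, ]
    vals <- vapply(seq_len(nrow(dims)), function(d) {
      range_transform(u[d], ranges[[dims$what[d]]])
    }, numeric(1))
    if (integer_hill) {
      is_n <- dims$what == "n"
      vals[is_n] <- pmin(round(vals[is_n]), ranges$n$high)
    }
    edf <- edges
    for (w in c("V", "k", "K", "alpha", "n")) {
      edf[[w]] <- rep(NA_real_, nrow(edges))
    }
    if (nrow(edges)) {
      for (r in seq_len(nrow(edges))) {
        sel <- dims$kind == "edge" & dims$from == edges$from[r] &
          dims$to == edges$to[r]
        for (w in unique(dims$what[sel])) {
          edf[[w]][r] <- vals[sel & dims$what == w]
        }
      }
    }
    eta <- vals[dims$kind == "eta"][order(dims$to[dims$kind == "eta"])]
    sdf <- NULL
    if (!is.null(wiring) && nrow(wiring)) {
      sdf <- wiring
      for (w in c("V", "k", "n")) {
        sdf[[w]] <- vapply(seq_len(nrow(wiring)), function(r) {
          vals[dims$kind == "signal" & dims$signal == wiring$signal[r] &
                 dims$to == wiring$node[r] & dims$mode == wiring$mode[r] &
                 dims$what == w]
        }, numeric(1))
      }
    } else {
      sdf <- data.frame(signal = character(0), node = integer(0),
                        mode = character(0), V = numeric(0),
                        k = numeric(0), n = numeric(0))
    }
    list(edges = edf, eta = eta, signals = sdf)
  })
}

# Seed for the per-topology Latin hypercube: XOR of the run seed with the
# canonical topology ID (reduced into integer range), so every topology
# gets an independent, reproducible cube.
topology_seed <- function(seed, id) {
  bitwXor(as.integer(seed %% 2147483647),
          as.integer(id %% 2147483647))
}
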