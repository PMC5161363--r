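# Shared helpers: hand-built parameter sets and small random topologies.

# Parameter set skeleton for a topology: every edge gets the given kinetic
# constants; per-node eta and signal terms as supplied.
make_params <- function(t, eta, V = 1, k = 0.1, K = 1, alpha = 1, n = 2,
                        signals = NULL, wiring = NULL) {
  e <- topology_edges(t)
  e$V <- rep(V, length.out = nrow(e))
  e$k <- rep(k, length.out = nrow(e))
  e$K <- rep(K, length.out = nrow(e))
  e$alpha <- rep(alpha, length.out = nrow(e))
  e$n <- rep(n, length.out = nrow(e))
  if (is.null(signals)) {
    if (is.null(wiring)) wiring <- signal_wiring(t)
    signals <- wiring
    signals$V <- 10
    signals$k <- 0.1
    signals$n <- 2
  }
  list(edges = e, eta = eta, signals = signals)
}

random_topology <- function(n_nodes = 3, roles = integer(0),
                            p_edge = 0.4) {
  adj <- matrix(sample(0:2, n_nodes^2, replace = TRUE,
                       prob = c(1 - p_edge, p_edge / 2, p_edge / 2)),
                n_nodes, n_nodes)
  pavnet:::new_topology(as.integer(n_nodes), adj, roles)
}

# fast config for dynamics-level tests (short spans, few inits)
fast_config <- function(...) {
  run_config(t_end = 200, window = c(150, 200), t_check = 500,
             n_inits = 3, ...)
}

# Independent brute-force oracle: materialise every (pair, map) candidate
# and re-check all compatibility conditions by direct matrix comparison.
oracle_combinations <- function(poolL, poolR, arity) {
  forbidden <- list(c(2L, 2L), c(1L, 3L), c(3L, 3L))
  keep <- list()
  for (li in seq_along(poolL)) {
    for (ri in seq_along(poolR)) {
      tL <- poolL[[li]]
      tR <- poolR[[ri]]
      for (m in merge_maps(arity)) {
        ok <- TRUE
        for (r in seq_len(nrow(m))) {
          for (f in forbidden) {
            if (m[r, 1] == f[1] && m[r, 2] == f[2]) ok <- FALSE
          }
        }
        if (ok) {
          for (a in seq_len(nrow(m))) {
            for (b in seq_len(nrow(m))) {
              sL <- tL$adjacency[m[a, 1], m[b, 1]]
              sR <- tR$adjacency[m[a, 2], m[b, 2]]
              if (sL != 0 && sR != 0 && sL != sR) ok <- FALSE
            }
          }
        }
        if (ok && !any(m[, 1] == 3 & m[, 2] == 1)) {
          # required memory link must not contradict an inhibition
          iL <- match(3L, m[, 1])
          iR <- match(1L, m[, 2])
          if (!is.na(iL) && tR$adjacency[m[iL, 2], 1] == 2) ok <- FALSE
          if (!is.na(iR) && tL$adjacency[3, m[iR, 1]] == 2) ok <- FALSE
        }
        if (ok) {
          keep[[length(keep) + 1]] <- list(l = li, r = ri, m = m)
        }
      }
    }
  }
  keep
}

combo_key <- function(l, r, m) {
  paste(l, r, paste(m[, 1], m[, 2], sep = "~", collapse = ","), sep = "|")
}

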