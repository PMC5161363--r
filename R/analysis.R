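#' Regulation entropy of a topology
#'
#' For each node with at least one incoming edge (self-edges included),
#' the Shannon entropy (base 2) of the activation/inhibition split among
#' its incoming regulations is computed; the score is the mean over such
#' nodes. A node whose in-edges all share one sign contributes 0 bits, a
#' balanced mix contributes up to 1 bit, and a network with no edges
#' scores 0. Low regulation entropy means few conflicting regulations
#' converging on the same promoters.
#'
#' @param t a [topology()] (or a `combined_network`).
#' @return mean per-node in-edge sign entropy, in bits.
#' @export
regulation_entropy <- function(t) {
  if (inherits(t, "combined_network")) t <- t$topology
  adj <- t$adjacency
  h <- numeric(0)
  for (j in seq_len(t$n_nodes)) {
    a <- sum(adj[, j] == REG_ACT)
    i <- sum(adj[, j] == REG_INH)
    if (a + i == 0) next
    p <- c(a, i) / (a + i)
    p <- p[p > 0]
    h <- c(h, -sum(p * log2(p)))
  }
  if (!length(h)) 0 else mean(h)
}

#' Regulation-entropy baseline from random networks
#'
#' Samples networks in which every ordered node pair independently carries
#' one of the three regulation states with equal probability, and reports
#' their regulation entropies — the unconstrained reference against which
#' logically-valid combined networks are compared.
#'
#' @param n_nodes nodes per random network.
#' @param n_samples number of networks (>= 1).
#' @param seed RNG seed.
#' @return list of class `entropy_report`: `entropies` (per network) and
#'   `mean`.
#' @export
random_network_baseline <- function(n_nodes, n_samples, seed = 1) {
  stopifnot(n_samples >= 1)
  set.seed(as.integer(seed))
  ent <- vapply(seq_len(n_samples), function(s) {
    adj <- matrix(sample(0:2, n_nodes^2, replace = TRUE), n_nodes, n_nodes)
    regulation_entropy(new_topology(as.integer(n_nodes), adj, integer(0)))
  }, numeric(1))
  structure(list(entropies = ent, mean = mean(ent)),
            class = "entropy_report")
}

#' Hierarchical clustering of a topology pool
#'
#' Flattens each topology to its row-major sign vector, computes pairwise
#' Hamming distances (number of differing entries) and clusters with
#' average linkage. Used to order robust pools so that structurally
#' similar networks sit together, exposing the recurring core motifs.
#'
#' @param pool list of [topology()] objects (all the same size).
#' @return list: `order` (leaf order, indices into `pool`), `heights`
#'   (merge heights), `hclust` (the full tree), `signs` (the sign matrix,
#'   one row per topology, in input order).
#' @export
cluster_pool <- function(pool) {
  stopifnot(length(pool) >= 1)
  signs <- do.call(rbind, lapply(pool, function(t) as.vector(t(t$adjacency))))
  if (length(pool) == 1) {
    return(list(order = 1L, heights = numeric(0), hclust = NULL,
                signs = signs))
  }
  n <- nrow(signs)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(signs[i, ] != signs[j, ])
    }
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  list(order = hc$order, heights = hc$height, hclust = hc, signs = signs)
}

#' Size of the combination space
#'
#' Exact count of (learning network, recall network, merge map) candidates
#' at a given arity. Before sign filtering the count is
#' `poolL_size * poolR_size * n_maps`, where `n_maps` is the number of
#' role-legal merge maps (9, 18 and 6 maps at arity 1, 2, 3 before the
#' role constraints remove forbidden pairings). With pools supplied, the
#' sign-filtered count — the number of logically possible combinations —
#' is returned instead, matching `length(enumerate_combinations(...))`.
#'
#' @param poolL_size,poolR_size pool sizes (ignored when pools given).
#' @param arity 1, 2 or 3.
#' @param poolL,poolR optional topology lists for the filtered count.
#' @param role_filter apply the role constraints (default TRUE).
#' @return a count.
#' @export
combination_space_size <- function(poolL_size = NULL, poolR_size = NULL,
                                   arity = 1, poolL = NULL, poolR = NULL,
                                   role_filter = TRUE) {
  maps <- merge_maps(arity)
  if (role_filter) maps <- Filter(map_role_legal, maps)
  if (is.null(poolL) || is.null(poolR)) {
    stopifnot(poolL_size >= 0, poolR_size >= 0)
    return(poolL_size * poolR_size * length(maps))
  }
  cnt <- 0
  for (tL in poolL) {
    for (tR in poolR) {
      for (m in maps) {
        if (check_sign_compatibility(tL, tR, m)) cnt <- cnt + 1
      }
    }
  }
  cnt
}

#' Histogram of Q-values at the screening granularity
#'
#' @param q numeric vector of Q-values.
#' @param binwidth bin width (default 0.0005, the resolution at which the
#'   bulk of non-robust networks separates from the robust tail).
#' @return data frame `bin_lo`, `bin_hi`, `count`.
#' @export
q_histogram <- function(q, binwidth = 5e-4) {
  if (!length(q)) {
    return(data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      count = integer(0)))
  }
  bins <- floor(q / binwidth)
  tab <- table(bins)
  data.frame(bin_lo = as.numeric(names(tab)) * binwidth,
             bin_hi = (as.numeric(names(tab)) + 1) * binwidth,
             count = as.integer(tab))
}
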