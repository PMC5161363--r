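#' @useDynLib pavnet, .registration = TRUE
#' @importFrom stats hclust dist as.dist runif setNames aggregate
#' @importFrom utils write.table read.table
NULL

REG_NONE <- 0L
REG_ACT <- 1L
REG_INH <- 2L

ROLE_NAMES <- c("ring_input", "food_input", "memory_output",
                "memory_input", "output_fs", "internal")

#' Construct a signed directed regulatory network topology
#'
#' A topology is an `n_nodes x n_nodes` adjacency matrix whose entry
#' `(i, j)` encodes the effect of node `i` on node `j`: `0` no regulation,
#' `1` activation, `2` inhibition. Self-pairs are allowed. Node roles
#' (which node receives which external signal, which node is read out) are
#' carried as a named integer vector mapping role name to node index.
#'
#' @param n_nodes number of nodes (>= 1).
#' @param adjacency integer matrix of regulation codes (0/1/2); defaults to
#'   the empty network.
#' @param roles named integer vector, role name -> node index (1-based).
#'   Standard single-module role sets are [learning_roles()] and
#'   [recall_roles()].
#' @param edges optional data frame with columns `from`, `to`, `sign`
#'   (`"+"`/`"-"` or 1/2) used instead of `adjacency`.
#' @return an object of class `topology`.
#' @export
topology <- function(n_nodes, adjacency = NULL, roles = integer(0),
                     edges = NULL) {
  stopifnot(length(n_nodes) == 1L, n_nodes >= 1)
  n_nodes <- as.integer(n_nodes)
  if (is.null(adjacency)) {
    adjacency <- matrix(0L, n_nodes, n_nodes)
  }
  if (!is.null(edges) && nrow(edges) > 0) {
    sgn <- edges$sign
    if (is.character(sgn)) sgn <- ifelse(sgn == "+", REG_ACT, REG_INH)
    for (r in seq_len(nrow(edges))) {
      adjacency[edges$from[r], edges$to[r]] <- as.integer(sgn[r])
    }
  }
  storage.mode(adjacency) <- "integer"
  validate_topology(new_topology(n_nodes, adjacency, roles))
}

new_topology <- function(n_nodes, adjacency, roles) {
  structure(list(n_nodes = n_nodes, adjacency = adjacency,
                 roles = roles), class = "topology")
}

validate_topology <- function(t) {
  adj <- t$adjacency
  if (!is.matrix(adj) || any(dim(adj) != t$n_nodes)) {
    stop("adjacency must be an n_nodes x n_nodes matrix", call. = FALSE)
  }
  if (!all(adj %in% c(REG_NONE, REG_ACT, REG_INH))) {
    stop("adjacency entries must be 0 (none), 1 (activation) or 2 (inhibition)",
         call. = FALSE)
  }
  if (length(t$roles)) {
    idx <- as.integer(t$roles)
    if (any(idx < 1L | idx > t$n_nodes)) {
      stop("role indices out of range", call. = FALSE)
    }
    non_int <- t$roles[names(t$roles) != "internal"]
    # merged nodes in combined networks may legitimately carry several roles,
    # but a single role name can only point at one node
    if (anyDuplicated(names(non_int))) {
      stop("duplicate role names", call. = FALSE)
    }
  }
  t
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("<topology: %d nodes, %d edges, id %s>\n", x$n_nodes,
              sum(x$adjacency != 0L), format(encode_id(x), scientific = FALSE)))
  if (length(x$roles)) {
    cat("  roles:", paste(sprintf("%s=%d", names(x$roles), x$roles),
                          collapse = ", "), "\n")
  }
  invisible(x)
}

#' Standard role maps for the two sub-modules
#'
#' The learning module reads node 1 as the ring-signal receiver (R), node 2
#' as the food-signal receiver (F) and node 3 as the memory output (M). The
#' recall module reads node 1 as the memory-signal receiver (M), node 2 as
#' the ring-signal receiver (R) and node 3 as the shared food-receiver /
#' salivation output (F&S).
#'
#' @return named integer vector role -> node index.
#' @export
learning_roles <- function() {
  c(ring_input = 1L, food_input = 2L, memory_output = 3L)
}

#' @rdname learning_roles
#' @export
recall_roles <- function() {
  c(memory_input = 1L, ring_input = 2L, output_fs = 3L)
}

#' Total number of candidate topologies on n nodes
#'
#' Every ordered node pair (self-pairs included) carries one of three
#' regulation states, so the design space holds `3^(n^2)` topologies:
#' 19683 for three nodes and 43046721 for four.
#'
#' @param n_nodes node count.
#' @return a double (the count exceeds integer range for `n_nodes >= 4`).
#' @export
n_topologies <- function(n_nodes) 3^(n_nodes^2)

#' Canonical integer ID of a topology
#'
#' The ID is the base-3 number read row-major off the adjacency matrix with
#' entry (1,1) as the most significant digit; digit 0 = none, 1 = activation,
#' 2 = inhibition. `encode_id()` and `decode_id()` are mutually inverse
#' bijections between topologies on `n` nodes and `[0, 3^(n^2) - 1]`.
#'
#' @param t a [topology()].
#' @return `encode_id`: a double ID; `decode_id`: a `topology`.
#' @export
encode_id <- function(t) {
  digits <- as.vector(t(t$adjacency))  # row-major
  sum(digits * 3^(rev(seq_along(digits)) - 1))
}

#' @rdname encode_id
#' @param id canonical ID in `[0, 3^(n_nodes^2) - 1]`.
#' @param n_nodes node count.
#' @param roles role map for the decoded topology.
#' @export
decode_id <- function(id, n_nodes, roles = integer(0)) {
  ncell <- n_nodes^2
  if (id < 0 || id > 3^ncell - 1) {
    stop(sprintf("id %s out of range [0, %s]", format(id),
                 format(3^ncell - 1)), call. = FALSE)
  }
  digits <- integer(ncell)
  x <- id
  for (pos in ncell:1) {
    digits[pos] <- as.integer(x %% 3)
    x <- (x - digits[pos]) / 3
  }
  adj <- matrix(digits, n_nodes, n_nodes, byrow = TRUE)
  validate_topology(new_topology(as.integer(n_nodes), adj, roles))
}

#' Enumerate every topology on n nodes
#'
#' Yields each assignment of the three regulation states to all `n^2`
#' ordered node pairs exactly once, in ascending canonical-ID order.
#' Symmetric duplicates are deliberately kept: roles pin node identities,
#' so relabelling-equivalent structures are distinct candidates.
#'
#' The full four-node space (43046721 topologies) is never materialised;
#' request explicit `ids` (or use [n_topologies()] for the count).
#'
#' @param n_nodes node count.
#' @param roles role map attached to every emitted topology.
#' @param ids optional vector of canonical IDs to decode (any `n_nodes`).
#' @param limit optional cap on the number of topologies returned.
#' @return list of `topology` objects.
#' @export
enumerate_topologies <- function(n_nodes, roles = integer(0), ids = NULL,
                                 limit = NULL) {
  if (is.null(ids)) {
    total <- n_topologies(n_nodes)
    if (!is.null(limit)) total <- min(total, limit)
    if (total > 3^9) {
      stop("refusing to materialise more than 3^9 topologies; ",
           "pass explicit `ids` or a `limit`", call. = FALSE)
    }
    ids <- seq_len(total) - 1
  } else if (!is.null(limit)) {
    ids <- ids[seq_len(min(length(ids), limit))]
  }
  lapply(ids, decode_id, n_nodes = n_nodes, roles = roles)
}

#' Exchange two nodes of a topology
#'
#' Swaps rows/columns `a` and `b` of the adjacency matrix and exchanges any
#' roles attached to the two nodes. Applying the same swap twice restores
#' the original topology. Used e.g. to express the functional symmetry of
#' the two input nodes of the learning module.
#'
#' @param t a [topology()].
#' @param a,b distinct node indices.
#' @return a `topology`.
#' @export
swap_nodes <- function(t, a, b) {
  n <- t$n_nodes
  if (a == b || a < 1 || b < 1 || a > n || b > n) {
    stop("swap_nodes needs two distinct valid node indices", call. = FALSE)
  }
  a <- as.integer(a)
  b <- as.integer(b)
  perm <- seq_len(n)
  perm[c(a, b)] <- c(b, a)
  adj <- t$adjacency[perm, perm, drop = FALSE]
  roles <- t$roles
  if (length(roles)) {
    roles[roles == a] <- -1L
    roles[roles == b] <- a
    roles[roles == -1L] <- b
  }
  validate_topology(new_topology(n, adj, roles))
}

#' Edge list of a topology
#'
#' @param t a [topology()].
#' @return data frame with columns `from`, `to`, `sign` (1 activation,
#'   2 inhibition); `none` pairs are omitted.
#' @export
topology_edges <- function(t) {
  idx <- which(t$adjacency != 0L, arr.ind = TRUE)
  data.frame(from = as.integer(idx[, 1]), to = as.integer(idx[, 2]),
             sign = as.integer(t$adjacency[idx]))
}
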