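#' Read and write the network JSON format
#'
#' Schema: `{"n_nodes": int, "roles": {"0": "ring_input", ...},
#' "edges": [{"from": i, "to": j, "sign": "+"|"-"}]}` with 0-based node
#' indices and `none` pairs omitted. A bare JSON string holding the
#' row-major base-3 digit string (e.g. 9 digits for a three-node network)
#' is also accepted. Writing then reading a network reproduces it exactly.
#'
#' @param t a [topology()].
#' @param path file path.
#' @param roles role map attached when reading a digit string.
#' @return `read_network_json`: a `topology`; `write_network_json`:
#'   `path`, invisibly.
#' @export
write_network_json <- function(t, path) {
  e <- topology_edges(t)
  obj <- list(n_nodes = t$n_nodes,
              roles = as.list(stats::setNames(names(t$roles),
                                              as.character(t$roles - 1L))),
              edges = lapply(seq_len(nrow(e)), function(r) {
                list(from = e$from[r] - 1L, to = e$to[r] - 1L,
                     sign = if (e$sign[r] == REG_ACT) "+" else "-")
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path, roles = integer(0)) {
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) {
                    stop("malformed network JSON in '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (is.character(obj) && length(obj) == 1) {
    return(id_string_to_topology(obj, roles))
  }
  if (is.null(obj$n_nodes)) {
    stop("malformed network JSON in '", path, "': missing n_nodes",
         call. = FALSE)
  }
  n <- as.integer(obj$n_nodes)
  rl <- integer(0)
  if (length(obj$roles)) {
    rl <- stats::setNames(as.integer(names(obj$roles)) + 1L,
                          vapply(obj$roles, as.character, ""))
    rl <- rl[names(rl) != "internal"]
  }
  adj <- matrix(0L, n, n)
  for (e in obj$edges) {
    if (is.null(e$from) || is.null(e$to) || !e$sign %in% c("+", "-")) {
      stop("malformed edge entry in '", path, "'", call. = FALSE)
    }
    adj[as.integer(e$from) + 1L, as.integer(e$to) + 1L] <-
      if (e$sign == "+") REG_ACT else REG_INH
  }
  validate_topology(new_topology(n, adj, rl))
}

#' Base-3 digit-string form of a topology
#'
#' Row-major digits, entry (1,1) first; `0` none, `1` activation,
#' `2` inhibition — the canonical ID written out digit by digit.
#'
#' @param t a [topology()].
#' @param s digit string (length `n^2`).
#' @param roles role map for the decoded topology.
#' @return `topology_to_id_string`: character scalar;
#'   `id_string_to_topology`: a `topology`.
#' @export
topology_to_id_string <- function(t) {
  paste(as.vector(t(t$adjacency)), collapse = "")
}

#' @rdname topology_to_id_string
#' @export
id_string_to_topology <- function(s, roles = integer(0)) {
  digits <- as.integer(strsplit(s, "")[[1]])
  n <- as.integer(sqrt(length(digits)))
  if (n^2 != length(digits) || !all(digits %in% 0:2)) {
    stop("not a base-3 network digit string: ", s, call. = FALSE)
  }
  validate_topology(new_topology(n, matrix(digits, n, n, byrow = TRUE),
                                 roles))
}

#' Write screening results / combination manifests as TSV
#'
#' Deterministic tab-separated outputs with a header row; columns are the
#' data-frame columns of [screen_topologies()] or
#' [screen_combinations()].
#'
#' @param df results data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_tsv
#' @export
read_results_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write a selected pool as JSON
#'
#' Stores the ranked pool (IDs and Q-values) together with the role map so
#' it can be rehydrated for combination runs.
#'
#' @param pool data frame from [select_pool()].
#' @param roles role map of the pool's topologies.
#' @param path file path.
#' @return `write_pool_json`: `path` invisibly; `read_pool_json`: list
#'   with `pool` (data frame) and `roles`.
#' @export
write_pool_json <- function(pool, roles, path) {
  obj <- list(roles = as.list(stats::setNames(as.integer(roles),
                                              names(roles))),
              pool = pool)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_pool_json
#' @export
read_pool_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  roles <- stats::setNames(as.integer(unlist(obj$roles)),
                           names(obj$roles))
  list(pool = as.data.frame(obj$pool), roles = roles)
}
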