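#' Node-identification maps between a learning and a recall module
#'
#' A merge map identifies `arity` nodes of a learning-module network with
#' `arity` nodes of a recall-module network (a partial injective matching).
#' `merge_maps(arity)` enumerates all such matchings before any role or
#' sign filtering: 9 one-node maps, 18 two-node maps, 6 three-node maps.
#'
#' @param arity number of identified node pairs (1, 2 or 3).
#' @return list of integer matrices with columns `learning`, `recall`.
#' @export
merge_maps <- function(arity) {
  stopifnot(arity %in% 1:3)
  maps <- list()
  sets <- utils::combn(3, arity, simplify = FALSE)
  perms <- list(`1` = list(1L), `2` = list(c(1L, 2L), c(2L, 1L)),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  for (ls in sets) {
    for (rs in sets) {
      for (p in perms[[as.character(arity)]]) {
        m <- cbind(learning = as.integer(ls), recall = as.integer(rs[p]))
        maps[[length(maps) + 1]] <- m
      }
    }
  }
  maps
}

# Role-forbidden node identifications (learning index, recall index):
# the food receiver may not also receive the ring signal, and the learning
# memory output may not be the recall output. With the standard role maps
# (learning R=1, F=2, M=3; recall M=1, R=2, F&S=3) that forbids
# food_input~ring_input (2,2), ring_input~output_fs (1,3) and
# memory_output~output_fs (3,3).
ROLE_FORBIDDEN <- matrix(c(2L, 2L, 1L, 3L, 3L, 3L), ncol = 2, byrow = TRUE)

map_role_legal <- function(map) {
  for (r in seq_len(nrow(map))) {
    hit <- ROLE_FORBIDDEN[, 1] == map[r, 1] & ROLE_FORBIDDEN[, 2] == map[r, 2]
    if (any(hit)) return(FALSE)
  }
  TRUE
}

#' Logical compatibility of a sub-network combination
#'
#' A combination is logically possible when no two identified nodes carry
#' contradictory regulations: for every ordered pair of merged slots
#' (self-pairs included) the learning-side sign and the recall-side sign
#' must be equal, or at least one of them must be `none`. Role constraints
#' are enforced as well (see `merge_maps()`), and when the learning memory
#' output is not identified with the recall memory input the mandatory
#' activation link from the former to the latter must not contradict an
#' inhibition contributed by either source network.
#'
#' @param tL learning-module [topology()].
#' @param tR recall-module [topology()].
#' @param map merge map (matrix with columns `learning`, `recall`).
#' @return `TRUE` iff the combination is role-legal and sign-compatible.
#' @export
check_sign_compatibility <- function(tL, tR, map) {
  if (!is.matrix(map) || ncol(map) != 2 || nrow(map) < 1 || nrow(map) > 3 ||
      anyDuplicated(map[, 1]) || anyDuplicated(map[, 2]) ||
      any(map < 1L) || any(map > 3L)) {
    stop("malformed merge map", call. = FALSE)
  }
  if (!map_role_legal(map)) return(FALSE)
  for (a in seq_len(nrow(map))) {
    for (b in seq_len(nrow(map))) {
      sL <- tL$adjacency[map[a, 1], map[b, 1]]
      sR <- tR$adjacency[map[a, 2], map[b, 2]]
      if (sL != REG_NONE && sR != REG_NONE && sL != sR) return(FALSE)
    }
  }
  # the added memory_output -> memory_input activation edge must not land
  # on a slot one source already inhibits
  mem_merged <- any(map[, 1] == 3L & map[, 2] == 1L)
  if (!mem_merged) {
    iL <- match(3L, map[, 1])  # recall node merged with learning M, if any
    if (!is.na(iL) && tR$adjacency[map[iL, 2], 1L] == REG_INH) return(FALSE)
    iR <- match(1L, map[, 2])  # learning node merged with recall M-in
    if (!is.na(iR) && tL$adjacency[3L, map[iR, 1]] == REG_INH) return(FALSE)
  }
  TRUE
}

#' Merge a learning and a recall sub-network into one candidate network
#'
#' Identified nodes keep the union of both sources' edges (the
#' sign-compatibility precondition guarantees no conflict; `none` yields to
#' the defined sign). Learning nodes keep indices 1-3; unmerged recall
#' nodes are appended in ascending recall order, giving `6 - arity` nodes.
#' When the learning memory output is not identified with the recall
#' memory input, an activation edge from the former to the latter is added
#' so the stored memory state can drive recall.
#'
#' @inheritParams check_sign_compatibility
#' @return an object of class `combined_network`: a list with `topology`
#'   (roles `ring_input_l`, `food_input`, `memory_output`, `memory_input`,
#'   `ring_input_r`, `output_fs`), `provenance` (learning/recall IDs and
#'   the map) and `added_memory_edge`.
#' @export
combine_networks <- function(tL, tR, map) {
  if (!check_sign_compatibility(tL, tR, map)) {
    stop("incompatible combination (sign conflict or role violation)",
         call. = FALSE)
  }
  arity <- nrow(map)
  n <- 6L - arity
  rmap <- integer(3)  # recall node -> combined node
  rmap[map[, 2]] <- map[, 1]
  nxt <- 4L
  for (r in setdiff(1:3, map[, 2])) {
    rmap[r] <- nxt
    nxt <- nxt + 1L
  }
  adj <- matrix(0L, n, n)
  adj[1:3, 1:3] <- tL$adjacency
  for (i in 1:3) {
    for (j in 1:3) {
      s <- tR$adjacency[i, j]
      if (s != REG_NONE) {
        cur <- adj[rmap[i], rmap[j]]
        if (cur != REG_NONE && cur != s) {
          stop("edge union conflict; combination precondition violated",
               call. = FALSE)
        }
        adj[rmap[i], rmap[j]] <- s
      }
    }
  }
  mem_merged <- any(map[, 1] == 3L & map[, 2] == 1L)
  added <- FALSE
  if (!mem_merged) {
    if (adj[3L, rmap[1L]] == REG_INH) {
      stop("memory link conflicts with an inhibition edge", call. = FALSE)
    }
    added <- adj[3L, rmap[1L]] == REG_NONE
    adj[3L, rmap[1L]] <- REG_ACT
  }
  roles <- c(ring_input_l = 1L, food_input = 2L, memory_output = 3L,
             memory_input = rmap[1L], ring_input_r = rmap[2L],
             output_fs = rmap[3L])
  topo <- validate_topology(new_topology(n, adj, roles))
  structure(list(topology = topo,
                 provenance = list(learning_id = encode_id(tL),
                                   recall_id = encode_id(tR), map = map),
                 added_memory_edge = added),
            class = "combined_network")
}

#' @export
print.combined_network <- function(x, ...) {
  m <- x$provenance$map
  cat(sprintf(
    "<combined_network: %d nodes, learning %s + recall %s, merge %s%s>\n",
    x$topology$n_nodes,
    format(x$provenance$learning_id, scientific = FALSE),
    format(x$provenance$recall_id, scientific = FALSE),
    paste(sprintf("%d~%d", m[, 1], m[, 2]), collapse = ","),
    if (x$added_memory_edge) ", +memory edge" else ""))
  invisible(x)
}

#' Enumerate all logically possible combinations of two pools
#'
#' Emits `combine_networks(tL, tR, m)` for every learning-pool member,
#' recall-pool member and merge map of the given arity that passes
#' [check_sign_compatibility()]. No deduplication is applied: each
#' provenance (pair + map) is kept, matching how combination counts are
#' reported.
#'
#' @param poolL list of learning-module topologies.
#' @param poolR list of recall-module topologies.
#' @param arity 1, 2 or 3 merged node pairs.
#' @return list of `combined_network` objects.
#' @export
enumerate_combinations <- function(poolL, poolR, arity) {
  maps <- merge_maps(arity)
  out <- vector("list", 0)
  for (tL in poolL) {
    for (tR in poolR) {
      for (m in maps) {
        if (check_sign_compatibility(tL, tR, m)) {
          out[[length(out) + 1]] <- combine_networks(tL, tR, m)
        }
      }
    }
  }
  out
}

#' Signal wiring of a combined network
#'
#' The food and ring signals fan out to the receiver nodes of both
#' modules: food multiplicatively at the learning food receiver and
#' additively at the recall output node; ring multiplicatively at both
#' ring receivers (a single term when the two receivers are one merged
#' node — one physical signal, one receptor). The memory signal is
#' internal to a combined network and never driven externally.
#'
#' @param c a [combine_networks()] result.
#' @return data frame `signal`, `node`, `mode`.
#' @export
combined_wiring <- function(c) {
  r <- c$topology$roles
  w <- data.frame(signal = c("food", "ring"),
                  node = c(r[["food_input"]], r[["ring_input_l"]]),
                  mode = c("mult", "mult"), stringsAsFactors = FALSE)
  if (r[["ring_input_r"]] != r[["ring_input_l"]]) {
    w <- rbind(w, data.frame(signal = "ring", node = r[["ring_input_r"]],
                             mode = "mult"))
  }
  rbind(w, data.frame(signal = "food", node = r[["output_fs"]],
                      mode = "add"))
}

#' Test the whole Pavlovian-like function on one parameter set
#'
#' A combined network must reproduce both module truth tables with one
#' shared dynamical state, judged with the combined-network thresholds
#' (off below 5, on above 10): (1) a unique no-signal baseline for both
#' the memory and the salivation output; (2) food alone: salivation on,
#' memory off; (3) ring alone: both off; (4) food and ring together:
#' memory switches on to a plateau; (5) with signals removed the memory
#' output retains at least the configured fraction of that plateau at the
#' persistence checkpoint; (6) continuing from the persistent state, ring
#' alone now turns salivation on — the conditioned reflex.
#'
#' @param c a [combine_networks()] result.
#' @param params parameter set for `c$topology` sampled with
#'   [combined_wiring()].
#' @param config a [run_config()].
#' @param ics optional initial-condition matrix.
#' @param point_frac steady-test sample position for
#'   `steady_mode = "point"`.
#' @return a verdict, as for [test_learning()].
#' @export
test_pavlovian <- function(c, params, config = run_config(), ics = NULL,
                           point_frac = 0.5) {
  topo <- c$topology
  m_node <- topo$roles[["memory_output"]]
  s_node <- topo$roles[["output_fs"]]
  out_nodes <- sort(unique(c(m_node, s_node)))
  sys <- build_system(topo, params, combined_wiring(c))
  if (is.null(ics)) {
    set.seed(as.integer(config$seed))
    ics <- draw_ics(topo$n_nodes, out_nodes, config)
  }
  thr <- config$ratio_combined
  mk <- as.character(m_node)
  sk <- as.character(s_node)

  base <- eval_condition(sys, signal_levels(config), ics, out_nodes,
                         config, point_frac)
  if (base$status != "ok") return(fail_verdict(base$status))
  y_off_m <- base$values[, mk]
  y_off_s <- base$values[, sk]
  if (config$ic_agreement == "value" &&
      (!values_agree(y_off_m, config) || !values_agree(y_off_s, config))) {
    return(fail_verdict("multistable"))
  }

  check <- function(res, node_key, y_off, want) {
    cls <- condition_class(res$values[, node_key], y_off, thr, config)
    if (cls %in% c("multistable", "indeterminate-ratio")) return(cls)
    if (cls != want) return("truth-table")
    NULL
  }

  food <- eval_condition(sys, signal_levels(config, food = TRUE), ics,
                         out_nodes, config, point_frac)
  if (food$status != "ok") return(fail_verdict(food$status))
  for (bad in c(check(food, mk, y_off_m, "off"),
                check(food, sk, y_off_s, "on"))) {
    return(fail_verdict(bad))
  }

  ring <- eval_condition(sys, signal_levels(config, ring = TRUE), ics,
                         out_nodes, config, point_frac)
  if (ring$status != "ok") return(fail_verdict(ring$status))
  for (bad in c(check(ring, mk, y_off_m, "off"),
                check(ring, sk, y_off_s, "off"))) {
    return(fail_verdict(bad))
  }

  both <- eval_condition(sys, signal_levels(config, food = TRUE,
                                            ring = TRUE),
                         ics, out_nodes, config, point_frac)
  if (both$status != "ok") return(fail_verdict(both$status))
  bad <- check(both, mk, y_off_m, "on")
  if (!is.null(bad)) return(fail_verdict(bad))
  y_on_m <- both$values[, mk]

  hold <- continue_condition(sys, signal_levels(config), both$finals,
                             config$t_check - config$t_end, config,
                             sample_dt = config$t_check - config$t_end)
  if (!hold$ok) return(fail_verdict("sim-failed"))
  held <- hold$states[dim(hold$states)[1], , m_node]
  if (any(held < config$retain_frac * y_on_m)) {
    return(fail_verdict("persistence"))
  }
  persist_finals <- matrix(hold$states[dim(hold$states)[1], , ],
                           nrow = nrow(ics))

  recall2 <- eval_condition(sys, signal_levels(config, ring = TRUE),
                            persist_finals, s_node, config, point_frac)
  if (recall2$status != "ok") return(fail_verdict(recall2$status))
  cls <- condition_class(recall2$values[, 1], y_off_s, thr, config)
  if (cls %in% c("multistable", "indeterminate-ratio")) {
    return(fail_verdict(cls))
  }
  if (cls != "on") return(fail_verdict("truth-table"))

  list(passed = TRUE, failure_stage = "none",
       y_off_memory = mean(y_off_m), y_off_recall = mean(y_off_s),
       y_on_memory = mean(y_on_m),
       y_recall_trained = mean(recall2$values[, 1]))
}

#' Q-screen a list of combined networks
#'
#' Runs [compute_q()] with [test_pavlovian()] on every combined network
#' and returns the combination manifest. A combined network counts as able
#' to perform the Pavlovian-like function when at least one sampled
#' parameter set passes.
#'
#' @param combos list of `combined_network`s
#'   (from [enumerate_combinations()]).
#' @param n_sets,seed,config as in [compute_q()].
#' @param workers forked parallel workers.
#' @return data frame `learning_id`, `recall_id`, `arity`, `merge_map`,
#'   `added_memory_edge`, `n_sets`, `n_pass`, `q`.
#' @export
screen_combinations <- function(combos, n_sets = 1000, seed = 1,
                                config = run_config(), workers = 1L) {
  one <- function(cb) {
    q <- compute_q(cb, "pavlovian", n_sets, seed, config)
    m <- cb$provenance$map
    data.frame(learning_id = cb$provenance$learning_id,
               recall_id = cb$provenance$recall_id,
               arity = nrow(m),
               merge_map = paste(sprintf("%d~%d", m[, 1], m[, 2]),
                                 collapse = ","),
               added_memory_edge = cb$added_memory_edge,
               n_sets = q$n_sets, n_pass = q$n_pass, q = q$q,
               stringsAsFactors = FALSE)
  }
  if (!length(combos)) {
    return(data.frame(learning_id = numeric(0), recall_id = numeric(0),
                      arity = integer(0), merge_map = character(0),
                      added_memory_edge = logical(0), n_sets = integer(0),
                      n_pass = integer(0), q = numeric(0)))
  }
  rows <- if (workers > 1L && requireNamespace("parallel", quietly = TRUE)) {
    parallel::mclapply(combos, one, mc.cores = workers)
  } else {
    lapply(combos, one)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
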