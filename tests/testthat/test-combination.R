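test_that("sign-compatibility follows the merged-slot rules", {
  tL_self_act <- topology(3, roles = learning_roles(),
                          edges = data.frame(from = 2, to = 2, sign = "+"))
  tR_self_inh <- topology(3, roles = recall_roles(),
                          edges = data.frame(from = 3, to = 3, sign = "-"))
  tR_empty <- topology(3, roles = recall_roles())
  m_food_fs <- cbind(learning = 2L, recall = 3L)
  # + on itself vs - on itself: contradiction
  expect_false(check_sign_compatibility(tL_self_act, tR_self_inh,
                                        m_food_fs))
  # + on itself vs no self-regulation: allowed
  expect_true(check_sign_compatibility(tL_self_act, tR_empty, m_food_fs))
  # the food receiver may never be merged with a ring receiver
  m_food_ring <- cbind(learning = 2L, recall = 2L)
  expect_false(check_sign_compatibility(tL_self_act, tR_empty,
                                        m_food_ring))
  expect_false(check_sign_compatibility(
    topology(3, roles = learning_roles()), tR_empty, m_food_ring))
  # cross-edges between two merged pairs must agree as well
  tL_cross <- topology(3, roles = learning_roles(),
                       edges = data.frame(from = 2, to = 1, sign = "+"))
  tR_cross <- topology(3, roles = recall_roles(),
                       edges = data.frame(from = 3, to = 2, sign = "-"))
  m2 <- cbind(learning = c(2L, 1L), recall = c(3L, 2L))
  expect_false(check_sign_compatibility(tL_cross, tR_cross, m2))
  expect_true(check_sign_compatibility(tL_cross,
                                       topology(3, roles = recall_roles()),
                                       m2))
  expect_error(check_sign_compatibility(tL_cross, tR_cross,
                                        cbind(1L, 5L)), "malformed")
})

test_that("combine_networks merges edges, roles and the memory link", {
  tL <- topology(3, roles = learning_roles(),
                 edges = data.frame(from = c(1, 2), to = c(3, 3),
                                    sign = c("+", "+")))
  tR <- topology(3, roles = recall_roles(),
                 edges = data.frame(from = c(1, 2), to = c(3, 3),
                                    sign = c("+", "+")))
  # memory_output ~ memory_input: 5 nodes, no added edge
  c1 <- combine_networks(tL, tR, cbind(learning = 3L, recall = 1L))
  expect_equal(c1$topology$n_nodes, 5L)
  expect_false(c1$added_memory_edge)
  expect_equal(c1$topology$roles[["memory_input"]], 3L)
  # learning edges intact, recall edges rebased onto nodes 4, 5
  expect_equal(c1$topology$adjacency[1, 3], 1L)
  expect_equal(c1$topology$adjacency[3, 5], 1L)  # M -> F&S
  expect_equal(c1$topology$adjacency[4, 5], 1L)  # recall R -> F&S

  # memory_output ~ recall ring node: added activation M -> memory_input
  c2 <- combine_networks(tL, tR, cbind(learning = 3L, recall = 2L))
  expect_equal(c2$topology$n_nodes, 5L)
  expect_true(c2$added_memory_edge)
  mem_in <- c2$topology$roles[["memory_input"]]
  expect_equal(mem_in, 4L)
  expect_equal(c2$topology$adjacency[3, mem_in], 1L)

  # arity 3 with the memory pair merged on empty modules: 3-node empty net
  c3 <- combine_networks(topology(3, roles = learning_roles()),
                         topology(3, roles = recall_roles()),
                         cbind(learning = c(1L, 2L, 3L),
                               recall = c(2L, 3L, 1L)))
  expect_equal(c3$topology$n_nodes, 3L)
  expect_true(all(c3$topology$adjacency == 0L))
  expect_false(c3$added_memory_edge)

  expect_error(combine_networks(tL, tR, cbind(learning = 2L, recall = 2L)),
               "incompatible")
})

test_that("enumerate_combinations equals the brute-force oracle", {
  set.seed(31)
  poolL <- lapply(1:4, function(i) random_topology(3, learning_roles()))
  poolR <- lapply(1:4, function(i) random_topology(3, recall_roles()))
  for (arity in 1:3) {
    combos <- enumerate_combinations(poolL, poolR, arity)
    got <- sort(vapply(combos, function(cb) {
      combo_key(match(cb$provenance$learning_id,
                      vapply(poolL, encode_id, numeric(1))),
                match(cb$provenance$recall_id,
                      vapply(poolR, encode_id, numeric(1))),
                cb$provenance$map)
    }, character(1)))
    want <- sort(vapply(oracle_combinations(poolL, poolR, arity),
                        function(o) combo_key(o$l, o$r, o$m),
                        character(1)))
    expect_identical(got, want)
  }
})

test_that("two singleton empty pools admit all six role-legal 1-node maps", {
  poolL <- list(topology(3, roles = learning_roles()))
  poolR <- list(topology(3, roles = recall_roles()))
  combos <- enumerate_combinations(poolL, poolR, 1)
  expect_length(combos, 6)
  expect_length(oracle_combinations(poolL, poolR, 1), 6)
})

test_that("every emitted combined network satisfies its invariants", {
  set.seed(77)
  poolL <- lapply(1:3, function(i) random_topology(3, learning_roles()))
  poolR <- lapply(1:3, function(i) random_topology(3, recall_roles()))
  for (arity in 1:3) {
    for (cb in enumerate_combinations(poolL, poolR, arity)) {
      topo <- cb$topology
      r <- topo$roles
      expect_equal(topo$n_nodes, 6L - nrow(cb$provenance$map))
      # food receiver never doubles as a ring receiver
      expect_false(r[["food_input"]] %in% c(r[["ring_input_l"]],
                                            r[["ring_input_r"]]))
      # learning memory output is never the recall output
      expect_false(r[["memory_output"]] == r[["output_fs"]])
      # unmerged memory nodes are linked by an activation edge
      if (r[["memory_output"]] != r[["memory_input"]]) {
        expect_equal(
          topo$adjacency[r[["memory_output"]], r[["memory_input"]]], 1L)
      }
      # edge union: every source edge is present under the merge map
      m <- cb$provenance$map
      rmap <- integer(3)
      rmap[m[, 2]] <- m[, 1]
      nxt <- 4L
      for (rr in setdiff(1:3, m[, 2])) {
        rmap[rr] <- nxt
        nxt <- nxt + 1L
      }
      tL <- decode_id(cb$provenance$learning_id, 3)
      tR <- decode_id(cb$provenance$recall_id, 3)
      for (i in 1:3) for (j in 1:3) {
        if (tL$adjacency[i, j] != 0) {
          expect_equal(topo$adjacency[i, j], tL$adjacency[i, j])
        }
        if (tR$adjacency[i, j] != 0) {
          expect_equal(topo$adjacency[rmap[i], rmap[j]],
                       tR$adjacency[i, j])
        }
      }
    }
  }
})

test_that("combined networks carry no more sign conflict than random nets", {
  # logical-consistency filtering drives the regulation entropy of merged
  # networks below the unconstrained baseline (directional, 3 sigma)
  set.seed(5)
  poolL <- lapply(1:10, function(i) random_topology(3, learning_roles()))
  poolR <- lapply(1:10, function(i) random_topology(3, recall_roles()))
  combos <- enumerate_combinations(poolL, poolR, 1)
  expect_gte(length(combos), 100)
  ec <- vapply(combos, regulation_entropy, numeric(1))
  base <- random_network_baseline(5, 200, seed = 6)
  se <- sqrt(stats::var(ec) / length(ec) +
               stats::var(base$entropies) / length(base$entropies))
  expect_lt(mean(ec), base$mean - 3 * se)
})

# Combined fixture: direct learning module (R -> M+, F -> M+) with a
# near-frozen memory node merged memory-to-memory with a recall module
# M -> S+, R -> S+ plus a self-inhibition basal on S that keeps the
# salivation baseline at a small positive level.
pavlovian_fixture <- function() {
  tL <- topology(3, roles = learning_roles(),
                 edges = data.frame(from = c(1, 2), to = c(3, 3),
                                    sign = c("+", "+")))
  tR <- topology(3, roles = recall_roles(),
                 edges = data.frame(from = c(1, 2, 3), to = c(3, 3, 3),
                                    sign = c("+", "+", "-")))
  cb <- combine_networks(tL, tR, cbind(learning = 3L, recall = 1L))
  e <- topology_edges(cb$topology)
  e$V <- NA_real_; e$k <- NA_real_; e$K <- NA_real_
  e$alpha <- NA_real_; e$n <- NA_real_
  set_edge <- function(e, from, to, ...) {
    i <- which(e$from == from & e$to == to)
    for (nm in names(list(...))) e[[nm]][i] <- list(...)[[nm]]
    e
  }
  # weak learning drive so the frozen memory stays below the recall
  # half-max when untrained and far above it when trained
  e <- set_edge(e, 1, 3, V = 0.045, k = 0.1, n = 2)
  e <- set_edge(e, 2, 3, V = 0.045, k = 0.1, n = 2)
  e <- set_edge(e, 3, 5, V = 1, k = 1, n = 3)     # memory reads out
  e <- set_edge(e, 4, 5, V = 1, k = 0.1, n = 2)   # recall ring AND
  e <- set_edge(e, 5, 5, k = 0.05, K = 1, alpha = 1, n = 2)  # basal
  w <- combined_wiring(cb)
  w$V <- 10; w$k <- 0.1; w$n <- 2
  p <- list(edges = e, eta = c(0.05, 0.05, 1e-8, 0.05, 0.01),
            signals = w)
  list(cb = cb, p = p)
}

test_that("a merged direct learning + gated recall design is Pavlovian", {
  fx <- pavlovian_fixture()
  cfg <- run_config(n_inits = 4)
  v <- test_pavlovian(fx$cb, fx$p, cfg, point_frac = 0.5)
  expect_true(v$passed)
  expect_equal(v$failure_stage, "none")
  # fixed-point oracle for the salivation baseline: the self-inhibition
  # basal balances degradation, eta*S = k*K^2/(K^2 + S^2)
  s_base <- uniroot(function(s) 0.01 * s - 0.05 / (1 + s^2), c(0, 10))$root
  expect_equal(v$y_off_recall, s_base, tolerance = 0.01)
  # trained ring response saturates the memory readout: S ~ (V + basal)/eta
  expect_gt(v$y_recall_trained, 10 * v$y_off_recall)
  expect_gt(v$y_on_memory, 10 * v$y_off_memory)
})

test_that("a combined network with zero recall production fails at food", {
  tL <- topology(3, roles = learning_roles())
  tR <- topology(3, roles = recall_roles())
  cb <- combine_networks(tL, tR, cbind(learning = 3L, recall = 1L))
  p <- make_params(cb$topology, eta = rep(0.05, 5), wiring = NULL,
                   signals = {
                     w <- combined_wiring(cb)
                     w$V <- 0; w$k <- 0.1; w$n <- 2  # dead signal inputs
                     w
                   })
  v <- test_pavlovian(cb, p, run_config(n_inits = 3), point_frac = 0.5)
  expect_false(v$passed)
  expect_equal(v$failure_stage, "truth-table")
})

test_that("the empty one-node combination cannot learn", {
  tL <- topology(3, roles = learning_roles())
  tR <- topology(3, roles = recall_roles())
  cb <- combine_networks(tL, tR, cbind(learning = 3L, recall = 1L))
  q <- compute_q(cb, "pavlovian", n_sets = 20, seed = 5,
                 run_config(n_inits = 3))
  expect_equal(q$q, 0)
})
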