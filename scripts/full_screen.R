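#!/usr/bin/env Rscript

# One-command full-scale reproduction driver.
#
#   Rscript scripts/full_screen.R [--seed 1] [--n-sets 10000]
#                                 [--workers 32] [--out-dir results/full]
#                                 [--stage all|learning|recall|combine]
#
# Screens all 19683 three-node topologies for the learning function
# (pool: Q > 0.007) and the recall function (pool: Q > 0.008), enumerates
# all logically possible one-, two- and three-node combinations of the two
# pools, screens every combination for the whole Pavlovian-like function,
# and writes per-stage TSVs plus a summary JSON with the headline counts
# (pool sizes, combination counts, networks able to perform the function,
# top Q-value, and the Q-value of the four-node logic design).
#
# At full scale (10^4 parameter sets per topology) this is a
# cluster-sized computation — on the order of CPU-years for the module
# screens; use --workers on a large machine or split by --stage /
# pavnet's screen_topologies(ids = ...) across nodes. Reduce --n-sets for
# a proportionally cheaper (noisier) survey.

suppressPackageStartupMessages(library(pavnet))

args <- commandArgs(trailingOnly = TRUE)
flag <- function(name, default) {
  i <- which(args == paste0("--", name))
  if (length(i)) args[i + 1] else default
}
seed <- as.integer(flag("seed", "1"))
n_sets <- as.integer(flag("n-sets", "10000"))
workers <- as.integer(flag("workers", "1"))
out_dir <- flag("out-dir", "results/full")
stage <- flag("stage", "all")
limit <- flag("limit", NULL)  # screen only the first K IDs (smoke runs)
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- run_config(n_sets = n_sets, seed = seed, workers = workers)
all_ids <- 0:(n_topologies(3) - 1)
if (!is.null(limit)) all_ids <- all_ids[seq_len(as.integer(limit))]
summary <- list(seed = seed, n_sets = n_sets)

path <- function(f) file.path(out_dir, f)

if (stage %in% c("all", "learning")) {
  message("screening ", length(all_ids), " topologies for learning ...")
  resL <- screen_topologies(all_ids, "learning", n_sets, seed, cfg,
                            workers = workers)
  write_results_tsv(resL, path("learning_q.tsv"))
  poolL <- select_pool(resL, cfg$q_threshold_learning)
  write_pool_json(poolL, learning_roles(), path("learning_pool.json"))
  summary$learning_pool_size <- nrow(poolL)
}

if (stage %in% c("all", "recall")) {
  message("screening ", length(all_ids), " topologies for recall ...")
  resR <- screen_topologies(all_ids, "recall", n_sets, seed, cfg,
                            workers = workers)
  write_results_tsv(resR, path("recall_q.tsv"))
  poolR <- select_pool(resR, cfg$q_threshold_recall)
  write_pool_json(poolR, recall_roles(), path("recall_pool.json"))
  summary$recall_pool_size <- nrow(poolR)
}

if (stage %in% c("all", "combine")) {
  pl <- read_pool_json(path("learning_pool.json"))
  pr <- read_pool_json(path("recall_pool.json"))
  poolL <- pool_topologies(pl$pool, 3, pl$roles)
  poolR <- pool_topologies(pr$pool, 3, pr$roles)
  top_q <- 0
  for (arity in 1:3) {
    message("combining at arity ", arity, " ...")
    combos <- enumerate_combinations(poolL, poolR, arity)
    summary[[paste0("combinations_arity", arity)]] <- length(combos)
    man <- screen_combinations(combos, n_sets, seed, cfg,
                               workers = workers)
    write_results_tsv(man, path(sprintf("pavlovian_arity%d.tsv", arity)))
    summary[[paste0("pavlovian_capable_arity", arity)]] <-
      sum(man$n_pass > 0)
    if (nrow(man) > 0) top_q <- max(top_q, man$q)
    # regulation entropy: valid combinations vs size-matched random nets
    nn <- 6 - arity
    summary[[paste0("entropy_combined_", nn, "node")]] <-
      if (length(combos)) {
        mean(vapply(combos, regulation_entropy, numeric(1)))
      } else NA

    summary[[paste0("entropy_random_", nn, "node")]] <-
      random_network_baseline(nn, 100, seed)$mean
  }
  summary$top_pavlovian_q <- top_q
  zq <- compute_q(fixture_zhang_network(), "pavlovian", n_sets, seed, cfg)
  summary$zhang_design_q <- zq$q
}

jsonlite::write_json(summary, path("summary.json"), auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
message("summary written to ", path("summary.json"))
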