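#' The four-node Boolean-logic conditioning circuit as a combined network
#'
#' The reference digital design of the conditioning circuit (Zhang et al.,
#' built bottom-up in E. coli from two AND gates, one OR gate and a
#' one-bit memory) maps onto this package's formalism as a two-node
#' combination: a learning module `R -> M (+), F -> M (+), M -> M (+)`
#' (the self-activation realises the one-bit memory) merged with a recall
#' module `M -> F&S (+), R -> F&S (+)` by identifying the two ring
#' receivers and the two memory nodes. The result is a four-node network
#' over R, F, M and S in which the multiplicative composition of the
#' activation edges plays the AND gates and the additive food signal at
#' the output plays the OR branch.
#'
#' @return a `combined_network` (see [combine_networks()]).
#' @export
fixture_zhang_network <- function() {
  tL <- topology(3, roles = learning_roles(),
                 edges = data.frame(from = c(1, 2, 3), to = c(3, 3, 3),
                                    sign = c("+", "+", "+")))
  tR <- topology(3, roles = recall_roles(),
                 edges = data.frame(from = c(1, 2), to = c(3, 3),
                                    sign = c("+", "+")))
  # identify ring receivers (learning 1 ~ recall 2) and memory nodes
  # (learning 3 ~ recall 1)
  combine_networks(tL, tR, cbind(learning = c(1L, 3L),
                                 recall = c(2L, 1L)))
}
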