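#' Network specification
#'
#' A recurrent excitatory/inhibitory population with random
#' (Erdos-Renyi-style) directed connectivity: every ordered pair of
#' distinct neurons receives an edge independently with probability
#' `p_exc` when the source is excitatory and `p_inh` when inhibitory.
#' Neurons are embedded at uniform positions in the unit square; positions
#' are used only for visualisation/export, not for connectivity.
#'
#' @param n_exc Number of excitatory neurons (default 3200).
#' @param n_inh Number of inhibitory neurons (default 800, a 4:1 ratio).
#' @param p_exc Connection probability for excitatory sources (default
#'   0.05).
#' @param p_inh Connection probability for inhibitory sources (default
#'   0.20).
#' @param allow_self Allow self-connections (default `FALSE`).
#' @param seed Integer seed for reproducible construction.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(n_exc = 3200, n_inh = 800, p_exc = 0.05,
                         p_inh = 0.20, allow_self = FALSE, seed = 1L) {
  stopifnot(n_exc >= 0, n_inh >= 0,
            p_exc >= 0, p_exc <= 1, p_inh >= 0, p_inh <= 1)
  structure(list(n_exc = n_exc, n_inh = n_inh, p_exc = p_exc,
                 p_inh = p_inh, allow_self = allow_self,
                 seed = as.integer(seed)),
            class = "network_spec")
}

#' Build a random E/I network
#'
#' Samples the directed edge list and the 2D embedding from the seeded
#' generator. Neurons `1..n_exc` are excitatory, the remainder inhibitory.
#'
#' @param spec A [network_spec()] object.
#' @return A list of class `insnet_network` with elements `spec`,
#'   `n` (total neurons), `type` (factor `"E"`/`"I"` per neuron),
#'   `positions` (n-by-2 matrix in the unit square) and `edges`
#'   (data.frame with columns `pre`, `post`, `exc`).
#' @export
build_network <- function(spec = network_spec()) {
  stopifnot(inherits(spec, "network_spec"))
  n <- spec$n_exc + spec$n_inh
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) .Random.seed else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(spec$seed)
  positions <- cbind(x = stats::runif(n), y = stats::runif(n))
  pre <- vector("list", n)
  post <- vector("list", n)
  for (i in seq_len(n)) {
    p <- if (i <= spec$n_exc) spec$p_exc else spec$p_inh
    targets <- if (spec$allow_self) seq_len(n) else seq_len(n)[-i]
    hit <- targets[stats::runif(length(targets)) < p]
    pre[[i]] <- rep.int(i, length(hit))
    post[[i]] <- hit
  }
  edges <- data.frame(pre = unlist(pre), post = unlist(post))
  edges$exc <- edges$pre <= spec$n_exc
  structure(list(spec = spec, n = n,
                 type = factor(ifelse(seq_len(n) <= spec$n_exc, "E", "I"),
                               levels = c("E", "I")),
                 positions = positions, edges = edges),
            class = "insnet_network")
}

#' @export
print.insnet_network <- function(x, ...) {
  cat("E/I spiking network:", x$spec$n_exc, "excitatory +", x$spec$n_inh,
      "inhibitory neurons,", nrow(x$edges), "edges\n")
  cat("  connection probabilities: p_exc =", x$spec$p_exc,
      ", p_inh =", x$spec$p_inh, "; seed =", x$spec$seed, "\n")
  invisible(x)
}
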