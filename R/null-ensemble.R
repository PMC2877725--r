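#' Degree-preserving randomization of a regulatory network
#'
#' Rewires the network by attempted pairwise edge swaps
#' (r1->t1, r2->t2) => (r1->t2, r2->t1), the standard Markov-chain null
#' model for directed graphs with fixed margins. A swap is rejected when it
#' would duplicate an existing edge, or create a self-edge in a network
#' that had none, so the returned network has exactly the input's out-degree
#' for every regulator and in-degree for every target while interaction
#' partners are otherwise random. `ceil(swap_factor * |edges|)` swaps are
#' attempted; degenerate networks in which no swap is ever legal (e.g. a
#' complete bipartite graph, whose margins force the edge set) are returned
#' unchanged.
#'
#' @param net A [regulatory_network()].
#' @param swap_factor Attempted swaps per edge (default 10, ample mixing
#'   for the sparse networks this package handles).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A rewired [regulatory_network()] on the same node set.
#' @export
shuffle_preserving_degrees <- function(net, swap_factor = 10, seed = NULL) {
  stopifnot(inherits(net, "regulatory_network"), swap_factor > 0)
  if (!is.null(seed)) set.seed(seed)
  ne <- nrow(net$edges)
  if (ne < 2) return(net)
  from0 <- match(net$edges$regulator, net$nodes) - 1L
  to0 <- match(net$edges$target, net$nodes) - 1L
  allow_loops <- any(from0 == to0)
  sw <- cpp_edge_swap(from0, to0, length(net$nodes),
                      as.integer(ceiling(swap_factor * ne)), allow_loops)
  regulatory_network(net$nodes[sw[, 1] + 1L], net$nodes[sw[, 2] + 1L],
                     nodes = net$nodes, name = net$name)
}

#' Null-ensemble statistics of shared-target counts
#'
#' Generates an ensemble of degree-preserving randomized networks (see
#' [shuffle_preserving_degrees()]) and records, for every unordered pair of
#' regulators, the mean and standard deviation of the number of targets
#' the pair co-regulates across the ensemble. These are the mu and sigma
#' entering the co-regulation coefficient CC = x/mu and the z-score
#' z = (x - mu)/sigma used to filter partnership edges. Pairs that share a
#' target neither in the real network nor in any null network are omitted
#' (their CC is undefined and no partnership edge is at stake).
#'
#' The standard deviation is the population SD over the ensemble, so a
#' single-replicate ensemble yields sigma = 0. Each replicate runs under
#' its own sub-seed derived from `seed`, making the ensemble reproducible
#' for a fixed (seed, ensemble_size, swap_factor).
#'
#' @param net A [regulatory_network()].
#' @param ensemble_size Number of randomized networks (the reference
#'   analysis uses 1,000; smaller ensembles trade sharpness of mu/sigma for
#'   speed).
#' @param swap_factor Attempted swaps per edge in each replicate.
#' @param seed Integer master seed; `NULL` uses the current RNG state.
#' @return An object of class `null_cotarget_stats`: list with `pairs` (data
#'   frame `r1`, `r2`, `mu`, `sd`, with `r1 < r2` lexicographically),
#'   `ensemble_size`, `swap_factor`, `seed`.
#' @export
null_cotarget_stats <- function(net, ensemble_size = 1000, swap_factor = 10,
                                seed = NULL) {
  stopifnot(inherits(net, "regulatory_network"))
  if (ensemble_size < 1) stop("`ensemble_size` must be at least 1")
  regs <- regulators(net)
  tgts <- net_targets(net)
  m <- length(regs)
  reg_idx <- match(net$edges$regulator, regs)
  from0 <- match(net$edges$regulator, net$nodes) - 1L
  to0 <- match(net$edges$target, net$nodes) - 1L
  tgt_of_node <- match(net$nodes, tgts)  # NA for pure regulators
  allow_loops <- any(from0 == to0)
  ne <- nrow(net$edges)
  attempts <- as.integer(ceiling(swap_factor * ne))
  rep_seeds <- derive_seeds(seed, ensemble_size)

  real <- cpp_pair_counts(reg_idx, match(net$edges$target, tgts), m,
                          length(tgts))
  s1 <- matrix(0, m, m)
  s2 <- matrix(0, m, m)
  for (r in seq_len(ensemble_size)) {
    set.seed(rep_seeds[r])
    sw <- cpp_edge_swap(from0, to0, length(net$nodes), attempts, allow_loops)
    cnt <- cpp_pair_counts(reg_idx, tgt_of_node[sw[, 2] + 1L], m,
                           length(tgts))
    s1 <- s1 + cnt
    s2 <- s2 + cnt * cnt
  }
  mu <- s1 / ensemble_size
  sdv <- sqrt(pmax(s2 / ensemble_size - mu * mu, 0))
  keep <- which(upper.tri(real) & (real > 0 | s1 > 0), arr.ind = TRUE)
  keep <- keep[order(keep[, 1], keep[, 2]), , drop = FALSE]
  pairs <- data.frame(r1 = regs[keep[, 1]], r2 = regs[keep[, 2]],
                      mu = mu[keep], sd = sdv[keep],
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs, ensemble_size = ensemble_size,
                 swap_factor = swap_factor, seed = seed),
            class = "null_cotarget_stats")
}

#' @export
print.null_cotarget_stats <- function(x, ...) {
  cat(sprintf(
    "Null co-target statistics: %d regulator pairs, ensemble of %d (swap factor %g)\n",
    nrow(x$pairs), x$ensemble_size, x$swap_factor))
  invisible(x)
}

#' Write null-ensemble statistics as TSV
#'
#' @param stats A [null_cotarget_stats()] object.
#' @param path Output path.
#' @export
write_null_stats <- function(stats, path) {
  stopifnot(inherits(stats, "null_cotarget_stats"))
  df <- stats$pairs
  df$ensemble_size <- stats$ensemble_size
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(stats)
}
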