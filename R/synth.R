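#' Generate a synthetic bipartite regulator-target network
#'
#' Emulates the statistical shape of curated transcriptional networks: a
#' modest number of regulators, a much larger target pool, and a
#' heavy-tailed regulator out-degree distribution (a few hub regulators
#' with very many targets, most with few). Each regulator draws an
#' out-degree from the requested law, clipped to `[1, n_targets]`, then
#' samples that many distinct targets uniformly from the pool.
#'
#' The defaults mirror the scale of the curated yeast transcriptional
#' dataset (157 regulators, 4,410 targets); exponent 1.4 gives a mean
#' out-degree near 80, i.e. roughly 13,000 interactions.
#'
#' @param n_regulators Number of regulators (m).
#' @param n_targets Size of the target pool (N).
#' @param out_degree_law `"powerlaw"` (p(k) proportional to k^-exponent on
#'   1..n_targets, sampled by discrete inverse transform), `"poisson"`
#'   (mean `mean_degree`, clipped to at least 1) or `"fixed"`
#'   (`round(mean_degree)` targets each).
#' @param mean_degree Mean out-degree for the poisson/fixed laws.
#' @param exponent Power-law exponent (gamma > 0) for `"powerlaw"`.
#' @param allow_shared_targets If `FALSE`, regulators receive disjoint
#'   target sets (requires the degree total to fit in the pool); the
#'   resulting network has zero co-target pairs, an analytic null for
#'   partnership construction.
#' @param seed Integer seed for reproducibility; `NULL` uses the current
#'   RNG state.
#' @param name Network label.
#' @return A [regulatory_network()].
#' @examples
#' net <- make_bipartite_network(20, 200, "poisson", mean_degree = 5, seed = 1)
#' network_summary(net)
#' @export
make_bipartite_network <- function(n_regulators = 157, n_targets = 4410,
                                   out_degree_law = c("powerlaw", "poisson",
                                                      "fixed"),
                                   mean_degree = 10, exponent = 1.4,
                                   allow_shared_targets = TRUE, seed = NULL,
                                   name = "synthetic bipartite network") {
  out_degree_law <- match.arg(out_degree_law)
  stopifnot(n_regulators >= 1, n_targets >= 1)
  if (!is.null(seed)) set.seed(seed)
  k <- switch(out_degree_law,
    fixed = rep(round(mean_degree), n_regulators),
    poisson = stats::rpois(n_regulators, mean_degree),
    powerlaw = {
      stopifnot(exponent > 0)
      p <- (seq_len(n_targets))^(-exponent)
      sample.int(n_targets, n_regulators, replace = TRUE, prob = p)
    })
  k <- pmin(pmax(k, 1L), n_targets)
  reg_ids <- sprintf(paste0("R%0", nchar(n_regulators), "d"),
                     seq_len(n_regulators))
  tgt_ids <- sprintf(paste0("T%0", nchar(n_targets), "d"),
                     seq_len(n_targets))
  if (allow_shared_targets) {
    tgt_idx <- lapply(k, function(ki) sample.int(n_targets, ki))
  } else {
    if (sum(k) > n_targets)
      stop(sprintf(
        "disjoint target sets are infeasible: %d targets requested from a pool of %d",
        sum(k), n_targets))
    pool <- sample.int(n_targets)
    ends <- cumsum(k)
    tgt_idx <- mapply(function(a, b) pool[a:b], ends - k + 1, ends,
                      SIMPLIFY = FALSE)
  }
  regulatory_network(rep(reg_ids, k), tgt_ids[unlist(tgt_idx)],
                     nodes = c(reg_ids, tgt_ids), name = name)
}

#' Generate an operon-structured (bacterial-style) synthetic network
#'
#' In bacteria, regulators bind promoters of operons and thereby regulate
#' every gene in the operon. The generator first builds operons (sizes
#' 1 + Poisson(genes_per_operon_mean - 1), so every operon has at least one
#' gene), then lets each regulator sample target *operons* under the
#' requested out-degree law, and finally expands each regulated operon to
#' all of its member genes. The returned operon map inverts the expansion
#' exactly: [collapse_operons()] applied to the gene-level network with
#' this map recovers the operon-level network.
#'
#' Defaults mirror the curated E. coli dataset scale: 160 regulators and a
#' pool of 800 operons with a mean of ~1.8 genes each (~1,440 genes);
#' exponent 1.7 gives a mean of ~10 operons per regulator, i.e. roughly
#' 3,000 gene-level interactions.
#'
#' @param n_regulators Number of regulators.
#' @param n_operons Size of the operon pool.
#' @param out_degree_law,mean_degree,exponent Operon-level out-degree law,
#'   as in [make_bipartite_network()].
#' @param genes_per_operon_mean Mean operon size (>= 1).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param name Network label.
#' @return A list with `network` (gene-level [regulatory_network()]) and
#'   `map` (the [operon_map()]).
#' @export
make_operon_network <- function(n_regulators = 160, n_operons = 800,
                                out_degree_law = c("powerlaw", "poisson",
                                                   "fixed"),
                                mean_degree = 10, exponent = 1.7,
                                genes_per_operon_mean = 1.8, seed = NULL,
                                name = "synthetic operon network") {
  out_degree_law <- match.arg(out_degree_law)
  stopifnot(n_regulators >= 1, n_operons >= 1, genes_per_operon_mean >= 1)
  if (!is.null(seed)) set.seed(seed)
  sizes <- 1L + stats::rpois(n_operons, genes_per_operon_mean - 1)
  op_ids <- sprintf(paste0("O%0", nchar(n_operons), "d"), seq_len(n_operons))
  gene_op <- rep(op_ids, sizes)
  gene_ids <- sprintf(paste0("G%0", nchar(sum(sizes)), "d"),
                      seq_len(sum(sizes)))
  map <- operon_map(gene_ids, gene_op)
  genes_by_op <- split(gene_ids, gene_op)
  k <- switch(out_degree_law,
    fixed = rep(round(mean_degree), n_regulators),
    poisson = stats::rpois(n_regulators, mean_degree),
    powerlaw = {
      p <- (seq_len(n_operons))^(-exponent)
      sample.int(n_operons, n_regulators, replace = TRUE, prob = p)
    })
  k <- pmin(pmax(k, 1L), n_operons)
  reg_ids <- sprintf(paste0("R%0", nchar(n_regulators), "d"),
                     seq_len(n_regulators))
  reg_col <- vector("list", n_regulators)
  tgt_col <- vector("list", n_regulators)
  for (i in seq_len(n_regulators)) {
    ops <- op_ids[sample.int(n_operons, k[i])]
    genes <- unlist(genes_by_op[ops], use.names = FALSE)
    reg_col[[i]] <- rep(reg_ids[i], length(genes))
    tgt_col[[i]] <- genes
  }
  net <- regulatory_network(unlist(reg_col), unlist(tgt_col),
                            nodes = c(reg_ids, gene_ids), name = name)
  list(network = net, map = map)
}

#' Construct a partners-versus-targets series
#'
#' One point per regulator: `k` its number of targets (out-degree in the
#' regulatory network), `f` its number of partners (degree in the filtered
#' partnership network). Synthetic scatter may carry real-valued `f`.
#'
#' @param regulator Character identifiers (one per point).
#' @param k Nonnegative target counts.
#' @param f Nonnegative partner counts.
#' @return A data frame of class `partner_target_series`.
#' @export
partner_target_series <- function(regulator, k, f) {
  regulator <- as.character(regulator)
  stopifnot(length(regulator) == length(k), length(k) == length(f))
  if (anyDuplicated(regulator))
    stop("one point per regulator: duplicated identifiers")
  if (any(k < 0) || any(f < 0))
    stop("`k` and `f` must be nonnegative")
  structure(data.frame(regulator = regulator, k = as.numeric(k),
                       f = as.numeric(f), stringsAsFactors = FALSE),
            class = c("partner_target_series", "data.frame"))
}

#' Noisy scatter from an exponential saturation curve
#'
#' Draws `y = a (1 - exp(-b x)) + Gaussian(0, noise_sd)`, truncated at 0
#' because partner counts are nonnegative. Used to exercise and validate
#' the curve-fitting routines.
#'
#' @param a Saturation plateau (a > 0).
#' @param b Approach rate (b > 0).
#' @param xs Positive abscissae (target counts).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A [partner_target_series()] with pseudo-regulator identifiers.
#' @export
make_saturation_scatter <- function(a, b, xs, noise_sd = 0, seed = NULL) {
  stopifnot(a > 0, b > 0, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  y <- a * (1 - exp(-b * xs))
  if (noise_sd > 0) y <- y + stats::rnorm(length(xs), 0, noise_sd)
  partner_target_series(sprintf(paste0("P%0", nchar(length(xs)), "d"),
                                seq_along(xs)),
                        xs, pmax(y, 0))
}
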