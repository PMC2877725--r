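#' Shared-target counts for all regulator pairs
#'
#' For every unordered pair of regulators, the number of targets they both
#' regulate (the size of the intersection of their out-neighborhoods),
#' computed as the bipartite projection of the sparse regulator-by-target
#' incidence matrix. Pairs sharing no target are omitted.
#'
#' @param net A [regulatory_network()].
#' @return Data frame `r1`, `r2`, `x` with `r1 < r2` lexicographically and
#'   `x >= 1`, sorted by pair.
#' @export
cotarget_counts <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  regs <- regulators(net)
  tgts <- net_targets(net)
  if (!nrow(net$edges) || length(regs) < 2)
    return(data.frame(r1 = character(0), r2 = character(0), x = numeric(0),
                      stringsAsFactors = FALSE))
  inc <- Matrix::sparseMatrix(i = match(net$edges$regulator, regs),
                              j = match(net$edges$target, tgts),
                              x = 1,
                              dims = c(length(regs), length(tgts)))
  sh <- methods::as(Matrix::tcrossprod(inc), "TsparseMatrix")
  keep <- sh@i < sh@j  # strict upper triangle: unordered pairs, 0-based
  i <- sh@i[keep] + 1L
  j <- sh@j[keep] + 1L
  x <- sh@x[keep]
  ord <- order(i, j)
  data.frame(r1 = regs[i][ord], r2 = regs[j][ord], x = x[ord],
             stringsAsFactors = FALSE)
}

#' Build the co-regulation (partnership) network
#'
#' Places an undirected edge between two regulators whenever they share at
#' least one target, then filters the candidate edges against the null
#' ensemble. Three retention rules are supported:
#' \describe{
#'   \item{`"cc"`}{co-regulation coefficient CC = x/mu (real shared count
#'     over null-ensemble mean); retain CC > threshold (default 1, i.e.
#'     "more frequent than random"). When mu = 0 with x > 0 the pair is
#'     maximally over-represented: CC is +Inf and the edge is retained.}
#'   \item{`"z"`}{z = (x - mu)/sigma; retain z > threshold (default 0,
#'     which orders edges identically to CC > 1 whenever sigma > 0). When
#'     sigma = 0 the null is degenerate and the edge is kept iff x > mu.}
#'   \item{`"none"`}{retain every candidate edge (annotations still
#'     computed where defined).}
#' }
#'
#' @param net A [regulatory_network()].
#' @param stats A [null_cotarget_stats()] computed from `net`; must cover
#'   every pair with a positive real shared count.
#' @param filter One of `"cc"`, `"z"`, `"none"`.
#' @param threshold Retention threshold; defaults to 1 for `"cc"`, 0 for
#'   `"z"`, unused for `"none"`. Negative thresholds are rejected for the
#'   CC filter (CC is a ratio of counts, necessarily nonnegative).
#' @return An object of class `coreg_network`: list with `nodes` (all
#'   regulators of `net`, including those left partnerless), `edges` (data
#'   frame `r1`, `r2`, `x`, `mu`, `sigma`, `cc`, `z`), `filter`,
#'   `threshold`.
#' @export
build_coregulation <- function(net, stats, filter = c("cc", "z", "none"),
                               threshold = NULL) {
  stopifnot(inherits(net, "regulatory_network"),
            inherits(stats, "null_cotarget_stats"))
  filter <- match.arg(filter)
  if (is.null(threshold))
    threshold <- switch(filter, cc = 1, z = 0, none = NA_real_)
  if (filter == "cc" && !is.na(threshold) && threshold < 0)
    stop("negative threshold is not meaningful for the CC filter")
  cts <- cotarget_counts(net)
  edges <- data.frame(r1 = character(0), r2 = character(0), x = numeric(0),
                      mu = numeric(0), sigma = numeric(0), cc = numeric(0),
                      z = numeric(0), stringsAsFactors = FALSE)
  if (nrow(cts)) {
    idx <- match(paste(cts$r1, cts$r2, sep = "\r"),
                 paste(stats$pairs$r1, stats$pairs$r2, sep = "\r"))
    if (anyNA(idx)) {
      miss <- which(is.na(idx))[1]
      stop(sprintf("no null statistics for regulator pair (%s, %s)",
                   cts$r1[miss], cts$r2[miss]))
    }
    mu <- stats$pairs$mu[idx]
    sigma <- stats$pairs$sd[idx]
    cc <- ifelse(mu > 0, cts$x / mu, Inf)
    z <- ifelse(sigma > 0, (cts$x - mu) / sigma, NA_real_)
    keep <- switch(filter,
      cc = cc > threshold,
      z = ifelse(sigma > 0, (cts$x - mu) / sigma > threshold, cts$x > mu),
      none = rep(TRUE, nrow(cts)))
    edges <- data.frame(r1 = cts$r1, r2 = cts$r2, x = cts$x, mu = mu,
                        sigma = sigma, cc = cc, z = z,
                        stringsAsFactors = FALSE)[keep, , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = regulators(net), edges = edges, filter = filter,
                 threshold = threshold, source_name = net$name),
            class = "coreg_network")
}

#' @export
print.coreg_network <- function(x, ...) {
  cat(sprintf(
    "Co-regulation network from '%s': %d regulators, %d partnership edges (filter: %s%s)\n",
    x$source_name, length(x$nodes), nrow(x$edges), x$filter,
    if (is.na(x$threshold)) "" else sprintf(" > %g", x$threshold)))
  invisible(x)
}

#' Partnership degree of every regulator
#'
#' Degree in the filtered partnership network; regulators of the source
#' network absent from any retained edge get f = 0.
#'
#' @param coreg A [build_coregulation()] result.
#' @return Named integer vector over the regulators.
#' @export
partner_counts <- function(coreg) {
  stopifnot(inherits(coreg, "coreg_network"))
  cnt <- table(factor(c(coreg$edges$r1, coreg$edges$r2),
                      levels = coreg$nodes))
  stats::setNames(as.integer(cnt), coreg$nodes)
}

#' Target-level co-regulation network
#'
#' The dual construction: an undirected edge between two targets whenever
#' at least one regulator controls both (their in-neighborhoods
#' intersect). Equal, by duality, to the co-target pairs of the
#' edge-reversed network. Built unfiltered: the null-model filter applies
#' to the regulator-level partnership network only.
#'
#' @param net A [regulatory_network()].
#' @return An object of class `coregulated_targets`: list with `nodes`
#'   (all targets) and `edges` (data frame `t1`, `t2`, `x` = number of
#'   shared regulators).
#' @export
co_regulated_targets <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  rev_net <- regulatory_network(net$edges$target, net$edges$regulator,
                                name = net$name)
  df <- cotarget_counts(rev_net)
  names(df) <- c("t1", "t2", "x")
  structure(list(nodes = net_targets(net), edges = df),
            class = "coregulated_targets")
}

#' @export
print.coregulated_targets <- function(x, ...) {
  cat(sprintf("Co-regulated target network: %d targets, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Write a partnership network as TSV with a provenance sidecar
#'
#' Emits one row per retained edge (`r1`, `r2`, `x`, `mu`, `sigma`, `cc`,
#' `z`; infinite CC written as `inf`, undefined z as `NA`) and a JSON
#' sidecar (`<path>.json`) recording the filter, threshold and null
#' ensemble parameters.
#'
#' @param coreg A [build_coregulation()] result.
#' @param path Output TSV path.
#' @param stats Optional [null_cotarget_stats()] whose parameters are
#'   recorded in the sidecar.
#' @export
write_coregulation <- function(coreg, path, stats = NULL) {
  stopifnot(inherits(coreg, "coreg_network"))
  df <- coreg$edges
  df$cc <- ifelse(is.infinite(df$cc), "inf", format(df$cc, digits = 15))
  df$z <- ifelse(is.na(df$z), "NA", format(df$z, digits = 15))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  prov <- list(source = coreg$source_name, filter = coreg$filter,
               threshold = coreg$threshold,
               n_regulators = length(coreg$nodes),
               n_edges = nrow(coreg$edges))
  if (!is.null(stats))
    prov <- c(prov, list(ensemble_size = stats$ensemble_size,
                         swap_factor = stats$swap_factor,
                         seed = stats$seed))
  jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(coreg)
}
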