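#' Construct a directed regulatory network
#'
#' A regulatory network is a directed graph with edges pointing from
#' regulators (transcription factors, kinases) to their targets (genes,
#' substrates). Edges are a set: duplicate regulator/target pairs are
#' collapsed. Roles are degree-derived, not declared: any node with
#' out-degree at least 1 acts as a regulator, any node with in-degree at
#' least 1 as a target, and a node may hold both roles. Self-edges (a
#' regulator listed as its own target) are retained as ordinary edges.
#'
#' @param regulator,target Character vectors of equal length giving the
#'   endpoints of each directed edge.
#' @param nodes Optional character vector of node identifiers. Must contain
#'   every edge endpoint; may list additional isolated nodes (used, e.g., by
#'   the growth simulator whose node-addition moves create unconnected
#'   nodes). Defaults to the endpoints of the edges.
#' @param name Free-text label carried through downstream reports.
#' @return An object of class `regulatory_network`: a list with elements
#'   `edges` (a two-column data frame, lexicographically sorted), `nodes`
#'   (sorted character vector) and `name`.
#' @examples
#' net <- regulatory_network(c("A", "A", "B"), c("g1", "g2", "g2"))
#' network_summary(net)
#' @export
regulatory_network <- function(regulator, target, nodes = NULL,
                               name = "network") {
  regulator <- as.character(regulator)
  target <- as.character(target)
  if (length(regulator) != length(target))
    stop("`regulator` and `target` must have equal length")
  if (anyNA(regulator) || anyNA(target))
    stop("edge endpoints must not be NA")
  if (length(regulator) && any(!nzchar(regulator) | !nzchar(target)))
    stop("edge endpoints must be non-empty identifiers")
  edges <- unique(data.frame(regulator = regulator, target = target,
                             stringsAsFactors = FALSE))
  edges <- edges[order(edges$regulator, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  endpoints <- unique(c(edges$regulator, edges$target))
  if (is.null(nodes)) {
    nodes <- endpoints
  } else {
    nodes <- unique(as.character(nodes))
    if (!all(endpoints %in% nodes))
      stop("`nodes` must contain every edge endpoint")
  }
  structure(list(edges = edges, nodes = sort(nodes), name = name),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf(
    "Regulatory network '%s': %d nodes, %d interactions (%d regulators, %d targets)\n",
    x$name, length(x$nodes), s$num_interactions, s$num_regulators,
    s$num_targets))
  invisible(x)
}

#' Regulator and target identifiers of a network
#'
#' Regulators are the nodes with out-degree >= 1, targets the nodes with
#' in-degree >= 1; both are returned sorted.
#'
#' @param net A [regulatory_network()].
#' @return Sorted character vector of identifiers.
#' @export
regulators <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  sort(unique(net$edges$regulator))
}

#' @rdname regulators
#' @export
net_targets <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  sort(unique(net$edges$target))
}

#' Out-degrees (number of targets) per regulator
#'
#' @param net A [regulatory_network()].
#' @return Named integer vector over [regulators()] (out-degrees) or
#'   [net_targets()] (in-degrees).
#' @export
out_degrees <- function(net) {
  regs <- regulators(net)
  d <- table(factor(net$edges$regulator, levels = regs))
  stats::setNames(as.integer(d), regs)
}

#' @rdname out_degrees
#' @export
in_degrees <- function(net) {
  tgts <- net_targets(net)
  d <- table(factor(net$edges$target, levels = tgts))
  stats::setNames(as.integer(d), tgts)
}

#' Basic size summary of a regulatory network
#'
#' Counts regulators (out-degree >= 1), targets (in-degree >= 1) and
#' interactions (distinct directed edges). A node acting in both roles is
#' counted in both tallies, as in curated regulatory datasets where some
#' transcription factors are themselves regulated.
#'
#' @param net A [regulatory_network()].
#' @return A list with `num_regulators`, `num_targets`, `num_interactions`.
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  structure(list(num_regulators = length(unique(net$edges$regulator)),
                 num_targets = length(unique(net$edges$target)),
                 num_interactions = nrow(net$edges)),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("regulators: %d   targets: %d   interactions: %d\n",
              x$num_regulators, x$num_targets, x$num_interactions))
  invisible(x)
}

#' Read a regulatory network from a two-column edge list
#'
#' Expects one interaction per line: regulator, then target. Lines starting
#' with `#` are comments; blank lines are skipped. Fields are
#' whitespace-trimmed and identifiers are case-sensitive. Duplicate
#' interactions are collapsed to a single edge with a warning.
#'
#' @param source Path to a text file, or a connection.
#' @param delim Field delimiter, default tab.
#' @param header Logical; skip the first non-comment line?
#' @param comment_char Lines starting with this character are ignored.
#' @param name Label for the network; defaults to the file name.
#' @return A [regulatory_network()].
#' @export
read_edge_list <- function(source, delim = "\t", header = FALSE,
                           comment_char = "#", name = NULL) {
  lines <- readLines(source)
  keep <- !startsWith(trimws(lines, "left"), comment_char) &
    nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (header && length(lines)) {
    lines <- lines[-1]
    line_no <- line_no[-1]
  }
  if (!length(lines)) stop("empty edge list: no data lines found")
  fields <- strsplit(lines, delim, fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2))
    stop(sprintf("malformed edge list: fewer than 2 fields on line %d",
                 line_no[which(nf < 2)[1]]))
  reg <- trimws(vapply(fields, `[[`, "", 1L))
  tgt <- trimws(vapply(fields, `[[`, "", 2L))
  n_dup <- length(reg) - nrow(unique(data.frame(reg, tgt)))
  if (n_dup > 0)
    warning(sprintf("collapsed %d duplicate interaction(s)", n_dup))
  if (is.null(name))
    name <- if (is.character(source)) basename(source) else "network"
  regulatory_network(reg, tgt, name = name)
}

#' Write a regulatory network as a two-column edge list
#'
#' Output is tab-delimited and lexicographically sorted by regulator then
#' target, so files are deterministic and diffable. An empty network
#' produces an empty file.
#'
#' @param net A [regulatory_network()].
#' @param sink Path or connection to write to.
#' @export
write_edge_list <- function(net, sink) {
  stopifnot(inherits(net, "regulatory_network"))
  writeLines(if (nrow(net$edges)) paste(net$edges$regulator,
                                        net$edges$target, sep = "\t")
             else character(0),
             sink)
  invisible(net)
}

#' Construct a gene-to-operon map
#'
#' Bacterial genes are co-transcribed in operons under a shared promoter;
#' the map assigns each gene to exactly one operon. Genes absent from the
#' map are treated downstream as singleton operons (operon id = gene id).
#'
#' @param gene Character vector of gene identifiers (no duplicates with
#'   conflicting operons allowed).
#' @param operon Character vector of operon identifiers, same length.
#' @return Named character vector of class `operon_map` (names = genes,
#'   values = operons).
#' @export
operon_map <- function(gene, operon) {
  gene <- as.character(gene)
  operon <- as.character(operon)
  if (length(gene) != length(operon))
    stop("`gene` and `operon` must have equal length")
  pairs <- unique(data.frame(gene, operon, stringsAsFactors = FALSE))
  dup <- unique(pairs$gene[duplicated(pairs$gene)])
  if (length(dup))
    stop(sprintf("gene '%s' is assigned to more than one operon", dup[1]))
  structure(stats::setNames(pairs$operon, pairs$gene), class = "operon_map")
}

#' Read a gene-to-operon map from a two-column file
#'
#' @inheritParams read_edge_list
#' @return An [operon_map()].
#' @export
read_operon_map <- function(source, delim = "\t", header = FALSE,
                            comment_char = "#") {
  lines <- readLines(source)
  keep <- !startsWith(trimws(lines, "left"), comment_char) &
    nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (header && length(lines)) {
    lines <- lines[-1]
    line_no <- line_no[-1]
  }
  if (!length(lines)) stop("empty operon map")
  fields <- strsplit(lines, delim, fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2))
    stop(sprintf("malformed operon map: fewer than 2 fields on line %d",
                 line_no[which(nf < 2)[1]]))
  operon_map(trimws(vapply(fields, `[[`, "", 1L)),
             trimws(vapply(fields, `[[`, "", 2L)))
}

#' @export
print.operon_map <- function(x, ...) {
  cat(sprintf("Operon map: %d genes in %d operons\n", length(x),
              length(unique(unclass(x)))))
  invisible(x)
}

# internal: derive `n` reproducible sub-seeds from one master seed
# (NULL seed draws from the current RNG stream)
derive_seeds <- function(seed, n) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max, n)
}
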