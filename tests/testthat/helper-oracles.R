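# Independent brute-force oracles, deliberately naive implementations
# kept separate from the package's code paths.

# pairwise shared-target counts by explicit set intersection
brute_cotarget_counts <- function(net) {
  regs <- regulators(net)
  tg <- lapply(regs, function(r)
    net$edges$target[net$edges$regulator == r])
  names(tg) <- regs
  out <- list()
  if (length(regs) >= 2) {
    for (i in seq_len(length(regs) - 1)) {
      for (j in seq(i + 1, length(regs))) {
        x <- length(intersect(tg[[i]], tg[[j]]))
        if (x > 0)
          out[[length(out) + 1]] <- data.frame(
            r1 = regs[i], r2 = regs[j], x = x, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(r1 = character(0), r2 = character(0), x = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# degree scan by explicit per-node counting
brute_summary <- function(net) {
  nodes <- net$nodes
  outd <- vapply(nodes, function(v) sum(net$edges$regulator == v), 0)
  ind <- vapply(nodes, function(v) sum(net$edges$target == v), 0)
  list(num_regulators = sum(outd >= 1), num_targets = sum(ind >= 1),
       num_interactions = nrow(net$edges))
}

# all 0/1 matrices with the given row and column sums (small cases only)
enumerate_fixed_margin <- function(row_deg, col_deg) {
  nr <- length(row_deg)
  nc <- length(col_deg)
  res <- list()
  choose_cols <- function(avail, k) {
    if (k == 0) return(list(integer(0)))
    if (length(avail) < k) return(list())
    if (length(avail) == k) return(list(avail))
    utils::combn(avail, k, simplify = FALSE)
  }
  rec <- function(r, remaining, rows) {
    if (r > nr) {
      if (all(remaining == 0))
        res[[length(res) + 1]] <<- do.call(rbind, rows)
      return(invisible())
    }
    for (cols in choose_cols(which(remaining > 0), row_deg[r])) {
      row <- integer(nc)
      row[cols] <- 1L
      rem2 <- remaining
      rem2[cols] <- rem2[cols] - 1L
      rec(r + 1, rem2, c(rows, list(row)))
    }
  }
  rec(1, as.integer(col_deg), list())
  res
}

# exact mean (and sd) of the shared-target count of rows (i, j) over the
# uniform distribution on fixed-margin realizations
exact_pair_overlap <- function(row_deg, col_deg, i, j) {
  mats <- enumerate_fixed_margin(row_deg, col_deg)
  ov <- vapply(mats, function(m) sum(m[i, ] * m[j, ]), 0)
  list(mean = mean(ov), sd = stats::sd(ov) * sqrt((length(ov) - 1) / length(ov)),
       n_realizations = length(mats))
}

# small fixture networks
toy_net <- function() {
  regulatory_network(c("A", "A", "B", "B", "C"),
                     c("g1", "g2", "g2", "g3", "g4"),
                     name = "toy")
}

complete_bipartite <- function(n_reg, n_tgt) {
  regs <- paste0("R", seq_len(n_reg))
  tgts <- paste0("t", seq_len(n_tgt))
  regulatory_network(rep(regs, each = n_tgt), rep(tgts, n_reg),
                     name = sprintf("K%dx%d", n_reg, n_tgt))
}

# regulators partitioned into blocks that share targets only within their
# own block: restricted partner pools cap the saturation plateau at the
# block size, while degree-preserving randomization mixes across blocks
block_structured_network <- function(n_blocks, reg_per_block, tgt_per_block,
                                     exponent = 1.4, seed = 1) {
  reg <- character(0)
  tgt <- character(0)
  for (b in seq_len(n_blocks)) {
    blk <- make_bipartite_network(reg_per_block, tgt_per_block, "powerlaw",
                                  exponent = exponent, seed = seed + b)
    reg <- c(reg, sprintf("B%d_%s", b, blk$edges$regulator))
    tgt <- c(tgt, sprintf("B%d_%s", b, blk$edges$target))
  }
  regulatory_network(reg, tgt, name = sprintf("%d-block network", n_blocks))
}
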