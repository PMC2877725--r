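# Explanatory models for the saturation of partnership counts: the
# closed-form random-target-acquisition model (with its Monte-Carlo
# oracle) and the generative evolutionary network-growth simulator.

#' Expected partners under random target acquisition
#'
#' In a pool of `N` available targets shared by `m` regulators holding `n`
#' targets each on average, a regulator that acquires targets uniformly at
#' random accumulates co-regulatory partners at rate
#' `df/dk = (n/N) (m - f)`: each newly acquired target yields a new
#' partner when it is already regulated by a regulator not yet partnered.
#' Solving gives the exponential saturation curve
#' `f(k) = m (1 - exp(-(n/N) k))`, i.e. plateau `a = m` and rate
#' `b = n/N`. The derivation assumes a dilute pool (`n*m` small relative
#' to `N`, so few targets are multiply regulated); outside that regime the
#' closed form overestimates the Monte-Carlo truth.
#'
#' @param k Number of targets acquired (nonnegative, vectorized).
#' @param m Total number of regulators.
#' @param N Size of the target pool.
#' @param n Mean targets per regulator (0 < n <= N).
#' @return Expected number of partners, same length as `k`.
#' @examples
#' analytic_partner_curve(100, m = 20, N = 1000, n = 10)  # 20 (1 - e^-1)
#' @export
analytic_partner_curve <- function(k, m, N, n) {
  stopifnot(m >= 1, N >= 1, n > 0, n <= N, all(k >= 0))
  m * (1 - exp(-(n / N) * k))
}

#' Monte-Carlo oracle for the random-acquisition model
#'
#' Simulates the acquisition process directly: `m - 1` background
#' regulators each hold `n` distinct targets drawn uniformly from the
#' `N`-pool (redrawn independently per replicate), while a focal regulator
#' acquires `k = 1..k_max` distinct targets uniformly at random. `f(k)` is
#' the number of background regulators sharing at least one target with
#' the focal regulator's first `k` targets, averaged over replicates.
#' This simulation is the brute-force reference for
#' [analytic_partner_curve()] and exposes the closed form's finite-size
#' bias (the true plateau is `m - 1`, not `m`).
#'
#' @param m Total number of regulators (focal plus `m - 1` background).
#' @param N Size of the target pool.
#' @param n Targets held by each background regulator.
#' @param k_max Largest focal target count (must not exceed `N`).
#' @param replicates Number of independent replicates.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Data frame of class `acquisition_curve` with columns `k`, `f`
#'   (mean partners) and `se` (standard error of the mean across
#'   replicates).
#' @export
simulate_random_acquisition <- function(m, N, n, k_max, replicates = 500,
                                        seed = NULL) {
  stopifnot(m >= 1, N >= 1, n >= 1, n <= N, replicates >= 1)
  if (k_max > N) stop("`k_max` must not exceed the target pool size N")
  if (!is.null(seed)) set.seed(seed)
  fmat <- matrix(0, replicates, k_max)
  if (m > 1) {
    for (r in seq_len(replicates)) {
      focal <- sample.int(N, k_max)
      # first acquisition step (1..k_max) at which each background
      # regulator is hit; NA if never
      first_hit <- vapply(seq_len(m - 1), function(j) {
        pos <- match(sample.int(N, n), focal)
        if (all(is.na(pos))) NA_integer_ else min(pos, na.rm = TRUE)
      }, integer(1))
      first_hit <- first_hit[!is.na(first_hit)]
      fmat[r, ] <- cumsum(tabulate(first_hit, nbins = k_max))
    }
  }
  f_mean <- colMeans(fmat)
  f_se <- apply(fmat, 2, stats::sd) / sqrt(replicates)
  structure(data.frame(k = seq_len(k_max), f = f_mean, se = f_se),
            class = c("acquisition_curve", "data.frame"))
}

#' Configuration for the generative network-growth model
#'
#' The simulator grows a regulatory network from one TF regulating one TG
#' by repeatedly applying one of eight moves, chosen by `move_probs`:
#' node addition (`add_tf`, `add_tg`), node duplication with partial edge
#' inheritance (`dup_tf`, `dup_tg`; each incident edge is copied
#' independently with probability `inheritance_rate`), conversion of a TF
#' into a regulated TF-TG node (`tf_to_tg`), edge turnover (`add_edge`,
#' `del_edge`) and node deletion (`del_node`).
#'
#' The default move probabilities are a documented package choice,
#' calibrated once so that the default 10,000 iterations yield roughly
#' 160-200 TFs, ~2,100 TGs and ~4,000 interactions -- the output scale of
#' the reference analysis -- with duplication strong enough to produce the
#' out-degree heterogeneity real regulatory networks show. The 30%
#' inheritance rate and the iteration count follow the reference analysis.
#'
#' @param add_tf,add_tg,dup_tf,dup_tg,tf_to_tg,add_edge,del_edge,del_node
#'   Move probabilities; must sum to 1 (tolerance 1e-9).
#' @param inheritance_rate Probability that a duplicated node inherits each
#'   incident edge of its template, in `[0, 1]`.
#' @param iterations Number of moves to apply.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return List of class `growth_config`.
#' @export
growth_config <- function(add_tf = 0.006, add_tg = 0.08, dup_tf = 0.014,
                          dup_tg = 0.16, tf_to_tg = 0.01, add_edge = 0.51,
                          del_edge = 0.19, del_node = 0.03,
                          inheritance_rate = 0.30, iterations = 10000,
                          seed = NULL) {
  probs <- c(add_tf = add_tf, add_tg = add_tg, dup_tf = dup_tf,
             dup_tg = dup_tg, tf_to_tg = tf_to_tg, add_edge = add_edge,
             del_edge = del_edge, del_node = del_node)
  if (any(probs < 0)) stop("move probabilities must be nonnegative")
  if (abs(sum(probs) - 1) > 1e-9)
    stop(sprintf("move probabilities must sum to 1 (got %.12f)", sum(probs)))
  stopifnot(inheritance_rate >= 0, inheritance_rate <= 1, iterations >= 1)
  structure(list(move_probs = probs, inheritance_rate = inheritance_rate,
                 iterations = as.integer(iterations), seed = seed),
            class = "growth_config")
}

#' Simulate evolutionary growth of a regulatory network
#'
#' Starts from one TF regulating one TG and applies `iterations` moves
#' drawn from the configured move distribution (see [growth_config()]).
#' Role bookkeeping: newly added or duplicated nodes carry their declared
#' role; `tf_to_tg` converts a TF into a TF-TG node that gains an in-edge
#' from another TF while keeping all its out-edges, and remains eligible
#' for TF-role moves. TF-TG nodes duplicate according to the role under
#' which they were selected (out-edges as TF, in-edges as TG). Moves with
#' no legal action (e.g. deleting an edge from an edgeless network, or
#' adding an edge to a saturated bipartite graph) are skipped and counted,
#' so `iterations` is an exact move budget.
#'
#' @param config A [growth_config()].
#' @return A [regulatory_network()] over the surviving nodes (isolated
#'   nodes included), with an `audit` attribute: per-move applied/skipped
#'   counts (summing to `iterations`), final TF/TG/TF-TG tallies and the
#'   per-iteration edge-count trajectory.
#' @export
simulate_growth <- function(config) {
  stopifnot(inherits(config, "growth_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  probs <- config$move_probs
  n_it <- config$iterations
  inh <- config$inheritance_rate

  # node state; roles: "TF", "TG", "TFTG" (converted TF)
  cap_n <- 64L
  role <- character(cap_n)
  alive <- logical(cap_n)
  n_nodes <- 2L
  role[1:2] <- c("TF", "TG")
  alive[1:2] <- TRUE
  # edge state, swap-with-last deletion
  cap_e <- 256L
  efrom <- integer(cap_e)
  eto <- integer(cap_e)
  ne <- 1L
  efrom[1] <- 1L
  eto[1] <- 2L

  grow_nodes <- function() {
    cap_n <<- cap_n * 2L
    length(role) <<- cap_n
    length(alive) <<- cap_n
    alive[is.na(alive)] <<- FALSE
  }
  add_node <- function(r) {
    if (n_nodes >= cap_n) grow_nodes()
    n_nodes <<- n_nodes + 1L
    role[n_nodes] <<- r
    alive[n_nodes] <<- TRUE
    n_nodes
  }
  add_edges <- function(from, to) {
    k <- length(from)
    if (k == 0L) return(invisible())
    while (ne + k > cap_e) {
      cap_e <<- cap_e * 2L
      length(efrom) <<- cap_e
      length(eto) <<- cap_e
    }
    efrom[(ne + 1L):(ne + k)] <<- from
    eto[(ne + 1L):(ne + k)] <<- to
    ne <<- ne + k
  }
  del_edge_at <- function(idx) {  # idx sorted increasing
    for (i in rev(idx)) {
      efrom[i] <<- efrom[ne]
      eto[i] <<- eto[ne]
      ne <<- ne - 1L
    }
  }
  pick <- function(cand) cand[sample.int(length(cand), 1L)]

  moves <- sample(names(probs), n_it, replace = TRUE, prob = probs)
  applied <- stats::setNames(integer(length(probs)), names(probs))
  skipped <- applied
  edge_trajectory <- integer(n_it)

  for (it in seq_len(n_it)) {
    mv <- moves[it]
    ok <- switch(mv,
      add_tf = {
        add_node("TF")
        TRUE
      },
      add_tg = {
        add_node("TG")
        TRUE
      },
      dup_tf = {
        cand <- which(alive[1:n_nodes] & role[1:n_nodes] != "TG")
        if (!length(cand)) FALSE else {
          v <- pick(cand)
          new <- add_node("TF")
          out_e <- which(efrom[seq_len(ne)] == v)
          inherit <- out_e[stats::runif(length(out_e)) < inh]
          add_edges(rep(new, length(inherit)), eto[inherit])
          TRUE
        }
      },
      dup_tg = {
        cand <- which(alive[1:n_nodes] & role[1:n_nodes] != "TF")
        if (!length(cand)) FALSE else {
          v <- pick(cand)
          new <- add_node("TG")
          in_e <- which(eto[seq_len(ne)] == v)
          inherit <- in_e[stats::runif(length(in_e)) < inh]
          add_edges(efrom[inherit], rep(new, length(inherit)))
          TRUE
        }
      },
      tf_to_tg = {
        pure_tf <- which(alive[1:n_nodes] & role[1:n_nodes] == "TF")
        tf_like <- which(alive[1:n_nodes] & role[1:n_nodes] != "TG")
        if (!length(pure_tf) || length(tf_like) < 2) FALSE else {
          v <- pick(pure_tf)
          u <- pick(setdiff(tf_like, v))
          role[v] <- "TFTG"
          add_edges(u, v)
          TRUE
        }
      },
      add_edge = {
        tf_like <- which(alive[1:n_nodes] & role[1:n_nodes] != "TG")
        tg_like <- which(alive[1:n_nodes] & role[1:n_nodes] != "TF")
        if (!length(tf_like) || !length(tg_like)) FALSE else {
          done <- FALSE
          for (try in 1:100) {
            r <- pick(tf_like)
            t <- pick(tg_like)
            if (r != t && !any(efrom[seq_len(ne)] == r & eto[seq_len(ne)] == t)) {
              add_edges(r, t)
              done <- TRUE
              break
            }
          }
          done
        }
      },
      del_edge = {
        if (ne < 1L) FALSE else {
          del_edge_at(sample.int(ne, 1L))
          TRUE
        }
      },
      del_node = {
        cand <- which(alive[1:n_nodes])
        if (!length(cand)) FALSE else {
          v <- pick(cand)
          alive[v] <- FALSE
          inc <- which(efrom[seq_len(ne)] == v | eto[seq_len(ne)] == v)
          if (length(inc)) del_edge_at(inc)
          TRUE
        }
      })
    if (ok) applied[mv] <- applied[mv] + 1L else skipped[mv] <- skipped[mv] + 1L
    edge_trajectory[it] <- ne
  }

  live <- which(alive[1:n_nodes])
  ids <- stats::setNames(sprintf(paste0("n%0", nchar(n_nodes), "d"),
                                 seq_len(n_nodes))[live], live)
  keep_e <- seq_len(ne)
  net <- regulatory_network(ids[as.character(efrom[keep_e])],
                            ids[as.character(eto[keep_e])],
                            nodes = unname(ids),
                            name = "generative growth network")
  audit <- list(
    applied = as.list(applied), skipped = as.list(skipped),
    iterations = n_it,
    n_tf = sum(role[live] == "TF"),
    n_tg = sum(role[live] == "TG"),
    n_tftg = sum(role[live] == "TFTG"),
    edge_trajectory = edge_trajectory)
  attr(net, "audit") <- audit
  net
}
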