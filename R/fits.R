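# Degree distributions, power-law diagnostics, partners-vs-targets series,
# and linear vs exponential-saturation model fitting.

new_saturation_fit <- function(family, params, r_squared, n_points) {
  structure(list(family = family, params = params, r_squared = r_squared,
                 n_points = n_points),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  p <- paste(sprintf("%s = %.6g", names(x$params), x$params),
             collapse = ", ")
  cat(sprintf("%s fit: %s; R^2 = %.4f (n = %d)\n", x$family, p,
              x$r_squared, x$n_points))
  invisible(x)
}

r_squared_about_mean <- function(obs, fitted) {
  ss_res <- sum((obs - fitted)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) return(0)
  1 - ss_res / ss_tot
}

#' Empirical partnership-degree distribution
#'
#' The probability mass P(k) of the number of partners k across the
#' regulators of a partnership network.
#'
#' @param coreg A [build_coregulation()] result.
#' @param include_zero Include regulators with no partners (k = 0)?
#' @return Data frame `k`, `p` with `sum(p) == 1`.
#' @export
degree_distribution <- function(coreg, include_zero = TRUE) {
  f <- partner_counts(coreg)
  if (!include_zero) f <- f[f > 0]
  if (!length(f))
    stop("no regulators with partners; use include_zero = TRUE")
  tab <- table(f)
  data.frame(k = as.integer(names(tab)),
             p = as.numeric(tab) / length(f))
}

#' Power-law diagnostic on a degree distribution
#'
#' Ordinary least squares of log P(k) on log k over the support points with
#' k >= 1 and P(k) > 0, the conventional log-log regression diagnostic. A
#' heavy-tailed (inhomogeneous) distribution yields a large R-squared with
#' gamma > 0; the homogeneous partnership degree distributions this
#' package characterizes yield low R-squared.
#'
#' @param dist Data frame `k`, `p` from [degree_distribution()].
#' @return A `saturation_fit` with family `"powerlaw"` and params `gamma`
#'   (negated slope) and `log_intercept`.
#' @export
fit_powerlaw <- function(dist) {
  stopifnot(is.data.frame(dist), all(c("k", "p") %in% names(dist)))
  sel <- dist$k >= 1 & dist$p > 0
  if (sum(sel) < 3)
    stop("power-law fit needs at least 3 support points with k >= 1, P(k) > 0")
  x <- log(dist$k[sel])
  y <- log(dist$p[sel])
  if (stats::var(y) == 0)
    return(new_saturation_fit("powerlaw",
                              c(gamma = 0, log_intercept = mean(y)),
                              0, sum(sel)))
  fit <- stats::lm(y ~ x)
  new_saturation_fit("powerlaw",
                     c(gamma = -unname(stats::coef(fit)[2]),
                       log_intercept = unname(stats::coef(fit)[1])),
                     r_squared_about_mean(y, stats::fitted(fit)), sum(sel))
}

#' Partners-versus-targets series of a regulatory network
#'
#' One point per regulator: its number of targets (out-degree in the
#' regulatory network) against its number of partners (degree in the
#' filtered partnership network, 0 if absent). This is the scatter all
#' scaling fits consume.
#'
#' @param net A [regulatory_network()].
#' @param coreg A [build_coregulation()] result derived from `net` (the
#'   regulator sets must match).
#' @return A [partner_target_series()].
#' @export
partners_vs_targets <- function(net, coreg) {
  stopifnot(inherits(net, "regulatory_network"),
            inherits(coreg, "coreg_network"))
  regs <- regulators(net)
  if (!identical(regs, sort(coreg$nodes)))
    stop("regulator sets differ: the partnership network was not derived from this regulatory network")
  k <- out_degrees(net)
  f <- partner_counts(coreg)[regs]
  partner_target_series(regs, as.numeric(k), as.numeric(f))
}

as_series_df <- function(series) {
  stopifnot(is.data.frame(series), all(c("k", "f") %in% names(series)))
  data.frame(k = as.numeric(series$k), f = as.numeric(series$f))
}

#' Linear fit of partners on targets
#'
#' Ordinary least squares `f = slope * k + intercept` on the raw
#' per-regulator scatter.
#'
#' @param series A [partner_target_series()] (or any data frame with
#'   columns `k` and `f`).
#' @return A `saturation_fit` with family `"linear"`.
#' @export
fit_linear <- function(series) {
  d <- as_series_df(series)
  if (nrow(d) < 3) stop("linear fit needs at least 3 points")
  if (stats::var(d$k) == 0)
    stop("degenerate series: no variance in the number of targets")
  fit <- stats::lm(f ~ k, data = d)
  new_saturation_fit("linear",
                     c(slope = unname(stats::coef(fit)[2]),
                       intercept = unname(stats::coef(fit)[1])),
                     r_squared_about_mean(d$f, stats::fitted(fit)), nrow(d))
}

#' Exponential-saturation fit of partners on targets
#'
#' Nonlinear least squares of `f = a (1 - exp(-b k))` with constraints
#' a >= 0, b >= 0, via bounded Levenberg-Marquardt. `a` is the saturation
#' plateau (the limiting number of partners), `b` the approach rate.
#' Initialization: `a0 = 1.05 * max(f)`, and `b0` from a through-origin
#' regression of `-log(1 - f/a0)` on `k` (the linearization of the model
#' at fixed plateau). Convergence is to a relative parameter/objective
#' tolerance below 1e-8 within 500 iterations; non-convergence and
#' all-zero `f` raise errors.
#'
#' R-squared is computed as 1 - SS_res/SS_tot about the mean of `f`; it
#' may be negative for fits worse than the constant mean and is reported
#' as-is.
#'
#' @inheritParams fit_linear
#' @return A `saturation_fit` with family `"exp_saturation"` and params
#'   `a`, `b`.
#' @export
fit_exp_saturation <- function(series) {
  d <- as_series_df(series)
  if (nrow(d) < 3) stop("saturation fit needs at least 3 points")
  if (all(d$f == 0)) stop("all partner counts are zero; nothing to fit")
  a0 <- 1.05 * max(d$f)
  y0 <- -log(1 - d$f / a0)
  b0 <- sum(d$k * y0) / sum(d$k^2)
  if (!is.finite(b0) || b0 <= 0) b0 <- 1 / mean(d$k[d$k > 0])
  fit <- tryCatch(
    minpack.lm::nlsLM(f ~ a * (1 - exp(-b * k)), data = d,
                      start = list(a = a0, b = b0), lower = c(0, 0),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-10, ptol = 1e-10)),
    error = function(e)
      stop(sprintf("saturation fit did not converge (started at a = %.6g, b = %.6g): %s",
                   a0, b0, conditionMessage(e)), call. = FALSE))
  p <- stats::coef(fit)
  fitted <- p[["a"]] * (1 - exp(-p[["b"]] * d$k))
  new_saturation_fit("exp_saturation", c(a = p[["a"]], b = p[["b"]]),
                     r_squared_about_mean(d$f, fitted), nrow(d))
}

#' Compare linear and exponential-saturation fits
#'
#' Fits both families to the same series and prefers the one with the
#' larger R-squared. Ties within 1e-12 go to the linear family (fewer
#' effective shape parameters); in the near-linear regime (b*k << 1 for
#' all sampled k) both families fit almost equally well and the reported
#' `delta_r_squared` quantifies how thin the preference is.
#'
#' @inheritParams fit_linear
#' @return List of class `fit_comparison` with elements `linear`,
#'   `exp_saturation`, `preferred` (family name) and `delta_r_squared`
#'   (exponential minus linear R-squared).
#' @export
compare_fits <- function(series) {
  lin <- fit_linear(series)
  ex <- fit_exp_saturation(series)
  delta <- ex$r_squared - lin$r_squared
  preferred <- if (abs(delta) < 1e-12) "linear" else
    if (delta > 0) "exp_saturation" else "linear"
  structure(list(linear = lin, exp_saturation = ex, preferred = preferred,
                 delta_r_squared = delta),
            class = "fit_comparison")
}

#' @export
print.fit_comparison <- function(x, ...) {
  cat(sprintf("preferred: %s (delta R^2 = %.3g)\n", x$preferred,
              x$delta_r_squared))
  print(x$linear)
  print(x$exp_saturation)
  invisible(x)
}

#' Collapse target genes to operons
#'
#' Replaces every target gene by its operon identifier (genes absent from
#' the map are treated as singleton operons and kept as-is); parallel
#' edges produced by the merge are collapsed. Regulator identifiers are
#' untouched. The collapse recalibrates a bacterial network's effective
#' number of distinct targets: a regulator's out-degree becomes its number
#' of regulated operons and can only decrease.
#'
#' @param net A [regulatory_network()].
#' @param map An [operon_map()].
#' @return A [regulatory_network()] over regulators and operons.
#' @export
collapse_operons <- function(net, map) {
  stopifnot(inherits(net, "regulatory_network"), inherits(map, "operon_map"))
  ops <- unclass(map)[net$edges$target]
  tgt <- ifelse(is.na(ops), net$edges$target, ops)
  regulatory_network(net$edges$regulator, tgt,
                     name = paste0(net$name, " [operon-collapsed]"))
}

#' Down-sample a network for robustness analysis
#'
#' Emulates data incompleteness: removes a fraction of nodes (with their
#' incident edges; regulators and targets alike) or of edges, uniformly at
#' random, in several independent trials. Rerunning the pipeline on the
#' down-sampled networks probes whether the partners-versus-targets
#' relationship survives incomplete data.
#'
#' @param net A [regulatory_network()].
#' @param fraction Fraction to remove, in `[0, 1)`.
#' @param mode `"nodes"` or `"edges"`.
#' @param trials Number of independent trials (default 3).
#' @param seed Integer master seed; `NULL` uses the current RNG state.
#' @return List of `trials` down-sampled [regulatory_network()]s.
#' @export
downsample <- function(net, fraction, mode = c("nodes", "edges"),
                       trials = 3, seed = NULL) {
  stopifnot(inherits(net, "regulatory_network"),
            fraction >= 0, fraction < 1, trials >= 1)
  mode <- match.arg(mode)
  sub_seeds <- derive_seeds(seed, trials)
  lapply(seq_len(trials), function(tr) {
    set.seed(sub_seeds[tr])
    out <- if (mode == "nodes") {
      n_rm <- round(fraction * length(net$nodes))
      if (n_rm == 0) return(net)
      keep <- setdiff(net$nodes, sample(net$nodes, n_rm))
      sel <- net$edges$regulator %in% keep & net$edges$target %in% keep
      regulatory_network(net$edges$regulator[sel], net$edges$target[sel],
                         nodes = keep,
                         name = sprintf("%s [%.0f%% nodes removed, trial %d]",
                                        net$name, 100 * fraction, tr))
    } else {
      ne <- nrow(net$edges)
      n_rm <- round(fraction * ne)
      if (n_rm == 0) return(net)
      sel <- sort(sample.int(ne, ne - n_rm))
      regulatory_network(net$edges$regulator[sel], net$edges$target[sel],
                         nodes = net$nodes,
                         name = sprintf("%s [%.0f%% edges removed, trial %d]",
                                        net$name, 100 * fraction, tr))
    }
    if (!nrow(out$edges))
      warning(sprintf("down-sampling trial %d produced an empty network", tr))
    out
  })
}
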