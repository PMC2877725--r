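# End-to-end orchestration: network -> null ensemble -> partnership
# network -> scaling fits, with optional operon recalibration,
# randomized-network comparison and down-sampling robustness.

#' Configure an end-to-end partnership analysis
#'
#' @param input A [regulatory_network()] or a path to a two-column edge
#'   list readable by [read_edge_list()].
#' @param operon_map An [operon_map()], a path readable by
#'   [read_operon_map()], or `NULL` to skip the operon-collapsed variant.
#' @param ensemble_size Null-ensemble size (reference analysis: 1,000).
#' @param swap_factor Attempted swaps per edge during randomization.
#' @param filter,threshold Partnership edge retention rule, see
#'   [build_coregulation()].
#' @param compare_random Also run the analysis on one degree-preserving
#'   randomized copy of the input (the real-versus-random comparison)?
#' @param downsample_fractions Numeric vector of removal fractions for the
#'   robustness stage (e.g. `c(0.2, 0.4)`); empty to skip.
#' @param downsample_modes Removal modes, subset of `c("nodes", "edges")`.
#' @param downsample_trials Independent trials per fraction/mode.
#' @param output_dir Directory for TSV/JSON outputs and the run manifest;
#'   `NULL` keeps results in memory only.
#' @param seed Master seed; fanned out to per-stage sub-seeds recorded in
#'   the manifest.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input, operon_map = NULL, ensemble_size = 1000,
                            swap_factor = 10, filter = "cc",
                            threshold = NULL, compare_random = TRUE,
                            downsample_fractions = numeric(0),
                            downsample_modes = c("nodes", "edges"),
                            downsample_trials = 3, output_dir = NULL,
                            seed = 1) {
  if (is.character(input) && !file.exists(input))
    stop(sprintf("input edge list '%s' does not exist", input))
  if (is.character(operon_map) && !file.exists(operon_map))
    stop(sprintf("operon map '%s' does not exist", operon_map))
  downsample_modes <- match.arg(downsample_modes, several.ok = TRUE)
  structure(list(input = input, operon_map = operon_map,
                 ensemble_size = ensemble_size, swap_factor = swap_factor,
                 filter = filter, threshold = threshold,
                 compare_random = compare_random,
                 downsample_fractions = downsample_fractions,
                 downsample_modes = downsample_modes,
                 downsample_trials = downsample_trials,
                 output_dir = output_dir, seed = seed),
            class = "pipeline_config")
}

# fit stages may fail legitimately (e.g. an empty partnership network);
# record the failure instead of aborting the run
try_fit <- function(expr) {
  tryCatch(expr, error = function(e)
    structure(list(message = conditionMessage(e)), class = "fit_error"))
}

#' @export
print.fit_error <- function(x, ...) {
  cat(sprintf("fit unavailable: %s\n", x$message))
  invisible(x)
}

analyse_network <- function(net, ensemble_size, swap_factor, filter,
                            threshold, seed) {
  stats <- null_cotarget_stats(net, ensemble_size = ensemble_size,
                               swap_factor = swap_factor, seed = seed)
  coreg <- build_coregulation(net, stats, filter = filter,
                              threshold = threshold)
  series <- partners_vs_targets(net, coreg)
  list(stats = stats, coreg = coreg, series = series,
       degree_distribution = try_fit(degree_distribution(coreg)),
       powerlaw = try_fit(fit_powerlaw(degree_distribution(coreg))),
       comparison = try_fit(compare_fits(series)))
}

#' Run the full partnership-network analysis
#'
#' Stages: read/accept the regulatory network; null-ensemble statistics;
#' partnership network under the configured filter; partners-vs-targets
#' series; partnership degree distribution with power-law diagnostic;
#' linear and exponential-saturation fits with preference; optionally the
#' same analysis on a degree-preserving randomized copy, on the
#' operon-collapsed network, and on down-sampled networks. Any structural
#' stage failure aborts with the stage name; fit failures on degenerate
#' results (e.g. an empty partnership network) are recorded as
#' `fit_error` objects instead.
#'
#' When `output_dir` is set, writes the series (TSV), the partnership
#' network (TSV + provenance JSON), the fits (JSON) and a run manifest
#' (JSON) recording seeds, stages and network sizes; numeric output is
#' deterministic for a fixed seed.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- derive_seeds(config$seed, 4)
  names(seeds) <- c("null_ensemble", "random_comparison", "operon_variant",
                    "downsample")
  stage <- "load input"
  report <- tryCatch({
    net <- if (inherits(config$input, "regulatory_network")) config$input
           else read_edge_list(config$input)
    omap <- if (is.null(config$operon_map)) NULL
            else if (inherits(config$operon_map, "operon_map")) config$operon_map
            else read_operon_map(config$operon_map)

    stage <- "partnership analysis"
    main <- analyse_network(net, config$ensemble_size, config$swap_factor,
                            config$filter, config$threshold,
                            seeds[["null_ensemble"]])

    random <- NULL
    if (isTRUE(config$compare_random)) {
      stage <- "randomized comparison"
      rnd_seeds <- derive_seeds(seeds[["random_comparison"]], 2)
      rnd_net <- shuffle_preserving_degrees(net, config$swap_factor,
                                            seed = rnd_seeds[1])
      random <- analyse_network(rnd_net, config$ensemble_size,
                                config$swap_factor, config$filter,
                                config$threshold, rnd_seeds[2])
    }

    operon <- NULL
    if (!is.null(omap)) {
      stage <- "operon recalibration"
      op_net <- collapse_operons(net, omap)
      operon <- analyse_network(op_net, config$ensemble_size,
                                config$swap_factor, config$filter,
                                config$threshold, seeds[["operon_variant"]])
      operon$network <- op_net
    }

    robustness <- NULL
    if (length(config$downsample_fractions)) {
      stage <- "downsample robustness"
      ds_seeds <- derive_seeds(seeds[["downsample"]],
                               length(config$downsample_fractions) *
                                 length(config$downsample_modes))
      robustness <- list()
      si <- 0
      for (fr in config$downsample_fractions) {
        for (md in config$downsample_modes) {
          si <- si + 1
          nets <- downsample(net, fr, md, trials = config$downsample_trials,
                             seed = ds_seeds[si])
          sub_seeds <- derive_seeds(ds_seeds[si] %% 1000000L + 1L,
                                    length(nets))
          fits <- lapply(seq_along(nets), function(i) {
            sub <- analyse_network(nets[[i]], config$ensemble_size,
                                   config$swap_factor, config$filter,
                                   config$threshold, sub_seeds[i])
            sub$comparison
          })
          robustness[[sprintf("%s_%g", md, fr)]] <- fits
        }
      }
    }

    list(network = net, summary = network_summary(net), main = main,
         random = random, operon = operon, robustness = robustness,
         seeds = as.list(seeds), config = config)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  class(report) <- "pipeline_report"
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Partnership pipeline report\n")
  print(x$summary)
  print(x$main$coreg)
  print(x$main$comparison)
  invisible(x)
}

fit_to_list <- function(fit) {
  if (is.null(fit)) return(NULL)
  if (inherits(fit, "fit_error")) return(list(error = fit$message))
  if (inherits(fit, "fit_comparison"))
    return(list(linear = fit_to_list(fit$linear),
                exp_saturation = fit_to_list(fit$exp_saturation),
                preferred = fit$preferred,
                delta_r_squared = fit$delta_r_squared))
  list(family = fit$family, params = as.list(fit$params),
       r_squared = fit$r_squared, n_points = fit$n_points)
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- report$config
  utils::write.table(
    data.frame(regulator = report$main$series$regulator,
               k = report$main$series$k,
               f = report$main$series$f),
    file.path(dir, "partners_vs_targets.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_coregulation(report$main$coreg, file.path(dir, "coregulation.tsv"),
                     stats = report$main$stats)
  fits <- list(main = fit_to_list(report$main$comparison),
               main_powerlaw = fit_to_list(report$main$powerlaw),
               random = fit_to_list(report$random$comparison),
               operon = fit_to_list(report$operon$comparison))
  jsonlite::write_json(fits, file.path(dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(
    package = "partnernet",
    version = as.character(utils::packageVersion("partnernet")),
    seed = cfg$seed, stage_seeds = report$seeds,
    ensemble_size = cfg$ensemble_size, swap_factor = cfg$swap_factor,
    filter = cfg$filter, threshold = cfg$threshold,
    network = list(name = report$network$name,
                   num_regulators = report$summary$num_regulators,
                   num_targets = report$summary$num_targets,
                   num_interactions = report$summary$num_interactions),
    stages = c("load input", "partnership analysis",
               if (!is.null(report$random)) "randomized comparison",
               if (!is.null(report$operon)) "operon recalibration",
               if (!is.null(report$robustness)) "downsample robustness"),
    audit = {
      a <- attr(report$network, "audit")
      a$edge_trajectory <- NULL  # bulky per-iteration trace, memory only
      a
    })
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}

#' Grow a synthetic network and analyse its partnership structure
#'
#' Runs [simulate_growth()] under `growth` and feeds the resulting network
#' through [run_pipeline()]. The growth audit (per-move counts, final
#' TF/TG tallies) is attached to the report and written to the manifest.
#'
#' @param growth A [growth_config()].
#' @param pipeline A [pipeline_config()] whose `input` is ignored, or
#'   `NULL` for defaults (CC > 1 filter, ensemble of 100).
#' @return A `pipeline_report` with an extra `growth_audit` element and
#'   `preferred_family` shortcut.
#' @export
run_growth_experiment <- function(growth, pipeline = NULL) {
  stopifnot(inherits(growth, "growth_config"))
  net <- simulate_growth(growth)
  if (is.null(pipeline))
    pipeline <- pipeline_config(net, ensemble_size = 100,
                                compare_random = FALSE,
                                seed = if (is.null(growth$seed)) 1
                                       else growth$seed)
  else pipeline$input <- net
  report <- run_pipeline(pipeline)
  report$growth_audit <- attr(net, "audit")
  report$preferred_family <-
    if (inherits(report$main$comparison, "fit_error")) NA_character_
    else report$main$comparison$preferred
  report
}
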