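# End-to-end runners: each writes its tabular outputs plus a manifest that
# suffices to re-run the command identically. Tabular outputs of a re-run
# from the manifest are byte-identical (the manifest itself carries the
# only timestamp).

pahrisk_version <- function() {
  as.character(utils::packageVersion("pahrisk"))
}

write_manifest <- function(out_dir, command, options, inputs = list(),
                           outputs, seed = NULL) {
  manifest <- list(
    command = command,
    tool = "pahrisk", version = pahrisk_version(),
    seed = seed, options = options, inputs = inputs,
    outputs = lapply(outputs, function(p)
      list(file = basename(p), md5 = md5_of(p))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(out_dir, "manifest.json")
  # I(17) significant digits: doubles in the config echo must survive the
  # JSON round trip bit-exactly for re-runs to be checksum-identical
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = I(17))
  path
}

#' Simulate a derivative table to disk
#'
#' Runs \code{\link{simulate_derivatives}} and writes
#' \code{derivatives.csv}, \code{ground_truth.tsv} and
#' \code{manifest.json} into \code{out_dir}.
#'
#' @param config a \code{\link{sim_config}}.
#' @param out_dir output directory (created if needed).
#' @return named paths of the files written, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  if (!inherits(config, "sim_config"))
    stop_validation("config must be a sim_config object")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_derivatives(config)
  f_tab <- file.path(out_dir, "derivatives.csv")
  f_tru <- file.path(out_dir, "ground_truth.tsv")
  write_derivative_table(sim$derivatives, f_tab)
  write_table_precise(sim$ground_truth, f_tru, sep = "\t")
  cfg_echo <- config
  cfg_echo$parents <- config$parents$acronym     # serializable echo
  cfg_echo$p_increase <- as.list(config$p_increase)  # keep names in JSON
  cfg_echo$p_active <- as.list(config$p_active)
  f_man <- write_manifest(out_dir, "simulate",
                          options = unclass(cfg_echo),
                          outputs = list(f_tab, f_tru), seed = config$seed)
  invisible(c(derivatives = f_tab, ground_truth = f_tru, manifest = f_man))
}

#' Run the full assessment pipeline to disk
#'
#' Reads a derivative table, runs \code{\link{risk_assessment}}, and writes
#' \code{risk_profiles.tsv}, \code{factor_scores.tsv}, \code{ranking.tsv},
#' \code{risk_assessment.json} and \code{manifest.json}.
#'
#' @param table_path derivative-table CSV/TSV.
#' @param out_dir output directory.
#' @param registry_path optional parent-registry CSV overriding the built-in
#'   registry.
#' @inheritParams risk_assessment
#' @return named paths written, invisibly.
#' @export
run_assess <- function(table_path, out_dir, registry_path = NULL,
                       aggregation = "max", parent_mode = "sum",
                       high_risk_fraction = 0.30) {
  registry <- if (is.null(registry_path)) parent_registry()
              else read_parent_registry(registry_path)
  derivs <- read_derivative_table(table_path, registry = registry)
  fit <- risk_assessment(derivs, registry, aggregation = aggregation,
                         parent_mode = parent_mode,
                         high_risk_fraction = high_risk_fraction)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f_prof <- file.path(out_dir, "risk_profiles.tsv")
  f_sc <- file.path(out_dir, "factor_scores.tsv")
  f_rank <- file.path(out_dir, "ranking.tsv")
  f_json <- file.path(out_dir, "risk_assessment.json")
  write_risk_profiles(fit$profiles, f_prof)
  write_table_precise(fit$factor_scores, f_sc, sep = "\t")
  write_table_precise(fit$parent_ra, f_rank, sep = "\t")
  jsonlite::write_json(list(
    config = fit$config, n_derivatives = fit$n_derivatives,
    pathway_ra = fit$pathway_ra, parent_ra = fit$parent_ra
  ), f_json, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  opts <- list(aggregation = aggregation, parent_mode = parent_mode,
               high_risk_fraction = high_risk_fraction,
               registry_path = registry_path)
  f_man <- write_manifest(out_dir, "assess", options = opts,
                          inputs = list(table = list(
                            path = normalizePath(table_path),
                            md5 = md5_of(table_path))),
                          outputs = list(f_prof, f_sc, f_rank, f_json))
  invisible(c(profiles = f_prof, factor_scores = f_sc, ranking = f_rank,
              report = f_json, manifest = f_man))
}

#' Validate QSAR predictions from disk or the packaged reference set
#'
#' With \code{pairs = "reference"}, recomputes the relative errors of the
#' packaged reference activity pairs against the published column.
#' Otherwise reads an activity-pair table and reports relative errors plus
#' the external validation statistics available from observed/predicted
#' pairs.
#'
#' @param pairs \code{"reference"} or a file path.
#' @param out optional path for a JSON report.
#' @return the validation data.frame or report list, invisibly.
#' @export
run_validate_qsar <- function(pairs = "reference", out = NULL) {
  if (identical(pairs, "reference")) {
    res <- validate_qsar_reference()
    report <- list(source = "reference",
                   n = nrow(res), max_deviation = max(res$deviation),
                   rows = res)
  } else {
    x <- read_activity_pairs(pairs)
    tr <- x$split == "training"; te <- !tr
    if (sum(te) < 3)
      stop_validation("too few test pairs (need at least 3)")
    x$rel_err <- relative_error(x$observed, x$predicted)
    r2p <- vapply(c("standard", "sd_testmean", "pearson2"), function(fm)
      as.numeric(external_r2_pred(x$observed[tr], x$observed[te],
                                  x$predicted[te], fm)), numeric(1))
    report <- list(source = pairs, n = nrow(x),
                   R2_training = r_squared(x$observed[tr], x$predicted[tr]),
                   R2_pred = as.list(r2p),
                   SEP = sep_external(x$observed[te], x$predicted[te]),
                   rows = x)
  }
  if (!is.null(out))
    jsonlite::write_json(report, out, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  invisible(report)
}

#' Re-run a command from its manifest
#'
#' Reproduces a \code{simulate} or \code{assess} run from the manifest it
#' wrote. Tabular outputs of the re-run are byte-identical to the
#' originals.
#'
#' @param manifest_path path to a \code{manifest.json}.
#' @param out_dir directory for the re-run outputs.
#' @return named paths written, invisibly.
#' @export
run_from_manifest <- function(manifest_path, out_dir) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (identical(m$command, "simulate")) {
    o <- m$options
    cfg <- sim_config(
      seed = o$seed,
      parents = parent_registry()[
        match(o$parents, parent_registry()$acronym), , drop = FALSE],
      pathways = o$pathways, n_per_pathway = o$n_cells,
      p_increase = unlist(o$p_increase),
      increase_meanlog = o$increase_meanlog,
      increase_sdlog = o$increase_sdlog, decrease_max = o$decrease_max,
      dev_shape = unlist(o$dev_shape), geno_shape = unlist(o$geno_shape),
      p_active = unlist(o$p_active), logbcf_mean = o$logbcf_mean,
      logbcf_sd = o$logbcf_sd,
      persistence_meanlog = o$persistence_meanlog,
      persistence_sdlog = o$persistence_sdlog,
      missing_rate = o$missing_rate)
    run_simulate(cfg, out_dir)
  } else if (identical(m$command, "assess")) {
    o <- m$options
    rp <- o$registry_path
    if (!length(rp)) rp <- NULL
    run_assess(m$inputs$table$path, out_dir,
               registry_path = rp,
               aggregation = o$aggregation, parent_mode = o$parent_mode,
               high_risk_fraction = o$high_risk_fraction)
  } else {
    stop_validation("manifest command not re-runnable: ",
                    m$command %||% "<missing>")
  }
}
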