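# Ordinal screening rubric. Toxicity-increase and persistence-increase
# factors score 0/1/2 on the percent change versus the parent; probability
# factors score on absolute probability bins; activity factors are 0/1;
# bioconcentration scores on absolute logBCF thresholds.

#' Score a percent increase (0 / 1 / 2)
#'
#' No increase (change \eqn{\le} 0) is negligible risk and scores 0; an
#' increase in (0, 50] scores 1; an increase above 50 percent scores 2. The
#' boundary at exactly +50 falls in the lower bin.
#'
#' @param percent_change signed percent change versus parent (vectorized).
#' @return integer scores in \{0, 1, 2\}; \code{NA} passes through.
#' @examples
#' score_continuous_increase(c(-12.3, 25, 50, 64.92))
#' @export
score_continuous_increase <- function(percent_change) {
  bad <- is.nan(percent_change) |
    (!is.na(percent_change) & !is.finite(percent_change))
  if (any(bad)) stop_validation("percent change must be finite")
  ifelse(is.na(percent_change), NA_integer_,
         ifelse(percent_change <= 0, 0L,
                ifelse(percent_change <= 50, 1L, 2L)))
}

#' Score a model probability (0 / 1 / 2)
#'
#' Low probability [0, 0.30) scores 0, medium [0.30, 0.70] scores 1, high
#' (0.70, 1] scores 2. The published bin edges overlap at 0.30 and 0.70;
#' both boundaries resolve to the medium bin, ">0.70" being the only strict
#' bound stated.
#'
#' @param prob probability in \eqn{[0,1]} (vectorized).
#' @return integer scores in \{0, 1, 2\}; \code{NA} passes through.
#' @export
score_probability <- function(prob) {
  ok <- is.na(prob) | (is.finite(prob) & prob >= 0 & prob <= 1)
  if (!all(ok)) stop_validation("probability out of [0, 1]: ",
                                format(prob[!ok][1]))
  ifelse(is.na(prob), NA_integer_,
         ifelse(prob < 0.30, 0L, ifelse(prob <= 0.70, 1L, 2L)))
}

#' Score a binary activity call (0 / 1)
#' @param active 0/1 activity call (vectorized); \code{NA} passes through.
#' @return integer 0 or 1.
#' @export
score_binary <- function(active) {
  ok <- is.na(active) | active %in% c(0, 1)
  if (!all(ok)) stop_validation("activity call must be 0 or 1")
  as.integer(active)
}

#' Score a log10 bioconcentration factor (0 / 1 / 2)
#'
#' logBCF < 2.0 scores 0; 2.0 \eqn{\le} logBCF < 3.0 scores 1; logBCF
#' \eqn{\ge} 3.0 (strong bioenrichment) scores 2.
#'
#' @param logbcf log10 BCF (vectorized); \code{NA} passes through.
#' @return integer scores in \{0, 1, 2\}.
#' @export
score_bcf <- function(logbcf) {
  bad <- !is.na(logbcf) & !is.finite(logbcf)
  if (any(bad)) stop_validation("logBCF must be finite")
  ifelse(is.na(logbcf), NA_integer_,
         ifelse(logbcf < 2, 0L, ifelse(logbcf < 3, 1L, 2L)))
}

#' Factor scores of one (parent, pathway) derivative set
#'
#' Scores every derivative on the eleven rubric factors and aggregates each
#' factor across derivatives. \code{a_i} is the environmental-risk factor
#' (phytotoxicity increase); \code{b_ij} the six human-health factors
#' (neurotoxicity and immunotoxicity increases, developmental and
#' genotoxicity probabilities, carcinogenicity and endocrine activity);
#' \code{c_ij} the four environmental-behaviour factors (logBCF by absolute
#' threshold, half-life, persistence and air half-life by percent increase).
#'
#' The default aggregation is the componentwise maximum — conservative
#' screening, so a single high-risk by-product is never diluted; \code{mean}
#' is available (non-integer factor values permitted) and the mode is
#' stamped into the result. A factor whose endpoint is missing from every
#' derivative contributes 0.
#'
#' @param derivatives rows of a derivative table for one (parent, pathway).
#' @param registry parent registry with baselines.
#' @param aggregation \code{"max"} (default) or \code{"mean"}.
#' @return object of class \code{factor_scores}: list with
#'   \code{parent_acronym}, \code{pathway_id}, \code{a_i}, \code{b_ij}
#'   (named length 6), \code{c_ij} (named length 4), \code{aggregation},
#'   \code{n_derivatives}.
#' @examples
#' cfg <- sim_config(seed = 7, n_per_pathway = 4, pathways = "photolysis")
#' sim <- simulate_derivatives(cfg)
#' d <- sim$derivatives
#' score_pathway(d[d$parent_acronym == "BaP", ], parent_registry())
#' @export
score_pathway <- function(derivatives, registry = parent_registry(),
                          aggregation = c("max", "mean")) {
  aggregation <- match.arg(aggregation)
  x <- as.data.frame(derivatives)
  if (!nrow(x)) stop_validation("empty derivative set: nothing to score")
  parent <- unique(x$parent_acronym)
  pathway <- unique(x$pathway_id)
  if (length(parent) != 1L || length(pathway) != 1L)
    stop_validation("score_pathway expects a single (parent, pathway) set")
  if (!parent %in% registry$acronym)
    stop_validation("parent_acronym '", parent, "' not in the registry")

  per <- list(
    phytotoxicity   = score_continuous_increase(
                        endpoint_change(x, "phytotoxicity", registry)),
    neurotoxicity   = score_continuous_increase(
                        endpoint_change(x, "neurotoxicity", registry)),
    immunotoxicity  = score_continuous_increase(
                        endpoint_change(x, "immunotoxicity", registry)),
    developmental   = score_probability(x[["dev_prob"]]),
    genotoxicity    = score_probability(x[["geno_prob"]]),
    carcinogenicity = score_binary(x[["carc_active"]]),
    endocrine       = score_binary(x[["endo_active"]]),
    logBCF          = score_bcf(x[["logbcf"]] %||% rep(NA_real_, nrow(x))),
    half_life       = score_continuous_increase(
                        endpoint_change(x, "half_life", registry)),
    persistence     = score_continuous_increase(
                        endpoint_change(x, "persistence", registry)),
    air_half_life   = score_continuous_increase(
                        endpoint_change(x, "air_half_life", registry))
  )
  agg <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(0)
    if (aggregation == "max") max(v) else mean(v)
  }
  s <- vapply(per, agg, numeric(1))
  structure(list(
    parent_acronym = parent, pathway_id = pathway,
    a_i = unname(s["phytotoxicity"]),
    b_ij = s[c("neurotoxicity", "immunotoxicity", "developmental",
               "genotoxicity", "carcinogenicity", "endocrine")],
    c_ij = s[c("logBCF", "half_life", "persistence", "air_half_life")],
    aggregation = aggregation, n_derivatives = nrow(x)
  ), class = "factor_scores")
}

#' @export
print.factor_scores <- function(x, ...) {
  cat(sprintf("Factor scores: %s / %s (%d derivatives, aggregation = %s)\n",
              x$parent_acronym, x$pathway_id, x$n_derivatives,
              x$aggregation))
  cat("  a  (environmental risk):     ", x$a_i, "\n")
  cat("  b  (human health):           ",
      paste(sprintf("%s=%g", names(x$b_ij), x$b_ij), collapse = " "), "\n")
  cat("  c  (environmental behaviour):",
      paste(sprintf("%s=%g", names(x$c_ij), x$c_ij), collapse = " "), "\n")
  invisible(x)
}

# flatten a list of factor_scores into the TSV schema
factor_scores_table <- function(scores) {
  do.call(rbind, lapply(scores, function(s) data.frame(
    parent_acronym = s$parent_acronym, pathway_id = s$pathway_id,
    a_i = s$a_i,
    b_neuro = unname(s$b_ij["neurotoxicity"]),
    b_immuno = unname(s$b_ij["immunotoxicity"]),
    b_dev = unname(s$b_ij["developmental"]),
    b_geno = unname(s$b_ij["genotoxicity"]),
    b_carc = unname(s$b_ij["carcinogenicity"]),
    b_endo = unname(s$b_ij["endocrine"]),
    c_bcf = unname(s$c_ij["logBCF"]),
    c_halflife = unname(s$c_ij["half_life"]),
    c_persistence = unname(s$c_ij["persistence"]),
    c_airhalflife = unname(s$c_ij["air_half_life"]),
    aggregation_mode = s$aggregation,
    stringsAsFactors = FALSE
  )))
}
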