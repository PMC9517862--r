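#' Full risk-prioritization assessment
#'
#' The package's central fit: from a table of per-derivative endpoint
#' predictions it computes, per (parent, pathway), the risk probability and
#' degree of every endpoint, the ordinal factor scores, the total exposed
#' risk value \eqn{RA_i}, and then ranks parents by their combined risk and
#' flags the high-risk tail. High-risk flags are exported in both views:
#' within each pathway family (parents compared inside one transformation
#' route) and at parent level (totals across routes).
#'
#' @param derivatives a \code{derivative_table}, a compatible data.frame, or
#'   a file path.
#' @param registry parent registry with baselines; defaults to
#'   \code{\link{parent_registry}()}.
#' @param aggregation factor aggregation across derivatives within a
#'   pathway: \code{"max"} (default, conservative) or \code{"mean"}.
#' @param parent_mode fold combining pathway RA values into a parent total:
#'   \code{"sum"} (default), \code{"mean"} or \code{"max"}.
#' @param high_risk_fraction top fraction flagged high-risk, default 0.30.
#' @return object of class \code{pah_risk}: list with \code{profiles} (long
#'   risk probability/degree table), \code{factor_scores} (wide per-pathway
#'   scores), \code{pathway_ra} (per (parent, pathway) RA with components,
#'   within-pathway rank and high-risk flag), \code{parent_ra} (ranked
#'   parent totals with flags), \code{config}, and \code{n_derivatives}.
#' @examples
#' sim <- simulate_derivatives(sim_config(seed = 3, n_per_pathway = 3))
#' fit <- risk_assessment(sim$derivatives)
#' fit
#' head(summary(fit))
#' @export
risk_assessment <- function(derivatives, registry = parent_registry(),
                            aggregation = c("max", "mean"),
                            parent_mode = c("sum", "mean", "max"),
                            high_risk_fraction = 0.30) {
  aggregation <- match.arg(aggregation)
  parent_mode <- match.arg(parent_mode)
  if (is.character(derivatives) && length(derivatives) == 1L)
    derivatives <- read_derivative_table(derivatives, registry = registry)
  if (!inherits(derivatives, "derivative_table"))
    derivatives <- as_derivative_table(as.data.frame(derivatives),
                                       registry = registry)
  x <- as.data.frame(derivatives)

  profiles <- pathway_risk_profiles(derivatives, registry)

  grp <- interaction(x$parent_acronym, x$pathway_id, drop = TRUE, sep = "\r")
  scores <- lapply(split(x, grp), score_pathway, registry = registry,
                   aggregation = aggregation)
  score_tab <- factor_scores_table(scores)

  ras <- lapply(scores, compute_ra)
  pathway_ra <- data.frame(
    parent_acronym = vapply(ras, `[[`, character(1), "parent_acronym"),
    pathway_id = vapply(ras, `[[`, character(1), "pathway_id"),
    A = vapply(ras, function(r) r$components[["A"]], numeric(1)),
    B = vapply(ras, function(r) r$components[["B"]], numeric(1)),
    C = vapply(ras, function(r) r$components[["C"]], numeric(1)),
    RA = vapply(ras, `[[`, numeric(1), "RA"),
    stringsAsFactors = FALSE
  )
  rownames(pathway_ra) <- NULL

  # high-risk view 1: within each pathway family, across parents
  pathway_ra$rank_within_pathway <- NA_integer_
  pathway_ra$high_risk <- NA
  for (p in unique(pathway_ra$pathway_id)) {
    i <- which(pathway_ra$pathway_id == p)
    r <- rank_parents(pathway_ra[i, c("parent_acronym", "RA")])
    pathway_ra$rank_within_pathway[i] <-
      r$rank[match(pathway_ra$parent_acronym[i], r$parent_acronym)]
    pathway_ra$high_risk[i] <-
      classify_high_risk(pathway_ra$RA[i], high_risk_fraction)
  }
  pathway_ra <- pathway_ra[order(pathway_ra$pathway_id,
                                 pathway_ra$rank_within_pathway), ]
  rownames(pathway_ra) <- NULL

  # high-risk view 2: parent totals across pathways
  totals <- vapply(split(pathway_ra$RA, pathway_ra$parent_acronym),
                   switch(parent_mode, sum = sum, mean = mean, max = max),
                   numeric(1))
  parent_ra <- rank_parents(totals)
  parent_ra$high_risk <- classify_high_risk(parent_ra$RA,
                                            high_risk_fraction)

  structure(list(
    profiles = profiles, factor_scores = score_tab,
    pathway_ra = pathway_ra, parent_ra = parent_ra,
    config = list(aggregation = aggregation, parent_mode = parent_mode,
                  high_risk_fraction = high_risk_fraction),
    n_derivatives = nrow(x)
  ), class = "pah_risk")
}

#' @export
print.pah_risk <- function(x, ...) {
  cat("PAH transformation-pathway risk assessment\n")
  cat(sprintf("  %d derivatives, %d parents, %d pathways\n",
              x$n_derivatives,
              length(unique(x$pathway_ra$parent_acronym)),
              length(unique(x$pathway_ra$pathway_id))))
  cat(sprintf(
    "  factor aggregation: %s; parent totals: %s; high-risk fraction: %.2f\n",
    x$config$aggregation, x$config$parent_mode,
    x$config$high_risk_fraction))
  cat("Parent ranking by total exposed risk RA:\n")
  top <- utils::head(x$parent_ra, 16)
  cat(sprintf("  %2d. %-6s RA = %7.3f%s\n", top$rank, top$parent_acronym,
              top$RA, ifelse(top$high_risk, "  [high risk]", "")),
      sep = "")
  invisible(x)
}

#' @export
plot.pah_risk <- function(x, ...) {
  r <- x$parent_ra
  op <- graphics::par(mar = c(5, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(r$RA), names.arg = rev(r$parent_acronym),
                    horiz = TRUE, las = 1,
                    col = ifelse(rev(r$high_risk), "firebrick", "grey70"),
                    xlab = "total exposed risk RA",
                    main = "Parent PAHs by total exposed risk", ...)
  invisible(x)
}

#' @export
summary.pah_risk <- function(object, ...) {
  p <- object$pathway_ra
  data.frame(
    pathway_id = unique(p$pathway_id),
    n_parents = as.vector(table(p$pathway_id)[unique(p$pathway_id)]),
    top_parent = vapply(unique(p$pathway_id), function(pw) {
      s <- p[p$pathway_id == pw, ]
      s$parent_acronym[which.min(s$rank_within_pathway)]
    }, character(1)),
    max_RA = vapply(unique(p$pathway_id), function(pw)
      max(p$RA[p$pathway_id == pw]), numeric(1)),
    n_high_risk = vapply(unique(p$pathway_id), function(pw)
      sum(p$high_risk[p$pathway_id == pw]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
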