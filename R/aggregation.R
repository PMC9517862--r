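# Risk-entropy aggregation: RA_i = a_i + sum(b_ij)/6 + sum(c_ij)/4, the
# total exposed risk evaluation value of pathway i, followed by per-parent
# totals, ranking and top-fraction high-risk classification.

#' Total exposed risk value of a pathway
#'
#' Combines the factor scores of one (parent, pathway) into
#' \deqn{RA_i = A_i + B_i + C_i = a_i + \frac{1}{6}\sum_{j=1}^{6} b_{ij}
#'       + \frac{1}{4}\sum_{j=1}^{4} c_{ij}.}
#' The denominators are the fixed factor-set sizes (6 human-health, 4
#' environmental-behaviour factors), independent of missing endpoints —
#' missing factors score 0. Under the rubric maxima
#' (binary factors capped at 1) \eqn{RA \le 2 + 10/6 + 8/4 = 5.667}.
#'
#' @param scores a \code{\link{score_pathway}} result, or any list with
#'   \code{a_i} (length 1), \code{b_ij} (length 6) and \code{c_ij}
#'   (length 4).
#' @return object of class \code{risk_assessment}: list with
#'   \code{parent_acronym}, \code{pathway_id}, \code{RA}, \code{components}
#'   (named A, B, C), \code{rank} and \code{high_risk} (unset here).
#' @examples
#' compute_ra(list(a_i = 2, b_ij = c(2, 2, 2, 2, 1, 1),
#'                 c_ij = c(2, 2, 2, 2)))$RA  # 5.6667, the rubric maximum
#' @export
compute_ra <- function(scores) {
  if (length(scores$a_i) != 1L || length(scores$b_ij) != 6L ||
      length(scores$c_ij) != 4L)
    stop_validation("factor scores must have 1 a, 6 b and 4 c components")
  A <- as.numeric(scores$a_i)
  B <- sum(as.numeric(scores$b_ij)) / 6
  C <- sum(as.numeric(scores$c_ij)) / 4
  structure(list(
    parent_acronym = scores$parent_acronym %||% NA_character_,
    pathway_id = scores$pathway_id %||% NA_character_,
    RA = A + B + C, components = c(A = A, B = B, C = C),
    rank = NA_integer_, high_risk = NA
  ), class = "risk_assessment")
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat(sprintf("RA = %.4f  (A = %.4f, B = %.4f, C = %.4f)  %s / %s\n",
              x$RA, x$components["A"], x$components["B"], x$components["C"],
              x$parent_acronym, x$pathway_id))
  invisible(x)
}

#' Combine pathway risk values into a parent-level total
#'
#' @param pathway_assessments list of \code{risk_assessment} objects (or a
#'   numeric vector of RA values) for one parent.
#' @param mode \code{"sum"} (default), \code{"mean"} or \code{"max"}.
#' @return parent-level \code{risk_assessment} (pathway unset; components
#'   combined with the same fold).
#' @export
total_parent_risk <- function(pathway_assessments,
                              mode = c("sum", "mean", "max")) {
  mode <- match.arg(mode)
  if (!length(pathway_assessments))
    stop_validation("no pathway assessments to combine")
  if (is.numeric(pathway_assessments)) {
    ra <- pathway_assessments
    comp <- NULL
    parent <- NA_character_
  } else {
    ra <- vapply(pathway_assessments, function(a) a$RA, numeric(1))
    comp <- vapply(pathway_assessments, function(a) a$components, numeric(3))
    parent <- unique(vapply(pathway_assessments,
                            function(a) a$parent_acronym, character(1)))
    if (length(parent) != 1L)
      stop_validation("pathway assessments span more than one parent")
  }
  fold <- switch(mode, sum = sum, mean = mean, max = max)
  structure(list(
    parent_acronym = parent, pathway_id = NA_character_,
    RA = fold(ra),
    components = if (is.null(comp)) c(A = NA_real_, B = NA_real_, C = NA_real_)
                 else apply(comp, 1, fold),
    rank = NA_integer_, high_risk = NA, mode = mode
  ), class = "risk_assessment")
}

#' Rank parents by total exposed risk
#'
#' Descending by RA; exact ties broken lexicographically by acronym for
#' determinism and flagged in the \code{tied} column.
#'
#' @param parent_assessments data.frame with columns \code{parent_acronym}
#'   and \code{RA} (one row per parent), or a named numeric vector.
#' @return the data.frame ordered by rank, with \code{rank} (1 = highest
#'   risk) and \code{tied} columns added.
#' @export
rank_parents <- function(parent_assessments) {
  x <- parent_assessments
  if (is.numeric(x) && !is.null(names(x)))
    x <- data.frame(parent_acronym = names(x), RA = unname(x),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(x$parent_acronym))
    stop_validation("duplicate parent entries: ",
                    paste(unique(x$parent_acronym[
                      duplicated(x$parent_acronym)]), collapse = ", "))
  ord <- order(-x$RA, x$parent_acronym)
  x <- x[ord, , drop = FALSE]
  x$rank <- seq_len(nrow(x))
  x$tied <- duplicated(x$RA) | duplicated(x$RA, fromLast = TRUE)
  rownames(x) <- NULL
  x
}

#' Flag the top fraction as high-risk
#'
#' Flags the \eqn{\lceil f \cdot n \rceil} highest-RA entries; entries tied
#' with the value at the cutoff are all flagged. An RA of zero carries no
#' risk and is never flagged, whatever the fraction.
#'
#' @param ra numeric RA values.
#' @param fraction fraction in (0, 1]; default 0.30 (a user-definable
#'   screening threshold).
#' @return logical vector aligned with \code{ra}.
#' @examples
#' classify_high_risk(c(5, 4, 3, 2, 1, 0, 0, 0, 0, 0))  # top 3 of 10
#' @export
classify_high_risk <- function(ra, fraction = 0.30) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      !is.finite(fraction) || fraction <= 0 || fraction > 1)
    stop_validation("fraction must be a number in (0, 1]")
  if (!length(ra)) stop_validation("no RA values to classify")
  k <- ceiling(fraction * length(ra))
  cutoff <- sort(ra, decreasing = TRUE)[k]
  ra >= cutoff & ra > 0
}
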