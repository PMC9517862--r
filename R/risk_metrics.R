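#' Percent toxicity change of a derivative versus its parent
#'
#' For the binding-free-energy endpoints, toxicity is carried by the
#' magnitude of a negative free energy: more negative binding means stronger
#' receptor affinity and higher predicted toxicity. The change is therefore
#' computed on magnitudes,
#' \deqn{100 (|\Delta G_{deriv}| - |\Delta G_{parent}|) / |\Delta G_{parent}|,}
#' so a positive result means the derivative binds more strongly than its
#' parent. Scale-invariant: multiplying both energies by k > 0 (a unit
#' change) leaves the result unchanged.
#'
#' @param parent_value,derivative_value binding free energies in kJ/mol;
#'   both must be finite and negative. Vectorized (recycled pairwise).
#' @return signed percent change.
#' @examples
#' percent_change_continuous(-100, -150)  #  50: half again as toxic
#' percent_change_continuous(-100, -50)   # -50: toxicity halved
#' @export
percent_change_continuous <- function(parent_value, derivative_value) {
  if (any(!is.finite(parent_value)) || any(!is.finite(derivative_value)))
    stop_validation("binding free energies must be finite")
  if (any(parent_value == 0))
    stop_validation("parent binding free energy of 0: change undefined")
  if (any(parent_value > 0) || any(derivative_value >= 0))
    stop_validation("binding free energies must be negative (kJ/mol)")
  (abs(derivative_value) - abs(parent_value)) / abs(parent_value) * 100
}

#' Probability-scale toxicity change
#'
#' Developmental-toxicity and genotoxicity endpoints are model probabilities;
#' their change versus the parent is reported as an absolute difference on
#' the probability scale (a parent at 0.70 and a derivative at 0.72 is a
#' 0.02-degree increase), not as a percent.
#'
#' @param parent_prob,derivative_prob probabilities in \eqn{[0,1]}.
#' @return signed difference, derivative minus parent.
#' @export
change_probabilistic <- function(parent_prob, derivative_prob) {
  p <- c(parent_prob, derivative_prob)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop_validation("probabilities must lie in [0, 1]")
  derivative_prob - parent_prob
}

#' Risk probability of a pathway's derivative set
#'
#' The fraction (as a percent) of derivatives whose toxicity increased
#' relative to the parent; for binary endpoints, the fraction predicted
#' active. An exact tie counts as not increased. An empty collection (every
#' derivative missing the endpoint) returns \code{NA_real_}, the documented
#' no-data marker — it is not a zero risk.
#'
#' @param changes signed toxicity changes (percent or probability scale), or
#'   0/1 activity calls when \code{binary = TRUE}. \code{NA}s are dropped.
#' @param binary interpret \code{changes} as activity calls.
#' @return percent in \eqn{[0, 100]}, or \code{NA_real_} if no data.
#' @examples
#' risk_probability(c(12, -3))            # 50
#' risk_probability(c(1, 1, 0), binary = TRUE)
#' @export
risk_probability <- function(changes, binary = FALSE) {
  changes <- changes[!is.na(changes)]
  if (!length(changes)) return(NA_real_)
  if (binary) {
    if (!all(changes %in% c(0, 1)))
      stop_validation("binary changes must be 0/1 activity calls")
    return(100 * mean(changes == 1))
  }
  100 * mean(changes > 0)
}

#' Risk degree of a pathway's derivative set
#'
#' The mean change among only those derivatives whose toxicity increased
#' (the at-risk subset). When no derivative increased the degree is 0 by
#' convention — negligible risk, not a negative one. An empty collection
#' returns \code{NA_real_}.
#'
#' @inheritParams risk_probability
#' @return mean increase (percent, or probability-scale for probabilistic
#'   endpoints); fraction active for binary endpoints.
#' @examples
#' risk_degree(c(10, 30, -5))  # 20: mean of the two increases
#' risk_degree(c(-10, -5))     # 0 by convention
#' @export
risk_degree <- function(changes, binary = FALSE) {
  changes <- changes[!is.na(changes)]
  if (!length(changes)) return(NA_real_)
  if (binary) {
    if (!all(changes %in% c(0, 1)))
      stop_validation("binary changes must be 0/1 activity calls")
    return(mean(changes == 1))
  }
  up <- changes[changes > 0]
  if (!length(up)) return(0)
  mean(up)
}

# per-row change of one endpoint versus the parent baseline; NA where the
# endpoint (or the baseline) is missing
endpoint_change <- function(x, endpoint, registry) {
  info <- endpoint_info(endpoint)
  col <- info$column
  if (!col %in% names(x)) return(rep(NA_real_, nrow(x)))
  v <- x[[col]]
  base <- registry[[col]][match(x$parent_acronym, registry$acronym)]
  out <- rep(NA_real_, nrow(x))
  ok <- !is.na(v) & !is.na(base)
  if (!any(ok)) return(out)
  out[ok] <- switch(info$scale,
    free_energy = percent_change_continuous(base[ok], v[ok]),
    probability = change_probabilistic(base[ok], v[ok]),
    binary      = v[ok],                       # fraction-active convention
    time        = (v[ok] - base[ok]) / base[ok] * 100,
    log10       = (v[ok] - base[ok]) / base[ok] * 100)
  out
}

#' Per-pathway risk probability and degree profiles
#'
#' For every (parent, pathway, endpoint) combination present in the table,
#' computes the risk probability (percent of derivatives with increased
#' toxicity; percent active for the binary endpoints) and the risk degree
#' (mean increase among the increased; zero when none increased), with the
#' count of derivatives carrying that endpoint.
#'
#' @param derivatives a \code{derivative_table} (see
#'   \code{\link{read_derivative_table}}).
#' @param registry parent registry supplying baselines; defaults to
#'   \code{\link{parent_registry}()}.
#' @param endpoints endpoint ids to profile; default all eleven.
#' @return data.frame: \code{parent_acronym}, \code{pathway_id},
#'   \code{endpoint_id}, \code{probability_pct}, \code{degree},
#'   \code{n_derivatives}. Combinations with no data carry \code{NA}
#'   probability and degree.
#' @export
pathway_risk_profiles <- function(derivatives, registry = parent_registry(),
                                  endpoints = pah_endpoints()$endpoint_id) {
  x <- as.data.frame(derivatives)
  if (!nrow(x)) stop_validation("empty derivative table")
  grp <- interaction(x$parent_acronym, x$pathway_id, drop = TRUE, sep = "\r")
  keys <- do.call(rbind, strsplit(levels(grp), "\r", fixed = TRUE))
  ep <- pah_endpoints()

  out <- vector("list", length(endpoints))
  for (k in seq_along(endpoints)) {
    e <- endpoints[k]
    binary <- ep$kind[ep$endpoint_id == e] == "binary"
    ch <- endpoint_change(x, e, registry)
    by_grp <- split(ch, grp)
    out[[k]] <- data.frame(
      parent_acronym = keys[, 1], pathway_id = keys[, 2], endpoint_id = e,
      probability_pct = vapply(by_grp, risk_probability, numeric(1),
                               binary = binary),
      degree = vapply(by_grp, risk_degree, numeric(1), binary = binary),
      n_derivatives = vapply(by_grp, function(v) sum(!is.na(v)), integer(1)),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out)
  out <- out[order(out$parent_acronym, out$pathway_id,
                   match(out$endpoint_id, ep$endpoint_id)), ]
  rownames(out) <- NULL
  out
}

#' Write risk profiles as long-format TSV
#' @param profiles output of \code{\link{pathway_risk_profiles}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_risk_profiles <- function(profiles, path) {
  write_table_precise(profiles, path, sep = "\t")
}
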