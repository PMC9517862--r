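# Seeded generator of derivative endpoint tables with the statistical
# structure the analysis assumes: per-endpoint increase probabilities,
# heavy-right-tailed (log-normal) increase magnitudes, Beta-distributed
# model probabilities, Bernoulli activity calls, Gaussian logBCF and
# log-normal persistence ratios, with endpoint-independent missingness.
# Every (parent, pathway, endpoint) cell of the ground-truth table records
# the analytic increase probability and mean increase implied by the
# configuration, so parameter recovery by the analysis stages is checkable.

default_p_increase <- function() {
  # neurotoxicity increases for nearly every derivative; immunotoxicity for
  # roughly a third; phytotoxicity for roughly half
  c(neurotoxicity = 0.90, immunotoxicity = 152 / 473,
    phytotoxicity = 222 / 473)
}

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic derivative-table
#' generator. Defaults emulate the study conditions of the 473-derivative
#' screening set: most derivatives more neurotoxic than their parent,
#' roughly one third more immunotoxic (152/473), roughly half more
#' phytotoxic (222/473), about half carcinogenic-active (247/473) and a
#' quarter endocrine-active (123/473); continuous increase magnitudes are
#' log-normal with a heavy right tail (percent increases spanning roughly
#' 0.1 to several hundred percent); decreases are uniform on (0, 40];
#' developmental/genotoxicity probabilities are Beta-distributed;
#' persistence metrics are parent baselines times a log-normal ratio; 1% of
#' endpoint values are missing at random (mirroring structurally
#' unpredictable derivatives such as ring-cleaved products).
#'
#' @param seed integer seed; per-parent substreams are derived from it by a
#'   stable hash of the acronym, so adding a parent does not perturb the
#'   draws of the others.
#' @param parents parent registry (rows with \code{role == "target"} are
#'   used).
#' @param pathways pathway ids to generate.
#' @param n_per_pathway derivatives per (parent, pathway): a single count, a
#'   \code{c(min, max)} range sampled uniformly, or a vector of length
#'   parents x pathways (parent-major order).
#' @param p_increase named per-endpoint probabilities that a derivative's
#'   toxicity increases (continuous binding endpoints).
#' @param increase_meanlog,increase_sdlog log-normal parameters of the
#'   percent-increase magnitude.
#' @param decrease_max upper bound (percent) of the uniform decrease drawn
#'   for non-increased derivatives.
#' @param dev_shape,geno_shape \code{c(shape1, shape2)} Beta parameters of
#'   the developmental / genotoxicity probabilities.
#' @param p_active named Bernoulli rates for carcinogenicity and endocrine
#'   activity.
#' @param logbcf_mean,logbcf_sd Gaussian parameters of derivative logBCF.
#' @param persistence_meanlog,persistence_sdlog log-normal parameters of the
#'   derivative/parent persistence ratio (shared by the three persistence
#'   metrics).
#' @param missing_rate per-endpoint Bernoulli missingness probability.
#' @return validated object of class \code{sim_config}.
#' @examples
#' sim_config(seed = 1, n_per_pathway = 5, pathways = "photolysis")
#' @export
sim_config <- function(seed = 1L,
                       parents = parent_registry(),
                       pathways = pah_pathways(),
                       n_per_pathway = 3L,
                       p_increase = default_p_increase(),
                       increase_meanlog = 3.0, increase_sdlog = 1.0,
                       decrease_max = 40,
                       dev_shape = c(2, 3), geno_shape = c(2, 3),
                       p_active = c(carcinogenicity = 247 / 473,
                                    endocrine = 123 / 473),
                       logbcf_mean = 3.0, logbcf_sd = 0.8,
                       persistence_meanlog = -0.05,
                       persistence_sdlog = 0.4,
                       missing_rate = 0.01) {
  parents <- parents[parents$role == "target", , drop = FALSE]
  if (!nrow(parents)) stop_validation("config error: no target parents")
  bad_pw <- setdiff(pathways, pah_pathways())
  if (length(bad_pw))
    stop_validation("config error: unknown pathway_id: ",
                    paste(bad_pw, collapse = ", "))
  need <- names(default_p_increase())
  if (!all(need %in% names(p_increase)))
    stop_validation("config error: p_increase must name ",
                    paste(need, collapse = ", "))
  probs <- c(p_increase, p_active, missing_rate = missing_rate)
  if (any(probs < 0 | probs > 1))
    stop_validation("config error: probability outside [0, 1] in '",
                    names(probs)[which(probs < 0 | probs > 1)[1]], "'")
  if (increase_sdlog <= 0 || persistence_sdlog <= 0 || logbcf_sd <= 0 ||
      decrease_max <= 0)
    stop_validation("config error: scales must be positive")
  if (any(c(dev_shape, geno_shape) <= 0))
    stop_validation("config error: Beta shapes must be positive")
  seed <- as.integer(seed)

  n_cells <- nrow(parents) * length(pathways)
  n <- n_per_pathway
  if (length(n) == 1L) n <- rep(as.integer(n), n_cells)
  else if (length(n) == 2L && n[1] < n[2]) n <- as.integer(n)  # range
  else if (length(n) == n_cells) n <- as.integer(n)
  else stop_validation("config error: n_per_pathway must be a count, a ",
                       "c(min, max) range, or one count per cell")

  structure(list(
    seed = seed, parents = parents, pathways = pathways, n_cells = n,
    p_increase = p_increase[need],
    increase_meanlog = increase_meanlog, increase_sdlog = increase_sdlog,
    decrease_max = decrease_max, dev_shape = dev_shape,
    geno_shape = geno_shape, p_active = p_active,
    logbcf_mean = logbcf_mean, logbcf_sd = logbcf_sd,
    persistence_meanlog = persistence_meanlog,
    persistence_sdlog = persistence_sdlog,
    missing_rate = missing_rate
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic derivative-table configuration\n")
  cat(sprintf("  seed %d; %d parents x %d pathways\n", x$seed,
              nrow(x$parents), length(x$pathways)))
  n_total <- if (length(x$n_cells) == 2L) "range-sampled" else
    format(sum(x$n_cells))
  cat(sprintf("  derivatives: %s total\n", n_total))
  cat(sprintf("  p_increase: %s\n",
              paste(sprintf("%s=%.3f", names(x$p_increase), x$p_increase),
                    collapse = ", ")))
  cat(sprintf("  p_active: %s; missing_rate %.3f\n",
              paste(sprintf("%s=%.3f", names(x$p_active), x$p_active),
                    collapse = ", "), x$missing_rate))
  invisible(x)
}

#' Study-condition preset
#'
#' The configuration used throughout the package's own checks: the 16
#' priority parents, all 11 pathways, 473 derivatives in total (the cells of
#' the parent-by-pathway grid receive 3 or 2 derivatives in fixed order),
#' and the per-endpoint rates documented in \code{\link{sim_config}}.
#'
#' @param seed integer seed.
#' @param n_per_pathway override the 473-total allocation with an explicit
#'   per-cell count (used for large-n parameter-recovery runs).
#' @return \code{sim_config} object.
#' @export
preset_paperlike <- function(seed = 2022L, n_per_pathway = NULL) {
  parents <- parent_registry()
  pathways <- pah_pathways()
  if (is.null(n_per_pathway)) {
    n_cells <- nrow(parents) * length(pathways)        # 176
    base <- 473 %/% n_cells                            # 2
    extra <- 473 %% n_cells                            # 121 cells get +1
    n_per_pathway <- rep(base, n_cells) +
      c(rep(1L, extra), rep(0L, n_cells - extra))
  }
  sim_config(seed = seed, parents = parents, pathways = pathways,
             n_per_pathway = n_per_pathway)
}

# analytic ground truth per endpoint for one parent
truth_rows <- function(cfg, parent_row) {
  ml <- cfg$increase_meanlog; sl <- cfg$increase_sdlog
  mean_incr <- exp(ml + sl^2 / 2)
  beta_truth <- function(p0, sh) {
    p <- 1 - stats::pbeta(p0, sh[1], sh[2])
    if (p == 0) return(c(p = 0, deg = 0))
    e_tail <- sh[1] / (sh[1] + sh[2]) *
      (1 - stats::pbeta(p0, sh[1] + 1, sh[2]))
    c(p = p, deg = e_tail / p - p0)
  }
  dev <- beta_truth(parent_row$dev_prob, cfg$dev_shape)
  geno <- beta_truth(parent_row$geno_prob, cfg$geno_shape)
  pm <- cfg$persistence_meanlog; ps <- cfg$persistence_sdlog
  p_pers <- stats::pnorm(pm / ps)
  deg_pers <- 100 * (exp(pm + ps^2 / 2) * stats::pnorm((pm + ps^2) / ps) /
                       p_pers - 1)
  z <- (parent_row$logbcf - cfg$logbcf_mean) / cfg$logbcf_sd
  p_bcf <- 1 - stats::pnorm(z)
  e_bcf <- cfg$logbcf_mean + cfg$logbcf_sd * stats::dnorm(z) / p_bcf
  deg_bcf <- 100 * (e_bcf - parent_row$logbcf) / parent_row$logbcf

  data.frame(
    endpoint_id = c(names(cfg$p_increase), "developmental", "genotoxicity",
                    names(cfg$p_active), "logBCF", "half_life",
                    "persistence", "air_half_life"),
    p_increase_true = c(unname(cfg$p_increase) * 100, dev["p"] * 100,
                        geno["p"] * 100, unname(cfg$p_active) * 100,
                        p_bcf * 100, rep(p_pers * 100, 3)),
    degree_true = c(rep(mean_incr, 3), dev["deg"], geno["deg"],
                    unname(cfg$p_active), deg_bcf, rep(deg_pers, 3)),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic derivative table
#'
#' Draws a schema-valid derivative endpoint table under a
#' \code{\link{sim_config}}, together with the analytic ground-truth table
#' of per-(parent, pathway, endpoint) increase probabilities and mean
#' increases implied by the configuration. Derivative ids follow the
#' \code{PARENT-k} convention. Fully deterministic given the seed.
#'
#' @param config a \code{sim_config}.
#' @return \code{list(derivatives, ground_truth)}; \code{derivatives} is a
#'   validated \code{derivative_table}.
#' @examples
#' sim <- simulate_derivatives(sim_config(seed = 42, n_per_pathway = 2))
#' nrow(sim$derivatives)
#' @export
simulate_derivatives <- function(config) {
  if (!inherits(config, "sim_config"))
    stop_validation("config must be a sim_config object")
  cfg <- config
  parents <- cfg$parents
  n_pw <- length(cfg$pathways)
  ranged <- length(cfg$n_cells) == 2L

  tabs <- vector("list", nrow(parents))
  truths <- vector("list", nrow(parents))
  for (i in seq_len(nrow(parents))) {
    pr <- parents[i, ]
    set.seed((cfg$seed + stable_hash(pr$acronym)) %% 2147483647L)
    n_i <- if (ranged)
      sample(cfg$n_cells[1]:cfg$n_cells[2], n_pw, replace = TRUE)
    else cfg$n_cells[(i - 1) * n_pw + seq_len(n_pw)]
    n_tot <- sum(n_i)
    pathway <- rep(cfg$pathways, times = n_i)

    draw_dg <- function(endpoint, baseline) {
      p <- cfg$p_increase[[endpoint]]
      up <- stats::runif(n_tot) < p
      pct <- ifelse(up,
                    stats::rlnorm(n_tot, cfg$increase_meanlog,
                                  cfg$increase_sdlog),
                    -stats::runif(n_tot, 0, cfg$decrease_max))
      -abs(baseline) * (1 + pct / 100)
    }
    d <- data.frame(
      derivative_id = paste0(pr$acronym, "-", seq_len(n_tot)),
      parent_acronym = pr$acronym,
      pathway_id = pathway,
      neuro_dg_kjmol = draw_dg("neurotoxicity", pr$neuro_dg_kjmol),
      immuno_dg_kjmol = draw_dg("immunotoxicity", pr$immuno_dg_kjmol),
      phyto_dg_kjmol = draw_dg("phytotoxicity", pr$phyto_dg_kjmol),
      dev_prob = stats::rbeta(n_tot, cfg$dev_shape[1], cfg$dev_shape[2]),
      geno_prob = stats::rbeta(n_tot, cfg$geno_shape[1], cfg$geno_shape[2]),
      carc_active = as.integer(stats::runif(n_tot) <
                                 cfg$p_active[["carcinogenicity"]]),
      endo_active = as.integer(stats::runif(n_tot) <
                                 cfg$p_active[["endocrine"]]),
      logbcf = stats::rnorm(n_tot, cfg$logbcf_mean, cfg$logbcf_sd),
      half_life = pr$half_life *
        stats::rlnorm(n_tot, cfg$persistence_meanlog, cfg$persistence_sdlog),
      persistence = pr$persistence *
        stats::rlnorm(n_tot, cfg$persistence_meanlog, cfg$persistence_sdlog),
      air_half_life = pr$air_half_life *
        stats::rlnorm(n_tot, cfg$persistence_meanlog, cfg$persistence_sdlog),
      stringsAsFactors = FALSE
    )
    if (cfg$missing_rate > 0) {
      ep_cols <- c(mandatory_columns()[-(1:3)], optional_columns())
      for (col in ep_cols)
        d[[col]][stats::runif(n_tot) < cfg$missing_rate] <- NA
    }
    tabs[[i]] <- d
    tr <- truth_rows(cfg, pr)
    truths[[i]] <- do.call(rbind, lapply(cfg$pathways, function(pw) {
      out <- tr
      out$parent_acronym <- pr$acronym
      out$pathway_id <- pw
      out
    }))
  }
  derivatives <- do.call(rbind, tabs)
  ground_truth <- do.call(rbind, truths)
  ground_truth <- ground_truth[, c("parent_acronym", "pathway_id",
                                   "endpoint_id", "p_increase_true",
                                   "degree_true")]
  rownames(derivatives) <- rownames(ground_truth) <- NULL
  list(derivatives = as_derivative_table(derivatives, registry = parents),
       ground_truth = ground_truth)
}
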