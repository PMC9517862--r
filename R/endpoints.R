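#' Endpoint vocabulary
#'
#' The eleven toxicity and environmental-behaviour endpoints carried per
#' derivative. The three receptor-binding endpoints (neurotoxicity via AHR,
#' immunotoxicity via p53, phytotoxicity via plant peroxidase) are continuous
#' binding free energies in kJ/mol and are always negative, with more
#' negative meaning stronger binding and hence higher predicted toxicity.
#' Developmental toxicity and genotoxicity are model probabilities in
#' \eqn{[0,1]}; carcinogenicity and endocrine disruption are binary activity
#' calls; logBCF is a log10 bioconcentration factor; the three persistence
#' metrics are positive times in whatever consistent unit the table uses.
#'
#' @return A data.frame with columns \code{endpoint_id}, \code{kind}
#'   (continuous/probability/binary), \code{scale} (free_energy, probability,
#'   binary, log10, time), \code{column} (the derivative-table column name),
#'   and \code{factor_group} (\code{A} environmental risk, \code{B} human
#'   health, \code{C} environmental behaviour).
#' @examples
#' pah_endpoints()
#' @export
pah_endpoints <- function() {
  data.frame(
    endpoint_id = c("neurotoxicity", "immunotoxicity", "phytotoxicity",
                    "developmental", "genotoxicity", "carcinogenicity",
                    "endocrine", "logBCF", "half_life", "persistence",
                    "air_half_life"),
    kind = c("continuous", "continuous", "continuous",
             "probability", "probability", "binary", "binary",
             "continuous", "continuous", "continuous", "continuous"),
    scale = c("free_energy", "free_energy", "free_energy",
              "probability", "probability", "binary", "binary",
              "log10", "time", "time", "time"),
    column = c("neuro_dg_kjmol", "immuno_dg_kjmol", "phyto_dg_kjmol",
               "dev_prob", "geno_prob", "carc_active", "endo_active",
               "logbcf", "half_life", "persistence", "air_half_life"),
    factor_group = c("B", "B", "A", "B", "B", "B", "B", "C", "C", "C", "C"),
    stringsAsFactors = FALSE
  )
}

#' Pathway vocabulary
#'
#' Controlled vocabulary of the metabolism and environmental transformation
#' routes along which PAH derivatives form.
#'
#' @return Character vector of canonical pathway identifiers.
#' @examples
#' pah_pathways()
#' @export
pah_pathways <- function() {
  c("photolysis", "photocatalytic_degradation", "bacterial_degradation",
    "fungal_degradation", "microalgae_degradation", "aerobic_degradation",
    "plant_degradation", "human_metabolism", "rat_metabolism",
    "mouse_metabolism", "fish_metabolism")
}

endpoint_info <- function(id) {
  ep <- pah_endpoints()
  ep[match(id, ep$endpoint_id), , drop = FALSE]
}

mandatory_columns <- function() {
  c("derivative_id", "parent_acronym", "pathway_id",
    "neuro_dg_kjmol", "immuno_dg_kjmol", "phyto_dg_kjmol",
    "dev_prob", "geno_prob", "carc_active", "endo_active")
}

optional_columns <- function() {
  c("logbcf", "half_life", "persistence", "air_half_life")
}
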