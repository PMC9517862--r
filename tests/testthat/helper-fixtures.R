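# in-code fixture builders

# one fully-populated derivative row; override any column
make_row <- function(derivative_id = "BaP-1", parent_acronym = "BaP",
                     pathway_id = "photolysis", neuro_dg_kjmol = -80,
                     immuno_dg_kjmol = -100, phyto_dg_kjmol = -110,
                     dev_prob = 0.5, geno_prob = 0.4, carc_active = 1,
                     endo_active = 0, logbcf = 3.5, half_life = 1100,
                     persistence = 120, air_half_life = 12) {
  data.frame(derivative_id = derivative_id, parent_acronym = parent_acronym,
             pathway_id = pathway_id, neuro_dg_kjmol = neuro_dg_kjmol,
             immuno_dg_kjmol = immuno_dg_kjmol,
             phyto_dg_kjmol = phyto_dg_kjmol, dev_prob = dev_prob,
             geno_prob = geno_prob, carc_active = carc_active,
             endo_active = endo_active, logbcf = logbcf,
             half_life = half_life, persistence = persistence,
             air_half_life = air_half_life, stringsAsFactors = FALSE)
}

make_table <- function(n = 2, ...) {
  rows <- lapply(seq_len(n), function(i) make_row(
    derivative_id = paste0("BaP-", i), ...))
  do.call(rbind, rows)
}

# a table where every factor scores zero against the default registry:
# all toxicities decreased, low probabilities, inactive, logBCF < 2,
# persistence decreased
make_zero_risk_table <- function(parents = c("BaP", "NAP"),
                                 pathways = c("photolysis",
                                              "human_metabolism")) {
  reg <- parent_registry()
  rows <- list()
  k <- 0
  for (p in parents) for (pw in pathways) for (i in 1:2) {
    k <- k + 1
    b <- reg[reg$acronym == p, ]
    rows[[k]] <- make_row(
      derivative_id = paste0(p, "-", i, "-", pw),
      parent_acronym = p, pathway_id = pw,
      neuro_dg_kjmol = b$neuro_dg_kjmol * 0.9,
      immuno_dg_kjmol = b$immuno_dg_kjmol * 0.9,
      phyto_dg_kjmol = b$phyto_dg_kjmol * 0.9,
      dev_prob = 0.1, geno_prob = 0.1, carc_active = 0, endo_active = 0,
      logbcf = 1.5, half_life = b$half_life * 0.8,
      persistence = b$persistence * 0.8,
      air_half_life = b$air_half_life * 0.8)
  }
  do.call(rbind, rows)
}

# random rubric-valid factor-score vector
random_scores <- function() {
  list(a_i = sample(0:2, 1),
       b_ij = c(sample(0:2, 4, replace = TRUE),
                sample(0:1, 2, replace = TRUE)),
       c_ij = sample(0:2, 4, replace = TRUE))
}
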