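test_that("the increase rubric bins percent changes at 0, 50", {
  expect_equal(score_continuous_increase(c(-12.3, 0, 25, 50, 50.0001, 64.92)),
               c(0L, 0L, 1L, 1L, 2L, 2L))
  expect_error(score_continuous_increase(NaN), "finite")
})

test_that("the probability rubric bins at 0.30 and 0.70, boundaries medium", {
  expect_equal(score_probability(c(0.10, 0.2999, 0.30, 0.50, 0.70, 0.7001,
                                   0.85, 1)),
               c(0L, 0L, 1L, 1L, 1L, 2L, 2L, 2L))
  expect_error(score_probability(1.1), "\\[0, 1\\]")
})

test_that("binary scoring is the identity on activity calls and idempotent", {
  expect_equal(score_binary(c(0, 1, 1)), c(0L, 1L, 1L))
  expect_equal(score_binary(score_binary(c(0, 1))), c(0L, 1L))
  expect_error(score_binary(0.5), "0 or 1")
})

test_that("logBCF scoring uses the 2.0 / 3.0 thresholds", {
  expect_equal(score_bcf(c(1.5, 1.9999, 2.0, 2.5, 2.9999, 3.0, 4.2)),
               c(0L, 0L, 1L, 1L, 1L, 2L, 2L))
})

test_that("every scoring function is monotone non-decreasing", {
  set.seed(31)
  checks <- list(
    list(f = score_continuous_increase, x = sort(runif(200, -200, 200))),
    list(f = score_probability, x = sort(runif(200))),
    list(f = score_bcf, x = sort(runif(200, 0, 5))),
    list(f = score_binary, x = sort(sample(0:1, 50, replace = TRUE)))
  )
  for (ck in checks)
    expect_true(all(diff(ck$f(ck$x)) >= 0))
})

test_that("pathway factor scores aggregate componentwise", {
  reg <- parent_registry()
  b <- reg[reg$acronym == "BaP", ]
  tab <- rbind(
    make_row("BaP-1", neuro_dg_kjmol = b$neuro_dg_kjmol * 1.2),  # +20 -> 1
    make_row("BaP-2", neuro_dg_kjmol = b$neuro_dg_kjmol * 1.8)   # +80 -> 2
  )
  s_max <- score_pathway(tab, reg, aggregation = "max")
  expect_equal(unname(s_max$b_ij["neurotoxicity"]), 2)
  s_mean <- score_pathway(tab, reg, aggregation = "mean")
  expect_equal(unname(s_mean$b_ij["neurotoxicity"]), 1.5)
  expect_equal(s_max$n_derivatives, 2)
})

test_that("max aggregation is invariant to order and duplication", {
  set.seed(13)
  sim <- simulate_derivatives(sim_config(seed = 13, n_per_pathway = 5,
                                         pathways = "photolysis"))
  x <- as.data.frame(sim$derivatives)
  one <- x[x$parent_acronym == "PHE", ]
  reg <- parent_registry()
  base <- score_pathway(one, reg)
  shuf <- score_pathway(one[sample(nrow(one)), ], reg)
  dup <- score_pathway(rbind(one, transform(one,
           derivative_id = paste0(derivative_id, "-dup"))), reg)
  for (comp in c("a_i", "b_ij", "c_ij")) {
    expect_equal(shuf[[comp]], base[[comp]])
    expect_equal(dup[[comp]], base[[comp]])
  }
})

test_that("factor scores stay within the rubric ranges", {
  for (seed in 1:4) {
    sim <- simulate_derivatives(sim_config(seed = seed, n_per_pathway = 6,
                                           pathways = c("photolysis",
                                                        "rat_metabolism")))
    x <- as.data.frame(sim$derivatives)
    grp <- split(x, paste(x$parent_acronym, x$pathway_id))
    for (g in grp) {
      s <- score_pathway(g, parent_registry())
      expect_true(s$a_i >= 0 && s$a_i <= 2)
      expect_true(sum(s$b_ij) >= 0 && sum(s$b_ij) <= 10)
      expect_true(all(s$b_ij[c("carcinogenicity", "endocrine")] <= 1))
      expect_true(sum(s$c_ij) >= 0 && sum(s$c_ij) <= 8)
    }
  }
})

test_that("endpoints missing from every derivative contribute score zero", {
  tab <- make_table(2)
  tab$logbcf <- NA
  tab$half_life <- NA
  s <- score_pathway(tab, parent_registry())
  expect_equal(unname(s$c_ij["logBCF"]), 0)
  expect_equal(unname(s$c_ij["half_life"]), 0)
  expect_error(score_pathway(tab[0, ], parent_registry()), "empty")
})
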