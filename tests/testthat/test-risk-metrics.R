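test_that("percent change on binding energies follows the magnitude rule", {
  expect_equal(percent_change_continuous(-70.481, -70.481), 0)
  expect_equal(percent_change_continuous(-100, -50), -50)
  # the strongest BaP derivative increase reported for neurotoxicity
  expect_equal(percent_change_continuous(-70.481, -116.237), 64.92,
               tolerance = 0.01 / 64.92)
  expect_error(percent_change_continuous(0, -50), "undefined")
  expect_error(percent_change_continuous(-50, 10), "negative")
  expect_error(percent_change_continuous(-50, Inf), "finite")
})

test_that("percent change is invariant to a common unit rescaling", {
  set.seed(41)
  for (i in 1:25) {
    p <- -runif(1, 20, 120); d <- -runif(1, 20, 120)
    k <- runif(1, 0.1, 10)
    expect_equal(percent_change_continuous(p * k, d * k),
                 percent_change_continuous(p, d), tolerance = 1e-12)
  }
})

test_that("probability-scale change is plain subtraction over the grid", {
  expect_equal(change_probabilistic(0.5, 0.5), 0)
  expect_equal(change_probabilistic(0.70, 0.72), 0.02)
  grid <- expand.grid(p = seq(0, 1, 0.1), d = seq(0, 1, 0.1))
  got <- mapply(change_probabilistic, grid$p, grid$d)
  expect_equal(got, grid$d - grid$p)
  expect_error(change_probabilistic(0.5, 1.2), "\\[0, 1\\]")
})

test_that("risk probability counts increases, with NA for no data", {
  expect_equal(risk_probability(c(10, -5)), 50)      # 1 of 2 increased
  expect_equal(risk_probability(c(-1, -2, -3)), 0)
  expect_equal(risk_probability(numeric(0)), NA_real_)
  expect_equal(risk_probability(c(NA, NA)), NA_real_)
  expect_equal(risk_probability(c(1, 1, 0, 1), binary = TRUE), 75)
  # ties (zero change) count as not increased
  expect_equal(risk_probability(c(0, 0, 5)), 100 / 3)
})

test_that("risk degree is the filtered mean with the zero-default", {
  expect_equal(risk_degree(c(10, 30, -80)), 20)
  expect_equal(risk_degree(c(-10, -30)), 0)
  expect_equal(risk_degree(numeric(0)), NA_real_)
})

test_that("probability and degree agree with brute-force counting on random multisets", {
  set.seed(99)
  for (i in 1:50) {
    ch <- round(runif(sample(1:40, 1), -100, 300), 1)
    n_up <- 0; s_up <- 0
    for (v in ch) if (v > 0) { n_up <- n_up + 1; s_up <- s_up + v }
    expect_equal(risk_probability(ch), 100 * n_up / length(ch))
    expect_equal(risk_degree(ch), if (n_up) s_up / n_up else 0)
    perm <- sample(ch)
    expect_equal(risk_probability(perm), risk_probability(ch))
    expect_equal(risk_degree(perm), risk_degree(ch))
  }
})

test_that("zero probability and zero degree imply each other", {
  set.seed(7)
  for (i in 1:60) {
    ch <- runif(sample(1:20, 1), -100, 100)
    if (i %% 3 == 0) ch <- -abs(ch)
    p <- risk_probability(ch); d <- risk_degree(ch)
    expect_equal(p == 0, d == 0)
  }
})

test_that("pathway profiles aggregate per (parent, pathway, endpoint)", {
  reg <- parent_registry()
  b <- reg[reg$acronym == "BaP", ]
  tab <- rbind(
    make_row("BaP-1", neuro_dg_kjmol = b$neuro_dg_kjmol * 1.2),  # +20%
    make_row("BaP-2", neuro_dg_kjmol = b$neuro_dg_kjmol * 0.8),  # -20%
    make_row("BaP-3", neuro_dg_kjmol = NA)                       # missing
  )
  prof <- pathway_risk_profiles(as_derivative_table(tab), reg)
  neuro <- prof[prof$endpoint_id == "neurotoxicity", ]
  expect_equal(neuro$n_derivatives, 2)
  expect_equal(neuro$probability_pct, 50)
  expect_equal(neuro$degree, 20, tolerance = 1e-9)
  carc <- prof[prof$endpoint_id == "carcinogenicity", ]
  expect_equal(carc$probability_pct, 100)   # all rows active
  expect_equal(carc$degree, 1)
})

test_that("profiles report NA probability when an endpoint is absent everywhere", {
  tab <- make_table(2)
  tab$logbcf <- NA
  prof <- pathway_risk_profiles(as_derivative_table(tab))
  lb <- prof[prof$endpoint_id == "logBCF", ]
  expect_equal(lb$n_derivatives, 0)
  expect_true(is.na(lb$probability_pct))
})
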