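test_that("RA follows the fixed-denominator formula", {
  zero <- compute_ra(list(a_i = 0, b_ij = rep(0, 6), c_ij = rep(0, 4)))
  expect_equal(zero$RA, 0)
  maximal <- compute_ra(list(a_i = 2, b_ij = c(2, 2, 2, 2, 1, 1),
                             c_ij = rep(2, 4)))
  expect_equal(maximal$RA, 2 + 10 / 6 + 8 / 4, tolerance = 1e-9)
  mixed <- compute_ra(list(a_i = 1, b_ij = c(1, 0, 2, 0, 1, 0),
                           c_ij = c(1, 1, 0, 0)))
  expect_equal(mixed$RA, 1 + 4 / 6 + 2 / 4, tolerance = 1e-9)
  expect_equal(unname(mixed$components), c(1, 4 / 6, 2 / 4),
               tolerance = 1e-12)
  expect_error(compute_ra(list(a_i = 1, b_ij = rep(1, 5),
                               c_ij = rep(1, 4))), "6 b")
})

test_that("RA equals the sum of its components and stays in bounds", {
  set.seed(21)
  for (i in 1:200) {
    s <- random_scores()
    ra <- compute_ra(s)
    expect_equal(ra$RA, sum(ra$components), tolerance = 1e-9)
    expect_true(ra$RA >= 0 && ra$RA <= 2 + 10 / 6 + 8 / 4 + 1e-9)
  }
})

test_that("parent totals fold pathway RA values per mode", {
  mk <- function(ra, pw) structure(list(parent_acronym = "BaP",
    pathway_id = pw, RA = ra, components = c(A = ra, B = 0, C = 0),
    rank = NA, high_risk = NA), class = "risk_assessment")
  one <- list(mk(1.7, "photolysis"))
  for (m in c("sum", "mean", "max"))
    expect_equal(total_parent_risk(one, m)$RA, 1.7)
  two <- list(mk(1, "photolysis"), mk(2, "human_metabolism"))
  expect_equal(total_parent_risk(two, "sum")$RA, 3)
  expect_equal(total_parent_risk(two, "mean")$RA, 1.5)
  expect_equal(total_parent_risk(two, "max")$RA, 2)
  set.seed(4)
  ras <- runif(9, 0, 5)
  expect_equal(total_parent_risk(ras, "sum")$RA, sum(ras))
  expect_equal(total_parent_risk(ras, "mean")$RA, mean(ras))
  expect_equal(total_parent_risk(ras, "max")$RA, max(ras))
  expect_error(total_parent_risk(list()), "no pathway")
})

test_that("parents rank descending with deterministic lexicographic ties", {
  r <- rank_parents(c(BaP = 3, DahA = 1))
  expect_equal(r$parent_acronym, c("BaP", "DahA"))
  expect_equal(r$rank, 1:2)
  tied <- rank_parents(c(PYR = 2, ACE = 2, NAP = 2))
  expect_equal(tied$parent_acronym, c("ACE", "NAP", "PYR"))
  expect_true(all(tied$tied))
  set.seed(8)
  vals <- stats::setNames(runif(16), parent_registry()$acronym)
  r2 <- rank_parents(vals)
  expect_equal(r2$parent_acronym,
               names(sort(vals, decreasing = TRUE)))
  expect_equal(rank_parents(r2[, c("parent_acronym", "RA")]),
               r2[, c("parent_acronym", "RA", "rank", "tied")])
  expect_error(rank_parents(data.frame(parent_acronym = c("BaP", "BaP"),
                                       RA = 1:2)), "duplicate")
})

test_that("high-risk classification takes the ceiling of the top fraction", {
  expect_equal(sum(classify_high_risk(10:1, 0.30)), 3)
  expect_equal(classify_high_risk(5), TRUE)           # single entry
  expect_equal(sum(classify_high_risk(c(1, 2), 0.30)), 1)  # ceiling(0.6)
  # ties at the cutoff are all flagged
  expect_equal(classify_high_risk(c(3, 2, 2, 2, 1, 0.5, 0.2, 0.1, 0.1, 0),
                                  0.30),
               c(TRUE, TRUE, TRUE, TRUE, rep(FALSE, 6)))
  # zero RA is never a risk
  expect_false(any(classify_high_risk(rep(0, 5), 0.30)))
  expect_error(classify_high_risk(1:3, 0), "fraction")
  expect_error(classify_high_risk(1:3, 1.2), "fraction")
})

test_that("flags match brute-force threshold selection and ignore order", {
  set.seed(12)
  for (i in 1:30) {
    ra <- round(runif(sample(3:25, 1), 0, 5), 2)
    k <- ceiling(0.3 * length(ra))
    thr <- sort(ra, decreasing = TRUE)[k]
    brute <- vapply(ra, function(v) v >= thr && v > 0, logical(1))
    expect_equal(classify_high_risk(ra, 0.3), brute)
    perm <- sample(seq_along(ra))
    expect_equal(classify_high_risk(ra[perm], 0.3), brute[perm])
  }
})

test_that("increasing any single factor never decreases RA", {
  set.seed(55)
  for (i in 1:300) {
    s <- random_scores()
    ra0 <- compute_ra(s)$RA
    comp <- sample(c("a_i", "b_ij", "c_ij"), 1)
    j <- sample(length(s[[comp]]), 1)
    cap <- if (comp == "b_ij" && j >= 5) 1 else 2
    s2 <- s
    s2[[comp]][j] <- min(cap, s[[comp]][j] + sample(1:2, 1))
    expect_true(compute_ra(s2)$RA >= ra0 - 1e-12)
  }
})
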