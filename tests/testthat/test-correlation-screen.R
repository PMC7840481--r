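test_that("spearman recovers exact and hand-computed values", {
  # perfect monotone association
  expect_equal(spearman(1:10, (1:10)^3)$rho, 1)
  # tie-free case against the 1 - 6*sum(d^2)/(n(n^2-1)) formula
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  s <- spearman(x, y)
  d <- rank(x) - rank(y)
  expect_equal(s$rho, 1 - 6 * sum(d^2) / (5 * 24))  # = 0.8
  expect_equal(s$rho, oracle_spearman(x, y))
  # t-approximation p-value
  tstat <- s$rho * sqrt(3 / (1 - s$rho^2))
  expect_equal(s$p, 2 * pt(-abs(tstat), df = 3))
})

test_that("ties are handled by mid-ranks, matching the oracle", {
  x <- c(1, 2, 2, 3, 4, 4, 4, 5)
  y <- c(3, 1, 4, 4, 2, 6, 5, 7)
  expect_equal(spearman(x, y)$rho, oracle_spearman(x, y))
  # constant vector: undefined, flagged as NA
  expect_true(is.na(spearman(rep(1, 6), 1:6)$rho))
})

test_that("spearman is invariant under strictly increasing transforms", {
  set.seed(12)
  x <- rnorm(30); y <- rnorm(30)
  base <- spearman(x, y)$rho
  expect_equal(spearman(exp(x), y)$rho, base)
  expect_equal(spearman(x, rank(y))$rho, base)
  expect_equal(spearman(x^3, exp(y))$rho, base)
})

make_screen_fixture <- function(seed = 13, n_per_group = 10,
                                n_mirna = 20, n_nc = 3,
                                planted = list()) {
  sim <- small_sim(seed = seed, n_per_group = n_per_group,
                   n_mirna = n_mirna, n_nc = n_nc, planted = planted)
  list(sim = sim, cm = size_factors(sim$counts))
}

test_that("screen enumerates all pairs and the coherence rule is a sign rule", {
  fx <- make_screen_fixture()
  rec <- screen_correlations(fx$cm, fx$sim$intake, fx$sim$metadata)
  expect_equal(nrow(rec) + nrow(attr(rec, "dropped_pairs")), 20 * 3)
  rho_mat <- as.matrix(rec[paste0("rho_", c("omnivore", "vegetarian",
                                            "vegan"))])
  expect_identical(rec$coherent,
                   apply(rho_mat, 1, function(r) all(r > 0) || all(r < 0)))
  # significant implies coherent
  expect_true(all(!rec$significant | rec$coherent))
  # sign clash can never be significant
  clash <- apply(rho_mat, 1, function(r) length(unique(sign(r))) > 1)
  expect_true(all(!rec$significant[clash]))
})

test_that("screen output is invariant to subject order within groups", {
  fx <- make_screen_fixture(seed = 14)
  rec1 <- screen_correlations(fx$cm, fx$sim$intake, fx$sim$metadata)
  perm <- sample(ncol(fx$cm$counts))
  cm2 <- fx$cm
  cm2$counts <- cm2$counts[, perm]
  cm2$normalized <- cm2$normalized[, perm]
  cm2$size_factors <- cm2$size_factors[perm]
  rec2 <- screen_correlations(cm2, fx$sim$intake, fx$sim$metadata)
  expect_equal(rec2, rec1, ignore_attr = TRUE)
})

test_that("small groups are rejected by name", {
  fx <- make_screen_fixture(seed = 15)
  meta <- fx$sim$metadata
  vegan_ids <- meta$subject_id[meta$diet_group == "vegan"]
  keep <- setdiff(meta$subject_id, vegan_ids[-(1:3)])
  cm2 <- fx$cm
  cm2$counts <- cm2$counts[, keep]
  cm2$normalized <- cm2$normalized[, keep]
  cm2$size_factors <- cm2$size_factors[keep]
  expect_error(
    screen_correlations(cm2, fx$sim$intake, meta),
    "vegan"
  )
})

test_that("planted pairs are recovered; near-null strengths are not flagged", {
  planted <- list(planted_effect("mir001", "cholesterol", 0.5),
                  planted_effect("mir002", "linoleic_acid", -0.5))
  hits <- 0; weak_hits <- 0; n_rep <- 5
  for (i in seq_len(n_rep)) {
    fx <- make_screen_fixture(seed = 100 + i, n_per_group = 40,
                              planted = planted)
    rec <- screen_correlations(fx$cm, fx$sim$intake, fx$sim$metadata)
    key <- paste(rec$mirna_id, rec$nc_id)
    hits <- hits + sum(rec$significant[key %in%
      c("mir001 cholesterol", "mir002 linoleic_acid")])
  }
  expect_gte(hits / (2 * n_rep), 0.9)

  weak <- list(planted_effect("mir001", "cholesterol", 0.15))
  for (i in seq_len(n_rep)) {
    fx <- make_screen_fixture(seed = 200 + i, n_per_group = 40,
                              planted = weak)
    rec <- screen_correlations(fx$cm, fx$sim$intake, fx$sim$metadata)
    weak_hits <- weak_hits + rec$significant[
      rec$mirna_id == "mir001" & rec$nc_id == "cholesterol"]
  }
  expect_lt(weak_hits / n_rep, 0.5)
})

test_that("trend classification demands strict monotonicity in |rho|", {
  expect_equal(classify_trend(c(0.20, 0.30, 0.45)), "increasing")
  expect_equal(classify_trend(c(-0.20, -0.30, -0.45)), "increasing")
  expect_equal(classify_trend(c(0.50, 0.30, 0.10)), "decreasing")
  expect_equal(classify_trend(c(0.40, 0.40, 0.45)), "none")
  expect_equal(classify_trend(c(0.40, 0.60, 0.45)), "none")
  expect_error(classify_trend(c(0.1, NA, 0.3)), "missing")
  # randomized records against a pairwise-comparison oracle
  set.seed(16)
  m <- matrix(runif(300, -1, 1), ncol = 3)
  got <- classify_trend(m)
  oracle <- apply(abs(m), 1, function(a) {
    if (a[1] < a[2] && a[2] < a[3]) "increasing"
    else if (a[1] > a[2] && a[2] > a[3]) "decreasing"
    else "none"
  })
  expect_identical(got, oracle)
})

test_that("cohort checks behave on planted compositions", {
  set.seed(17)
  n <- 40
  meta <- data.frame(
    subject_id = paste0("S", 1:(3 * n)),
    diet_group = rep(c("omnivore", "vegetarian", "vegan"), each = n),
    sex = rep(rep(c("F", "M"), c(24, 16)), 3),  # identical compositions
    age = rnorm(3 * n, 45, 10),
    bmi = c(rnorm(n, 28, 2), rnorm(n, 23, 2), rnorm(n, 23, 2))
  )
  meta$bmi_class <- derive_bmi_class(meta$bmi)
  ck <- cohort_checks(meta)
  expect_gt(ck$sex_chisq$p, 0.99)  # no association by construction
  # BMI shifted +5 in omnivores: both omnivore contrasts significant
  wil <- ck$bmi_wilcoxon
  omn <- wil$group1 == "omnivore" | wil$group2 == "omnivore"
  expect_true(all(wil$p[omn] < 0.05))
})

test_that("the 2x2 chi-square statistic equals the closed-form oracle", {
  x <- rep(c("A", "B", "A", "B"), c(10, 20, 20, 10))
  g <- rep(c("g1", "g2"), each = 30)
  t <- suppressWarnings(chisq.test(table(x, g)))
  # Yates-corrected closed form: N(|ad-bc| - N/2)^2 / (r1 r2 c1 c2)
  stat <- 60 * (abs(10 * 10 - 20 * 20) - 30)^2 / (30 * 30 * 30 * 30)
  expect_equal(unname(t$statistic), stat)
})
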