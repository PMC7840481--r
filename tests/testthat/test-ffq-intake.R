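test_that("single-item intakes follow the per-100g formula", {
  # 2 consumptions/day x 50 g x 10 units per 100 g = 10 units/day
  ffq <- data.frame(subject_id = "s1", item_id = "a",
                    frequency = 2, portion = 50)
  comp <- data.frame(item_id = "a", energy_kcal = 200, sodium = 10)
  it <- compute_intake(ffq, comp)
  expect_equal(unname(it$raw["s1", "sodium"]), 10)
  expect_equal(unname(it$energy_kcal_day["s1"]), 2 * 50 * 200 / 100)
})

test_that("intakes are additive over items and subjects with no rows get zero", {
  ffq <- data.frame(subject_id = c("s1", "s1"), item_id = c("a", "b"),
                    frequency = c(1, 1), portion = c(100, 100))
  comp <- data.frame(item_id = c("a", "b"), energy_kcal = c(100, 100),
                     iron = c(3, 4))
  it <- compute_intake(ffq, comp)
  expect_equal(unname(it$raw["s1", "iron"]), 7)

  # all frequencies zero -> zero intakes and zero energy
  z <- compute_intake(
    data.frame(subject_id = "s2", item_id = "a", frequency = 0,
               portion = 50),
    comp
  )
  expect_equal(unname(z$raw["s2", "iron"]), 0)
  expect_equal(unname(z$energy_kcal_day["s2"]), 0)
})

test_that("a randomized FFQ matches the brute-force row-by-row oracle", {
  set.seed(17)
  subjects <- paste0("s", 1:6)
  items <- paste0("i", 1:10)
  ffq <- expand.grid(subject_id = subjects, item_id = items,
                     stringsAsFactors = FALSE)
  ffq$frequency <- runif(nrow(ffq), 0, 3)
  ffq$portion <- runif(nrow(ffq), 20, 200)
  comp <- data.frame(item_id = items, energy_kcal = runif(10, 50, 500),
                     sodium = runif(10, 0, 20), iron = runif(10, 0, 5))
  it <- compute_intake(ffq, comp)
  for (s in subjects) {
    rows <- ffq[ffq$subject_id == s, ]
    for (nut in c("sodium", "iron")) {
      manual <- sum(rows$frequency * rows$portion *
                      comp[[nut]][match(rows$item_id, comp$item_id)] / 100)
      expect_equal(unname(it$raw[s, nut]), manual)
    }
  }
})

test_that("bad FFQ input is rejected with informative errors", {
  comp <- data.frame(item_id = "a", energy_kcal = 100, iron = 1)
  expect_error(compute_intake(
    data.frame(subject_id = "s", item_id = "zz", frequency = 1,
               portion = 10), comp), "zz")
  expect_error(compute_intake(
    data.frame(subject_id = "s", item_id = "a", frequency = -1,
               portion = 10), comp), "negative")
  expect_message(compute_intake(
    data.frame(subject_id = "s", item_id = "a", frequency = 1,
               portion = 10),
    data.frame(item_id = "a", energy_kcal = 100, iron = NA)),
    "missing")
})

test_that("kcal normalization is a density per 1,000 kcal", {
  it <- intake_table(matrix(4, 1, 1, dimnames = list("s1", "sodium")),
                     energy_kcal_day = 2000)
  expect_equal(unname(kcal_normalize(it)$normalized["s1", "sodium"]), 2)
})

test_that("scaling all frequencies scales raw intakes and fixes densities", {
  set.seed(23)
  items <- paste0("i", 1:5)
  ffq <- data.frame(subject_id = "s1", item_id = items,
                    frequency = runif(5, 0.1, 2),
                    portion = runif(5, 30, 150))
  comp <- data.frame(item_id = items, energy_kcal = runif(5, 50, 400),
                     zinc = runif(5, 0, 10))
  ffq2 <- ffq; ffq2$frequency <- ffq2$frequency * 3
  a <- kcal_normalize(compute_intake(ffq, comp))
  b <- kcal_normalize(compute_intake(ffq2, comp))
  expect_equal(b$raw, a$raw * 3)
  expect_equal(b$normalized, a$normalized)
})

test_that("merging two questionnaires adds their intakes", {
  comp <- data.frame(item_id = c("a", "b"), energy_kcal = c(100, 200),
                     iron = c(2, 6))
  q1 <- data.frame(subject_id = "s1", item_id = "a", frequency = 1,
                   portion = 100)
  q2 <- data.frame(subject_id = "s1", item_id = "b", frequency = 2,
                   portion = 50)
  merged <- compute_intake(rbind(q1, q2), comp)
  expect_equal(merged$raw, compute_intake(q1, comp)$raw +
                 compute_intake(q2, comp)$raw)
})

test_that("zero-energy subjects are excluded from the normalized table", {
  raw <- matrix(c(1, 2), 2, 1, dimnames = list(c("s1", "s2"), "iron"))
  it <- intake_table(raw, energy_kcal_day = c(2000, 0))
  expect_warning(norm <- kcal_normalize(it), "excluded")
  expect_equal(rownames(norm$normalized), "s1")
  expect_equal(rownames(norm$raw), c("s1", "s2"))  # raw retained
})

test_that("the 23-NC vocabulary is complete and validated", {
  v <- nc_compounds()
  expect_equal(nrow(v), 23)
  expect_equal(sort(unique(v$nc_class)),
               c("lipid-related", "micro-element", "vitamin-related"))
  expect_equal(unname(nc_classes()["sodium"]), "micro-element")
  expect_equal(unname(nc_classes()["vitamin_d"]), "vitamin-related")
  expect_error(nutrimir:::validate_nc_ids("not_a_nutrient"), "unknown")
  expect_error(nutrimir:::validate_nc_ids("sodium", require_all = TRUE),
               "missing")
})

test_that("the residual method centres at the mean and removes energy trend", {
  set.seed(31)
  energy <- runif(50, 1500, 3000)
  raw <- matrix(0.002 * energy + rnorm(50, 0, 0.1), 50, 1,
                dimnames = list(paste0("s", 1:50), "vitamin_d"))
  raw <- pmax(raw, 0)
  it <- kcal_normalize(intake_table(raw, energy), method = "residual")
  expect_equal(mean(it$normalized), mean(it$raw), tolerance = 1e-8)
  expect_lt(abs(cor(it$normalized[, 1], energy)), 0.05)
})
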