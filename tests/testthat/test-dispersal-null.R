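# exhaustive enumeration of the null-median distribution for small candidate
# sets: independent oracle for random_median_draws()
enumerate_null_medians <- function(sets) {
  grids <- expand.grid(sets, KEEP.OUT.ATTRS = FALSE)
  meds <- apply(as.matrix(grids), 1, median)
  tab <- table(meds) / length(meds)
  tibble::tibble(median = as.numeric(names(tab)), prob = as.numeric(tab))
}

test_that("candidate sets respect availability, self-exclusion, and counting", {
  reg <- tiny_registry()  # boxes a,b pre-1987; c from 1990
  rec <- tiny_recruits()  # hatched 1985, 1990, 1995
  sets <- candidate_distances(rec, reg)
  expect_equal(lengths(sets$distances), c(1L, 2L, 2L))  # self excluded
  # pre-cutoff recruit only sees the early boxes
  expect_equal(sets$distances[[1]], 5)        # a -> b only
  expect_equal(sort(sets$distances[[2]]), c(5, 5))  # b -> a and b -> c
  expect_setequal(sets$distances[[3]], c(5, 10))
  # include_self keeps the 0-km natal distance
  sets_self <- candidate_distances(rec, reg, include_self = TRUE)
  expect_equal(lengths(sets_self$distances), c(2L, 3L, 3L))
  expect_true(all(vapply(sets_self$distances, min, numeric(1)) == 0))
})

test_that("boxes at (0,0),(3,4),(6,8) give candidate distances {5,10} from the origin", {
  reg <- box_registry(
    data.frame(box_id = c("o", "p", "q"), x_km = c(0, 3, 6),
               y_km = c(0, 4, 8), first_year = rep(1980, 3)), 1980)
  sets <- candidate_distances(
    tibble::tibble(recruit_id = "r", natal_box_id = "o", hatch_year = 1990), reg)
  expect_setequal(sets$distances[[1]], c(5, 10))
})

test_that("degenerate singleton candidate sets yield constant null medians", {
  meds <- random_median_draws(list(3.2, 3.2, 3.2), m = 50)
  expect_equal(meds, rep(3.2, 50))
})

test_that("single recruit with two candidates splits null medians 50/50", {
  withr::with_seed(1, meds <- random_median_draws(list(c(1, 3)), m = 20000))
  expect_true(all(meds %in% c(1, 3)))
  expect_equal(mean(meds == 1), 0.5, tolerance = 0.02)
})

test_that("null-median distribution matches exhaustive enumeration (3 recruits)", {
  sets <- list(c(1, 4), c(2, 6), c(3, 5))
  oracle <- enumerate_null_medians(sets)
  withr::with_seed(7, meds <- random_median_draws(sets, m = 40000))
  obs <- table(factor(meds, levels = oracle$median))
  gof <- suppressWarnings(chisq.test(obs, p = oracle$prob))
  expect_gt(gof$p.value, 0.01)
})

test_that("randomization p-values follow the add-one convention on the attainable grid", {
  sets <- list(c(1, 3), c(2, 5), c(1, 8))
  res <- randomization_test(c(1, 2, 1), sets, m = 99, seed = 4)
  expect_true(res$p_value >= 1 / 100 && res$p_value <= 1)
  expect_equal(res$p_value * 100, round(res$p_value * 100))
  # observed median below every attainable null median -> minimum p
  res_min <- randomization_test(c(0.1, 0.1, 0.1), sets, m = 999, seed = 4)
  expect_equal(res_min$p_value, 1 / 1000)
  # observed median tied with every null median -> p = 1 (ties count)
  res_tie <- randomization_test(c(2, 2, 2), list(2, 2, 2), m = 999, seed = 4)
  expect_equal(res_tie$p_value, 1)
  expect_equal(res_tie$expected_median_km, 2)
})

test_that("upper and two-sided tails behave consistently", {
  sets <- list(c(1, 3), c(2, 5), c(1, 8))
  obs <- c(8, 8, 8)  # observed median above all null medians
  lo <- randomization_test(obs, sets, m = 199, tail = "lower", seed = 2)
  up <- randomization_test(obs, sets, m = 199, tail = "upper", seed = 2)
  ts <- randomization_test(obs, sets, m = 199, tail = "two.sided", seed = 2)
  expect_equal(up$p_value, 1 / 200)
  expect_equal(lo$p_value, 1)
  expect_equal(ts$p_value, min(1, 2 * min(lo$p_value, up$p_value)))
})

test_that("identical seed, inputs and m give bit-identical results", {
  reg <- random_registry(n = 8, seed = 11)
  rec <- tibble::tibble(
    recruit_id = sprintf("r%d", 1:5),
    natal_box_id = reg$box_id[1:5],
    breeding_box_id = reg$box_id[c(2, 3, 4, 5, 6)],
    hatch_year = c(1985, 1990, 1992, 1988, 1991),
    morph = c("gray", "gray", "brown", "brown", "gray"))
  a <- dispersal_null_test(rec, reg, m = 199, seed = 99, by_morph = TRUE)
  b <- dispersal_null_test(rec, reg, m = 199, seed = 99, by_morph = TRUE)
  expect_identical(a, b)
})

test_that("mismatched recruit sets and empty strata are rejected", {
  sets <- list(c(1, 2), c(3, 4))
  expect_error(randomization_test(c(1, 2, 3), sets, m = 9), "same recruits")
  reg <- tiny_registry()
  rec <- tiny_recruits()
  expect_error(morph_stratified_test(rec, reg, morph = "albino"), "empty morph stratum")
})

test_that("a stratum equal to the full sample reproduces the unstratified test", {
  reg <- tiny_registry()
  rec <- tiny_recruits()
  rec$morph <- "gray"
  full <- dispersal_null_test(rec, reg, m = 99, seed = 5)$all
  strat <- morph_stratified_test(rec, reg, morph = "gray", m = 99, seed = 5)
  expect_identical(full, strat)
})

test_that("disjoint morph strata partition the recruits", {
  reg <- random_registry(n = 8, seed = 12)
  rec <- tibble::tibble(
    recruit_id = sprintf("r%d", 1:6),
    natal_box_id = reg$box_id[1:6],
    breeding_box_id = reg$box_id[c(2, 1, 4, 3, 6, 5)],
    hatch_year = rep(1990, 6),
    morph = c("gray", "gray", "gray", "brown", "brown", "gray"))
  res <- dispersal_null_test(rec, reg, m = 49, seed = 3, by_morph = TRUE)
  expect_equal(res$gray$n_recruits + res$brown$n_recruits, res$all$n_recruits)
})

test_that("the smaller stratum has the wider null-median distribution", {
  p <- small_params(seed = 21)
  b <- simulate_population(p)
  res <- dispersal_null_test(b$recruits, b$registry, m = 499, seed = 6,
                             by_morph = TRUE)
  expect_lt(res$brown$n_recruits, res$gray$n_recruits)
  expect_gt(sd(res$brown$random_medians), sd(res$gray$random_medians))
})

test_that("the pooled-urn variant draws from the union of candidate sets", {
  sets <- list(1, 100)  # per-recruit draws are deterministic; pooled are not
  per_recruit <- random_median_draws(sets, m = 50)
  expect_equal(per_recruit, rep(50.5, 50))
  withr::with_seed(2, pooled <- random_median_draws(sets, m = 500, pooled = TRUE))
  expect_setequal(unique(pooled), c(1, 50.5, 100))
})

test_that("tidying and plotting a randomization result works", {
  reg <- tiny_registry()
  rec <- tiny_recruits()
  res <- dispersal_null_test(rec, reg, m = 49, seed = 1, by_morph = TRUE)
  td <- tidy(res)
  expect_setequal(td$stratum, c("all", "gray", "brown"))
  expect_true(all(td$p_value > 0 & td$p_value <= 1))
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(autoplot(res$all), "ggplot")
})
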