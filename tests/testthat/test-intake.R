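classified_db <- function() {
  db <- assign_saccharides(tiny_db())
  db <- assign_starch(db)
  classify_free_sugar(db)
}

test_that("daily intake is amount/100 * content, additive over foods", {
  db <- classified_db()
  rec <- data.frame(person_id = "p1", day = 1L,
                    food_code = c("RICE", "MILK"),
                    amount_g = c(150, 200))
  d <- compute_daily_intake(rec, db)
  expect_equal(d$starch, 150 / 100 * 36)
  expect_equal(d$lactose, 200 / 100 * 4.4)
  expect_equal(d$energy, 1.5 * 156 + 2 * 67)
  # additivity of one nutrient across two foods
  rec2 <- data.frame(person_id = "p1", day = 1L,
                     food_code = c("APPLE", "JUICE"),
                     amount_g = c(100, 200))
  d2 <- compute_daily_intake(rec2, db)
  expect_equal(d2$sucrose, 3.5 + 2 * 2.3)
})

test_that("unknown food codes are listed in the error", {
  db <- classified_db()
  rec <- data.frame(person_id = "p1", day = 1L, food_code = "GHOST",
                    amount_g = 10)
  err <- expect_error(compute_daily_intake(rec, db),
                      class = "unknown_food_error")
  expect_match(conditionMessage(err), "GHOST")
})

test_that("per-day totals conserve sugar identities", {
  out <- assigned_synthetic(small_gen_config(seed = 9))
  rec <- generate_dietary_records(small_gen_config(seed = 9), out$db)
  daily <- compute_daily_intake(rec$records, out$db)
  sacch_sum <- unname(rowSums(daily[, saccharide_components()]))
  expect_equal(daily$total_sugar, sacch_sum, tolerance = 1e-12)
  expect_equal(daily$free_sugar + daily$naturally_occurring_sugar,
               daily$total_sugar, tolerance = 1e-12)
})

test_that("percent energy and EI/EER follow their formulas", {
  expect_equal(percent_energy(50, 2000), 10)
  expect_equal(percent_energy(0, 1500), 0)
  expect_equal(percent_energy(100, 1600), 25)
  expect_error(percent_energy(10, 0), class = "invariant_error")
  expect_equal(ei_eer(2000, 2000), 1)
  expect_equal(ei_eer(1220, 1000), 1.22)
  expect_equal(ei_eer(0, 1800), 0)
  expect_error(ei_eer(1000, 0), class = "invariant_error")
})

test_that("multi-day averaging equals the mean of daily vectors", {
  db <- classified_db()
  rec <- data.frame(person_id = "p1", day = c(1L, 2L),
                    food_code = c("RICE", "RICE"),
                    amount_g = c(100, 200))
  persons <- data.frame(person_id = "p1", sex = "male",
                        age_group = "adult", age = 30, eer_kcal = 2600)
  daily <- compute_daily_intake(rec, db)
  pi <- person_intake(daily, persons)
  expect_equal(pi$starch, mean(c(36, 72)))
  expect_equal(pi$n_days, 2L)
  # 1-day person passes through unchanged
  rec1 <- rec[1, ]
  pi1 <- person_intake(compute_daily_intake(rec1, db), persons)
  expect_equal(pi1$starch, 36)
})

test_that("WHO adherence uses closed thresholds with one-decimal output", {
  adh <- who_adherence(c(4, 6, 11))
  expect_equal(adh$ge10, 33.3)
  expect_equal(adh$ge5, 66.7)
  expect_equal(who_adherence(rep(4.9, 5)), list(ge10 = 0, ge5 = 0))
  at10 <- who_adherence(c(10.0, 1))
  expect_equal(at10$ge10, 50)  # exactly 10.0 counts as excessive
  at5 <- who_adherence(c(5.0, 1, 1, 1))
  expect_equal(at5$ge5, 25)
  expect_error(who_adherence(numeric(0)), class = "empty_set_error")
})

test_that("sex comparisons: t-test and chi-square match hand oracles", {
  # identical groups
  same <- compare_sexes(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # hand-computed pooled-variance t, df = 4
  tt <- compare_sexes(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$statistic, -3.6742346, tolerance = 1e-6)
  expect_equal(tt$p_value, 0.021312, tolerance = 1e-4)
  # degenerate zero-variance equal means
  degen <- compare_sexes(c(2, 2), c(2, 2))
  expect_equal(degen$p_value, 1)
  # chi-square: balanced table
  chi <- compare_sexes(c(50, 50), c(50, 50), kind = "prevalence")
  expect_equal(chi$statistic, 0)
  expect_equal(chi$p_value, 1)
  # chi-square without continuity correction vs closed form
  chi2 <- compare_sexes(c(30, 70), c(50, 50), kind = "prevalence")
  tab <- rbind(c(30, 70), c(50, 50))
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(chi2$statistic, sum((tab - e)^2 / e), tolerance = 1e-12)
})

test_that("t-test direction agrees with a permutation oracle", {
  set.seed(99)
  a <- rnorm(12, 10, 2); b <- rnorm(12, 12, 2)
  obs <- mean(a) - mean(b)
  pool <- c(a, b)
  perm <- replicate(400, {
    idx <- sample(24, 12)
    mean(pool[idx]) - mean(pool[-idx])
  })
  cmp <- compare_sexes(a, b)
  expect_equal(sign(cmp$statistic), sign(obs))
  # one-sided permutation p consistent with the t-test's half p-value
  p_perm <- mean(perm <= obs)
  expect_lt(abs(p_perm - cmp$p_value / 2), 0.05)
})

test_that("contributions are mean-of-ratios with exact row sums", {
  db <- classified_db()
  # person A eats only rice starch, person B only... rice has the starch
  rec <- data.frame(person_id = c("A", "A", "B"),
                    day = 1L,
                    food_code = c("RICE", "APPLE", "APPLE"),
                    amount_g = c(100, 100, 100))
  ct <- contribution_by_group(rec, db, "total_sugar")
  # A: rice contributes 0.3 g of A's 11.7 g sugar; B: 100% fruits
  a_rice <- 0.3 / (0.3 + 11.4) * 100
  expect_equal(ct$pct[ct$food_group == "rice and grains"], a_rice / 2)
  expect_equal(ct$pct[ct$food_group == "fruits"],
               ((100 - a_rice) + 100) / 2)
  expect_equal(sum(ct$pct), 100, tolerance = 1e-9)
  # single person, one group
  solo <- data.frame(person_id = "A", day = 1L, food_code = "RICE",
                     amount_g = 100)
  ct2 <- contribution_by_group(solo, db, "starch")
  expect_equal(ct2$pct[ct2$food_group == "rice and grains"], 100)
  # zero-intake persons are excluded and an all-zero population errors
  beef <- data.frame(person_id = "Z", day = 1L, food_code = "BEEF",
                     amount_g = 100)
  expect_error(contribution_by_group(beef, db, "starch"),
               class = "empty_set_error")
})

test_that("others bucket collapses groups under the display threshold", {
  out <- assigned_synthetic(small_gen_config(seed = 13))
  rec <- generate_dietary_records(small_gen_config(seed = 13), out$db)
  ct <- contribution_by_group(rec$records, out$db, "starch",
                              other_threshold = 7)
  expect_true(all(ct$pct[ct$food_group != "others"] >= 7))
  expect_equal(sum(ct$pct), 100, tolerance = 1e-9)
})
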