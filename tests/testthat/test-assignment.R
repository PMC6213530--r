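test_that("literature aggregation honours mean/median and rejects empties", {
  expect_equal(aggregate_representative(c(1, 2, 3), "mean"), 2)
  expect_equal(aggregate_representative(c(1, 2, 10), "median"), 2)
  expect_equal(aggregate_representative(4.2, "mean"), 4.2)
  expect_equal(aggregate_representative(4.2, "median"), 4.2)
  expect_error(aggregate_representative(numeric(0)),
               class = "empty_set_error")
})

test_that("dry-weight scaling applies the ratio form exactly", {
  expect_equal(scale_to_form(4, 10, 20), 8)
  expect_equal(scale_to_form(7, 15, 15), 7)
  expect_equal(scale_to_form(0, 3, 99), 0)
  expect_error(scale_to_form(1, 0, 10), class = "division_error")
})

test_that("overseas conversion multiplies only disaccharides by 0.95", {
  uk <- convert_overseas(list(mono_equiv = TRUE, sucrose = 10,
                              glucose = 10, lactose = 2))
  expect_equal(uk[["sucrose"]], 9.5)
  expect_equal(uk[["lactose"]], 1.9)
  expect_equal(uk[["glucose"]], 10)  # monosaccharides untouched
  us <- convert_overseas(list(mono_equiv = FALSE, sucrose = 10))
  expect_equal(us[["sucrose"]], 10)
})

test_that("recipe computation handles identity, mixture, concentration", {
  db <- tiny_db()
  db$content <- c(10, 0, 5, 2, 1, 0)
  one <- list(ingredients = data.frame(ingredient = "RICE",
                                       weight_g = 100), yield_g = 100)
  expect_equal(compute_from_recipe(one, db, "content")[["content"]], 10)
  mix <- list(ingredients = data.frame(ingredient = c("RICE", "APPLE"),
                                       weight_g = c(50, 50)),
              yield_g = 100)
  expect_equal(compute_from_recipe(mix, db, "content")[["content"]], 5)
  conc <- list(ingredients = data.frame(ingredient = "RICE",
                                        weight_g = 100), yield_g = 50)
  expect_equal(compute_from_recipe(conc, db, "content")[["content"]], 20)
})

test_that("recipe computation reports missing dependencies and bad inputs", {
  db <- tiny_db()
  db$glucose[1] <- NA
  rc <- list(ingredients = data.frame(ingredient = "RICE",
                                      weight_g = 100), yield_g = 100)
  expect_error(compute_from_recipe(rc, db), class = "dependency_error")
  rc$ingredients$ingredient <- "NOPE"
  expect_error(compute_from_recipe(rc, tiny_db()),
               class = "dependency_error")
  bad <- list(ingredients = data.frame(ingredient = "RICE",
                                       weight_g = 100), yield_g = 0)
  expect_error(compute_from_recipe(bad, tiny_db()),
               class = "invariant_error")
})

test_that("cyclic recipes are rejected", {
  db <- tiny_db()
  db[, saccharide_components()] <- NA_real_
  recipes <- data.frame(product = c("RICE", "APPLE"),
                        ingredient = c("APPLE", "RICE"),
                        weight_g = 100, yield_g = 100)
  expect_error(assign_saccharides(db, recipes = recipes),
               class = "cycle_error")
})

test_that("cascade resolves sources in order with provenance", {
  out <- assigned_synthetic(small_gen_config())
  db <- out$db; syn <- out$syn
  expect_false(anyNA(db$provenance))
  expect_false(anyNA(db$starch_provenance))
  # provenance partition: counts sum to table size
  expect_equal(sum(provenance_summary(db)$n), nrow(db))
  expect_equal(sum(provenance_summary(db, "starch")$n), nrow(db))
  # analytical items untouched, provenance step 1
  an <- names(syn$truth$source)[syn$truth$source == "analytical"]
  expect_true(all(db$provenance[db$code %in% an] == "STFCJ_ANALYTICAL"))
  # ground-truth source labels match assigned provenance
  map <- c(analytical = "STFCJ_ANALYTICAL", literature = "LITERATURE",
           same_form = "SAME_FOOD_OTHER_FORM", similar = "SIMILAR_FOOD",
           recipe = "RECIPE", overseas = "OVERSEAS_DB",
           zero_carb = "ZERO_FALLBACK", none = "ZERO_FALLBACK")
  expect_equal(unname(map[syn$truth$source[db$code]]), db$provenance)
  # unresolvable items are reported, not silently zeroed
  none <- names(syn$truth$source)[syn$truth$source == "none"]
  expect_setequal(attr(db, "exceptions"), none)
})

test_that("cascade recovers masked ground truth exactly", {
  out <- assigned_synthetic(small_gen_config(seed = 21, n_items = 200))
  db <- out$db; syn <- out$syn
  tr <- syn$truth$contents
  comps <- saccharide_components()
  exact <- syn$truth$source %in%
    c("analytical", "same_form", "similar", "recipe", "overseas",
      "literature", "zero_carb")
  expect_gt(sum(exact), 100)
  expect_lt(max(abs(as.matrix(db[exact, comps]) -
                      as.matrix(tr[exact, comps]))), 1e-9)
  expect_lt(max(abs(db$starch[exact] - tr$starch[exact])), 1e-9)
})

test_that("cascade is deterministic and step-monotone", {
  cfg <- small_gen_config(seed = 31)
  a <- assigned_synthetic(cfg)$db
  b <- assigned_synthetic(cfg)$db
  expect_identical(a, b)
  # an item resolved at step k keeps that step (no overwriting): the
  # analytical step runs first, so analytical items must be at step 1
  expect_true(all(a$assign_step[a$provenance == "STFCJ_ANALYTICAL"] == 1L))
  expect_true(all(diff(sort(unique(a$assign_step))) >= 1))
})

test_that("no assigned component exceeds available carbohydrate", {
  out <- assigned_synthetic(small_gen_config(seed = 41))
  db <- out$db
  avail <- available_carbohydrate(db)
  imputed <- db$provenance != "STFCJ_ANALYTICAL"
  m <- as.matrix(db[imputed, saccharide_components()])
  expect_true(all(m <= avail[imputed] + 1e-9))
  expect_true(all(db$starch[db$starch_provenance != "STFCJ_ANALYTICAL"] <=
                    avail[db$starch_provenance != "STFCJ_ANALYTICAL"] + 1e-9))
})

test_that("starch closing steps: carbohydrate difference then zero", {
  db <- tiny_db()
  db$starch <- NA_real_
  db <- assign_saccharides(db)
  db <- assign_starch(db)
  # rice: avail = 100-60-2.5-0.3-0.1-0.3 = 36.8, sugar 0.3 -> 36.5
  rice <- db[db$code == "RICE", ]
  expect_equal(rice$starch, 36.8 - 0.3)
  expect_equal(rice$starch_provenance, "CARB_DIFFERENCE")
  # sugar: avail 99.3, total sugar 99.3 -> clamped 0, still step 7
  sug <- db[db$code == "SUGAR", ]
  expect_equal(sug$starch, 0)
  expect_equal(sug$starch_provenance, "CARB_DIFFERENCE")
})

test_that("analytical starch is never overwritten", {
  db <- tiny_db()
  db <- assign_saccharides(db)
  db <- assign_starch(db)
  expect_equal(db$starch[db$code == "RICE"], 36)
  expect_equal(db$starch_provenance[db$code == "RICE"],
               "STFCJ_ANALYTICAL")
})

test_that("overseas country priority is honoured", {
  db <- tiny_db()
  db[db$code == "APPLE", saccharide_components()] <- NA_real_
  ovs <- rbind(
    data.frame(code = "APPLE", country = "AU",
               component = saccharide_components(),
               value = 1, mono_equiv = FALSE),
    data.frame(code = "APPLE", country = "US",
               component = saccharide_components(),
               value = 2, mono_equiv = FALSE))
  db2 <- assign_saccharides(db, overseas = ovs)
  expect_equal(db2$glucose[db2$code == "APPLE"], 2)  # US wins
  cfg <- assignment_config(overseas_priority = c("AU", "UK", "US"))
  db3 <- assign_saccharides(db, overseas = ovs, config = cfg)
  expect_equal(db3$glucose[db3$code == "APPLE"], 1)
})

test_that("provenance percentages use half-up rounding and subsets", {
  db <- tiny_db()
  db <- assign_saccharides(db)
  db <- assign_starch(db)
  one <- provenance_summary(db, subset = "RICE")
  expect_equal(one$pct[one$source == "STFCJ_ANALYTICAL"], 100)
  expect_equal(sum(one$n), 1)
})
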