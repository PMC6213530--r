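# Shared fixtures and independent oracles, built in code.

# a small hand-written composition table covering the main group types
tiny_db <- function() {
  db <- data.frame(
    code = c("RICE", "APPLE", "MILK", "SUGAR", "JUICE", "BEEF"),
    name = c("cooked rice", "apple raw", "whole milk",
             "granulated sugar", "apple juice", "beef lean"),
    food_group = c("rice and grains", "fruits", "dairy products",
                   "sugars and jams", "fruit juices", "meats"),
    form = c("cooked", "raw", "processed", "processed", "processed",
             "raw"),
    water = c(60, 85, 87.4, 0.7, 88, 70),
    protein = c(2.5, 0.2, 3.3, 0, 0.1, 20),
    lipid = c(0.3, 0.3, 3.8, 0, 0.1, 9),
    ash = c(0.1, 0.2, 0.7, 0, 0.2, 1),
    dietary_fiber = c(0.3, 1.9, 0, 0, 0, 0),
    energy = c(156, 57, 67, 387, 44, 170),
    glucose = c(0, 1.6, 0, 0, 2.4, 0),
    fructose = c(0, 6.3, 0, 0, 5.5, 0),
    galactose = c(0, 0, 0, 0, 0, 0),
    sucrose = c(0.1, 3.5, 0, 99.3, 2.3, 0),
    maltose = c(0.2, 0, 0, 0, 0, 0),
    lactose = c(0, 0, 4.4, 0, 0, 0),
    trehalose = c(0, 0, 0, 0, 0, 0),
    starch = c(36, 0.1, 0, 0, 0, 0),
    provenance = NA_character_,
    stringsAsFactors = FALSE)
  db
}

# brute-force one-way random-effects ANOVA: explicit double loops,
# written independently of variance_components()
brute_force_anova <- function(values, person) {
  ids <- unique(person)
  k <- length(ids)
  N <- length(values)
  grand <- sum(values) / N
  ssw <- 0; ssb <- 0; sum_ni2 <- 0
  for (id in ids) {
    v <- values[person == id]
    m <- sum(v) / length(v)
    for (x in v) ssw <- ssw + (x - m)^2
    ssb <- ssb + length(v) * (m - grand)^2
    sum_ni2 <- sum_ni2 + length(v)^2
  }
  msw <- ssw / (N - k)
  msb <- ssb / (k - 1)
  n0 <- (N - sum_ni2 / N) / (k - 1)
  list(sigma2_w = msw, sigma2_b = max(0, (msb - msw) / n0),
       grand_mean = grand)
}

# small generator config for fast end-to-end tests
small_gen_config <- function(seed = 11, n_items = 150, ...) {
  generator_config(
    seed = seed, n_items = n_items,
    n_persons = list(toddler = c(male = 6, female = 6),
                     preschool = c(male = 6, female = 6),
                     schoolchild = c(male = 8, female = 8),
                     adult = c(male = 10, female = 10)),
    ...)
}

# generate + fully assign + classify a table in one go
assigned_synthetic <- function(cfg) {
  syn <- generate_composition_table(cfg)
  db <- assign_saccharides(syn$table, syn$literature, syn$links,
                           syn$recipes, syn$overseas)
  db <- assign_starch(db, syn$literature, syn$links, syn$recipes,
                      syn$overseas)
  db <- classify_free_sugar(db, recipes = syn$recipes)
  list(db = db, syn = syn)
}
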