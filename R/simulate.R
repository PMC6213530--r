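## Synthetic-data generator: composition tables with masked values that
## the assignment cascade can resolve exactly, and multi-day dietary
## records with known habitual intakes.
##
## The generator is a stated world, not a tuning knob: its defaults are
## the survey's published conditions (2222 items with 39.6% analysed,
## 1/3/3/4 recording days, stratum sample sizes, stratum starch
## targets) plus typical nutrition-survey variance magnitudes
## (between-person CV 0.25, within-person CV 0.35, lognormal).
## Ground truth for derived items is defined downstream of the
## one-decimal rounding of emitted reference values, so the cascade's
## exact formulas reproduce it to machine precision.

#' Generator configuration
#'
#' @param seed integer seed; the whole generation is deterministic
#'   given it.
#' @param n_items number of food items.
#' @param fraction_analytical fraction of items carrying analytical
#'   saccharide and starch values (default 0.396).
#' @param remainder_mix named fractions over the non-analytical items:
#'   `literature`, `same_form`, `similar`, `recipe`, `overseas`,
#'   `zero_carb` (available carbohydrate exactly 0), `none`
#'   (unresolvable). Must sum to 1.
#' @param source_counts optional named integer vector (names
#'   `analytical, literature, same_form, similar, recipe, overseas,
#'   zero_carb, none`) overriding the fractions with exact counts;
#'   must sum to `n_items`.
#' @param n_persons named list, one element per age group
#'   (`toddler, preschool, schoolchild, adult`), each `c(male =, female
#'   =)` counts.
#' @param days named recording days per age group (1/3/3/4).
#' @param cv_between,cv_within lognormal between-/within-person
#'   coefficients of variation of daily starch intake.
#' @param starch_targets named list per age group of `c(male =, female
#'   =)` stratum mean starch targets, g/day.
#' @param ei_eer_targets named list per age group of `c(male =, female
#'   =)` target EI/EER ratios used to calibrate the synthetic EER
#'   table.
#' @param foods_per_day foods sampled per person-day.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_items = 2222L,
                             fraction_analytical = 0.396,
                             remainder_mix = c(literature = 0.10,
                                               same_form = 0.15,
                                               similar = 0.20,
                                               recipe = 0.15,
                                               overseas = 0.20,
                                               zero_carb = 0.10,
                                               none = 0.10),
                             source_counts = NULL,
                             n_persons = list(
                               toddler = c(male = 183, female = 185),
                               preschool = c(male = 186, female = 190),
                               schoolchild = c(male = 435, female = 480),
                               adult = c(male = 196, female = 196)),
                             days = c(toddler = 1, preschool = 3,
                                      schoolchild = 3, adult = 4),
                             cv_between = 0.25,
                             cv_within = 0.35,
                             starch_targets = list(
                               toddler = c(male = 61.1, female = 55.6),
                               preschool = c(male = 116.4, female = 107.8),
                               schoolchild = c(male = 206.0, female = 176.3),
                               adult = c(male = 203.4, female = 153.8)),
                             ei_eer_targets = list(
                               toddler = c(male = 1.22, female = 1.23),
                               preschool = c(male = 1.00, female = 1.00),
                               schoolchild = c(male = 1.00, female = 1.00),
                               adult = c(male = 1.00, female = 1.00)),
                             foods_per_day = 10L) {
  if (n_items < 1) ss_stop("config_error", "n_items must be >= 1")
  if (fraction_analytical < 0 || fraction_analytical > 1) {
    ss_stop("config_error", "fraction_analytical outside [0, 1]")
  }
  if (is.null(source_counts)) {
    if (any(remainder_mix < 0) ||
        abs(sum(remainder_mix) - 1) > 1e-6) {
      ss_stop("config_error", "remainder_mix must be non-negative and sum to 1")
    }
  } else {
    if (sum(source_counts) != n_items) {
      ss_stop("config_error", "source_counts must sum to n_items")
    }
  }
  if (cv_between <= 0 || cv_within < 0) {
    ss_stop("config_error", "CVs must be positive (within may be 0)")
  }
  structure(list(seed = as.integer(seed), n_items = as.integer(n_items),
                 fraction_analytical = fraction_analytical,
                 remainder_mix = remainder_mix,
                 source_counts = source_counts,
                 n_persons = n_persons, days = days,
                 cv_between = cv_between, cv_within = cv_within,
                 starch_targets = starch_targets,
                 ei_eer_targets = ei_eer_targets,
                 foods_per_day = as.integer(foods_per_day)),
            class = "generator_config")
}

## per-group composition parameters (g/100 g magnitudes of the
## national table; the stated world of the generator)
group_params <- function() {
  p <- function(group, water, avail, sugar_share, starch_share, mix) {
    data.frame(food_group = group, water = water, avail = avail,
               sugar_share = sugar_share, starch_share = starch_share,
               mix = mix, stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    p("rice and grains", 60, 36, 0.02, 0.95, "grain"),
    p("bread", 38, 46, 0.10, 0.92, "grain"),
    p("noodle", 70, 26, 0.02, 0.95, "grain"),
    p("other grain products", 12, 70, 0.05, 0.92, "grain"),
    p("potatoes", 80, 16, 0.06, 0.92, "veg"),
    p("pulses and nuts", 10, 20, 0.30, 0.60, "veg"),
    p("vegetables", 92, 4, 0.80, 0.30, "veg"),
    p("mushrooms", 92, 3, 0.30, 0.20, "veg"),
    p("seaweeds", 90, 4, 0.20, 0.20, "veg"),
    p("fruits", 86, 11, 0.92, 0.02, "fruit"),
    p("fruit juices", 89, 10.5, 0.95, 0.00, "fruit"),
    p("vegetable juices", 93, 5, 0.90, 0.02, "veg"),
    p("fish and shellfish", 74, 1, 0.40, 0.30, "misc"),
    p("meats", 65, 0.6, 0.40, 0.30, "misc"),
    p("eggs", 76, 0.5, 0.40, 0.10, "misc"),
    p("dairy products", 87, 5, 0.92, 0.01, "dairy"),
    p("fat and oil", 1, 0.3, 0.40, 0.10, "misc"),
    p("sugars and jams", 2, 97, 0.95, 0.02, "sweet"),
    p("confectionaries", 20, 60, 0.50, 0.85, "sweet"),
    p("sugar-sweetened beverages", 88, 11, 0.92, 0.02, "bev"),
    p("alcoholic beverages", 92, 4, 0.40, 0.10, "bev"),
    p("tea and coffee", 99, 0.3, 0.40, 0.10, "misc"),
    p("seasonings", 60, 25, 0.50, 0.60, "sweet"),
    p("other foods", 50, 30, 0.30, 0.60, "misc")
  ))
}

## component weight profiles, one per mix id
component_mixes <- function() {
  list(
    fruit = c(glucose = 0.30, fructose = 0.35, galactose = 0.00,
              sucrose = 0.35, maltose = 0.00, lactose = 0.00,
              trehalose = 0.00),
    dairy = c(glucose = 0.03, fructose = 0.00, galactose = 0.02,
              sucrose = 0.00, maltose = 0.00, lactose = 0.95,
              trehalose = 0.00),
    grain = c(glucose = 0.40, fructose = 0.05, galactose = 0.00,
              sucrose = 0.10, maltose = 0.45, lactose = 0.00,
              trehalose = 0.00),
    sweet = c(glucose = 0.10, fructose = 0.10, galactose = 0.00,
              sucrose = 0.78, maltose = 0.02, lactose = 0.00,
              trehalose = 0.00),
    veg   = c(glucose = 0.40, fructose = 0.38, galactose = 0.01,
              sucrose = 0.20, maltose = 0.00, lactose = 0.00,
              trehalose = 0.01),
    bev   = c(glucose = 0.25, fructose = 0.25, galactose = 0.00,
              sucrose = 0.50, maltose = 0.00, lactose = 0.00,
              trehalose = 0.00),
    misc  = c(glucose = 0.30, fructose = 0.20, galactose = 0.02,
              sucrose = 0.30, maltose = 0.10, lactose = 0.05,
              trehalose = 0.03)
  )
}

r1 <- function(x) round(x, 1)

## draw one base item's unrounded contents given its group parameters
draw_base_item <- function(gp, mixes) {
  # floor at 0.8 so one-decimal rounding never yields available
  # carbohydrate 0 for an item meant to resolve via a real source
  avail <- max(0.8, min(95, gp$avail * exp(stats::rnorm(1, 0, 0.25))))
  water <- max(0.5, min(99, gp$water + stats::runif(1, -4, 4)))
  if (water + avail > 97) water <- 97 - avail
  resid <- 100 - water - avail
  w <- stats::runif(4, 0.2, 1)          # protein, lipid, ash, fiber
  w <- w / sum(w) * resid
  sugar_total <- avail * gp$sugar_share * stats::runif(1, 0.70, 0.98)
  # 0.8 g margin below available carbohydrate so one-decimal rounding of
  # proximates can never trip the cascade's cap on scaled descendants
  sugar_total <- min(sugar_total, max(avail - 0.8, 0))
  mix <- mixes[[gp$mix]]
  jit <- mix * stats::runif(7, 0.8, 1.2)
  comps <- if (sum(jit) > 0) sugar_total * jit / sum(jit) else mix * 0
  starch <- (avail - sugar_total) * gp$starch_share *
    stats::runif(1, 0.85, 1)
  starch <- max(0, min(starch, avail - sugar_total - 0.8))
  list(water = water, protein = w[1], lipid = w[2], ash = w[3],
       dietary_fiber = w[4], comps = comps, starch = starch,
       energy = 4 * w[1] + 9 * w[2] + 4 * avail)
}

source_count_vector <- function(config) {
  all_src <- c("analytical", "literature", "same_form", "similar",
               "recipe", "overseas", "zero_carb", "none")
  if (!is.null(config$source_counts)) {
    cnt <- stats::setNames(integer(8), all_src)
    cnt[names(config$source_counts)] <- as.integer(config$source_counts)
    return(cnt)
  }
  n <- config$n_items
  n_an <- round_half_up(config$fraction_analytical * n)
  rest <- n - n_an
  mix <- config$remainder_mix
  cnt <- stats::setNames(integer(8), all_src)
  cnt["analytical"] <- n_an
  raw <- mix * rest
  fl <- floor(raw)
  extra <- rest - sum(fl)
  if (extra > 0) {
    ord <- order(raw - fl, decreasing = TRUE)
    fl[ord[seq_len(extra)]] <- fl[ord[seq_len(extra)]] + 1
  }
  cnt[names(fl)] <- as.integer(fl)
  cnt
}

#' Generate a composition table with masked, resolvable values
#'
#' Items are drawn per food group with internally consistent proximates
#' (proximates + available carbohydrate = 100; starch + total sugar
#' below available carbohydrate with margin). Analytical items keep
#' their profiles; the remainder is masked and equipped with the
#' auxiliary source (literature rows whose median is the truth,
#' same-form/similar dry-weight links, recipes, overseas entries with
#' the UK monosaccharide-equivalent convention) that resolves it.
#' Ground truth is recorded per item.
#'
#' @param config a [generator_config()].
#' @return list of class `synthetic_composition`: `table` (masked),
#'   `literature`, `links`, `recipes`, `overseas`, and `truth` (list
#'   with `contents` data.frame, `source` named vector, `stfcj_info`
#'   codes whose values trace to in-table saccharide information).
#' @export
generate_composition_table <- function(config = generator_config()) {
  set.seed(config$seed)
  cnt <- source_count_vector(config)
  n <- config$n_items
  n_derived <- cnt[["same_form"]] + cnt[["similar"]] + cnt[["recipe"]]
  if (n_derived > 0 && cnt[["analytical"]] < 2) {
    ss_stop("config_error",
            "derived sources need at least 2 analytical items")
  }
  if (cnt[["recipe"]] > 0 && cnt[["analytical"]] < 2) {
    ss_stop("config_error", "recipes need at least 2 analytical items")
  }

  gp <- group_params()
  mixes <- component_mixes()
  comps <- saccharide_components()
  zero_groups <- c("meats", "fish and shellfish", "eggs", "fat and oil",
                   "tea and coffee")

  src <- rep(names(cnt), times = cnt)
  codes <- sprintf("F%04d", seq_len(n))
  # groups: cover all 24 when the table is large enough
  grp_pool <- setdiff(food_groups(), character(0))
  groups <- sample(grp_pool, n, replace = TRUE)
  if (n >= 24) groups[seq_len(24)] <- sample(grp_pool)
  # zero-carb items must live in near-zero-carbohydrate groups
  groups[src == "zero_carb"] <- sample(zero_groups, sum(src == "zero_carb"),
                                       replace = TRUE)

  tab <- data.frame(code = codes, name = paste0(groups, " item ",
                                                seq_len(n)),
                    food_group = groups,
                    form = sample(c("raw", "cooked", "processed"), n,
                                  replace = TRUE, prob = c(.5, .3, .2)),
                    water = NA_real_, protein = NA_real_,
                    lipid = NA_real_, ash = NA_real_,
                    dietary_fiber = NA_real_, energy = NA_real_,
                    stringsAsFactors = FALSE)
  for (cc in comps) tab[[cc]] <- NA_real_
  tab$starch <- NA_real_
  tab$provenance <- NA_character_

  truth <- matrix(NA_real_, n, 9,
                  dimnames = list(codes, c(comps, "starch",
                                           "total_sugar")))
  lit_rows <- list(); link_rows <- list(); rec_rows <- list()
  ovs_rows <- list()

  # rounding proximates to one decimal can push available carbohydrate
  # a hair below zero; repair by trimming fiber, then ash/protein/lipid
  fix_budget <- function(i) {
    repeat {
      avail <- 100 - tab$water[i] - tab$protein[i] - tab$lipid[i] -
        tab$ash[i] - tab$dietary_fiber[i]
      if (avail >= -1e-9) break
      for (f in c("dietary_fiber", "ash", "protein", "lipid")) {
        take <- min(tab[[f]][i], -avail)
        if (take > 0) {
          tab[[f]][i] <<- r1(tab[[f]][i] - take)
          break
        }
      }
    }
  }

  put_proximates <- function(i, b) {
    tab$water[i] <<- r1(b$water); tab$protein[i] <<- r1(b$protein)
    tab$lipid[i] <<- r1(b$lipid); tab$ash[i] <<- r1(b$ash)
    tab$dietary_fiber[i] <<- r1(b$dietary_fiber)
    tab$energy[i] <<- round(b$energy)
    fix_budget(i)
  }

  base_idx <- which(src %in% c("analytical", "literature", "overseas",
                               "none"))
  for (i in base_idx) {
    b <- draw_base_item(gp[gp$food_group == groups[i], ], mixes)
    put_proximates(i, b)
    if (src[i] == "analytical") {
      vals <- r1(b$comps)
      tab[i, comps] <- as.list(vals)
      tab$starch[i] <- r1(b$starch)
      truth[i, comps] <- vals
      truth[i, "starch"] <- r1(b$starch)
    } else if (src[i] == "literature") {
      vals <- r1(b$comps)
      truth[i, comps] <- vals
      for (cc in comps) {
        v <- vals[[cc]]
        d <- r1(min(v, v * 0.15))
        lit_rows[[length(lit_rows) + 1L]] <-
          data.frame(code = codes[i], component = cc,
                     value = c(v - d, v, v + d),
                     source_id = paste0("study", 1:3),
                     stringsAsFactors = FALSE)
      }
      # starch resolves by carbohydrate difference downstream
      avail_i <- 100 - tab$water[i] - tab$protein[i] - tab$lipid[i] -
        tab$ash[i] - tab$dietary_fiber[i]
      truth[i, "starch"] <- max(0, avail_i - sum(vals))
    } else if (src[i] == "overseas") {
      ctry <- sample(c("US", "UK", "AU"), 1)
      stored <- r1(b$comps)
      tr <- stored
      if (ctry == "UK") {
        di <- disaccharide_components()
        stored[di] <- r1(b$comps[di] / 0.95)
        tr[di] <- stored[di] * 0.95
      }
      truth[i, comps] <- tr
      truth[i, "starch"] <- r1(b$starch)
      ovs_rows[[length(ovs_rows) + 1L]] <-
        data.frame(code = codes[i], country = ctry,
                   component = c(comps, "starch"),
                   value = c(unname(stored), r1(b$starch)),
                   mono_equiv = ctry == "UK", stringsAsFactors = FALSE)
      # occasionally a lower-priority country carries the item too;
      # its (different) values must lose against the priority order
      if (stats::runif(1) < 0.2 && ctry != "AU") {
        ovs_rows[[length(ovs_rows) + 1L]] <-
          data.frame(code = codes[i], country = "AU",
                     component = c(comps, "starch"),
                     value = r1(c(unname(b$comps), b$starch) * 1.1),
                     mono_equiv = FALSE, stringsAsFactors = FALSE)
      }
    } else {  # none: values exist but no source resolves them
      truth[i, comps] <- r1(b$comps)
      truth[i, "starch"] <- r1(b$starch)
    }
  }

  for (i in which(src == "zero_carb")) {
    prot <- r1(stats::runif(1, 5, 20))
    lip <- r1(stats::runif(1, 2, 15))
    water <- r1(min(gp$water[gp$food_group == groups[i]] +
                      stats::runif(1, -4, 4), 99 - prot - lip))
    fib <- 0
    ash <- r1(100 - water - prot - lip - fib)  # 1-decimal exact residual
    tab$water[i] <- water; tab$protein[i] <- prot; tab$lipid[i] <- lip
    tab$ash[i] <- ash; tab$dietary_fiber[i] <- fib
    tab$energy[i] <- round(4 * prot + 9 * lip)
    truth[i, comps] <- 0
    truth[i, "starch"] <- 0
  }

  an_idx <- which(src == "analytical")
  for (i in which(src %in% c("same_form", "similar"))) {
    ri <- sample(an_idx, 1)
    dry_ref <- 100 - tab$water[ri]
    r_max <- min(1.3, 0.99 * 99 / max(dry_ref, 1e-9))
    r <- stats::runif(1, min(0.5, r_max * 0.8), r_max)
    water_t <- r1(100 - r * dry_ref)
    tab$water[i] <- water_t
    tab$protein[i] <- r1(r * tab$protein[ri])
    tab$lipid[i] <- r1(r * tab$lipid[ri])
    tab$ash[i] <- r1(r * tab$ash[ri])
    tab$dietary_fiber[i] <- r1(r * tab$dietary_fiber[ri])
    tab$energy[i] <- round(r * tab$energy[ri])
    fix_budget(i)
    ratio <- (100 - tab$water[i]) / (100 - tab$water[ri])  # emitted waters
    truth[i, comps] <- unlist(tab[ri, comps]) * ratio
    truth[i, "starch"] <- tab$starch[ri] * ratio
    rel <- if (src[i] == "same_form") "same_food_other_form" else
      "similar_food"
    if (src[i] == "same_form") {
      tab$food_group[i] <- tab$food_group[ri]
      tab$form[i] <- "cooked"
    }
    link_rows[[length(link_rows) + 1L]] <-
      data.frame(target = codes[i], reference = codes[ri],
                 relation = rel, stringsAsFactors = FALSE)
  }

  for (i in which(src == "recipe")) {
    k <- sample(2:3, 1)
    ing <- sample(an_idx, k)
    wts <- round(stats::runif(k, 30, 300))
    total <- sum(wts)
    yield <- round(total * stats::runif(1, 0.85, 1.15))
    for (tries in 1:6) {
      per100 <- function(col) sum(tab[[col]][ing] * wts) / yield
      prof <- vapply(comps, per100, numeric(1))
      st <- per100("starch")
      prot <- r1(per100("protein")); lip <- r1(per100("lipid"))
      ash <- r1(per100("ash")); fib <- r1(per100("dietary_fiber"))
      avail_need <- (sum(prof) + st) * 1.05 + 0.5
      water <- r1(100 - prot - lip - ash - fib - avail_need)
      if (water >= 2) break
      yield <- round(yield * 1.3)
    }
    tab$water[i] <- water; tab$protein[i] <- prot; tab$lipid[i] <- lip
    tab$ash[i] <- ash; tab$dietary_fiber[i] <- fib
    fix_budget(i)
    tab$energy[i] <- round(sum(tab$energy[ing] * wts) / yield)
    truth[i, comps] <- prof
    truth[i, "starch"] <- st
    rec_rows[[length(rec_rows) + 1L]] <-
      data.frame(product = codes[i], ingredient = codes[ing],
                 weight_g = wts, yield_g = yield,
                 stringsAsFactors = FALSE)
  }

  truth[, "total_sugar"] <- rowSums(truth[, comps, drop = FALSE])

  bind <- function(rows, template) {
    if (length(rows)) do.call(rbind, rows) else template
  }
  out <- list(
    table = tab,
    literature = bind(lit_rows,
                      data.frame(code = character(), component = character(),
                                 value = numeric(), source_id = character())),
    links = bind(link_rows,
                 data.frame(target = character(), reference = character(),
                            relation = character())),
    recipes = bind(rec_rows,
                   data.frame(product = character(), ingredient = character(),
                              weight_g = numeric(), yield_g = numeric())),
    overseas = bind(ovs_rows,
                    data.frame(code = character(), country = character(),
                               component = character(), value = numeric(),
                               mono_equiv = logical())),
    truth = list(
      contents = data.frame(code = codes, as.data.frame(truth,
                                                        row.names = NULL),
                            stringsAsFactors = FALSE),
      source = stats::setNames(src, codes),
      stfcj_info = codes[src %in% c("analytical", "same_form", "similar",
                                    "recipe", "overseas")])
  )
  class(out) <- "synthetic_composition"
  out
}

#' Generate persons and multi-day dietary records
#'
#' Each person draws a habitual starch level, lognormal around the
#' stratum target with the between-person CV; each day multiplies
#' lognormal within-person noise. Foods are sampled from the table
#' (staple groups guaranteed) and amounts are rescaled so the computed
#' starch of the day equals the drawn day total, so the other nutrients
#' ride along with realistic food patterns. The synthetic EER table is
#' calibrated as stratum mean energy intake divided by the stratum's
#' EI/EER target.
#'
#' @param config a [generator_config()].
#' @param db fully assigned (and classified) composition table.
#' @return list of class `synthetic_records`: `persons`, `records`,
#'   `truth` (per-person habitual starch, g/day).
#' @export
generate_dietary_records <- function(config, db) {
  set.seed(config$seed + 1000003L)
  if (is.null(db$starch) || anyNA(db$starch)) {
    ss_stop("dependency_error", "db must have starch assigned")
  }
  staple <- db$food_group %in% c("rice and grains", "bread", "noodle",
                                 "potatoes")
  if (!any(staple & db$starch > 0)) {
    ss_stop("config_error",
            "table has no starch-bearing staple foods; targets unreachable")
  }
  # sampling weights: common groups eaten more often
  gw <- c("rice and grains" = .14, "vegetables" = .14, "bread" = .05,
          "noodle" = .05, "potatoes" = .03, "fruits" = .07,
          "dairy products" = .08, "meats" = .08,
          "fish and shellfish" = .07, "eggs" = .04,
          "confectionaries" = .06, "sugar-sweetened beverages" = .04,
          "seasonings" = .06, "pulses and nuts" = .03,
          "tea and coffee" = .03, "other foods" = .03)
  w_item <- rep(0.001, nrow(db))
  for (g in names(gw)) {
    sel <- db$food_group == g
    if (any(sel)) w_item[sel] <- gw[[g]] / sum(sel)
  }
  sb <- sqrt(log(1 + config$cv_between^2))
  sw <- sqrt(log(1 + config$cv_within^2))
  age_range <- list(toddler = 1:2, preschool = 3:6, schoolchild = 8:14,
                    adult = 20:69)

  persons <- list(); records <- list(); truths <- list()
  pc <- 0L
  staple_idx <- which(staple & db$starch > 0)
  other_idx <- seq_len(nrow(db))
  for (ag in names(config$n_persons)) {
    for (sx in c("male", "female")) {
      np <- config$n_persons[[ag]][[sx]]
      if (np < 1) next
      nd <- config$days[[ag]]
      target <- config$starch_targets[[ag]][[sx]]
      pf <- exp(stats::rnorm(np, -sb^2 / 2, sb))
      ids <- sprintf("P%05d", pc + seq_len(np))
      pc <- pc + np
      energy_mean <- numeric(np)
      for (p in seq_len(np)) {
        df <- exp(stats::rnorm(nd, -sw^2 / 2, sw))
        for (d in seq_len(nd)) {
          n_staple <- min(3L, config$foods_per_day)
          pick <- c(sample(staple_idx, n_staple, replace = TRUE),
                    sample(other_idx,
                           max(config$foods_per_day - n_staple, 0L),
                           replace = TRUE, prob = w_item))
          amt <- exp(stats::rnorm(length(pick), log(60), 0.6))
          s0 <- sum(amt * db$starch[pick] / 100)
          amt <- amt * target * pf[p] * df[d] / s0
          amt <- round(amt, 1)
          records[[length(records) + 1L]] <-
            data.frame(person_id = ids[p], day = d,
                       food_code = db$code[pick], amount_g = amt,
                       stringsAsFactors = FALSE)
          energy_mean[p] <- energy_mean[p] +
            sum(amt * db$energy[pick] / 100) / nd
        }
      }
      eer <- round(mean(energy_mean) / config$ei_eer_targets[[ag]][[sx]])
      persons[[length(persons) + 1L]] <-
        data.frame(person_id = ids, sex = sx, age_group = ag,
                   age = sample(age_range[[ag]], np, replace = TRUE),
                   eer_kcal = eer, stringsAsFactors = FALSE)
      truths[[length(truths) + 1L]] <-
        data.frame(person_id = ids, age_group = ag, sex = sx,
                   habitual_starch = target * pf,
                   stringsAsFactors = FALSE)
    }
  }
  out <- list(persons = do.call(rbind, persons),
              records = do.call(rbind, records),
              truth = do.call(rbind, truths))
  rownames(out$persons) <- rownames(out$records) <-
    rownames(out$truth) <- NULL
  class(out) <- "synthetic_records"
  out
}
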