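## Applying the assigned database to weighed dietary records.
##
## Records store the net consumed amount (leftovers already
## subtracted) in grams of edible portion; contents are per 100 g, so
## intake = amount / 100 * content, summed over the foods of a
## person-day.

#' Nutrients computed per person-day
#' @return Character vector of intake column names.
#' @export
intake_nutrients <- function() {
  c("available_carbohydrate", "starch", saccharide_components(),
    "total_sugar", "free_sugar", "naturally_occurring_sugar")
}

#' Per person-day nutrient intake
#'
#' @param records data.frame `person_id, day, food_code, amount_g`.
#' @param db fully assigned and classified composition table.
#' @return data.frame with one row per person-day: `person_id, day,
#'   energy` (kcal/day) and one column per [intake_nutrients()] (g/day).
#'   A person-day with no foods never appears; callers treat absent
#'   days as all-zero.
#' @export
compute_daily_intake <- function(records, db) {
  idx <- match(records$food_code, db$code)
  if (anyNA(idx)) {
    ss_stop("unknown_food_error",
            sprintf("food code(s) not in table: %s",
                    paste(unique(records$food_code[is.na(idx)]),
                          collapse = ", ")))
  }
  if (any(records$amount_g < 0)) {
    ss_stop("invariant_error", "negative consumed amount")
  }
  if (is.null(db$free_sugar)) {
    ss_stop("dependency_error",
            "table lacks free sugar; run classify_free_sugar first")
  }
  avail <- available_carbohydrate(db)
  cols <- cbind(energy = db$energy,
                available_carbohydrate = avail,
                starch = db$starch,
                as.matrix(db[, saccharide_components()]),
                total_sugar = db$total_sugar,
                free_sugar = db$free_sugar,
                naturally_occurring_sugar = db$naturally_occurring_sugar)
  contrib <- cols[idx, , drop = FALSE] * (records$amount_g / 100)
  key <- interaction(records$person_id, records$day, drop = TRUE)
  agg <- rowsum(contrib, key, reorder = FALSE)
  first <- !duplicated(key)
  out <- data.frame(person_id = records$person_id[first],
                    day = records$day[first],
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(agg, row.names = NULL))
}

#' Energy-adjusted intake (% of energy)
#'
#' grams x energy factor (kcal/g, Atwater 4 for starch and all sugars)
#' divided by energy intake, times 100.
#'
#' @param grams nutrient intake, g/day.
#' @param energy energy intake, kcal/day; must be positive.
#' @param factor kcal per gram (default 4).
#' @return Percent of energy.
#' @export
#' @examples
#' percent_energy(50, 2000)  # 10
percent_energy <- function(grams, energy, factor = 4) {
  if (any(energy <= 0)) {
    ss_stop("invariant_error", "energy intake must be positive")
  }
  grams * factor / energy * 100
}

#' Ratio of reported energy intake to estimated energy requirement
#'
#' The EI/EER ratio screens for misreporting: values far from 1 signal
#' under- or over-reporting at the group level.
#'
#' @param ei mean reported energy intake, kcal/day.
#' @param eer estimated energy requirement, kcal/day; must be positive.
#' @return EI / EER.
#' @export
#' @examples
#' ei_eer(1220, 1000)  # 1.22
ei_eer <- function(ei, eer) {
  if (any(eer <= 0)) {
    ss_stop("invariant_error", "EER must be positive")
  }
  ei / eer
}

#' Prevalence of free-sugar intake at or above the WHO thresholds
#'
#' The WHO recommendation is free sugar below 10% (conditionally 5%) of
#' energy intake; "excessive" is the closed condition >= threshold, so
#' a member at exactly 10.0 %E counts.
#'
#' @param pct_energy free-sugar %E values of one group.
#' @return list with `ge10` and `ge5`: percentages (one decimal,
#'   half-up) of the group at or above 10 and 5 %E.
#' @export
#' @examples
#' who_adherence(c(4, 6, 11))  # ge10 = 33.3, ge5 = 66.7
who_adherence <- function(pct_energy) {
  if (!length(pct_energy)) {
    ss_stop("empty_set_error", "empty group")
  }
  list(ge10 = round_half_up(100 * mean(pct_energy >= 10), 1),
       ge5 = round_half_up(100 * mean(pct_energy >= 5), 1))
}

#' Compare two sex groups
#'
#' Means are compared with the equal-variance two-sample t-test;
#' prevalences with Pearson's chi-square test without continuity
#' correction. P values are two-sided; significance tiers 0.05 / 0.01 /
#' 0.001.
#'
#' @param a,b for `kind = "mean"`, numeric value vectors (each length
#'   >= 2); for `kind = "prevalence"`, integer vectors `c(events,
#'   non-events)`.
#' @param kind `"mean"` or `"prevalence"`.
#' @return list `statistic`, `p_value`, `method`, `stars`.
#' @export
#' @examples
#' compare_sexes(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, p ~ 0.0214
compare_sexes <- function(a, b, kind = c("mean", "prevalence")) {
  kind <- match.arg(kind)
  if (kind == "mean") {
    if (length(a) < 2 || length(b) < 2) {
      ss_stop("invariant_error", "each group needs >= 2 observations")
    }
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      st <- if (mean(a) == mean(b)) 0 else Inf * sign(mean(a) - mean(b))
      p <- if (mean(a) == mean(b)) 1 else 0
    } else {
      tt <- stats::t.test(a, b, var.equal = TRUE)
      st <- unname(tt$statistic)
      p <- tt$p.value
    }
    method <- "two-sample t-test (equal variance)"
  } else {
    tab <- rbind(a, b)
    if (any(!is.finite(tab)) || any(tab < 0)) {
      ss_stop("invariant_error", "prevalence needs finite 2x2 counts")
    }
    if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) {
      st <- 0
      p <- 1
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      st <- unname(ct$statistic)
      p <- ct$p.value
      if (is.nan(st)) { st <- 0; p <- 1 }
    }
    method <- "Pearson chi-square (no continuity correction)"
  }
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else ""
  list(statistic = st, p_value = p, method = method, stars = stars)
}

#' Per-person mean intakes, %E and EI/EER
#'
#' Averages the person-day vectors over each person's recorded days
#' (1-day records pass through unchanged), energy-adjusts every
#' nutrient and attaches EI/EER.
#'
#' @param daily output of [compute_daily_intake()].
#' @param persons data.frame `person_id, sex, age_group, age, eer_kcal`.
#' @param energy_factor kcal per gram for %E (default 4).
#' @return data.frame, one row per person: identifiers, `n_days`,
#'   `energy`, `ei_eer`, one `<nutrient>` g/day column and one
#'   `<nutrient>_pctE` column per nutrient.
#' @export
person_intake <- function(daily, persons, energy_factor = 4) {
  nut <- c("energy", intake_nutrients())
  m <- rowsum(as.matrix(daily[, nut]), daily$person_id, reorder = FALSE)
  nd <- as.vector(table(factor(daily$person_id,
                               levels = rownames(m))))
  m <- m / nd
  idx <- match(rownames(m), persons$person_id)
  if (anyNA(idx)) {
    ss_stop("unknown_food_error",
            sprintf("person(s) missing from metadata: %s",
                    paste(rownames(m)[is.na(idx)][1:5], collapse = ", ")))
  }
  out <- persons[idx, , drop = FALSE]
  out$n_days <- nd
  out$energy <- m[, "energy"]
  out$ei_eer <- ei_eer(out$energy, out$eer_kcal)
  for (v in intake_nutrients()) {
    out[[v]] <- m[, v]
    out[[paste0(v, "_pctE")]] <-
      percent_energy(m[, v], m[, "energy"], energy_factor)
  }
  rownames(out) <- NULL
  out
}

#' Food-group contribution to a nutrient's intake
#'
#' For each person, the share of each food group in that person's total
#' intake of the nutrient over all recorded days; the table reports the
#' mean of the per-person shares (mean of ratios, not ratio of means).
#' Persons with zero intake of the nutrient are excluded and reported
#' in `attr(, "excluded")`. Rows sum to 100.
#'
#' @param records dietary records (`person_id, day, food_code,
#'   amount_g`).
#' @param db assigned, classified composition table.
#' @param nutrient one of [intake_nutrients()] or `"energy"`.
#' @param other_threshold if non-NULL, groups contributing less than
#'   this percentage are collapsed into an `"others"` row (display
#'   convention: < 7%).
#' @return data.frame `food_group, pct` sorted by descending share.
#' @export
contribution_by_group <- function(records, db, nutrient,
                                  other_threshold = NULL) {
  idx <- match(records$food_code, db$code)
  if (anyNA(idx)) {
    ss_stop("unknown_food_error",
            sprintf("food code(s) not in table: %s",
                    paste(unique(records$food_code[is.na(idx)]),
                          collapse = ", ")))
  }
  content <- switch(nutrient,
    energy = db$energy,
    available_carbohydrate = available_carbohydrate(db),
    db[[nutrient]])
  if (is.null(content)) {
    ss_stop("config_error", sprintf("unknown nutrient '%s'", nutrient))
  }
  amount <- records$amount_g / 100 * content[idx]
  grp <- factor(db$food_group[idx], levels = food_groups())
  pid <- unique(records$person_id)
  m <- tapply(amount, list(factor(records$person_id, levels = pid), grp),
              sum, default = 0)
  totals <- rowSums(m)
  zero <- totals <= 0
  excluded <- pid[zero]
  if (all(zero)) {
    ss_stop("empty_set_error",
            sprintf("no person has positive intake of %s", nutrient))
  }
  shares <- m[!zero, , drop = FALSE] / totals[!zero] * 100
  pct <- colMeans(shares)
  out <- data.frame(food_group = names(pct), pct = unname(pct),
                    stringsAsFactors = FALSE)
  if (!is.null(other_threshold)) {
    small <- out$pct < other_threshold
    if (any(small)) {
      out <- rbind(out[!small, , drop = FALSE],
                   data.frame(food_group = "others",
                              pct = sum(out$pct[small])))
    }
  }
  out <- out[order(-out$pct), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "nutrient") <- nutrient
  out
}
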