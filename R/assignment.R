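## Stepwise value assignment: fill saccharide profiles and starch for
## items lacking analytical values, in a fixed, configurable cascade
## with per-item provenance.
##
## Cascade (default order):
##   1 analytical values already in the table
##   2 all-zero profile where available carbohydrate is 0
##   3 literature values (mean/median aggregation)
##   4 same food, other form  (dry-weight scaling)
##   5 similar food           (identical ratio form)
##   6 recipe calculation
##   7 overseas tables        (UK disaccharides are monosaccharide
##                             equivalents, x 0.95)
##   then a capped all-zero fallback, reported as an exception.
## Starch replaces the fallback with carbohydrate-difference (Step 7)
## and zero (Step 8).

#' Assignment cascade configuration
#'
#' @param order step order for the imputation cascade; a permutation or
#'   subset of the default. The zero fallback always runs last.
#' @param aggregation `"median"` (default) or `"mean"` for literature
#'   values. The starch literature always aggregates with the same rule.
#' @param aggregation_overrides optional named character vector, food
#'   code -> method, overriding `aggregation` per food.
#' @param overseas_priority country preference when several overseas
#'   tables carry the same item.
#' @param cap_to_available cap every imputed component at available
#'   carbohydrate (default TRUE).
#' @return A list of class `assignment_config`.
#' @export
assignment_config <- function(order = c("analytical", "zero_carb",
                                        "literature", "same_form",
                                        "similar", "recipe", "overseas"),
                              aggregation = c("median", "mean"),
                              aggregation_overrides = NULL,
                              overseas_priority = c("US", "UK", "AU"),
                              cap_to_available = TRUE) {
  aggregation <- match.arg(aggregation)
  known <- c("analytical", "zero_carb", "literature", "same_form",
             "similar", "recipe", "overseas")
  if (!all(order %in% known)) {
    ss_stop("config_error",
            sprintf("unknown cascade step(s): %s",
                    paste(setdiff(order, known), collapse = ", ")))
  }
  structure(list(order = order, aggregation = aggregation,
                 aggregation_overrides = aggregation_overrides,
                 overseas_priority = overseas_priority,
                 cap_to_available = isTRUE(cap_to_available)),
            class = "assignment_config")
}

#' Representative value from a set of literature values
#'
#' Several analytical studies may report the same component for the
#' same food; the representative value is their mean or median.
#'
#' @param values numeric vector of reported values (g/100 g).
#' @param method `"median"` (default) or `"mean"`.
#' @return Scalar representative value.
#' @export
#' @examples
#' aggregate_representative(c(1, 2, 10), "median")  # 2
aggregate_representative <- function(values, method = c("median", "mean")) {
  method <- match.arg(method)
  values <- values[!is.na(values)]
  if (!length(values)) {
    ss_stop("empty_set_error", "no literature values to aggregate")
  }
  if (method == "mean") mean(values) else stats::median(values)
}

#' Dry-weight scaling between forms or similar foods
#'
#' content(target) = content(reference) * dry_target / dry_ref.
#' Used both for the same food in another form (raw -> cooked) and for
#' similar foods of the same family or order.
#'
#' @param value_ref reference content, g/100 g.
#' @param dry_ref dry weight of the reference item, g/100 g; must be > 0.
#' @param dry_target dry weight of the target item, g/100 g.
#' @return Scaled content, g/100 g.
#' @export
#' @examples
#' scale_to_form(4, dry_ref = 10, dry_target = 20)  # 8
scale_to_form <- function(value_ref, dry_ref, dry_target) {
  if (any(dry_ref <= 0)) {
    ss_stop("division_error", "reference dry weight must be positive")
  }
  value_ref * dry_target / dry_ref
}

#' Convert an overseas table entry to the domestic convention
#'
#' UK tables express disaccharides as monosaccharide equivalents
#' (hydrolysed mass); conversion back multiplies the four disaccharides
#' by 0.95. Monosaccharides are never converted, and the conversion is
#' applied exactly once.
#'
#' @param entry a list or one-row data.frame with a logical
#'   `mono_equiv` element and any of the seven saccharide components.
#' @return Named numeric vector over [saccharide_components()]; absent
#'   components are NA.
#' @export
#' @examples
#' convert_overseas(list(mono_equiv = TRUE, sucrose = 10, glucose = 10))
convert_overseas <- function(entry) {
  if (is.data.frame(entry)) entry <- as.list(entry[1, , drop = FALSE])
  comps <- saccharide_components()
  vals <- vapply(comps, function(cc) {
    v <- entry[[cc]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  if (isTRUE(entry$mono_equiv)) {
    di <- disaccharide_components()
    vals[di] <- vals[di] * 0.95
  }
  vals
}

#' Nutrient content of a recipe product per 100 g
#'
#' content = sum(ingredient content * ingredient weight) / yield weight.
#' Cooking losses concentrate (yield < total raw weight) or dilute the
#' product.
#'
#' @param recipe a list with `ingredients` (data.frame with columns
#'   `ingredient`, `weight_g`) and `yield_g` (> 0).
#' @param db composition table holding the ingredient contents.
#' @param components columns of `db` to aggregate.
#' @return Named numeric vector of per-100 g contents.
#' @export
compute_from_recipe <- function(recipe, db,
                                components = saccharide_components()) {
  ing <- recipe$ingredients
  if (is.null(ing) || !nrow(ing)) {
    ss_stop("invariant_error", "recipe has no ingredients")
  }
  if (is.null(recipe$yield_g) || recipe$yield_g <= 0) {
    ss_stop("invariant_error", "recipe yield must be positive")
  }
  if (any(ing$weight_g <= 0)) {
    ss_stop("invariant_error", "ingredient weights must be positive")
  }
  idx <- match(ing$ingredient, db$code)
  if (anyNA(idx)) {
    ss_stop("dependency_error",
            sprintf("recipe ingredient(s) not in table: %s",
                    paste(ing$ingredient[is.na(idx)], collapse = ", ")))
  }
  m <- as.matrix(db[idx, components, drop = FALSE])
  if (anyNA(m)) {
    ss_stop("dependency_error",
            sprintf("recipe ingredient(s) without assigned values: %s",
                    paste(unique(ing$ingredient[apply(is.na(m), 1, any)]),
                          collapse = ", ")))
  }
  out <- colSums(m * ing$weight_g) / recipe$yield_g
  names(out) <- components
  out
}

## ---- internal cascade machinery ---------------------------------------

## recipes long format -> named list of recipe objects
split_recipes <- function(recipes) {
  if (is.null(recipes) || !nrow(recipes)) return(list())
  out <- lapply(split(recipes, recipes$product), function(r) {
    list(product = r$product[1],
         ingredients = data.frame(ingredient = r$ingredient,
                                  weight_g = r$weight_g),
         yield_g = r$yield_g[1])
  })
  out
}

## cycle check over product -> ingredient edges restricted to products
check_recipe_acyclic <- function(recipe_list) {
  products <- names(recipe_list)
  state <- stats::setNames(integer(length(products)), products)  # 0/1/2
  visit <- function(p) {
    if (state[[p]] == 1L) {
      ss_stop("cycle_error",
              sprintf("cyclic recipe dependency involving '%s'", p))
    }
    if (state[[p]] == 2L) return(invisible())
    state[[p]] <<- 1L
    deps <- intersect(recipe_list[[p]]$ingredients$ingredient, products)
    for (d in deps) visit(d)
    state[[p]] <<- 2L
    invisible()
  }
  for (p in products) visit(p)
  invisible(TRUE)
}

cap_values <- function(vals, cap, enable) {
  if (!enable) return(vals)
  pmin(vals, cap)
}

## literature long format -> representative values for one family
literature_wide <- function(literature, components, config) {
  if (is.null(literature) || !nrow(literature)) return(NULL)
  lit <- literature[literature$component %in% components, , drop = FALSE]
  if (!nrow(lit)) return(NULL)
  agg <- function(code, values) {
    method <- config$aggregation
    ov <- config$aggregation_overrides
    if (!is.null(ov) && code %in% names(ov)) method <- ov[[code]]
    aggregate_representative(values, method)
  }
  res <- lapply(split(lit, lit$code), function(d) {
    vapply(split(d$value, d$component), function(v) {
      agg(d$code[1], v)
    }, numeric(1))
  })
  res
}

## pick one overseas country per code by priority; wide per-code profile
overseas_profiles <- function(overseas, components, config) {
  if (is.null(overseas) || !nrow(overseas)) return(NULL)
  ovs <- overseas[overseas$component %in% components, , drop = FALSE]
  if (!nrow(ovs)) return(NULL)
  lapply(split(ovs, ovs$code), function(d) {
    pr <- match(d$country, config$overseas_priority)
    pr[is.na(pr)] <- length(config$overseas_priority) + 1L
    ctry <- d$country[order(pr)][1]
    d <- d[d$country == ctry, , drop = FALSE]
    entry <- as.list(stats::setNames(d$value, d$component))
    entry$mono_equiv <- isTRUE(d$mono_equiv[1])
    entry
  })
}

## ---- the two public cascades ------------------------------------------

#' Assign complete saccharide profiles to every item
#'
#' Runs the stepwise cascade over items lacking a complete profile,
#' records provenance and the step at which each item was resolved, and
#' finishes with an all-zero capped fallback for items no source can
#' resolve (returned in `attr(, "exceptions")`, never silently
#' dropped). Items already assigned at step k are never overwritten at
#' a later step.
#'
#' @param db composition table (see [composition_columns()]).
#' @param literature data.frame `code, component, value, source_id`.
#' @param links data.frame `target, reference, relation` with relation
#'   `same_food_other_form` or `similar_food`.
#' @param recipes data.frame `product, ingredient, weight_g, yield_g`.
#' @param overseas data.frame `code, country, component, value,
#'   mono_equiv`.
#' @param config an [assignment_config()].
#' @return `db` with complete profiles, `provenance`, `assign_step` and
#'   `total_sugar` columns; unresolved codes in `attr(, "exceptions")`.
#' @export
assign_saccharides <- function(db, literature = NULL, links = NULL,
                               recipes = NULL, overseas = NULL,
                               config = assignment_config()) {
  comps <- saccharide_components()
  db$provenance <- NA_character_
  db$assign_step <- NA_integer_
  avail <- available_carbohydrate(db)
  assigned <- rep(FALSE, nrow(db))

  set_item <- function(i, vals, source, step) {
    vals <- cap_values(pmax(vals, 0), avail[i], config$cap_to_available &&
                         source != "STFCJ_ANALYTICAL")
    db[i, comps] <<- as.list(vals)
    db$provenance[i] <<- source
    db$assign_step[i] <<- step
    assigned[i] <<- TRUE
  }

  recipe_list <- split_recipes(recipes)
  if (length(recipe_list)) check_recipe_acyclic(recipe_list)

  step_no <- 0L
  for (step in config$order) {
    step_no <- step_no + 1L
    todo <- which(!assigned)
    if (!length(todo)) break
    switch(step,
      analytical = {
        hit <- todo[has_complete_profile(db[todo, , drop = FALSE])]
        for (i in hit) {
          db$provenance[i] <- "STFCJ_ANALYTICAL"
          db$assign_step[i] <- step_no
          assigned[i] <- TRUE
        }
      },
      zero_carb = {
        hit <- todo[avail[todo] == 0]
        for (i in hit) {
          set_item(i, stats::setNames(numeric(7), comps),
                   "ZERO_FALLBACK", step_no)
        }
      },
      literature = {
        lw <- literature_wide(literature, comps, config)
        if (!is.null(lw)) {
          hit <- todo[db$code[todo] %in% names(lw)]
          for (i in hit) {
            vals <- stats::setNames(numeric(7), comps)
            got <- lw[[db$code[i]]]
            vals[names(got)] <- got
            set_item(i, vals, "LITERATURE", step_no)
          }
        }
      },
      same_form = ,
      similar = {
        rel <- if (step == "same_form") "same_food_other_form" else
          "similar_food"
        src <- if (step == "same_form") "SAME_FOOD_OTHER_FORM" else
          "SIMILAR_FOOD"
        lk <- if (is.null(links)) NULL else
          links[links$relation == rel, , drop = FALSE]
        if (!is.null(lk) && nrow(lk)) {
          repeat {
            progress <- FALSE
            for (r in seq_len(nrow(lk))) {
              ti <- match(lk$target[r], db$code)
              ri <- match(lk$reference[r], db$code)
              if (is.na(ti) || is.na(ri)) next
              if (assigned[ti] || !assigned[ri]) next
              dr <- dry_weight(db$water[ri])
              if (dr == 0) next  # skip this step for this item
              vals <- scale_to_form(unlist(db[ri, comps]), dr,
                                    dry_weight(db$water[ti]))
              set_item(ti, vals, src, step_no)
              progress <- TRUE
            }
            if (!progress) break
          }
        }
      },
      recipe = {
        if (length(recipe_list)) {
          repeat {
            progress <- FALSE
            for (rc in recipe_list) {
              ti <- match(rc$product, db$code)
              if (is.na(ti) || assigned[ti]) next
              ii <- match(rc$ingredients$ingredient, db$code)
              if (anyNA(ii) || !all(assigned[ii])) next
              vals <- compute_from_recipe(rc, db, comps)
              set_item(ti, vals, "RECIPE", step_no)
              progress <- TRUE
            }
            if (!progress) break
          }
        }
      },
      overseas = {
        op <- overseas_profiles(overseas, comps, config)
        if (!is.null(op)) {
          hit <- todo[db$code[todo] %in% names(op)]
          for (i in hit) {
            vals <- convert_overseas(op[[db$code[i]]])
            vals[is.na(vals)] <- 0
            set_item(i, vals, "OVERSEAS_DB", step_no)
          }
        }
      }
    )
  }

  exceptions <- db$code[!assigned]
  for (i in which(!assigned)) {
    set_item(i, stats::setNames(numeric(7), comps), "ZERO_FALLBACK",
             step_no + 1L)
  }
  db$total_sugar <- row_total_sugar(db)
  attr(db, "exceptions") <- exceptions
  db
}

#' Assign starch to every item
#'
#' Same cascade as [assign_saccharides()] for the source-based steps,
#' then two closing steps: starch = max(0, available carbohydrate -
#' total sugar) for remaining items with available carbohydrate > 0
#' (provenance `CARB_DIFFERENCE`), and starch = 0 for the rest
#' (`ZERO_FALLBACK`). Requires complete saccharide profiles (run
#' [assign_saccharides()] first).
#'
#' @inheritParams assign_saccharides
#' @return `db` with `starch`, `starch_provenance` and
#'   `starch_assign_step` filled for every item.
#' @export
assign_starch <- function(db, literature = NULL, links = NULL,
                          recipes = NULL, overseas = NULL,
                          config = assignment_config()) {
  if (!all(has_complete_profile(db))) {
    ss_stop("dependency_error",
            "assign_saccharides must run before assign_starch")
  }
  ts <- row_total_sugar(db)
  avail <- available_carbohydrate(db)
  db$starch_provenance <- NA_character_
  db$starch_assign_step <- NA_integer_
  assigned <- rep(FALSE, nrow(db))

  set_item <- function(i, val, source, step) {
    val <- cap_values(max(val, 0), avail[i], source != "STFCJ_ANALYTICAL")
    db$starch[i] <<- val
    db$starch_provenance[i] <<- source
    db$starch_assign_step[i] <<- step
    assigned[i] <<- TRUE
  }

  recipe_list <- split_recipes(recipes)
  if (length(recipe_list)) check_recipe_acyclic(recipe_list)
  lw <- literature_wide(literature, "starch", config)
  op <- overseas_profiles(overseas, "starch", config)

  step_no <- 0L
  for (step in setdiff(config$order, "zero_carb")) {
    step_no <- step_no + 1L
    todo <- which(!assigned)
    if (!length(todo)) break
    switch(step,
      analytical = {
        hit <- todo[!is.na(db$starch[todo])]
        for (i in hit) {
          db$starch_provenance[i] <- "STFCJ_ANALYTICAL"
          db$starch_assign_step[i] <- step_no
          assigned[i] <- TRUE
        }
      },
      literature = {
        if (!is.null(lw)) {
          hit <- todo[db$code[todo] %in% names(lw)]
          for (i in hit) {
            set_item(i, lw[[db$code[i]]][["starch"]], "LITERATURE",
                     step_no)
          }
        }
      },
      same_form = ,
      similar = {
        rel <- if (step == "same_form") "same_food_other_form" else
          "similar_food"
        src <- if (step == "same_form") "SAME_FOOD_OTHER_FORM" else
          "SIMILAR_FOOD"
        lk <- if (is.null(links)) NULL else
          links[links$relation == rel, , drop = FALSE]
        if (!is.null(lk) && nrow(lk)) {
          repeat {
            progress <- FALSE
            for (r in seq_len(nrow(lk))) {
              ti <- match(lk$target[r], db$code)
              ri <- match(lk$reference[r], db$code)
              if (is.na(ti) || is.na(ri)) next
              if (assigned[ti] || !assigned[ri]) next
              dr <- dry_weight(db$water[ri])
              if (dr == 0) next
              set_item(ti, scale_to_form(db$starch[ri], dr,
                                         dry_weight(db$water[ti])),
                       src, step_no)
              progress <- TRUE
            }
            if (!progress) break
          }
        }
      },
      recipe = {
        if (length(recipe_list)) {
          repeat {
            progress <- FALSE
            for (rc in recipe_list) {
              ti <- match(rc$product, db$code)
              if (is.na(ti) || assigned[ti]) next
              ii <- match(rc$ingredients$ingredient, db$code)
              if (anyNA(ii) || !all(assigned[ii])) next
              val <- compute_from_recipe(rc, db, "starch")
              set_item(ti, val[["starch"]], "RECIPE", step_no)
              progress <- TRUE
            }
            if (!progress) break
          }
        }
      },
      overseas = {
        if (!is.null(op)) {
          hit <- todo[db$code[todo] %in% names(op)]
          for (i in hit) {
            set_item(i, op[[db$code[i]]][["starch"]], "OVERSEAS_DB",
                     step_no)
          }
        }
      }
    )
  }

  # Step 7: carbohydrate difference where available carbohydrate > 0
  step_no <- step_no + 1L
  for (i in which(!assigned & avail > 0)) {
    set_item(i, avail[i] - ts[i], "CARB_DIFFERENCE", step_no)
  }
  # Step 8: zero for the remainder
  step_no <- step_no + 1L
  for (i in which(!assigned)) {
    set_item(i, 0, "ZERO_FALLBACK", step_no)
  }
  db
}

#' Provenance counts and percentages
#'
#' Counts items per assignment source for one nutrient family, with the
#' percentage denominator either the whole table or a caller-supplied
#' subset (for example, the subset whose values trace back to in-table
#' saccharide information).
#'
#' @param db assigned composition table.
#' @param family `"saccharide"` or `"starch"`.
#' @param subset optional character vector of codes (or logical vector)
#'   restricting both counts and the percentage denominator.
#' @return data.frame `source, n, pct` over all eight sources; counts
#'   sum to the (subset) table size; percentages rounded half-up to one
#'   decimal.
#' @export
provenance_summary <- function(db, family = c("saccharide", "starch"),
                               subset = NULL) {
  family <- match.arg(family)
  col <- if (family == "saccharide") "provenance" else "starch_provenance"
  if (is.null(db[[col]]) || anyNA(db[[col]])) {
    ss_stop("dependency_error",
            sprintf("table is not fully assigned for family '%s'", family))
  }
  if (!is.null(subset)) {
    keep <- if (is.logical(subset)) subset else db$code %in% subset
    db <- db[keep, , drop = FALSE]
  }
  src <- factor(db[[col]], levels = assignment_sources())
  n <- as.integer(table(src))
  data.frame(source = assignment_sources(), n = n,
             pct = round_half_up(100 * n / nrow(db), 1),
             stringsAsFactors = FALSE)
}
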