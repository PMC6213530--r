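## Free vs. naturally occurring sugar under the WHO definition.
##
## Free sugar: all mono- and disaccharides added by the manufacturer,
## cook or consumer, plus sugars naturally present in honey, syrups,
## fruit juice and fruit juice concentrate. Naturally occurring sugar
## is total sugar minus free sugar (intrinsic fruit sugar, milk
## lactose, ...). The split is decided by an ordered rule tree, first
## match wins; the tree is data (a JSON file), not code.

#' Default free-sugar rule tree
#'
#' Ordered rules, evaluated on food group first, then form, then a name
#' pattern. Outcomes: `NONE_FREE`, `ALL_FREE`, `FRACTION` (share `p` of
#' total sugar is free), `FROM_RECIPE` (free sugar summed over recipe
#' ingredients). Groups whose sugar the WHO definition counts as free
#' regardless of origin (sugars and jams incl. honey and syrups,
#' confectionaries, sugar-sweetened beverages, fruit juices) are
#' `ALL_FREE`; unprocessed plant foods, plain dairy and staple grains
#' are `NONE_FREE`; seasonings (sweetened sauces mixed with naturally
#' sugar-bearing ferments) take `FRACTION(0.5)`, the 50% convention of
#' published stepwise added-sugar methods; composite foods go
#' `FROM_RECIPE`. Unmatched items fall to the configured default
#' fraction and are flagged.
#'
#' @return data.frame with columns `ordinal, groups, forms, name_regex,
#'   outcome, fraction` (`groups`/`forms` are `|`-separated, empty =
#'   any).
#' @export
default_free_sugar_rules <- function() {
  rule <- function(ordinal, groups = "", forms = "", name_regex = "",
                   outcome, fraction = NA_real_) {
    data.frame(ordinal = ordinal, groups = groups, forms = forms,
               name_regex = name_regex, outcome = outcome,
               fraction = fraction, stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    rule(1, groups = paste("sugars and jams", "confectionaries",
                           "sugar-sweetened beverages", "fruit juices",
                           sep = "|"),
         outcome = "ALL_FREE"),
    rule(2, groups = "fruits|vegetables", forms = "raw|cooked",
         outcome = "NONE_FREE"),
    rule(3, groups = paste("dairy products", "rice and grains", "noodle",
                           "potatoes", "pulses and nuts", "mushrooms",
                           "seaweeds", "fish and shellfish", "meats",
                           "eggs", "fat and oil", "vegetable juices",
                           "tea and coffee", "alcoholic beverages",
                           sep = "|"),
         outcome = "NONE_FREE"),
    rule(4, groups = "seasonings", outcome = "FRACTION", fraction = 0.5),
    rule(5, groups = "bread|other grain products|other foods",
         name_regex = "sweet|cake|sugar",
         outcome = "ALL_FREE"),
    rule(6, groups = paste("bread", "other grain products", "other foods",
                           "fruits", "vegetables", sep = "|"),
         outcome = "FROM_RECIPE")
  ))
}

#' Read / write a free-sugar rule file (JSON)
#'
#' @param path file path.
#' @return data.frame of rules (see [default_free_sugar_rules()]).
#' @export
read_free_sugar_rules <- function(path) {
  rules <- jsonlite::fromJSON(path)
  need <- c("ordinal", "outcome")
  miss <- setdiff(need, names(rules))
  if (length(miss)) {
    ss_stop("schema_error",
            sprintf("rule file lacks column(s): %s",
                    paste(miss, collapse = ", ")))
  }
  for (col in c("groups", "forms", "name_regex")) {
    if (is.null(rules[[col]])) rules[[col]] <- ""
    rules[[col]][is.na(rules[[col]])] <- ""
  }
  if (is.null(rules$fraction)) rules$fraction <- NA_real_
  rules[order(rules$ordinal), , drop = FALSE]
}

#' @rdname read_free_sugar_rules
#' @param rules rule data.frame.
#' @export
write_free_sugar_rules <- function(rules, path) {
  jsonlite::write_json(rules, path, dataframe = "rows", na = "null",
                       digits = NA)
  invisible(path)
}

## first matching rule index for one item; NA if none
match_rule <- function(item, rules) {
  for (r in seq_len(nrow(rules))) {
    g <- rules$groups[r]
    if (nzchar(g) &&
        !(item$food_group %in% strsplit(g, "|", fixed = TRUE)[[1]])) next
    f <- rules$forms[r]
    if (nzchar(f) &&
        !(item$form %in% strsplit(f, "|", fixed = TRUE)[[1]])) next
    rx <- rules$name_regex[r]
    if (nzchar(rx) && !grepl(rx, item$name, ignore.case = TRUE)) next
    return(r)
  }
  NA_integer_
}

#' Naturally occurring sugar
#'
#' @param total total sugar, g/100 g.
#' @param free free sugar, g/100 g; must not exceed `total`.
#' @return total - free, g/100 g.
#' @export
#' @examples
#' naturally_occurring(20, 15)  # 5
naturally_occurring <- function(total, free) {
  if (any(free > total + 1e-12) || any(free < 0)) {
    ss_stop("invariant_error", "free sugar outside [0, total sugar]")
  }
  total - free
}

#' Classify free vs. naturally occurring sugar for a whole table
#'
#' Applies the ordered rule tree to every item. `FROM_RECIPE` items are
#' resolved after all direct items, iterating so nested recipes work;
#' their free sugar is the recipe-aggregated free sugar of the
#' ingredients, clamped to the item's own total sugar so conservation
#' (free + naturally occurring = total) holds exactly. Items matching
#' no rule (or `FROM_RECIPE` without a recipe) take
#' `default_fraction` of total sugar as free and are listed in
#' `attr(, "unmatched")`.
#'
#' @param db assigned composition table with a `total_sugar` column (run
#'   [assign_saccharides()] first).
#' @param rules ordered rule data.frame; default
#'   [default_free_sugar_rules()].
#' @param recipes recipe table (`product, ingredient, weight_g,
#'   yield_g`) for `FROM_RECIPE` outcomes.
#' @param default_fraction free share for unmatched items (default 0.5).
#' @return `db` with `free_sugar`, `naturally_occurring_sugar` and
#'   `free_sugar_rule` columns; unmatched codes in `attr(, "unmatched")`.
#' @export
classify_free_sugar <- function(db, rules = default_free_sugar_rules(),
                                recipes = NULL, default_fraction = 0.5) {
  if (is.null(db$total_sugar) || anyNA(db$total_sugar)) {
    db$total_sugar <- row_total_sugar(db)
  }
  if (anyNA(db$total_sugar)) {
    ss_stop("dependency_error",
            "total sugar missing; run assign_saccharides first")
  }
  rules <- rules[order(rules$ordinal), , drop = FALSE]
  n <- nrow(db)
  free <- rep(NA_real_, n)
  rule_id <- rep(NA_integer_, n)
  pending_recipe <- logical(n)
  unmatched <- character(0)

  for (i in seq_len(n)) {
    r <- match_rule(db[i, , drop = FALSE], rules)
    rule_id[i] <- if (is.na(r)) NA_integer_ else rules$ordinal[r]
    out <- if (is.na(r)) "UNMATCHED" else rules$outcome[r]
    ts <- db$total_sugar[i]
    if (out == "NONE_FREE") {
      free[i] <- 0
    } else if (out == "ALL_FREE") {
      free[i] <- ts
    } else if (out == "FRACTION") {
      p <- rules$fraction[r]
      if (is.na(p) || p < 0 || p > 1) {
        ss_stop("config_error",
                sprintf("rule %d: FRACTION needs p in [0, 1]",
                        rules$ordinal[r]))
      }
      free[i] <- p * ts
    } else if (out == "FROM_RECIPE") {
      pending_recipe[i] <- TRUE
    } else {  # UNMATCHED
      unmatched <- c(unmatched, db$code[i])
      free[i] <- default_fraction * db$total_sugar[i]
    }
  }

  recipe_list <- split_recipes(recipes)
  if (any(pending_recipe)) {
    repeat {
      progress <- FALSE
      for (i in which(pending_recipe & is.na(free))) {
        rc <- recipe_list[[db$code[i]]]
        if (is.null(rc)) {
          # composite without a recipe: fall to the default fraction
          unmatched <- c(unmatched, db$code[i])
          free[i] <- default_fraction * db$total_sugar[i]
          progress <- TRUE
          next
        }
        ii <- match(rc$ingredients$ingredient, db$code)
        if (anyNA(ii)) {
          ss_stop("dependency_error",
                  sprintf("recipe for '%s' uses unknown ingredient(s)",
                          db$code[i]))
        }
        if (any(is.na(free[ii]))) next
        tmp <- db
        tmp$free_sugar <- free
        val <- compute_from_recipe(rc, tmp, "free_sugar")[["free_sugar"]]
        free[i] <- min(max(val, 0), db$total_sugar[i])
        progress <- TRUE
      }
      if (!any(pending_recipe & is.na(free))) break
      if (!progress) {
        ss_stop("cycle_error",
                "unresolvable FROM_RECIPE dependency among recipes")
      }
    }
  }

  db$free_sugar <- free
  db$naturally_occurring_sugar <- naturally_occurring(db$total_sugar, free)
  db$free_sugar_rule <- rule_id
  attr(db, "unmatched") <- unique(unmatched)
  db
}
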