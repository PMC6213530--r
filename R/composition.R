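## Core domain arithmetic on the composition table.
##
## A composition table is a plain data.frame, one row per food item,
## with the columns of composition_columns(). All contents are g/100 g
## edible portion; NA is the explicit MISSING sentinel (0 is a measured
## or assigned value, never a stand-in for "unknown").

#' Canonical composition-table columns
#'
#' @param extended if TRUE, include the derived/bookkeeping columns
#'   produced by the assignment and classification stages.
#' @return Character vector of column names in stable order.
#' @export
composition_columns <- function(extended = FALSE) {
  base <- c("code", "name", "food_group", "form",
            "water", "protein", "lipid", "ash", "dietary_fiber",
            "energy", saccharide_components(), "starch", "provenance")
  if (!extended) return(base)
  c(base, "starch_provenance", "assign_step", "starch_assign_step",
    "total_sugar", "free_sugar", "naturally_occurring_sugar",
    "free_sugar_rule")
}

#' Available carbohydrate by difference
#'
#' Carbohydrate by difference is 100 minus water, protein, lipid and
#' ash; available carbohydrate subtracts dietary fiber from it. Small
#' negative results (proximate rounding) are clamped to 0 with a
#' warning.
#'
#' @param db composition table (data.frame) or any data.frame carrying
#'   the proximate columns.
#' @return Numeric vector, g/100 g, never negative.
#' @export
#' @examples
#' db <- data.frame(code = "x", water = 80, protein = 5, lipid = 2,
#'                  ash = 1, dietary_fiber = 2)
#' available_carbohydrate(db)  # 10
available_carbohydrate <- function(db) {
  for (p in proximate_components()) {
    if (is.null(db[[p]])) {
      ss_stop("missing_data_error",
              sprintf("proximate column '%s' is absent", p), field = p)
    }
    bad <- which(is.na(db[[p]]))
    if (length(bad)) {
      ss_stop("missing_data_error",
              sprintf("proximate '%s' is MISSING for item(s): %s", p,
                      paste(utils::head(db$code[bad], 5), collapse = ", ")),
              field = p)
    }
  }
  carb <- 100 - db$water - db$protein - db$lipid - db$ash
  avail <- carb - db$dietary_fiber
  # snap binary representation error of 1-decimal proximates to exact 0
  avail[abs(avail) <= 1e-9] <- 0
  neg <- avail < 0
  if (any(neg)) {
    ss_warn("negative_carbohydrate_warning",
            sprintf("available carbohydrate clamped to 0 for %d item(s)",
                    sum(neg)))
    avail[neg] <- 0
  }
  avail
}

#' Total sugar of a saccharide profile
#'
#' The sum of the seven mono- and disaccharides. All seven components
#' must be present; an incomplete profile signals
#' `incomplete_profile_error` so the assignment cascade can continue
#' with the next source.
#'
#' @param profile named numeric vector, list, or one-row data.frame with
#'   the seven components of [saccharide_components()].
#' @return Total sugar, g/100 g.
#' @export
#' @examples
#' total_sugar(c(glucose = 1, fructose = 2, galactose = 0, sucrose = 3,
#'               maltose = 0, lactose = 0, trehalose = 0))  # 6
total_sugar <- function(profile) {
  comps <- saccharide_components()
  if (is.data.frame(profile)) profile <- as.list(profile[1, , drop = FALSE])
  vals <- vapply(comps, function(cc) {
    v <- profile[[cc]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  if (anyNA(vals)) {
    ss_stop("incomplete_profile_error",
            sprintf("saccharide component(s) MISSING: %s",
                    paste(comps[is.na(vals)], collapse = ", ")))
  }
  if (any(vals < 0)) {
    ss_stop("invariant_error", "negative saccharide component")
  }
  sum(vals)
}

## Row-wise total sugar over a table; NA where the profile is incomplete.
row_total_sugar <- function(db) {
  m <- as.matrix(db[, saccharide_components(), drop = FALSE])
  out <- rowSums(m)
  out[apply(m, 1L, anyNA)] <- NA_real_
  out
}

## TRUE where all seven components are present.
has_complete_profile <- function(db) {
  !apply(is.na(as.matrix(db[, saccharide_components(), drop = FALSE])),
         1L, any)
}

#' Dry weight of an item
#'
#' 100 g minus water content; the scaling basis for transferring values
#' between raw and cooked/processed forms of a food.
#'
#' @param x numeric water content (g/100 g) or a data.frame with a
#'   `water` column.
#' @return Dry weight, g/100 g.
#' @export
#' @examples
#' dry_weight(60)  # 40
dry_weight <- function(x) {
  water <- if (is.data.frame(x)) x$water else x
  if (anyNA(water)) {
    ss_stop("missing_data_error", "water content is MISSING",
            field = "water")
  }
  if (any(water > 100 | water < 0)) {
    ss_stop("invariant_error", "water content outside [0, 100]")
  }
  100 - water
}

#' Validate composition-table invariants
#'
#' Checks the structural invariants: proximate sum at most 100, food
#' groups drawn from the 24 defaults, unique codes, and (when assigned)
#' starch + total sugar within `tolerance` of available carbohydrate.
#' Violations of the carbohydrate budget are reported via warning, not
#' error (composition-table rounding routinely produces small excesses).
#'
#' @param db composition table.
#' @param tolerance g/100 g allowed for starch + total sugar above
#'   available carbohydrate (default 0.5).
#' @return `db`, invisibly.
#' @export
validate_composition <- function(db, tolerance = 0.5) {
  if (anyDuplicated(db$code)) {
    ss_stop("invariant_error", "duplicate item codes in composition table")
  }
  unknown <- setdiff(unique(db$food_group), food_groups())
  if (length(unknown)) {
    ss_stop("invariant_error",
            sprintf("unknown food group(s): %s",
                    paste(unknown, collapse = ", ")))
  }
  psum <- db$water + db$protein + db$lipid + db$ash
  if (any(psum > 100 + 1e-9, na.rm = TRUE)) {
    ss_stop("invariant_error",
            "water + protein + lipid + ash exceeds 100 g/100 g")
  }
  ts <- row_total_sugar(db)
  ok <- !is.na(ts) & !is.na(db$starch)
  if (any(ok)) {
    avail <- available_carbohydrate(db[ok, , drop = FALSE])
    over <- db$starch[ok] + ts[ok] > avail + tolerance
    if (any(over)) {
      ss_warn("carbohydrate_budget_warning",
              sprintf(
                "starch + total sugar exceeds available carbohydrate by > %g g/100 g for %d item(s)",
                tolerance, sum(over)))
    }
  }
  invisible(db)
}
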