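## CSV readers/writers with schema validation. CSV is RFC 4180, UTF-8,
## header required; an empty cell is the MISSING sentinel (NA), which
## round-trips.

read_checked <- function(path, schema, what) {
  if (!file.exists(path)) {
    ss_stop("schema_error", sprintf("%s file not found: %s", what, path))
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character",
                         fileEncoding = "UTF-8")
  miss <- setdiff(names(schema), names(raw))
  if (length(miss)) {
    ss_stop("schema_error",
            sprintf("%s file lacks column(s): %s", what,
                    paste(miss, collapse = ", ")))
  }
  for (col in names(schema)) {
    type <- schema[[col]]
    v <- raw[[col]]
    v[v == ""] <- NA
    if (type == "numeric" || type == "integer") {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad)) {
        ss_stop("parse_error",
                sprintf("%s: non-numeric value '%s' at row %d, column '%s'",
                        what, v[bad[1]], bad[1], col),
                row = bad[1], col = col)
      }
      raw[[col]] <- if (type == "integer") as.integer(num) else num
    } else if (type == "logical") {
      raw[[col]] <- as.logical(v)
    } else {
      raw[[col]] <- v
    }
  }
  raw
}

#' Read / write a composition table CSV
#'
#' Columns are [composition_columns()]; empty cells are MISSING (NA);
#' extra columns produced by later stages round-trip unchanged.
#'
#' @param path file path.
#' @return Composition table data.frame.
#' @export
read_composition <- function(path) {
  base <- composition_columns()
  types <- stats::setNames(rep("numeric", length(base)), base)
  types[c("code", "name", "food_group", "form", "provenance")] <-
    "character"
  tab <- read_checked(path, as.list(types), "composition")
  for (col in intersect(c("starch_provenance", "free_sugar_rule",
                          "assign_step", "starch_assign_step",
                          "total_sugar", "free_sugar",
                          "naturally_occurring_sugar"), names(tab))) {
    if (!col %in% c("starch_provenance")) {
      suppressWarnings(tab[[col]] <- as.numeric(tab[[col]]))
    }
  }
  tab
}

#' @rdname read_composition
#' @param db composition table.
#' @export
write_composition <- function(db, path) {
  utils::write.csv(db, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read auxiliary source tables
#'
#' Literature values (`code, component, value, source_id`), similarity
#' links (`target, reference, relation`), recipes (`product,
#' ingredient, weight_g, yield_g`), overseas entries (`code, country,
#' component, value, mono_equiv`), dietary records (`person_id, day,
#' food_code, amount_g`) and person metadata (`person_id, sex,
#' age_group, age, eer_kcal`).
#'
#' @param path file path.
#' @return data.frame with validated schema.
#' @export
read_literature <- function(path) {
  read_checked(path, list(code = "character", component = "character",
                          value = "numeric", source_id = "character"),
               "literature")
}

#' @rdname read_literature
#' @export
read_links <- function(path) {
  read_checked(path, list(target = "character", reference = "character",
                          relation = "character"), "links")
}

#' @rdname read_literature
#' @export
read_recipes <- function(path) {
  read_checked(path, list(product = "character", ingredient = "character",
                          weight_g = "numeric", yield_g = "numeric"),
               "recipes")
}

#' @rdname read_literature
#' @export
read_overseas <- function(path) {
  read_checked(path, list(code = "character", country = "character",
                          component = "character", value = "numeric",
                          mono_equiv = "logical"), "overseas")
}

#' @rdname read_literature
#' @export
read_records <- function(path) {
  read_checked(path, list(person_id = "character", day = "integer",
                          food_code = "character", amount_g = "numeric"),
               "records")
}

#' @rdname read_literature
#' @export
read_persons <- function(path) {
  read_checked(path, list(person_id = "character", sex = "character",
                          age_group = "character", age = "numeric",
                          eer_kcal = "numeric"), "persons")
}

## FNV-1a over a string; cheap stable fingerprint for config provenance
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
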