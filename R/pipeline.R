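## Umbrella pipeline: build database -> classify free sugar -> intakes
## -> habitual distributions -> contributions, with a JSON-able report.

#' Pipeline configuration
#'
#' Schema-validated before any stage runs; unknown keys are rejected.
#'
#' @param seed integer seed (used only by generator-driven runs; the
#'   pipeline itself is deterministic).
#' @param energy_factor kcal per gram of carbohydrate for %E (default
#'   4, Atwater).
#' @param thresholds WHO free-sugar thresholds, %E (closed, `>=`).
#' @param cascade an [assignment_config()].
#' @param rules free-sugar rule tree (data.frame) or path to a JSON
#'   rule file; NULL for [default_free_sugar_rules()].
#' @param default_fraction free share for unmatched items.
#' @param other_threshold contribution display threshold (%) below
#'   which groups collapse into "others" (default 7).
#' @param lambda_grid grid for the best-power search.
#' @param rounding decimals for reported summaries.
#' @param verbose print stage progress.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, energy_factor = 4,
                            thresholds = c(10, 5),
                            cascade = assignment_config(),
                            rules = NULL, default_fraction = 0.5,
                            other_threshold = 7,
                            lambda_grid = seq(-2, 2, by = 0.01),
                            rounding = 1, verbose = FALSE) {
  cfg <- structure(list(seed = as.integer(seed),
                        energy_factor = energy_factor,
                        thresholds = thresholds, cascade = cascade,
                        rules = rules,
                        default_fraction = default_fraction,
                        other_threshold = other_threshold,
                        lambda_grid = lambda_grid, rounding = rounding,
                        verbose = isTRUE(verbose)),
                   class = "pipeline_config")
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  known <- c("seed", "energy_factor", "thresholds", "cascade", "rules",
             "default_fraction", "other_threshold", "lambda_grid",
             "rounding", "verbose")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    ss_stop("config_error",
            sprintf("unknown config key(s): %s",
                    paste(unknown, collapse = ", ")))
  }
  if (cfg$energy_factor <= 0) {
    ss_stop("config_error", "energy_factor must be positive")
  }
  if (length(cfg$thresholds) != 2 || any(cfg$thresholds <= 0)) {
    ss_stop("config_error", "thresholds must be two positive %E values")
  }
  cfg
}

stage_log <- function(cfg, report, stage, ...) {
  msg <- sprintf(...)
  if (cfg$verbose) message(sprintf("[%s] %s", stage, msg))
  report$log <- c(report$log, sprintf("[%s] %s", stage, msg))
  report
}

round_cfg <- function(x, cfg) round_half_up(x, cfg$rounding)

#' Run the full pipeline
#'
#' build-db -> classify-free-sugar -> estimate-intake -> habitual ->
#' contributions. Inputs may be in-memory data.frames or CSV paths.
#' Habitual distributions are estimated per nutrient within each
#' age-sex stratum and skipped (marked `not estimated`) for strata
#' recorded on a single day, for whom day-to-day variance is not
#' estimable.
#'
#' @param composition composition table or path.
#' @param persons person metadata or path.
#' @param records dietary records or path.
#' @param literature,links,recipes,overseas auxiliary sources or paths
#'   (optional).
#' @param config a [pipeline_config()].
#' @return Nested report list (JSON-serialisable): provenance,
#'   stratified intake summaries, EI/EER, WHO adherence (habitual where
#'   estimable), food-group contributions, per-stage log, config hash.
#' @export
run_pipeline <- function(composition, persons, records,
                         literature = NULL, links = NULL, recipes = NULL,
                         overseas = NULL, config = pipeline_config()) {
  config <- validate_pipeline_config(config)
  load_maybe <- function(x, reader) {
    if (is.character(x) && length(x) == 1) reader(x) else x
  }
  db <- load_maybe(composition, read_composition)
  persons <- load_maybe(persons, read_persons)
  records <- load_maybe(records, read_records)
  literature <- load_maybe(literature, read_literature)
  links <- load_maybe(links, read_links)
  recipes <- load_maybe(recipes, read_recipes)
  overseas <- load_maybe(overseas, read_overseas)
  rules <- config$rules
  if (is.null(rules)) rules <- default_free_sugar_rules()
  if (is.character(rules)) rules <- read_free_sugar_rules(rules)

  report <- list(log = character(0))
  report$config_hash <-
    fnv1a(jsonlite::toJSON(config[c("seed", "energy_factor",
                                    "thresholds", "rounding")],
                           auto_unbox = TRUE, digits = NA))

  # -- build-db
  db <- assign_saccharides(db, literature, links, recipes, overseas,
                           config$cascade)
  exceptions <- attr(db, "exceptions")
  db <- assign_starch(db, literature, links, recipes, overseas,
                      config$cascade)
  report <- stage_log(config, report, "build-db",
                      "%d items assigned, %d exception(s)",
                      nrow(db), length(exceptions))
  report$exceptions <- exceptions
  report$provenance <- list(
    saccharide = provenance_summary(db, "saccharide"),
    starch = provenance_summary(db, "starch"))

  # -- classify-free-sugar
  db <- classify_free_sugar(db, rules, recipes, config$default_fraction)
  report <- stage_log(config, report, "classify-free-sugar",
                      "%d item(s) unmatched by the rule tree",
                      length(attr(db, "unmatched")))
  report$unmatched_rules <- attr(db, "unmatched")

  # -- estimate-intake
  daily <- compute_daily_intake(records, db)
  pi <- person_intake(daily, persons, config$energy_factor)
  report <- stage_log(config, report, "estimate-intake",
                      "%d persons, %d person-days", nrow(pi), nrow(daily))

  strata <- split(pi, list(pi$age_group, pi$sex), drop = TRUE)
  summarise_stratum <- function(s) {
    nut <- intake_nutrients()
    out <- list(n = nrow(s),
                n_days = unique(s$n_days),
                energy = list(mean = round_cfg(mean(s$energy), config),
                              sd = round_cfg(stats::sd(s$energy), config)),
                ei_eer = round_half_up(mean(s$ei_eer), 2))
    for (v in nut) {
      out[[v]] <- list(
        mean = round_cfg(mean(s[[v]]), config),
        sd = round_cfg(stats::sd(s[[v]]), config),
        pctE_mean = round_cfg(mean(s[[paste0(v, "_pctE")]]), config),
        pctE_sd = round_cfg(stats::sd(s[[paste0(v, "_pctE")]]), config))
    }
    out
  }
  report$strata <- lapply(strata, summarise_stratum)

  # -- habitual (multi-day strata only)
  daily$age_group <- persons$age_group[match(daily$person_id,
                                             persons$person_id)]
  daily$sex <- persons$sex[match(daily$person_id, persons$person_id)]
  hab_nutrients <- c("starch", "total_sugar", "free_sugar")
  report$habitual <- list()
  report$who_adherence <- list()
  for (key in names(strata)) {
    s <- strata[[key]]
    dsub <- daily[daily$person_id %in% s$person_id, , drop = FALSE]
    multi_day <- max(s$n_days) >= 2
    if (!multi_day) {
      report$habitual[[key]] <- "not estimated (1-day records)"
      # adherence falls back to the observed single-day %E
      adh <- who_adherence(s$free_sugar_pctE)
    } else {
      hsec <- list()
      for (v in hab_nutrients) {
        keep <- dsub[[v]] > 0
        model <- fit_habitual(dsub[[v]][keep], dsub$person_id[keep],
                              grid = config$lambda_grid)
        hsec[[v]] <- list(lambda = model$lambda,
                          sigma2_between = model$sigma2_b,
                          sigma2_within = model$sigma2_w)
      }
      # habitual free-sugar %E for WHO adherence
      pe <- percent_energy(dsub$free_sugar, dsub$energy,
                           config$energy_factor)
      keep <- pe > 0
      model <- fit_habitual(pe[keep], dsub$person_id[keep],
                            grid = config$lambda_grid)
      est <- habitual_estimates(model)
      hsec$free_sugar_pctE <- list(lambda = model$lambda,
                                   sigma2_between = model$sigma2_b,
                                   sigma2_within = model$sigma2_w)
      report$habitual[[key]] <- hsec
      adh <- who_adherence(est$habitual)
    }
    report$who_adherence[[key]] <-
      list(ge10_pct = adh$ge10, ge5_pct = adh$ge5)
  }
  report <- stage_log(config, report, "habitual",
                      "estimated for %d stratum/strata",
                      sum(vapply(report$habitual, is.list, logical(1))))

  # -- contributions (both sexes combined, per nutrient)
  report$contributions <- lapply(
    stats::setNames(nm = c("available_carbohydrate", "starch",
                           "total_sugar", "sucrose", "fructose",
                           "naturally_occurring_sugar", "free_sugar")),
    function(v) {
      ct <- contribution_by_group(records, db, v,
                                  other_threshold = config$other_threshold)
      ct$pct <- round_cfg(ct$pct, config)
      ct
    })
  report <- stage_log(config, report, "contributions", "done")

  report$db <- db
  report$person_intake <- pi
  report
}

#' Write a pipeline report to JSON
#'
#' Drops the bulky data.frame members (`db`, `person_intake`) and
#' serialises the rest.
#'
#' @param report output of [run_pipeline()].
#' @param path output path.
#' @export
write_report <- function(report, path) {
  slim <- report[setdiff(names(report), c("db", "person_intake"))]
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}
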