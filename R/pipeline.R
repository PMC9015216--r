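#' Ingest and cross-validate the four analysis tables
#'
#' Checks that recruit identifiers are unique, that every natal and breeding
#' box exists in the registry, that morph / sex / age levels are parseable,
#' and that every hatch year has a winter anomaly. All problems are itemized
#' in a single validation error. Rows missing any model variable are flagged
#' (`complete` column) but kept; the complete-case subset is what the models
#' consume.
#'
#' @param registry A `box_registry` (or a data frame plus `era_cutoff_year`).
#' @param recruits Recruit table with `recruit_id`, `natal_box_id`,
#'   `breeding_box_id`, `hatch_year`, `sex`, `morph`, `body_mass_g`,
#'   `age_at_recruitment`, `brood_id`.
#' @param winters Winter covariates: `winter_year`, `anomaly_c`.
#' @param prey Prey table: `year` and `prey_index` (or `captures` +
#'   `trap_nights`, from which the index is computed).
#' @param era_cutoff_year Needed only when `registry` is a bare data frame.
#' @return A validated list of class `owl_bundle` whose `recruits` table
#'   carries `dispersal_km`, `anomaly_c`, `prey_index` and a logical
#'   `complete` flag.
#' @export
ingest_bundle <- function(registry, recruits, winters, prey,
                          era_cutoff_year = NULL) {
  if (!inherits(registry, "box_registry")) {
    if (is.null(era_cutoff_year)) {
      stop("supply era_cutoff_year when registry is a bare data frame",
           call. = FALSE)
    }
    registry <- box_registry(registry, era_cutoff_year)
  }
  recruits <- tibble::as_tibble(recruits)
  winters <- tibble::as_tibble(winters)
  prey <- tibble::as_tibble(prey)

  problems <- character(0)
  note <- function(...) problems <<- c(problems, paste0(...))

  if (nrow(recruits) == 0) stop("recruit table is empty", call. = FALSE)
  dup <- unique(recruits$recruit_id[duplicated(recruits$recruit_id)])
  if (length(dup) > 0) note("duplicate recruit_id: ", paste(dup, collapse = ", "))

  for (col in c("natal_box_id", "breeding_box_id")) {
    bad <- setdiff(unique(as.character(recruits[[col]])), registry$box_id)
    bad <- bad[!is.na(bad)]
    if (length(bad) > 0) note(col, " not in registry: ", paste(bad, collapse = ", "))
  }
  bad_morph <- setdiff(unique(as.character(recruits$morph)), c("gray", "brown", NA))
  if (length(bad_morph) > 0) note("unparseable morph level(s): ",
                                  paste(bad_morph, collapse = ", "))
  bad_sex <- setdiff(unique(as.character(recruits$sex)), c("female", "male", NA))
  if (length(bad_sex) > 0) note("unparseable sex level(s): ",
                                paste(bad_sex, collapse = ", "))
  bad_age <- setdiff(unique(as.character(recruits$age_at_recruitment)),
                     c("1", "2", "3+", NA))
  if (length(bad_age) > 0) note("unparseable age level(s): ",
                                paste(bad_age, collapse = ", "))
  missing_winters <- setdiff(unique(recruits$hatch_year), winters$winter_year)
  if (length(missing_winters) > 0) {
    note("no winter anomaly for hatch year(s): ",
         paste(missing_winters, collapse = ", "))
  }
  if (length(problems) > 0) {
    stop("bundle validation failed:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }

  if (!"prey_index" %in% names(prey)) {
    prey$prey_index <- prey_index(prey$captures, prey$trap_nights)
  }
  recruits <- dispersal_distances(recruits, registry) |>
    dplyr::left_join(dplyr::select(winters, "winter_year", "anomaly_c"),
                     by = c(hatch_year = "winter_year")) |>
    dplyr::left_join(dplyr::select(prey, "year", "prey_index"),
                     by = c(hatch_year = "year"))
  model_vars <- c("dispersal_km", "morph", "sex", "body_mass_g",
                  "age_at_recruitment", "anomaly_c", "prey_index", "brood_id")
  recruits$complete <- stats::complete.cases(recruits[, model_vars])

  structure(list(registry = registry, recruits = recruits,
                 winters = winters, prey = prey),
            class = "owl_bundle")
}

# round-half-up to `digits` decimals (R's round() is round-half-even)
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Descriptive statistics of a recruit table
#'
#' Mean, SD, minimum and maximum dispersal distance overall and by sex and
#' morph, plus age-class counts with percentages (rounded half-up to one
#' decimal). With a single recruit the SD is reported as missing.
#'
#' @param recruits Recruit table carrying `dispersal_km` (plus `sex`,
#'   `morph`, `age_at_recruitment` where present).
#' @return A list of tibbles: `overall`, `by_sex`, `by_morph`, `age_classes`.
#' @export
descriptives <- function(recruits) {
  recruits <- tibble::as_tibble(recruits)
  stopifnot("dispersal_km" %in% names(recruits))
  summarise_disp <- function(d) {
    tibble::tibble(n = nrow(d),
                   mean_km = mean(d$dispersal_km),
                   sd_km = stats::sd(d$dispersal_km),
                   min_km = min(d$dispersal_km),
                   max_km = max(d$dispersal_km))
  }
  out <- list(overall = summarise_disp(recruits))
  if ("sex" %in% names(recruits)) {
    out$by_sex <- recruits |>
      dplyr::filter(!is.na(.data$sex)) |>
      dplyr::group_by(sex = .data$sex) |>
      dplyr::group_modify(~summarise_disp(.x)) |>
      dplyr::ungroup()
  }
  if ("morph" %in% names(recruits)) {
    out$by_morph <- recruits |>
      dplyr::filter(!is.na(.data$morph)) |>
      dplyr::group_by(morph = .data$morph) |>
      dplyr::group_modify(~summarise_disp(.x)) |>
      dplyr::ungroup()
  }
  if ("age_at_recruitment" %in% names(recruits)) {
    ages <- recruits |> dplyr::filter(!is.na(.data$age_at_recruitment))
    out$age_classes <- ages |>
      dplyr::count(age = .data$age_at_recruitment) |>
      dplyr::mutate(pct = round_half_up(100 * .data$n / sum(.data$n), 1))
    if (sum(out$age_classes$n) != nrow(ages)) {
      stop("internal partition check failed: age-class counts do not sum",
           call. = FALSE)
    }
  }
  out
}

#' Run the full dispersal analysis pipeline
#'
#' Orchestrates ingest -> descriptives -> yearly morph-proportion GLM ->
#' dispersal mixed models (all-ages and one-year-old analysis sets) ->
#' randomization test of observed vs detectable median dispersal (overall
#' and per morph). Any stage failure aborts with the stage name. With
#' `out_dir` set, tabular results are written as CSV plus a machine-readable
#' JSON report embedding the configuration and input checksums.
#'
#' @param bundle An `owl_bundle` from [ingest_bundle()] or
#'   [simulate_population()].
#' @param reps Randomization repetitions (default 999).
#' @param seed Seed for the randomization draws (mandatory; no silent clock
#'   seeding).
#' @param tail Tail of the randomization test.
#' @param sets Analysis sets to fit.
#' @param by_morph Also run morph-stratified randomization tests?
#' @param out_dir Optional output directory.
#' @return A list of class `dispersal_report` with elements `descriptives`,
#'   `counts`, `glm`, `lmm`, `randomization`, `config`.
#' @export
run_dispersal_pipeline <- function(bundle, reps = 999, seed,
                                   tail = c("lower", "upper", "two.sided"),
                                   sets = c("all_ages", "one_year_olds"),
                                   by_morph = TRUE, out_dir = NULL) {
  tail <- match.arg(tail)
  sets <- match.arg(sets, several.ok = TRUE)
  if (missing(seed) || !is.numeric(seed)) {
    stop("a numeric seed is required for reproducibility", call. = FALSE)
  }
  t0 <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    st <- Sys.time()
    res <- tryCatch(force(expr), error = function(e) {
      if (!is.null(out_dir)) {
        dir.create(file.path(out_dir, "failed"), recursive = TRUE,
                   showWarnings = FALSE)
      }
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), st, units = "secs"))
    res
  }

  bundle <- stage("ingest", {
    if (!inherits(bundle, "owl_bundle") || !"complete" %in% names(bundle$recruits)) {
      ingest_bundle(bundle$registry, bundle$recruits, bundle$winters, bundle$prey)
    } else bundle
  })
  recruits <- bundle$recruits

  desc <- stage("descriptives", descriptives(recruits))
  counts <- list(
    n_recruits = nrow(recruits),
    n_complete = sum(recruits$complete),
    n_morph_known = sum(!is.na(recruits$morph)),
    n_by_morph = table(recruits$morph)
  )

  glm_fit <- stage("morph_proportion_glm",
                   fit_brown_proportion_glm(
                     yearly_morph_proportions(recruits, bundle$winters)))

  lmm_fits <- stage("dispersal_lmm", {
    out <- list()
    for (s in sets) out[[s]] <- fit_dispersal_lmm(recruits, set = s)
    out
  })

  rand <- stage("randomization",
                dispersal_null_test(recruits, bundle$registry, m = reps,
                                    tail = tail, by_morph = by_morph,
                                    seed = seed))

  config <- list(reps = reps, seed = seed, tail = tail, sets = sets,
                 by_morph = by_morph,
                 config_hash = rlang::hash(list(reps, seed, tail, sets, by_morph)),
                 input_checksums = list(
                   registry = rlang::hash(tibble::as_tibble(bundle$registry)),
                   recruits = rlang::hash(bundle$recruits),
                   winters = rlang::hash(bundle$winters),
                   prey = rlang::hash(bundle$prey)))

  report <- structure(
    list(descriptives = desc, counts = counts, glm = glm_fit, lmm = lmm_fits,
         randomization = rand, config = config,
         timings = timings,
         elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "dispersal_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a pipeline report to disk
#'
#' Writes per-set coefficient / term-test / variance-component CSVs, the
#' randomization summary and raw null medians, a descriptives JSON, a
#' machine-readable report JSON (config hash and input checksums included),
#' and a run log with seed, package versions, and stage timings.
#'
#' @param report A `dispersal_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(report$lmm)) {
    fit <- report$lmm[[s]]
    readr::write_csv(fit$coefficients, file.path(dir, paste0("lmm_", s, "_coefficients.csv")))
    readr::write_csv(fit$anova, file.path(dir, paste0("lmm_", s, "_terms.csv")))
    readr::write_csv(fit$varcomp, file.path(dir, paste0("lmm_", s, "_varcomp.csv")))
  }
  readr::write_csv(tidy(report$randomization), file.path(dir, "randomization.csv"))
  nulls <- purrr::imap(report$randomization, function(r, nm) {
    tibble::tibble(stratum = nm, null_median_km = r$random_medians)
  }) |> dplyr::bind_rows()
  readr::write_csv(nulls, file.path(dir, "randomization_null_medians.csv"))
  readr::write_csv(glance(report$glm), file.path(dir, "morph_proportion_glm.csv"))
  jsonlite::write_json(report$descriptives, file.path(dir, "descriptives.json"),
                       auto_unbox = TRUE, digits = NA)
  machine <- list(
    config = report$config,
    counts = lapply(report$counts, function(x) if (is.table(x)) as.list(x) else x),
    glm = as.list(glance(report$glm)),
    lmm = lapply(report$lmm, function(f) list(
      n_used = f$n_used, n_dropped = f$n_dropped,
      coefficients = f$coefficients, terms = f$anova, varcomp = f$varcomp,
      fixef_vcov = as.matrix(stats::vcov(f$fit)))),
    randomization = tidy(report$randomization))
  jsonlite::write_json(machine, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  log_lines <- c(
    paste0("seed: ", report$config$seed),
    paste0("R: ", R.version.string),
    paste0("lme4: ", as.character(utils::packageVersion("lme4"))),
    paste0("lmerTest: ", as.character(utils::packageVersion("lmerTest"))),
    sprintf("stage %s: %.2f s", names(report$timings),
            unlist(report$timings)),
    sprintf("total: %.2f s", report$elapsed_s))
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.dispersal_report <- function(x, ...) {
  cat("Dispersal analysis report\n")
  cat(sprintf("  recruits: %d (%d complete cases)\n",
              x$counts$n_recruits, x$counts$n_complete))
  ov <- x$descriptives$overall
  cat(sprintf("  dispersal: mean %.1f km (SD %.1f), range %.1f-%.1f km\n",
              ov$mean_km, ov$sd_km, ov$min_km, ov$max_km))
  cat(sprintf("  morph-proportion GLM slope: %.3f +/- %.3f (P = %.3g)\n",
              x$glm$slope_estimate, x$glm$slope_se, x$glm$p_value))
  for (s in names(x$lmm)) {
    ia <- dplyr::filter(x$lmm[[s]]$anova, grepl(":", .data$term))
    cat(sprintf("  LMM %s (n = %d): interaction F%d,%.1f = %.2f, P = %.3g\n",
                s, x$lmm[[s]]$n_used, ia$num_df[1], ia$den_df[1],
                ia$f_statistic[1], ia$p.value[1]))
  }
  rt <- tidy(x$randomization)
  for (i in seq_len(nrow(rt))) {
    cat(sprintf("  randomization [%s]: observed %.1f vs expected %.1f km, P = %.3g\n",
                rt$stratum[i], rt$observed_median_km[i],
                rt$expected_median_km[i], rt$p_value[i]))
  }
  invisible(x)
}
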