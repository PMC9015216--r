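#' Candidate (detectable) dispersal distances per recruit
#'
#' For each recruit, the distances from its natal box to every box it could
#' have been detected settling in: all boxes for cohorts hatched in the era
#' cutoff year or later, only the early box set for earlier cohorts. The
#' self-distance (natal box itself) is excluded by default, since settling in
#' the natal box is not a dispersal event.
#'
#' @param recruits A data frame with columns `recruit_id`, `natal_box_id`,
#'   `hatch_year` (and optionally `morph`, carried through).
#' @param registry A `box_registry`.
#' @param include_self Keep the 0-km natal self-distance in each set?
#' @return A tibble with one row per recruit: `recruit_id`, `natal_box_id`,
#'   `hatch_year`, `morph` (if present), and a list-column `distances` of km
#'   values.
#' @export
candidate_distances <- function(recruits, registry, include_self = FALSE) {
  recruits <- tibble::as_tibble(recruits)
  stopifnot(all(c("recruit_id", "natal_box_id", "hatch_year") %in% names(recruits)))
  if (anyDuplicated(recruits$recruit_id)) {
    stop("duplicate recruit_id in recruit table", call. = FALSE)
  }
  dmat <- pairwise_distances(registry)
  cut <- era_cutoff(registry)
  # availability only depends on which side of the cutoff the cohort falls
  early_ids <- registry$box_id[registry$first_year < cut]
  if (any(recruits$hatch_year < cut) && length(early_ids) == 0) {
    first_bad <- recruits$recruit_id[recruits$hatch_year < cut][1]
    stop("recruit ", first_bad, ": no boxes available before the era cutoff",
         call. = FALSE)
  }

  natal <- as.character(recruits$natal_box_id)
  missing_natal <- setdiff(natal, registry$box_id)
  if (length(missing_natal) > 0) {
    stop("natal box id(s) not in registry: ",
         paste(unique(missing_natal), collapse = ", "), call. = FALSE)
  }

  sets <- purrr::map2(natal, recruits$hatch_year, function(nb, hy) {
    avail <- if (hy >= cut) registry$box_id else early_ids
    if (!include_self) avail <- setdiff(avail, nb)
    if (length(avail) == 0) {
      stop("recruit with natal box ", nb,
           ": empty candidate set after self-exclusion", call. = FALSE)
    }
    unname(dmat[nb, avail])
  })

  out <- recruits[, intersect(c("recruit_id", "natal_box_id", "hatch_year", "morph"),
                              names(recruits))]
  out$distances <- sets
  out
}

#' Monte-Carlo null medians under random settlement
#'
#' Each repetition draws, for every recruit, one distance uniformly at random
#' from that recruit's own candidate set (`pooled = FALSE`, the default) or
#' from the union of all candidate distances (`pooled = TRUE`), then takes
#' the median across recruits.
#'
#' @param sets Output of [candidate_distances()], or a bare list of numeric
#'   candidate vectors.
#' @param m Number of repetitions.
#' @param pooled Draw from a single pooled urn of all candidate distances
#'   instead of per-recruit sets?
#' @return Numeric vector of `m` null medians.
#' @export
random_median_draws <- function(sets, m, pooled = FALSE) {
  stopifnot(is.numeric(m), length(m) == 1, m >= 1)
  m <- as.integer(m)
  dist_list <- if (is.data.frame(sets)) sets$distances else sets
  if (length(dist_list) == 0 || any(lengths(dist_list) == 0)) {
    stop("every candidate set must be nonempty", call. = FALSE)
  }
  n <- length(dist_list)
  if (pooled) {
    urn <- unlist(dist_list, use.names = FALSE)
    draws <- matrix(urn[sample.int(length(urn), n * m, replace = TRUE)],
                    nrow = n, ncol = m)
  } else {
    draws <- vapply(dist_list,
                    function(d) d[sample.int(length(d), m, replace = TRUE)],
                    numeric(m))
    draws <- if (m == 1L) matrix(draws, nrow = n) else t(draws)
  }
  apply(draws, 2, stats::median)
}

#' Randomization test of observed median dispersal vs random settlement
#'
#' Compares the observed median natal dispersal distance with the
#' distribution of median distances expected if every recruit settled in a
#' box drawn uniformly at random from its detectable set. The P value uses
#' the add-one convention, `p = (count + 1) / (m + 1)`, counting the observed
#' outcome in the denominator; with the default lower tail the count is the
#' number of null medians less than or equal to the observed median (ties are
#' counted, which is conservative). The minimum attainable P at `m = 999` is
#' 1/1000, conventionally printed as "P < 0.001".
#'
#' @param observed Numeric vector of observed dispersal distances (km), one
#'   per recruit, in the same order as `sets`.
#' @param sets Output of [candidate_distances()] for the same recruits.
#' @param m Number of Monte-Carlo repetitions (default 999).
#' @param tail `"lower"` (default; evidence that observed dispersal is
#'   shorter than random settlement predicts), `"upper"`, or `"two.sided"`.
#' @param pooled Passed to [random_median_draws()].
#' @param seed Optional integer; if given, the draw is made reproducible
#'   without disturbing the caller's RNG state.
#' @return An object of class `dispersal_null`: a list with
#'   `observed_median_km`, `expected_median_km` (median of the null medians),
#'   `p_value`, `random_medians`, `n_recruits`, `m`, `tail`, `seed`.
#' @export
randomization_test <- function(observed, sets, m = 999, tail = c("lower", "upper", "two.sided"),
                               pooled = FALSE, seed = NULL) {
  tail <- match.arg(tail)
  stopifnot(m >= 1)
  dist_list <- if (is.data.frame(sets)) sets$distances else sets
  if (length(observed) != length(dist_list)) {
    stop("observed distances and candidate sets must cover the same recruits (",
         length(observed), " vs ", length(dist_list), ")", call. = FALSE)
  }
  if (anyNA(observed)) stop("observed distances contain NA", call. = FALSE)

  draw <- function() random_median_draws(sets, m, pooled = pooled)
  nulls <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())

  obs_med <- stats::median(observed)
  p_lower <- (sum(nulls <= obs_med) + 1) / (m + 1)
  p_upper <- (sum(nulls >= obs_med) + 1) / (m + 1)
  p <- switch(tail,
              lower = p_lower,
              upper = p_upper,
              two.sided = min(1, 2 * min(p_lower, p_upper)))

  structure(
    list(observed_median_km = obs_med,
         expected_median_km = stats::median(nulls),
         p_value = p,
         random_medians = nulls,
         n_recruits = length(observed),
         m = as.integer(m),
         tail = tail,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "dispersal_null"
  )
}

#' Randomization test from a recruit table, optionally per morph
#'
#' Convenience wrapper: computes observed dispersal distances and candidate
#' sets from a recruit table and registry, then runs [randomization_test()]
#' on the full sample and, if `by_morph = TRUE`, on each morph stratum.
#'
#' @param recruits Recruit table with `recruit_id`, `natal_box_id`,
#'   `breeding_box_id`, `hatch_year`, and `morph` when stratifying.
#' @param registry A `box_registry`.
#' @param by_morph Also run the test within each morph?
#' @param include_self Passed to [candidate_distances()].
#' @inheritParams randomization_test
#' @return An object of class `dispersal_null_set`: a named list of
#'   `dispersal_null` results (`all`, plus one per morph level when
#'   stratified).
#' @export
dispersal_null_test <- function(recruits, registry, m = 999,
                                tail = c("lower", "upper", "two.sided"),
                                by_morph = FALSE, pooled = FALSE,
                                include_self = FALSE, seed = NULL) {
  tail <- match.arg(tail)
  recruits <- dispersal_distances(tibble::as_tibble(recruits), registry)
  run_stratum <- function(rows, strat_seed) {
    sets <- candidate_distances(rows, registry, include_self = include_self)
    randomization_test(rows$dispersal_km, sets, m = m, tail = tail,
                       pooled = pooled, seed = strat_seed)
  }
  results <- list(all = run_stratum(recruits, seed))
  if (by_morph) {
    if (!"morph" %in% names(recruits)) {
      stop("by_morph = TRUE needs a morph column", call. = FALSE)
    }
    morphs <- recruits$morph[!is.na(recruits$morph)]
    for (lev in unique(as.character(morphs))) {
      rows <- recruits[!is.na(recruits$morph) & recruits$morph == lev, ]
      if (nrow(rows) == 0) stop("empty morph stratum: ", lev, call. = FALSE)
      strat_seed <- if (is.null(seed)) NULL else seed + match(lev, unique(as.character(morphs)))
      results[[lev]] <- run_stratum(rows, strat_seed)
    }
  }
  structure(results, class = "dispersal_null_set")
}

#' Randomization test restricted to one morph stratum
#'
#' Identical procedure to [dispersal_null_test()]'s full-sample test, run on
#' the recruits of a single morph. With the same seed, a stratum equal to the
#' full sample reproduces the unstratified result exactly.
#'
#' @inheritParams dispersal_null_test
#' @param morph Morph level to keep (e.g. `"gray"` or `"brown"`).
#' @return A `dispersal_null` object.
#' @export
morph_stratified_test <- function(recruits, registry, morph, m = 999,
                                  tail = c("lower", "upper", "two.sided"),
                                  pooled = FALSE, include_self = FALSE,
                                  seed = NULL) {
  tail <- match.arg(tail)
  recruits <- tibble::as_tibble(recruits)
  if (!"morph" %in% names(recruits)) stop("recruits need a morph column", call. = FALSE)
  rows <- recruits[!is.na(recruits$morph) & recruits$morph == morph, ]
  if (nrow(rows) == 0) stop("empty morph stratum: ", morph, call. = FALSE)
  rows <- dispersal_distances(rows, registry)
  sets <- candidate_distances(rows, registry, include_self = include_self)
  randomization_test(rows$dispersal_km, sets, m = m, tail = tail,
                     pooled = pooled, seed = seed)
}

#' @export
print.dispersal_null <- function(x, ...) {
  cat("Randomization test of median natal dispersal (", x$tail, " tail)\n", sep = "")
  cat(sprintf("  recruits: %d   repetitions: %d\n", x$n_recruits, x$m))
  cat(sprintf("  observed median: %.2f km   expected (null) median: %.2f km\n",
              x$observed_median_km, x$expected_median_km))
  p_min <- 1 / (x$m + 1)
  p_lab <- if (x$p_value <= p_min) sprintf("P < %.3g", p_min + 1e-12) else
    sprintf("P = %.3g", x$p_value)
  cat("  ", p_lab, "\n", sep = "")
  invisible(x)
}

#' @export
print.dispersal_null_set <- function(x, ...) {
  for (nm in names(x)) {
    cat("[", nm, "]\n", sep = "")
    print(x[[nm]])
  }
  invisible(x)
}

#' Tidy a randomization test result
#'
#' @param x A `dispersal_null` or `dispersal_null_set`.
#' @param ... Unused.
#' @return A tibble with one row per stratum: `stratum`, `n`,
#'   `observed_median_km`, `expected_median_km`, `p_value`, `m`, `tail`.
#' @export
tidy.dispersal_null <- function(x, ...) {
  tibble::tibble(stratum = "all", n = x$n_recruits,
                 observed_median_km = x$observed_median_km,
                 expected_median_km = x$expected_median_km,
                 p_value = x$p_value, m = x$m, tail = x$tail)
}

#' @rdname tidy.dispersal_null
#' @export
tidy.dispersal_null_set <- function(x, ...) {
  out <- purrr::map(x, tidy)
  dplyr::bind_rows(out, .id = "stratum2") |>
    dplyr::mutate(stratum = .data$stratum2) |>
    dplyr::select(-"stratum2")
}

#' @rdname tidy.dispersal_null
#' @export
glance.dispersal_null <- function(x, ...) tidy(x)

#' Histogram of null medians with the observed median marked
#'
#' The analog of the detectable-vs-observed distance figure: the Monte-Carlo
#' distribution of median dispersal distances expected under random
#' settlement, with a vertical line at the observed median.
#'
#' @param object A `dispersal_null` or `dispersal_null_set`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dispersal_null <- function(object, bins = 30, ...) {
  df <- tibble::tibble(stratum = "all", null_median_km = object$random_medians)
  obs <- tibble::tibble(stratum = "all", observed = object$observed_median_km)
  null_median_histogram(df, obs, bins)
}

#' @rdname autoplot.dispersal_null
#' @export
autoplot.dispersal_null_set <- function(object, bins = 30, ...) {
  df <- purrr::imap(object, function(r, nm) {
    tibble::tibble(stratum = nm, null_median_km = r$random_medians)
  }) |> dplyr::bind_rows()
  obs <- purrr::imap(object, function(r, nm) {
    tibble::tibble(stratum = nm, observed = r$observed_median_km)
  }) |> dplyr::bind_rows()
  null_median_histogram(df, obs, bins) +
    ggplot2::facet_wrap(~stratum, ncol = 1)
}

null_median_histogram <- function(df, obs, bins) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_median_km)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", color = "grey30") +
    ggplot2::geom_vline(data = obs,
                        ggplot2::aes(xintercept = .data$observed),
                        color = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "median dispersal distance (km)", y = "repetitions") +
    ggplot2::theme_minimal()
}
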