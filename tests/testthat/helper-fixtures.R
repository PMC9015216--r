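# Small in-code fixtures shared across test files.

tiny_registry <- function(era_cutoff_year = 1987) {
  box_registry(
    data.frame(box_id = c("a", "b", "c"),
               x_km = c(0, 3, 6), y_km = c(0, 4, 8),
               first_year = c(1980, 1980, 1990)),
    era_cutoff_year = era_cutoff_year
  )
}

random_registry <- function(n = 12, cutoff = 1987, seed = 1) {
  withr::with_seed(seed, box_registry(
    data.frame(box_id = sprintf("b%02d", seq_len(n)),
               x_km = runif(n, 0, 20), y_km = runif(n, 0, 20),
               first_year = sample(c(1980, 1990), n, replace = TRUE,
                                   prob = c(0.6, 0.4))),
    era_cutoff_year = cutoff
  ))
}

# daily climate series with constant or supplied winter temperatures
daily_climate <- function(years, temp_fun = function(y) -5) {
  purrr::map(years, function(y) {
    days <- seq(as.Date(sprintf("%d-11-01", y)),
                as.Date(sprintf("%d-03-31", y + 1)), by = "day")
    tibble::tibble(date = days, temp_c = temp_fun(y))
  }) |> dplyr::bind_rows() |> dplyr::distinct(date, .keep_all = TRUE)
}

# small recruit table on tiny_registry-compatible boxes
tiny_recruits <- function() {
  tibble::tibble(
    recruit_id = c("r1", "r2", "r3"),
    natal_box_id = c("a", "b", "a"),
    breeding_box_id = c("b", "a", "c"),
    hatch_year = c(1985, 1990, 1995),
    morph = c("gray", "brown", "gray")
  )
}

# quick small-scale simulation parameters (keeps module tests fast)
small_params <- function(seed = 1, ...) {
  sim_params(n_years = 12, n_boxes = 60, n_broods_per_year = 18,
             recruitment_prob = 0.25, start_year = 1979,
             era_cutoff_year = 1983, seed = seed, ...)
}
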