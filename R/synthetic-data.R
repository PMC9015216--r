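#' Simulation parameters for a synthetic owl population
#'
#' Defaults reproduce the study conditions the analysis was designed for: 40
#' annual cohorts on a ~500 km^2 elongated area (45 km x 11 km, so that
#' box-pair distances peak around 10-15 km and dispersal up to ~40 km is
#' detectable) with ~360 nest boxes (half of them part of the original
#' network, half added when the area was enlarged in the ninth study year),
#' ~3,000 ringed offspring of which ~6% recruit, a
#' one-locus two-allele color polymorphism with brown dominance at allele
#' frequency 0.16 (~30% brown phenotypes), and a dispersal mean structure at
#' the fitted-model scale: intercept 10.5 km, brown-vs-gray offset 0.3 km,
#' anomaly slope -0.9 km/degC for gray, a brown-by-anomaly interaction of
#' +2.4 km/degC, and -0.8 km per SD of fledging mass. Random-intercept SDs
#' default to 0 (year, brood) and 1.84 km (nest box), residual SD 6.5 km;
#' winter anomalies are i.i.d. normal with SD 2 degC and the prey index
#' cycles with a 3-year period.
#'
#' @param n_years Number of annual cohorts.
#' @param n_boxes Number of nest boxes.
#' @param area_width_km,area_height_km Study-area rectangle (km).
#' @param start_year First hatch year.
#' @param era_cutoff_year Year the late box set becomes available.
#' @param frac_early_boxes Fraction of boxes in the early (pre-cutoff) set.
#' @param n_broods_per_year Breeding attempts per year.
#' @param brown_allele_freq Frequency of the dominant brown allele.
#' @param beta_intercept_km,beta_morph_km,beta_anomaly_km_per_c,beta_interaction_km_per_c,beta_mass_km_per_sd
#'   Fixed effects of the latent dispersal-distance model.
#' @param sigma_year,sigma_brood,sigma_box,sigma_resid Random-intercept and
#'   residual SDs (km).
#' @param recruitment_prob Per-offspring probability of local recruitment.
#' @param anomaly_sd_c SD of winter temperature anomalies (degC).
#' @param prey_cycle_period Period (years) of the small-mammal cycle.
#' @param mass_mean_g,mass_sd_g Fledging body-mass distribution.
#' @param floor_km Lower truncation of the latent dispersal distance.
#' @param seed RNG seed; mandatory for reproducible bundles.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_years = 40, n_boxes = 360,
                       area_width_km = 45, area_height_km = 11,
                       start_year = 1979, era_cutoff_year = 1987,
                       frac_early_boxes = 0.5, n_broods_per_year = 25,
                       brown_allele_freq = 0.16,
                       beta_intercept_km = 10.5, beta_morph_km = 0.3,
                       beta_anomaly_km_per_c = -0.9,
                       beta_interaction_km_per_c = 2.4,
                       beta_mass_km_per_sd = -0.8,
                       sigma_year = 0, sigma_brood = 0, sigma_box = 1.84,
                       sigma_resid = 6.5,
                       recruitment_prob = 0.06, anomaly_sd_c = 2,
                       prey_cycle_period = 3,
                       mass_mean_g = 350, mass_sd_g = 30,
                       floor_km = 0.1, seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$n_years >= 1, p$n_boxes >= 2,
            p$sigma_year >= 0, p$sigma_brood >= 0, p$sigma_box >= 0,
            p$sigma_resid >= 0,
            p$recruitment_prob > 0, p$recruitment_prob < 1,
            p$brown_allele_freq >= 0, p$brown_allele_freq <= 1,
            p$anomaly_sd_c >= 0, p$mass_sd_g > 0, p$floor_km > 0,
            is.numeric(p$seed), length(p$seed) == 1)
  p$seed <- as.integer(p$seed)
  structure(p, class = "sim_params")
}

parse_genotype <- function(g) {
  alleles <- strsplit(as.character(g), "")[[1]]
  if (length(alleles) != 2 || !all(alleles %in% c("B", "b"))) {
    stop("a genotype is two alleles from {B, b}, e.g. \"Bb\"", call. = FALSE)
  }
  alleles
}

#' Mendelian offspring genotypes from a parental cross
#'
#' One allele is drawn uniformly at random from each parent; the phenotype is
#' brown if the offspring carries at least one dominant `B` allele, gray
#' otherwise.
#'
#' @param mother,father Parental genotypes as two-character strings over
#'   alleles `B` (brown, dominant) and `b` (gray, recessive), e.g. `"Bb"`.
#' @param n Number of offspring to draw.
#' @return A tibble with columns `allele1`, `allele2`, `genotype`,
#'   `phenotype` (`"brown"` or `"gray"`).
#' @examples
#' withr::with_seed(1, mendelian_offspring("Bb", "Bb", n = 4))
#' @export
mendelian_offspring <- function(mother, father, n = 1) {
  ma <- parse_genotype(mother)
  fa <- parse_genotype(father)
  a1 <- ma[sample.int(2, n, replace = TRUE)]
  a2 <- fa[sample.int(2, n, replace = TRUE)]
  tibble::tibble(
    allele1 = a1, allele2 = a2,
    genotype = genotype_string(a1, a2),
    phenotype = ifelse(a1 == "B" | a2 == "B", "brown", "gray")
  )
}

# canonical BB / Bb / bb label, independent of allele order and locale
genotype_string <- function(a1, a2) {
  n_b <- (a1 == "B") + (a2 == "B")
  c("bb", "Bb", "BB")[n_b + 1]
}

# Hardy-Weinberg draw of n genotypes at brown-allele frequency p.
hw_genotypes <- function(n, p) {
  a1 <- ifelse(stats::runif(n) < p, "B", "b")
  a2 <- ifelse(stats::runif(n) < p, "B", "b")
  genotype_string(a1, a2)
}

#' Simulate the annual environment: winter anomalies and prey index
#'
#' Winter anomalies are i.i.d. normal with mean zero; the prey index carries
#' a sinusoidal component with the configured cycle period (amplitude 6, mean
#' level 10 captures per 100 trap nights, noise SD 2, floored at 0.5) and is
#' back-converted to capture counts at the standard effort of 384 trap
#' nights.
#'
#' @param params A [sim_params()] object.
#' @return A list with tibbles `winters` (`winter_year`, `anomaly_c`) and
#'   `prey` (`year`, `captures`, `trap_nights`, `prey_index`).
#' @export
simulate_environment <- function(params) {
  years <- params$start_year + seq_len(params$n_years) - 1L
  anomaly <- stats::rnorm(params$n_years, 0, params$anomaly_sd_c)
  cyc <- 6 * sin(2 * pi * seq_len(params$n_years) / params$prey_cycle_period)
  idx <- pmax(0.5, 10 + cyc + stats::rnorm(params$n_years, 0, 2))
  trap_nights <- rep(384L, params$n_years)
  captures <- round(idx * trap_nights / 100)
  list(
    winters = tibble::tibble(winter_year = years, anomaly_c = anomaly),
    prey = tibble::tibble(year = years, captures = captures,
                          trap_nights = trap_nights,
                          prey_index = prey_index(captures, trap_nights))
  )
}

#' Simulate a full synthetic population bundle
#'
#' Generates a nest-box registry, annual environment, breeding broods with
#' Mendelian morph inheritance, and locally recruiting offspring whose
#' dispersal follows the latent linear model
#' `intercept + morph + anomaly + morph:anomaly + mass + year/brood/box
#' random intercepts + residual`, truncated below at `floor_km`. The
#' breeding box is the available box (era rule applied, natal box and boxes
#' nearer than the floor excluded) whose distance from the natal box is
#' closest to the latent distance, ties broken by lowest `box_id` — so the
#' generating model is exactly the fitted mixed model plus settlement
#' discretization. With `settlement = "random"` the breeding box is instead
#' drawn uniformly from the available boxes (self excluded), the null the
#' randomization test assumes.
#'
#' If a replicate produces zero recruits it is regenerated with the seed
#' incremented (and a message); the seed actually used is recorded in the
#' bundle.
#'
#' @param params A [sim_params()] object.
#' @param settlement `"kernel"` (distance-matching, the default) or
#'   `"random"` (uniform over available boxes).
#' @return A list of class `owl_bundle`: `registry`, `recruits`, `winters`,
#'   `prey`, `params` (with `seed_used`), `settlement`.
#' @export
simulate_population <- function(params, settlement = c("kernel", "random")) {
  settlement <- match.arg(settlement)
  stopifnot(inherits(params, "sim_params"))
  seed <- params$seed
  for (attempt in 1:25) {
    bundle <- withr::with_seed(seed, sim_population_once(params, settlement))
    if (nrow(bundle$recruits) > 0) break
    message("replicate produced zero recruits; regenerating with seed ", seed + 1L)
    seed <- seed + 1L
  }
  if (nrow(bundle$recruits) == 0) {
    stop("no recruits after 25 regeneration attempts", call. = FALSE)
  }
  bundle$params <- params
  bundle$params$seed_used <- seed
  bundle$settlement <- settlement
  class(bundle) <- "owl_bundle"
  bundle
}

#' @rdname simulate_population
#' @export
simulate_random_settlement <- function(params) {
  simulate_population(params, settlement = "random")
}

sim_population_once <- function(params, settlement) {
  years <- params$start_year + seq_len(params$n_years) - 1L

  n_early <- max(2L, round(params$frac_early_boxes * params$n_boxes))
  first_year <- rep(params$era_cutoff_year, params$n_boxes)
  first_year[sample.int(params$n_boxes, n_early)] <- params$start_year
  boxes <- tibble::tibble(
    box_id = sprintf("B%03d", seq_len(params$n_boxes)),
    x_km = stats::runif(params$n_boxes, 0, params$area_width_km),
    y_km = stats::runif(params$n_boxes, 0, params$area_height_km),
    first_year = first_year
  )
  registry <- box_registry(boxes, params$era_cutoff_year)
  dmat <- pairwise_distances(registry)

  env <- simulate_environment(params)
  anomaly_by_year <- stats::setNames(env$winters$anomaly_c, env$winters$winter_year)

  # broods: each year, distinct natal boxes among those already deployed
  broods <- purrr::map(years, function(y) {
    avail <- registry$box_id[registry$first_year <= y]
    n_b <- min(params$n_broods_per_year, length(avail))
    tibble::tibble(
      hatch_year = y,
      natal_box_id = avail[sample.int(length(avail), n_b)],
      brood_size = sample(1:5, n_b, replace = TRUE,
                          prob = c(0.10, 0.25, 0.30, 0.25, 0.10)),
      mother = hw_genotypes(n_b, params$brown_allele_freq),
      father = hw_genotypes(n_b, params$brown_allele_freq)
    )
  }) |> dplyr::bind_rows()
  broods$brood_id <- sprintf("%d_%03d", broods$hatch_year,
                             stats::ave(broods$hatch_year, broods$hatch_year,
                                        FUN = seq_along))

  off <- broods[rep(seq_len(nrow(broods)), broods$brood_size), ]
  n_off <- nrow(off)
  m_allele <- ifelse(stats::runif(n_off) < 0.5,
                     substr(off$mother, 1, 1), substr(off$mother, 2, 2))
  f_allele <- ifelse(stats::runif(n_off) < 0.5,
                     substr(off$father, 1, 1), substr(off$father, 2, 2))
  off$genotype <- genotype_string(m_allele, f_allele)
  off$morph <- ifelse(m_allele == "B" | f_allele == "B", "brown", "gray")
  off$body_mass_g <- stats::rnorm(n_off, params$mass_mean_g, params$mass_sd_g)
  off$recruited <- stats::runif(n_off) < params$recruitment_prob
  n_ringed <- n_off

  rec <- off[off$recruited, ]
  if (nrow(rec) == 0) {
    return(list(registry = registry,
                recruits = rec[0, ],
                winters = env$winters, prey = env$prey,
                n_ringed = n_ringed))
  }
  n_rec <- nrow(rec)
  rec$recruit_id <- sprintf("R%04d", seq_len(n_rec))
  rec$sex <- sample(c("female", "male"), n_rec, replace = TRUE)
  rec$age_at_recruitment <- sample(c("1", "2", "3+"), n_rec, replace = TRUE,
                                   prob = c(0.464, 0.307, 0.229))

  year_eff <- stats::setNames(stats::rnorm(length(years), 0, params$sigma_year),
                              years)
  brood_eff <- stats::setNames(stats::rnorm(nrow(broods), 0, params$sigma_brood),
                               broods$brood_id)
  box_eff <- stats::setNames(stats::rnorm(nrow(registry), 0, params$sigma_box),
                             registry$box_id)

  is_brown <- as.numeric(rec$morph == "brown")
  anomaly <- unname(anomaly_by_year[as.character(rec$hatch_year)])
  mass_z <- (rec$body_mass_g - params$mass_mean_g) / params$mass_sd_g
  latent <- params$beta_intercept_km +
    params$beta_morph_km * is_brown +
    params$beta_anomaly_km_per_c * anomaly +
    params$beta_interaction_km_per_c * is_brown * anomaly +
    params$beta_mass_km_per_sd * mass_z +
    unname(year_eff[as.character(rec$hatch_year)]) +
    unname(brood_eff[rec$brood_id]) +
    unname(box_eff[rec$natal_box_id]) +
    stats::rnorm(n_rec, 0, params$sigma_resid)
  latent <- pmax(params$floor_km, latent)
  rec$latent_km <- latent

  cut <- era_cutoff(registry)
  early_ids <- registry$box_id[registry$first_year < cut]
  breeding <- character(n_rec)
  for (i in seq_len(n_rec)) {
    avail <- if (rec$hatch_year[i] >= cut) registry$box_id else early_ids
    avail <- setdiff(avail, rec$natal_box_id[i])
    d <- dmat[rec$natal_box_id[i], avail]
    if (settlement == "kernel") {
      ok <- d >= params$floor_km
      if (any(ok)) { avail <- avail[ok]; d <- d[ok] }
      breeding[i] <- avail[which.min(abs(d - latent[i]))]  # first match = lowest id
    } else {
      breeding[i] <- avail[sample.int(length(avail), 1)]
    }
  }
  rec$breeding_box_id <- breeding
  rec$dispersal_km <- dmat[cbind(rec$natal_box_id, rec$breeding_box_id)]

  recruits <- tibble::as_tibble(rec)[, c(
    "recruit_id", "brood_id", "natal_box_id", "breeding_box_id", "hatch_year",
    "sex", "morph", "genotype", "body_mass_g", "age_at_recruitment",
    "latent_km", "dispersal_km")]
  list(registry = registry, recruits = recruits,
       winters = env$winters, prey = env$prey, n_ringed = n_ringed)
}

#' @export
print.owl_bundle <- function(x, ...) {
  cat("Synthetic population bundle (", x$settlement, " settlement)\n", sep = "")
  cat(sprintf("  boxes: %d   cohorts: %d   ringed: %d   recruits: %d\n",
              nrow(x$registry), nrow(x$winters), x$n_ringed, nrow(x$recruits)))
  cat("  seed used:", x$params$seed_used, "\n")
  invisible(x)
}

#' Write a bundle's tables as CSV files plus a params sidecar
#'
#' @param bundle An `owl_bundle`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tibble::as_tibble(bundle$registry), file.path(dir, "registry.csv"))
  readr::write_csv(bundle$recruits, file.path(dir, "recruits.csv"))
  readr::write_csv(bundle$winters, file.path(dir, "winters.csv"))
  readr::write_csv(bundle$prey, file.path(dir, "prey.csv"))
  par <- bundle$params
  class(par) <- NULL
  jsonlite::write_json(c(par, list(settlement = bundle$settlement)),
                       file.path(dir, "params.json"), auto_unbox = TRUE)
  invisible(dir)
}
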