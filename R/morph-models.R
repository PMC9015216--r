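#' Yearly morph proportions joined to winter anomalies
#'
#' Aggregates a recruit table into one row per hatch year with the count of
#' brown recruits, the total with known morph, and the post-fledging winter
#' anomaly, ready for [fit_brown_proportion_glm()].
#'
#' @param recruits Data frame with `hatch_year` and `morph` (`"gray"` /
#'   `"brown"`; NA morphs are dropped).
#' @param winters Data frame with `winter_year` and `anomaly_c`.
#' @return A tibble with columns `year`, `n_brown`, `n_total`, `anomaly_c`.
#' @export
yearly_morph_proportions <- function(recruits, winters) {
  recruits |>
    dplyr::filter(!is.na(.data$morph)) |>
    dplyr::group_by(year = .data$hatch_year) |>
    dplyr::summarise(n_brown = sum(.data$morph == "brown"),
                     n_total = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(winters, by = c(year = "winter_year")) |>
    dplyr::select("year", "n_brown", "n_total", "anomaly_c")
}

#' Binomial GLM of yearly brown proportion on winter anomaly
#'
#' Fits a logit-link binomial model of the proportion of brown recruits per
#' hatch year on the winter temperature anomaly of each cohort's first
#' post-fledging winter, weighted by the yearly totals.
#'
#' @param yearly A data frame with columns `n_brown`, `n_total`, `anomaly_c`
#'   (one row per year), e.g. from [yearly_morph_proportions()].
#' @return An object of class `morph_prop_glm` wrapping the [stats::glm()]
#'   fit, with elements `slope_estimate`, `slope_se`, `z_value`, `p_value`,
#'   `n_years`, `separation`.
#' @export
fit_brown_proportion_glm <- function(yearly) {
  yearly <- tibble::as_tibble(yearly)
  stopifnot(all(c("n_brown", "n_total", "anomaly_c") %in% names(yearly)))
  yearly <- dplyr::filter(yearly, .data$n_total >= 1, !is.na(.data$anomaly_c))
  if (nrow(yearly) < 2) {
    stop("need at least 2 years with recruits and anomaly data", call. = FALSE)
  }
  tot_brown <- sum(yearly$n_brown)
  if (tot_brown == 0 || tot_brown == sum(yearly$n_total)) {
    stop("all recruits are one morph; the proportion model is undefined",
         call. = FALSE)
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(cbind(n_brown, n_total - n_brown) ~ anomaly_c,
               family = stats::binomial(), data = yearly),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (separation) {
    warning("possible complete separation; estimates may be unstable",
            call. = FALSE)
  }
  cf <- summary(fit)$coefficients
  structure(
    list(fit = fit,
         slope_estimate = unname(cf["anomaly_c", "Estimate"]),
         slope_se = unname(cf["anomaly_c", "Std. Error"]),
         z_value = unname(cf["anomaly_c", "z value"]),
         p_value = unname(cf["anomaly_c", "Pr(>|z|)"]),
         n_years = nrow(yearly),
         separation = separation),
    class = "morph_prop_glm"
  )
}

#' @export
print.morph_prop_glm <- function(x, ...) {
  cat("Binomial GLM: yearly brown proportion ~ winter anomaly\n")
  cat(sprintf("  years: %d   slope: %.3f +/- %.3f   z = %.2f   P = %.3g\n",
              x$n_years, x$slope_estimate, x$slope_se, x$z_value, x$p_value))
  if (x$separation) cat("  (flagged: possible complete separation)\n")
  invisible(x)
}

#' @rdname tidy.dispersal_lmm
#' @export
tidy.morph_prop_glm <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(cf), estimate = cf[, 1], std.error = cf[, 2],
                 statistic = cf[, 3], p.value = cf[, 4])
}

#' @rdname tidy.dispersal_lmm
#' @export
glance.morph_prop_glm <- function(x, ...) {
  tibble::tibble(slope_estimate = x$slope_estimate, slope_se = x$slope_se,
                 z_value = x$z_value, p_value = x$p_value,
                 n_years = x$n_years, separation = x$separation)
}

# ---- linear mixed model of dispersal distance --------------------------------

#' Linear mixed model of natal dispersal distance
#'
#' Fits, by REML, a linear mixed model of dispersal distance with fixed
#' effects morph, winter temperature anomaly, their interaction, prey index,
#' sex, and standardized fledging body mass — plus age at recruitment in the
#' all-ages analysis set — and crossed random intercepts for hatch year,
#' brood, and natal nest box. Reference levels are gray, female, and age 1.
#' Body mass is z-scored over the complete cases actually entering the model,
#' separately per analysis set. Term tests are marginal (Type III) F tests
#' with Satterthwaite denominator degrees of freedom, so a multi-level factor
#' such as age is tested as a single term.
#'
#' @param recruits Data frame with columns `dispersal_km`, `morph`, `sex`,
#'   `body_mass_g`, `age_at_recruitment` (values 1, 2, "3+"), `hatch_year`,
#'   `brood_id`, `natal_box_id`, `anomaly_c`, `prey_index`.
#' @param set `"all_ages"` (age term included) or `"one_year_olds"`
#'   (restricted to age-1 recruits, age term dropped).
#' @return An object of class `dispersal_lmm` with the `lmerTest` fit and
#'   tidied `coefficients`, `anova` (term F tests), `varcomp`, sample-size
#'   bookkeeping (`n_input`, `n_used`), and a `converged` flag.
#' @export
fit_dispersal_lmm <- function(recruits, set = c("all_ages", "one_year_olds")) {
  set <- match.arg(set)
  recruits <- tibble::as_tibble(recruits)
  needed <- c("dispersal_km", "morph", "sex", "body_mass_g", "age_at_recruitment",
              "hatch_year", "brood_id", "natal_box_id", "anomaly_c", "prey_index")
  missing_cols <- setdiff(needed, names(recruits))
  if (length(missing_cols) > 0) {
    stop("recruits missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n_input <- nrow(recruits)
  d <- recruits |>
    dplyr::mutate(
      morph = factor(as.character(.data$morph), levels = c("gray", "brown")),
      sex = factor(as.character(.data$sex), levels = c("female", "male")),
      age_at_recruitment = factor(as.character(.data$age_at_recruitment),
                                  levels = c("1", "2", "3+")),
      hatch_year = factor(.data$hatch_year),
      brood_id = factor(.data$brood_id),
      natal_box_id = factor(.data$natal_box_id)
    )
  if (set == "one_year_olds") {
    d <- dplyr::filter(d, .data$age_at_recruitment == "1")
  }
  d <- tidyr::drop_na(d, dplyr::all_of(needed))
  n_used <- nrow(d)
  if (n_used < 10) stop("too few complete cases (", n_used, ")", call. = FALSE)
  d$mass_z <- standardize(d$body_mass_g)

  fixed <- "dispersal_km ~ morph * anomaly_c + prey_index + sex + mass_z"
  if (set == "all_ages") fixed <- paste(fixed, "+ age_at_recruitment")
  form <- stats::as.formula(paste(
    fixed, "+ (1 | hatch_year) + (1 | brood_id) + (1 | natal_box_id)"))

  fit <- withCallingHandlers(
    lmerTest::lmer(form, data = d, REML = TRUE,
                   control = lme4::lmerControl(
                     check.nobs.vs.nlev = "ignore",
                     check.nobs.vs.nRE = "ignore")),
    message = function(m) {
      if (grepl("singular", conditionMessage(m))) invokeRestart("muffleMessage")
    }
  )
  conv <- length(fit@optinfo$conv$lme4) == 0 ||
    is.null(fit@optinfo$conv$lme4$messages) ||
    all(grepl("singular|boundary", fit@optinfo$conv$lme4$messages))

  cf <- stats::coef(summary(fit))
  coef_tbl <- tibble::tibble(
    term = rownames(cf), estimate = unname(cf[, "Estimate"]),
    std.error = unname(cf[, "Std. Error"]), df = unname(cf[, "df"]),
    statistic = unname(cf[, "t value"]), p.value = unname(cf[, "Pr(>|t|)"]))

  an <- suppressMessages(stats::anova(fit, type = 3, ddf = "Satterthwaite"))
  anova_tbl <- tibble::tibble(
    term = rownames(an), num_df = an$NumDF, den_df = an$DenDF,
    f_statistic = an$`F value`, p.value = an$`Pr(>F)`)

  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- tibble::tibble(group = vc$grp, variance = vc$vcov, sd = vc$sdcor)

  structure(
    list(fit = fit, set = set, formula = form,
         coefficients = coef_tbl, anova = anova_tbl, varcomp = varcomp,
         n_input = n_input, n_used = n_used, n_dropped = n_input - n_used,
         reml_loglik = as.numeric(stats::logLik(fit)),
         converged = conv),
    class = "dispersal_lmm"
  )
}

#' @export
print.dispersal_lmm <- function(x, ...) {
  cat("Linear mixed model of natal dispersal distance (", x$set, ")\n", sep = "")
  cat(sprintf("  complete cases used: %d of %d input rows\n", x$n_used, x$n_input))
  cat("Fixed-effect coefficients (Satterthwaite df):\n")
  print(as.data.frame(x$coefficients), digits = 3, row.names = FALSE)
  cat("Type III term tests:\n")
  print(as.data.frame(x$anova), digits = 3, row.names = FALSE)
  cat("Variance components:\n")
  print(as.data.frame(x$varcomp), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Tidy and glance methods for fitted model objects
#'
#' `tidy()` returns per-coefficient (default) or per-term (`effects =
#' "terms"`) summaries; `glance()` returns one-row model summaries.
#'
#' @param x A fitted `dispersal_lmm` or `morph_prop_glm`.
#' @param effects For `dispersal_lmm`: `"coefficients"`, `"terms"` (Type III
#'   F tests), or `"varcomp"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.dispersal_lmm <- function(x, effects = c("coefficients", "terms", "varcomp"), ...) {
  effects <- match.arg(effects)
  switch(effects,
         coefficients = x$coefficients,
         terms = x$anova,
         varcomp = x$varcomp)
}

#' @rdname tidy.dispersal_lmm
#' @export
glance.dispersal_lmm <- function(x, ...) {
  tibble::tibble(set = x$set, n_used = x$n_used, n_dropped = x$n_dropped,
                 reml_loglik = x$reml_loglik, sigma = stats::sigma(x$fit),
                 converged = x$converged)
}

# ---- Satterthwaite degrees of freedom ---------------------------------------

#' Satterthwaite denominator degrees of freedom
#'
#' The moment-matching approximation `df = 2 * v^2 / (g' W g)` where `v` is
#' the estimated variance of a contrast, `g` the gradient of that variance
#' with respect to the variance components, and `W` the asymptotic covariance
#' of the variance-component estimates.
#'
#' @param var_value Estimated variance of the contrast (scalar > 0).
#' @param grad Gradient of the contrast variance w.r.t. the variance
#'   components (numeric vector).
#' @param vcov_varpar Asymptotic covariance matrix of the variance-component
#'   estimates.
#' @return The approximate degrees of freedom (scalar > 0).
#' @export
satterthwaite_df <- function(var_value, grad, vcov_varpar) {
  grad <- as.numeric(grad)
  vcov_varpar <- as.matrix(vcov_varpar)
  stopifnot(length(grad) == nrow(vcov_varpar), nrow(vcov_varpar) == ncol(vcov_varpar))
  denom <- as.numeric(t(grad) %*% vcov_varpar %*% grad)
  if (!is.finite(denom) || denom <= 0) {
    stop("non-positive variance of the contrast variance; cannot form df",
         call. = FALSE)
  }
  2 * var_value^2 / denom
}

#' Satterthwaite df for a fixed-effect contrast of a random-intercept LMM
#'
#' Computes the contrast variance `c' (X' V^-1 X)^-1 c`, its analytic
#' gradient with respect to the variance components, and the REML expected
#' (Fisher) information of the variance components, then applies
#' [satterthwaite_df()]. Supports models whose random part consists of
#' random intercepts only (any number of crossed grouping factors). With all
#' random-effect variances at zero (or dropped at the boundary) the result
#' collapses exactly to the residual degrees of freedom `n - p`.
#'
#' Matrices are formed densely, so this is intended for data sets up to a
#' few thousand observations.
#'
#' @param fit A fitted `lmerMod`/`lmerModLmerTest` with intercept-only random
#'   terms, or a `dispersal_lmm`.
#' @param contrast Numeric contrast vector over the fixed-effect
#'   coefficients (length = number of fixed effects).
#' @param varcomp Optional variance-component vector at which to evaluate,
#'   ordered as the model's grouping factors followed by the residual
#'   variance; defaults to the REML estimates.
#' @param boundary_tol Random-effect variances below `boundary_tol` times the
#'   residual variance are treated as at the zero boundary and dropped from
#'   the variance parameterization.
#' @return Degrees of freedom (scalar). Falls back to `n - p` with a warning
#'   if the information matrix is singular.
#' @export
contrast_df <- function(fit, contrast, varcomp = NULL, boundary_tol = 1e-6) {
  if (inherits(fit, "dispersal_lmm")) fit <- fit$fit
  stopifnot(inherits(fit, "lmerMod"))
  cnms <- lme4::getME(fit, "cnms")
  if (!all(vapply(cnms, function(z) identical(z, "(Intercept)"), logical(1)))) {
    stop("contrast_df() supports random-intercept models only", call. = FALSE)
  }
  X <- as.matrix(lme4::getME(fit, "X"))
  y <- lme4::getME(fit, "y")
  n <- nrow(X); p <- ncol(X)
  contrast <- as.numeric(contrast)
  stopifnot(length(contrast) == p)

  flist <- lme4::getME(fit, "flist")
  # one indicator cross-product per grouping factor: Vk[i,j] = 1{f_i == f_j}
  Vk <- lapply(flist, function(f) {
    M <- outer(as.integer(f), as.integer(f), "==")
    storage.mode(M) <- "double"
    M
  })

  if (is.null(varcomp)) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    sigma2 <- vc$vcov[vc$grp == "Residual"]
    tau2 <- vapply(names(flist), function(g) vc$vcov[vc$grp == g][1], numeric(1))
  } else {
    stopifnot(length(varcomp) == length(flist) + 1)
    tau2 <- varcomp[seq_along(flist)]
    sigma2 <- varcomp[length(varcomp)]
  }

  keep <- tau2 > boundary_tol * sigma2
  Vk <- Vk[keep]
  tau2 <- tau2[keep]

  V <- diag(sigma2, n)
  for (k in seq_along(Vk)) V <- V + tau2[k] * Vk[[k]]
  Vi <- solve(V)
  ViX <- Vi %*% X
  A <- crossprod(X, ViX)
  Ai <- solve(A)
  var_c <- as.numeric(t(contrast) %*% Ai %*% contrast)

  # REML projection P = V^-1 - V^-1 X (X'V^-1X)^-1 X'V^-1
  P <- Vi - ViX %*% Ai %*% t(ViX)
  derivs <- c(Vk, list(diag(1, n)))  # d V / d tau2_k, d V / d sigma2

  b <- ViX %*% Ai %*% contrast
  grad <- vapply(derivs, function(D) as.numeric(t(b) %*% D %*% b), numeric(1))

  K <- length(derivs)
  info <- matrix(0, K, K)
  PD <- lapply(derivs, function(D) P %*% D)
  for (k in seq_len(K)) for (l in k:K) {
    info[k, l] <- info[l, k] <- 0.5 * sum(PD[[k]] * t(PD[[l]]))
  }
  W <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(W)) {
    warning("singular variance-component information; falling back to residual df",
            call. = FALSE)
    return(n - p)
  }
  satterthwaite_df(var_c, grad, W)
}

# ---- marginal effects --------------------------------------------------------

#' Marginal effects of the morph-by-anomaly interaction
#'
#' Predicted dispersal distance for each morph along a grid of winter
#' anomalies, with other covariates held at their means (continuous) or
#' reference levels (factors), and 95% confidence bands from the
#' fixed-effect covariance matrix.
#'
#' @param x A `dispersal_lmm`.
#' @param anomaly_grid Numeric grid of anomaly values; defaults to 25 points
#'   spanning the observed range.
#' @param morph_levels Morph levels to predict for.
#' @param level Confidence level.
#' @return A tibble of class `morph_marginal` with columns `morph`,
#'   `anomaly_c`, `estimate`, `conf.low`, `conf.high`, `extrapolated`.
#' @export
marginal_effects <- function(x, anomaly_grid = NULL,
                             morph_levels = c("gray", "brown"), level = 0.95) {
  stopifnot(inherits(x, "dispersal_lmm"))
  fit <- x$fit
  mf <- stats::model.frame(fit)
  obs_range <- range(mf$anomaly_c)
  if (is.null(anomaly_grid)) {
    anomaly_grid <- seq(obs_range[1], obs_range[2], length.out = 25)
  }
  newdata <- tidyr::expand_grid(
    morph = factor(morph_levels, levels = levels(mf$morph)),
    anomaly_c = anomaly_grid
  )
  newdata$prey_index <- mean(mf$prey_index)
  newdata$mass_z <- 0
  newdata$sex <- factor("female", levels = levels(mf$sex))
  if ("age_at_recruitment" %in% names(mf)) {
    newdata$age_at_recruitment <- factor("1", levels = levels(mf$age_at_recruitment))
  }
  tt <- stats::delete.response(stats::terms(fit, fixed.only = TRUE))
  Xnew <- stats::model.matrix(tt, newdata, xlev = stats::.getXlevels(tt, mf))
  beta <- lme4::fixef(fit)
  Vb <- as.matrix(stats::vcov(fit))
  est <- as.numeric(Xnew %*% beta)
  se <- sqrt(rowSums((Xnew %*% Vb) * Xnew))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  out <- tibble::tibble(
    morph = as.character(newdata$morph),
    anomaly_c = newdata$anomaly_c,
    estimate = est,
    conf.low = est - zq * se,
    conf.high = est + zq * se,
    extrapolated = newdata$anomaly_c < obs_range[1] | newdata$anomaly_c > obs_range[2]
  )
  class(out) <- c("morph_marginal", class(out))
  out
}

#' Plot marginal morph-by-anomaly effects
#'
#' @param object A `morph_marginal` tibble from [marginal_effects()].
#' @param ... Unused.
#' @return A ggplot object: one line with 95% ribbon per morph.
#' @export
autoplot.morph_marginal <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$anomaly_c, y = .data$estimate,
                               color = .data$morph, fill = .data$morph)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::scale_color_manual(values = c(gray = "grey55", brown = "sienna4"),
                                aesthetics = c("colour", "fill")) +
    ggplot2::labs(x = "winter temperature anomaly (°C)",
                  y = "predicted dispersal distance (km)") +
    ggplot2::theme_minimal()
}
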