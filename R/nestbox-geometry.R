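#' Build a validated nest-box registry
#'
#' A registry is a tibble of nest boxes with planar coordinates (km) and the
#' first calendar year each box was available, plus an era cutoff year that
#' splits the network into an early and a late box set (the study area was
#' enlarged once, so recruits hatched before the cutoff could only settle in
#' boxes of the early set).
#'
#' Coordinates may be supplied either as planar km (`x_km`, `y_km`) or as
#' geographic degrees (`lat`, `lon`). Geographic coordinates are projected
#' once, at ingest, onto a local azimuthal-equidistant planar frame centered
#' on the registry centroid; over a study area of a few hundred km^2 the
#' planar Euclidean distance then agrees with the geodesic to well below the
#' shortest dispersal distances of interest.
#'
#' @param boxes A data frame with columns `box_id`, `first_year`, and either
#'   `x_km`/`y_km` (planar km) or `lat`/`lon` (decimal degrees).
#' @param era_cutoff_year Calendar year splitting the early and late box sets.
#'   Boxes with `first_year < era_cutoff_year` form the early set.
#' @return A tibble of class `box_registry` with columns `box_id` (character),
#'   `x_km`, `y_km`, `first_year`, and attribute `era_cutoff_year`.
#' @examples
#' reg <- box_registry(
#'   data.frame(box_id = c("a", "b"), x_km = c(0, 3), y_km = c(0, 4),
#'              first_year = c(1980, 1990)),
#'   era_cutoff_year = 1987
#' )
#' pairwise_distances(reg)
#' @export
box_registry <- function(boxes, era_cutoff_year) {
  stopifnot(is.data.frame(boxes))
  boxes <- tibble::as_tibble(boxes)
  required <- c("box_id", "first_year")
  missing_cols <- setdiff(required, names(boxes))
  if (length(missing_cols) > 0) {
    stop("registry is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(boxes) < 2) {
    stop("a registry needs at least 2 boxes", call. = FALSE)
  }
  boxes$box_id <- as.character(boxes$box_id)
  if (anyDuplicated(boxes$box_id)) {
    dup <- unique(boxes$box_id[duplicated(boxes$box_id)])
    stop("duplicate box_id in registry: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }

  has_planar <- all(c("x_km", "y_km") %in% names(boxes))
  has_geo <- all(c("lat", "lon") %in% names(boxes))
  if (!has_planar && !has_geo) {
    stop("registry needs either x_km/y_km or lat/lon coordinates", call. = FALSE)
  }
  if (!has_planar) {
    boxes <- project_lonlat(boxes)
  }

  bad <- !is.finite(boxes$x_km) | !is.finite(boxes$y_km)
  if (any(bad)) {
    stop("non-finite coordinates for box(es): ",
         paste(boxes$box_id[bad], collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(boxes$first_year) || any(!is.finite(boxes$first_year))) {
    stop("first_year must be finite numeric years", call. = FALSE)
  }
  if (!is.numeric(era_cutoff_year) || length(era_cutoff_year) != 1 ||
      !is.finite(era_cutoff_year)) {
    stop("era_cutoff_year must be a single year", call. = FALSE)
  }
  if (era_cutoff_year < min(boxes$first_year) ||
      era_cutoff_year > max(boxes$first_year) + 1) {
    stop("era_cutoff_year ", era_cutoff_year,
         " lies outside the span of first_year values", call. = FALSE)
  }

  out <- dplyr::select(boxes, "box_id", "x_km", "y_km", "first_year")
  attr(out, "era_cutoff_year") <- era_cutoff_year
  class(out) <- c("box_registry", class(out))
  out
}

# Azimuthal-equidistant projection about the registry centroid: each box is
# placed at (d sin(theta), d cos(theta)) where d is the geodesic distance and
# theta the initial bearing from the centroid.
project_lonlat <- function(boxes) {
  if (any(!is.finite(boxes$lat)) || any(!is.finite(boxes$lon))) {
    bad <- boxes$box_id[!is.finite(boxes$lat) | !is.finite(boxes$lon)]
    stop("non-finite coordinates for box(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  center <- c(mean(boxes$lon), mean(boxes$lat))
  pts <- cbind(boxes$lon, boxes$lat)
  d_km <- geosphere::distGeo(center, pts) / 1000
  theta <- geosphere::bearing(center, pts) * pi / 180
  theta[is.na(theta)] <- 0  # a box exactly at the centroid has no bearing
  boxes$x_km <- d_km * sin(theta)
  boxes$y_km <- d_km * cos(theta)
  boxes
}

#' Era cutoff year of a registry
#' @param registry A `box_registry`.
#' @return The cutoff year as a scalar.
#' @export
era_cutoff <- function(registry) {
  cut <- attr(registry, "era_cutoff_year")
  if (is.null(cut)) stop("not a box_registry: missing era_cutoff_year", call. = FALSE)
  cut
}

#' Pairwise Euclidean distances between all boxes
#'
#' @param registry A `box_registry`.
#' @return A symmetric numeric matrix in km with zero diagonal; rows and
#'   columns named by `box_id`.
#' @export
pairwise_distances <- function(registry) {
  coords <- as.matrix(registry[, c("x_km", "y_km")])
  rownames(coords) <- registry$box_id
  d <- as.matrix(stats::dist(coords, method = "euclidean"))
  dimnames(d) <- list(registry$box_id, registry$box_id)
  d
}

#' Boxes detectable for a recruit of a given hatch year
#'
#' Recruits hatched before the era cutoff could only be observed settling in
#' boxes of the early set (`first_year < era_cutoff_year`); recruits hatched
#' in the cutoff year or later could settle anywhere in the full network.
#'
#' @param registry A `box_registry`.
#' @param hatch_year Calendar year the recruit hatched.
#' @return The subset of registry rows available to that cohort.
#' @export
available_boxes <- function(registry, hatch_year) {
  stopifnot(is.numeric(hatch_year), length(hatch_year) == 1, is.finite(hatch_year))
  cut <- era_cutoff(registry)
  out <- if (hatch_year >= cut) {
    registry
  } else {
    dplyr::filter(registry, .data$first_year < cut)
  }
  if (nrow(out) == 0) {
    stop("no boxes available for hatch year ", hatch_year,
         " (empty pre-", cut, " set)", call. = FALSE)
  }
  out
}

#' Natal dispersal distance between two boxes
#'
#' The straight-line (Euclidean) distance in km from the natal box to the
#' first-breeding box, both expressed in the same planar frame. A distance of
#' 0 (re-use of the natal box) is permitted here; whether such records enter
#' an analysis is decided downstream.
#'
#' @param natal,breeding Single-row data frames (or lists) with `x_km` and
#'   `y_km` elements, e.g. rows of a `box_registry`.
#' @return Distance in km (scalar, >= 0).
#' @export
natal_dispersal_distance <- function(natal, breeding) {
  x1 <- as.numeric(natal$x_km);    y1 <- as.numeric(natal$y_km)
  x2 <- as.numeric(breeding$x_km); y2 <- as.numeric(breeding$y_km)
  if (length(x1) != 1 || length(x2) != 1 ||
      !all(is.finite(c(x1, y1, x2, y2)))) {
    stop("both boxes must carry one finite x_km/y_km coordinate pair",
         call. = FALSE)
  }
  sqrt((x1 - x2)^2 + (y1 - y2)^2)
}

#' Attach dispersal distances to a recruit table
#'
#' Joins natal and breeding coordinates from the registry and computes the
#' straight-line dispersal distance per recruit.
#'
#' @param recruits A data frame with `natal_box_id` and `breeding_box_id`.
#' @param registry A `box_registry` containing every referenced box.
#' @return The recruit tibble with a `dispersal_km` column appended.
#' @export
dispersal_distances <- function(recruits, registry) {
  recruits <- tibble::as_tibble(recruits)
  idx_n <- match(as.character(recruits$natal_box_id), registry$box_id)
  idx_b <- match(as.character(recruits$breeding_box_id), registry$box_id)
  if (anyNA(idx_n) || anyNA(idx_b)) {
    bad <- unique(c(recruits$natal_box_id[is.na(idx_n)],
                    recruits$breeding_box_id[is.na(idx_b)]))
    stop("box id(s) not in registry: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  recruits$dispersal_km <- sqrt(
    (registry$x_km[idx_n] - registry$x_km[idx_b])^2 +
    (registry$y_km[idx_n] - registry$y_km[idx_b])^2
  )
  recruits
}

#' Read / write a nest-box registry CSV
#'
#' The CSV carries columns `box_id`, `first_year`, and either `x_km`/`y_km`
#' or `lat`/`lon` (comma-separated, UTF-8, header row).
#'
#' @param path File path.
#' @param era_cutoff_year Passed to [box_registry()].
#' @return `read_box_registry()` returns a `box_registry`.
#' @export
read_box_registry <- function(path, era_cutoff_year) {
  box_registry(readr::read_csv(path, show_col_types = FALSE), era_cutoff_year)
}

#' @rdname read_box_registry
#' @param registry A `box_registry` to write.
#' @export
write_box_registry <- function(registry, path) {
  readr::write_csv(tibble::as_tibble(registry), path)
  invisible(path)
}
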