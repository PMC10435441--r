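#' Simulate a skin reflectance spectrum
#'
#' One Monte Carlo run per grid wavelength. A "wet skin" variant is obtained
#' by building the same stack with a film and/or raised water fractions.
#'
#' @param stack a `skin_stack` whose grid covers the requested wavelengths.
#' @param geometry a [sensor_geometry()].
#' @param config a [sim_config()]; each wavelength gets a derived sub-seed.
#' @param wavelengths wavelengths to simulate (default: the stack grid).
#' @param detect `"aperture"` uses the detector-square estimate, `"total"`
#'   the total top-surface (diffuse + specular) reflectance, which has far
#'   lower variance at strongly absorbed wavelengths.
#' @return data.frame: `wavelength_nm`, `reflectance`, `se`.
#' @export
simulate_reflectance_spectrum <- function(stack, geometry = sensor_geometry(),
                                          config = sim_config(),
                                          wavelengths = stack$wavelengths,
                                          detect = c("aperture", "total")) {
  detect <- match.arg(detect)
  out <- lapply(seq_along(wavelengths), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, i)
    rec <- run_mc(stack, geometry, cfg, wavelengths[i])
    if (detect == "aperture")
      data.frame(wavelength_nm = wavelengths[i], reflectance = rec$reflectance,
                 se = rec$reflectance_se)
    else
      data.frame(wavelength_nm = wavelengths[i],
                 reflectance = rec$total_reflectance,
                 se = rec$total_reflectance_se)
  })
  do.call(rbind, out)
}

#' Film-thickness x incidence-angle reflectance map
#'
#' Full Cartesian sweep emulating the in-silico wrist-movement experiment:
#' for every (film thickness, incidence angle, wavelength) cell a fresh stack
#' is built and simulated; each cell carries its Monte Carlo standard error.
#'
#' @param films_um film thickness grid, micrometers (default 0-500, 11 pts).
#' @param angles_deg incidence angle grid, degrees (default 0-45, 10 pts).
#' @param wavelengths wavelengths in nm (default 970 and 1450).
#' @param composition,layers passed to [build_skin_stack()].
#' @param geometry base [sensor_geometry()]; its incidence angle is overridden
#'   by the sweep.
#' @param config a [sim_config()]; cells get derived sub-seeds.
#' @param detect see [simulate_reflectance_spectrum()].
#' @return object of class `"reflectance_map"`: arrays `reflectance` and `se`
#'   of shape (films, angles, wavelengths) plus the grids.
#' @export
film_angle_map <- function(films_um = seq(0, 500, length.out = 11),
                           angles_deg = seq(0, 45, length.out = 10),
                           wavelengths = c(970, 1450),
                           composition = list(), layers = default_skin_layers(),
                           geometry = sensor_geometry(), config = sim_config(),
                           detect = c("aperture", "total"),
                           tables = chromophore_tables()) {
  detect <- match.arg(detect)
  if (!length(films_um) || !length(angles_deg) || !length(wavelengths))
    stop("film, angle and wavelength grids must be non-empty")
  grid <- wavelength_grid(sort(wavelengths))
  dims <- c(length(films_um), length(angles_deg), length(wavelengths))
  dn <- list(film_um = films_um, angle_deg = angles_deg,
             wavelength_nm = wavelengths)
  refl <- array(NA_real_, dims, dimnames = dn)
  se <- array(NA_real_, dims, dimnames = dn)
  cell <- 0L
  for (i in seq_along(films_um)) {
    stack <- build_skin_stack(composition, grid = grid,
                              film_thickness_mm = films_um[i] / 1000,
                              layers = layers, tables = tables)
    for (j in seq_along(angles_deg)) {
      geo <- geometry
      geo$theta_in_deg <- angles_deg[j]
      for (k in seq_along(wavelengths)) {
        cell <- cell + 1L
        cfg <- config
        cfg$seed <- derive_seed(config$seed, cell)
        rec <- run_mc(stack, geo, cfg, wavelengths[k])
        if (detect == "aperture") {
          refl[i, j, k] <- rec$reflectance
          se[i, j, k] <- rec$reflectance_se
        } else {
          refl[i, j, k] <- rec$total_reflectance
          se[i, j, k] <- rec$total_reflectance_se
        }
      }
    }
  }
  structure(list(reflectance = refl, se = se, films_um = films_um,
                 angles_deg = angles_deg, wavelengths = wavelengths,
                 detect = detect, seed = config$seed,
                 n_photons = config$n_photons),
            class = "reflectance_map")
}

#' @export
print.reflectance_map <- function(x, ...) {
  cat("<reflectance_map>", length(x$films_um), "film x",
      length(x$angles_deg), "angle x", length(x$wavelengths),
      "wavelength cells (", x$detect, "detection,", x$n_photons,
      "packets/cell )\n")
  invisible(x)
}

#' Signed reflectance trend versus film thickness
#'
#' Least-squares slope of reflectance against film thickness at a fixed
#' incidence angle, with a 3-sigma sign test against the combined Monte Carlo
#' standard error of the slope.
#'
#' @param map a `reflectance_map`.
#' @param wavelength one of the map's wavelengths.
#' @param angle_deg one of the map's angles (default: first).
#' @return list: `trend` (`"up"`, `"down"` or `"flat"`), `slope`
#'   (reflectance per micrometer), `slope_se`, `z`.
#' @export
wavelength_trend_curve <- function(map, wavelength,
                                   angle_deg = map$angles_deg[1]) {
  k <- match(wavelength, map$wavelengths)
  j <- match(angle_deg, map$angles_deg)
  if (is.na(k) || is.na(j)) stop("wavelength or angle not in the map")
  if (length(map$films_um) < 3) {
    warning("fewer than 3 film thicknesses; reporting flat trend")
    return(list(trend = "flat", slope = 0, slope_se = NA_real_, z = NA_real_))
  }
  x <- map$films_um
  y <- map$reflectance[, j, k]
  s <- map$se[, j, k]
  xc <- x - mean(x)
  denom <- sum(xc^2)
  slope <- sum(xc * y) / denom
  slope_se <- sqrt(sum((xc / denom)^2 * s^2))
  z <- if (slope_se > 0) slope / slope_se else 0
  trend <- if (abs(z) < 3 || slope == 0) "flat" else if (slope > 0) "up" else "down"
  list(trend = trend, slope = slope, slope_se = slope_se, z = z)
}
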