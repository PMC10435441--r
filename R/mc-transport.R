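#' Sample a photon free path length
#'
#' Path lengths between interaction events follow the Beer--Lambert
#' distribution `p(l) = mu_t exp(-mu_t l)`; inverse-CDF sampling gives
#' `l = -log(u) / mu_t`.
#'
#' @param mu_t interaction coefficient, 1/mm; must be > 0 (a purely
#'   non-interacting layer is handled by direct boundary transfer inside the
#'   tracer, not here).
#' @param u uniform deviate(s) in (0, 1).
#' @return path length(s) in mm.
#' @export
#' @examples
#' sample_free_path(1, exp(-1)) # exactly 1 mm
sample_free_path <- function(mu_t, u) {
  if (any(mu_t <= 0)) stop("mu_t must be > 0")
  if (any(u <= 0) || any(u >= 1)) stop("deviates must lie in (0, 1)")
  -log(u) / mu_t
}

#' Henyey--Greenstein phase function
#'
#' Probability density of the scattering deflection cosine,
#' `p(cos theta) = (1 - g^2) / (4 pi (1 + g^2 - 2 g cos theta)^{3/2})`
#' (normalized over the sphere). At `g = 0` it reduces to the isotropic
#' `1/(4 pi)`.
#'
#' @param cos_theta deflection cosine(s) in \[-1, 1\].
#' @param g anisotropy factor, |g| < 1.
#' @return density per unit solid angle.
#' @export
hg_phase_function <- function(cos_theta, g) {
  if (abs(g) >= 1) stop("anisotropy g must satisfy |g| < 1")
  (1 - g^2) / (4 * pi * (1 + g^2 - 2 * g * cos_theta)^1.5)
}

#' Sample a new scattering direction from the Henyey--Greenstein function
#'
#' Inverse-CDF sampling of the deflection cosine with a uniform azimuth,
#' rotated into the frame of the incoming direction.
#'
#' @param g anisotropy factor, |g| < 1.
#' @param direction incoming unit 3-vector.
#' @param u two uniform deviates in (0, 1): deflection and azimuth.
#' @return new unit 3-vector.
#' @export
sample_scatter_direction <- function(g, direction, u) {
  if (abs(g) >= 1) stop("anisotropy g must satisfy |g| < 1")
  if (length(direction) != 3L || abs(sqrt(sum(direction^2)) - 1) > 1e-9)
    stop("direction must be a unit 3-vector")
  if (length(u) != 2L || any(u <= 0) || any(u >= 1))
    stop("u must be two deviates in (0, 1)")
  ct <- if (abs(g) < 1e-6) 1 - 2 * u[1] else {
    t <- (1 - g^2) / (1 - g + 2 * g * u[1])
    (1 + g^2 - t^2) / (2 * g)
  }
  ct <- min(1, max(-1, ct))
  st <- sqrt(1 - ct^2)
  phi <- 2 * pi * u[2]
  wx <- direction[1]; wy <- direction[2]; wz <- direction[3]
  if (abs(wz) > 0.99999) {
    out <- c(st * cos(phi), st * sin(phi), ct * sign(wz))
  } else {
    den <- sqrt(1 - wz^2)
    out <- c(st * (wx * wz * cos(phi) - wy * sin(phi)) / den + wx * ct,
             st * (wy * wz * cos(phi) + wx * sin(phi)) / den + wy * ct,
             -den * st * cos(phi) + wz * ct)
  }
  out / sqrt(sum(out^2))
}

#' Attenuate a photon packet weight by absorption
#'
#' `W' = W exp(-mu_a l)`; the difference `W - W'` is the amount credited to
#' the absorbed-weight tally by the tracer.
#'
#' @param w current weight(s) in (0, 1\].
#' @param mu_a absorption coefficient, 1/mm, >= 0.
#' @param l path length, mm, >= 0.
#' @return attenuated weight.
#' @export
attenuate_weight <- function(w, mu_a, l) {
  if (any(w <= 0) || any(w > 1)) stop("weight must lie in (0, 1]")
  if (any(mu_a < 0) || any(l < 0)) stop("mu_a and l must be >= 0")
  w * exp(-mu_a * l)
}

#' Unpolarized Fresnel reflectance
#'
#' @param n1,n2 refractive indices on the incidence and transmission sides.
#' @param cos_i cosine of the incidence angle (>= 0).
#' @return reflection probability in \[0, 1\] (1 beyond the critical angle).
#' @export
#' @examples
#' fresnel_reflectance(1, 1.5, 1) # ((1 - 1.5)/(1 + 1.5))^2 = 0.04
fresnel_reflectance <- function(n1, n2, cos_i) {
  sin_i <- sqrt(pmax(0, 1 - cos_i^2))
  sin_t <- n1 / n2 * sin_i
  ifelse(sin_t >= 1, 1, {
    cos_t <- sqrt(pmax(0, 1 - pmin(sin_t, 1)^2))
    rs <- (n1 * cos_i - n2 * cos_t) / (n1 * cos_i + n2 * cos_t)
    rp <- (n1 * cos_t - n2 * cos_i) / (n1 * cos_t + n2 * cos_i)
    (rs^2 + rp^2) / 2
  })
}

#' Reflect or refract a packet at a planar interface
#'
#' With probability equal to the unpolarized Fresnel reflectance the packet is
#' specularly reflected; otherwise it is refracted by Snell's law. Beyond the
#' critical angle reflection is certain.
#'
#' @param direction incident unit 3-vector.
#' @param n1,n2 refractive indices (incidence / transmission side), >= 1.
#' @param u uniform deviate in \[0, 1) deciding reflect vs refract.
#' @param normal interface unit normal (default z axis).
#' @return list with `direction` (unit 3-vector), `reflected` (logical) and
#'   `reflectance` (the Fresnel probability used).
#' @export
boundary_interaction <- function(direction, n1, n2, u, normal = c(0, 0, 1)) {
  if (n1 < 1 || n2 < 1) stop("refractive indices must be >= 1")
  cos_i <- abs(sum(direction * normal))
  R <- fresnel_reflectance(n1, n2, cos_i)
  if (u < R) {
    d <- direction - 2 * sum(direction * normal) * normal
    return(list(direction = d, reflected = TRUE, reflectance = R))
  }
  tang <- direction - sum(direction * normal) * normal
  tang <- tang * n1 / n2
  nz <- sqrt(max(0, 1 - sum(tang^2)))
  d <- tang + sign(sum(direction * normal)) * nz * normal
  list(direction = d / sqrt(sum(d^2)), reflected = FALSE, reflectance = R)
}

#' Sensor geometry of the wrist PPG module
#'
#' Pencil-beam source entering the top surface at `theta_in` degrees from the
#' normal (tilted toward the detector), and a square detector of the stated
#' side length centered `separation_mm` away. Detection requires exit through
#' the top surface inside the square within the numerical-aperture half-angle.
#'
#' @param separation_mm LED--photodetector center separation, mm (the hardware
#'   uses 3.5 or 5.5 mm).
#' @param side_mm detector side length, mm (hardware: 1.5 mm square).
#' @param theta_in_deg incidence angle from the surface normal, degrees,
#'   in \[0, 90).
#' @param na_half_angle_deg acceptance half-angle, degrees (90 = no NA cut).
#' @return object of class `"sensor_geometry"`.
#' @export
sensor_geometry <- function(separation_mm = 3.5, side_mm = 1.5,
                            theta_in_deg = 0, na_half_angle_deg = 90) {
  if (side_mm <= 0) stop("detector side length must be > 0")
  if (theta_in_deg < 0 || theta_in_deg >= 90)
    stop("incidence angle must lie in [0, 90) degrees")
  structure(list(separation_mm = separation_mm, side_mm = side_mm,
                 theta_in_deg = theta_in_deg,
                 na_half_angle_deg = na_half_angle_deg),
            class = "sensor_geometry")
}

#' Monte Carlo simulation configuration
#'
#' @param n_photons number of photon packets (>= 1).
#' @param seed RNG master seed; each packet gets an independent substream.
#' @param roulette_threshold weight below which Russian roulette is played.
#'   The default is far below the classical 1e-4 because weight-based detection
#'   at strongly absorbed wavelengths (1450 nm) relies on packets carrying
#'   weights of order 1e-7 and smaller.
#' @param roulette_survival survival probability; survivors are rescaled by
#'   its inverse so termination is unbiased.
#' @param max_interactions cap on events per packet; packets hitting it are
#'   moved to a dedicated truncation tally.
#' @return object of class `"sim_config"`.
#' @export
sim_config <- function(n_photons = 1e5, seed = 1,
                       roulette_threshold = 1e-12, roulette_survival = 0.1,
                       max_interactions = 1e5) {
  if (n_photons < 1) stop("n_photons must be >= 1")
  if (roulette_threshold <= 0 || roulette_threshold >= 1)
    stop("roulette_threshold must lie in (0, 1)")
  if (roulette_survival <= 0 || roulette_survival >= 1)
    stop("roulette_survival must lie in (0, 1)")
  structure(list(n_photons = as.integer(n_photons), seed = as.integer(seed),
                 roulette_threshold = roulette_threshold,
                 roulette_survival = roulette_survival,
                 max_interactions = as.integer(max_interactions)),
            class = "sim_config")
}

#' Run the photon-packet Monte Carlo at one wavelength
#'
#' Traces `n_photons` packets through the stack: exponential free paths in the
#' scattering coefficient, Henyey--Greenstein deflections, continuous
#' absorption weighting `W <- W exp(-mu_a l)`, Fresnel reflection/refraction at
#' every index mismatch, unbiased Russian roulette, and aperture detection at
#' the top surface.
#'
#' @param stack a `skin_stack` (or any list with the same fields).
#' @param geometry a [sensor_geometry()].
#' @param config a [sim_config()].
#' @param wavelength wavelength in nm; must be on the stack grid.
#' @return object of class `"detection_record"`: weight ledger (detected,
#'   escaped-undetected, transmitted, absorbed, truncated), the detected
#'   reflectance estimate with its Monte Carlo standard error, the total
#'   top-surface reflectance with standard error, and provenance (seed,
#'   photon count, wavelength, geometry).
#' @export
run_mc <- function(stack, geometry = sensor_geometry(), config = sim_config(),
                   wavelength = stack$wavelengths[1]) {
  props <- stack_at_wavelength(stack, wavelength)
  raw <- .mc_run_cpp(
    props$mu_a, props$mu_s, props$g, props$n, props$thickness,
    props$n_ambient,
    0.0, geometry$theta_in_deg,
    geometry$separation_mm, geometry$side_mm / 2, geometry$side_mm / 2,
    geometry$na_half_angle_deg,
    config$n_photons, as.double(config$seed),
    config$roulette_threshold, config$roulette_survival,
    config$max_interactions, FALSE)
  rec <- c(raw, list(wavelength = wavelength, seed = config$seed,
                     n_photons = config$n_photons, geometry = geometry))
  class(rec) <- "detection_record"
  rec
}

#' @export
print.detection_record <- function(x, ...) {
  cat(sprintf("<detection_record> %g nm, %d packets (seed %d)\n",
              x$wavelength, x$n_photons, x$seed))
  cat(sprintf("  detected reflectance: %.4g +/- %.2g (%d packets)\n",
              x$reflectance, x$reflectance_se, as.integer(x$detected_count)))
  cat(sprintf("  total top reflectance: %.4g +/- %.2g\n",
              x$total_reflectance, x$total_reflectance_se))
  bal <- with(x, detected_weight + escaped_weight + transmitted_weight +
                absorbed_weight + truncated_weight)
  cat(sprintf("  ledger: absorbed %.4g, transmitted %.4g, truncated %.3g, balance %.3g\n",
              x$absorbed_weight, x$transmitted_weight, x$truncated_weight,
              bal - x$launched_weight))
  invisible(x)
}

#' Trace photon packets and return their terminal events
#'
#' Runs the same tracer as [run_mc()] but additionally reports every packet's
#' terminal event, one of `"detected"`, `"escaped"`, `"transmitted"`,
#' `"absorbed_roulette"`, `"truncated"`.
#'
#' @inheritParams run_mc
#' @return list: `events` (character vector, one per packet) and `record`
#'   (the aggregate `detection_record`).
#' @export
trace_photon <- function(stack, geometry = sensor_geometry(),
                         config = sim_config(n_photons = 1),
                         wavelength = stack$wavelengths[1]) {
  props <- stack_at_wavelength(stack, wavelength)
  raw <- .mc_run_cpp(
    props$mu_a, props$mu_s, props$g, props$n, props$thickness,
    props$n_ambient,
    0.0, geometry$theta_in_deg,
    geometry$separation_mm, geometry$side_mm / 2, geometry$side_mm / 2,
    geometry$na_half_angle_deg,
    config$n_photons, as.double(config$seed),
    config$roulette_threshold, config$roulette_survival,
    config$max_interactions, TRUE)
  codes <- c("detected", "escaped", "transmitted", "absorbed_roulette",
             "truncated")
  events <- codes[raw$events + 1L]
  raw$events <- NULL
  rec <- c(raw, list(wavelength = wavelength, seed = config$seed,
                     n_photons = config$n_photons, geometry = geometry))
  class(rec) <- "detection_record"
  list(events = events, record = rec)
}

#' Build a bare homogeneous slab stack (for benchmarks and toy problems)
#'
#' A single- or multi-slab medium with directly specified optical properties;
#' shares the `skin_stack` representation so it can drive [run_mc()].
#'
#' @param mu_a,mu_s,g,n per-layer vectors (recycled to a common length).
#' @param thickness_mm per-layer thicknesses; `Inf` allowed for the last.
#' @param wavelength nominal wavelength label, nm.
#' @param n_ambient ambient refractive index.
#' @return a `skin_stack` object.
#' @export
slab_stack <- function(mu_a, mu_s, g = 0, n = 1, thickness_mm = Inf,
                       wavelength = 970, n_ambient = 1) {
  L <- max(length(mu_a), length(mu_s), length(g), length(n),
           length(thickness_mm))
  mu_a <- rep_len(mu_a, L); mu_s <- rep_len(mu_s, L)
  g <- rep_len(g, L); n <- rep_len(n, L)
  thickness_mm <- rep_len(thickness_mm, L)
  if (any(mu_a < 0) || any(mu_s < 0)) stop("mu_a and mu_s must be >= 0")
  structure(list(
    names = paste0("slab", seq_len(L)), thickness_mm = thickness_mm,
    g = g, n = n,
    mu_a = matrix(mu_a, L, 1, dimnames = list(NULL, wavelength)),
    mu_s = matrix(mu_s, L, 1, dimnames = list(NULL, wavelength)),
    wavelengths = wavelength, composition = list(),
    film_thickness_mm = 0, n_ambient = n_ambient, layers = NULL
  ), class = "skin_stack")
}
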