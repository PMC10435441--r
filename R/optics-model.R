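#' Wavelength grid
#'
#' Validated vector of vacuum wavelengths for spectrally resolved optical
#' properties. The chromophore tables shipped with the package cover
#' 450--1750 nm; outside that range no extrapolation is performed.
#'
#' @param wavelengths numeric vector of vacuum wavelengths in nm,
#'   strictly increasing, all inside \[450, 1750\].
#' @return numeric vector with class `"wavelength_grid"`.
#' @export
#' @examples
#' wavelength_grid(c(535, 940, 970, 1450))
wavelength_grid <- function(wavelengths) {
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) < 1L || anyNA(wavelengths))
    stop("wavelength grid must be a non-empty numeric vector without NA")
  if (any(diff(wavelengths) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (min(wavelengths) < 450 || max(wavelengths) > 1750)
    stop("wavelengths must lie within the validated 450-1750 nm range")
  structure(wavelengths, class = "wavelength_grid")
}

#' Chromophore and layer scattering tables
#'
#' Loads the packaged literature-class spectra used to assemble layer optical
#' properties: pure water absorption (Hale--Querry/Segelstein-class table),
#' oxy-/deoxy-hemoglobin molar extinction (Prahl-class anchors, converted to
#' whole-blood absorption at 150 g/L, 64500 g/mol), a melanosome power-law
#' absorption model and the standard skin baseline absorption formula, plus
#' power-law reduced-scattering parameters per tissue class. All absorption
#' coefficients are returned in 1/mm.
#'
#' @param grid optional `wavelength_grid`; when supplied, the tabulated spectra
#'   are linearly interpolated onto it and returned as vectors.
#' @return list with elements `water`, `hbo2`, `hb`, `melanin`, `baseline`
#'   (each a function of wavelength in nm returning mu_a in 1/mm, or a vector
#'   on `grid` if given) and `scattering` (data.frame of per-tissue power-law
#'   parameters).
#' @export
chromophore_tables <- function(grid = NULL) {
  water <- read.csv(system.file("extdata", "water_absorption.csv",
                                package = "ppgsweat"), comment.char = "#")
  hemo <- read.csv(system.file("extdata", "hemoglobin_extinction.csv",
                               package = "ppgsweat"), comment.char = "#")
  interp <- function(x, y) {
    force(x); force(y)
    function(wl) {
      if (any(wl < min(x)) || any(wl > max(x)))
        stop("wavelength outside tabulated range [", min(x), ", ", max(x), "] nm")
      approx(x, y, xout = wl)$y
    }
  }
  # molar extinction (1/(cm M)) -> whole-blood mu_a (1/mm):
  # ln(10) * eps * C / MW, C = 150 g/L, MW = 64500 g/mol, then cm -> mm.
  blood_scale <- log(10) * 150 / 64500 / 10
  f_water <- interp(water$wavelength_nm, water$mu_a_per_cm / 10)
  f_hbo2 <- interp(hemo$wavelength_nm, hemo$eps_hbo2 * blood_scale)
  f_hb <- interp(hemo$wavelength_nm, hemo$eps_hb * blood_scale)
  # Jacques-style interior-of-melanosome absorption, 1/mm
  f_mel <- function(wl) {
    check_range(wl)
    6.6e11 * wl^-3.33 / 10
  }
  # standard skin baseline absorption, 1/mm
  f_base <- function(wl) {
    check_range(wl)
    (0.244 + 85.3 * exp(-(wl - 154) / 66.2)) / 100
  }
  check_range <- function(wl) {
    if (any(wl < 450) || any(wl > 1750))
      stop("wavelength outside tabulated range [450, 1750] nm")
  }
  scattering <- data.frame(
    tissue = c("stratum_corneum", "epidermis", "dermis", "hypodermis"),
    a_red_per_mm = c(7.0, 6.87, 4.53, 3.52), # mu_s' at 500 nm, 1/mm
    b = c(1.2, 1.16, 1.29, 0.68),
    stringsAsFactors = FALSE
  )
  out <- list(water = f_water, hbo2 = f_hbo2, hb = f_hb,
              melanin = f_mel, baseline = f_base, scattering = scattering)
  if (!is.null(grid)) {
    wl <- as.numeric(grid)
    out[c("water", "hbo2", "hb", "melanin", "baseline")] <-
      lapply(out[c("water", "hbo2", "hb", "melanin", "baseline")],
             function(f) f(wl))
  }
  out
}

#' Absorption coefficient of a skin layer from its chromophore composition
#'
#' Linear mixing rule: volume-fraction-weighted sum of the chromophore
#' absorption spectra plus the skin baseline,
#' `mu_a = C_mel mu_mel + C_blood (S mu_HbO2 + (1-S) mu_Hb) + f_w mu_water + mu_base`.
#'
#' @param composition list with fractions in \[0,1\]: `melanin`, `blood`,
#'   `oxygen_saturation`, `water` (missing entries default to 0; saturation
#'   defaults to 0.97).
#' @param wavelength numeric, nm, inside the tabulated range.
#' @param tables chromophore tables from [chromophore_tables()] (functions form).
#' @return absorption coefficient in 1/mm (vectorized over `wavelength`).
#' @export
#' @examples
#' absorption_coefficient(list(water = 1), 1450) /
#'   absorption_coefficient(list(water = 1), 970) # water-band contrast >> 1
absorption_coefficient <- function(composition, wavelength,
                                   tables = chromophore_tables()) {
  comp <- list(melanin = 0, blood = 0, oxygen_saturation = 0.97, water = 0)
  unknown <- setdiff(names(composition), names(comp))
  if (length(unknown)) stop("unknown composition fields: ",
                            paste(unknown, collapse = ", "))
  comp[names(composition)] <- composition
  frac <- unlist(comp)
  if (any(frac < 0) || any(frac > 1))
    stop("composition fractions must lie in [0, 1]")
  s <- comp$oxygen_saturation
  comp$melanin * tables$melanin(wavelength) +
    comp$blood * (s * tables$hbo2(wavelength) + (1 - s) * tables$hb(wavelength)) +
    comp$water * tables$water(wavelength) +
    tables$baseline(wavelength)
}

#' Power-law scattering coefficient for a tissue class
#'
#' Reduced scattering `mu_s'(lambda) = a (lambda/500)^(-b)` per tissue class,
#' converted to the full scattering coefficient via `mu_s = mu_s'/(1 - g)`.
#'
#' @param tissue one of `"stratum_corneum"`, `"epidermis"`, `"dermis"`,
#'   `"hypodermis"`.
#' @param wavelength nm.
#' @param g anisotropy factor used for the conversion.
#' @param tables chromophore tables (for the parameter data.frame).
#' @return scattering coefficient mu_s in 1/mm.
#' @export
scattering_coefficient <- function(tissue, wavelength, g = 0.9,
                                   tables = chromophore_tables()) {
  p <- tables$scattering[tables$scattering$tissue == tissue, ]
  if (nrow(p) != 1L) stop("unknown tissue class: ", tissue)
  if (abs(g) >= 1) stop("anisotropy g must satisfy |g| < 1")
  p$a_red_per_mm * (wavelength / 500)^(-p$b) / (1 - g)
}

#' Default seven-layer skin parameterization
#'
#' The seven functional sub-layers (epidermis: stratum corneum + living
#' epidermis; dermis: papillary, upper blood net, reticular, deep blood net;
#' hypodermis) with default thicknesses, water and blood volume fractions,
#' anisotropy and refractive index. Values follow the multi-layer skin model
#' family the simulator is built around; every column can be overridden.
#'
#' @return data.frame with one row per sub-layer.
#' @export
default_skin_layers <- function() {
  data.frame(
    name = c("stratum_corneum", "living_epidermis", "papillary_dermis",
             "upper_blood_dermis", "reticular_dermis", "deep_blood_dermis",
             "hypodermis"),
    tissue = c("stratum_corneum", "epidermis", "dermis", "dermis",
               "dermis", "dermis", "hypodermis"),
    thickness_mm = c(0.02, 0.08, 0.15, 0.10, 1.50, 0.20, 6.0),
    water = c(0.05, 0.20, 0.50, 0.60, 0.70, 0.70, 0.70),
    blood = c(0.00, 0.00, 0.04, 0.30, 0.04, 0.10, 0.05),
    melanin_host = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    g = c(0.86, 0.80, 0.90, 0.90, 0.90, 0.90, 0.80),
    n = c(1.50, 1.34, 1.40, 1.39, 1.40, 1.38, 1.44),
    stringsAsFactors = FALSE
  )
}

#' Build the layered skin stack with spectrally resolved optical properties
#'
#' Assembles the medium the Monte Carlo walks through: an optional topical
#' water/sweat film, the seven functional skin sub-layers, and a semi-infinite
#' base with hypodermis properties. The film has pure-water absorption, no
#' scattering and n = 1.33.
#'
#' @param composition list: `C_mel` melanin volume fraction in the living
#'   epidermis, `C_blood` global blood-fraction scale (multiplies the per-layer
#'   blood column), `S_blood` oxygen saturation; all in \[0,1\].
#' @param grid [wavelength_grid()].
#' @param film_thickness_mm topical film thickness, mm; 0 omits the film layer.
#' @param layers optional data.frame overriding [default_skin_layers()]
#'   (e.g. ultrasound-informed thicknesses); must keep exactly 7 rows.
#' @param n_ambient refractive index above the stack (air = 1).
#' @param tables chromophore tables.
#' @return object of class `"skin_stack"`: per-layer data.frame plus
#'   `mu_a`/`mu_s` matrices (layers x wavelengths) and metadata.
#' @export
#' @examples
#' st <- build_skin_stack(grid = wavelength_grid(c(970, 1450)),
#'                        film_thickness_mm = 0.1)
#' st
build_skin_stack <- function(composition = list(),
                             grid = wavelength_grid(c(535, 940, 970, 1450)),
                             film_thickness_mm = 0,
                             layers = default_skin_layers(),
                             n_ambient = 1.0,
                             tables = chromophore_tables()) {
  comp <- list(C_mel = 0.02, C_blood = 1.0, S_blood = 0.97)
  unknown <- setdiff(names(composition), names(comp))
  if (length(unknown)) stop("unknown composition fields: ",
                            paste(unknown, collapse = ", "))
  comp[names(composition)] <- composition
  if (any(unlist(comp) < 0) || any(unlist(comp) > 1))
    stop("composition fractions must lie in [0, 1]")
  if (nrow(layers) != 7L)
    stop("exactly seven functional skin sub-layers are required, got ",
         nrow(layers))
  if (any(layers$thickness_mm <= 0)) stop("layer thicknesses must be > 0")
  if (film_thickness_mm < 0) stop("film_thickness_mm must be >= 0")
  wl <- as.numeric(grid)

  base <- layers[7L, ]             # semi-infinite continuation of hypodermis
  has_film <- film_thickness_mm > 0
  nm <- c(if (has_film) "film", layers$name, "base")
  nlay <- length(nm)

  thick <- c(if (has_film) film_thickness_mm, layers$thickness_mm, Inf)
  gvec <- c(if (has_film) 0, layers$g, base$g)
  nvec <- c(if (has_film) 1.33, layers$n, base$n)

  mu_a <- matrix(0, nlay, length(wl), dimnames = list(nm, wl))
  mu_s <- matrix(0, nlay, length(wl), dimnames = list(nm, wl))
  layer_mu <- function(row) {
    absorption_coefficient(
      list(melanin = if (row$melanin_host) comp$C_mel else 0,
           blood = comp$C_blood * row$blood,
           oxygen_saturation = comp$S_blood,
           water = row$water),
      wl, tables = tables)
  }
  for (i in seq_len(7L)) {
    idx <- i + has_film
    mu_a[idx, ] <- layer_mu(layers[i, ])
    mu_s[idx, ] <- scattering_coefficient(layers$tissue[i], wl,
                                          g = layers$g[i], tables = tables)
  }
  mu_a[nlay, ] <- layer_mu(base)
  mu_s[nlay, ] <- scattering_coefficient(base$tissue, wl, g = base$g,
                                         tables = tables)
  if (has_film) mu_a[1L, ] <- tables$water(wl)  # pure water film, mu_s = 0

  stopifnot(all(mu_a >= 0), all(mu_s >= 0), all(abs(gvec) < 1), all(nvec >= 1))
  structure(list(
    names = nm, thickness_mm = thick, g = gvec, n = nvec,
    mu_a = mu_a, mu_s = mu_s, wavelengths = wl,
    composition = comp, film_thickness_mm = film_thickness_mm,
    n_ambient = n_ambient, layers = layers
  ), class = "skin_stack")
}

#' @export
print.skin_stack <- function(x, ...) {
  cat("<skin_stack>", length(x$names), "media,",
      length(x$wavelengths), "wavelengths (",
      min(x$wavelengths), "-", max(x$wavelengths), "nm )\n")
  cat("  film:", if (x$film_thickness_mm > 0)
    paste0(x$film_thickness_mm * 1000, " um") else "none", "\n")
  cat("  layers:", paste(x$names, collapse = " > "), "\n")
  invisible(x)
}

# scalar per-layer optical properties at one wavelength (internal)
stack_at_wavelength <- function(stack, wavelength) {
  j <- match(wavelength, stack$wavelengths)
  if (is.na(j)) stop("wavelength ", wavelength, " nm is not on the stack grid")
  list(mu_a = stack$mu_a[, j], mu_s = stack$mu_s[, j],
       g = stack$g, n = stack$n, thickness = stack$thickness_mm,
       n_ambient = stack$n_ambient)
}
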