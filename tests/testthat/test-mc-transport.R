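test_that("free-path sampling: closed form, mean, scaling, domain", {
  expect_equal(sample_free_path(1, exp(-1)), 1.0)
  set.seed(42)
  u <- runif(1e5)
  l1 <- sample_free_path(2, u)
  expect_close(mean(l1), 0.5, 3 * sd(l1) / sqrt(length(l1)))
  expect_equal(mean(sample_free_path(4, u)), mean(l1) / 2)  # mu_t doubling
  expect_error(sample_free_path(0, 0.5), "mu_t")
  expect_error(sample_free_path(1, 0), "\\(0, 1\\)")
  # goodness of fit against the exponential law at n = 1e5, alpha = 0.01
  expect_gt(suppressWarnings(stats::ks.test(l1, "pexp", 2))$p.value, 0.01)
})

test_that("Henyey-Greenstein sampling: density, <cos> = g, isotropy, GOF", {
  expect_equal(hg_phase_function(0.3, 0), 1 / (4 * pi))
  expect_equal(hg_phase_function(-1, 0), 1 / (4 * pi))
  set.seed(7)
  n <- 1e5
  u <- matrix(runif(2 * n), n, 2)
  for (g in c(0, 0.9)) {
    ct <- vapply(seq_len(n), function(i)
      sample_scatter_direction(g, c(0, 0, 1), u[i, ])[3], 0)
    se <- sd(ct) / sqrt(n)
    expect_close(mean(ct), g, 3 * se)
    if (g > 0) {
      # analytic CDF of the deflection cosine
      hg_cdf <- function(c) (1 - g^2) / (2 * g) *
        (1 / sqrt(1 + g^2 - 2 * g * c) - 1 / (1 + g))
      expect_gt(suppressWarnings(stats::ks.test(ct, hg_cdf))$p.value, 0.01)
    }
  }
  expect_error(sample_scatter_direction(1, c(0, 0, 1), c(0.5, 0.5)), "g")
  expect_error(sample_scatter_direction(0.5, c(0, 0, 2), c(0.5, 0.5)), "unit")
  # output is always a unit vector
  d <- sample_scatter_direction(0.9, c(1, 0, 0) / sqrt(1), c(0.01, 0.99))
  expect_close(sqrt(sum(d^2)), 1, 1e-9)
})

test_that("weight attenuation: closed form, identity, composition", {
  expect_equal(attenuate_weight(1, 0.5, 2), exp(-1))
  expect_equal(attenuate_weight(0.7, 0, 5), 0.7)
  expect_equal(attenuate_weight(attenuate_weight(1, 0.3, 1.2), 0.3, 0.8),
               attenuate_weight(1, 0.3, 2.0))
  expect_error(attenuate_weight(0, 0.1, 1), "weight")
})

test_that("boundary interaction: Fresnel closed forms, matched, TIR", {
  expect_equal(fresnel_reflectance(1, 1.5, 1), 0.04)
  b <- boundary_interaction(c(0, 0, 1), 1.2, 1.2, u = 0.5)
  expect_false(b$reflected)
  expect_equal(b$reflectance, 0)
  expect_equal(b$direction, c(0, 0, 1))
  # total internal reflection beyond the critical angle (1.4 -> 1.0, > 45.6 deg)
  th <- 50 * pi / 180
  tir <- boundary_interaction(c(sin(th), 0, -cos(th)), 1.4, 1.0, u = 0.999)
  expect_true(tir$reflected)
  expect_equal(tir$reflectance, 1)
  expect_equal(tir$direction, c(sin(th), 0, cos(th)))
  # Snell's law on refraction
  rf <- boundary_interaction(c(sin(th), 0, cos(th)), 1.0, 1.4, u = 0.999)
  expect_false(rf$reflected)
  expect_close(rf$direction[1], sin(th) / 1.4, 1e-12)
})

test_that("Beer-Lambert limit: scattering-free slab transmits e^{-mu_a d}", {
  st <- slab_stack(mu_a = 0.5, mu_s = 0, g = 0, n = 1, thickness_mm = 2)
  r <- run_mc(st, sensor_geometry(), sim_config(n_photons = 2000, seed = 1))
  expect_equal(r$transmitted_weight / r$launched_weight, exp(-1),
               tolerance = 1e-12)
})

test_that("weight ledger conserves to 1e-6 relative, with roulette active", {
  stacks <- list(
    build_skin_stack(grid = wavelength_grid(c(970, 1450)),
                     film_thickness_mm = 0.1),
    slab_stack(mu_a = c(0.05, 2), mu_s = c(3, 1), g = c(0.8, 0),
               n = c(1.4, 1.37), thickness_mm = c(0.5, 4)))
  for (st in stacks) for (wl in st$wavelengths) {
    r <- run_mc(st, sensor_geometry(),
                sim_config(n_photons = 5000, seed = 11,
                           roulette_threshold = 1e-3), wl)
    bal <- with(r, detected_weight + escaped_weight + transmitted_weight +
                  absorbed_weight + truncated_weight)
    expect_close(bal / r$launched_weight, 1, 1e-6)
    expect_gte(r$reflectance, 0)
    expect_lte(r$reflectance, 1)
  }
})

test_that("non-absorbing stack: all launched weight exits", {
  st <- slab_stack(mu_a = c(0, 0), mu_s = c(2, 1), g = c(0.5, 0), n = 1,
                   thickness_mm = c(1, 3))
  r <- run_mc(st, sensor_geometry(), sim_config(n_photons = 3000, seed = 4))
  out <- r$detected_weight + r$escaped_weight + r$transmitted_weight
  expect_close(out / r$launched_weight, 1, 1e-9)
  expect_equal(r$absorbed_weight, 0)
})

test_that("fixed seed reproduces the event sequence; seeds differ otherwise", {
  st <- build_skin_stack(grid = wavelength_grid(970))
  cfg <- sim_config(n_photons = 400, seed = 21)
  a <- trace_photon(st, sensor_geometry(), cfg)
  b <- trace_photon(st, sensor_geometry(), cfg)
  expect_identical(a$events, b$events)
  expect_identical(a$record$detected_weight, b$record$detected_weight)
  c2 <- trace_photon(st, sensor_geometry(), sim_config(n_photons = 400, seed = 22))
  expect_false(identical(a$events, c2$events))
  expect_true(all(a$events %in% c("detected", "escaped", "transmitted",
                                  "absorbed_roulette", "truncated")))
})

test_that("truncation tally stays below 0.1% of packets on the default stack", {
  st <- build_skin_stack(grid = wavelength_grid(c(970, 1450)))
  for (wl in c(970, 1450)) {
    r <- run_mc(st, sensor_geometry(), sim_config(n_photons = 5000, seed = 3), wl)
    expect_lt(r$truncated_weight / r$launched_weight, 1e-3)
  }
})

test_that("reflectance is monotone non-increasing in layer mu_a (3-point ladder)", {
  refl <- vapply(c(0.05, 0.4, 2.0), function(ma) {
    st <- slab_stack(mu_a = ma, mu_s = 2, g = 0.5, n = 1, thickness_mm = Inf)
    run_mc(st, sensor_geometry(), sim_config(n_photons = 3e4, seed = 5))$total_reflectance
  }, 0)
  ses <- 0.01  # MC error allowance; true gaps here are > 0.1
  expect_true(all(diff(refl) < ses))
  expect_lt(refl[3], refl[1])
})

test_that("zero-thickness film degenerates to the bare-skin stack", {
  grid <- wavelength_grid(c(970, 1450))
  a <- build_skin_stack(grid = grid, film_thickness_mm = 0)
  b <- build_skin_stack(grid = grid)
  expect_identical(a, b)                # no film layer is inserted at all
  expect_length(a$names, 8L)
  cfg <- sim_config(n_photons = 2000, seed = 9)
  ra <- run_mc(a, sensor_geometry(), cfg, 1450)
  rb <- run_mc(b, sensor_geometry(), cfg, 1450)
  expect_identical(ra$total_reflectance, rb$total_reflectance)
  expect_identical(ra$detected_weight, rb$detected_weight)
})

test_that("oracle equivalence: layered toy stacks match an independent MC", {
  # semi-infinite isotropic albedo-0.9 benchmark (van de Hulst: 0.4174)
  st <- slab_stack(mu_a = 0.1, mu_s = 0.9, g = 0, n = 1, thickness_mm = 200)
  r <- run_mc(st, sensor_geometry(), sim_config(n_photons = 4e4, seed = 13))
  o <- oracle_layered_mc(0.1, 0.9, 0, 200, n_phot = 3e4, seed = 17)
  se <- sqrt(r$total_reflectance_se^2 + o$reflectance_se^2)
  expect_close(r$total_reflectance, o$reflectance, 3 * se)
  expect_close(o$reflectance, 0.4174, 3 * o$reflectance_se + 0.003)

  # two-layer anisotropic slab, transmission and reflection
  mu_a <- c(0.05, 0.2); mu_s <- c(2, 1); g <- c(0.7, 0); th <- c(1, 5)
  st2 <- slab_stack(mu_a, mu_s, g, n = 1, thickness_mm = th)
  r2 <- run_mc(st2, sensor_geometry(), sim_config(n_photons = 4e4, seed = 19))
  o2 <- oracle_layered_mc(mu_a, mu_s, g, th, n_phot = 3e4, seed = 23)
  se_r <- sqrt(r2$total_reflectance_se^2 + o2$reflectance_se^2)
  expect_close(r2$total_reflectance, o2$reflectance, 3 * se_r)
  tr_pkg <- r2$transmitted_weight / r2$launched_weight
  se_t <- sqrt(o2$transmittance_se^2 + (tr_pkg * 0.02)^2 + 1e-6)
  expect_close(tr_pkg, o2$transmittance, 3 * se_t)
})
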