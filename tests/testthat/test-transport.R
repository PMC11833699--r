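test_that("launch sampling covers the emitting surface", {
  # degenerate disk always emits from the exact center
  s0 <- source_spec("disk", center = c(1, 2, 3), direction = c(0, 0, 1),
                    wavelength = 810, radius_mm = 0)
  draws <- sample_launch(s0, 100, seed = 1)
  expect_true(all(draws[, 1] == 1 & draws[, 2] == 2 & draws[, 3] == 3))
  expect_true(all(draws[, 6] == 1))

  # disk: sample mean within 3 standard errors of the center
  s1 <- source_spec("disk", center = c(0, 0, 0), direction = c(0, 0, 1),
                    wavelength = 810, radius_mm = 10)
  d1 <- sample_launch(s1, 1e5, seed = 2)
  se <- 10 / 2 / sqrt(1e5) # sd of one coordinate of a uniform disk = r/2
  expect_lt(abs(mean(d1[, 1])), 3 * se)
  expect_lt(abs(mean(d1[, 2])), 3 * se)
  expect_true(all(abs(d1[, 1]^2 + d1[, 2]^2) <= 100 + 1e-9))

  # rect: all samples inside the rectangle
  s2 <- source_spec("rect", center = c(0, 0, 0), direction = c(0, 0, 1),
                    wavelength = 810, width_mm = 40, height_mm = 34)
  d2 <- sample_launch(s2, 1e5, seed = 3)
  expect_true(all(abs(d2[, 1]) <= 20 + 1e-9))
  expect_true(all(abs(d2[, 2]) <= 17 + 1e-9))
})

test_that("Henyey-Greenstein sampling has first moment g", {
  for (g in c(0, 0.5, 0.9)) {
    draws <- sample_hg(2e5, g, seed = 17 + round(g * 10))
    expect_true(all(draws >= -1 & draws <= 1))
    expect_lt(abs(mean(draws) - g), 3 * sd(draws) / sqrt(2e5))
  }
  # clamped forward limit
  d <- sample_hg(1e4, 0.9999, seed = 5)
  expect_true(all(d >= -1 & d <= 1))
  expect_gt(mean(d), 0.99)
})

test_that("energy is conserved exactly with roulette off", {
  lib <- turbid_lib(mua = 0.1, mus = 10, g = 0.9, n = 1.4)
  pm <- make_slab(data.frame(class = "medium", thickness_mm = 15),
                  shape = c(31, 31, 15))
  ph <- build_phantom(pm, lib, 810)
  src <- source_spec("disk", center = c(0, 0, ph$grid$origin[3] - 1),
                     direction = c(0, 0, 1), wavelength = 810, radius_mm = 3)
  res <- run_mc(ph, src, sim_config(n_photons = 2e4, seed = 9,
                                    weight_threshold = 0))
  expect_lt(abs(res$absorbed_fraction + res$escaped_fraction +
                res$capped_fraction - 1), 1e-9)
  expect_equal(res$capped_fraction, 0)
  # per-voxel absorbed integrates to the scalar tally
  expect_lt(abs(sum(res$absorbed) - res$absorbed_fraction), 1e-6)
  expect_true(all(res$fluence >= 0))
})

test_that("roulette conserves energy in expectation", {
  lib <- turbid_lib(mua = 0.05, mus = 10, g = 0.9, n = 1.4)
  pm <- make_slab(data.frame(class = "medium", thickness_mm = 10),
                  shape = c(21, 21, 10))
  ph <- build_phantom(pm, lib, 810)
  src <- source_spec("disk", center = c(0, 0, ph$grid$origin[3] - 1),
                     direction = c(0, 0, 1), wavelength = 810, radius_mm = 2)
  # roulette_net = killed - boosted weight; zero-mean if unbiased
  nets <- vapply(1:20, function(s) {
    run_mc(ph, src, sim_config(n_photons = 1e4, seed = s,
                               weight_threshold = 1e-2,
                               roulette_survival = 0.1))$roulette_net
  }, numeric(1))
  expect_lt(abs(mean(nets)), 3 * sd(nets) / sqrt(20))
})

test_that("a collimated beam in a pure absorber follows Beer-Lambert", {
  pm <- make_slab(data.frame(class = "absorber", thickness_mm = 40),
                  shape = c(21, 21, 40))
  ph <- build_phantom(pm, absorber_lib(0.1), 810)
  src <- source_spec("disk", center = c(0, 0, ph$grid$origin[3] - 1),
                     direction = c(0, 0, 1), wavelength = 810, radius_mm = 5)
  res <- run_mc(ph, src, sim_config(n_photons = 1e4, seed = 2,
                                    weight_threshold = 0))
  layer <- apply(res$fluence, 3, sum)
  # every packet deposits the same depth profile, so the ratio is exact up
  # to the 1e-7 mm face-crossing nudge (~1e-8 over 20 crossings)
  expect_lt(abs(layer[11] / layer[1] - exp(-1)), 1e-6)
  expect_lt(abs(layer[21] / layer[1] - exp(-2)), 1e-6)
  expect_true(all(diff(layer) < 0))
})

test_that("simulation is deterministic given the seed", {
  lib <- turbid_lib()
  pm <- make_slab(data.frame(class = "medium", thickness_mm = 10),
                  shape = c(15, 15, 10))
  ph <- build_phantom(pm, lib, 810)
  src <- source_spec("disk", center = c(0, 0, ph$grid$origin[3] - 1),
                     direction = c(0, 0, 1), wavelength = 810, radius_mm = 2)
  cfg <- sim_config(n_photons = 5e3, seed = 123)
  r1 <- run_mc(ph, src, cfg)
  r2 <- run_mc(ph, src, cfg)
  expect_identical(r1$fluence, r2$fluence)
  expect_identical(r1$absorbed_fraction, r2$absorbed_fraction)
  r3 <- run_mc(ph, src, sim_config(n_photons = 5e3, seed = 124))
  expect_false(identical(r1$fluence, r3$fluence))
})

test_that("estimator variance shrinks with the photon count", {
  lib <- turbid_lib(mua = 0.05, mus = 5, g = 0.8, n = 1.4)
  pm <- make_slab(data.frame(class = "medium", thickness_mm = 8),
                  shape = c(15, 15, 8))
  ph <- build_phantom(pm, lib, 810)
  src <- source_spec("disk", center = c(0, 0, ph$grid$origin[3] - 1),
                     direction = c(0, 0, 1), wavelength = 810, radius_mm = 2)
  probe <- function(n, seeds) vapply(seeds, function(s) {
    r <- run_mc(ph, src, sim_config(n_photons = n, seed = s))
    r$fluence[8, 8, 5]
  }, numeric(1))
  sd_small <- sd(probe(500, 1:12))
  sd_big <- sd(probe(8000, 21:32))
  # 16x photons: sd ratio should be near 4 (loose band for 12 replicates)
  expect_gt(sd_small / sd_big, 2)
  expect_lt(sd_small / sd_big, 8)
})

test_that("cosine-lobe emission conserves energy and shortens penetration", {
  pm <- make_slab(data.frame(class = "absorber", thickness_mm = 30),
                  shape = c(41, 41, 30))
  ph <- build_phantom(pm, absorber_lib(0.1), 810)
  src <- source_spec("disk", center = c(0, 0, ph$grid$origin[3] - 1),
                     direction = c(0, 0, 1), wavelength = 810, radius_mm = 3)
  col <- run_mc(ph, src, sim_config(n_photons = 5e3, seed = 31,
                                    weight_threshold = 0))
  cos <- run_mc(ph, src, sim_config(n_photons = 5e3, seed = 31,
                                    weight_threshold = 0,
                                    emission = "cosine"))
  expect_lt(abs(cos$absorbed_fraction + cos$escaped_fraction +
                cos$capped_fraction - 1), 1e-9)
  depth <- function(r) {
    lay <- apply(r$absorbed, 3, sum)
    sum(lay * seq_along(lay)) / sum(lay)
  }
  expect_lt(depth(cos), depth(col)) # oblique launches deposit shallower
})

test_that("time gates partition the steady-state fluence", {
  lib <- turbid_lib(mua = 0.02, mus = 5, g = 0.8, n = 1.37)
  pm <- make_slab(data.frame(class = "medium", thickness_mm = 20),
                  shape = c(21, 21, 20))
  ph <- build_phantom(pm, lib, 810)
  src <- source_spec("disk", center = c(0, 0, ph$grid$origin[3] - 1),
                     direction = c(0, 0, 1), wavelength = 810, radius_mm = 2)
  res <- run_mc(ph, src, sim_config(n_photons = 5e3, seed = 4, n_gates = 8,
                                    time_gate_ns = 0.05))
  gate_sum <- rowSums(res$gates)
  steady <- as.vector(res$fluence)
  expect_lt(max(abs(gate_sum - steady)), 1e-9 * max(steady))
})

test_that("physical scaling is linear in power and validates sources", {
  pm <- make_slab(data.frame(class = "absorber", thickness_mm = 10),
                  shape = c(15, 15, 10))
  ph <- build_phantom(pm, absorber_lib(), 810)
  mk <- function(pd) source_spec("disk", center = c(0, 0, ph$grid$origin[3] - 1),
                                 direction = c(0, 0, 1), wavelength = 810,
                                 power_density_mw_cm2 = pd, radius_mm = 10)
  expect_equal(source_power(mk(20)), pi * 1^2 * 20) # 62.83 mW
  res <- run_mc(ph, mk(20), sim_config(n_photons = 2e3, seed = 1))
  p1 <- scale_to_physical(res, list(mk(20)))
  p2 <- scale_to_physical(res, list(mk(40)))
  expect_equal(p2$fluence_mw_mm2, 2 * p1$fluence_mw_mm2)
  expect_error(scale_to_physical(res, list()), "no sources")
})

test_that("source placement lands on the scalp surface of a sphere", {
  grid <- volume_grid(c(41, 41, 41))
  co <- as.matrix(expand.grid(x = -20:20, y = -20:20, z = -20:20))
  mask <- array(sqrt(rowSums(co^2)) <= 18, c(41, 41, 41))
  top <- place_source_on_scalp(mask, grid, 0, 0)
  expect_equal(top$center, c(0, 0, 18))
  expect_equal(top$direction, c(0, 0, -1))
  side <- place_source_on_scalp(mask, grid, 0, 90, standoff_mm = 2)
  expect_equal(side$center, c(20, 0, 0), tolerance = 1e-12)
  expect_equal(side$direction, c(-1, 0, 0), tolerance = 1e-12)

  hemi <- mask
  hemi[, , 1:21] <- FALSE # keep z > 0 only
  expect_error(place_source_on_scalp(hemi, grid, 0, 180), "misses")
})

test_that("run_mc rejects sources at unmapped wavelengths", {
  pm <- make_slab(data.frame(class = "absorber", thickness_mm = 5),
                  shape = c(9, 9, 5))
  ph <- build_phantom(pm, absorber_lib(), 810)
  src <- source_spec("disk", center = c(0, 0, -5), direction = c(0, 0, 1),
                     wavelength = 1070, radius_mm = 1)
  expect_error(run_mc(ph, src), "not mapped")
})
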