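# shared small simulation for the dose-accounting tests
local_sim <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    fx <- small_head()
    ph <- build_phantom(fx$probmaps, default_spectral_library(), 810)
    top <- place_source_on_scalp(fx$head_mask, ph$grid, 0, 0, 1)
    s1 <- source_spec("disk", top$center, top$direction, wavelength = 810,
                      radius_mm = 5)
    left <- place_source_on_scalp(fx$head_mask, ph$grid, 180, 90, 1)
    s2 <- source_spec("disk", left$center, left$direction, wavelength = 810,
                      radius_mm = 5)
    res <- run_mc(ph, list(s1, s2), sim_config(n_photons = 4e4, seed = 21),
                  per_source = TRUE)
    cache <<- list(fx = fx, ph = ph, res = res, s1 = s1, s2 = s2)
    cache
  }
})

test_that("ray profiles report the closed-form mueff and layer transitions", {
  lib <- turbid_lib(mua = 0.02, mus = 10, g = 0.9, n = 1.37)
  pm <- make_slab(data.frame(class = "medium", thickness_mm = 20),
                  shape = c(11, 11, 20))
  ph <- build_phantom(pm, lib, 810)
  z0 <- ph$grid$origin[3]
  pr <- profile_along_ray(ph, 810, origin = c(0, 0, z0),
                          direction = c(0, 0, 1), step_mm = 1)
  expect_equal(unique(pr$mueff_mm1), sqrt(3 * 0.02 * (0.02 + 1)))

  lib2 <- spectral_library(list(
    top = list("810" = list(mua = 0.02, mus = 10, g = 0.9, n = 1.4)),
    bottom = list("810" = list(mua = 0.1, mus = 20, g = 0.8, n = 1.4))))
  pm2 <- make_slab(data.frame(class = c("top", "bottom"),
                              thickness_mm = c(10, 10)),
                   shape = c(11, 11, 20))
  ph2 <- build_phantom(pm2, lib2, 810)
  pr2 <- profile_along_ray(ph2, 810, origin = c(0, 0, ph2$grid$origin[3]),
                           direction = c(0, 0, 1), step_mm = 1)
  step_at <- which(diff(pr2$mueff_mm1) > 0)
  expect_lte(abs(step_at - 10), 1) # transition within one voxel of z = 10
  expect_error(profile_along_ray(ph2, 810, c(0, 0, 0), c(0, 0, 0)), "nonzero")
})

test_that("fluence decays monotonically with depth in a pure absorber", {
  pm <- make_slab(data.frame(class = "absorber", thickness_mm = 30),
                  shape = c(15, 15, 30))
  ph <- build_phantom(pm, absorber_lib(0.1), 810)
  z0 <- ph$grid$origin[3]
  src <- source_spec("disk", center = c(0, 0, z0 - 1), direction = c(0, 0, 1),
                     wavelength = 810, radius_mm = 4)
  res <- run_mc(ph, src, sim_config(n_photons = 5e3, seed = 6))
  pr <- profile_along_ray(ph, 810, origin = c(0, 0, z0),
                          direction = c(0, 0, 1), result = res)
  expect_true(all(diff(pr$fluence_mw_mm2) <= 1e-12))
})

test_that("dose tables form an exhaustive partition of absorbed energy", {
  ss <- local_sim()
  dose <- roi_dose(ss$res, ss$fx$atlas, ss$fx$probmaps)
  reg <- dose[dose$unit == "region", ]
  expect_lt(abs(sum(reg$pct_of_absorbed) - 100), 0.01)
  tis <- dose[dose$unit == "tissue", ]
  expect_lt(abs(sum(tis$pct_of_absorbed) - 100), 0.01)
  expect_true(all(dose$pct_of_launched <= dose$pct_of_absorbed + 1e-9))

  # a single region covering every absorbing voxel takes 100%
  grid <- ss$res$grid
  lab <- array(1L, grid$shape)
  full <- label_atlas(grid, lab, data.frame(label = 1L, region = "everything"))
  d2 <- roi_dose(ss$res, full, NULL)
  expect_equal(d2$pct_of_absorbed[d2$name == "everything"], 100)

  # region absent from the volume: zero row with the empty flag
  lab0 <- array(0L, grid$shape)
  lab0[1, 1, 1] <- 1L
  ghost <- label_atlas(grid, lab0, data.frame(label = c(1L, 2L),
                                              region = c("corner", "ghost")))
  d3 <- roi_dose(ss$res, ghost, NULL)
  g <- d3[d3$name == "ghost", ]
  expect_equal(g$pct_of_absorbed, 0)
  expect_true(g$empty)
  expect_equal(g$mean_fluence_mw_mm2, 0)
})

test_that("a vertex source on a symmetric head deposits equally left and right", {
  fx <- small_head()
  ph <- build_phantom(fx$probmaps, default_spectral_library(), 810)
  top <- place_source_on_scalp(fx$head_mask, ph$grid, 0, 0, 1)
  src <- source_spec("disk", top$center, top$direction, wavelength = 810,
                     radius_mm = 5)
  rel_diff <- vapply(c(31, 32), function(s) {
    res <- run_mc(ph, src, sim_config(n_photons = 3e4, seed = s))
    dose <- roi_dose(res, fx$atlas, NULL)
    l <- dose$pct_of_absorbed[dose$name == "gm_left_hemisphere"]
    r <- dose$pct_of_absorbed[dose$name == "gm_right_hemisphere"]
    abs(l - r) / (l + r)
  }, numeric(1))
  expect_lt(min(rel_diff), 0.1)
})

test_that("energy flows conserve and reproduce the dose table", {
  ss <- local_sim()
  fl <- energy_flow(ss$res, ss$fx$atlas, ss$fx$probmaps)
  # total outflow equals total absorbed energy
  expect_lt(abs(sum(fl$fraction_of_launched) - ss$res$absorbed_fraction), 1e-9)
  # per-source outflow equals that source's power-weighted absorbed fraction
  share <- {
    p <- vapply(ss$res$sources, source_power, numeric(1))
    p / sum(p)
  }
  for (sidx in 1:2) {
    expect_lt(abs(sum(fl$fraction_of_launched[fl$source == sidx]) -
                  share[sidx] * sum(ss$res$per_source[[sidx]]$absorbed)), 1e-9)
  }
  # node conservation: tissue-level inflow equals outflow by construction;
  # marginals over sources+regions reproduce the probability-weighted sums
  gm <- sum(fl$fraction_of_launched[fl$tissue == "gray_matter"])
  brute <- sum(ss$res$absorbed * ss$fx$probmaps$maps$gray_matter)
  expect_lt(abs(gm - brute), 1e-9)
  # brute-force per-voxel aggregation for one (source, tissue, region) cell
  cell <- fl$fraction_of_launched[fl$source == 1 &
                                  fl$tissue == "gray_matter" &
                                  fl$region == "gm_left_hemisphere"]
  sel <- ss$fx$atlas$labels == 1L
  brute_cell <- share[1] * sum((ss$res$per_source[[1]]$absorbed *
                                ss$fx$probmaps$maps$gray_matter)[sel])
  expect_lt(abs(cell - brute_cell), 1e-12)

  res_plain <- run_mc(ss$ph, list(ss$s1), sim_config(n_photons = 1e3, seed = 1))
  expect_error(energy_flow(res_plain, ss$fx$atlas, ss$fx$probmaps),
               "per_source")
})

test_that("tPSF gates partition the steady-state ROI mean and respect causality", {
  lib <- turbid_lib(mua = 0.02, mus = 5, g = 0.8, n = 1.37)
  pm <- make_slab(data.frame(class = "medium", thickness_mm = 40),
                  shape = c(21, 21, 40))
  ph <- build_phantom(pm, lib, 810)
  z0 <- ph$grid$origin[3]
  src <- source_spec("disk", center = c(0, 0, z0), direction = c(0, 0, 1),
                     wavelength = 810, radius_mm = 0.1) # near-pencil beam
  res <- run_mc(ph, src, sim_config(n_photons = 5e3, seed = 8, n_gates = 40,
                                    time_gate_ns = 0.02))
  roi <- array(FALSE, ph$grid$shape)
  roi[11, 11, 31] <- TRUE # 30 mm beyond the entry voxel
  tp <- extract_tpsf(res, roi)
  steady <- mean(res$fluence[roi])
  expect_lt(abs(sum(tp$mean_fluence) - steady), 1e-9 * max(steady, 1e-300))
  # no arrivals before 30 mm x n / c
  tmin <- 30 * 1.37 / 299.792458
  early <- which(!is.na(tp$t_start_ns) & tp$t_start_ns + 0.02 <= tmin)
  expect_true(all(tp$mean_fluence[early] == 0))

  # empty ROI: zero series, flagged
  tp0 <- extract_tpsf(res, array(FALSE, ph$grid$shape))
  expect_true(attr(tp0, "empty_roi"))
  expect_true(all(tp0$mean_fluence == 0))

  # single-gate series equals steady state
  res1 <- run_mc(ph, src, sim_config(n_photons = 2e3, seed = 8, n_gates = 1,
                                     time_gate_ns = 100))
  tp1 <- extract_tpsf(res1, roi)
  expect_lt(abs(sum(tp1$mean_fluence) - mean(res1$fluence[roi])), 1e-12)
})

test_that("pearson correlation handles hand-worked and degenerate cases", {
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(3, 2, 1))
  r <- pearson_matrix(m)
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_equal(diag(r), c(a = 1, b = 1, c = 1))

  m2 <- rbind(x = c(1, 2, 3), y = c(1, 3, 2))
  expect_equal(pearson_matrix(m2)["x", "y"], 0.5)

  m3 <- rbind(flat = c(2, 2, 2), var = c(1, 2, 3))
  r3 <- pearson_matrix(m3)
  expect_equal(r3["flat", "var"], 0)
  expect_equal(attr(r3, "constant_rows"), "flat")

  expect_error(pearson_matrix(matrix(1:3, 3, 1)), "2 sources")
})

test_that("UPGMA clustering reproduces hand-worked merges", {
  tree <- hierarchical_cluster(matrix(c(0, 1, 5), 3, 1))
  expect_equal(tree$height, c(1, 4.5))
  expect_equal(sort(tree$merge[1, ]), c(-2, -1)) # {0, 1} merge first

  dup <- hierarchical_cluster(rbind(c(1, 1), c(1, 1), c(5, 5)))
  expect_equal(dup$height[1], 0)

  expect_error(hierarchical_cluster(rbind(c(1, NA), c(2, 3))), "non-finite")

  out <- hierarchical_cluster(matrix(c(0, 1, 5, 6), 4, 1), k = 2)
  expect_equal(unname(out$clusters), c(1, 1, 2, 2))
})

test_that("UPGMA agrees with a brute-force oracle on random instances", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    m <- matrix(rnorm(n * 3), n, 3)
    tree <- hierarchical_cluster(m)
    oracle <- upgma_oracle(m)
    expect_equal(tree$height, oracle$heights, tolerance = 1e-12)
    got_sets <- hclust_merge_sets(tree)
    for (s in seq_along(oracle$merges)) {
      got <- got_sets[[s]]
      want <- oracle$merges[[s]]
      match_direct <- identical(got[[1]], want[[1]]) &&
        identical(got[[2]], want[[2]])
      match_swap <- identical(got[[1]], want[[2]]) &&
        identical(got[[2]], want[[1]])
      expect_true(match_direct || match_swap)
    }
    # independent cross-check against the reference average-linkage tree
    expect_equal(tree$height, stats::hclust(dist(m), "average")$height,
                 tolerance = 1e-12)
  }
})

test_that("simple regression matches hand least-squares and the t formula", {
  exact <- linear_regression(0:4, 2 * (0:4))
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 0)
  expect_equal(exact$r_squared, 1)

  fit <- linear_regression(c(0, 1, 2, 3), c(1, 3, 2, 5))
  expect_equal(fit$slope, 1.1, tolerance = 1e-12)
  expect_equal(fit$intercept, 1.1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 6.05 / 8.75, tolerance = 1e-12)
  expect_equal(fit$r_squared, fit$pearson_r^2, tolerance = 1e-12)
  # textbook slope t-test: t = b / (s / sqrt(Sxx)), df = n - 2
  x <- c(0, 1, 2, 3); y <- c(1, 3, 2, 5)
  b <- 1.1; yhat <- 1.1 + b * x
  s2 <- sum((y - yhat)^2) / 2
  t_hand <- b / sqrt(s2 / sum((x - mean(x))^2))
  expect_equal(fit$t, t_hand, tolerance = 1e-9)
  expect_equal(fit$p, 2 * pt(-abs(t_hand), df = 2), tolerance = 1e-9)

  expect_error(linear_regression(rep(1, 5), rnorm(5)), "constant")
  expect_error(linear_regression(1:2, 1:2), "3 observations")
})

test_that("group comparison follows the assumption decision tree", {
  # identical paired samples: t = 0, p = 1
  a <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  same <- group_compare(a, a, paired = TRUE)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_equal(same$test, "t")

  # seeded normal samples: t-test selected, p matches the pooled-t formula
  set.seed(14)
  x <- rnorm(25); y <- rnorm(25, 0.3)
  cmp <- group_compare(x, y)
  expect_equal(cmp$test, "t")
  sp2 <- ((24) * var(x) + (24) * var(y)) / 48
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (2 / 25))
  expect_equal(cmp$statistic, t_hand, tolerance = 1e-9)
  expect_equal(cmp$p, 2 * pt(-abs(t_hand), df = 48), tolerance = 1e-9)

  # heavily skewed sample fails the KS gate: Wilcoxon branch
  set.seed(15)
  skew <- rexp(30)^3
  cmp2 <- group_compare(skew, rnorm(30))
  expect_equal(cmp2$test, "wilcoxon")
  expect_lte(cmp2$normal_a, 0.05)

  expect_error(group_compare(1:2, 1:5), "at least 3")
  expect_error(group_compare(1:5, 1:4, paired = TRUE), "equal lengths")
})

test_that("penetration rate isolates the brain compartment", {
  ss <- local_sim()
  pr <- penetration_rate(ss$res, ss$fx$probmaps)
  brain <- with(ss$fx$probmaps$maps,
                gray_matter + white_matter + csf)
  expect_equal(pr, sum(ss$res$absorbed * brain) / sum(ss$res$absorbed))
  expect_gt(pr, 0)
  expect_lt(pr, 1)
})

test_that("response matrices order regions by the atlas lookup", {
  ss <- local_sim()
  m <- response_matrix(ss$res, ss$fx$atlas)
  expect_equal(rownames(m), ss$fx$atlas$lookup$region)
  expect_equal(ncol(m), 2)
  expect_true(all(m >= 0))
  # the left-hemisphere region responds more to the left source
  expect_gt(m["gm_left_hemisphere", 2], m["gm_right_hemisphere", 2])
})
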