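#' Optical and fluence profile along a ray
#'
#' Samples the phantom's effective attenuation coefficient
#' (`sqrt(3 mua (mua + mus'))`, nearest voxel) and, optionally, the
#' physically scaled fluence rate of a simulation at regular steps along a
#' ray through the volume — the depth profile along an illumination
#' direction. Samples falling outside the grid are truncated.
#'
#' @param phantom An `optical_phantom`.
#' @param wavelength Wavelength, nm.
#' @param origin Ray origin, world mm.
#' @param direction Ray direction (normalized internally; zero is an error).
#' @param step_mm Sampling step, mm.
#' @param result Optional `sim_result` for fluence sampling.
#' @param sources Sources for physical scaling (default from `result`).
#' @return Data frame with `depth_mm`, `mueff_mm1` and (if `result` given)
#'   `fluence_mw_mm2`.
#' @export
profile_along_ray <- function(phantom, wavelength, origin, direction,
                              step_mm = 1, result = NULL, sources = NULL) {
  stopifnot(inherits(phantom, "optical_phantom"), length(origin) == 3)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("ray direction must be nonzero")
  direction <- direction / nrm
  grid <- phantom$grid
  tmax <- sqrt(sum((grid$shape * grid$voxel_size)^2))
  depth <- seq(0, tmax, by = step_mm)
  pts <- sweep(depth %o% direction, 2, origin, "+")
  v <- round(world_to_voxel(grid, pts))
  ok <- v[, 1] >= 1 & v[, 1] <= grid$shape[1] &
        v[, 2] >= 1 & v[, 2] <= grid$shape[2] &
        v[, 3] >= 1 & v[, 3] <= grid$shape[3]
  if (!any(ok)) stop("ray does not intersect the grid")
  depth <- depth[ok]
  idx <- v[ok, , drop = FALSE]
  key <- as.character(wavelength)
  if (!key %in% names(phantom$mua))
    stop("wavelength ", wavelength, " nm not mapped in this phantom")
  mua <- phantom$mua[[key]][idx]
  musp <- (1 - phantom$g[[key]][idx]) * phantom$mus[[key]][idx]
  out <- data.frame(depth_mm = depth, mueff_mm1 = sqrt(3 * mua * (mua + musp)))
  if (!is.null(result)) {
    stopifnot(inherits(result, "sim_result"))
    phys <- scale_to_physical(result,
                              sources = if (is.null(sources)) result$sources else sources)
    out$fluence_mw_mm2 <- phys$fluence_mw_mm2[idx]
  }
  out
}

#' Region and tissue dose table
#'
#' Aggregates the absorbed-energy volume of a simulation over atlas regions
#' and over tissue classes (probability-weighted), reporting each as a
#' percentage of the total absorbed energy, a percentage of the launched
#' energy, the mean fluence rate (mW/mm^2, physically scaled) and the volume
#' aggregated over. Regions are an exhaustive partition (voxels without an
#' atlas label are reported as `unlabeled`), so the region
#' percent-of-absorbed column sums to 100; tissue rows include a `residual`
#' row for absorption not assigned to any class.
#'
#' @param result A `sim_result`.
#' @param atlas A `label_atlas` (may be NULL to skip region rows).
#' @param tissue_maps A `probability_maps` (may be NULL to skip tissue rows).
#' @param sources Sources for physical scaling (default from `result`).
#' @return Data frame with columns `unit` ("region"/"tissue"), `name`,
#'   `pct_of_absorbed`, `pct_of_launched`, `mean_fluence_mw_mm2`,
#'   `volume_mm3`, `empty` (TRUE for regions with no voxels, whose mean
#'   fluence is reported as 0).
#' @export
roi_dose <- function(result, atlas = NULL, tissue_maps = NULL,
                     sources = result$sources) {
  stopifnot(inherits(result, "sim_result"))
  grid <- result$grid
  vv <- prod(grid$voxel_size)
  total_abs <- sum(result$absorbed)
  if (total_abs <= 0) stop("simulation deposited no energy")
  phys <- scale_to_physical(result, sources)
  rows <- list()

  if (!is.null(atlas)) {
    stopifnot(inherits(atlas, "label_atlas"))
    if (!identical(atlas$grid$shape, grid$shape))
      stop("atlas grid does not match the simulation grid")
    lut <- rbind(atlas$lookup, data.frame(label = 0L, region = "unlabeled"))
    for (q in seq_len(nrow(lut))) {
      sel <- atlas$labels == lut$label[q]
      nv <- sum(sel)
      dep <- sum(result$absorbed[sel])
      rows[[length(rows) + 1]] <- data.frame(
        unit = "region", name = lut$region[q],
        pct_of_absorbed = 100 * dep / total_abs,
        pct_of_launched = 100 * dep,
        mean_fluence_mw_mm2 = if (nv > 0) mean(phys$fluence_mw_mm2[sel]) else 0,
        volume_mm3 = nv * vv, empty = nv == 0)
    }
  }

  if (!is.null(tissue_maps)) {
    stopifnot(inherits(tissue_maps, "probability_maps"))
    if (!identical(tissue_maps$grid$shape, grid$shape))
      stop("tissue map grid does not match the simulation grid")
    assigned <- 0
    for (cls in tissue_maps$classes) {
      w <- tissue_maps$maps[[cls]]
      dep <- sum(result$absorbed * w)
      assigned <- assigned + dep
      wsum <- sum(w)
      rows[[length(rows) + 1]] <- data.frame(
        unit = "tissue", name = cls,
        pct_of_absorbed = 100 * dep / total_abs,
        pct_of_launched = 100 * dep,
        mean_fluence_mw_mm2 = if (wsum > 0)
          sum(phys$fluence_mw_mm2 * w) / wsum else 0,
        volume_mm3 = wsum * vv, empty = wsum == 0)
    }
    resid <- total_abs - assigned
    rows[[length(rows) + 1]] <- data.frame(
      unit = "tissue", name = "residual",
      pct_of_absorbed = 100 * resid / total_abs,
      pct_of_launched = 100 * resid,
      mean_fluence_mw_mm2 = 0, volume_mm3 = 0, empty = FALSE)
  }
  if (length(rows) == 0) stop("provide an atlas and/or tissue maps")
  do.call(rbind, rows)
}

#' Source -> tissue -> region energy-flow table
#'
#' Decomposes the absorbed energy of a multi-source simulation into directed
#' flows source -> tissue class -> region (the input of a Sankey diagram).
#' Flows are fractions of the total launched energy; by construction the
#' outflow of every node equals its inflow, and marginal sums reproduce the
#' per-source absorbed fractions. Requires a run with
#' `per_source = TRUE`.
#'
#' @param result A `sim_result` run with per-source volumes.
#' @param atlas A `label_atlas`.
#' @param tissue_maps A `probability_maps`; a `residual` pseudo-class keeps
#'   the flows conservative when the class probabilities do not sum to 1.
#' @return Data frame with columns `source`, `tissue`, `region`,
#'   `fraction_of_launched`.
#' @export
energy_flow <- function(result, atlas, tissue_maps) {
  stopifnot(inherits(result, "sim_result"), inherits(atlas, "label_atlas"),
            inherits(tissue_maps, "probability_maps"))
  if (is.null(result$per_source))
    stop("energy_flow needs per-source tallies: rerun run_mc with per_source = TRUE")
  if (!identical(atlas$grid$shape, result$grid$shape) ||
      !identical(tissue_maps$grid$shape, result$grid$shape))
    stop("atlas/tissue grids do not match the simulation grid")
  share <- {
    p <- vapply(result$sources, source_power, numeric(1))
    p / sum(p)
  }
  lut <- rbind(atlas$lookup, data.frame(label = 0L, region = "unlabeled"))
  ptot <- Reduce(`+`, tissue_maps$maps)
  classes <- c(tissue_maps$classes, "residual")
  rows <- list()
  for (sidx in seq_along(result$sources)) {
    abs_s <- result$per_source[[sidx]]$absorbed * share[sidx]
    for (cls in classes) {
      w <- if (cls == "residual") pmax(1 - ptot, 0) else tissue_maps$maps[[cls]]
      contrib <- abs_s * w
      for (q in seq_len(nrow(lut))) {
        f <- sum(contrib[atlas$labels == lut$label[q]])
        rows[[length(rows) + 1]] <- data.frame(
          source = sidx, tissue = cls, region = lut$region[q],
          fraction_of_launched = f)
      }
    }
  }
  do.call(rbind, rows)
}

#' Temporal point spread function of a region of interest
#'
#' Mean fluence per time gate over an ROI voxel set from a time-gated
#' simulation; the gate series (including the late-arrival overflow gate)
#' sums to the steady-state ROI mean by construction.
#'
#' @param result A `sim_result` run with `n_gates >= 1`.
#' @param roi Logical array selecting the ROI voxels.
#' @return Data frame with `gate`, `t_start_ns` (NA for the overflow gate)
#'   and `mean_fluence`; attribute `empty_roi` flags an empty ROI (series of
#'   zeros).
#' @export
extract_tpsf <- function(result, roi) {
  stopifnot(inherits(result, "sim_result"))
  if (is.null(result$gates)) stop("result has no time gates")
  .check_volume(result$grid, roi, "roi")
  sel <- as.vector(roi)
  ng <- ncol(result$gates)
  empty <- !any(sel)
  vals <- if (empty) rep(0, ng) else
    colSums(result$gates[sel, , drop = FALSE]) / sum(sel)
  out <- data.frame(
    gate = seq_len(ng),
    t_start_ns = c((seq_len(ng - 1) - 1) * result$config$time_gate_ns, NA),
    mean_fluence = vals)
  attr(out, "empty_roi") <- empty
  out
}

#' Region response matrix over multiple sources
#'
#' Mean fluence rate (physically scaled, mW/mm^2) per atlas region for each
#' source of a per-source simulation: the response of each brain region to
#' each light source. Row order follows the atlas lookup.
#'
#' @param result A `sim_result` run with `per_source = TRUE`.
#' @param atlas A `label_atlas`.
#' @return Matrix regions x sources.
#' @export
response_matrix <- function(result, atlas) {
  stopifnot(inherits(result, "sim_result"), inherits(atlas, "label_atlas"))
  if (is.null(result$per_source))
    stop("response_matrix needs per-source tallies: rerun run_mc with per_source = TRUE")
  if (!identical(atlas$grid$shape, result$grid$shape))
    stop("atlas grid does not match the simulation grid")
  powers <- vapply(result$sources, source_power, numeric(1))
  m <- matrix(0, nrow(atlas$lookup), length(result$sources),
              dimnames = list(atlas$lookup$region,
                              paste0("source", seq_along(result$sources))))
  for (q in seq_len(nrow(atlas$lookup))) {
    sel <- atlas$labels == atlas$lookup$label[q]
    nv <- sum(sel)
    for (sidx in seq_along(result$sources)) {
      fl <- result$per_source[[sidx]]$fluence
      m[q, sidx] <- if (nv > 0) mean(fl[sel]) * powers[sidx] else 0
    }
  }
  m
}

#' Pairwise Pearson correlation of region responses
#'
#' Correlation matrix of the rows of a region x source response matrix.
#' Rows with zero variance have undefined correlations; these entries are
#' reported as 0 and the offending regions flagged in the
#' `constant_rows` attribute.
#'
#' @param m Numeric matrix (regions x sources), at least 2 columns.
#' @return Symmetric correlation matrix with unit diagonal; attribute
#'   `constant_rows` lists zero-variance rows.
#' @export
pearson_matrix <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("at least 2 sources (columns) are required")
  sds <- apply(m, 1, stats::sd)
  const <- which(sds == 0)
  r <- suppressWarnings(stats::cor(t(m)))
  r[const, ] <- 0
  r[, const] <- 0
  diag(r) <- 1
  attr(r, "constant_rows") <- if (length(const))
    rownames(m)[const] else character(0)
  r
}

#' Agglomerative UPGMA clustering of region responses
#'
#' Unweighted pair-group average (UPGMA) hierarchical clustering of the rows
#' of a matrix under Euclidean distance: at every step the two clusters with
#' the smallest average inter-cluster distance merge, ties broken
#' deterministically in favour of the lowest row indices. Returns a standard
#' `hclust` object (plottable, cuttable with [stats::cutree()]).
#'
#' @param m Numeric matrix with at least 2 rows; rows with non-finite
#'   entries are an error.
#' @param k Optional number of flat clusters to cut the tree into.
#' @return An `hclust` object; if `k` is given, a list with `tree` and
#'   `clusters` (integer memberships).
#' @export
hierarchical_cluster <- function(m, k = NULL) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (n < 2) stop("at least 2 rows are required")
  bad <- which(!apply(m, 1, function(r) all(is.finite(r))))
  if (length(bad) > 0)
    stop("non-finite rows: ",
         paste(if (is.null(rownames(m))) bad else rownames(m)[bad],
               collapse = ", "))
  D <- as.matrix(stats::dist(m))
  active <- seq_len(n)
  members <- lapply(seq_len(n), function(i) i)
  node_id <- -seq_len(n) # hclust convention: negative = singleton
  sizes <- rep(1L, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA)
    bestd <- Inf
    na <- length(active)
    for (a in seq_len(na - 1)) for (b in (a + 1):na) {
      i <- active[a]; j <- active[b]
      if (D[i, j] < bestd - 1e-15) { # strict improvement, lowest-index ties win
        bestd <- D[i, j]
        best <- c(i, j)
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- c(node_id[i], node_id[j])
    height[step] <- bestd
    # Lance-Williams update for UPGMA
    for (kk in setdiff(active, c(i, j))) {
      D[i, kk] <- D[kk, i] <-
        (sizes[i] * D[i, kk] + sizes[j] * D[j, kk]) / (sizes[i] + sizes[j])
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    node_id[i] <- step
    active <- setdiff(active, j)
  }
  tree <- structure(list(
    merge = merge, height = height, order = .hclust_order(merge, n),
    labels = rownames(m), method = "average",
    dist.method = "euclidean", call = match.call()),
    class = "hclust")
  if (is.null(k)) return(tree)
  list(tree = tree, clusters = stats::cutree(tree, k = k))
}

.hclust_order <- function(merge, n) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(n - 1)
}

#' Simple linear regression with slope inference
#'
#' Ordinary least squares of `y` on `x` with the two-tailed t-test for the
#' slope (n - 2 degrees of freedom), as used for dose-response analysis
#' (scale-score change rate over energy deposition, white- over gray-matter
#' deposition).
#'
#' @param x,y Numeric vectors, length >= 3; `x` must not be constant.
#' @return List of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `t`, `p`, `n`, `pearson_r`.
#' @export
linear_regression <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3) stop("at least 3 observations are required")
  if (stats::sd(x) == 0) stop("x is constant")
  fit <- stats::lm(y ~ x)
  # an exact fit triggers lm's "essentially perfect fit" warning; the slope
  # and R^2 are still well defined, only the t/p are degenerate
  sm <- suppressWarnings(summary(fit))
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    t = sm$coefficients[2, "t value"],
    p = sm$coefficients[2, "Pr(>|t|)"],
    n = length(x),
    pearson_r = unname(stats::cor(x, y))),
    class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("linear regression (n=%d): slope=%.5g, intercept=%.5g, R2=%.4f, t=%.3f, p=%.4g\n",
              x$n, x$slope, x$intercept, x$r_squared, x$t, x$p))
  invisible(x)
}

#' Two-group comparison with assumption-guided test selection
#'
#' Implements the decision tree used for group comparisons in small
#' photobiomodulation cohorts: normality of each sample (or of the paired
#' differences) is checked with a Kolmogorov-Smirnov test against a normal
#' distribution with the sample's mean and SD, variance equality with
#' Levene's test (independent samples only). When both gates pass
#' (p > 0.05), a t-test is used (independent or paired); otherwise the
#' Wilcoxon rank-sum (independent) or signed-rank (paired) test. Two-tailed
#' p-values and 95 percent confidence intervals; no multiple-testing
#' correction is applied by default (set `p_adjust` to apply
#' Benjamini-Hochberg externally over a family of such calls).
#'
#' @param a,b Numeric samples (n >= 3 each; equal lengths when paired).
#' @param paired Paired comparison?
#' @return List of class `group_comparison`: `test` ("t" or "wilcoxon"),
#'   `reason`, `statistic`, `p`, `conf_int`, `normal_a`, `normal_b`,
#'   `equal_variance` (NA when paired), `significant` (at 0.05).
#' @export
group_compare <- function(a, b, paired = FALSE) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) < 3 || length(b) < 3)
    stop("each sample needs at least 3 observations")
  if (paired && length(a) != length(b))
    stop("paired samples must have equal lengths")

  ks_norm <- function(x) {
    if (stats::sd(x) == 0) return(1) # degenerate: treat as normal
    suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
  }

  if (paired) {
    d <- a - b
    p_norm <- ks_norm(d)
    normal <- p_norm > 0.05
    lev <- NA_real_
    if (all(d == 0)) {
      res <- list(statistic = 0, p = 1, conf_int = c(0, 0))
      test <- "t"; reason <- "paired differences all zero"
    } else if (normal) {
      tt <- stats::t.test(a, b, paired = TRUE, conf.level = 0.95)
      res <- list(statistic = unname(tt$statistic), p = tt$p.value,
                  conf_int = as.numeric(tt$conf.int))
      test <- "t"; reason <- "paired differences normal (KS p > 0.05)"
    } else {
      wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                                conf.int = TRUE))
      res <- list(statistic = unname(wt$statistic), p = wt$p.value,
                  conf_int = as.numeric(wt$conf.int))
      test <- "wilcoxon"
      reason <- "paired differences non-normal (KS p <= 0.05)"
    }
    norm_a <- norm_b <- p_norm
  } else {
    norm_a <- ks_norm(a)
    norm_b <- ks_norm(b)
    g <- factor(rep(c("a", "b"), c(length(a), length(b))))
    lev <- car::leveneTest(c(a, b), g)[1, "Pr(>F)"]
    if (norm_a > 0.05 && norm_b > 0.05 && lev > 0.05) {
      tt <- stats::t.test(a, b, var.equal = TRUE, conf.level = 0.95)
      res <- list(statistic = unname(tt$statistic), p = tt$p.value,
                  conf_int = as.numeric(tt$conf.int))
      test <- "t"
      reason <- "both samples normal (KS p > 0.05) and variances equal (Levene p > 0.05)"
    } else {
      wt <- suppressWarnings(stats::wilcox.test(a, b, conf.int = TRUE))
      res <- list(statistic = unname(wt$statistic), p = wt$p.value,
                  conf_int = as.numeric(wt$conf.int))
      test <- "wilcoxon"
      reason <- "normality or variance-equality gate failed"
    }
  }
  structure(list(test = test, reason = reason, statistic = res$statistic,
                 p = res$p, conf_int = res$conf_int, normal_a = norm_a,
                 normal_b = norm_b, equal_variance = lev,
                 significant = res$p < 0.05, paired = paired),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group comparison: %s%s test (%s)\n  statistic=%.4g, p=%.4g, 95%% CI [%.4g, %.4g]%s\n",
              if (x$paired) "paired " else "", x$test, x$reason,
              x$statistic, x$p, x$conf_int[1], x$conf_int[2],
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Extracerebral penetration rate
#'
#' Fraction of the total absorbed energy deposited in the brain compartment
#' (gray matter + white matter + CSF): a summary of how much of the absorbed
#' dose makes it past the extracerebral tissues. This package defines the
#' penetration rate as (energy in GM + WM + CSF) / (total absorbed energy);
#' the definition is stated here because competing conventions (e.g.
#' normalizing by launched energy) exist.
#'
#' @param result A `sim_result`.
#' @param tissue_maps A `probability_maps` containing `gray_matter`,
#'   `white_matter` and `csf` classes.
#' @return Scalar fraction in \[0, 1\].
#' @export
penetration_rate <- function(result, tissue_maps) {
  stopifnot(inherits(result, "sim_result"),
            inherits(tissue_maps, "probability_maps"))
  need <- c("gray_matter", "white_matter", "csf")
  miss <- setdiff(need, tissue_maps$classes)
  if (length(miss) > 0)
    stop("tissue maps missing classes: ", paste(miss, collapse = ", "))
  brain <- Reduce(`+`, tissue_maps$maps[need])
  sum(result$absorbed * brain) / sum(result$absorbed)
}
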