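# Independent oracles and shared tiny fixtures for the test suite.
# These deliberately re-derive results from first principles (flood fill,
# direct tridiagonal solve, exhaustive pairwise averaging) so they share no
# code path with the implementations they check.

# two-class toy spectral library
toy_lib <- function() {
  spectral_library(list(
    a = list("810" = list(mua = 0.02, mus = 10, g = 0.9, n = 1.37),
             "850" = list(mua = 0.04, mus = 8, g = 0.85, n = 1.37)),
    b = list("810" = list(mua = 0.08, mus = 20, g = 0.8, n = 1.45),
             "850" = list(mua = 0.10, mus = 18, g = 0.75, n = 1.45)),
    air = list("810" = list(mua = 0, mus = 0, g = 0, n = 1),
               "850" = list(mua = 0, mus = 0, g = 0, n = 1))))
}

# pure absorber / pure scatterer single-node libraries for physics tests
absorber_lib <- function(mua = 0.1) {
  spectral_library(list(
    absorber = list("810" = list(mua = mua, mus = 0, g = 0, n = 1))))
}

turbid_lib <- function(mua = 0.01, mus = 10, g = 0.9, n = 1.37) {
  spectral_library(list(
    medium = list("810" = list(mua = mua, mus = mus, g = g, n = n))))
}

# --- oracle: recursive flood fill for connected components -----------------
flood_fill_components <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  m <- rowSums(abs(offs))
  offs <- offs[m > 0 & m <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), ,
               drop = FALSE]
  lab <- array(0L, d)
  cur <- 0L
  for (v in which(mask)) {
    if (lab[v] != 0L) next
    cur <- cur + 1L
    queue <- v
    lab[v] <- cur
    while (length(queue) > 0) {
      u <- queue[1]
      queue <- queue[-1]
      k <- (u - 1) %/% (d[1] * d[2])
      r <- (u - 1) %% (d[1] * d[2])
      ijk <- c(r %% d[1], r %/% d[1], k) + 1
      for (q in seq_len(nrow(offs))) {
        nb <- ijk + offs[q, ]
        if (any(nb < 1) || any(nb > d)) next
        w <- nb[1] + d[1] * (nb[2] - 1 + d[2] * (nb[3] - 1))
        if (mask[w] && lab[w] == 0L) {
          lab[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  lab
}

# --- oracle: natural cubic spline by direct tridiagonal solve ---------------
natural_spline_eval <- function(x, y, xout) {
  n <- length(x)
  if (n == 2) return(approx(x, y, xout = xout)$y)
  h <- diff(x)
  # solve for second derivatives M, M[1] = M[n] = 0
  A <- matrix(0, n - 2, n - 2)
  rhs <- numeric(n - 2)
  for (i in 2:(n - 1)) {
    r <- i - 1
    if (r > 1) A[r, r - 1] <- h[i - 1] / 6
    A[r, r] <- (h[i - 1] + h[i]) / 3
    if (r < n - 2) A[r, r + 1] <- h[i] / 6
    rhs[r] <- (y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1]
  }
  M <- c(0, solve(A, rhs), 0)
  vapply(xout, function(s) {
    i <- max(1, min(n - 1, findInterval(s, x, rightmost.closed = TRUE)))
    t1 <- x[i + 1] - s
    t2 <- s - x[i]
    (M[i] * t1^3 + M[i + 1] * t2^3) / (6 * h[i]) +
      (y[i] / h[i] - M[i] * h[i] / 6) * t1 +
      (y[i + 1] / h[i] - M[i + 1] * h[i] / 6) * t2
  }, numeric(1))
}

# --- oracle: brute-force UPGMA ----------------------------------------------
# recomputes every inter-cluster average distance from the original points
# at every step; ties resolved toward the clusters holding the lowest
# original row indices
upgma_oracle <- function(m) {
  n <- nrow(m)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  merges <- list()
  d0 <- as.matrix(dist(m))
  while (length(clusters) > 1) {
    best <- NULL
    bestd <- Inf
    for (a in seq_len(length(clusters) - 1)) {
      for (b in (a + 1):length(clusters)) {
        dd <- mean(d0[clusters[[a]], clusters[[b]]])
        if (dd < bestd - 1e-15) {
          bestd <- dd
          best <- c(a, b)
        }
      }
    }
    heights <- c(heights, bestd)
    merges[[length(merges) + 1]] <-
      list(sort(clusters[[best[1]]]), sort(clusters[[best[2]]]))
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# member sets of each merge of an hclust tree, for comparison with the oracle
hclust_merge_sets <- function(tree) {
  n <- length(tree$height)
  sets <- vector("list", n)
  expand <- function(id) {
    if (id < 0) return(-id)
    sets_all[[id]]
  }
  sets_all <- vector("list", n)
  out <- vector("list", n)
  for (s in seq_len(n)) {
    left <- if (tree$merge[s, 1] < 0) -tree$merge[s, 1] else sets_all[[tree$merge[s, 1]]]
    right <- if (tree$merge[s, 2] < 0) -tree$merge[s, 2] else sets_all[[tree$merge[s, 2]]]
    sets_all[[s]] <- c(left, right)
    out[[s]] <- list(sort(left), sort(right))
  }
  out
}

# small layered head shared by several simulation tests
small_head <- function() {
  make_layered_head(
    radii = c(soft_tissue = 30, skull = 26, csf = 23, gray_matter = 21,
              white_matter = 16),
    scalp_offset = c(0, 0, 0))
}
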