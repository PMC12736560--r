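# Shared fixtures: small deterministic simulations and hand-built shapes.

# one straight tubule of given diameter/angle centred in its own field
single_tubule_sim <- function(diameter = 25, angle = 0, length_nm = 1200,
                              labeling_density = 0.05, locs_per_emitter = 4,
                              sigma = 2, background = 0, seed = 1L) {
  ctr <- c(1250, 1250)
  u <- c(cos(angle), sin(angle))
  tb <- tubule_spec(rbind(ctr - length_nm / 2 * u, ctr + length_nm / 2 * u),
                    diameter)
  fs <- field_spec(c(2500, 2500), list(tb), labeling_density,
                   locs_per_emitter, sigma, background, seed = seed)
  simulate_tubule_field(fs)
}

# manually built branch object along one image row (for measure_tubule
# unit tests that should not depend on skeleton fragmentation)
row_branch <- function(row, cols) {
  pm <- cbind(row = rep(row, length(cols)), col = cols)
  structure(list(path = pm, endpoints = pm[c(1L, nrow(pm)), , drop = FALSE],
                 is_cycle = FALSE, length_px = length(cols) - 1),
            class = "branch")
}

# brute-force Hessian oracle: explicit per-pixel correlation with the same
# sampled Gaussian-derivative kernels and reflective indexing, then eigen()
oracle_hessian <- function(img, sigma) {
  k0 <- tubulemorph:::gauss_kernel(sigma, 0L)
  k1 <- tubulemorph:::gauss_kernel(sigma, 1L)
  k2 <- tubulemorph:::gauss_kernel(sigma, 2L)
  rad <- (length(k0) - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  refl <- function(i, n) {
    while (any(i < 1L | i > n)) {
      i <- ifelse(i < 1L, 1L - i, i)
      i <- ifelse(i > n, 2L * n + 1L - i, i)
    }
    i
  }
  corr2 <- function(kx, ky) {
    out <- matrix(0, nr, nc)
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      acc <- 0
      for (dy in -rad:rad) for (dx in -rad:rad) {
        acc <- acc + ky[dy + rad + 1L] * kx[dx + rad + 1L] *
          img[refl(r + dy, nr), refl(cc + dx, nc)]
      }
      out[r, cc] <- acc
    }
    out
  }
  hxx <- sigma^2 * corr2(k2, k0)
  hyy <- sigma^2 * corr2(k0, k2)
  hxy <- sigma^2 * corr2(k1, k1)
  l1 <- matrix(0, nr, nc); l2 <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    ev <- eigen(matrix(c(hxx[r, cc], hxy[r, cc], hxy[r, cc], hyy[r, cc]), 2L),
                symmetric = TRUE)$values
    ord <- order(abs(ev))
    l1[r, cc] <- ev[ord[1L]]
    l2[r, cc] <- ev[ord[2L]]
  }
  list(lambda1 = l1, lambda2 = l2, hxx = hxx, hxy = hxy, hyy = hyy)
}

# exhaustive Otsu oracle: minimize weighted within-class variance over all
# midpoints of adjacent sorted unique values
oracle_otsu <- function(x) {
  u <- sort(unique(x))
  cand <- (u[-1L] + u[-length(u)]) / 2
  wcv <- vapply(cand, function(t) {
    a <- x[x <= t]; b <- x[x > t]
    va <- if (length(a) > 1L) stats::var(a) * (length(a) - 1) else 0
    vb <- if (length(b) > 1L) stats::var(b) * (length(b) - 1) else 0
    va + vb
  }, numeric(1L))
  cand[which.min(wcv)]
}

# exact Kruskal-Wallis permutation oracle, independent of the package path:
# enumerate index subsets with combn and score with stats::kruskal.test
oracle_kw_exact_p <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  sizes <- lengths(groups)
  h_obs <- unname(stats::kruskal.test(x, factor(rep(seq_along(groups),
                                                    sizes)))$statistic)
  n <- length(x)
  total <- 0; extreme <- 0
  rec <- function(avail, g, labels) {
    if (g == length(sizes)) {
      lab <- labels
      lab[avail] <- length(sizes)
      h <- unname(stats::kruskal.test(x, factor(lab))$statistic)
      total <<- total + 1
      if (h >= h_obs - 1e-9) extreme <<- extreme + 1
      return(invisible())
    }
    for (pick in utils::combn(avail, sizes[g], simplify = FALSE)) {
      lab <- labels
      lab[pick] <- g
      rec(setdiff(avail, pick), g + 1L, lab)
    }
  }
  rec(seq_len(n), 1L, integer(n))
  extreme / total
}
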