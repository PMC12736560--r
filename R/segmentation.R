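# Multi-scale Hessian (Frangi) vesselness enhancement and global
# thresholding of STORM reconstructions.

#' Parameters of the Frangi vesselness filter
#'
#' @param sigmas Gaussian scales in pixels (non-empty, all > 0). Defaults
#'   {1, 1.5, 2} px cover tubule widths of roughly 1-4 px.
#' @param beta blobness weight (dimensionless, > 0); 0.5 is the usual
#'   convention.
#' @param c structureness weight in intensity units, or `NULL` to use half
#'   of the maximum Hessian Frobenius norm per scale.
#' @return A `vesselness_params` object.
#' @export
vesselness_params <- function(sigmas = c(1, 1.5, 2), beta = 0.5, c = NULL) {
  if (!is.numeric(sigmas) || length(sigmas) == 0 || any(sigmas <= 0))
    stop_field("sigmas", "must be a non-empty vector of positive scales")
  check_scalar(beta, "beta")
  if (beta <= 0) stop_field("beta", "must be > 0")
  if (!is.null(c)) {
    check_scalar(c, "c")
    if (c <= 0) stop_field("c", "must be > 0")
  }
  structure(list(sigmas = as.numeric(sigmas), beta = beta, c = c),
            class = "vesselness_params")
}

# 1-D Gaussian and derivative kernels sampled at integer offsets,
# truncated at 4 sigma, then calibrated to exact discrete moments so that
# polynomial inputs give their analytic derivatives: the smoother sums to
# 1, the first-derivative kernel has zero sum and first moment of
# magnitude 1, the second-derivative kernel has zero sum and zero first
# moment and second moment 2.
gauss_kernel <- function(sigma, order = 0L) {
  rad <- max(1L, ceiling(4 * sigma))
  t <- -rad:rad
  g <- exp(-t^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  g <- g / sum(g)
  if (order == 0L) return(g)
  if (order == 1L) {
    k <- -t / sigma^2 * g
    return(k / abs(sum(t * k)))
  }
  k <- (t^2 - sigma^2) / sigma^4 * g
  k <- k - mean(k)
  k * (2 / sum(t^2 * k))
}

# Separable correlation with symmetric (reflective, half-sample) padding.
# kx applies along x (columns), ky along y (rows). All Hessian kernels are
# even or appear in odd pairs, so correlation and convolution agree.
conv_along_cols <- function(x, k) {
  n <- ncol(x)
  rad <- (length(k) - 1L) %/% 2L
  xp <- x[, reflect_idx(n, rad), drop = FALSE]
  out <- matrix(0, nrow(x), n)
  for (j in seq_along(k))
    if (k[j] != 0) out <- out + k[j] * xp[, j:(j + n - 1L), drop = FALSE]
  out
}

conv_sep <- function(img, kx, ky) {
  t(conv_along_cols(t(conv_along_cols(img, kx)), ky))
}

#' Hessian eigenvalue fields of an image at one Gaussian scale
#'
#' Computes the scale-normalized Hessian of Gaussian-smoothed image
#' (second-derivative-of-Gaussian filtering, multiplied by sigma^2 so
#' responses are comparable across scales) and its per-pixel eigenvalues
#' ordered by absolute value, `|lambda1| <= |lambda2|`. Boundaries use
#' reflective padding.
#'
#' @param image numeric matrix (rows = y, cols = x).
#' @param sigma Gaussian scale in pixels, > 0.
#' @return list with matrices `lambda1`, `lambda2` and the Hessian entries
#'   `hxx`, `hxy`, `hyy`.
#' @export
hessian_eigenvalues <- function(image, sigma) {
  check_scalar(sigma, "sigma")
  if (sigma <= 0) stop_field("sigma", "must be > 0")
  image <- as.matrix(image)
  g0 <- gauss_kernel(sigma, 0L)
  g1 <- gauss_kernel(sigma, 1L)
  g2 <- gauss_kernel(sigma, 2L)
  s2 <- sigma^2
  hxx <- s2 * conv_sep(image, g2, g0)
  hyy <- s2 * conv_sep(image, g0, g2)
  hxy <- s2 * conv_sep(image, g1, g1)
  # closed-form symmetric 2x2 eigenvalues
  half_tr <- (hxx + hyy) / 2
  disc <- sqrt(((hxx - hyy) / 2)^2 + hxy^2)
  e_hi <- half_tr + disc
  e_lo <- half_tr - disc
  swap <- abs(e_hi) <= abs(e_lo)       # lambda1 = smaller magnitude
  lambda1 <- ifelse(swap, e_hi, e_lo)
  lambda2 <- ifelse(swap, e_lo, e_hi)
  list(lambda1 = lambda1, lambda2 = lambda2, hxx = hxx, hxy = hxy, hyy = hyy)
}

#' Frangi vesselness of a 2D image
#'
#' Per scale, with eigenvalues `|l1| <= |l2|`, blobness `Rb = l1/l2` and
#' structureness `S = sqrt(l1^2 + l2^2)`, the response is
#' `exp(-Rb^2/(2 beta^2)) * (1 - exp(-S^2/(2 c^2)))`, set to 0 wherever
#' `l2 >= 0` (bright curvilinear structures on a dark background have
#' negative principal curvature). The output is the maximum over scales,
#' in `[0, 1]`.
#'
#' @param image numeric matrix.
#' @param params a [vesselness_params()].
#' @return matrix of vesselness values in `[0, 1]`.
#' @export
frangi_vesselness <- function(image, params = vesselness_params()) {
  if (!inherits(params, "vesselness_params"))
    stop_field("params", "must be a vesselness_params object")
  image <- as.matrix(image)
  best <- matrix(0, nrow(image), ncol(image))
  for (sigma in params$sigmas) {
    ev <- hessian_eigenvalues(image, sigma)
    s_field <- sqrt(ev$lambda1^2 + ev$lambda2^2)
    # numerically flat images: second derivatives at rounding-error level
    if (max(s_field) <= 1e-10 * max(1, max(abs(image)))) next
    c_val <- if (is.null(params$c)) max(s_field) / 2 else params$c
    v <- matrix(0, nrow(image), ncol(image))
    ok <- ev$lambda2 < 0
    if (any(ok) && c_val > 0) {
      rb2 <- (ev$lambda1[ok] / ev$lambda2[ok])^2
      v[ok] <- exp(-rb2 / (2 * params$beta^2)) *
        (1 - exp(-s_field[ok]^2 / (2 * c_val^2)))
    }
    best <- pmax(best, v)
  }
  best
}

# Otsu threshold on continuous values: exhaustive search over midpoints of
# adjacent sorted unique values, maximizing between-class variance.
otsu_threshold <- function(x) {
  u <- sort(unique(as.numeric(x)))
  if (length(u) < 2L) return(Inf)      # constant image: nothing to segment
  cand <- (u[-1L] + u[-length(u)]) / 2
  n <- length(x)
  xs <- sort(as.numeric(x))
  csum <- cumsum(xs)
  total <- csum[n]
  # for each candidate, class 0 = values <= cand (values < threshold side)
  n0 <- findInterval(cand, xs)
  w0 <- n0 / n
  w1 <- 1 - w0
  mu0 <- csum[n0] / n0
  mu1 <- (total - csum[n0]) / (n - n0)
  between <- w0 * w1 * (mu0 - mu1)^2
  cand[which.max(between)]
}

#' Global threshold of a vesselness field into a tubule mask
#'
#' @param vesselness numeric matrix (a [frangi_vesselness()] output, or any
#'   image).
#' @param method `"otsu"` (between-class-variance maximizing threshold over
#'   the continuous values) or `"fixed"`.
#' @param value threshold for `method = "fixed"`.
#' @return A `tubule_mask`: list with logical `mask` (`vesselness >=
#'   threshold`) and the `threshold` used. An all-constant input yields an
#'   empty mask under `"otsu"` (threshold `Inf`).
#' @details With `method = "fixed"` outside the observed intensity range
#'   the mask is empty or full and a warning is raised.
#' @export
global_threshold <- function(vesselness, method = c("otsu", "fixed"),
                             value = NULL) {
  method <- match.arg(method)
  vesselness <- as.matrix(vesselness)
  thr <- if (method == "otsu") {
    otsu_threshold(vesselness)
  } else {
    if (is.null(value)) stop_field("value", "required for method = 'fixed'")
    check_scalar(value, "value")
    rng <- range(vesselness)
    if (value < rng[1L] || value > rng[2L])
      warning("fixed threshold ", value, " outside observed range [",
              signif(rng[1L], 4), ", ", signif(rng[2L], 4),
              "]; mask is empty or full", call. = FALSE)
    value
  }
  structure(list(mask = vesselness >= thr, threshold = thr),
            class = "tubule_mask")
}

#' @export
print.tubule_mask <- function(x, ...) {
  cat(sprintf("tubule_mask: %d x %d px, %d foreground px, threshold %.4g\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$threshold))
  invisible(x)
}
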