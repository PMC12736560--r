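#' Specify a tubule (single microtubule or bundle) for simulation
#'
#' A tubule is described by its centerline polyline and an outer diameter.
#' A single microtubule has an outer diameter of about 25 nm; lateral
#' association into bundles is modelled as a single tubule of larger
#' diameter, which matches a width-only readout.
#'
#' @param centerline numeric matrix (n x 2) of ordered (x, y) points in nm,
#'   n >= 2, consecutive points distinct.
#' @param outer_diameter outer diameter in nm, > 0.
#' @param label identifier for ground-truth bookkeeping.
#' @return A `tubule_spec` object.
#' @export
tubule_spec <- function(centerline, outer_diameter, label = "tubule") {
  centerline <- as.matrix(centerline)
  if (!is.numeric(centerline) || ncol(centerline) != 2L || nrow(centerline) < 2L)
    stop_field("centerline", "must be a numeric n x 2 matrix with n >= 2")
  if (any(!is.finite(centerline)))
    stop_field("centerline", "must be finite")
  steps <- diff(centerline)
  if (any(rowSums(steps^2) == 0))
    stop_field("centerline", "consecutive points must be distinct")
  check_scalar(outer_diameter, "outer_diameter")
  if (outer_diameter <= 0) stop_field("outer_diameter", "must be > 0")
  structure(list(centerline = centerline, outer_diameter = outer_diameter,
                 label = as.character(label)[1L]),
            class = "tubule_spec")
}

#' Specify a field of tubules for SMLM simulation
#'
#' Describes the statistical structure of a dSTORM acquisition of labelled
#' tubules: emitters are placed along each centerline as a Poisson process,
#' displaced uniformly across the projected tubule cross-section, and each
#' emitter yields a Poisson number of localizations blurred by Gaussian
#' localization error. Background localizations are uniform over the field.
#'
#' @param field_size numeric length-2, field width and height in nm.
#' @param tubules list of [tubule_spec()] objects.
#' @param labeling_density emitters per nm of centerline, >= 0.
#' @param locs_per_emitter_mean mean localizations per emitter, >= 0.
#' @param loc_precision_sigma localization error s.d. in nm, >= 0.
#' @param background_density background localizations per nm^2, >= 0.
#' @param density_multipliers optional per-tubule multipliers of
#'   `labeling_density` (recycled); a bundle of k laterally associated
#'   microtubules carries about k times the tubulin epitopes of a single
#'   one, so bundle tubules are usually given multiplier `diameter / 25`.
#' @param seed integer seed; the whole simulation is deterministic given it.
#' @return A `field_spec` object.
#' @export
field_spec <- function(field_size, tubules, labeling_density,
                       locs_per_emitter_mean, loc_precision_sigma = 0,
                       background_density = 0, density_multipliers = 1,
                       seed = 1L) {
  if (!is.numeric(field_size) || length(field_size) != 2L ||
      any(!is.finite(field_size)) || any(field_size <= 0))
    stop_field("field_size", "must be two positive numbers (width, height) in nm")
  if (!is.list(tubules) || !all(vapply(tubules, inherits, logical(1L), "tubule_spec")))
    stop_field("tubules", "must be a list of tubule_spec objects")
  check_scalar(labeling_density, "labeling_density", min = 0)
  check_scalar(locs_per_emitter_mean, "locs_per_emitter_mean", min = 0)
  check_scalar(loc_precision_sigma, "loc_precision_sigma", min = 0)
  check_scalar(background_density, "background_density", min = 0)
  check_scalar(seed, "seed")
  density_multipliers <- rep_len(as.numeric(density_multipliers),
                                 length(tubules))
  if (any(!is.finite(density_multipliers)) || any(density_multipliers < 0))
    stop_field("density_multipliers", "must be finite and >= 0")
  structure(list(field_size = as.numeric(field_size), tubules = tubules,
                 labeling_density = labeling_density,
                 locs_per_emitter_mean = locs_per_emitter_mean,
                 loc_precision_sigma = loc_precision_sigma,
                 background_density = background_density,
                 density_multipliers = density_multipliers,
                 seed = as.integer(seed)),
            class = "field_spec")
}

new_loc_table <- function(frame, x, y, intensity, uncertainty) {
  structure(data.frame(frame = as.integer(frame), x = x, y = y,
                       intensity = intensity, uncertainty = uncertainty),
            class = c("loc_table", "data.frame"))
}

#' Simulate an SMLM localization table with ground truth
#'
#' Emitters are placed along each tubule centerline at a Poisson-distributed
#' count with mean `labeling_density * arc_length`, each displaced to a
#' uniformly random transverse offset in `[-d/2, +d/2]` (a filled projected
#' cylinder). Each emitter yields `Poisson(locs_per_emitter_mean)`
#' localizations perturbed by isotropic Gaussian error of s.d.
#' `loc_precision_sigma`; background localizations are uniform over the
#' field at `background_density` per nm^2.
#'
#' Random draws occur in a fixed documented order (per tubule: emitter
#' count, arc positions, transverse offsets, per-emitter localization
#' counts, x noise, y noise; then background count and positions; then
#' frames and photon counts for all records), so results are bitwise
#' reproducible given `seed`.
#'
#' @param spec a [field_spec()].
#' @return A list with `locs` (a `loc_table` data frame: frame, x, y,
#'   intensity, uncertainty) and `truth` (per-localization tubule
#'   assignment, per-tubule true diameter/length/emitter count, and the
#'   background count).
#' @export
simulate_tubule_field <- function(spec) {
  if (!inherits(spec, "field_spec")) stop_field("spec", "must be a field_spec")
  with_rng(spec$seed, {
    xs <- numeric(0); ys <- numeric(0); assign_lab <- character(0)
    truth_rows <- vector("list", length(spec$tubules))
    for (i in seq_along(spec$tubules)) {
      tb <- spec$tubules[[i]]
      cs <- polyline_arclength(tb$centerline)
      len <- cs[length(cs)]
      mult <- if (is.null(spec$density_multipliers)) 1 else
        spec$density_multipliers[i]
      n_em <- stats::rpois(1L, spec$labeling_density * mult * len)
      n_loc_i <- 0L
      if (n_em > 0) {
        s <- stats::runif(n_em, 0, len)
        off <- stats::runif(n_em, -tb$outer_diameter / 2, tb$outer_diameter / 2)
        pt <- polyline_point_at(tb$centerline, s)
        # unit normal = tangent rotated by 90 degrees (x right, y down)
        ex <- pt$point[, 1L] - off * pt$tangent[, 2L]
        ey <- pt$point[, 2L] + off * pt$tangent[, 1L]
        k <- stats::rpois(n_em, spec$locs_per_emitter_mean)
        n_loc_i <- sum(k)
        if (n_loc_i > 0) {
          lx <- rep(ex, k); ly <- rep(ey, k)
          if (spec$loc_precision_sigma > 0) {
            lx <- lx + stats::rnorm(n_loc_i, 0, spec$loc_precision_sigma)
            ly <- ly + stats::rnorm(n_loc_i, 0, spec$loc_precision_sigma)
          }
          xs <- c(xs, lx); ys <- c(ys, ly)
          assign_lab <- c(assign_lab, rep(tb$label, n_loc_i))
        }
      }
      truth_rows[[i]] <- data.frame(label = tb$label,
                                    diameter_nm = tb$outer_diameter,
                                    length_nm = len,
                                    n_emitters = n_em,
                                    n_localizations = n_loc_i)
    }
    n_bg <- stats::rpois(1L, spec$background_density *
                           spec$field_size[1L] * spec$field_size[2L])
    if (n_bg > 0) {
      xs <- c(xs, stats::runif(n_bg, 0, spec$field_size[1L]))
      ys <- c(ys, stats::runif(n_bg, 0, spec$field_size[2L]))
      assign_lab <- c(assign_lab, rep(NA_character_, n_bg))
    }
    n <- length(xs)
    frame <- if (n > 0) sample.int(10000L, n, replace = TRUE) else integer(0)
    photons <- if (n > 0) stats::rgamma(n, shape = 2, scale = 500) else numeric(0)
    unc <- if (spec$loc_precision_sigma > 0)
      rep(spec$loc_precision_sigma, n) else rep(NA_real_, n)
    locs <- new_loc_table(frame, xs, ys, photons, unc)
    truth <- list(assignment = assign_lab,
                  tubules = do.call(rbind, truth_rows),
                  n_background = n_bg)
    list(locs = locs, truth = truth)
  })
}

#' Specify a two-channel 3D confocal stack simulation
#'
#' Emulates a double-immunofluorescence z-stack of a cylindrical cell: a set
#' of filament-like structures (short dilated segments) is drawn for channel
#' A; a controllable fraction of them also carries channel-B signal, and the
#' remainder of channel B comes from B-only structures. Each channel is
#' blurred by a Gaussian PSF and corrupted by additive Gaussian noise.
#' Structures are placed with a minimum separation so their supports are
#' disjoint, making ground-truth colocalization fractions exact.
#'
#' @param shape integer length-3 stack shape (z, y, x) in voxels.
#' @param voxel_size voxel edge length(s) in nm; scalar or length-3 (z, y, x).
#' @param n_structures number of channel-A structures.
#' @param fraction_colocalized fraction of A structures that also appear in
#'   channel B, in `[0, 1]`; the shared count is `round(fraction * n)`.
#' @param structure_radius structure radius in nm.
#' @param structure_length structure segment length in nm.
#' @param psf_sigma Gaussian PSF s.d. in nm; scalar or length-3 (z, y, x).
#'   0 disables blurring.
#' @param noise_sd additive Gaussian noise s.d. (intensity units); 0 disables.
#' @param amplitude structure intensity amplitude.
#' @param seed integer seed.
#' @return A `confocal_spec` object.
#' @export
confocal_spec <- function(shape = c(16L, 64L, 64L), voxel_size = 100,
                          n_structures = 10L, fraction_colocalized = 0.5,
                          structure_radius = 150, structure_length = 600,
                          psf_sigma = 0, noise_sd = 0, amplitude = 100,
                          seed = 1L) {
  if (!is.numeric(shape) || length(shape) != 3L || any(shape < 1))
    stop_field("shape", "must be three positive voxel counts (z, y, x)")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) stop_field("voxel_size", "must be > 0")
  check_scalar(fraction_colocalized, "fraction_colocalized", min = 0, max = 1)
  check_scalar(n_structures, "n_structures", min = 0)
  psf_sigma <- rep_len(as.numeric(psf_sigma), 3L)
  if (any(psf_sigma < 0)) stop_field("psf_sigma", "must be >= 0")
  check_scalar(noise_sd, "noise_sd", min = 0)
  check_scalar(seed, "seed")
  structure(list(shape = as.integer(shape), voxel_size = voxel_size,
                 n_structures = as.integer(n_structures),
                 fraction_colocalized = fraction_colocalized,
                 structure_radius = structure_radius,
                 structure_length = structure_length,
                 psf_sigma = psf_sigma, noise_sd = noise_sd,
                 amplitude = amplitude, seed = as.integer(seed)),
            class = "confocal_spec")
}

# Rasterize a capsule (segment p0-p1 dilated by radius r, all nm) into a
# zyx voxel array mask. Voxel centers at (k - 0.5) * voxel_size.
rasterize_capsule <- function(shape, voxel_size, p0, p1, r) {
  zc <- ((seq_len(shape[1L]) - 0.5) * voxel_size[1L])
  yc <- ((seq_len(shape[2L]) - 0.5) * voxel_size[2L])
  xc <- ((seq_len(shape[3L]) - 0.5) * voxel_size[3L])
  g <- expand.grid(z = zc, y = yc, x = xc)
  ab <- p1 - p0
  len2 <- sum(ab^2)
  if (len2 == 0) {
    d2 <- (g$z - p0[1L])^2 + (g$y - p0[2L])^2 + (g$x - p0[3L])^2
  } else {
    t <- ((g$z - p0[1L]) * ab[1L] + (g$y - p0[2L]) * ab[2L] +
            (g$x - p0[3L]) * ab[3L]) / len2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (g$z - (p0[1L] + t * ab[1L]))^2 + (g$y - (p0[2L] + t * ab[2L]))^2 +
      (g$x - (p0[3L] + t * ab[3L]))^2
  }
  array(d2 <= r^2, dim = shape)
}

# Separable Gaussian blur of a 3D array, sigma in voxels per axis.
gauss_blur3 <- function(a, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    rad <- max(1L, ceiling(4 * s))
    k <- stats::dnorm(-rad:rad, sd = s)
    k <- k / sum(k)
    a <- apply_along3(a, ax, function(v) conv1_reflect(v, k))
  }
  a
}

apply_along3 <- function(a, axis, f) {
  d <- dim(a)
  perm <- switch(axis, `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L), `3` = c(3L, 1L, 2L))
  b <- aperm(a, perm)
  m <- matrix(b, nrow = d[axis])
  m <- apply(m, 2L, f)
  b <- array(m, dim = d[perm])
  aperm(b, order(perm))
}

# Symmetric (half-sample reflective) padding indices: padded position p
# maps to original index reflect(p - rad).
reflect_idx <- function(n, rad) {
  i <- (1L - rad):(n + rad)
  while (any(i < 1L | i > n)) {
    i <- ifelse(i < 1L, 1L - i, i)
    i <- ifelse(i > n, 2L * n + 1L - i, i)
  }
  i
}

# 1-D correlation with reflective padding; k indexed by offsets -rad..rad.
conv1_reflect <- function(v, k) {
  n <- length(v)
  rad <- (length(k) - 1L) %/% 2L
  vp <- v[reflect_idx(n, rad)]
  out <- numeric(n)
  for (j in seq_along(k))
    if (k[j] != 0) out <- out + k[j] * vp[j:(j + n - 1L)]
  out
}

#' Simulate a two-channel confocal stack with known colocalization
#'
#' @param spec a [confocal_spec()].
#' @return A list with `channel_a`, `channel_b` (z, y, x arrays), and
#'   `truth`: per-structure centers/orientation, which structures are
#'   shared, the exact fraction of channel-A integrated signal lying in
#'   shared structures (`coloc_signal_fraction_a`, the noiseless PSF-free
#'   Manders M1), and the clean structure masks.
#' @export
simulate_confocal_stack <- function(spec) {
  if (!inherits(spec, "confocal_spec")) stop_field("spec", "must be a confocal_spec")
  with_rng(spec$seed, {
    shp <- spec$shape
    ext <- shp * spec$voxel_size            # (z, y, x) extent in nm
    n <- spec$n_structures
    n_shared <- round(spec$fraction_colocalized * n)
    # rejection-sample centers with pairwise separation > length + 2r so
    # structure supports never overlap (A structures plus B-only structures)
    min_sep <- spec$structure_length + 2 * spec$structure_radius +
      max(spec$voxel_size)
    n_total <- n + (n - n_shared)           # A structures + B-only structures
    centers <- matrix(NA_real_, n_total, 3L)
    # structures lie in-plane, so only the radius matters along z
    margin <- c(spec$structure_radius,
                rep(spec$structure_length / 2 + spec$structure_radius, 2L))
    if (any(2 * margin >= ext))
      stop("stack too small for the requested structure size", call. = FALSE)
    placed <- 0L; tries <- 0L
    while (placed < n_total && tries < 20000L) {
      tries <- tries + 1L
      cand <- c(stats::runif(1L, margin[1L], ext[1L] - margin[1L]),
                stats::runif(1L, margin[2L], ext[2L] - margin[2L]),
                stats::runif(1L, margin[3L], ext[3L] - margin[3L]))
      ok <- placed == 0L ||
        all(sqrt(rowSums((centers[seq_len(placed), , drop = FALSE] -
                            matrix(cand, placed, 3L, byrow = TRUE))^2)) > min_sep)
      if (ok) { placed <- placed + 1L; centers[placed, ] <- cand }
    }
    if (placed < n_total)
      stop("could not place ", n_total, " non-overlapping structures; ",
           "reduce n_structures or structure size", call. = FALSE)
    # random orientations (mostly in-plane, as for cortical filaments)
    phi <- stats::runif(n_total, 0, 2 * pi)
    dirs <- cbind(0, sin(phi), cos(phi))
    half <- spec$structure_length / 2
    masks <- vector("list", n_total)
    for (i in seq_len(n_total)) {
      masks[[i]] <- rasterize_capsule(shp, spec$voxel_size,
                                      centers[i, ] - half * dirs[i, ],
                                      centers[i, ] + half * dirs[i, ],
                                      spec$structure_radius)
    }
    shared_ids <- seq_len(n_shared)         # first n_shared A structures shared
    a_ids <- seq_len(n)
    b_ids <- c(shared_ids, if (n_total > n) (n + 1L):n_total)
    zero <- array(0, dim = shp)
    mask_a <- Reduce(`+`, masks[a_ids], accumulate = FALSE, right = FALSE,
                     init = zero) > 0
    mask_b <- if (length(b_ids))
      Reduce(`+`, masks[b_ids], init = zero) > 0 else zero > 0
    clean_a <- spec$amplitude * mask_a
    clean_b <- spec$amplitude * mask_b
    vox_a <- sum(mask_a)
    vox_shared <- if (length(shared_ids))
      sum(Reduce(`+`, masks[shared_ids], init = zero) > 0) else 0L
    frac_a_in_shared <- if (vox_a > 0) vox_shared / vox_a else NA_real_
    sig_vox <- spec$psf_sigma / spec$voxel_size
    ch_a <- gauss_blur3(clean_a, sig_vox)
    ch_b <- gauss_blur3(clean_b, sig_vox)
    if (spec$noise_sd > 0) {
      ch_a <- ch_a + array(stats::rnorm(prod(shp), 0, spec$noise_sd), shp)
      ch_b <- ch_b + array(stats::rnorm(prod(shp), 0, spec$noise_sd), shp)
      ch_a[ch_a < 0] <- 0
      ch_b[ch_b < 0] <- 0
    }
    truth <- list(centers = centers, shared_ids = shared_ids,
                  a_ids = a_ids, b_ids = b_ids,
                  coloc_signal_fraction_a = frac_a_in_shared,
                  mask_a = mask_a, mask_b = mask_b)
    list(channel_a = ch_a, channel_b = ch_b, truth = truth)
  })
}
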