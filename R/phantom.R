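#' Specification of a left-ventricular SPECT phantom
#'
#' Describes a digital LV phantom: a half-ellipsoid myocardial shell with a
#' Gaussian transmural count profile, optional perfusion defects and optional
#' Poisson count noise. Defects are defined in polar coordinates (angle from
#' the anterior wall, counterclockwise from the apex view, x long-axis span
#' as a fraction 0 = apex to 1 = base), which keeps the ground-truth segment
#' uptake computable analytically.
#'
#' @param grid `(n_slices, n_rows, n_cols)` of the count volume.
#' @param voxel_size_mm voxel size in mm along (slice, row, col).
#' @param wall_radius_mm mid-wall radius at the base.
#' @param wall_sigma_mm SD of the Gaussian transmural count profile.
#' @param peak_counts count value at the mid-wall of a defect-free region.
#' @param defects list of defects, each a list with `center_deg` (angle of the
#'   defect centre from anterior, counterclockwise), `width_deg` (> 0),
#'   `span` (length-2 fractional long-axis range in `[0, 1]`), `severity`
#'   (remaining fraction of normal uptake, in `[0, 1]`; 0 = absent uptake)
#'   and optionally `edge_deg` (width of a raised-cosine angular transition
#'   at the defect border; default 0 = sharp edge).
#' @param poisson_noise logical; apply Poisson noise to the counts.
#' @param tracer tracer label for the generated volume.
#' @param seed integer seed used when `poisson_noise` is `TRUE`; the same
#'   spec and seed give bit-identical volumes.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(12L, 64L, 64L),
                         voxel_size_mm = c(8, 2, 2),
                         wall_radius_mm = 28,
                         wall_sigma_mm = 6,
                         peak_counts = 1000,
                         defects = list(),
                         poisson_noise = FALSE,
                         tracer = "TL_STRESS",
                         seed = 1L) {
  for (d in defects) {
    if (is.null(d$severity) || d$severity < 0 || d$severity > 1)
      stop("defect severity must lie in [0, 1]")
    if (is.null(d$width_deg) || d$width_deg <= 0)
      stop("defect width must be positive")
    if (is.null(d$span) || length(d$span) != 2L || d$span[1] > d$span[2] ||
        d$span[1] < 0 || d$span[2] > 1)
      stop("defect span must be an increasing pair in [0, 1]")
  }
  structure(list(grid = as.integer(grid), voxel_size_mm = voxel_size_mm,
                 wall_radius_mm = wall_radius_mm, wall_sigma_mm = wall_sigma_mm,
                 peak_counts = peak_counts, defects = defects,
                 poisson_noise = isTRUE(poisson_noise), tracer = tracer,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# wrapped angular distance in degrees
ang_dist <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

# multiplicative defect attenuation at (angle alpha_deg from anterior,
# long-axis fraction u); vectorized over alpha. `edge_deg` > 0 replaces the
# sharp angular border by a raised-cosine transition of that width.
defect_factor <- function(defects, alpha_deg, u) {
  f <- rep(1, length(alpha_deg))
  for (d in defects) {
    if (u >= d$span[1] && u <= d$span[2]) {
      e <- if (is.null(d$edge_deg)) 0 else d$edge_deg
      dist <- ang_dist(alpha_deg, d$center_deg)
      if (e <= 0) {
        hit <- dist <= d$width_deg / 2
        f[hit] <- f[hit] * d$severity
      } else {
        t <- pmin(pmax((d$width_deg / 2 + e / 2 - dist) / e, 0), 1)
        w <- (1 - cos(pi * t)) / 2
        f <- f * (1 + (d$severity - 1) * w)
      }
    }
  }
  f
}

#' Generate a phantom SPECT volume with analytic ground truth
#'
#' Builds the count volume described by a [phantom_spec()] and, alongside it,
#' the analytic ground-truth segment uptake: the relative uptake of each
#' polar-map bin is the product of the severities of the defects covering its
#' (angle, long-axis) position, resampled onto rings exactly as
#' [build_polar_map()] resamples slices, normalized to a maximum of 100 and
#' averaged per segment. The truth never touches the voxel grid, so it is an
#' independent reference for the imaging pipeline.
#'
#' Overlapping defects compose multiplicatively (a warning is issued).
#'
#' @param spec a [phantom_spec()].
#' @param n_rings,n_sectors polar geometry used for the ground truth.
#' @return List with `volume` (a [short_axis_volume()]) and
#'   `truth_segment_uptake` (17 values, percent).
#' @export
make_phantom <- function(spec, n_rings = 36L, n_sectors = 60L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(spec$defects) > 1L) {
    for (i in seq_along(spec$defects)[-1]) {
      for (k in seq_len(i - 1)) {
        a <- spec$defects[[i]]; b <- spec$defects[[k]]
        if (ang_dist(a$center_deg, b$center_deg) <
            (a$width_deg + b$width_deg) / 2 &&
            a$span[1] <= b$span[2] && b$span[1] <= a$span[2]) {
          warning("overlapping defects compose multiplicatively")
        }
      }
    }
  }
  n_slices <- spec$grid[1]; nr <- spec$grid[2]; nc <- spec$grid[3]
  dy <- spec$voxel_size_mm[2]; dx <- spec$voxel_size_mm[3]
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  counts <- array(0, dim = spec$grid)
  yy <- (matrix(seq_len(nr), nr, nc) - cy) * dy      # downward, mm
  xx <- (matrix(seq_len(nc), nr, nc, byrow = TRUE) - cx) * dx
  rho <- sqrt(xx^2 + yy^2)
  # angle from anterior (image up), counterclockwise from the apex view
  alpha <- (atan2(-yy, xx) * 180 / pi - 90) %% 360
  for (s in seq_len(n_slices)) {
    u <- (s - 0.5) / n_slices # long-axis fraction, 0 apex
    r_mid <- spec$wall_radius_mm * sqrt(1 - (1 - u)^2)
    sl <- spec$peak_counts * exp(-(rho - r_mid)^2 / (2 * spec$wall_sigma_mm^2))
    fac <- matrix(defect_factor(spec$defects, as.vector(alpha), u), nr, nc)
    counts[s, , ] <- sl * fac
  }
  if (spec$poisson_noise) {
    set.seed(spec$seed)
    counts <- array(stats::rpois(length(counts), counts), dim = spec$grid)
  }
  vol <- short_axis_volume(counts, spec$voxel_size_mm, tracer = spec$tracer)
  truth <- phantom_truth(spec, n_rings, n_sectors)
  list(volume = vol, truth_segment_uptake = truth)
}

# Analytic per-segment uptake for a phantom spec under the default mask.
phantom_truth <- function(spec, n_rings = 36L, n_sectors = 60L) {
  n_slices <- spec$grid[1]
  alpha <- (seq_len(n_sectors) - 1) * 360 / n_sectors
  prof <- t(vapply(seq_len(n_slices), function(s)
    defect_factor(spec$defects, alpha, (s - 0.5) / n_slices),
    numeric(n_sectors)))
  pos <- seq(1, n_slices, length.out = n_rings)
  up <- apply(prof, 2, function(col)
    stats::approx(seq_len(n_slices), col, xout = pos)$y)
  up <- matrix(up, n_rings, n_sectors)
  up[1, ] <- mean(prof[1, ])
  up <- up / max(up) * 100
  mask <- build_segment_mask(n_rings, n_sectors)
  vapply(1:17, function(s) mean(up[mask == s]), numeric(1))
}

#' Run the imaging pipeline on a volume
#'
#' Convenience wrapper: profiles, polar map, normalization.
#'
#' @param volume a [short_axis_volume()].
#' @param n_rings,n_sectors polar geometry.
#' @param percentile passed to [normalize_uptake()].
#' @return A normalized `polar_map`.
#' @export
volume_to_polar <- function(volume, n_rings = 36L, n_sectors = 60L,
                            percentile = NULL) {
  prof <- extract_profiles(volume, n_angles = n_sectors)
  normalize_uptake(build_polar_map(prof, n_rings = n_rings), percentile)
}

#' Build a normal database from a defect-free phantom population
#'
#' Runs each phantom through the imaging pipeline and records the per-segment
#' mean and SD of percent uptake across the population, for each requested
#' tracer label.
#'
#' @param specs list of at least 2 defect-free [phantom_spec()]s.
#' @param mask a `segment_mask` defining the geometry.
#' @param tracers tracer labels the database should cover.
#' @return A [normal_db()].
#' @export
build_normal_db <- function(specs, mask = build_segment_mask(),
                            tracers = c("TL_STRESS", "TL_REST", "BMIPP")) {
  if (length(specs) < 2L) stop("need at least 2 phantoms")
  if (any(vapply(specs, function(s) length(s$defects) > 0L, logical(1))))
    stop("normal-database population must be defect-free")
  n_rings <- nrow(mask); n_sectors <- ncol(mask)
  ups <- vapply(specs, function(sp) {
    ph <- make_phantom(sp, n_rings, n_sectors)
    polar <- volume_to_polar(ph$volume, n_rings, n_sectors)
    segment_mean_uptake(polar, mask)
  }, numeric(17))
  mu <- rowMeans(ups)
  sdv <- apply(ups, 1, stats::sd)
  if (any(sdv <= 0))
    stop("degenerate SD: identical phantoms give zero per-segment SD; ",
         "add Poisson noise (a noise floor) to the population")
  normal_db(data.frame(
    tracer = rep(tracers, each = 17),
    segment = rep(1:17, length(tracers)),
    mean = rep(pmin(mu, 100), length(tracers)),
    sd = rep(sdv, length(tracers))))
}
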