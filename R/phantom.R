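# Synthetic labeled pancreas phantoms.
#
# The pancreas is emulated as a curved tube around a cubic Bezier
# centerline: a straight preset, a "J" preset (hockey-stick bend of about
# 90 degrees, the normal morphology) and a "U" preset (about 160 degrees,
# the irregular worst case). The tube tapers from a thick head to a thin
# tail, and head/body/tail labels are assigned by arc-length fraction
# along the centerline with default fractions 0.40/0.33/0.26 of organ
# length. Intensities are generated in arbitrary units (regional mean +
# Gaussian noise over a soft-tissue background) and are deliberately NOT
# normalized: phantoms are meant to be pushed through the real
# preprocessing path.

#' Specification of a synthetic pancreas phantom
#'
#' @param shape integer(3) grid size in voxels.
#' @param preset centerline curvature preset: `"straight"`, `"J"`
#'   (approx. 90 degree hook) or `"U"` (approx. 160 degree bend).
#' @param fractions numeric(3) head/body/tail length fractions; any
#'   positive triple is renormalized to sum 1.
#' @param radius_head,radius_tail tube radius (voxels) at the head and
#'   tail end; the radius tapers linearly in between and the head must be
#'   at least as thick as the tail. Defaults follow the anatomical
#'   proportion of the organ (anteroposterior diameter 1-3 cm against a
#'   12-15 cm length): head radius about 0.11 of the tube length at the
#'   default 32-voxel grid.
#' @param region_means mean intensity (arbitrary units) per subregion.
#' @param noise_sd intensity noise standard deviation.
#' @param background_mean mean intensity of non-pancreas tissue.
#' @param tumor logical; add a tumor-like local intensity perturbation
#'   (texture only, the mask is untouched).
#' @param tumor_radius,tumor_contrast tumor sphere radius (voxels) and
#'   additive intensity change.
#' @param spacing voxel size in mm.
#' @param control_jitter sd (in units of the grid) of Gaussian jitter
#'   applied to the centerline control points; 0 = exact preset.
#' @param seed RNG seed making the phantom reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32, 32, 32), preset = c("J", "straight", "U"),
                         fractions = c(0.40, 0.33, 0.26),
                         radius_head = 3, radius_tail = 1.5,
                         region_means = c(90, 110, 130), noise_sd = 10,
                         background_mean = 40, tumor = FALSE,
                         tumor_radius = 3, tumor_contrast = -40,
                         spacing = c(1, 1, 1), control_jitter = 0,
                         seed = 1L) {
  preset <- match.arg(preset)
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3L || any(fractions <= 0))
    stop("fractions must be 3 positive numbers")
  fractions <- fractions / sum(fractions)
  if (radius_tail < 1 || radius_head < radius_tail)
    stop("need radius_head >= radius_tail >= 1")
  structure(list(shape = as.integer(shape), preset = preset,
                 fractions = fractions, radius_head = radius_head,
                 radius_tail = radius_tail, region_means = region_means,
                 noise_sd = noise_sd, background_mean = background_mean,
                 tumor = tumor, tumor_radius = tumor_radius,
                 tumor_contrast = tumor_contrast, spacing = spacing,
                 control_jitter = control_jitter, seed = as.integer(seed)),
            class = "phantom_spec")
}

# cubic Bezier control points in the unit cube, head end first
preset_control_points <- function(preset) {
  switch(preset,
    straight = rbind(c(0.02, 0.50, 0.50), c(0.35, 0.50, 0.50),
                     c(0.65, 0.50, 0.50), c(0.98, 0.50, 0.50)),
    J = rbind(c(0.05, 0.30, 0.45), c(0.45, 0.15, 0.50),
              c(0.95, 0.35, 0.55), c(0.85, 0.85, 0.50)),
    U = rbind(c(0.08, 0.20, 0.45), c(0.30, 1.00, 0.50),
              c(0.70, 1.00, 0.55), c(0.92, 0.20, 0.50)))
}

bezier_points <- function(cp, n = 400) {
  t <- seq(0, 1, length.out = n)
  b <- cbind((1 - t)^3, 3 * (1 - t)^2 * t, 3 * (1 - t) * t^2, t^3)
  b %*% cp
}

#' Generate one labeled pancreas phantom
#'
#' Builds the tubular mask around the spec's centerline, assigns
#' head/body/tail labels by arc-length fraction, and fills in noisy
#' intensities (raw units; run [preprocess_volume()] before modelling).
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (a [pancreas_volume]), `labels` (integer
#'   array), `arc` (per-voxel centerline arc-length fraction, `NA` outside
#'   the mask) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$shape
  margin <- spec$radius_head + 1.5

  cp <- preset_control_points(spec$preset)
  if (spec$control_jitter > 0)
    cp <- cp + matrix(rnorm(12, 0, spec$control_jitter), 4, 3)
  # map unit cube -> grid, leaving room for the tube radius
  lo <- 1 + margin
  hi <- d - margin
  if (any(hi <= lo)) stop("tube exits grid: shape too small for radius")
  pts <- sweep(sweep(bezier_points(cp), 2, hi - lo, "*"), 2, lo, "+")
  if (any(pts < 1 + spec$radius_head * 0.99) ||
      any(sweep(pts, 2, as.numeric(d), "-") > -spec$radius_head * 0.99))
    stop("tube exits grid")

  seg <- sqrt(rowSums(diff(pts)^2))
  if (sum(seg) < 1e-9) stop("degenerate (zero-length) centerline")
  arc_s <- c(0, cumsum(seg)) / sum(seg)   # arc-length fraction per sample

  # distance of every voxel to the sampled centerline (running min)
  gx <- seq_len(d[1]); gy <- seq_len(d[2]); gz <- seq_len(d[3])
  X <- array(gx, dim = d)
  Y <- array(rep(gy, each = d[1]), dim = d)
  Z <- array(rep(gz, each = d[1] * d[2]), dim = d)
  best <- array(Inf, dim = d)
  nearest <- array(1L, dim = d)
  for (i in seq_len(nrow(pts))) {
    dd <- (X - pts[i, 1])^2 + (Y - pts[i, 2])^2 + (Z - pts[i, 3])^2
    upd <- dd < best
    best[upd] <- dd[upd]
    nearest[upd] <- i
  }
  radius <- spec$radius_head +
    (spec$radius_tail - spec$radius_head) * arc_s[nearest]
  mask <- best <= radius^2

  s <- array(arc_s[nearest], dim = d)
  fH <- spec$fractions[1]; fB <- spec$fractions[2]
  labels <- array(0L, dim = d)
  labels[mask & s < fH] <- SUBREGIONS[["head"]]
  labels[mask & s >= fH & s < fH + fB] <- SUBREGIONS[["body"]]
  labels[mask & s >= fH + fB] <- SUBREGIONS[["tail"]]

  means <- array(spec$background_mean, dim = d)
  for (k in 1:3) means[labels == k] <- spec$region_means[k]
  intens <- means + array(rnorm(prod(d), 0, spec$noise_sd), dim = d)
  if (spec$tumor) {
    mvox <- which(mask)
    ctr <- coord_of(mvox[sample.int(length(mvox), 1)], d)[1, ]
    dd <- (X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2
    intens[dd <= spec$tumor_radius^2] <-
      intens[dd <= spec$tumor_radius^2] + spec$tumor_contrast
  }
  intens <- pmax(intens, 0)

  arc <- array(NA_real_, dim = d)
  arc[mask] <- s[mask]
  vol <- pancreas_volume(intens, mask, spacing = spec$spacing,
                         orientation = "RAS")
  list(volume = vol, labels = labels, arc = arc, spec = spec)
}

#' Generate a jittered phantom dataset
#'
#' Draws `n` phantoms whose size (tube radii), subregion fractions, noise
#' level and centerline control points are jittered case by case around a
#' base specification, emulating inter-subject variation in pancreas size
#' and morphology. A manifest records every resolved spec.
#'
#' @param n number of cases.
#' @param base_spec the [phantom_spec()] jitter is applied around.
#' @param size_jitter relative half-range of the tube-radius scale
#'   (default 0.3, i.e. +-30 percent).
#' @param fraction_jitter relative half-range applied to each length
#'   fraction before renormalization (default 0.05).
#' @param noise_jitter relative half-range of the noise sd.
#' @param control_jitter sd of centerline control-point jitter (grid
#'   units).
#' @param seed master seed; per-case seeds derive from it.
#' @return list with `cases` (each: `id`, `volume`, `labels`, `arc`,
#'   `spec`) and `manifest` (data frame, one row per case).
#' @export
generate_phantom_dataset <- function(n, base_spec = phantom_spec(),
                                     size_jitter = 0.3,
                                     fraction_jitter = 0.05,
                                     noise_jitter = 0.2,
                                     control_jitter = 0.02,
                                     seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  if (size_jitter < 0 || size_jitter >= 1 || fraction_jitter < 0 ||
      fraction_jitter >= 1)
    stop("invalid jitter ranges")
  set.seed(seed)
  case_seeds <- sample.int(1e6, n)
  scales <- runif(n, 1 - size_jitter, 1 + size_jitter)
  fjit <- matrix(runif(3 * n, 1 - fraction_jitter, 1 + fraction_jitter), n, 3)
  njit <- runif(n, 1 - noise_jitter, 1 + noise_jitter)

  cases <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- base_spec
    sp$radius_head <- max(base_spec$radius_head * scales[i], 1.5)
    sp$radius_tail <- max(base_spec$radius_tail * scales[i], 1)
    if (sp$radius_tail > sp$radius_head) sp$radius_tail <- sp$radius_head
    fr <- base_spec$fractions * fjit[i, ]
    sp$fractions <- fr / sum(fr)
    sp$noise_sd <- base_spec$noise_sd * njit[i]
    sp$control_jitter <- control_jitter
    sp$seed <- case_seeds[i]
    ph <- generate_phantom(sp)
    ph$id <- sprintf("phantom_%03d", i)
    cases[[i]] <- ph
    rows[[i]] <- data.frame(
      id = ph$id, preset = sp$preset, seed = sp$seed,
      radius_head = sp$radius_head, radius_tail = sp$radius_tail,
      f_head = sp$fractions[1], f_body = sp$fractions[2],
      f_tail = sp$fractions[3], noise_sd = sp$noise_sd,
      mask_voxels = sum(ph$volume$mask))
  }
  list(cases = cases, manifest = do.call(rbind, rows))
}
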