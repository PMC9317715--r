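test_that("phantoms are deterministic, connected, and anatomically ordered", {
  for (preset in c("straight", "J", "U")) {
    ph <- generate_phantom(phantom_spec(preset = preset, seed = 21))
    ph2 <- generate_phantom(phantom_spec(preset = preset, seed = 21))
    expect_identical(ph$volume$intensities, ph2$volume$intensities)
    expect_identical(ph$labels, ph2$labels)

    # single 26-connected component
    expect_silent(assert_connected_mask(ph$volume))
    # labels live exactly on the mask
    expect_true(all((ph$labels > 0) == ph$volume$mask))
    # head never touches tail (H-B-T adjacency order)
    isH <- ph$labels == 1L
    isT <- ph$labels == 3L
    expect_false(any(isH & pancseg:::dilate26(isT)))
  }
})

test_that("label boundaries sit at the centerline arc-length fractions", {
  ph <- generate_phantom(phantom_spec(preset = "straight", seed = 5,
                                      fractions = c(0.4, 0.33, 0.26)))
  fr <- ph$spec$fractions
  # voxels are labeled by arc fraction: check the split points directly
  expect_lt(max(ph$arc[ph$labels == 1L]), fr[1] + 1e-9)
  expect_gte(min(ph$arc[ph$labels == 2L]), fr[1])
  expect_lt(max(ph$arc[ph$labels == 2L]), fr[1] + fr[2] + 1e-9)
  expect_gte(min(ph$arc[ph$labels == 3L]), fr[1] + fr[2])
  # and in physical terms on the straight tube: the head/body boundary
  # x-extent is ~40% of the tube's x-extent (+- 1 voxel)
  xs <- which(apply(ph$volume$mask, 1, any))
  xlen <- max(xs) - min(xs)
  bx <- max(which(apply(ph$labels == 1L, 1, any)))
  expect_lt(abs((bx - min(xs)) / xlen - fr[1]), 1.5 / xlen + 0.02)
})

test_that("head end is thicker than tail end", {
  ph <- generate_phantom(phantom_spec(preset = "J", seed = 12))
  area_h <- sum(ph$labels == 1L) / sum(!is.na(ph$arc) & ph$arc < 0.40)
  # mean cross-section: head voxels per unit arc vs tail voxels
  vol_h <- sum(ph$labels == 1L) / 0.40
  vol_t <- sum(ph$labels == 3L) / 0.27
  expect_gt(vol_h, vol_t)
})

test_that("alpha at the head/body label boundary matches the head fraction", {
  ph <- generate_phantom(phantom_spec(preset = "straight", seed = 3,
                                      radius_head = 3, radius_tail = 3))
  pre <- preprocess_volume(ph$volume, ph$labels, padding = 2)
  f <- subregion_features(pre$volume, pre$labels)
  fr <- ph$spec$fractions
  boundary_alpha <- max(f$alpha[pre$labels == 1L])
  expect_lt(abs(boundary_alpha - fr[1]), 2 * 1 / f$length_l + 0.05)
})

test_that("Bayes fitted on matched phantoms recovers fraction midpoints", {
  ds <- generate_phantom_dataset(4, phantom_spec(preset = "straight",
                                                 radius_head = 3,
                                                 radius_tail = 3),
                                 fraction_jitter = 0, size_jitter = 0,
                                 control_jitter = 0, seed = 6)
  prepped <- lapply(ds$cases, function(cs)
    preprocess_volume(cs$volume, cs$labels, padding = 2))
  feats <- lapply(prepped, function(pr) subregion_features(pr$volume, pr$labels))
  fit <- fit_subregion_bayes(feats, lapply(prepped, `[[`, "labels"))
  fr <- c(0.40, 0.33, 0.26) / sum(c(0.40, 0.33, 0.26))
  mids <- c(fr[1] / 2, fr[1] + fr[2] / 2, fr[1] + fr[2] + fr[3] / 2)
  expect_lt(max(abs(fit$mu_alpha - mids)), 0.08)
  # anatomical ordering of the class means
  expect_true(all(diff(fit$mu_alpha) > 0))
  expect_true(all(diff(fit$mu_beta) > 0))
})

test_that("dataset jitter respects bounds and the manifest is reproducible", {
  base <- phantom_spec(preset = "J")
  ds <- generate_phantom_dataset(8, base, size_jitter = 0.3,
                                 fraction_jitter = 0.05, seed = 99)
  expect_equal(nrow(ds$manifest), 8)
  expect_gt(length(unique(ds$manifest$mask_voxels)), 1)
  expect_true(all(ds$manifest$radius_head <=
                  base$radius_head * 1.3 + 1e-9))
  fr <- as.matrix(ds$manifest[, c("f_head", "f_body", "f_tail")])
  expect_equal(rowSums(fr), rep(1, 8))
  # each fraction stays within the jitter band around the base value
  base_fr <- matrix(base$fractions, 8, 3, byrow = TRUE)
  expect_true(all(fr / base_fr > 0.88 & fr / base_fr < 1.12))
  ds2 <- generate_phantom_dataset(8, base, size_jitter = 0.3,
                                  fraction_jitter = 0.05, seed = 99)
  expect_identical(ds$manifest, ds2$manifest)

  # per-case masks are connected and ordered
  for (cs in ds$cases[1:3]) {
    expect_silent(assert_connected_mask(cs$volume))
    expect_false(any((cs$labels == 1L) & pancseg:::dilate26(cs$labels == 3L)))
  }
})

test_that("tumor perturbation changes texture but not the mask", {
  sp0 <- phantom_spec(preset = "J", seed = 14, tumor = FALSE)
  sp1 <- phantom_spec(preset = "J", seed = 14, tumor = TRUE)
  p0 <- generate_phantom(sp0)
  p1 <- generate_phantom(sp1)
  expect_identical(p0$volume$mask, p1$volume$mask)
  expect_identical(p0$labels, p1$labels)
  expect_gt(sum(p0$volume$intensities != p1$volume$intensities), 0)
})

test_that("degenerate specs error cleanly", {
  expect_error(phantom_spec(radius_head = 1, radius_tail = 3), "radius")
  expect_error(phantom_spec(fractions = c(0.5, -0.1, 0.6)), "positive")
  expect_error(generate_phantom(phantom_spec(shape = c(8, 8, 8))),
               "tube exits grid")
})
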