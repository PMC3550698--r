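vol_uniform <- annulus_volume()
prof_uniform <- extract_profiles(vol_uniform, n_angles = 60)

test_that("uniform annulus gives a flat circumferential profile", {
  expect_equal(dim(prof_uniform$values), c(8, 60))
  # rotational symmetry: every profile value equals the wall count
  expect_true(all(abs(prof_uniform$values - 1000) < 1))
  # centre stays at the grid centre
  expect_true(all(abs(prof_uniform$center_per_slice - 21) < 0.05))
})

test_that("a reduced sector appears in the profile at its angles only", {
  vol <- annulus_volume(sector = list(center = 180, width = 60, frac = 0.4))
  prof <- extract_profiles(vol, n_angles = 60)
  ang <- (seq_len(60) - 1) * 6
  inside <- pmin(abs(ang - 180), 360 - abs(ang - 180)) < 24 # clear of edges
  outside <- pmin(abs(ang - 180), 360 - abs(ang - 180)) > 36
  expect_true(all(abs(prof$values[, inside] - 400) < 20))
  expect_true(all(abs(prof$values[, outside] - 1000) < 20))
})

test_that("profile extraction matches a dense ray-marching oracle", {
  vol <- annulus_volume(n_slices = 5,
                        sector = list(center = 135, width = 90, frac = 0.4))
  prof <- extract_profiles(vol, n_angles = 24)
  ora <- oracle_profile(vol$counts[3, , ], prof$center_per_slice[3, ], 24)
  expect_true(all(abs(prof$values[3, ] - ora) <= 1))
})

test_that("empty volumes and empty slices are handled", {
  z <- array(0, c(6, 15, 15))
  expect_error(extract_profiles(short_axis_volume(z, tracer = "BMIPP")),
               "empty volume")
  counts <- annulus_volume(n_slices = 6, n = 15, r_mid = 5, w = 2)$counts
  counts[4, , ] <- 0
  vol <- short_axis_volume(counts, tracer = "TL_REST")
  prof <- extract_profiles(vol, 24)
  expect_equal(prof$empty_slices, 4L)
  expect_true(all(prof$values[4, ] == 0))
  expect_error(extract_profiles(vol_uniform, n_angles = 6), "at least 12")
})

test_that("profile extraction is equivariant under quarter-turn rotation", {
  # sector edges at 7.5 and 52.5 degrees, midway between bin centres
  vol <- annulus_volume(n_slices = 5, n = 41,
                        sector = list(center = 30, width = 45, frac = 0.3))
  prof <- extract_profiles(vol, n_angles = 24)
  # rotate every slice by 90 degrees counterclockwise in the image plane
  rot <- vol$counts
  for (s in 1:5) rot[s, , ] <- t(vol$counts[s, , ])[ncol(vol$counts[s, , ]):1, ]
  prof_rot <- extract_profiles(
    short_axis_volume(rot, vol$voxel_size_mm, vol$tracer), n_angles = 24)
  shifted <- prof$values[, c(19:24, 1:18)] # 24/4 = 6-bin circular shift
  expect_equal(prof_rot$values, shifted, tolerance = 1e-6)
})

test_that("polar map resampling maps apex to centre and base to rim", {
  pm <- build_polar_map(prof_uniform, n_rings = 36)
  expect_equal(dim(pm$uptake), c(36, 60))
  expect_true(all(abs(pm$uptake - 1000) < 1)) # constant in, constant out

  # linear apex->base gradient: per-slice constant profiles 100..800
  grad <- prof_uniform
  grad$values <- matrix(rep(seq(100, 800, length.out = 8), 60), 8, 60)
  pmg <- build_polar_map(grad, n_rings = 20)
  # closed-form linear interpolation: ring r sits at slice position
  # 1 + (r-1)*7/19, value 100 + (pos-1)*100
  pos <- 1 + (seq_len(20) - 1) * 7 / 19
  expected <- 100 + (pos - 1) * 100
  expect_equal(pmg$uptake[-1, 1], expected[-1], tolerance = 1e-10)
  expect_equal(pmg$uptake[1, 1], 100) # apical cap = mean of apical profile
  expect_true(all(diff(pmg$uptake[, 5]) >= 0)) # monotone ring values

  one <- prof_uniform
  one$values <- one$values[1, , drop = FALSE]
  expect_error(build_polar_map(one), "insufficient slices")
})

test_that("normalization rescales to percent of the maximal data point", {
  pm <- build_polar_map(prof_uniform, 12)
  pm$uptake[] <- 500
  pm$uptake[3, 7] <- 250; pm$uptake[5, 2] <- 50
  npm <- normalize_uptake(pm)
  expect_equal(max(npm$uptake), 100)
  expect_equal(npm$uptake[3, 7], 50)
  expect_equal(npm$uptake[5, 2], 10)
  expect_equal(npm$normalization_max, 500)
  expect_error(normalize_uptake(npm), "already normalized")

  flat <- build_polar_map(prof_uniform, 12)
  flat$uptake[] <- 500
  expect_true(all(normalize_uptake(flat)$uptake == 100))

  zero <- build_polar_map(prof_uniform, 12)
  zero$uptake[] <- 0
  expect_error(normalize_uptake(zero), "no counts")
})

test_that("percent uptake is invariant to global count scaling", {
  vol <- annulus_volume(sector = list(center = 300, width = 45, frac = 0.5))
  a <- volume_to_polar(vol)
  # lossless (power-of-two) rescaling: bit-identical percent uptake
  pow2 <- short_axis_volume(vol$counts * 64, vol$voxel_size_mm, vol$tracer)
  expect_identical(a$uptake, volume_to_polar(pow2)$uptake)
  # arbitrary rescaling rounds the input counts themselves, so identity
  # holds to floating-point precision
  arb <- short_axis_volume(vol$counts * 3.7, vol$voxel_size_mm, vol$tracer)
  expect_equal(a$uptake, volume_to_polar(arb)$uptake, tolerance = 1e-6)
})

test_that("polar maps round-trip through CSV", {
  pm <- volume_to_polar(annulus_volume(n_slices = 5, n = 21, r_mid = 6,
                                       w = 2), n_rings = 8, n_sectors = 12)
  f <- tempfile(fileext = ".csv")
  write_polar_map(pm, f, header_comment = "roundtrip check")
  back <- read_polar_map(f)
  expect_equal(back$uptake, pm$uptake, tolerance = 1e-12)
  expect_true(back$normalized)
  expect_equal(back$normalization_max, pm$normalization_max)
})
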