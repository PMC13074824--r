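phantom_fixture <- function(void_radius = 5e-3, noise_sd = 0, seed = 1) {
  g <- grid3d(41, 41, 41, 2e-3)
  simulate_phantom_image(g, void_radius = void_radius, signal_level = 100,
                         noise_mean = 10, noise_sd = noise_sd, seed = seed)
}

test_that("the 125% threshold rule recovers a 5 mm spherical void within 5%", {
  g <- grid3d(61, 61, 61, 0.5e-3)
  ph <- simulate_phantom_image(g, cylinder_radius = 0.014,
                               cylinder_height = 0.028,
                               void_radius = 5e-3, signal_level = 100,
                               noise_mean = 10)
  seg <- segment_signal_void(ph$image, ph$noise_region, ph$phantom_mask,
                             spacing = c(g$dx, g$dy, g$dz))
  expect_equal(seg$threshold_used, 12.5, tolerance = 1e-9)
  v_true <- 4 / 3 * pi * 5^3    # mm^3
  expect_lt(abs(seg$volume_mm3 - v_true) / v_true, 0.05)
  # extent of a 10 mm-diameter sphere: within one voxel of 10 mm per axis
  expect_true(all(abs(seg$extent_mm - 10) <= 0.5 + 1e-9))
})

test_that("no void gives an empty (volume-0) segmentation", {
  ph <- phantom_fixture(void_radius = 0)
  expect_message(
    seg <- segment_signal_void(ph$image, ph$noise_region, ph$phantom_mask,
                               spacing = rep(2e-3, 3)),
    "empty")
  expect_identical(seg$volume_mm3, 0)
  expect_identical(seg$extent_mm, c(0, 0, 0))
})

test_that("segmentation is invariant under positive image scaling", {
  ph <- phantom_fixture(noise_sd = 1, seed = 4)
  sp <- rep(2e-3, 3)
  s1 <- segment_signal_void(ph$image, ph$noise_region, ph$phantom_mask, sp)
  s2 <- segment_signal_void(ph$image * 7.3, ph$noise_region, ph$phantom_mask, sp)
  expect_identical(s1$mask, s2$mask)
  expect_identical(s1$volume_mm3, s2$volume_mm3)
})

test_that("a voxel at exactly 125% of the noise mean is excluded", {
  img <- array(100, c(5, 5, 5))
  noise <- array(FALSE, c(5, 5, 5)); noise[, , 1] <- TRUE
  img[, , 1] <- 10
  phantom <- !noise
  img[3, 3, 3] <- 12.5             # exactly the threshold
  img[2, 3, 3] <- 12.4999          # just below
  seg <- segment_signal_void(img, noise, phantom, rep(1e-3, 3))
  expect_false(seg$mask[3, 3, 3])
  expect_true(seg$mask[2, 3, 3])
})

test_that("growing the phantom mask never shrinks the candidate set", {
  ph <- phantom_fixture(noise_sd = 2, seed = 9)
  sp <- rep(2e-3, 3)
  threshold <- 1.25 * mean(ph$image[ph$noise_region])
  small <- ph$phantom_mask
  big <- array(TRUE, dim(small))
  cand_small <- (ph$image < threshold) & small
  cand_big <- (ph$image < threshold) & big
  expect_true(all(cand_big[cand_small]))
})

test_that("a seed point selects the matching component in a two-void image", {
  img <- array(100, c(20, 20, 8))
  noise <- array(FALSE, c(20, 20, 8)); noise[1:2, 1:2, ] <- TRUE
  img[noise] <- 10
  phantom <- !noise
  img[5:7, 5:7, 4] <- 5      # void A: 9 voxels
  img[14:15, 14:15, 4] <- 5  # void B: 4 voxels
  sp <- rep(1e-3, 3)
  seg_default <- segment_signal_void(img, noise, phantom, sp)
  expect_identical(seg_default$n_voxels, 9L)
  seg_b <- segment_signal_void(img, noise, phantom, sp,
                               seed_point = c(14, 14, 4))
  expect_identical(seg_b$n_voxels, 4L)
})

test_that("artifact_extent counts voxels per line, with a bounding-box variant", {
  m <- array(FALSE, c(10, 10, 10))
  m[4, 4, 4] <- TRUE
  expect_equal(artifact_extent(m, rep(0.6e-3, 3)), rep(0.6, 3))

  m2 <- array(FALSE, c(10, 10, 10))
  m2[2:6, 5, 5] <- TRUE
  expect_equal(artifact_extent(m2, rep(0.4e-3, 3)), c(2.0, 0.4, 0.4))

  # C-shape: line count differs from the bounding box along y
  m3 <- array(FALSE, c(10, 10, 3))
  m3[2:6, 2, 2] <- TRUE; m3[2:6, 6, 2] <- TRUE; m3[2, 2:6, 2] <- TRUE
  lc <- artifact_extent(m3, rep(1e-3, 3))
  bb <- artifact_extent(m3, rep(1e-3, 3), mode = "bounding_box")
  expect_equal(lc[1], 5)
  expect_equal(bb[1], 5)
  expect_equal(lc[2], 5)   # longest y line has 5 voxels
  expect_equal(bb[2], 5)
  # and an L-shape where they differ
  m4 <- array(FALSE, c(10, 10, 3))
  m4[2:4, 2, 2] <- TRUE; m4[2, 6, 2] <- TRUE
  expect_equal(artifact_extent(m4, rep(1e-3, 3))[2], 2)          # 2 voxels on line x=2
  expect_equal(artifact_extent(m4, rep(1e-3, 3), "bounding_box")[2], 5)

  expect_equal(artifact_extent(array(FALSE, c(3, 3, 3)), rep(1e-3, 3)),
               c(0, 0, 0))
})

test_that("a digitized 12 mm sphere reports ~12 mm extents", {
  g <- grid3d(31, 31, 31, 0.5e-3)
  dist2 <- outer(outer(g$x^2, g$y^2, `+`), g$z^2, `+`)
  m <- dist2 <= (6e-3)^2
  ext <- artifact_extent(m, rep(0.5e-3, 3))
  expect_true(all(abs(ext - 12) <= 0.5 + 1e-9))
})

test_that("segmentation volume equals brute-force count times voxel volume", {
  ph <- phantom_fixture(noise_sd = 1, seed = 2)
  sp <- rep(2e-3, 3)
  seg <- segment_signal_void(ph$image, ph$noise_region, ph$phantom_mask, sp)
  expect_equal(seg$volume_mm3, sum(seg$mask) * prod(sp) * 1e9,
               tolerance = 1e-12)
  expect_identical(seg$n_voxels, sum(seg$mask))
})
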