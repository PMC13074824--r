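make_vol <- function(arr, spacing = c(0.5e-3, 0.5e-3, 0.5e-3))
  pressure_volume(arr, spacing = spacing)

test_that("rmsd_volumes matches a brute-force loop and behaves linearly", {
  set.seed(11)
  a <- array(abs(rnorm(4 * 5 * 3)), c(4, 5, 3))
  b <- array(abs(rnorm(4 * 5 * 3)), c(4, 5, 3))
  va <- make_vol(a); vb <- make_vol(b)
  # brute-force voxel loop
  acc <- 0
  for (i in 1:4) for (j in 1:5) for (k in 1:3)
    acc <- acc + (a[i, j, k] - b[i, j, k])^2
  expect_equal(rmsd_volumes(va, vb), sqrt(acc / 60) / max(b), tolerance = 1e-12)

  expect_identical(rmsd_volumes(va, va), 0)
  v11 <- make_vol(1.1 * a)
  expect_equal(rmsd_volumes(v11, va), 0.1 * sqrt(mean(a^2)) / max(a),
               tolerance = 1e-12)

  # swapping arguments changes only the denominator
  r_ab <- rmsd_volumes(va, vb)
  r_ba <- rmsd_volumes(vb, va)
  expect_equal(r_ab * max(b), r_ba * max(a), tolerance = 1e-12)
  expect_equal(rmsd_volumes(va, vb, normalization = "joint_peak"),
               rmsd_volumes(vb, va, normalization = "joint_peak"),
               tolerance = 1e-15)
  expect_error(rmsd_volumes(va, make_vol(a[, , 1:2])), "different grids")
})

test_that("largest_contiguous_region keeps the biggest blob only", {
  arr <- array(0, c(12, 10, 8))
  arr[2:3, 2:3, 2] <- 1          # 8 voxels... (2x2x1 = 4)
  arr[2:3, 2:3, 2:3] <- 1        # blob A: 8 voxels
  arr[8:11, 8, 6] <- 1           # blob B: 4 voxels
  sp <- c(1e-3, 1e-3, 1e-3)
  reg <- largest_contiguous_region(arr, 0.5, sp)
  expect_identical(reg$n_voxels, 8L)
  expect_equal(reg$volume, 8e-9)
  expect_true(all(which(reg$mask) %in% which(arr > 0.5)))

  none <- largest_contiguous_region(arr, 2, sp)
  expect_identical(none$volume, 0)
  expect_false(any(none$mask))
})

test_that("two disjoint supra-threshold blobs of 10 and 7 voxels keep exactly 10", {
  arr <- array(0, c(10, 10, 6))
  arr[1:10, 1, 1] <- 1    # 10-voxel line
  arr[1:7, 5, 4] <- 1     # 7-voxel line
  reg <- largest_contiguous_region(arr, 0.5, c(1e-3, 1e-3, 1e-3))
  expect_identical(reg$n_voxels, 10L)
})

test_that("contiguous labelling agrees with a flood-fill oracle on random fields", {
  for (seed in 1:5) {
    set.seed(seed)
    mask <- array(runif(17 * 15 * 13) < 0.25, c(17, 15, 13))
    for (conn in c(6, 26)) {
      lab <- fusmark:::label_components(mask, conn)
      oracle <- flood_fill_oracle(mask, conn)
      # same partition: component count and size multiset
      expect_identical(max(lab), max(oracle))
      expect_identical(sort(tabulate(lab[lab > 0])),
                       sort(tabulate(oracle[oracle > 0])))
      reg <- largest_contiguous_region(mask * 1, 0.5, c(1e-3, 1e-3, 1e-3),
                                       connectivity = conn)
      expect_identical(reg$n_voxels, largest_component_oracle(mask, conn))
    }
  }
})

test_that("a digitized sphere's contiguous volume matches 4/3 pi r^3", {
  g <- grid3d(21, 21, 21, 0.5e-3)
  dist2 <- outer(outer(g$x^2, g$y^2, `+`), g$z^2, `+`)
  arr <- 1 * (dist2 <= (4e-3)^2)
  reg <- largest_contiguous_region(arr, 0.5, c(g$dx, g$dy, g$dz))
  true_vol <- 4 / 3 * pi * (4e-3)^3
  expect_lt(abs(reg$volume - true_vol) / true_vol, 0.05)
})

test_that("focus_metrics of a control against itself is the zero element", {
  g <- grid3d(15, 15, 21, 0.5e-3)
  vol <- make_vol(gaussian_field(g, c(1e-3, 1e-3, 3e-3)))
  fm <- focus_metrics(vol, vol)
  expect_identical(fm$peak_change, 0)
  expect_identical(fm$focus_volume_change, 0)
  expect_identical(fm$displacement_total, 0)
  expect_identical(fm$insertion_loss_db, 0)
})

test_that("a one-voxel shift reads as a pure displacement", {
  g <- grid3d(15, 15, 21, 0.5e-3)
  control <- gaussian_field(g, c(1e-3, 1e-3, 3e-3))
  shifted <- gaussian_field(g, c(1e-3, 1e-3, 3e-3),
                            center = c(0.5e-3, 0, 0))
  fm <- focus_metrics(make_vol(shifted), make_vol(control))
  expect_equal(fm$displacement_vector, c(0.5e-3, 0, 0), tolerance = 1e-12)
  expect_equal(fm$displacement_total, 0.5e-3, tolerance = 1e-12)
  expect_lt(abs(fm$peak_change), 1e-9)
})

test_that("the half-maximum focus volume of a separable Gaussian matches the closed form", {
  g <- grid3d(33, 33, 121, 0.25e-3)
  sig <- c(1e-3, 1e-3, 4e-3)
  vol <- make_vol(gaussian_field(g, sig), spacing = rep(0.25e-3, 3))
  fm <- focus_metrics(vol, vol)
  true_vol <- 4 * pi / 3 * prod(sig * sqrt(2 * log(2)))
  expect_lt(abs(fm$focus_volume - true_vol) / true_vol, 0.03)
})

test_that("insertion loss has a plane-peak variant", {
  g <- grid3d(11, 11, 15, 0.5e-3)
  control <- gaussian_field(g, c(1e-3, 1e-3, 2e-3))
  test <- 0.5 * control
  fm_v <- focus_metrics(make_vol(test), make_vol(control))
  expect_equal(fm_v$insertion_loss_db, -20 * log10(0.5), tolerance = 1e-9)
  fm_p <- focus_metrics(make_vol(test), make_vol(control),
                        insertion_loss_mode = "plane")
  expect_equal(fm_p$insertion_loss_db, -20 * log10(0.5), tolerance = 1e-9)
})

test_that("tidy.focus_metrics returns the expected one-row tibble", {
  g <- grid3d(11, 11, 11, 0.5e-3)
  vol <- make_vol(gaussian_field(g, c(1e-3, 1e-3, 1e-3)))
  td <- tidy(focus_metrics(vol, vol))
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 1L)
  expect_true(all(c("peak_change", "focus_volume_mm3", "displacement_mm",
                    "insertion_loss_db") %in% names(td)))
})
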