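test_that("slice_area arithmetic is exact", {
  expect_equal(slice_area(matrix(TRUE, 100, 100), 0.1), 1.00)
  expect_equal(slice_area(matrix(FALSE, 50, 50), 0.1), 0)
  half <- matrix(FALSE, 200, 200); half[1:100, ] <- TRUE
  expect_equal(slice_area(half, 0.05), 0.50)
  expect_error(slice_area(matrix(0.5, 2, 2), 0.1), "binary")
})

two_slice_stack <- function(t_sd = 0, a_sd = 0) {
  mask <- matrix(TRUE, 100, 100)   # 1 cm^2 at 0.1 mm/px
  structure(list(
    slices = tibble::tibble(
      slice = 1:2, thickness_mm = 1.5, thickness_sd_mm = t_sd,
      area_sd_cm2 = a_sd, mask = list(mask, mask)),
    pixel_scale_mm = 0.1, true_volume_cm3 = NA_real_,
    semi_axes_mm = NULL, seed = NA_integer_), class = "slice_stack")
}

test_that("two 1 cm^2 slices at exactly 1.5 mm give 0.300 cm^3 +/- 0", {
  est <- ablated_volume(two_slice_stack())
  expect_equal(est$volume_cm3, 0.300, tolerance = 1e-12)
  expect_identical(est$uncertainty_cm3, 0)
})

test_that("all-zero areas give 0 +/- 0, and volume ignores empty slices", {
  empty <- two_slice_stack()
  empty$slices$mask <- list(matrix(FALSE, 10, 10), matrix(FALSE, 10, 10))
  est <- ablated_volume(empty)
  expect_identical(est$volume_cm3, 0)
  expect_identical(est$uncertainty_cm3, 0)
})

test_that("volume and uncertainty are invariant under slice reordering", {
  st <- simulate_slice_stack(seed = 21)
  est <- ablated_volume(st)
  perm <- rev(seq_len(nrow(st$slices)))
  st2 <- st; st2$slices <- st$slices[perm, ]
  est2 <- ablated_volume(st2)
  expect_equal(est2$volume_cm3, est$volume_cm3, tolerance = 1e-12)
  expect_equal(est2$uncertainty_cm3, est$uncertainty_cm3, tolerance = 1e-12)
})

test_that("analytic combined uncertainty matches a 1e5-draw Monte Carlo", {
  set.seed(31)
  n <- 7
  A <- runif(n, 0.3, 2)          # cm^2
  t <- rnorm(n, 1.5, 0.05)       # mm
  uA <- runif(n, 0.02, 0.1)      # cm^2
  ut <- rep(0.1, n)              # mm
  masks <- lapply(A, function(a) {
    px <- round(a * 100 / 0.01)  # 0.1 mm pixels: 0.0001 cm^2 each
    m <- matrix(FALSE, 200, 200); m[seq_len(px)] <- TRUE; m
  })
  st <- structure(list(
    slices = tibble::tibble(slice = 1:n, thickness_mm = t,
                            thickness_sd_mm = ut, area_sd_cm2 = uA,
                            mask = masks),
    pixel_scale_mm = 0.1, true_volume_cm3 = NA_real_,
    semi_axes_mm = NULL, seed = NA_integer_), class = "slice_stack")
  est <- ablated_volume(st)
  A_real <- vapply(masks, slice_area, numeric(1), pixel_scale = 0.1)
  mc <- mc_volume_sd(A_real, t, uA, ut, n = 1e5)
  expect_lt(abs(est$uncertainty_cm3 - mc) / mc, 0.05)
})

test_that("a noiseless 5 mm sphere stack integrates to 4/3 pi r^3 within 5%", {
  st <- simulate_slice_stack(semi_axes = c(5, 5, 5), slice_thickness_sd = 0,
                             area_noise_fraction = 0, pixel_scale = 0.05,
                             seed = 1)
  est <- ablated_volume(st)
  v_true <- 4 / 3 * pi * 125 / 1000
  expect_lt(abs(est$volume_cm3 - v_true) / v_true, 0.05)
  expect_equal(st$true_volume_cm3, v_true, tolerance = 1e-12)
})

test_that("an ellipsoid outside the sliced range yields empty masks", {
  st <- simulate_slice_stack(semi_axes = c(5, 5, 5), n_slices = 4,
                             center_depth = 50, seed = 2)
  areas <- vapply(st$slices$mask, slice_area, numeric(1),
                  pixel_scale = st$pixel_scale_mm)
  expect_true(all(areas == 0))
})

test_that("slice stacks are reproducible under a fixed seed", {
  a <- simulate_slice_stack(seed = 5)
  b <- simulate_slice_stack(seed = 5)
  c <- simulate_slice_stack(seed = 6)
  expect_identical(a$slices$thickness_mm, b$slices$thickness_mm)
  expect_identical(a$slices$mask, b$slices$mask)
  expect_false(identical(a$slices$thickness_mm, c$slices$thickness_mm))
})

test_that("estimates cover the true ellipsoid volume within 2 u(V) in >= 90% of replicates", {
  hits <- vapply(1:200, function(r) {
    st <- simulate_slice_stack(semi_axes = c(5, 5, 5), pixel_scale = 0.2,
                               seed = 3000 + r)
    est <- ablated_volume(st)
    abs(est$volume_cm3 - st$true_volume_cm3) < 2 * est$uncertainty_cm3
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("tidy and glance expose the estimate as tibbles", {
  est <- ablated_volume(two_slice_stack())
  expect_equal(tidy(est)$volume_cm3, 0.3, tolerance = 1e-12)
  g <- glance(est)
  expect_identical(g$n_slices, 2L)
  expect_identical(g$n_ablated_slices, 2L)
})
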