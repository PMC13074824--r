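# Independent oracles used by the tests.  These deliberately avoid the
# package's own code paths: closed forms, brute-force loops and
# Monte-Carlo draws.

# O'Neil closed-form on-axis pressure of a focused bowl, in units of
# rho*c*u0, with z the signed axial distance from the centre of
# curvature (positive away from the source).  Derived by reducing the
# Rayleigh integral over the spherical cap to a line integral in R.
oneil_axial <- function(geom, z) {
  F <- geom$focal_length
  a <- geom$aperture_diameter / 2
  k <- 2 * pi * geom$frequency / geom$sound_speed
  if (abs(z) < 1e-12) {
    h <- F - sqrt(F^2 - a^2)
    return(complex(modulus = k * h, argument = k * F - pi / 2))
  }
  theta_max <- asin(a / F)
  R1 <- sqrt(F^2 + z^2 + 2 * F * z * cos(theta_max))
  (F / z) * (exp(1i * k * (F + z)) - exp(1i * k * R1))
}

# closed-form focal amplitude k * h (bowl depth h)
oneil_focal <- function(geom) {
  F <- geom$focal_length
  a <- geom$aperture_diameter / 2
  k <- 2 * pi * geom$frequency / geom$sound_speed
  k * (F - sqrt(F^2 - a^2))
}

# scalar depth-first flood fill, one voxel at a time
flood_fill_oracle <- function(mask, connectivity = 6) {
  d <- dim(mask)
  steps <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  steps <- steps[rowSums(abs(steps)) > 0, , drop = FALSE]
  if (connectivity == 6) steps <- steps[rowSums(abs(steps)) == 1, , drop = FALSE]
  lab <- array(0L, d)
  cur <- 0L
  for (v in which(mask)) {
    if (lab[v] > 0L) next
    cur <- cur + 1L
    stack <- v
    lab[v] <- cur
    while (length(stack)) {
      u <- stack[length(stack)]
      stack <- stack[-length(stack)]
      co <- arrayInd(u, d)
      for (s in seq_len(nrow(steps))) {
        nb <- co + steps[s, ]
        if (all(nb >= 1L) && all(nb <= d)) {
          li <- nb[1] + (nb[2] - 1L) * d[1] + (nb[3] - 1L) * d[1] * d[2]
          if (mask[li] && lab[li] == 0L) {
            lab[li] <- cur
            stack <- c(stack, li)
          }
        }
      }
    }
  }
  lab
}

# size of the largest flood-fill component
largest_component_oracle <- function(mask, connectivity = 6) {
  lab <- flood_fill_oracle(mask, connectivity)
  if (!any(lab > 0L)) return(0L)
  max(tabulate(lab[lab > 0L]))
}

# Monte-Carlo propagation of slice-stack uncertainty: sd over draws of
# sum(A_i * t_i) with independent normal components
mc_volume_sd <- function(A_cm2, t_mm, uA_cm2, ut_mm, n = 1e5, seed = 42) {
  set.seed(seed)
  tot <- numeric(n)
  for (i in seq_along(A_cm2)) {
    Ai <- rnorm(n, A_cm2[i], uA_cm2[i])
    ti <- rnorm(n, t_mm[i], ut_mm[i]) / 10   # mm -> cm
    tot <- tot + Ai * ti
  }
  sd(tot)
}

# separable 3D Gaussian magnitude field on a grid3d
gaussian_field <- function(grid, sigma, amplitude = 1, center = c(0, 0, 0)) {
  gx <- exp(-(grid$x - center[1])^2 / (2 * sigma[1]^2))
  gy <- exp(-(grid$y - center[2])^2 / (2 * sigma[2]^2))
  gz <- exp(-(grid$z - center[3])^2 / (2 * sigma[3]^2))
  amplitude * outer(outer(gx, gy), gz)
}
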