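# parametric test meshes with outward-oriented faces

cylinder_mesh <- function(r, len, nth = 48, nz = 40) {
  th <- seq(0, 2 * pi, length.out = nth + 1)[-(nth + 1)]
  zs <- seq(0, len, length.out = nz)
  V <- cbind(rep(r * cos(th), nz), rep(r * sin(th), nz), rep(zs, each = nth))
  F <- matrix(0L, 2 * nth * (nz - 1), 3)
  row <- 1L
  for (k in 1:(nz - 1)) for (i in 1:nth) {
    i2 <- i %% nth + 1
    a <- (k - 1) * nth + i; b <- (k - 1) * nth + i2
    cc <- k * nth + i; d <- k * nth + i2
    F[row, ] <- c(a, b, d); F[row + 1L, ] <- c(a, d, cc)
    row <- row + 2L
  }
  trimesh(V, F)
}

sphere_mesh <- function(R, n = 40) {
  th <- seq(0.12, pi - 0.12, length.out = n)
  ph <- seq(0, 2 * pi, length.out = 2 * n + 1)[-(2 * n + 1)]
  V <- cbind(R * rep(sin(th), each = 2 * n) * cos(ph),
             R * rep(sin(th), each = 2 * n) * sin(ph),
             R * rep(cos(th), each = 2 * n))
  F <- matrix(0L, 2 * 2 * n * (n - 1), 3)
  row <- 1L
  for (k in 1:(n - 1)) for (i in 1:(2 * n)) {
    i2 <- i %% (2 * n) + 1
    a <- (k - 1) * 2 * n + i; b <- (k - 1) * 2 * n + i2
    cc <- k * 2 * n + i; d <- k * 2 * n + i2
    F[row, ] <- c(a, d, b); F[row + 1L, ] <- c(a, cc, d)
    row <- row + 2L
  }
  trimesh(V, F)
}

plane_mesh <- function(n = 20) {
  gs <- expand.grid(x = 0:n, y = 0:n)
  V <- cbind(gs$x, gs$y, 0)
  F <- matrix(0L, 2 * n * n, 3)
  row <- 1L
  for (j in 0:(n - 1)) for (i in 0:(n - 1)) {
    a <- j * (n + 1) + i + 1; b <- a + 1; cc <- a + n + 1; d <- cc + 1
    F[row, ] <- c(a, b, d); F[row + 1L, ] <- c(a, d, cc)
    row <- row + 2L
  }
  trimesh(V, F)
}

# voxelized unit-radius sphere on an isotropic grid
sphere_volume <- function(R = 1, voxel = 0.02, pad = 0.2) {
  half <- R + pad
  n <- ceiling(2 * half / voxel)
  cs <- (seq_len(n) - 0.5) * voxel - half
  gx <- array(cs, c(n, n, n))
  gy <- aperm(gx, c(2, 1, 3))
  gz <- aperm(gx, c(3, 2, 1))
  voxel_volume(sqrt(gx^2 + gy^2 + gz^2) <= R, voxel, rep(-half, 3))
}
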