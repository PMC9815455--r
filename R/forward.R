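# Spherical-head forward model and planar-gradiometer sensor geometry.
#
# Head frame: x to the right, y anterior, z up, origin at the centre of the
# conducting sphere (metres).  The sensor array is a mirror-symmetric
# arrangement of sites on a spherical cap, each site carrying two orthogonal
# planar gradiometers (a "latitudinal" one along the polar tangent and an
# "azimuthal" one along the ring direction).  Azimuthal tangents follow a
# single global handedness, so a left-right antisymmetric source produces
# sign-antisymmetric azimuthal-gradiometer weights.

MU0_4PI <- 1e-7

#' Planar-gradiometer sensor layout on a spherical cap
#'
#' Builds a mirror-symmetric (about the sagittal plane x = 0) arrangement of
#' `n_sites` sensor sites in rings of constant polar angle, with two
#' orthogonal planar gradiometers per site.  This is a geometric stand-in
#' for a 102-site whole-head gradiometer helmet; the exact commercial
#' geometry is not reproduced.
#'
#' @param n_sites Number of sensor sites (must be even, >= 6); each site
#'   carries 2 channels. Default 102.
#' @param shell_radius Radius of the sensor shell (m).
#' @param conductor_radius Radius of the homogeneous conducting sphere (m).
#' @param baseline Planar-gradiometer baseline (m), the coil-centre
#'   separation used in the finite-difference response.
#' @return An object of class `sensor_layout`: list with site positions
#'   (`pos`, n x 3), radial normals (`normal`), the two tangential
#'   gradiometer orientations (`e_lat`, `e_azi`), channel bookkeeping and
#'   geometry scalars.
#' @export
sensor_layout <- function(n_sites = 102, shell_radius = 0.102,
                          conductor_radius = 0.095, baseline = 0.0168) {
  if (n_sites < 6 || n_sites %% 2 != 0)
    stop("n_sites must be an even number >= 6")
  n_rings <- max(2L, round(n_sites / 20))
  theta <- seq(20, 106, length.out = n_rings) * pi / 180
  w <- sin(theta)
  counts <- 2L * pmax(1L, round(n_sites * w / sum(w) / 2))
  # fix the total in steps of 2 so every ring keeps an even count
  i <- which.max(counts)
  while (sum(counts) != n_sites) {
    d <- n_sites - sum(counts)
    j <- if (d > 0) which.max(theta * (counts > 0)) else which.max(counts)
    counts[j] <- counts[j] + 2L * sign(d)
    if (counts[j] < 2L) counts[j] <- 2L
  }
  pos <- normal <- e_lat <- e_azi <- matrix(0, n_sites, 3)
  k <- 0L
  for (r in seq_len(n_rings)) {
    n_az <- counts[r]
    # half-offset azimuths: the set {+-(k-1/2) dphi} is mirror symmetric
    # about x = 0 and places no site on the midline
    phi <- ((seq_len(n_az) - 0.5) * 2 * pi / n_az) - pi
    st <- sin(theta[r]); ct <- cos(theta[r])
    for (p in phi) {
      k <- k + 1L
      d <- c(st * sin(p), st * cos(p), ct)
      pos[k, ] <- shell_radius * d
      normal[k, ] <- d
      e_lat[k, ] <- c(ct * sin(p), ct * cos(p), -st)
      e_azi[k, ] <- c(-cos(p), sin(p), 0)
    }
  }
  ch_site <- rep(seq_len(n_sites), each = 2L)
  ch_ori <- rep(c(1L, 2L), n_sites)
  structure(list(pos = pos, normal = normal, e_lat = e_lat, e_azi = e_azi,
                 shell_radius = shell_radius,
                 conductor_radius = conductor_radius, baseline = baseline,
                 n_sites = n_sites,
                 channel_names = sprintf("MEG%03d_%d", ch_site, ch_ori),
                 channel_site = ch_site, channel_ori = ch_ori),
            class = "sensor_layout")
}

#' @export
print.sensor_layout <- function(x, ...) {
  cat(sprintf("<sensor_layout> %d sites / %d planar gradiometers, shell %.3f m\n",
              x$n_sites, 2 * x$n_sites, x$shell_radius))
  invisible(x)
}

# Magnetic field of a current dipole in a homogeneous conducting sphere
# (closed form; the external field is independent of the conductivity
# profile).  `r` is an n x 3 matrix of field points, `r0`/`q` the dipole
# position and moment.  Returns an n x 3 matrix of B (tesla).
sphere_dipole_field <- function(r, r0, q) {
  if (is.null(dim(r))) r <- matrix(r, ncol = 3)
  a_vec <- sweep(r, 2, r0)                      # r - r0
  a <- sqrt(rowSums(a_vec^2))
  rn <- sqrt(rowSums(r^2))
  r0r <- as.numeric(r %*% r0)
  ar <- rowSums(a_vec * r)
  f_ <- a * (rn * a + rn^2 - r0r)
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  c1 <- a^2 / rn + ar / a + 2 * a + 2 * rn
  c2 <- a + 2 * rn + ar / a
  gradf <- r * c1 - matrix(r0, nrow(r), 3, byrow = TRUE) * c2
  qr <- as.numeric(r %*% qxr0)
  B <- (matrix(qxr0, nrow(r), 3, byrow = TRUE) * f_ - gradf * qr) /
    (4 * pi * f_^2) * (4 * pi * MU0_4PI)
  B[!is.finite(B)] <- 0
  B
}

#' Planar-gradiometer leadfield of a current dipole in a sphere
#'
#' Computes the response of every gradiometer channel to a current dipole
#' inside the conducting sphere, using the closed-form dipole-in-sphere
#' field.  The planar-gradiometer response is the finite difference of the
#' radial field component at the two coil centres of a pair, divided by the
#' baseline.  A radially oriented dipole (or one at the sphere centre)
#' yields a zero vector by spherical symmetry; this is returned, not an
#' error.
#'
#' @param dipole_pos Length-3 position (m), must lie inside the sphere.
#' @param dipole_moment Length-3 moment (A m).
#' @param sensors A [sensor_layout()].
#' @return Numeric vector of length `2 * n_sites` (T/m), ordered as
#'   `sensors$channel_names`.
#' @export
leadfield_sphere <- function(dipole_pos, dipole_moment, sensors) {
  if (sqrt(sum(dipole_pos^2)) >= sensors$conductor_radius)
    stop("dipole must lie inside the conducting sphere")
  b2 <- sensors$baseline / 2
  # 4 evaluation points per site: +-b/2 along each tangential orientation
  pts <- rbind(sensors$pos + b2 * sensors$e_lat,
               sensors$pos - b2 * sensors$e_lat,
               sensors$pos + b2 * sensors$e_azi,
               sensors$pos - b2 * sensors$e_azi)
  B <- sphere_dipole_field(pts, dipole_pos, dipole_moment)
  n <- sensors$n_sites
  bn <- rowSums(B * rbind(sensors$normal, sensors$normal,
                          sensors$normal, sensors$normal))
  g_lat <- (bn[1:n] - bn[(n + 1):(2 * n)]) / sensors$baseline
  g_azi <- (bn[(2 * n + 1):(3 * n)] - bn[(3 * n + 1):(4 * n)]) /
    sensors$baseline
  out <- numeric(2 * n)
  out[sensors$channel_ori == 1L] <- g_lat
  out[sensors$channel_ori == 2L] <- g_azi
  out
}

#' Orthonormal tangential basis at a point
#'
#' Two unit vectors perpendicular to the radial direction at `p` (the
#' orientation subspace visible to MEG in a spherical conductor); for `p`
#' at the origin an arbitrary basis is returned.
#'
#' @param p Length-3 position.
#' @return 2 x 3 matrix of basis row vectors.
#' @export
tangential_basis <- function(p) {
  r <- sqrt(sum(p^2))
  if (r < 1e-12) return(rbind(c(1, 0, 0), c(0, 1, 0)))
  n <- p / r
  ref <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- ref - sum(ref * n) * n
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(n[2] * t1[3] - n[3] * t1[2],
          n[3] * t1[1] - n[1] * t1[3],
          n[1] * t1[2] - n[2] * t1[1])
  rbind(t1, t2)
}

#' Default eye positions
#'
#' Two fixed points just inside the anterior-inferior wall of the
#' conducting sphere, mirrored about the midline; these carry the
#' corneo-retinal dipoles of the simulated eyes and anchor the eye region
#' used in component localization.
#'
#' @param sensors A [sensor_layout()] (unused except for future geometry
#'   coupling; kept for interface stability).
#' @return 2 x 3 matrix (left eye, right eye).
#' @export
eye_positions <- function(sensors = NULL) {
  rbind(left = c(-0.031, 0.082, -0.020),
        right = c(0.031, 0.082, -0.020))
}

#' Volumetric source grid with leadfields
#'
#' A cubic lattice of grid points inside the head sphere plus denser point
#' clusters around the two eye positions (so ocular sources are
#' localizable), with a `channels x 3` leadfield matrix per point computed
#' from the spherical forward model.
#'
#' @param sensors A [sensor_layout()].
#' @param spacing Brain-grid spacing (m). Default 0.007 (7 mm).
#' @param radius Brain-grid radius (m).
#' @param eye_pos 2 x 3 eye positions; default [eye_positions()].
#' @param eye_spacing,eye_radius Spacing and radius (m) of the eye-cluster
#'   lattices.
#' @return Object of class `forward_grid`: `points` (n x 3), `spacing`,
#'   `leadfield` (array channels x 3 x n), `in_eye_region` (logical),
#'   `eye_pos`, `sensors`.
#' @export
make_forward_grid <- function(sensors, spacing = 0.007, radius = 0.082,
                              eye_pos = eye_positions(),
                              eye_spacing = 0.003, eye_radius = 0.014) {
  ax <- seq(-radius, radius, by = spacing)
  pts <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  pts <- pts[rowSums(pts^2) < radius^2, , drop = FALSE]
  eye_pts <- NULL
  for (e in seq_len(nrow(eye_pos))) {
    axe <- seq(-eye_radius, eye_radius, by = eye_spacing)
    g <- as.matrix(expand.grid(x = axe, y = axe, z = axe))
    g <- g[rowSums(g^2) < eye_radius^2, , drop = FALSE]
    g <- sweep(g, 2, eye_pos[e, ], "+")
    g <- g[rowSums(g^2) < (0.99 * sensors$conductor_radius)^2, , drop = FALSE]
    eye_pts <- rbind(eye_pts, g)
  }
  all_pts <- rbind(pts, eye_pts)
  dimnames(all_pts) <- NULL
  n <- nrow(all_pts)
  m <- 2 * sensors$n_sites
  lf <- array(0, dim = c(m, 3, n))
  for (i in seq_len(n)) {
    p <- all_pts[i, ]
    for (d in 1:3) {
      q <- c(0, 0, 0); q[d] <- 1
      lf[, d, i] <- leadfield_sphere(p, q, sensors)
    }
  }
  d_eye <- pmin(sqrt(rowSums(sweep(all_pts, 2, eye_pos[1, ])^2)),
                sqrt(rowSums(sweep(all_pts, 2, eye_pos[2, ])^2)))
  # precomputed centered tangential leadfields (m x 2n) and inverse 2x2
  # Grams: turns topography localization into a single matrix product
  tanl <- matrix(0, m, 2L * n)
  binv <- array(0, dim = c(2, 2, n))
  for (i in seq_len(n)) {
    tb <- tangential_basis(all_pts[i, ])
    L2 <- lf[, , i] %*% t(tb)
    M <- sweep(L2, 2, colMeans(L2))
    tanl[, (2 * i - 1):(2 * i)] <- M
    binv[, , i] <- solve(crossprod(M) + diag(1e-30, 2))
  }
  structure(list(points = all_pts, spacing = spacing, leadfield = lf,
                 in_eye_region = d_eye <= 0.02, eye_pos = eye_pos,
                 sensors = sensors, tan_leadfield = tanl,
                 gram_inv = binv),
            class = "forward_grid")
}

#' @export
print.forward_grid <- function(x, ...) {
  cat(sprintf("<forward_grid> %d points (%.0f mm spacing), %d in eye region\n",
              nrow(x$points), 1000 * x$spacing, sum(x$in_eye_region)))
  invisible(x)
}
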