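# Shared fixture builders. Everything is generated in code at test time.

# Planar rectangular grid in the z = 0 plane, triangulated with a uniform
# diagonal split. Interior vertices of this mesh are symmetric, so the
# face-to-vertex transfer in tangential_gradient() is exact for linear
# fields there.
planar_grid_mesh <- function(nx = 10L, ny = 10L, lx = 1, ly = 1,
                             region = "dome") {
  xs <- seq(0, lx, length.out = nx + 1L)
  ys <- seq(0, ly, length.out = ny + 1L)
  verts <- as.matrix(expand.grid(x = xs, y = ys, z = 0))
  vid <- function(i, j) (j - 1L) * (nx + 1L) + i
  tris <- matrix(integer(0), ncol = 3L)
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      a <- vid(i, j); b <- vid(i + 1L, j)
      c_ <- vid(i, j + 1L); d <- vid(i + 1L, j + 1L)
      tris <- rbind(tris, c(a, b, d), c(a, d, c_))
    }
  }
  surface_mesh(verts, tris, region = rep(region, nrow(tris)))
}

# Faces of a planar grid mesh whose three vertices are all interior
# (needed where the cell-to-point transfer must be exact).
interior_faces <- function(mesh, lx = 1, ly = 1, tol = 1e-12) {
  v <- mesh$vertices
  interior_v <- v[, 1] > tol & v[, 1] < lx - tol &
    v[, 2] > tol & v[, 2] < ly - tol
  apply(mesh$triangles, 1L, function(tr) all(interior_v[tr]))
}

# Single-face mesh for per-face time-series descriptor tests.
one_face_mesh <- function(region = "dome") {
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
               rbind(c(1L, 2L, 3L)), region = region)
}

# Random in-plane (z = 0) WSS series on nf faces: vectors tangent to the
# planar grid by construction.
random_planar_series <- function(nf, nt = 5L, period = 0.8, seed = 1L) {
  set.seed(seed)
  times <- (seq_len(nt) - 1L) * period / nt
  wss <- array(0, dim = c(nf, 3L, nt))
  wss[, 1L, ] <- matrix(rnorm(nf * nt), nf, nt)
  wss[, 2L, ] <- matrix(rnorm(nf * nt), nf, nt)
  wss_time_series(times, wss, period = period)
}

# Independent dense-quadrature cycle average of the periodic piecewise
# linear interpolant of per-sample values `y` at sample times `times`:
# each inter-sample interval is integrated on its own fine trapezoid grid
# (exact for a linear segment), including the wrap-around segment.
dense_cycle_average <- function(y, times, period, n_sub = 64L) {
  nt <- length(times)
  knots_t <- c(times, times[1L] + period)
  knots_y <- c(y, y[1L])
  total <- 0
  for (k in seq_len(nt)) {
    tt <- seq(knots_t[k], knots_t[k + 1L], length.out = n_sub)
    yy <- knots_y[k] + (knots_y[k + 1L] - knots_y[k]) *
      (tt - knots_t[k]) / (knots_t[k + 1L] - knots_t[k])
    total <- total + sum(diff(tt) * (yy[-1L] + yy[-length(yy)]) / 2)
  }
  total / period
}

# Brute-force AUC by exhaustive pair enumeration with ties counted 1/2.
brute_force_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Conditional log-likelihood of a single-covariate matched-pair model.
cond_loglik_1d <- function(beta, d) sum(plogis(beta * d, log.p = TRUE))
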