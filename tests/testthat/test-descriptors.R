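make_series_1face <- function(vecs, period = 1) {
  nt <- nrow(vecs)
  times <- (seq_len(nt) - 1L) * period / nt
  wss <- array(0, dim = c(1L, 3L, nt))
  for (k in seq_len(nt)) wss[1L, , k] <- vecs[k, ]
  wss_time_series(times, wss, period = period)
}

test_that("time-averaged WSS reproduces constants and sinusoid means", {
  s <- make_series_1face(matrix(rep(c(3, 0, 0), 10), ncol = 3,
                                byrow = TRUE))
  expect_equal(time_avg_wss(s)$values, 3, tolerance = 1e-14)

  # magnitude 2 + sin(2*pi*t/T): the cycle mean is 2, and the periodic
  # trapezoid rule hits it exactly on a uniform grid
  nt <- 64L
  t <- (seq_len(nt) - 1L) / nt
  vecs <- cbind(2 + sin(2 * pi * t), 0, 0)
  expect_equal(time_avg_wss(make_series_1face(vecs))$values, 2,
               tolerance = 1e-12)
})

test_that("time-averaged WSS matches a dense-quadrature oracle", {
  set.seed(9)
  for (rep in 1:5) {
    vecs <- matrix(rnorm(15), ncol = 3)
    s <- make_series_1face(vecs)
    mags <- sqrt(rowSums(vecs^2))
    oracle <- dense_cycle_average(mags, s$times, s$period)
    expect_equal(time_avg_wss(s)$values, oracle, tolerance = 1e-12)
  }
})

test_that("OSI is 0 for fixed direction, 0.5 for perfect reversal", {
  s <- make_series_1face(cbind(c(1, 5, 2, 4), 0, 0))
  expect_equal(osi(s)$values, 0, tolerance = 1e-14)
  s_rev <- make_series_1face(cbind(c(2, 2, -2, -2), 0, 0))
  expect_equal(osi(s_rev)$values, 0.5, tolerance = 1e-14)
})

test_that("OSI matches a direct evaluation of both cycle integrals", {
  # three samples rotating 90 degrees in the plane
  vecs <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0))
  s <- make_series_1face(vecs)
  dt <- rep(1 / 3, 3)
  # periodic trapezoid of the vector and of its magnitude, by hand
  wrap <- rbind(vecs, vecs[1L, ])
  vec_int <- colSums((wrap[1:3, ] + wrap[2:4, ]) / 2 * dt)
  mag <- sqrt(rowSums(vecs^2))
  mag_int <- sum((c(mag, mag[1L])[1:3] + c(mag, mag[1L])[2:4]) / 2 * dt)
  oracle <- 0.5 * (1 - sqrt(sum(vec_int^2)) / mag_int)
  expect_equal(osi(s)$values, oracle, tolerance = 1e-12)
})

test_that("OSI on an all-zero face is missing with a logged count", {
  wss <- array(0, dim = c(2L, 3L, 4L))
  wss[1L, 1L, ] <- 1
  s <- wss_time_series((0:3) / 4, wss, period = 1)
  o <- osi(s)
  expect_equal(o$values, c(0, NA))
  expect_equal(attr(o, "n_missing"), 1L)
})

test_that("RRT is the reciprocal mean vector magnitude", {
  s <- make_series_1face(matrix(rep(c(4, 0, 0), 6), ncol = 3,
                                byrow = TRUE))
  expect_equal(rrt(s)$values, 0.25, tolerance = 1e-14)
  # perfect reversal: infinite residence time reported missing
  s_rev <- make_series_1face(cbind(c(2, 2, -2, -2), 0, 0))
  expect_true(is.na(rrt(s_rev)$values))
  expect_equal(attr(rrt(s_rev), "n_missing"), 1L)
})

test_that("RRT dual-formula identity holds on random series", {
  set.seed(4)
  for (rep in 1:20) {
    s <- random_planar_series(nf = 10L, nt = 8L, seed = rep)
    r <- rrt(s)$values
    o <- osi(s)$values
    w <- time_avg_wss(s)$values
    ok <- !is.na(r)
    expect_true(all(abs(r[ok] * (1 - 2 * o[ok]) * w[ok] - 1) < 1e-10))
  }
})

test_that("NWSS is a self-ratio and scale invariant", {
  mesh <- planar_grid_mesh(4L, 4L)
  mesh$region[seq(1L, 32L, by = 2L)] <- "parent"
  s <- random_planar_series(nrow(mesh$triangles), nt = 6L, seed = 2)
  wss_map <- time_avg_wss(s)

  uniform <- field_map(rep(5, nrow(mesh$triangles)), "WSS")
  expect_equal(nwss(uniform, mesh)$values,
               rep(1, nrow(mesh$triangles)), tolerance = 1e-14)

  n1 <- nwss(wss_map, mesh)$values
  scaled <- s
  scaled$wss <- scaled$wss * 10
  n2 <- nwss(time_avg_wss(scaled), mesh)$values
  expect_equal(n2, n1, tolerance = 1e-12)

  # direct arithmetic: parent mean 5 Pa, dome face at 2 Pa -> 0.4
  vals <- rep(5, nrow(mesh$triangles))
  vals[mesh$region == "dome"] <- 2
  expect_equal(unique(nwss(field_map(vals, "WSS"),
                           mesh)$values[mesh$region == "dome"]),
               0.4, tolerance = 1e-14)
})

test_that("WSSG vanishes on a uniform field and is exact on linear ones", {
  mesh <- planar_grid_mesh(8L, 8L)
  nt <- 4L
  nf <- nrow(mesh$triangles)
  uniform <- array(rep(c(1, 2, 0), each = nf), dim = c(nf, 3L, nt))
  s_uniform <- wss_time_series((0:(nt - 1)) / nt, uniform, period = 1)
  g <- wssg(mesh, s_uniform)$values
  expect_equal(max(abs(g)), 0, tolerance = 1e-10)

  # tau = (a * x) e_x: dtau_p/dp = a on interior faces
  a <- 3
  lin <- array(0, dim = c(nf, 3L, nt))
  lin[, 1L, ] <- a * mesh$face_centroid[, 1L]
  s_lin <- wss_time_series((0:(nt - 1)) / nt, lin, period = 1)
  g_lin <- wssg(mesh, s_lin)$values
  inner <- interior_faces(mesh)
  expect_equal(g_lin[inner], rep(a, sum(inner)), tolerance = 1e-10)
})

test_that("WSSG converges at O(h) on a quadratic field", {
  err_for <- function(n) {
    mesh <- planar_grid_mesh(n, n)
    nf <- nrow(mesh$triangles)
    x <- mesh$face_centroid[, 1L]
    arr <- array(0, dim = c(nf, 3L, 2L))
    arr[, 1L, ] <- 1 + x^2  # strictly positive: p = e_x everywhere
    s <- wss_time_series(c(0, 0.5), arr, period = 1)
    inner <- interior_faces(mesh)
    max(abs(wssg(mesh, s)$values[inner] - abs(2 * x[inner])))
  }
  e1 <- err_for(8L)
  e2 <- err_for(16L)
  e3 <- err_for(32L)
  expect_lt(e2, e1)
  expect_lt(e3, e2)
})

test_that("CHP matches its closed form at the extremes and midway", {
  mesh <- planar_grid_mesh(1L, 1L)  # two faces, both dome
  cfg <- chp_config(0.5, 0.5)
  # face 1 at WSSmax with OSI 0 -> 0; face 2 at WSSmin with OSI 0.5 -> 1
  wss_map <- field_map(c(10, 2), "WSS")
  osi_map <- field_map(c(0, 0.5), "OSI")
  expect_equal(chp(wss_map, osi_map, mesh, cfg)$values, c(0, 1),
               tolerance = 1e-12)

  # midway face (y = -0.5), OSI = 0.1:
  # 0.5 * (1 - 0.9375^(1/4)) + 0.5 * 0.2
  mesh3 <- surface_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(2, 0, 0)),
    rbind(c(1L, 2L, 3L), c(2L, 4L, 3L), c(2L, 5L, 4L)),
    region = rep("dome", 3L))
  wss3 <- field_map(c(2, 6, 10), "WSS")
  osi3 <- field_map(c(0, 0.1, 0), "OSI")
  vals <- chp(wss3, osi3, mesh3, cfg)$values
  expect_equal(vals[2L], 0.5 * (1 - 0.9375^(1 / 4)) + 0.5 * 0.2,
               tolerance = 1e-12)
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("degenerate constant dome WSS gives WSSnorm 0.5 with a warning", {
  mesh <- planar_grid_mesh(1L, 1L)
  wss_map <- field_map(c(3, 3), "WSS")
  osi_map <- field_map(c(0, 0), "OSI")
  expect_warning(v <- chp(wss_map, osi_map, mesh)$values, "constant")
  expect_equal(v, c(0.25, 0.25))
})

test_that("LSA covers the all-below and none-below extremes", {
  mesh <- planar_grid_mesh(4L, 4L)
  mesh$region[1:16] <- "parent"
  nf <- nrow(mesh$triangles)
  at_parent <- field_map(rep(5, nf), "WSS")
  expect_equal(lsa(at_parent, mesh), 0)
  vals <- rep(5, nf)
  vals[mesh$region == "dome"] <- 0.05 * 5
  expect_equal(lsa(field_map(vals, "WSS"), mesh), 1)
})

test_that("LSA is monotone non-decreasing in the threshold fraction", {
  spec <- phantom_spec(low_shear_fraction = 0.25, mesh_resolution = 0.3)
  mesh <- make_phantom_mesh(spec)
  wss_map <- time_avg_wss(make_wss_field(mesh, spec))
  fracs <- c(0.01, 0.05, 0.1, 0.5, 1, 2)
  vals <- vapply(fracs, function(f) lsa(wss_map, mesh, f), numeric(1L))
  expect_true(all(diff(vals) >= 0))
})

test_that("dome summaries match the explicit weighted-sum oracle", {
  mesh3 <- surface_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(3, 0, 0), c(0, 3, 0)),
    rbind(c(1L, 2L, 3L), c(1L, 4L, 5L)),
    region = c("dome", "dome"))
  # unequal areas 0.5 and 4.5
  s <- summarize_field(field_map(c(1, 3), "WSS"), mesh3)
  expect_equal(s$min, 1)
  expect_equal(s$max, 3)
  expect_equal(s$mean, (0.5 * 1 + 4.5 * 3) / 5, tolerance = 1e-14)
  expect_equal(s$ratio, 3)

  const <- summarize_field(field_map(c(2, 2), "x"), mesh3)
  expect_equal(unlist(const[c("min", "max", "mean", "ratio")]),
               c(min = 2, max = 2, mean = 2, ratio = 1))

  # equal-area faces at 1 and 3: unweighted and weighted agree
  mesh_eq <- planar_grid_mesh(1L, 1L)
  s_eq <- summarize_field(field_map(c(1, 3), "x"), mesh_eq)
  expect_equal(s_eq$mean, 2)
  expect_equal(s_eq$ratio, 3)
})

test_that("descriptor scaling laws hold on a phantom", {
  spec <- phantom_spec(mesh_resolution = 0.35, low_shear_fraction = 0.2,
                       oscillatory_fraction = 0.1, seed = 8)
  mesh <- make_phantom_mesh(spec)
  s <- make_wss_field(mesh, spec)
  s10 <- s
  s10$wss <- s10$wss * 10

  d1 <- suppressWarnings(compute_descriptors(mesh, s))
  d10 <- suppressWarnings(compute_descriptors(mesh, s10))
  # scale-invariant families
  for (col in c("NWSS_mean", "OSI_mean", "CHP_mean", "LSA")) {
    expect_equal(d10[[col]], d1[[col]], tolerance = 1e-10)
  }
  # linear families
  for (col in c("WSS_mean", "WSSG_mean")) {
    expect_equal(d10[[col]], 10 * d1[[col]], tolerance = 1e-10)
  }
  # OSI range
  o <- osi(s)$values
  expect_true(all(o >= 0 & o <= 0.5, na.rm = TRUE))
})
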