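#' Specification of a synthetic aneurysm phantom
#'
#' Defines the geometry and flow conditions of a synthetic phantom: a
#' hemispherical dome seated on a cylindrical parent-vessel segment, with a
#' designed low-shear cap around the dome apex and an optional oscillatory
#' (direction-reversing) band below it. The phantom stands in for
#' patient-specific CFD output: the generator's parameters are the ground
#' truth that the descriptor layer must recover (designed
#' `low_shear_fraction` = computed LSA, `parent_wss` = parent-vessel mean
#' WSS, and so on).
#'
#' @param dome_radius dome (hemisphere) radius, mm.
#' @param vessel_radius parent vessel radius, mm.
#' @param vessel_length parent vessel segment length, mm.
#' @param mesh_resolution target triangle edge length, mm.
#' @param low_shear_fraction designed fraction of dome area whose
#'   time-averaged WSS falls below 10% of the parent mean, in `[0, 1]`.
#' @param oscillatory_fraction designed fraction of dome area whose WSS
#'   reverses direction within the cycle, in `[0, 1]`;
#'   `low_shear_fraction + oscillatory_fraction` must not exceed 1.
#' @param base_wss magnitude of the time-averaged WSS on ordinary dome
#'   faces, Pa.
#' @param parent_wss time-averaged WSS magnitude on the parent vessel, Pa.
#' @param period cardiac cycle duration T, s.
#' @param n_timesteps samples per cycle (the CFD convention of 100 steps per
#'   cycle is the default).
#' @param waveform periodic modulation of the WSS magnitude, a function of
#'   time returning positive values with cycle mean 1; default
#'   `1 + 0.5 sin(2 pi t / T)`.
#' @param jitter relative half-width of the per-face uniform magnitude
#'   jitter applied to ordinary dome faces (0 disables it).
#' @param seed integer seed controlling all randomness in the phantom.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dome_radius = 2,
                         vessel_radius = 1.5,
                         vessel_length = 8,
                         mesh_resolution = 0.15,
                         low_shear_fraction = 0.2,
                         oscillatory_fraction = 0.1,
                         base_wss = 6,
                         parent_wss = 7,
                         period = 0.8,
                         n_timesteps = 100L,
                         waveform = NULL,
                         jitter = 0.1,
                         seed = 1L) {
  stopifnot(dome_radius > 0, vessel_radius > 0, vessel_length > 0,
            mesh_resolution > 0, base_wss > 0, parent_wss > 0,
            period > 0, n_timesteps >= 2L,
            low_shear_fraction >= 0, low_shear_fraction <= 1,
            oscillatory_fraction >= 0, oscillatory_fraction <= 1,
            jitter >= 0, jitter < 1)
  if (low_shear_fraction + oscillatory_fraction > 1) {
    stop("low_shear_fraction + oscillatory_fraction must be <= 1")
  }
  if (is.null(waveform)) {
    waveform <- function(t) 1 + 0.5 * sin(2 * pi * t / period)
  }
  structure(
    list(dome_radius = dome_radius, vessel_radius = vessel_radius,
         vessel_length = vessel_length, mesh_resolution = mesh_resolution,
         low_shear_fraction = low_shear_fraction,
         oscillatory_fraction = oscillatory_fraction,
         base_wss = base_wss, parent_wss = parent_wss,
         period = period, n_timesteps = as.integer(n_timesteps),
         waveform = waveform, jitter = jitter, seed = as.integer(seed)),
    class = "phantom_spec")
}

#' Build the phantom surface mesh
#'
#' Triangulates a hemispherical dome (UV parameterisation with an apex fan)
#' of radius `dome_radius` seated on a cylindrical parent segment, at the
#' requested edge length. Every face is labelled `dome` or `parent`, and the
#' designed low-shear and oscillatory patches are recorded as face
#' attributes (`patch`): the low-shear patch is the spherical cap around the
#' apex whose area fraction of the hemisphere is `low_shear_fraction`, and
#' the oscillatory patch is the band directly below it. Patch membership is
#' decided by face-centroid polar angle, so realised patch areas match the
#' designed fractions to mesh-resolution accuracy.
#'
#' The construction is fully deterministic: the same spec always yields the
#' identical mesh.
#'
#' @param spec a [phantom_spec()].
#' @return A [surface_mesh()] with an extra character attribute-like element
#'   `patch` (per face: `"low_shear"`, `"oscillatory"`, or `"none"`).
#' @export
make_phantom_mesh <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  r <- spec$dome_radius
  h <- spec$mesh_resolution

  n_theta <- max(3L, ceiling((pi / 2 * r) / h))
  n_phi <- max(8L, ceiling((2 * pi * r) / h))
  theta <- seq(0, pi / 2, length.out = n_theta + 1L)  # 0 = apex
  phi <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]

  # Dome apex sits on top; equator ring at z = 0, then raised so the rim
  # touches the top of the parent cylinder.
  zs <- r * cos(theta)
  rs <- r * sin(theta)
  verts <- rbind(c(0, 0, zs[1L]))
  ring_start <- integer(n_theta)  # first vertex index of ring i (theta[i+1])
  for (i in seq_len(n_theta)) {
    ring_start[i] <- nrow(verts) + 1L
    verts <- rbind(verts, cbind(rs[i + 1L] * cos(phi),
                                rs[i + 1L] * sin(phi),
                                zs[i + 1L]))
  }
  tris <- matrix(integer(0), ncol = 3L)
  # apex fan
  first <- ring_start[1L]
  idx <- function(ring, k) ring + ((k - 1L) %% n_phi)
  for (k in seq_len(n_phi)) {
    tris <- rbind(tris, c(1L, idx(first, k), idx(first, k + 1L)))
  }
  # latitude bands
  for (i in seq_len(n_theta - 1L)) {
    a <- ring_start[i]
    b <- ring_start[i + 1L]
    for (k in seq_len(n_phi)) {
      tris <- rbind(tris,
                    c(idx(a, k), idx(b, k), idx(b, k + 1L)),
                    c(idx(a, k), idx(b, k + 1L), idx(a, k + 1L)))
    }
  }
  n_dome_faces <- nrow(tris)

  # Parent vessel: open cylinder along x, axis at z = -(vessel_radius), so
  # its top surface (z = 0) carries the dome rim.
  rv <- spec$vessel_radius
  lv <- spec$vessel_length
  n_ax <- max(2L, ceiling(lv / h))
  n_circ <- max(8L, ceiling((2 * pi * rv) / h))
  xs <- seq(-lv / 2, lv / 2, length.out = n_ax + 1L)
  ang <- seq(0, 2 * pi, length.out = n_circ + 1L)[-(n_circ + 1L)]
  cyl_start <- nrow(verts)
  for (x in xs) {
    verts <- rbind(verts, cbind(x, rv * sin(ang), rv * cos(ang) - rv))
  }
  cyl_ring <- function(i) cyl_start + (i - 1L) * n_circ
  for (i in seq_len(n_ax)) {
    a <- cyl_ring(i)
    b <- cyl_ring(i + 1L)
    for (k in seq_len(n_circ)) {
      a1 <- a + k
      a2 <- a + (k %% n_circ) + 1L
      b1 <- b + k
      b2 <- b + (k %% n_circ) + 1L
      tris <- rbind(tris, c(a1, b1, b2), c(a1, b2, a2))
    }
  }
  region <- rep(c("dome", "parent"),
                c(n_dome_faces, nrow(tris) - n_dome_faces))
  mesh <- surface_mesh(verts, tris, region)

  # Patch labels from face-centroid polar angle on the dome. A spherical cap
  # of polar half-angle t has area fraction (1 - cos t) of the hemisphere.
  cen <- mesh$face_centroid
  ct <- pmin(1, pmax(-1, cen[, 3L] / sqrt(rowSums(cen^2))))  # cos(theta)
  patch <- rep("none", n_faces(mesh))
  f_ls <- spec$low_shear_fraction
  f_os <- spec$oscillatory_fraction
  dome <- region == "dome"
  if (f_ls > 0) {
    sel <- dome & ct > (1 - f_ls)
    if (!any(sel)) {
      stop("mesh_resolution too coarse to realise low_shear_fraction = ",
           f_ls)
    }
    patch[sel] <- "low_shear"
  }
  if (f_os > 0) {
    sel <- dome & ct <= (1 - f_ls) & ct > (1 - f_ls - f_os)
    if (!any(sel)) {
      stop("mesh_resolution too coarse to realise oscillatory_fraction = ",
           f_os)
    }
    patch[sel] <- "oscillatory"
  }
  mesh$patch <- patch
  mesh
}

#' Generate the pulsatile WSS field on a phantom mesh
#'
#' Synthesises a per-face tangential WSS vector time series emulating one
#' stable cardiac cycle of CFD output:
#' \itemize{
#'   \item ordinary dome faces carry magnitude `base_wss` (times a per-face
#'     jitter drawn once from the seed) along a fixed tangent direction,
#'     modulated by the waveform, so their time-averaged magnitude is the
#'     jittered base value;
#'   \item low-shear patch faces carry 5% of `parent_wss`, keeping them
#'     safely below the 10% LSA threshold;
#'   \item oscillatory patch faces follow `cos(2 pi t / T) + 0.2` along
#'     their tangent, reversing direction within the cycle (OSI about 0.35);
#'   \item parent faces carry exactly `parent_wss` on average.
#' }
#' All vectors are built in each face's tangent plane, so tangency holds to
#' round-off.
#'
#' @param mesh mesh from [make_phantom_mesh()].
#' @param spec the [phantom_spec()] used to build `mesh`.
#' @return A [wss_time_series()].
#' @export
make_wss_field <- function(mesh, spec) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(spec, "phantom_spec"))
  if (is.null(mesh$patch)) stop("mesh lacks phantom patch labels")
  nf <- n_faces(mesh)
  nt <- spec$n_timesteps
  times <- (seq_len(nt) - 1L) * spec$period / nt
  wave <- spec$waveform(times)
  if (any(wave <= 0)) stop("waveform must be strictly positive")

  # Per-face orthonormal tangent basis.
  n <- mesh$face_normal
  ref <- cbind(rep(1, nf), 0, 0)
  swap <- abs(n[, 1L]) > 0.9
  ref[swap, ] <- rep(c(0, 1, 0), each = sum(swap))
  t1 <- cross3(n, ref)
  t1 <- t1 / sqrt(rowSums(t1^2))

  withr_seed <- spec$seed
  set.seed(withr_seed)
  mag <- numeric(nf)
  dome <- mesh$region == "dome"
  ordinary <- dome & mesh$patch == "none"
  mag[ordinary] <- spec$base_wss *
    stats::runif(sum(ordinary), 1 - spec$jitter, 1 + spec$jitter)
  low <- mesh$patch == "low_shear"
  mag[low] <- 0.05 * spec$parent_wss
  osc <- mesh$patch == "oscillatory"
  mag[osc] <- spec$base_wss
  mag[mesh$region == "parent"] <- spec$parent_wss

  wss <- array(0, dim = c(nf, 3L, nt))
  osc_wave <- cos(2 * pi * times / spec$period) + 0.2
  for (k in seq_len(nt)) {
    amp <- mag * wave[k]
    amp[osc] <- mag[osc] * osc_wave[k]
    wss[, , k] <- amp * t1
  }
  wss_time_series(times, wss, period = spec$period)
}
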