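#' Time-averaged wall shear stress magnitude
#'
#' The cycle average of the instantaneous WSS magnitude on each face,
#' `WSS = (1/T) integral |WSS_i| dt`, computed with the periodic trapezoid
#' rule (the cycle is closed from the last sample back to the first).
#'
#' @param series a [wss_time_series()].
#' @return A [field_map()] in Pa.
#' @export
time_avg_wss <- function(series) {
  stopifnot(inherits(series, "wss_time_series"))
  mags <- sqrt(apply(series$wss^2, c(1L, 3L), sum))
  if (is.null(dim(mags))) mags <- matrix(mags, nrow = 1L)
  field_map(periodic_trapz(mags, series$times, series$period) /
              series$period,
            name = "WSS")
}

# Cycle-averaged WSS *vector* per face (n_faces x 3).
time_avg_wss_vector <- function(series) {
  nf <- dim(series$wss)[1L]
  out <- matrix(0, nf, 3L)
  for (c_ in 1:3) {
    comp <- series$wss[, c_, , drop = FALSE]
    dim(comp) <- dim(series$wss)[c(1L, 3L)]
    out[, c_] <- periodic_trapz(comp, series$times, series$period) /
      series$period
  }
  out
}

#' Oscillatory shear index
#'
#' `OSI = 1/2 (1 - |integral WSS_i dt| / integral |WSS_i| dt)` per face:
#' 0 for unidirectional shear, 0.5 when the cycle-averaged vector cancels
#' completely. Faces whose WSS vanishes at every sample have no defined
#' direction; they are returned as `NA` and the count is attached as
#' attribute `n_missing`.
#'
#' @param series a [wss_time_series()].
#' @return A [field_map()] in `[0, 0.5]`.
#' @export
osi <- function(series) {
  stopifnot(inherits(series, "wss_time_series"))
  mean_vec <- time_avg_wss_vector(series)
  num <- sqrt(rowSums(mean_vec^2))
  den <- time_avg_wss(series)$values
  vals <- ifelse(den > 0, 0.5 * (1 - pmin(1, num / den)), NA_real_)
  out <- field_map(vals, name = "OSI")
  attr(out, "n_missing") <- sum(is.na(vals))
  out
}

#' Relative residence time
#'
#' `RRT = 1 / |(1/T) integral WSS_i dt|`, the reciprocal magnitude of the
#' cycle-averaged WSS vector — algebraically identical to
#' `1 / ((1 - 2 OSI) * (1/T) integral |WSS_i| dt)`. Faces with a vanishing
#' mean vector (OSI = 0.5) have infinite residence time and are returned as
#' `NA`, with the count attached as attribute `n_missing`.
#'
#' @param series a [wss_time_series()].
#' @return A [field_map()] in 1/Pa.
#' @export
rrt <- function(series) {
  stopifnot(inherits(series, "wss_time_series"))
  mean_vec <- time_avg_wss_vector(series)
  mag <- sqrt(rowSums(mean_vec^2))
  vals <- ifelse(mag > 0, 1 / mag, NA_real_)
  out <- field_map(vals, name = "RRT")
  attr(out, "n_missing") <- sum(is.na(vals))
  out
}

#' Normalized wall shear stress
#'
#' Per-face time-averaged WSS divided by the area-weighted mean
#' time-averaged WSS of the parent-vessel region — the dimensionless form
#' that removes the patient-to-patient inflow scale.
#'
#' @param wss_map time-averaged WSS [field_map()] (from [time_avg_wss()]).
#' @param mesh the [surface_mesh()] the map lives on.
#' @return A [field_map()] (dimensionless) with attribute
#'   `parent_mean_wss` (Pa).
#' @export
nwss <- function(wss_map, mesh) {
  pm <- parent_mean_wss(wss_map, mesh)
  out <- field_map(wss_map$values / pm, name = "NWSS")
  attr(out, "parent_mean_wss") <- pm
  out
}

#' Area-weighted parent-vessel mean WSS
#'
#' @param wss_map time-averaged WSS [field_map()].
#' @param mesh the [surface_mesh()].
#' @return Scalar mean WSS (Pa) over `parent` faces.
#' @export
parent_mean_wss <- function(wss_map, mesh) {
  sel <- mesh$region == "parent" & !is.na(wss_map$values)
  if (!any(sel)) stop("mesh has no parent-vessel faces with defined WSS")
  pm <- sum(wss_map$values[sel] * mesh$face_area[sel]) /
    sum(mesh$face_area[sel])
  if (pm <= 0) stop("parent-vessel mean WSS is not positive")
  pm
}

#' Wall shear stress spatial gradient
#'
#' Magnitude of the spatial variation of the cycle-averaged WSS vector
#' field, decomposed in each face's flow-aligned frame:
#' `WSSG = sqrt((d tau_p / dp)^2 + (d tau_q / dq)^2)`, where `p` is the
#' unit direction of the face's time-averaged WSS, `q` the in-plane
#' perpendicular, and `tau_p`, `tau_q` the components of the time-averaged
#' WSS vector in that frame. Derivatives come from [tangential_gradient()]
#' applied to the three Cartesian components of the mean-WSS field and
#' contracted with the per-face frame. Faces with a vanishing mean vector
#' have no defined `p` direction and are returned `NA` (attribute
#' `n_missing`).
#'
#' @param mesh a [surface_mesh()].
#' @param series a [wss_time_series()] on `mesh`.
#' @return A [field_map()] in Pa/mm if mesh coordinates are mm (multiply by
#'   1000 for Pa/m; see [compute_descriptors()], which reports Pa/m).
#' @export
wssg <- function(mesh, series) {
  stopifnot(inherits(mesh, "surface_mesh"),
            inherits(series, "wss_time_series"))
  tau <- time_avg_wss_vector(series)
  mag <- sqrt(rowSums(tau^2))
  ok <- mag > 0
  p_hat <- tau / ifelse(ok, mag, 1)
  q_hat <- cross3(mesh$face_normal, p_hat)

  # gradient of each Cartesian component of the mean-WSS vector field
  gx <- tangential_gradient(mesh, tau[, 1L], on = "face")
  gy <- tangential_gradient(mesh, tau[, 2L], on = "face")
  gz <- tangential_gradient(mesh, tau[, 3L], on = "face")
  # d(tau . e)/d(dir) = sum_c e_c (grad tau_c . dir)
  dir_deriv <- function(e, dir) {
    e[, 1L] * rowSums(gx * dir) +
      e[, 2L] * rowSums(gy * dir) +
      e[, 3L] * rowSums(gz * dir)
  }
  dpp <- dir_deriv(p_hat, p_hat)
  dqq <- dir_deriv(q_hat, q_hat)
  vals <- ifelse(ok, sqrt(dpp^2 + dqq^2), NA_real_)
  out <- field_map(vals, name = "WSSG")
  attr(out, "n_missing") <- sum(!ok)
  out
}

#' CHP weighting configuration
#'
#' The combined hemodynamic parameter is a convex combination of a
#' normalized low-WSS term and the normalized OSI; the two weights must sum
#' to one. With no published values, equal weights are the default.
#'
#' @param omega1 weight of the normalized WSS term.
#' @param omega2 weight of the normalized OSI term.
#' @param wss_norm which WSS normalization to use: `"superellipse"`
#'   (quartic, the default) or `"linear"`.
#' @return An object of class `chp_config`.
#' @export
chp_config <- function(omega1 = 0.5, omega2 = 0.5,
                       wss_norm = c("superellipse", "linear")) {
  if (omega1 < 0 || omega2 < 0) stop("CHP weights must be non-negative")
  if (abs(omega1 + omega2 - 1) > 1e-12) {
    stop("CHP weights must sum to 1 (got ", omega1 + omega2, ")")
  }
  structure(list(omega1 = omega1, omega2 = omega2,
                 wss_norm = match.arg(wss_norm)),
            class = "chp_config")
}

#' Combined hemodynamic parameter
#'
#' `CHP = omega1 * WSSnorm + omega2 * OSInorm` per dome face, with
#' `OSInorm = 2 OSI` and a WSS normalization that maps the sac's own WSS
#' range onto `[0, 1]` with *low* WSS scoring high (rupture-prone thin wall
#' is low-WSS, high-OSI). The default normalization is the quarter
#' superellipse `WSSnorm = 1 - (1 - y^4)^(1/4)` with
#' `y = (WSS - WSSmax) / (WSSmax - WSSmin)`, so `WSSnorm` is 1 at the sac
#' minimum and 0 at the sac maximum; the `"linear"` variant uses
#' `(WSSmax - WSS) / (WSSmax - WSSmin)`.
#'
#' Extrema are taken over the non-missing dome faces of the same aneurysm.
#' If the dome WSS field is constant the normalization is degenerate and
#' `WSSnorm` is set to 0.5 everywhere with a warning.
#'
#' @param wss_map time-averaged WSS [field_map()].
#' @param osi_map OSI [field_map()].
#' @param mesh the [surface_mesh()]; extrema and output are over dome faces
#'   (other faces are `NA`).
#' @param cfg a [chp_config()].
#' @return A [field_map()] with values in `[0, 1]` on dome faces.
#' @export
chp <- function(wss_map, osi_map, mesh, cfg = chp_config()) {
  stopifnot(inherits(cfg, "chp_config"))
  dome <- mesh$region == "dome"
  w <- wss_map$values
  wd <- w[dome]
  if (all(is.na(wd))) stop("no defined dome WSS values")
  wmin <- min(wd, na.rm = TRUE)
  wmax <- max(wd, na.rm = TRUE)
  if (wmax > wmin) {
    y <- (w - wmax) / (wmax - wmin)  # in [-1, 0] on dome
    wssnorm <- switch(cfg$wss_norm,
      superellipse = 1 - (pmax(0, 1 - y^4))^(1 / 4),
      linear = -y)
  } else {
    warning("dome WSS field is constant; WSSnorm set to 0.5")
    wssnorm <- rep(0.5, length(w))
  }
  vals <- cfg$omega1 * wssnorm + cfg$omega2 * (2 * osi_map$values)
  vals[!dome] <- NA_real_
  field_map(vals, name = "CHP")
}

#' Low shear area fraction
#'
#' Fraction of the dome area whose time-averaged WSS lies below a set
#' fraction (default 10%) of the parent-vessel mean WSS.
#'
#' @param wss_map time-averaged WSS [field_map()].
#' @param mesh the [surface_mesh()].
#' @param threshold_fraction low-shear threshold as a fraction of the
#'   parent mean (default 0.1).
#' @return Scalar in `[0, 1]`.
#' @export
lsa <- function(wss_map, mesh, threshold_fraction = 0.1) {
  dome <- mesh$region == "dome"
  dome_area <- sum(mesh$face_area[dome])
  if (dome_area <= 0) stop("mesh has zero dome area")
  thr <- threshold_fraction * parent_mean_wss(wss_map, mesh)
  sel <- dome & !is.na(wss_map$values) & wss_map$values < thr
  sum(mesh$face_area[sel]) / dome_area
}

#' Dome summary of a per-face field
#'
#' Min, max, area-weighted mean and max/min ratio of a descriptor over the
#' dome faces, the row structure of a per-aneurysm descriptor table. Missing
#' faces are excluded (their count is returned). The ratio is `NA` when the
#' minimum is zero.
#'
#' @param map a [field_map()].
#' @param mesh the [surface_mesh()].
#' @param area_weighted use area-weighted mean (default) or plain mean.
#' @return A list with `min`, `max`, `mean`, `ratio`, `n_missing`.
#' @export
summarize_field <- function(map, mesh, area_weighted = TRUE) {
  dome <- mesh$region == "dome"
  v <- map$values[dome]
  a <- mesh$face_area[dome]
  ok <- !is.na(v)
  if (!any(ok)) stop("field '", map$name, "' has no defined dome values")
  v <- v[ok]
  a <- a[ok]
  mn <- min(v)
  mx <- max(v)
  mean_ <- if (area_weighted) sum(a * v) / sum(a) else mean(v)
  ratio <- if (mn > 0) mx / mn else {
    warning("field '", map$name, "' has zero minimum; ratio undefined")
    NA_real_
  }
  list(min = mn, max = mx, mean = mean_, ratio = ratio,
       n_missing = sum(!ok))
}

#' Full descriptor set for one aneurysm
#'
#' Computes all seven descriptor families from a mesh and its WSS time
#' series: dome summaries (min/max/mean/ratio) of WSS, NWSS, WSSG, OSI, RRT
#' and CHP, plus the scalar LSA and the parent-vessel mean WSS. WSSG is
#' reported in Pa/m (mesh coordinates are mm). Values are kept at full
#' precision; use [round_descriptors()] for a 3-decimal reporting variant.
#'
#' @param mesh a [surface_mesh()] with dome and parent faces.
#' @param series a [wss_time_series()] on `mesh`.
#' @param chp_cfg a [chp_config()].
#' @param id optional aneurysm identifier for the output row.
#' @param area_weighted passed to [summarize_field()].
#' @return A one-row `data.frame` with columns `<FIELD>_min`, `<FIELD>_max`,
#'   `<FIELD>_mean`, `<FIELD>_ratio` for each of WSS, NWSS, WSSG, OSI, RRT,
#'   CHP, plus `LSA` and `parent_mean_wss`.
#' @export
compute_descriptors <- function(mesh, series, chp_cfg = chp_config(),
                                id = NULL, area_weighted = TRUE) {
  wss_map <- time_avg_wss(series)
  osi_map <- osi(series)
  rrt_map <- rrt(series)
  nwss_map <- nwss(wss_map, mesh)
  wssg_map <- wssg(mesh, series)
  wssg_map$values <- wssg_map$values * 1000  # Pa/mm -> Pa/m
  chp_map <- chp(wss_map, osi_map, mesh, chp_cfg)

  maps <- list(WSS = wss_map, NWSS = nwss_map, WSSG = wssg_map,
               OSI = osi_map, RRT = rrt_map, CHP = chp_map)
  row <- list()
  for (nm in names(maps)) {
    s <- summarize_field(maps[[nm]], mesh, area_weighted = area_weighted)
    row[[paste0(nm, "_min")]] <- s$min
    row[[paste0(nm, "_max")]] <- s$max
    row[[paste0(nm, "_mean")]] <- s$mean
    row[[paste0(nm, "_ratio")]] <- s$ratio
  }
  row$LSA <- lsa(wss_map, mesh)
  row$parent_mean_wss <- parent_mean_wss(wss_map, mesh)
  out <- as.data.frame(row)
  if (!is.null(id)) out <- cbind(data.frame(id = id), out)
  out
}

#' Round a descriptor table for reporting
#'
#' Continuous results are conventionally reported to three decimal places;
#' this returns a copy of the table with every numeric column rounded,
#' leaving the full-precision original untouched.
#'
#' @param descriptors data.frame from [compute_descriptors()].
#' @param digits decimal places (default 3).
#' @return The rounded data.frame.
#' @export
round_descriptors <- function(descriptors, digits = 3L) {
  num <- vapply(descriptors, is.numeric, logical(1L))
  descriptors[num] <- lapply(descriptors[num], round, digits = digits)
  descriptors
}
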