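#' Triangulated aneurysm surface mesh
#'
#' A `surface_mesh` holds a triangulated wall surface: vertex positions in
#' millimetres, triangle connectivity, and a per-face anatomical region label
#' distinguishing the aneurysm dome from the parent vessel. Face areas and
#' unit normals are derived at construction and cached; all downstream
#' descriptor computations (area-weighted means, low-shear area, tangential
#' gradients) use these cached values.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param triangles integer matrix, one row per face, three 1-based vertex
#'   indices.
#' @param region character vector, one label per face, each one of
#'   `"dome"`, `"parent"`, `"other"`.
#' @return An object of class `surface_mesh` with components `vertices`,
#'   `triangles`, `region`, `face_area` (mm^2), `face_normal` (unit
#'   row vectors), `face_centroid` (mm).
#' @examples
#' v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
#' f <- rbind(c(1L, 2L, 3L), c(2L, 4L, 3L))
#' m <- surface_mesh(v, f, region = c("dome", "parent"))
#' m$face_area
#' @export
surface_mesh <- function(vertices, triangles, region) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(triangles) <- NULL
  if (ncol(vertices) != 3L) stop("`vertices` must have 3 columns (x, y, z)")
  if (ncol(triangles) != 3L) stop("`triangles` must have 3 columns")
  nf <- nrow(triangles)
  if (nf < 1L) stop("mesh has no faces")
  if (min(triangles) < 1L || max(triangles) > nrow(vertices)) {
    stop("`triangles` references vertices outside 1..", nrow(vertices))
  }
  region <- as.character(region)
  if (length(region) != nf) stop("`region` must have one label per face")
  bad <- setdiff(unique(region), c("dome", "parent", "other"))
  if (length(bad)) {
    stop("unknown region label(s): ", paste(bad, collapse = ", "))
  }

  a <- vertices[triangles[, 1L], , drop = FALSE]
  b <- vertices[triangles[, 2L], , drop = FALSE]
  c_ <- vertices[triangles[, 3L], , drop = FALSE]
  cr <- cross3(b - a, c_ - a)
  nrm2 <- sqrt(rowSums(cr^2))
  if (any(nrm2 <= 0)) {
    stop("degenerate zero-area face(s): ",
         paste(utils::head(which(nrm2 <= 0), 5L), collapse = ", "))
  }
  structure(
    list(
      vertices = vertices,
      triangles = triangles,
      region = region,
      face_area = nrm2 / 2,
      face_normal = cr / nrm2,
      face_centroid = (a + b + c_) / 3
    ),
    class = "surface_mesh"
  )
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "faces\n")
  tb <- table(x$region)
  cat("  regions:",
      paste(sprintf("%s=%d", names(tb), as.integer(tb)), collapse = ", "),
      "\n")
  cat(sprintf("  total area %.4f mm^2 (dome %.4f mm^2)\n",
              sum(x$face_area), sum(x$face_area[x$region == "dome"])))
  invisible(x)
}

n_faces <- function(mesh) nrow(mesh$triangles)

#' Total area of a mesh region
#'
#' @param mesh a [surface_mesh()].
#' @param region region label, e.g. `"dome"`.
#' @return Summed face area (mm^2) of the faces carrying that label.
#' @export
region_area <- function(mesh, region = "dome") {
  sum(mesh$face_area[mesh$region == region])
}

# Row-wise cross product of two n x 3 matrices.
cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Time-resolved wall shear stress vector field
#'
#' Stores one tangential WSS 3-vector (Pa) per face and per sample time over
#' one cardiac cycle. Sample times live in `[0, T)`; the field is treated as
#' periodic with period `T`, and all cycle integrals in the descriptor layer
#' use the periodic trapezoid rule that closes the cycle from the last sample
#' back to the first.
#'
#' @param times strictly increasing sample times (s), all in `[0, period)`.
#' @param wss array of dimension `n_faces x 3 x n_times`, WSS vectors in Pa.
#' @param period cycle duration T (s).
#' @return An object of class `wss_time_series`.
#' @export
wss_time_series <- function(times, wss, period) {
  times <- as.numeric(times)
  period <- as.numeric(period)
  if (length(period) != 1L || !is.finite(period) || period <= 0) {
    stop("`period` must be a positive scalar")
  }
  if (length(times) < 2L) stop("need at least 2 time samples")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (times[1L] < 0 || times[length(times)] >= period) {
    stop("`times` must lie in [0, period)")
  }
  wss <- as.array(wss)
  d <- dim(wss)
  if (length(d) != 3L || d[2L] != 3L || d[3L] != length(times)) {
    stop("`wss` must be an n_faces x 3 x n_times array")
  }
  if (!all(is.finite(wss))) stop("non-finite WSS values")
  structure(list(times = times, wss = wss, period = period),
            class = "wss_time_series")
}

#' @export
print.wss_time_series <- function(x, ...) {
  cat("wss_time_series:", dim(x$wss)[1L], "faces,", length(x$times),
      "time steps over period", x$period, "s\n")
  invisible(x)
}

#' Per-face scalar field
#'
#' A `field_map` carries one scalar value per mesh face for a named
#' descriptor (time-averaged WSS, OSI, ...). Faces where the descriptor is
#' undefined (e.g. OSI on an all-zero WSS series) hold `NA`; summaries skip
#' them and report how many were skipped.
#'
#' @param values numeric vector, one value per face (`NA` = undefined).
#' @param name descriptor label.
#' @return An object of class `field_map`.
#' @export
field_map <- function(values, name = "field") {
  values <- as.numeric(values)
  if (any(is.infinite(values) | is.nan(values))) {
    stop("field '", name, "' contains non-finite values; encode undefined ",
         "faces as NA")
  }
  structure(list(values = values, name = name), class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  v <- x$values
  cat(sprintf("field_map '%s': %d faces (%d missing), range [%g, %g]\n",
              x$name, length(v), sum(is.na(v)),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

# Periodic trapezoid integral over one cycle for each row of `mat`
# (n_faces x n_times), closing the cycle from the last sample back to the
# first. Exact for constants and for sinusoids sampled uniformly.
periodic_trapz <- function(mat, times, period) {
  nt <- length(times)
  dt <- diff(c(times, times[1L] + period))
  mid <- (mat[, c(seq_len(nt - 1L), nt), drop = FALSE] +
          mat[, c(seq(2L, nt), 1L), drop = FALSE]) / 2
  as.numeric(mid %*% dt)
}
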