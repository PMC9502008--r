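#' Write a surface mesh and WSS time series to disk
#'
#' Serialises the mesh as a legacy-ASCII VTK PolyData file with cell data:
#' an integer `region` array (0 = other, 1 = dome, 2 = parent) and one
#' 3-component `wss_t<k>` array per time step (Pa). Sample times, the cycle
#' period, and any provenance (e.g. the phantom spec that generated the
#' data) go to a JSON sidecar at `<path>.json`. Numeric values are written
#' with 17 significant digits so that [read_surface_series()] round-trips
#' coordinates and field values bit-exactly.
#'
#' @param mesh a [surface_mesh()].
#' @param series a [wss_time_series()] on the same mesh.
#' @param path output file path (conventionally `.vtk`).
#' @param provenance optional named list stored verbatim in the sidecar.
#' @return `path`, invisibly.
#' @seealso [read_surface_series()]
#' @export
write_surface_series <- function(mesh, series, path, provenance = NULL) {
  if (dim(series$wss)[1L] != n_faces(mesh)) {
    stop("series face count does not match mesh")
  }
  nt <- length(series$times)
  nf <- n_faces(mesh)
  nv <- nrow(mesh$vertices)

  fmt_rows <- function(m) {
    apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  }
  lines <- c(
    "# vtk DataFile Version 3.0",
    "aneuhemo surface series",
    "ASCII",
    "DATASET POLYDATA",
    sprintf("POINTS %d double", nv),
    fmt_rows(mesh$vertices),
    sprintf("POLYGONS %d %d", nf, 4L * nf),
    apply(mesh$triangles - 1L, 1L, function(r) {
      paste(c(3L, r), collapse = " ")
    }),
    sprintf("CELL_DATA %d", nf),
    sprintf("FIELD wall_data %d", 1L + nt),
    sprintf("region 1 %d int", nf),
    paste(region_to_code(mesh$region), collapse = " ")
  )
  for (k in seq_len(nt)) {
    lines <- c(lines,
               sprintf("wss_t%04d 3 %d double", k, nf),
               fmt_rows(series$wss[, , k]))
  }
  writeLines(lines, path)

  # times/period as %.17g strings: JSON number serialisation does not
  # guarantee bit round-trip, strings do
  sidecar <- list(
    format = "aneuhemo-surface-series",
    times = sprintf("%.17g", series$times),
    period = sprintf("%.17g", series$period),
    n_timesteps = nt,
    region_codes = list(other = 0L, dome = 1L, parent = 2L)
  )
  if (!is.null(provenance)) sidecar$provenance <- provenance
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a surface mesh and WSS time series
#'
#' Reads a file written by [write_surface_series()]: legacy-ASCII VTK
#' PolyData plus the `<path>.json` sidecar carrying sample times and the
#' cycle period. Fails with a message naming the file and the missing array
#' if the `region` labels or any expected `wss_t<k>` array is absent or has
#' the wrong length.
#'
#' @param path path to the `.vtk` file.
#' @return A list with components `mesh` ([surface_mesh()]), `series`
#'   ([wss_time_series()]), and `provenance` (list, possibly NULL).
#' @export
read_surface_series <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop("missing sidecar ", sidecar_path, " (times/period unavailable)")
  }
  sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  lines <- readLines(path)

  need <- function(pattern, what) {
    i <- grep(pattern, lines)
    if (!length(i)) stop("file ", path, ": missing ", what)
    i[1L]
  }
  toks <- function(i) strsplit(trimws(lines[i]), "\\s+")[[1L]]

  ip <- need("^POINTS ", "POINTS section")
  nv <- as.integer(toks(ip)[2L])
  vertices <- matrix(
    as.numeric(unlist(strsplit(trimws(lines[(ip + 1L):(ip + nv)]), "\\s+"))),
    ncol = 3L, byrow = TRUE)

  it <- need("^POLYGONS ", "POLYGONS section")
  nf <- as.integer(toks(it)[2L])
  poly <- matrix(
    as.integer(unlist(strsplit(trimws(lines[(it + 1L):(it + nf)]), "\\s+"))),
    ncol = 4L, byrow = TRUE)
  if (any(poly[, 1L] != 3L)) stop("file ", path, ": non-triangle polygon")
  triangles <- poly[, 2:4, drop = FALSE] + 1L

  read_field <- function(name, ncomp, mode) {
    i <- grep(paste0("^", name, " "), lines)
    if (!length(i)) stop("file ", path, ": missing cell array '", name, "'")
    hdr <- toks(i[1L])
    if (as.integer(hdr[2L]) != ncomp || as.integer(hdr[3L]) != nf) {
      stop("file ", path, ": array '", name, "' has wrong shape (",
           hdr[2L], "x", hdr[3L], ", expected ", ncomp, "x", nf, ")")
    }
    n_lines <- if (ncomp == 1L) 1L else nf
    vals <- as.numeric(unlist(strsplit(
      trimws(lines[(i[1L] + 1L):(i[1L] + n_lines)]), "\\s+")))
    if (length(vals) != ncomp * nf) {
      stop("file ", path, ": array '", name, "' truncated")
    }
    if (mode == "matrix") matrix(vals, ncol = ncomp, byrow = TRUE) else vals
  }

  region <- code_to_region(read_field("region", 1L, "vector"))
  nt <- as.integer(sidecar$n_timesteps)
  wss <- array(0, dim = c(nf, 3L, nt))
  for (k in seq_len(nt)) {
    wss[, , k] <- read_field(sprintf("wss_t%04d", k), 3L, "matrix")
  }

  mesh <- surface_mesh(vertices, triangles, region)
  series <- wss_time_series(as.numeric(sidecar$times), wss,
                            period = as.numeric(sidecar$period))
  list(mesh = mesh, series = series, provenance = sidecar$provenance)
}

region_to_code <- function(region) {
  c(other = 0L, dome = 1L, parent = 2L)[region]
}

code_to_region <- function(code) {
  out <- c("other", "dome", "parent")[as.integer(code) + 1L]
  if (any(is.na(out))) stop("unknown region code in file")
  out
}

#' Export a per-face field as CSV
#'
#' @param map a [field_map()].
#' @param path output CSV path; columns `face_id`, `value`.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(map, path) {
  utils::write.csv(
    data.frame(face_id = seq_along(map$values), value = map$values),
    path, row.names = FALSE)
  invisible(path)
}
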