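#' Build a habitat mask around a trap array
#'
#' Lays a regular lattice of cell centres over the axis-aligned bounding box of
#' the trap stations expanded by \code{buffer_km} on every side, then excludes
#' cells whose centre falls inside any exclusion polygon (even-odd rule,
#' all-or-nothing at the mesh resolution).
#'
#' @param design a \linkS4class{SurveyDesign}.
#' @param buffer_km buffer width in km (> 0); the motivating surveys used
#'   40 km (100 km where occasional long-distance dispersal was plausible).
#' @param mesh_km lattice spacing in km (default 1, i.e. 1 km^2 cells).
#' @param exclusions list of polygons (two-column matrices of vertices, km).
#' @return A \linkS4class{HabitatMask}.
#' @export
buildMask <- function(design, buffer_km, mesh_km = 1.0, exclusions = list()) {
  if (buffer_km <= 0) stopf("buffer_km must be > 0")
  if (mesh_km <= 0) stopf("mesh_km must be > 0")
  st <- design@stations
  xr <- range(st$x_km); yr <- range(st$y_km)
  xs <- seq(xr[1] - buffer_km, xr[2] + buffer_km, by = mesh_km)
  ys <- seq(yr[1] - buffer_km, yr[2] + buffer_km, by = mesh_km)
  cells <- as.matrix(expand.grid(x = xs, y = ys))
  include <- rep(TRUE, nrow(cells))
  for (poly in exclusions)
    include <- include & !pointInPolygon(cells, poly)
  if (!any(include))
    stopf("configuration error: all mask cells fall inside exclusions")
  new("HabitatMask", cells = cells, include = include, mesh_km = mesh_km)
}

# even-odd ray-casting test; pts n x 2, poly v x 2 (closed implicitly)
pointInPolygon <- function(pts, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Write a habitat mask to CSV
#'
#' Columns \code{x_km}, \code{y_km}, \code{include}; one row per lattice cell.
#'
#' @param mask a \linkS4class{HabitatMask}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeMask <- function(mask, path) {
  df <- data.frame(x_km = mask@cells[, 1], y_km = mask@cells[, 2],
                   include = as.integer(mask@include))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a habitat mask from CSV
#'
#' @param path CSV with columns \code{x_km}, \code{y_km}, \code{include} on a
#'   regular lattice (spacing tolerance 1e-6 km).
#' @return A \linkS4class{HabitatMask}.
#' @export
readMask <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x_km", "y_km", "include")
  if (!all(need %in% names(df)))
    stopf("format error: mask CSV needs columns %s", paste(need, collapse = ", "))
  mesh <- inferMesh(df$x_km, df$y_km)
  m <- new("HabitatMask", cells = cbind(x = df$x_km, y = df$y_km),
           include = as.logical(df$include), mesh_km = mesh)
  m
}

inferMesh <- function(x, y) {
  d <- c(diff(sort(unique(x))), diff(sort(unique(y))))
  d <- d[d > 1e-9]
  if (!length(d)) return(1.0)
  mesh <- min(d)
  r <- d / mesh
  if (any(abs(r - round(r)) > 1e-6))
    stopf("format error: irregular lattice spacing in mask file")
  mesh
}
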