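#' Regular analysis grids and per-cell layers
#'
#' A `ps_grid` is a data frame with columns `cell_id` (unique character),
#' `x`, `y` (centroid coordinates in abstract map units) and a `cell_size`
#' attribute. Coordinates are whatever unit the grid declares (km, decimal
#' degrees, ...); all distances in the package are Euclidean on centroids.
#'
#' A layer (`ps_layer`) is a numeric vector with one value per grid cell,
#' named by `cell_id`, in the same order as its grid, with `layer_name` and
#' `units` attributes. `NA` marks cells with no data.
#'
#' @param nx,ny number of columns and rows of cells (both >= 1).
#' @param cell_size edge length of a square cell, in map units.
#' @param origin coordinates of the lower-left corner of the grid.
#' @return `make_grid()` returns a `ps_grid` with `nx * ny` cells whose
#'   centroids form a regular lattice; cells are ordered row-major from the
#'   lower-left corner.
#' @examples
#' g <- make_grid(3, 2)
#' head(g)
#' @export
make_grid <- function(nx, ny, cell_size = 1, origin = c(0, 0)) {
  stopifnot(nx >= 1, ny >= 1, cell_size > 0)
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  g <- data.frame(
    cell_id = sprintf("c%05d", seq_len(nx * ny)),
    x = origin[1] + (ix - 0.5) * cell_size,
    y = origin[2] + (iy - 0.5) * cell_size,
    stringsAsFactors = FALSE
  )
  as_ps_grid(g, cell_size = cell_size)
}

#' Validate and classify a grid definition
#'
#' @param df data frame with columns `cell_id`, `x`, `y`.
#' @param cell_size cell edge length in the grid's map units.
#' @return a `ps_grid`.
#' @export
as_ps_grid <- function(df, cell_size = 1) {
  req <- c("cell_id", "x", "y")
  if (!all(req %in% names(df)))
    stop("grid definition needs columns: ", paste(req, collapse = ", "))
  df <- df[, req]
  df$cell_id <- as.character(df$cell_id)
  if (anyDuplicated(df$cell_id))
    stop("duplicate cell_id in grid: ",
         paste(unique(df$cell_id[duplicated(df$cell_id)]), collapse = ", "))
  if (anyDuplicated(df[, c("x", "y")]))
    stop("duplicate centroid coordinates in grid")
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)))
    stop("non-finite centroid coordinates in grid")
  attr(df, "cell_size") <- cell_size
  class(df) <- c("ps_grid", "data.frame")
  df
}

#' @rdname as_ps_grid
#' @param path CSV file with columns `cell_id,x,y`.
#' @export
read_grid <- function(path, cell_size = 1) {
  as_ps_grid(utils::read.csv(path, stringsAsFactors = FALSE), cell_size)
}

cell_size <- function(grid) attr(grid, "cell_size")

#' Construct a per-cell layer bound to a grid
#'
#' @param grid a `ps_grid`.
#' @param values numeric vector, one value per grid cell (grid order), or a
#'   named vector matched to `cell_id`.
#' @param name short layer name.
#' @param units unit string for documentation ("" if dimensionless).
#' @return a named numeric vector of class `ps_layer`.
#' @export
new_layer <- function(grid, values, name = "layer", units = "") {
  n <- nrow(grid)
  if (!is.null(names(values))) {
    if (!setequal(names(values), grid$cell_id))
      stop("layer names do not match grid cell ids")
    values <- values[grid$cell_id]
  } else if (length(values) != n) {
    stop("layer has ", length(values), " values but grid has ", n, " cells")
  }
  values <- as.numeric(values)
  names(values) <- grid$cell_id
  attr(values, "layer_name") <- name
  attr(values, "units") <- units
  class(values) <- "ps_layer"
  values
}

#' @export
print.ps_layer <- function(x, ...) {
  cat("<ps_layer> ", attr(x, "layer_name"),
      if (nzchar(attr(x, "units"))) paste0(" [", attr(x, "units"), "]"),
      ": ", length(x), " cells, ", sum(is.na(x)), " missing\n", sep = "")
  invisible(x)
}

# Infer the rectangular row/column layout of a regular grid.  Errors if the
# centroids do not form a complete nx-by-ny lattice.
grid_layout <- function(grid) {
  xs <- sort(unique(grid$x))
  ys <- sort(unique(grid$y))
  nx <- length(xs); ny <- length(ys)
  if (nx * ny != nrow(grid))
    stop("grid centroids do not form a complete rectangular lattice")
  col <- match(grid$x, xs)
  row <- match(grid$y, ys)
  idx <- matrix(NA_integer_, nrow = ny, ncol = nx)
  idx[cbind(row, col)] <- seq_len(nrow(grid))
  if (anyNA(idx))
    stop("grid centroids do not form a complete rectangular lattice")
  list(nx = nx, ny = ny, xs = xs, ys = ys, index = idx)
}

# Layer values as a ny-by-nx matrix, row 1 = smallest y.
layer_matrix <- function(grid, layer) {
  lay <- grid_layout(grid)
  m <- matrix(as.numeric(layer)[lay$index], nrow = lay$ny, ncol = lay$nx)
  m
}

matrix_layer <- function(grid, m, name = "layer", units = "") {
  lay <- grid_layout(grid)
  vals <- numeric(nrow(grid))
  vals[lay$index] <- m
  new_layer(grid, vals, name = name, units = units)
}
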