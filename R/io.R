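#' Parse and validate a Newick tree
#'
#' Wraps [ape::read.tree()] with strict validation: the text must be a single
#' Newick statement terminated by `";"`, parentheses must balance, tip labels
#' must be unique, and every edge must carry a finite, non-negative branch
#' length. Ultrametricity is checked (relative tip-depth spread of 1e-6) but
#' only warned about, since PD and PE are defined for arbitrary lengths.
#'
#' @param text a Newick string.
#' @return an [ape] `phylo` object, rooted, with `edge.length`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' sum(tr$edge.length)  # 5
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  text <- trimws(text)
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("newick parse error: unbalanced ')' at offset ", i)
    }
  }
  if (depth != 0L)
    stop("newick parse error: ", depth, " unclosed '(' at offset ",
         length(chars))
  if (!endsWith(text, ";"))
    stop("newick parse error: missing terminal ';' at offset ", nchar(text))
  if (sum(chars == ";") != 1L)
    stop("newick parse error: expected a single statement, found ",
         sum(chars == ";"), " ';'")
  # a bare single-tip statement ("A:1;") has no parentheses; wrap it so the
  # reader sees a valid clade
  parse_text <- if (!any(chars == "(")) {
    paste0("(", sub(";$", "", text), ");")
  } else text
  tree <- tryCatch(ape::read.tree(text = parse_text),
                   error = function(e) stop("newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree))
    stop("newick parse error: unreadable statement")
  validate_phylogeny(tree)
}

#' @rdname parse_newick
#' @param tree a `phylo` object.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length) ||
      length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length))
    stop("branch lengths are mandatory on every edge")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and >= 0")
  if (length(tree$tip.label) >= 2) {
    d <- node_depths(tree)[seq_along(tree$tip.label)]
    spread <- (max(d) - min(d)) / max(max(d), .Machine$double.eps)
    if (spread > 1e-6)
      warning("tree is not ultrametric (relative tip-depth spread ",
              signif(spread, 3), ")")
  }
  tree
}

#' @rdname parse_newick
#' @export
serialize_newick <- function(tree) {
  ape::write.tree(tree, digits = 15)
}

# Root-to-node path lengths, indexed by ape node number.
node_depths <- function(tree) {
  n_node <- max(tree$edge)
  depth <- numeric(n_node)
  ord <- rev(ape::postorder(tree))  # root-to-tip edge order
  for (e in ord) {
    depth[tree$edge[e, 2]] <- depth[tree$edge[e, 1]] + tree$edge.length[e]
  }
  depth
}

#' Build a presence/absence occurrence matrix on a grid
#'
#' Long-format records are deduplicated into a binary cells-by-species matrix
#' covering every grid cell (rows in grid order; cells with no record get an
#' all-zero row). Records whose `cell_id` is not in the grid are an error.
#' When a reference tree is supplied, species absent from its tips either
#' raise an error (default) or are dropped with a warning.
#'
#' @param records data frame with columns `cell_id` and `species`, one row
#'   per occurrence record (duplicates allowed).
#' @param grid a `ps_grid`.
#' @param tree optional `phylo`; occurrence species must be a subset of its
#'   tip labels.
#' @param unmatched what to do with species missing from `tree`:
#'   `"error"` (default) or `"drop"` (with a warning naming them).
#' @return an integer 0/1 matrix of class `ps_occ` (rows = cells, columns =
#'   species, sorted by name) with the grid attached as attribute `grid`.
#' @export
read_occurrences <- function(records, grid, tree = NULL,
                             unmatched = c("error", "drop")) {
  unmatched <- match.arg(unmatched)
  if (is.character(records) && length(records) == 1)
    records <- utils::read.csv(records, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "species") %in% names(records)))
    stop("occurrence records need columns cell_id, species")
  records$cell_id <- as.character(records$cell_id)
  records$species <- as.character(records$species)
  bad <- setdiff(records$cell_id, grid$cell_id)
  if (length(bad))
    stop("occurrence cell_id not in grid: ", paste(bad, collapse = ", "))
  if (!is.null(tree)) {
    miss <- setdiff(records$species, tree$tip.label)
    if (length(miss)) {
      if (unmatched == "error")
        stop("species not in tree: ", paste(miss, collapse = ", "))
      warning("dropping ", length(miss), " species not in tree: ",
              paste(miss, collapse = ", "))
      records <- records[!records$species %in% miss, , drop = FALSE]
    }
  }
  species <- sort(unique(records$species))
  m <- matrix(0L, nrow = nrow(grid), ncol = length(species),
              dimnames = list(grid$cell_id, species))
  if (nrow(records)) {
    m[cbind(match(records$cell_id, grid$cell_id),
            match(records$species, species))] <- 1L
  } else {
    warning("no occurrence records: empty matrix")
  }
  as_ps_occ(m, grid)
}

as_ps_occ <- function(m, grid) {
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L))) stop("occurrence values must be 0/1")
  attr(m, "grid") <- grid
  class(m) <- c("ps_occ", class(m))
  m
}

occ_grid <- function(occ) attr(occ, "grid")

#' Per-species range sizes (occupied cell counts)
#' @param occ a `ps_occ` matrix.
#' @return named integer vector of occupied-cell counts per species.
#' @export
range_sizes <- function(occ) colSums(occ == 1L)

#' @rdname read_occurrences
#' @param occ a `ps_occ` matrix.
#' @param path output CSV path (wide cells-by-species matrix).
#' @export
write_occurrences <- function(occ, path) {
  df <- data.frame(cell_id = rownames(occ), unclass(occ)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_occurrences
#' @export
read_occurrence_matrix <- function(path, grid) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df$cell_id)
  if (!identical(rownames(m), grid$cell_id))
    stop("occurrence matrix rows do not match grid cell ids")
  as_ps_occ(m, grid)
}

#' Read and write ESRI ASCII grid rasters
#'
#' A minimal reader/writer for the plain-text ESRI ASCII grid format
#' (`ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` header followed
#' by rows of values, top row first).
#'
#' @param path file path.
#' @return `read_asc()` returns a list with `values` (matrix, row 1 = top /
#'   largest y), `xll`, `yll`, `cellsize`; NODATA cells are `NA`.
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list(); i <- 1
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) == 2 && grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      i <- i + 1
    } else break
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[k]])) stop("ASCII grid header missing ", k)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid body has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  list(values = m, xll = hdr$xllcorner, yll = hdr$yllcorner,
       cellsize = hdr$cellsize)
}

#' @rdname read_asc
#' @param raster a list as returned by `read_asc()`.
#' @export
write_asc <- function(raster, path) {
  m <- raster$values
  hdr <- c(sprintf("ncols %d", ncol(m)), sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.10g", raster$xll),
           sprintf("yllcorner %.10g", raster$yll),
           sprintf("cellsize %.10g", raster$cellsize),
           "NODATA_value -9999")
  m[is.na(m)] <- -9999
  body <- apply(m, 1, function(r) paste(format(r, trim = TRUE, digits = 10),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# Centers of raster cells: x of column j, y of row i (row 1 = top).
asc_centers <- function(raster) {
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  list(x = raster$xll + (seq_len(nc) - 0.5) * raster$cellsize,
       y = raster$yll + (nr - seq_len(nr) + 0.5) * raster$cellsize)
}

#' Align a raster onto an analysis grid
#'
#' Resamples a raster (in the same coordinate system as the grid; no
#' reprojection) to one value per grid cell. `"mean"` averages all source
#' cells whose centers fall inside the target cell square; `"nearest"` takes
#' the source cell containing the centroid; `"bilinear"` interpolates
#' between the four surrounding source cell centers. Target cells with no
#' usable source data become `NA`.
#'
#' @param raster a list as returned by [read_asc()].
#' @param grid a `ps_grid`.
#' @param method one of `"mean"`, `"bilinear"`, `"nearest"`.
#' @param name,units metadata for the resulting layer.
#' @return a `ps_layer` on `grid`.
#' @export
align_layer <- function(raster, grid, method = c("mean", "bilinear", "nearest"),
                        name = "layer", units = "") {
  method <- match.arg(method)
  ctr <- asc_centers(raster)
  rx <- range(ctr$x) + c(-0.5, 0.5) * raster$cellsize
  ry <- range(ctr$y) + c(-0.5, 0.5) * raster$cellsize
  cs <- cell_size(grid)
  gx <- range(grid$x) + c(-0.5, 0.5) * cs
  gy <- range(grid$y) + c(-0.5, 0.5) * cs
  if (gx[2] <= rx[1] || gx[1] >= rx[2] || gy[2] <= ry[1] || gy[1] >= ry[2])
    stop("raster and grid extents are disjoint")
  m <- raster$values
  vals <- vapply(seq_len(nrow(grid)), function(i) {
    cx <- grid$x[i]; cy <- grid$y[i]
    if (method == "mean") {
      inx <- which(ctr$x >= cx - cs / 2 & ctr$x < cx + cs / 2)
      iny <- which(ctr$y >= cy - cs / 2 & ctr$y < cy + cs / 2)
      if (!length(inx) || !length(iny)) return(NA_real_)
      v <- m[iny, inx]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    } else if (method == "nearest") {
      jx <- which.min(abs(ctr$x - cx)); jy <- which.min(abs(ctr$y - cy))
      if (abs(ctr$x[jx] - cx) > raster$cellsize / 2 + 1e-9 ||
          abs(ctr$y[jy] - cy) > raster$cellsize / 2 + 1e-9) return(NA_real_)
      m[jy, jx]
    } else { # bilinear on the 4 surrounding centers
      if (cx < min(ctr$x) || cx > max(ctr$x) ||
          cy < min(ctr$y) || cy > max(ctr$y)) return(NA_real_)
      jx1 <- max(which(ctr$x <= cx)); jx2 <- min(jx1 + 1, length(ctr$x))
      # ctr$y is decreasing in row index
      jy2 <- max(which(ctr$y >= cy)); jy1 <- min(jy2 + 1, length(ctr$y))
      tx <- if (jx2 == jx1) 0 else (cx - ctr$x[jx1]) / (ctr$x[jx2] - ctr$x[jx1])
      ty <- if (jy1 == jy2) 0 else (cy - ctr$y[jy1]) / (ctr$y[jy2] - ctr$y[jy1])
      v <- c(m[jy1, jx1], m[jy1, jx2], m[jy2, jx1], m[jy2, jx2])
      if (anyNA(v)) return(NA_real_)
      (1 - ty) * ((1 - tx) * v[1] + tx * v[2]) +
        ty * ((1 - tx) * v[3] + tx * v[4])
    }
  }, numeric(1))
  new_layer(grid, vals, name = name, units = units)
}
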