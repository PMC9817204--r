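#' Branch range table: which grid cells each branch reaches
#'
#' For every edge of the tree, the branch's geographical range is the union
#' of the occupied cells of its descendant tips. This table is the shared
#' backbone of the per-cell PD and PE computations: a branch contributes its
#' full length to PD in every cell of its range, and length / range-size to
#' PE (Rosauer's apportionment, so every branch's length is divided across
#' the cells it reaches).
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param occ a `ps_occ` occurrence matrix; its species must all be tips of
#'   `tree` (tips without occurrences simply have empty ranges).
#' @return a list with `length` (per edge), `range` (logical edges-by-cells
#'   matrix), `range_size` (per edge, in cells), and `edge` (ape edge matrix).
#' @export
branch_range_table <- function(tree, occ) {
  miss <- setdiff(colnames(occ), tree$tip.label)
  if (length(miss))
    stop("occurrence species not in tree: ", paste(miss, collapse = ", "))
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  n_cell <- nrow(occ)
  # per-node cell range, built tips-up in postorder
  node_range <- matrix(FALSE, nrow = n_node, ncol = n_cell)
  hit <- match(colnames(occ), tree$tip.label)
  node_range[hit, ] <- t(occ == 1L)
  po <- ape::postorder(tree)
  for (e in po) {
    par <- tree$edge[e, 1]; chd <- tree$edge[e, 2]
    node_range[par, ] <- node_range[par, ] | node_range[chd, ]
  }
  rng <- node_range[tree$edge[, 2], , drop = FALSE]
  colnames(rng) <- rownames(occ)
  list(length = tree$edge.length, range = rng,
       range_size = rowSums(rng), edge = tree$edge)
}

#' Faith's phylogenetic diversity of a species set
#'
#' Rooted PD: the total branch length of the union of root-to-tip paths of
#' the given species, so a single species contributes its full path to the
#' root and the empty set has PD 0.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param present character vector of tip labels.
#' @return PD in branch-length units.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' compute_pd(tr, c("A", "B", "C"))  # 5
#' compute_pd(tr, "A")               # 2
#' @export
compute_pd <- function(tree, present) {
  present <- unique(as.character(present))
  bad <- setdiff(present, tree$tip.label)
  if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
  if (!length(present)) return(0)
  n_node <- max(tree$edge)
  on_path <- logical(n_node)
  on_path[match(present, tree$tip.label)] <- TRUE
  po <- ape::postorder(tree)
  for (e in po)
    on_path[tree$edge[e, 1]] <- on_path[tree$edge[e, 1]] ||
      on_path[tree$edge[e, 2]]
  sum(tree$edge.length[on_path[tree$edge[, 2]]])
}

#' Per-cell PD, PE, WE and richness
#'
#' `compute_pd_cells()` evaluates rooted PD for every grid cell at once;
#' `compute_pe()` evaluates phylogenetic endemism, where each branch length
#' is divided by the branch's range size (cells) before being summed over
#' the branches on the cell's root spanning path; `compute_we()` is weighted
#' endemism, the sum of inverse species range sizes over the cell's species.
#' Cells with no species score 0 on all three.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param occ a `ps_occ` matrix.
#' @param brt optional precomputed [branch_range_table()] (reused across the
#'   null-model replicates).
#' @return named numeric vector, one value per cell in grid order.
#' @export
compute_pd_cells <- function(tree, occ, brt = branch_range_table(tree, occ)) {
  v <- as.numeric(crossprod(brt$range, brt$length))
  names(v) <- rownames(occ)
  v
}

#' @rdname compute_pd_cells
#' @export
compute_pe <- function(tree, occ, brt = branch_range_table(tree, occ)) {
  w <- ifelse(brt$range_size > 0, brt$length / brt$range_size, 0)
  v <- as.numeric(crossprod(brt$range, w))
  names(v) <- rownames(occ)
  v
}

#' @rdname compute_pd_cells
#' @export
compute_we <- function(occ) {
  rs <- range_sizes(occ)
  inv <- ifelse(rs > 0, 1 / rs, 0)
  v <- as.numeric(occ %*% inv)
  names(v) <- rownames(occ)
  v
}

#' @rdname compute_pd_cells
#' @return `diversity_table()` returns a data frame with one row per cell:
#'   `cell_id`, `richness`, `pd`, `pe`, `we`.
#' @export
diversity_table <- function(tree, occ) {
  brt <- branch_range_table(tree, occ)
  data.frame(
    cell_id = rownames(occ),
    richness = as.integer(rowSums(occ == 1L)),
    pd = compute_pd_cells(tree, occ, brt),
    pe = compute_pe(tree, occ, brt),
    we = compute_we(occ),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Remove range-restricted species
#'
#' Species occupying fewer than `min_range_cells` grid cells are removed
#' before modelling: extreme micro-endemics concentrate outsized PE scores
#' in one or two cells and destabilize regression fits. The default of 3
#' removes species confined to at most 2 cells.
#'
#' @param occ a `ps_occ` matrix.
#' @param min_range_cells minimum occupied-cell count to keep a species.
#' @return list with `occ` (filtered matrix) and `removed` (data frame of
#'   species and their range sizes).
#' @export
filter_restricted_species <- function(occ, min_range_cells = 3) {
  rs <- range_sizes(occ)
  drop <- names(rs)[rs < min_range_cells]
  removed <- data.frame(species = drop, range_size = unname(rs[drop]),
                        stringsAsFactors = FALSE)
  keep <- setdiff(colnames(occ), drop)
  out <- as_ps_occ(unclass(occ)[, keep, drop = FALSE], occ_grid(occ))
  list(occ = out, removed = removed)
}
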