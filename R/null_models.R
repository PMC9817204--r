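#' Tip-shuffle null model
#'
#' Permutes the allocation of species to tree tips uniformly at random,
#' keeping the topology, the branch lengths and the community matrix fixed.
#' Under this null, a cell's PD distribution depends only on its richness.
#'
#' @param tree a `phylo`.
#' @param seed optional integer; when given, the shuffle is deterministic.
#' @return a `phylo` with permuted tip labels.
#' @export
tip_shuffle <- function(tree, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- tree
  out$tip.label <- sample(tree$tip.label)
  out
}

#' Fixed-fixed community randomization (independent swap)
#'
#' Sequential checkerboard swaps: each iteration draws two cells and two
#' species at random and, if the 2x2 submatrix is a checkerboard
#' (`10/01` or `01/10`), flips it. Row sums (cell richness) and column sums
#' (species range sizes) are preserved exactly at every step. Iterations are
#' attempted swaps; by default 10 times the number of presences.
#'
#' @param occ a `ps_occ` matrix with at least 2 cells and 2 species.
#' @param n_iterations number of attempted swaps.
#' @param seed optional integer for a deterministic result.
#' @return a randomized `ps_occ` with identical margins. If no swap was
#'   performed (e.g. the matrix has no checkerboard submatrix), the input is
#'   returned with a warning.
#' @export
independent_swap <- function(occ, n_iterations = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- unclass(occ)
  attr(m, "grid") <- NULL
  nr <- nrow(m); nc <- ncol(m)
  if (is.null(n_iterations)) n_iterations <- 10L * sum(m)
  if (nr < 2 || nc < 2) {
    warning("matrix too small to swap; returned unchanged")
    return(occ)
  }
  swapped <- 0L
  for (it in seq_len(n_iterations)) {
    r <- sample.int(nr, 2L)
    c <- sample.int(nc, 2L)
    a <- m[r[1], c[1]]; b <- m[r[1], c[2]]
    d <- m[r[2], c[1]]; e <- m[r[2], c[2]]
    if (a + e == 2L && b + d == 0L) {
      m[r[1], c[1]] <- 0L; m[r[2], c[2]] <- 0L
      m[r[1], c[2]] <- 1L; m[r[2], c[1]] <- 1L
      swapped <- swapped + 1L
    } else if (a + e == 0L && b + d == 2L) {
      m[r[1], c[1]] <- 1L; m[r[2], c[2]] <- 1L
      m[r[1], c[2]] <- 0L; m[r[2], c[1]] <- 0L
      swapped <- swapped + 1L
    }
  }
  if (swapped == 0L)
    warning("no checkerboard swap performed; matrix returned unchanged")
  as_ps_occ(m, occ_grid(occ))
}

#' Permutation null distribution of per-cell PD or PE
#'
#' Recomputes the chosen metric for `n_reps` randomized datasets (one
#' randomization shared by all cells per replicate, as in a whole-map
#' randomization) and summarizes per cell: null mean and sd, standardized
#' effect size SES = (obs - mean)/sd, and a rank p-value.
#'
#' The p-value pools the observed value with the replicates, counting ties
#' (within a relative tolerance of 1e-9) as half:
#' `p = (#\{null < obs\} + 0.5 #\{null = obs\} + 0.5) / (n_reps + 1)`.
#' A cell whose metric is invariant under the null (e.g. a cell holding all
#' species under tip shuffle) therefore gets p = 0.5 exactly, and its SES is
#' reported as 0 with `degenerate = TRUE` (null sd 0), never NaN, so the null
#' mean stays usable as a model covariate.
#'
#' @param tree a `phylo`.
#' @param occ a `ps_occ` matrix.
#' @param metric `"PD"` or `"PE"`.
#' @param null `"tip_shuffle"` (randomize tip labels) or
#'   `"independent_swap"` (fixed-fixed matrix randomization).
#' @param n_reps number of replicates (999 by default).
#' @param seed optional integer; fixes the whole replicate stream.
#' @param swap_iterations attempted swaps per independent-swap replicate
#'   (default 10 x presences).
#' @return a data frame of class `ps_null` with one row per cell:
#'   `cell_id, observed, null_mean, null_sd, ses, p, degenerate`; attributes
#'   `metric`, `null`, `n_reps`.
#' @export
null_distribution <- function(tree, occ, metric = c("PD", "PE"),
                              null = c("tip_shuffle", "independent_swap"),
                              n_reps = 999, seed = NULL,
                              swap_iterations = NULL) {
  metric <- match.arg(metric)
  null <- match.arg(null)
  if (!is.null(seed)) set.seed(seed)
  metric_fun <- function(tr, oc)
    if (metric == "PD") compute_pd_cells(tr, oc) else compute_pe(tr, oc)
  obs <- metric_fun(tree, occ)
  n_cell <- length(obs)
  s <- numeric(n_cell); s2 <- numeric(n_cell)
  n_less <- numeric(n_cell); n_tie <- numeric(n_cell)
  tol <- 1e-9 * (1 + abs(obs))
  for (r in seq_len(n_reps)) {
    if (null == "tip_shuffle") {
      v <- metric_fun(tip_shuffle(tree), occ)
    } else {
      v <- metric_fun(tree, suppressWarnings(
        independent_swap(occ, n_iterations = swap_iterations)))
    }
    d <- v - obs   # shifted accumulation avoids cancellation when the
    s <- s + d     # null is constant (label-invariant cells)
    s2 <- s2 + d * d
    tie <- abs(d) <= tol
    n_tie <- n_tie + tie
    n_less <- n_less + (d < 0 & !tie)
  }
  mu <- obs + s / n_reps
  varr <- pmax(0, s2 - s^2 / n_reps) / max(1, n_reps - 1)
  sd <- sqrt(varr)
  degenerate <- sd <= 1e-12 * (1 + abs(mu))
  ses <- ifelse(degenerate, 0, (obs - mu) / ifelse(degenerate, 1, sd))
  p <- (n_less + 0.5 * n_tie + 0.5) / (n_reps + 1)
  out <- data.frame(cell_id = names(obs), observed = unname(obs),
                    null_mean = unname(mu), null_sd = unname(sd),
                    ses = unname(ses), p = unname(p),
                    degenerate = unname(degenerate),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "metric") <- metric
  attr(out, "null") <- null
  attr(out, "n_reps") <- n_reps
  class(out) <- c("ps_null", "data.frame")
  out
}

#' Flag cells whose observed value exceeds the null
#'
#' One-sided, high tail: a cell is significant when its rank p-value is
#' strictly greater than the threshold (observed larger than expected).
#'
#' @param summary a `ps_null` data frame from [null_distribution()].
#' @param threshold significance threshold on p (default .95).
#' @return the summary with a logical `significant` column appended.
#' @export
classify_significant <- function(summary, threshold = 0.95) {
  summary$significant <- summary$p > threshold
  summary
}
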