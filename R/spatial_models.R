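#' Distance-band spatial weights
#'
#' Neighbors of a cell are all cells whose centroid lies within Euclidean
#' distance `d_max` (self excluded). The neighbor relation is symmetric;
#' weights are row-standardized ("W" coding), so each nonempty row sums
#' to 1. Cells with no neighbor ("islands") are an error by default since a
#' spatial-error model is undefined for them; `drop_islands = TRUE` removes
#' them with a warning instead.
#'
#' @param coords 2-column matrix (x, y) of cell centroids, rownames = ids.
#' @param d_max neighbor distance threshold, in map units.
#' @param drop_islands drop zero-neighbor cells instead of erroring.
#' @return a `ps_weights` list: `ids`, `coords`, `i`, `j`, `w` (triplet
#'   row-standardized weights), `d_max`, `n`.
#' @export
build_weights <- function(coords, d_max, drop_islands = FALSE) {
  coords <- as.matrix(coords)
  ids <- rownames(coords) %||% as.character(seq_len(nrow(coords)))
  D <- as.matrix(stats::dist(coords))
  nb <- D <= d_max & D > 0
  deg <- rowSums(nb)
  if (any(deg == 0)) {
    isl <- ids[deg == 0]
    if (!drop_islands)
      stop("cells with no neighbor at d_max = ", d_max, ": ",
           paste(isl, collapse = ", "),
           " (raise d_max or use drop_islands = TRUE)")
    warning("dropping ", length(isl), " island cell(s): ",
            paste(isl, collapse = ", "))
    keep <- deg > 0
    coords <- coords[keep, , drop = FALSE]
    ids <- ids[keep]
    nb <- nb[keep, keep, drop = FALSE]
    deg <- rowSums(nb)
  }
  idx <- which(nb, arr.ind = TRUE)
  w <- 1 / deg[idx[, 1]]
  structure(list(ids = ids, coords = coords,
                 i = unname(idx[, 1]), j = unname(idx[, 2]),
                 w = unname(w), d_max = d_max, n = length(ids)),
            class = "ps_weights")
}

#' @export
print.ps_weights <- function(x, ...) {
  cat("<ps_weights> ", x$n, " cells, distance band d_max = ", x$d_max,
      ", ", length(x$w), " links, row-standardized\n", sep = "")
  invisible(x)
}

# triplet weights -> W %*% m for a vector or matrix m
weights_mult <- function(weights, m) {
  m <- as.matrix(m)
  out <- matrix(0, nrow = weights$n, ncol = ncol(m))
  for (k in seq_len(ncol(m))) {
    tmp <- rowsum(weights$w * m[weights$j, k], weights$i)
    out[as.integer(rownames(tmp)), k] <- tmp
  }
  out
}

# Moran's I machinery on arbitrary triplet weights (w_ij, i != j)
moran_stat <- function(values, i, j, w, n) {
  z <- values - mean(values)
  s0 <- sum(w)
  if (s0 <= 0) stop("empty weights")
  den <- sum(z^2)
  if (den <= 0) stop("Moran's I undefined for constant values")
  I <- (n / s0) * sum(w * z[i] * z[j]) / den
  # S1 = 1/2 sum_{i,j} (w_ij + w_ji)^2 = sum over unordered pairs of t^2,
  # with t the two-direction weight sum for the pair
  ukey <- paste(pmin(i, j), pmax(i, j))
  t_u <- rowsum(w, ukey)
  s1 <- sum(t_u^2)
  # S2 = sum_i (row-sum_i + col-sum_i)^2
  rs <- numeric(n); cs <- numeric(n)
  tmp <- rowsum(w, i); rs[as.integer(rownames(tmp))] <- tmp
  tmp <- rowsum(w, j); cs[as.integer(rownames(tmp))] <- tmp
  s2 <- sum((rs + cs)^2)
  e_i <- -1 / (n - 1)
  var_i <- (n^2 * s1 - n * s2 + 3 * s0^2) / ((n^2 - 1) * s0^2) - e_i^2
  z_stat <- (I - e_i) / sqrt(var_i)
  p <- 2 * stats::pnorm(-abs(z_stat))
  list(I = I, expected = e_i, variance = var_i, p = p)
}

#' Global Moran's I under the normality approximation
#'
#' I = (n/S0) (sum_ij w_ij z_i z_j) / (sum_i z_i^2) with z the centered
#' values; expectation -1/(n-1); variance and two-sided p-value from the
#' normal approximation.
#'
#' @param values per-cell numeric vector (length = number of weight cells).
#' @param weights a `ps_weights`.
#' @return list with `I`, `expected`, `variance`, `p`.
#' @export
morans_i <- function(values, weights) {
  values <- as.numeric(values)
  if (length(values) != weights$n)
    stop("values length does not match weights")
  if (weights$n < 3) stop("Moran's I needs at least 3 cells")
  if (anyNA(values)) stop("missing values not allowed in morans_i")
  moran_stat(values, weights$i, weights$j, weights$w, weights$n)
}

#' Moran correlogram over distance classes
#'
#' Splits centroid pairs into contiguous distance classes (0, inc],
#' (inc, 2 inc], ... and evaluates Moran's I per class with binary weights
#' (1 for pairs in the class). Classes with fewer than 2 pairs are flagged
#' and carry NA statistics rather than being dropped.
#'
#' @param values per-cell numeric vector.
#' @param coords 2-column centroid matrix.
#' @param increment distance-class width (default 0.52 map units).
#' @param max_distance largest class bound; defaults to the maximum pair
#'   distance.
#' @return data frame of class `ps_correlogram`: `lower`, `upper`,
#'   `n_pairs`, `I`, `expected`, `variance`, `p`, `flagged`.
#' @export
correlogram <- function(values, coords, increment = 0.52,
                        max_distance = NULL) {
  coords <- as.matrix(coords)
  values <- as.numeric(values)
  stopifnot(nrow(coords) == length(values), increment > 0)
  n <- length(values)
  D <- as.matrix(stats::dist(coords))
  if (is.null(max_distance)) max_distance <- max(D)
  breaks <- seq(0, max_distance + increment * 1e-9, by = increment)
  if (breaks[length(breaks)] < max_distance)
    breaks <- c(breaks, breaks[length(breaks)] + increment)
  out <- data.frame(lower = breaks[-length(breaks)], upper = breaks[-1])
  out$n_pairs <- NA_integer_; out$I <- NA_real_
  out$expected <- NA_real_; out$variance <- NA_real_; out$p <- NA_real_
  out$flagged <- FALSE
  for (k in seq_len(nrow(out))) {
    sel <- D > out$lower[k] & D <= out$upper[k]
    diag(sel) <- FALSE
    idx <- which(sel, arr.ind = TRUE)
    out$n_pairs[k] <- nrow(idx) / 2
    if (out$n_pairs[k] < 2) {
      out$flagged[k] <- TRUE
      next
    }
    st <- tryCatch(
      moran_stat(values, idx[, 1], idx[, 2], rep(1, nrow(idx)), n),
      error = function(e) NULL)
    if (is.null(st)) { out$flagged[k] <- TRUE; next }
    out$I[k] <- st$I; out$expected[k] <- st$expected
    out$variance[k] <- st$variance; out$p[k] <- st$p
  }
  class(out) <- c("ps_correlogram", "data.frame")
  out
}

#' Neighborhood distance from a correlogram
#'
#' Scans the distance classes outward from zero and returns the upper bound
#' of the first class whose autocorrelation is not significant at `alpha`
#' (flagged classes are skipped). If every assessable class is significant,
#' the largest bound is returned with a warning.
#'
#' @param corr a `ps_correlogram`.
#' @param alpha significance level (default .05).
#' @param bonferroni divide `alpha` by the number of assessable classes
#'   before scanning (off by default; a stricter per-class level makes
#'   classes nonsignificant earlier and so shrinks `d_max`).
#' @return `d_max`, a distance in map units.
#' @export
neighbor_threshold <- function(corr, alpha = 0.05, bonferroni = FALSE) {
  ok <- !corr$flagged & !is.na(corr$p)
  if (bonferroni) alpha <- alpha / sum(ok)
  hit <- which(ok & corr$p >= alpha)
  if (length(hit)) return(corr$upper[hit[1]])
  warning("all correlogram classes significant; using the maximum distance")
  max(corr$upper[ok])
}

# Eigenvalues of the row-standardized weights: W = D^-1 B is similar to the
# symmetric D^-1/2 B D^-1/2, so the spectrum is real.
weights_eigen <- function(weights) {
  n <- weights$n
  deg <- numeric(n)
  deg[sort(unique(weights$i))] <-
    rowsum(rep(1, length(weights$i)), weights$i)
  B <- matrix(0, n, n)
  B[cbind(weights$i, weights$j)] <- 1
  s <- 1 / sqrt(deg)
  M <- B * outer(s, s)
  eigen(M, symmetric = TRUE, only.values = TRUE)$values
}

#' Maximum-likelihood spatial-error autoregressive model
#'
#' Fits y = X beta + u with spatially autocorrelated errors
#' u = lambda W u + eps, eps ~ N(0, sigma^2 I), by concentrated maximum
#' likelihood: for each trial lambda the data are spatially filtered
#' (A = I - lambda W), beta and sigma^2 drop out in closed form, and
#' log L(lambda) = log|A| - (n/2)(log(2 pi sigma^2(lambda)) + 1)
#' is maximized by golden-section/Brent search (tolerance 1e-8) on the
#' feasible interval (1/omega_min, 1/omega_max) given by the extreme
#' eigenvalues of W (computed exactly via the symmetrized weights).
#' Coefficient standard errors are the GLS ones at the ML lambda; AIC counts
#' k = |beta| + 2 parameters (lambda and sigma^2).
#'
#' @param y response vector (complete cases only).
#' @param X design matrix including an intercept column.
#' @param weights a `ps_weights` over the same cells as `y`.
#' @param ev optional precomputed eigenvalues of W (reused across fits).
#' @param lambda optional fixed value of the spatial-error parameter; when
#'   given the likelihood search is skipped (at `lambda = 0` the fit reduces
#'   exactly to ordinary least squares).
#' @return a `ps_sarfit` list: `coefficients` (estimate, se, z, p),
#'   `lambda`, `sigma2`, `logLik`, `AIC`, `n`, `k`, plus `y`, `fitted`,
#'   `residuals`, and `logLik_lm_null` (non-spatial intercept-only fit, the
#'   default yardstick for [nagelkerke_r2()]).
#' @export
fit_sar_error <- function(y, X, weights, ev = NULL, lambda = NULL) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(n == nrow(X), n == weights$n)
  if (anyNA(y) || anyNA(X)) stop("complete cases required")
  if (qr(X)$rank < ncol(X)) stop("singular design matrix")
  if (is.null(ev)) ev <- weights_eigen(weights)
  lo <- 1 / min(ev); hi <- 1 / max(ev)
  eps <- 1e-6 * (hi - lo)
  Wy <- weights_mult(weights, y)
  WX <- weights_mult(weights, X)
  profile <- function(lambda) {
    ys <- y - lambda * Wy
    Xs <- X - lambda * WX
    fit <- stats::lm.fit(Xs, ys)
    s2 <- sum(fit$residuals^2) / n
    ldet <- sum(log(1 - lambda * ev))
    ll <- ldet - (n / 2) * (log(2 * pi * s2) + 1)
    list(ll = ll, beta = fit$coefficients, s2 = s2, Xs = Xs, ys = ys,
         res = fit$residuals)
  }
  if (is.null(lambda)) {
    opt <- stats::optimize(function(l) profile(l)$ll,
                           interval = c(lo + eps, hi - eps),
                           maximum = TRUE, tol = 1e-8)
    lambda <- opt$maximum
  } else {
    stopifnot(lambda > lo, lambda < hi)
  }
  at <- profile(lambda)
  if (!is.finite(at$ll)) stop("non-finite likelihood at the optimum")
  XtXi <- chol2inv(qr.R(qr(at$Xs)))
  se <- sqrt(at$s2 * diag(XtXi))
  beta <- at$beta
  z <- beta / se
  pval <- 2 * stats::pnorm(-abs(z))
  k <- length(beta) + 2
  coef_tab <- data.frame(term = colnames(X) %||% paste0("b", seq_along(beta)),
                         estimate = unname(beta), se = unname(se),
                         z = unname(z), p = unname(pval),
                         stringsAsFactors = FALSE)
  # non-spatial intercept-only ML log-likelihood for pseudo-R2
  s2_0 <- mean((y - mean(y))^2)
  ll0 <- -(n / 2) * (log(2 * pi * s2_0) + 1)
  structure(list(coefficients = coef_tab, lambda = lambda, sigma2 = at$s2,
                 logLik = at$ll, AIC = -2 * at$ll + 2 * k, n = n, k = k,
                 y = y, fitted = y - at$res, residuals = at$res,
                 logLik_lm_null = ll0, ev_range = c(lo, hi)),
            class = "ps_sarfit")
}

#' @export
print.ps_sarfit <- function(x, ...) {
  cat("Spatial-error SAR (ML): n =", x$n, " lambda =", signif(x$lambda, 4),
      " logLik =", signif(x$logLik, 6), " AIC =", signif(x$AIC, 6), "\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Nagelkerke pseudo R-squared
#'
#' R2 = (1 - exp(-(2/n)(logL_M - logL_0))) / (1 - exp((2/n) logL_0)),
#' the Cox-Snell ratio rescaled to a [0, 1] maximum. The default null is
#' the NON-spatial intercept-only Gaussian fit to the same response.
#'
#' @param fit a `ps_sarfit`.
#' @param null_logL optional alternative null log-likelihood.
#' @return pseudo R-squared.
#' @export
nagelkerke_r2 <- function(fit, null_logL = NULL) {
  ll0 <- null_logL %||% fit$logLik_lm_null
  n <- fit$n
  cs <- 1 - exp(-(2 / n) * (fit$logLik - ll0))
  maxr2 <- 1 - exp((2 / n) * ll0)
  # with a continuous response the density can exceed 1, pushing the ratio
  # marginally outside [0, 1]; truncate to the nominal range
  min(max(cs / maxr2, 0), 1)
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Exhaustive all-subsets SAR model selection by AIC
#'
#' Fits a spatial-error SAR for every subset of the candidate predictors
#' (including the intercept-only model), always keeping `extra_fixed`
#' covariates (e.g. the null-model expected value) in the design, and ranks
#' the fits by AIC.
#'
#' @param y response vector.
#' @param candidates cells-by-predictors numeric matrix with column names
#'   (at most 15 candidates; 2^15 fits is the documented ceiling).
#' @param weights a `ps_weights` over the same cells.
#' @param extra_fixed optional matrix/vector of always-included covariates.
#' @return a `ps_ranking` list: `table` (one row per model, AIC-ascending,
#'   with `model`, `k`, `logLik`, `AIC`, `dAIC`, `lambda`, `r2`), `best`
#'   (the best `ps_sarfit`), and `best_coefficients` with significance
#'   stars at .05/.01/.001.
#' @export
all_subsets_selection <- function(y, candidates, weights, extra_fixed = NULL) {
  candidates <- as.matrix(candidates)
  if (is.null(colnames(candidates))) stop("candidates need column names")
  p <- ncol(candidates)
  if (p > 15) stop("at most 15 candidate predictors (2^15 fits)")
  if (!is.null(extra_fixed)) {
    extra_fixed <- as.matrix(extra_fixed)
    if (is.null(colnames(extra_fixed)))
      colnames(extra_fixed) <- paste0("fixed", seq_len(ncol(extra_fixed)))
  }
  ev <- weights_eigen(weights)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  rows <- vector("list", nrow(subsets))
  fits <- vector("list", nrow(subsets))
  for (s in seq_len(nrow(subsets))) {
    sel <- unlist(subsets[s, ])
    X <- cbind(`(Intercept)` = 1, extra_fixed,
               candidates[, sel, drop = FALSE])
    fit <- fit_sar_error(y, X, weights, ev = ev)
    fits[[s]] <- fit
    rows[[s]] <- data.frame(
      model = if (any(sel)) paste(colnames(candidates)[sel], collapse = "+")
              else "(intercept)",
      k = fit$k, logLik = fit$logLik, AIC = fit$AIC, lambda = fit$lambda,
      r2 = nagelkerke_r2(fit), stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  ord <- order(tab$AIC)
  tab <- tab[ord, ]
  tab$dAIC <- tab$AIC - tab$AIC[1]
  rownames(tab) <- NULL
  best <- fits[[ord[1]]]
  bc <- best$coefficients
  bc$stars <- significance_stars(bc$p)
  structure(list(table = tab, best = best, best_coefficients = bc),
            class = "ps_ranking")
}

#' @export
print.ps_ranking <- function(x, ...) {
  cat("SAR all-subsets selection:", nrow(x$table), "models\n")
  print(utils::head(x$table, 10), digits = 4)
  cat("Best model coefficients:\n")
  print(x$best_coefficients, digits = 4)
  invisible(x)
}
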