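make_rook_weights <- function(nx, ny) {
  g <- make_grid(nx, ny)
  co <- as.matrix(g[, c("x", "y")]); rownames(co) <- g$cell_id
  list(grid = g, coords = co, w = build_weights(co, 1.01))
}

test_that("distance-band weights are row-standardized and symmetric", {
  rk <- make_rook_weights(4, 4)
  w <- rk$w
  rowsums <- tapply(w$w, w$i, sum)
  expect_true(all(abs(rowsums - 1) < 1e-12))
  # symmetric neighbor relation before standardization
  pairs <- paste(w$i, w$j)
  expect_true(all(paste(w$j, w$i) %in% pairs))
  # interior rook cells have 4 neighbors at 1/4
  deg <- table(w$i)
  expect_equal(unname(deg[["6"]]), 4)
  expect_equal(w$w[w$i == 6], rep(0.25, 4))
  # two cells within range weight each other fully
  co2 <- matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE,
                dimnames = list(c("a", "b"), NULL))
  w2 <- build_weights(co2, 1.5)
  expect_equal(w2$w, c(1, 1))
})

test_that("islands are a hard error unless dropped explicitly", {
  co <- matrix(c(0, 0, 1, 0, 50, 50), 3, 2, byrow = TRUE,
               dimnames = list(c("a", "b", "far"), NULL))
  expect_error(build_weights(co, 2), "far")
  expect_warning(w <- build_weights(co, 2, drop_islands = TRUE), "island")
  expect_equal(w$ids, c("a", "b"))
})

test_that("morans_i matches the naive double-loop oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    nx <- sample(4:7, 1); ny <- sample(3:6, 1)
    rk <- make_rook_weights(nx, ny)
    v <- rnorm(nrow(rk$grid))
    ours <- morans_i(v, rk$w)
    oracle <- moran_bruteforce(v, dense_W(rk$w))
    expect_equal(ours$I, oracle$I, tolerance = 1e-12)
    expect_equal(ours$expected, oracle$expected, tolerance = 1e-12)
    expect_equal(ours$variance, oracle$variance, tolerance = 1e-12)
    expect_equal(ours$expected, -1 / (nrow(rk$grid) - 1))
  }
})

test_that("morans_i agrees with ape's implementation", {
  rk <- make_rook_weights(5, 5)
  set.seed(2)
  v <- rnorm(25)
  W <- dense_W(rk$w)
  ref <- ape::Moran.I(v, W)
  ours <- morans_i(v, rk$w)
  expect_equal(ours$I, ref$observed, tolerance = 1e-9)
  expect_equal(ours$expected, ref$expected, tolerance = 1e-9)
})

test_that("a perfect checkerboard on a rook grid gives I = -1", {
  rk <- make_rook_weights(4, 4)
  v <- (as.numeric(factor(rk$grid$x)) + as.numeric(factor(rk$grid$y))) %% 2
  expect_equal(morans_i(v, rk$w)$I, -1, tolerance = 1e-12)
  expect_error(morans_i(rep(3, 16), rk$w), "constant")
})

test_that("smoothed fields are detected as autocorrelated", {
  g <- make_grid(10, 10)
  co <- as.matrix(g[, c("x", "y")]); rownames(co) <- g$cell_id
  w <- build_weights(co, 1.01)
  hits <- sapply(1:50, function(s) {
    f <- as.numeric(simulate_env_layers(g, 1, 4, seed = 500 + s)[[1]])
    st <- morans_i(f, w)
    st$I > 0 && st$p < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("the correlogram collapses to global Moran's I in one class", {
  rk <- make_rook_weights(5, 4)
  set.seed(6)
  v <- rnorm(20)
  co <- rk$coords
  dmax <- max(dist(co))
  corr <- correlogram(v, co, increment = dmax + 1)
  expect_equal(nrow(corr), 1)
  # all-pairs binary weights
  D <- as.matrix(dist(co))
  W <- (D > 0) * 1
  oracle <- moran_bruteforce(v, W)
  expect_equal(corr$I[1], oracle$I, tolerance = 1e-12)
})

test_that("white-noise correlograms stay near the null expectation", {
  g <- make_grid(8, 8)
  co <- as.matrix(g[, c("x", "y")])
  set.seed(7)
  v <- rnorm(64)
  corr <- correlogram(v, co, increment = 1.5)
  ok <- !corr$flagged
  z <- abs(corr$I[ok] - corr$expected[ok]) / sqrt(corr$variance[ok])
  expect_true(all(z < 4))
})

test_that("sparse distance classes are flagged, not dropped", {
  co <- matrix(c(0, 0, 0.1, 0, 10, 0), 3, 2, byrow = TRUE)
  corr <- correlogram(c(1, 2, 3), co, increment = 1, max_distance = 10)
  expect_true(any(corr$flagged))
  expect_equal(nrow(corr), 10)
})

test_that("neighbor_threshold applies the first-nonsignificant rule", {
  corr <- data.frame(lower = 0:3, upper = 1:4, n_pairs = 10,
                     I = 0.5, expected = -0.1, variance = 0.01,
                     p = c(.001, .001, .21, .001), flagged = FALSE)
  expect_equal(neighbor_threshold(corr), 3)
  corr$p <- c(.21, .001, .001, .001)
  expect_equal(neighbor_threshold(corr), 1)
  corr$p <- rep(.001, 4)
  expect_warning(d <- neighbor_threshold(corr), "all")
  expect_equal(d, 4)
})

test_that("the SAR fit at lambda = 0 is exactly OLS", {
  rk <- make_rook_weights(8, 8)
  set.seed(21)
  n <- 64
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(n), x2 = rnorm(n))
  y <- X %*% c(1, 0.5, -0.5) + rnorm(n)
  fit <- fit_sar_error(y, X, rk$w, lambda = 0)
  ols <- stats::lm.fit(X, y)
  expect_equal(fit$coefficients$estimate, unname(ols$coefficients),
               tolerance = 1e-12)
  free <- fit_sar_error(y, X, rk$w)
  expect_gte(free$logLik, fit$logLik - 1e-10)
})

test_that("the concentrated likelihood matches a dense-matrix oracle", {
  for (seed in 1:3) {
    rk <- make_rook_weights(6, 6)
    set.seed(seed + 30)
    n <- 36
    X <- cbind(1, rnorm(n))
    colnames(X) <- c("(Intercept)", "x1")
    y <- X %*% c(0.5, 1) + rnorm(n)
    fit <- fit_sar_error(y, X, rk$w)
    W <- dense_W(rk$w)
    expect_equal(fit$logLik, sar_loglik_dense(y, X, W, fit$lambda),
                 tolerance = 1e-6)
    # and at a fixed interior lambda
    f2 <- fit_sar_error(y, X, rk$w, lambda = 0.4)
    expect_equal(f2$logLik, sar_loglik_dense(y, X, W, 0.4),
                 tolerance = 1e-6)
  }
})

test_that("SAR recovers parameters from spatially correlated errors", {
  rk <- make_rook_weights(20, 20)
  W <- dense_W(rk$w)
  n <- 400
  A_inv <- solve(diag(n) - 0.6 * W)
  set.seed(41)
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(n), x2 = rnorm(n))
  beta <- c(1, 0.5, -0.5)
  y <- X %*% beta + A_inv %*% rnorm(n)
  fit <- fit_sar_error(y, X, rk$w)
  expect_lt(abs(fit$lambda - 0.6), 0.25)
  dev <- abs(fit$coefficients$estimate - beta) / fit$coefficients$se
  expect_true(all(dev < 3.5))
})

test_that("Nagelkerke pseudo R2 is 0 at the null and near 1 when exact", {
  rk <- make_rook_weights(7, 7)
  set.seed(23)
  n <- 49
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(n))
  y0 <- rnorm(n)
  fit0 <- fit_sar_error(y0, X, rk$w, lambda = 0)
  expect_equal(nagelkerke_r2(fit0, null_logL = fit0$logLik), 0)
  y <- X %*% c(1, 2) + 1e-5 * rnorm(n)
  fit <- fit_sar_error(y, X, rk$w, lambda = 0)
  expect_gt(nagelkerke_r2(fit), 0.99)
  expect_lte(nagelkerke_r2(fit), 1)
})

test_that("all-subsets selection enumerates, ranks and stars models", {
  rk <- make_rook_weights(10, 10)
  set.seed(25)
  n <- 100
  cand <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 1 + 2 * cand[, "a"] + rnorm(n)
  rank <- all_subsets_selection(y, cand, rk$w)
  expect_equal(nrow(rank$table), 8)  # 2^3 including intercept-only
  expect_equal(rank$table$dAIC[1], 0)
  expect_true(!is.unsorted(rank$table$AIC))
  expect_true(grepl("a", rank$table$model[1]))
  expect_true("stars" %in% names(rank$best_coefficients))
  # AIC differences unchanged by affine rescaling of predictors
  cand2 <- cand
  cand2[, "a"] <- cand[, "a"] * 100 - 7
  rank2 <- all_subsets_selection(y, cand2, rk$w)
  expect_equal(rank2$table$dAIC[match(rank2$table$model, rank$table$model)],
               rank$table$dAIC, tolerance = 1e-6)
})

test_that("an always-in covariate appears in every fitted model", {
  rk <- make_rook_weights(8, 8)
  set.seed(26)
  n <- 64
  cand <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  fixed <- cbind(nullmean = rnorm(n))
  y <- 1 + fixed[, 1] + rnorm(n)
  rank <- all_subsets_selection(y, cand, rk$w, extra_fixed = fixed)
  expect_true("nullmean" %in% rank$best_coefficients$term)
  expect_equal(nrow(rank$table), 4)
})
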