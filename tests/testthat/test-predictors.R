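test_that("terrain indices vanish on flat terrain", {
  g <- make_grid(5, 4)
  dem <- new_layer(g, rep(100, nrow(g)), "altitude", "m")
  ti <- terrain_indices(g, dem)
  expect_true(all(abs(as.numeric(ti$slope)) < 1e-12))
  expect_true(all(abs(as.numeric(ti$tpi)) < 1e-12))
  expect_true(all(abs(as.numeric(ti$tri)) < 1e-12))
})

test_that("an inclined plane has constant interior slope and zero TPI", {
  g <- make_grid(6, 6)
  dem <- new_layer(g, g$x, "altitude", "m")
  ti <- terrain_indices(g, dem)
  interior <- g$x > 1 & g$x < 5 & g$y > 1 & g$y < 5
  slopes <- as.numeric(ti$slope)[interior]
  expect_lt(diff(range(slopes)), 1e-12)
  expect_equal(slopes[1], atan(1) * 180 / pi)  # dz/dx = 1 in map units
  expect_true(all(abs(as.numeric(ti$tpi)[interior]) < 1e-12))
})

test_that("the 3x3 peak window gives TPI = TRI = 6", {
  g <- make_grid(3, 3)
  z <- rep(4, 9); z[5] <- 10
  ti <- terrain_indices(g, new_layer(g, z))
  expect_equal(unname(as.numeric(ti$tpi)[5]), 6)
  expect_equal(unname(as.numeric(ti$tri)[5]), 6)
})

test_that("terrain indices ignore elevation shifts; TRI/slope mirror", {
  g <- make_grid(5, 5)
  set.seed(12)
  z <- rnorm(25, 500, 50)
  a <- terrain_indices(g, new_layer(g, z))
  b <- terrain_indices(g, new_layer(g, z + 1234.5))
  expect_equal(as.numeric(a$slope), as.numeric(b$slope), tolerance = 1e-9)
  expect_equal(as.numeric(a$tpi), as.numeric(b$tpi), tolerance = 1e-9)
  expect_equal(as.numeric(a$tri), as.numeric(b$tri), tolerance = 1e-9)
  # x-reflection: mirrored DEM gives mirrored slope/TRI
  m <- matrix(z, 5, 5)
  zm <- as.numeric(m[, 5:1])
  am <- terrain_indices(g, new_layer(g, zm))
  sm <- matrix(as.numeric(am$slope), 5, 5)[, 5:1]
  expect_equal(as.numeric(sm), as.numeric(matrix(as.numeric(a$slope), 5, 5)),
               tolerance = 1e-9)
  expect_error(terrain_indices(make_grid(1, 3),
                               new_layer(make_grid(1, 3), 1:3)), "2 x 2")
})

test_that("instability is zero for constant series and additive over steps", {
  set.seed(3)
  cur <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  same <- list(t1 = cur, t2 = cur, t3 = cur)
  inst <- pca_instability(same)
  expect_true(all(inst$mean == 0) && all(inst$sum == 0) && all(inst$sd == 0))
  # exactly 2 periods: mean = sum = single step, sd = 0
  past <- cur + matrix(rnorm(40, sd = 0.5), 20, 2)
  two <- pca_instability(list(t1 = past, t2 = cur))
  expect_equal(two$mean, two$sum)
  expect_true(all(two$sd == 0))
})

test_that("instability matches a long-form PCA oracle", {
  set.seed(8)
  periods <- lapply(1:4, function(i)
    matrix(rnorm(30 * 3, sd = i), 30, 3,
           dimnames = list(NULL, c("a", "b", "c"))))
  names(periods) <- paste0("t", 1:4)
  for (agg in c("mean", "sum", "sd")) {
    ours <- pca_instability(periods, aggregate = agg)[[agg]]
    oracle <- instability_bruteforce(periods, agg)
    expect_equal(ours, unname(oracle), tolerance = 1e-9)
  }
})

test_that("instability is invariant to affine rescaling of a variable", {
  set.seed(9)
  periods <- lapply(1:3, function(i)
    matrix(rnorm(25 * 2), 25, 2, dimnames = list(NULL, c("a", "b"))))
  names(periods) <- paste0("t", 1:3)
  base <- pca_instability(periods)$mean
  rescaled <- lapply(periods, function(m) {
    m[, "a"] <- 7 * m[, "a"] - 3
    m
  })
  expect_equal(pca_instability(rescaled)$mean, base, tolerance = 1e-9)
})

test_that("instability validates its inputs", {
  cur <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  bad <- cur; colnames(bad) <- c("a", "z")
  expect_error(pca_instability(list(t1 = bad, t2 = cur)), "mismatched")
  const <- cur; const[, 1] <- 5
  expect_error(pca_instability(list(t1 = cur, t2 = const)), "constant")
  expect_error(pca_instability(list(t1 = cur)), "at least 2")
})

test_that("lig and lgm wrappers aggregate the step distances", {
  g <- make_grid(5, 4)
  set.seed(10)
  mk <- function() matrix(rnorm(nrow(g) * 3), nrow(g), 3,
                          dimnames = list(NULL, c("a", "b", "c")))
  cur <- mk()
  lig <- lig_instability(g, cur, mk(), mk(), mk())
  expect_s3_class(lig, "ps_layer")
  expect_true(all(lig >= 0))

  vol <- new_layer(g, runif(nrow(g), 0.2, 2))
  series <- simulate_paleo_series(g, 43, vol, seed = 4)
  lgm <- lgm_instability(g, series)
  expect_equal(as.numeric(lgm$sum), as.numeric(lgm$mean) * 42,
               tolerance = 1e-9)
  expect_gte(cor(as.numeric(lgm$mean), as.numeric(vol),
                 method = "spearman"), 0.9)
})

test_that("correlation clustering groups |r| above the cut", {
  set.seed(11)
  x <- rnorm(200)
  panel <- cbind(a = x, b = x, c = -0.99 * x + 0.05 * rnorm(200),
                 d = rnorm(200))
  cl <- correlation_cluster(panel, cut = 0.7)
  grp <- setNames(cl$cluster, cl$layer)
  expect_equal(grp[["a"]], grp[["b"]])  # identical layers always together
  expect_equal(grp[["a"]], grp[["c"]])  # strong negative r grouped via |r|
  expect_false(grp[["d"]] == grp[["a"]])
  # independent noise -> singletons
  noise <- matrix(rnorm(500 * 4), 500, 4,
                  dimnames = list(NULL, letters[1:4]))
  cln <- correlation_cluster(noise, cut = 0.7)
  expect_equal(length(unique(cln$cluster)), 4)
})

test_that("VIFs match the direct least-squares oracle", {
  set.seed(13)
  n <- 300
  x1 <- rnorm(n); x2 <- 0.8 * x1 + 0.6 * rnorm(n); x3 <- rnorm(n)
  panel <- cbind(x1 = x1, x2 = x2, x3 = x3)
  expect_equal(unname(vif(panel)), unname(vif_bruteforce(panel)),
               tolerance = 1e-9)
})

test_that("stepwise VIF screening enforces the ceiling", {
  set.seed(14)
  n <- 200
  z <- rnorm(n)
  panel <- cbind(a = z + 0.1 * rnorm(n), b = z + 0.1 * rnorm(n),
                 c = rnorm(n), d = rnorm(n))
  out <- vif_stepwise(panel, threshold = 2.5)
  expect_lte(max(vif(panel[, out$retained])), 2.5)
  expect_true(nrow(out$log) <= ncol(panel) - 1)
  # orthogonal columns: nothing dropped
  ortho <- qr.Q(qr(matrix(rnorm(100 * 3), 100, 3)))
  colnames(ortho) <- c("u", "v", "w")
  expect_equal(vif_stepwise(ortho, 2.5)$retained, c("u", "v", "w"))
  # duplicated column: infinite VIF, one copy dropped first
  dup <- cbind(a = z, a2 = z, c = rnorm(n))
  outd <- vif_stepwise(dup, 2.5)
  expect_equal(outd$log$dropped[1], "a")  # alphabetical tie-break
  expect_false(all(c("a", "a2") %in% outd$retained))
})

test_that("scale_panel standardizes and records the transform", {
  set.seed(15)
  panel <- cbind(a = rnorm(50, 10, 3), b = runif(50))
  sc <- scale_panel(panel)
  expect_lt(max(abs(colMeans(sc))), 1e-12)
  expect_equal(unname(apply(sc, 2, sd)), c(1, 1), tolerance = 1e-12)
  rec <- attr(sc, "scaling")
  expect_equal(rec$mean[1], mean(panel[, "a"]))
  expect_error(scale_panel(cbind(k = rep(1, 10))), "constant")
})
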