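# Factor-analysis machinery against independent oracles: closed-form KMO
# at p = 2, regression-residual partial correlations at p = 3, an SVD-of-
# data PCA oracle, and a grid-search varimax oracle.

test_that("KMO equals 1/2 for every two-variable correlation matrix", {
  for (r in c(-0.9, -0.3, 0.1, 0.5, 0.99)) {
    R <- matrix(c(1, r, r, 1), 2)
    expect_equal(kmo(R)$overall, 0.5, tolerance = 1e-12)
    expect_equal(unname(kmo(R)$per_variable), c(0.5, 0.5), tolerance = 1e-12)
  }
})

test_that("KMO matches a regression-residual partial-correlation oracle", {
  set.seed(42)
  for (rep in 1:5) {
    f <- rnorm(300)
    x <- data.frame(a = 0.8 * f + rnorm(300, sd = runif(1, 0.3, 1)),
                    b = 0.7 * f + rnorm(300, sd = runif(1, 0.3, 1)),
                    c = 0.5 * f + rnorm(300, sd = runif(1, 0.3, 1)))
    R <- cor(x)
    # Brute force: partial correlation of each pair given the third
    # variable, from explicit regression residuals.
    pc <- function(i, j, k) {
      cor(resid(lm(x[[i]] ~ x[[k]])), resid(lm(x[[j]] ~ x[[k]])))
    }
    q <- c(pc(1, 2, 3), pc(1, 3, 2), pc(2, 3, 1))
    r_off <- c(R[1, 2], R[1, 3], R[2, 3])
    oracle <- sum(r_off^2) / (sum(r_off^2) + sum(q^2))
    expect_equal(kmo(R)$overall, oracle, tolerance = 1e-10)
  }
})

test_that("KMO handles a singular matrix via pseudo-inverse with warning", {
  R <- matrix(c(1, 1, 1, 1), 2)
  expect_warning(res <- kmo(R), "singular")
  expect_true(res$overall >= 0 && res$overall <= 1)
})

test_that("PCA extraction covers the degenerate closed forms", {
  set.seed(1)
  x <- matrix(rnorm(100), ncol = 1)
  fit <- extract_pca(x, 1)
  expect_equal(unname(fit$loadings[, 1]), 1)
  # Scores are population z-scores (1/n denominator).
  expect_equal(fit$scores[, 1],
               as.numeric(scale(x)) * sqrt(100 / 99))

  # Two perfectly correlated variables: first factor carries everything.
  y <- cbind(a = x[, 1], b = 2 * x[, 1])
  expect_warning(fit2 <- extract_pca(y, 1), "[Ss]ingular")
  expect_equal(unname(fit2$loadings[, 1]), c(1, 1), tolerance = 1e-12)
  expect_equal(sum(fit2$loadings^2) / 2, 1, tolerance = 1e-12)

  expect_error(extract_pca(y, 3), "n_factors")
  expect_error(extract_pca(cbind(x, 0), 1), "constant")
})

test_that("PCA loadings and scores match an SVD-of-data oracle", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 150
    f <- rnorm(n)
    x <- sapply(1:7, function(j) runif(1, 0.3, 0.9) * f + rnorm(n))
    k <- sample(1:3, 1)
    fit <- extract_pca(x, k)
    # Oracle: singular value decomposition of the standardized data.
    z <- scale(x)
    sv <- svd(z)
    lam <- sv$d^2 / (n - 1)
    L_oracle <- sv$v[, 1:k, drop = FALSE] %*% diag(sqrt(lam[1:k]), k)
    S_oracle <- sv$u[, 1:k, drop = FALSE] * sqrt(n)
    for (j in 1:k) {  # align the arbitrary column signs
      s <- sign(sum(L_oracle[, j] * fit$loadings[, j]))
      L_oracle[, j] <- s * L_oracle[, j]
      S_oracle[, j] <- s * S_oracle[, j]
    }
    expect_equal(unname(fit$loadings), L_oracle, tolerance = 1e-8)
    expect_equal(unname(fit$scores), S_oracle, tolerance = 1e-6)
    expect_equal(unname(colMeans(fit$scores^2)), rep(1, k),
                 tolerance = 1e-10)
  }
})

test_that("varimax at k = 2 attains the grid-search optimum", {
  set.seed(11)
  for (rep in 1:3) {
    L <- matrix(rnorm(14, sd = 0.5), ncol = 2)
    res <- varimax_rotation(L)
    expect_equal(crossprod(res$rotmat), diag(2), tolerance = 1e-10)

    # Oracle: exhaustive 0.001-radian scan over planar rotations of the
    # Kaiser-normalized loadings (reflections cannot change the criterion).
    sc <- sqrt(rowSums(L^2))
    A <- L / sc
    best <- -Inf
    for (theta in seq(0, pi / 2, by = 0.001)) {
      rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
      crit <- croppsi:::varimax_criterion(A %*% rot)
      best <- max(best, crit)
    }
    achieved <- croppsi:::varimax_criterion(res$loadings / sc)
    expect_gte(achieved, best - 1e-6)
    expect_equal(achieved, best, tolerance = 1e-4)

    # Independent library cross-check: our optimum is at least as good,
    # and the rotated loadings agree up to column sign/permutation.
    ref <- unclass(stats::varimax(L, normalize = TRUE)$loadings)
    expect_gte(achieved + 1e-8,
               croppsi:::varimax_criterion(ref / sc))
    align_err <- min(vapply(list(ref, ref[, 2:1]), function(m) {
      max(abs(abs(m) - abs(res$loadings)))
    }, numeric(1)))
    expect_lt(align_err, 1e-3)
  }
})

test_that("varimax is identity at k = 1 and fixes simple structure", {
  L1 <- matrix(c(0.9, 0.7, 0.5), ncol = 1)
  res <- varimax_rotation(L1)
  expect_identical(res$loadings, L1)
  expect_equal(res$rotmat, diag(1))

  Ls <- cbind(c(0.9, 0.8, 0, 0), c(0, 0, 0.7, 0.6))
  res <- varimax_rotation(Ls)
  sorted <- apply(abs(res$loadings), 2, sort)
  expect_equal(sorted, apply(abs(Ls), 2, sort), tolerance = 1e-8)
})

test_that("index build recovers the latent sign pattern and is stable", {
  x <- simulate_latent_indicators(300, seed = 5)
  model <- build_index(x, "within_polder")
  L <- model$loadings[croppsi_index_indicators, 1]
  expect_true(all(L[setdiff(croppsi_index_indicators, "ghg_footprint")] > 0))
  expect_lt(L[["ghg_footprint"]], 0)
  expect_gt(L[["pnp"]], 0)   # sign anchor

  # Scores are z-normalized within stratum.
  expect_equal(mean(model$scores$mcpi), 0, tolerance = 1e-10)
  expect_equal(mean(model$scores$mcpi^2), 1, tolerance = 1e-8)
  expect_true(model$kmo_overall >= 0 && model$kmo_overall <= 1)
  expect_true(all(model$proportion_variance >= 0 &
                    model$proportion_variance <= 1))
  expect_equal(model$proportion_variance, model$ss_loadings / 7)

  # Duplicating every observation changes nothing.
  dup <- build_index(dplyr::bind_rows(x, x), "within_polder")
  expect_equal(dup$loadings, model$loadings, tolerance = 1e-12)
  expect_equal(dup$scores$mcpi, rep(model$scores$mcpi, 2), tolerance = 1e-10)

  # Positive affine rescaling of a raw indicator is absorbed.
  resc <- dplyr::mutate(x, pkp = 1000 * pkp + 5)
  expect_equal(build_index(resc, "within_polder")$scores$mcpi,
               model$scores$mcpi, tolerance = 1e-10)

  expect_error(build_index(x[1:10, ], "within_polder"), "at least 30")
  expect_output(print(model), "croppsi_index_model")
})

test_that("Bartlett scores are an available alternative", {
  x <- simulate_latent_indicators(200, seed = 9)
  reg <- build_index(x, "within_polder")
  bart <- build_index(x, "within_polder", score_method = "bartlett")
  expect_equal(bart$loadings, reg$loadings)
  expect_gt(cor(bart$scores$mcpi, reg$scores$mcpi), 0.99)
  expect_false(isTRUE(all.equal(bart$scores$mcpi, reg$scores$mcpi)))
})

test_that("multi-factor fits expose rotated loadings and extra scores", {
  set.seed(13)
  n <- 250
  f1 <- rnorm(n)
  f2 <- rnorm(n)
  x <- tibble::tibble(
    household_id = sprintf("H%d", 1:n), stratum = "within_polder",
    system_label = "FFA",
    rey = 0.8 * f1 + 0.3 * rnorm(n), pnp = 0.8 * f1 + 0.3 * rnorm(n),
    pkp = 0.7 * f1 + 0.4 * rnorm(n), energy_efficiency = 0.8 * f2 + 0.3 * rnorm(n),
    bcr = 0.7 * f2 + 0.4 * rnorm(n), ghg_footprint = -0.7 * f2 + 0.4 * rnorm(n),
    hlep = 0.6 * f2 + 0.5 * rnorm(n))
  m2 <- build_index(x, "within_polder", n_factors = 2)
  expect_equal(ncol(m2$loadings), 2)
  expect_true("factor2_score" %in% names(m2$scores))
  # Varimax should separate the two blocks.
  expect_gt(abs(m2$loadings["energy_efficiency", 2]) +
              abs(m2$loadings["energy_efficiency", 1]), 0.6)
  expect_equal(unname(crossprod(m2$loadings) -
                        diag(diag(crossprod(m2$loadings)))),
               matrix(0, 2, 2), tolerance = 0.35)
})
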