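# Multi-criteria performance index: sampling adequacy, PCA extraction,
# varimax rotation, first-factor scores.

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Overall and per-variable MSA from a correlation matrix. The anti-image
#' partial correlations `q_ij` are obtained from the inverse correlation
#' matrix; the overall MSA is `sum(r^2) / (sum(r^2) + sum(q^2))` over
#' off-diagonal elements, and the per-variable MSA is the row-wise
#' analogue. A singular matrix is handled with the Moore-Penrose
#' pseudo-inverse and a warning.
#'
#' @param R Symmetric correlation matrix, p >= 2.
#' @return List with `overall` and `per_variable` (named when R has
#'   dimnames), both in `[0, 1]`.
#' @export
kmo <- function(R) {
  R <- as.matrix(R)
  p <- nrow(R)
  stopifnot(p >= 2, ncol(R) == p)
  inv <- tryCatch(solve(R), error = function(e) {
    warn("Correlation matrix is singular; using pseudo-inverse for KMO")
    pseudo_inverse(R)
  })
  d <- sqrt(diag(inv))
  Q <- -inv / tcrossprod(d)
  diag(Q) <- 0
  R0 <- R
  diag(R0) <- 0
  r2 <- R0^2
  q2 <- Q^2
  overall <- sum(r2) / (sum(r2) + sum(q2))
  per_var <- rowSums(r2) / (rowSums(r2) + rowSums(q2))
  names(per_var) <- rownames(R)
  list(overall = overall, per_variable = per_var)
}

# Column-standardize with the population (1/n) standard deviation.
standardize_population <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  z <- scale(x)
  if (any(attr(z, "scaled:scale") == 0)) {
    abort("constant variable(s): standardization impossible")
  }
  z[] <- z * sqrt(n / (n - 1))
  z
}

pseudo_inverse <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * s$d[1]
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Principal-component factor extraction
#'
#' Eigen-decomposes the correlation matrix of the (column-standardized)
#' data and returns the first `n_factors` loadings, each eigenvector
#' scaled by the square root of its eigenvalue, together with factor
#' scores by the regression (Thurstone) method on the standardized
#' variables. Column signs are fixed so each loading column's
#' largest-magnitude element is positive.
#'
#' @param x Numeric matrix or data frame of observations (rows) by
#'   variables (columns); standardized internally.
#' @param n_factors Number of components to retain, `1 <= n_factors <= p`.
#' @return List: `loadings` (p x k), `eigenvalues` (length p), `scores`
#'   (n x k, unit variance), `correlation` (p x p).
#' @export
extract_pca <- function(x, n_factors = 1) {
  # Standardization uses the population (1/n) standard deviation so that
  # duplicating every observation leaves z-scores, and hence factor
  # scores, exactly unchanged.
  x <- as.matrix(x)
  p <- ncol(x)
  if (n_factors < 1 || n_factors > p) {
    abort("n_factors must lie between 1 and the number of variables")
  }
  z <- standardize_population(x)
  R <- cor(x)
  eig <- eigen(R, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  L <- eig$vectors[, seq_len(n_factors), drop = FALSE] %*%
    diag(sqrt(lam[seq_len(n_factors)]), n_factors)
  # Deterministic sign: largest |loading| per column is positive.
  flip <- apply(L, 2, function(col) sign(col[which.max(abs(col))]))
  L <- sweep(L, 2, flip, `*`)
  rownames(L) <- colnames(x)
  scores <- factor_scores(z, R, L, method = "regression")
  list(loadings = L, eigenvalues = eig$values, scores = scores,
       correlation = R)
}

# Factor scores from standardized data. Regression (Thurstone):
# Z R^-1 L; Bartlett: weighted least squares with uniquenesses.
factor_scores <- function(z, R, L, method = c("regression", "bartlett")) {
  method <- match.arg(method)
  if (method == "regression") {
    w <- tryCatch(solve(R, L), error = function(e) {
      warn("Singular correlation matrix; regression scores via pseudo-inverse")
      pseudo_inverse(R) %*% L
    })
    z %*% w
  } else {
    psi <- pmax(1 - rowSums(L^2), 1e-6)
    W <- L / psi
    z %*% W %*% solve(crossprod(L, W))
  }
}

#' Varimax rotation
#'
#' Orthogonal rotation maximizing the varimax criterion (the summed
#' column variances of squared loadings), with Kaiser row normalization.
#' For a single factor, rotation is the identity. Iterates pairwise SVD
#' updates until the criterion stalls; if the iteration cap is hit the
#' best iterate is returned with a warning. The returned rotation matrix
#' is orthonormal to machine precision.
#'
#' @param L Loading matrix (p x k).
#' @param normalize Kaiser row normalization before rotation.
#' @param eps Relative criterion tolerance.
#' @param max_iter Iteration cap.
#' @return List: `loadings` (rotated), `rotmat` (k x k orthonormal),
#'   `criterion`, `converged`.
#' @export
varimax_rotation <- function(L, normalize = TRUE, eps = 1e-10,
                             max_iter = 5000L) {
  L <- as.matrix(L)
  p <- nrow(L)
  k <- ncol(L)
  if (k < 2) {
    return(list(loadings = L, rotmat = diag(k),
                criterion = varimax_criterion(L), converged = TRUE))
  }
  sc <- if (normalize) sqrt(rowSums(L^2)) else rep(1, p)
  if (any(sc == 0)) sc[sc == 0] <- 1
  A <- L / sc
  TT <- diag(k)
  d <- 0
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    z <- A %*% TT
    B <- crossprod(A, z^3 - z %*% diag(drop(rep(1, p) %*% z^2) / p, k))
    sv <- svd(B)
    TT <- sv$u %*% t(sv$v)
    d_old <- d
    d <- sum(sv$d)
    if (i > 1 && d < d_old * (1 + eps)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warn("varimax did not converge; returning best iterate")
  rotated <- (A %*% TT) * sc
  dimnames(rotated) <- dimnames(L)
  list(loadings = rotated, rotmat = TT,
       criterion = varimax_criterion(rotated / sc), converged = converged)
}

# The varimax objective: sum over factors of the variance of squared
# (row-normalized, if applied by the caller) loadings.
varimax_criterion <- function(L) {
  L2 <- L^2
  sum(apply(L2, 2, function(col) mean(col^2) - mean(col)^2))
}

#' Build the multi-criteria performance index for one stratum
#'
#' Fits a factor model to the seven performance indicators
#' (rice-equivalent yield, partial N and K productivity, energy
#' efficiency, benefit-cost ratio, partial GHG footprint, hired-labor
#' energy productivity; total energy production is excluded because most
#' efficiency indicators already carry it) within one stratum:
#' standardizes the indicators, checks sampling adequacy (KMO), extracts
#' principal components, varimax-rotates when more than one factor is
#' retained, and takes the first-factor score as the index. The sign
#' indeterminacy is resolved by forcing the partial-N-productivity
#' loading positive, which makes the GHG footprint load negative under
#' the expected structure.
#'
#' Rows with any masked (NA) indicator are dropped listwise before
#' fitting.
#'
#' @param indicators Output of [compute_indicators()] (or any tibble with
#'   the indicator columns plus `household_id`, `stratum`, `system_label`).
#' @param stratum Stratum to fit; must be present in the data.
#' @param n_factors Number of factors retained (1 by default: the first
#'   factor score is the index).
#' @param min_rows Sample-adequacy guard; refuse to fit on fewer complete
#'   rows.
#' @param score_method `"regression"` (Thurstone, default) or
#'   `"bartlett"`.
#' @param indicators_used Indicator columns entering the model.
#' @return A `croppsi_index_model`: loadings, SS loadings, proportion of
#'   variance, RMSR, KMO, correlation matrix and per-observation scores
#'   (`scores$mcpi` is the index).
#' @export
build_index <- function(indicators, stratum, n_factors = 1, min_rows = 30,
                        score_method = c("regression", "bartlett"),
                        indicators_used = croppsi_index_indicators) {
  score_method <- match.arg(score_method)
  stopifnot(stratum %in% indicators$stratum)
  sub <- indicators %>% filter(.data$stratum == !!stratum)
  complete <- complete.cases(sub[indicators_used])
  sub <- sub[complete, ]
  if (nrow(sub) < min_rows) {
    abort(paste0("Only ", nrow(sub), " complete rows in stratum '", stratum,
                 "'; at least ", min_rows, " required for a stable index"))
  }
  x <- as.matrix(sub[indicators_used])
  fit <- extract_pca(x, n_factors = n_factors)
  L <- fit$loadings
  rot <- varimax_rotation(L)
  L <- rot$loadings
  scores <- factor_scores(standardize_population(x), fit$correlation, L,
                          method = score_method)

  # Anchor: partial N productivity loads positive on the first factor.
  if (L["pnp", 1] < 0) {
    L[, 1] <- -L[, 1]
    scores[, 1] <- -scores[, 1]
  }

  ss <- colSums(L^2)
  resid <- fit$correlation - tcrossprod(L)
  off <- resid[upper.tri(resid)]
  adequacy <- kmo(fit$correlation)

  score_tbl <- dplyr::bind_cols(
    sub[c("household_id", "stratum", "system_label")],
    tibble::tibble(mcpi = scores[, 1])
  )
  if (n_factors > 1) {
    extra <- as.data.frame(scores[, -1, drop = FALSE])
    names(extra) <- paste0("factor", 2:n_factors, "_score")
    score_tbl <- dplyr::bind_cols(score_tbl, extra)
  }

  structure(list(
    stratum = stratum,
    indicator_names = indicators_used,
    n_obs = nrow(sub),
    n_dropped = sum(!complete),
    correlation = fit$correlation,
    kmo_overall = adequacy$overall,
    kmo_per_variable = adequacy$per_variable,
    loadings = L,
    ss_loadings = ss,
    proportion_variance = ss / length(indicators_used),
    rmsr = sqrt(mean(off^2)),
    scores = score_tbl,
    n_factors_retained = n_factors,
    score_method = score_method
  ), class = "croppsi_index_model")
}

#' @export
print.croppsi_index_model <- function(x, digits = 3, ...) {
  cat("<croppsi_index_model> stratum:", x$stratum, "\n")
  cat("  n =", x$n_obs, "complete observations (", x$n_dropped,
      "dropped with masked indicators )\n")
  cat("  overall KMO/MSA:", round(x$kmo_overall, digits), "\n")
  cat("  factor loadings (", x$n_factors_retained, "retained ):\n")
  print(round(x$loadings, digits))
  cat("  SS loadings:", round(x$ss_loadings, digits),
      "; proportion of variance:", round(x$proportion_variance, digits), "\n")
  cat("  RMSR:", round(x$rmsr, digits), "\n")
  invisible(x)
}
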