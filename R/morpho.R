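## Geometric morphometrics: generalized Procrustes analysis (translation,
## scale, rotation removed; no reflection), PCA of the Procrustes residuals,
## Welch t-tests on PCs above a variance gate, standardized PCA of radula
## ratio meristics, and the substrate x morph chi-squared test.

# optimal 2-D rotation of X onto Y (no reflection): SVD of the
# cross-covariance, determinant forced +1 so reflections are disallowed
rotate_onto <- function(X, Y) {
  s <- svd(crossprod(X, Y))
  d <- sign(det(s$u) * det(s$v))
  R <- s$u %*% diag(c(1, d)) %*% t(s$v)
  X %*% R
}

center_scale <- function(X) {
  X <- sweep(X, 2, colMeans(X))
  cs <- sqrt(sum(X^2))
  if (cs == 0) stopf("degenerate configuration: all landmarks coincident")
  list(conf = X / cs, size = cs)
}

#' Generalized Procrustes analysis of 2-D landmark configurations
#'
#' Iteratively centers each configuration, scales it to unit centroid size,
#' rotates it onto the current mean shape by orthogonal Procrustes rotation
#' (cross-covariance SVD, reflections disallowed), and updates the mean
#' (renormalized to unit size) until the mean shape changes by less than
#' `tol` or `max_iter` is reached.
#'
#' @param coords n x k x 2 array (n >= 2 specimens, k >= 3 landmarks).
#' @param tol Convergence tolerance on the mean shape (default 1e-8).
#' @param max_iter Iteration cap (default 100).
#' @return List of class `procrustes_gpa`: `aligned` (n x k x 2), `mean_shape`
#'   (k x 2), `centroid_sizes`, `residuals` (n x 2k matrix of aligned - mean),
#'   `iterations`.
#' @export
procrustes_gpa <- function(coords, tol = 1e-8, max_iter = 100) {
  n <- dim(coords)[1]; k <- dim(coords)[2]
  stopifnot(n >= 2, k >= 3)
  confs <- vector("list", n)
  sizes <- numeric(n)
  for (i in seq_len(n)) {
    cs <- center_scale(coords[i, , ])
    confs[[i]] <- cs$conf
    sizes[i] <- cs$size
  }
  mean_shape <- confs[[1]]
  iters <- 0L
  repeat {
    iters <- iters + 1L
    for (i in seq_len(n)) confs[[i]] <- rotate_onto(confs[[i]], mean_shape)
    new_mean <- Reduce(`+`, confs) / n
    new_mean <- new_mean / sqrt(sum(new_mean^2))
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol || iters >= max_iter) break
  }
  aligned <- array(0, dim = dim(coords), dimnames = dimnames(coords))
  for (i in seq_len(n)) aligned[i, , ] <- confs[[i]]
  res <- t(vapply(confs, function(cf) as.numeric(cf - mean_shape),
                  numeric(2 * k)))
  rownames(res) <- dimnames(coords)[[1]]
  structure(list(aligned = aligned, mean_shape = mean_shape,
                 centroid_sizes = sizes, residuals = res, iterations = iters),
            class = "procrustes_gpa")
}

#' Procrustes distance between two aligned configurations
#' @param a,b k x 2 matrices.
#' @return Square-root of the summed squared landmark differences.
#' @export
procrustes_distance <- function(a, b) sqrt(sum((a - b)^2))

#' PCA of Procrustes residuals
#'
#' Eigen-decomposition of the covariance of the flattened residuals. Variance
#' fractions are relative to the total variance; scores x loadings
#' reconstruct the centered residuals.
#'
#' @param gpa A `procrustes_gpa` result (>= 3 specimens).
#' @return List of class `shape_pca`: `scores`, `loadings`, `var_fraction`,
#'   `rank`.
#' @export
shape_pca <- function(gpa) {
  X <- gpa$residuals
  stopifnot(nrow(X) >= 3)
  X <- sweep(X, 2, colMeans(X))
  total <- sum(X^2)
  if (total < 1e-24)
    return(structure(list(scores = matrix(0, nrow(X), 0),
                          loadings = matrix(0, ncol(X), 0),
                          var_fraction = numeric(0), rank = 0L),
                     class = "shape_pca"))
  pc <- stats::prcomp(X, center = FALSE)
  ev <- pc$sdev^2
  r <- sum(ev > max(ev) * 1e-12)
  structure(list(scores = pc$x[, seq_len(r), drop = FALSE],
                 loadings = pc$rotation[, seq_len(r), drop = FALSE],
                 var_fraction = ev[seq_len(r)] / sum(ev),
                 rank = r),
            class = "shape_pca")
}

#' Welch t-tests on PCs above a variance gate
#'
#' Each PC capturing at least `min_var` of the total variance is tested
#' between the two groups with a two-tailed Welch t-test; PCs below the gate
#' are reported untested.
#'
#' @param pca A `shape_pca` (or any list with `scores` and `var_fraction`).
#' @param groups Factor/character vector of two group labels per specimen.
#' @param min_var Variance-fraction gate (default 0.05).
#' @return data.frame: pc, var_fraction, tested, t, p.
#' @export
pc_group_tests <- function(pca, groups, min_var = 0.05) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2)
  if (any(table(groups) < 2)) stopf("each group needs n >= 2")
  out <- data.frame(pc = seq_along(pca$var_fraction),
                    var_fraction = pca$var_fraction,
                    tested = pca$var_fraction >= min_var,
                    t = NA_real_, p = NA_real_)
  for (i in which(out$tested)) {
    tt <- stats::t.test(pca$scores[, i] ~ groups)
    out$t[i] <- unname(tt$statistic)
    out$p[i] <- tt$p.value
  }
  out
}

#' Standardized PCA of radula ratio meristics with group tests
#'
#' Variables (denticle width / total height ratio, rachis width ratio,
#' denticle count, ...) are standardized to unit variance before PCA since
#' their units differ; constant variables are dropped with a warning.
#' [pc_group_tests()] is then applied.
#'
#' @param measurements Numeric data.frame/matrix, one row per specimen.
#' @param groups Two-level group labels.
#' @param min_var Variance gate passed on to [pc_group_tests()].
#' @return List: `pca` (`shape_pca`-like) and `tests`.
#' @export
radula_meristics_pca <- function(measurements, groups, min_var = 0.05) {
  X <- as.matrix(measurements)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant variable(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  Z <- scale(X)
  pc <- stats::prcomp(Z, center = FALSE)
  ev <- pc$sdev^2
  pca <- list(scores = pc$x, loadings = pc$rotation,
              var_fraction = ev / sum(ev), rank = sum(ev > max(ev) * 1e-12))
  list(pca = pca, tests = pc_group_tests(pca, groups, min_var))
}

#' Chi-squared test of morph abundances across substrates
#'
#' Pearson chi-squared without continuity correction on the 2x2
#' substrate x morph table (df = 1).
#'
#' @param tab 2x2 non-negative integer matrix (substrate x morph).
#' @return List: `chisq`, `df`, `p`, `expected`.
#' @export
habitat_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2))
  if (any(tab < 0) || any(tab != round(tab))) stopf("table must hold non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) stopf("zero margin in table")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected)
}
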