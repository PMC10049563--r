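#' Pearson correlation matrix of the elements in one area
#'
#' @param samples Samples data frame (typically one functional area).
#' @param elements Elements to include; default all six.
#' @return Object of class `hm_corr`: list with `elements`, symmetric
#'   matrix `r` and sample count `n`. Zero-variance elements are flagged
#'   in an attribute and their correlations set to `NA`.
#' @export
pearson_matrix <- function(samples, elements = hm_elements()) {
  .validate_samples(samples, require_coords = FALSE)
  if (nrow(samples) < 3L) stop("need at least 3 samples", call. = FALSE)
  X <- as.matrix(samples[, elements, drop = FALSE])
  sds <- apply(X, 2L, stats::sd)
  flagged <- elements[sds == 0]
  r <- suppressWarnings(stats::cor(X))
  if (length(flagged)) {
    r[flagged, ] <- NA_real_
    r[, flagged] <- NA_real_
    diag(r) <- 1
  }
  structure(list(elements = elements, r = r, n = nrow(samples)),
            class = "hm_corr", flagged = flagged)
}

.as_corr <- function(x) {
  if (inherits(x, "hm_corr")) return(x)
  if (is.matrix(x)) {
    stopifnot(nrow(x) == ncol(x), max(abs(x - t(x))) < 1e-8)
    els <- rownames(x)
    if (is.null(els)) els <- paste0("V", seq_len(nrow(x)))
    return(structure(list(elements = els, r = x, n = NA_integer_),
                     class = "hm_corr"))
  }
  stop("expected an hm_corr object or a correlation matrix", call. = FALSE)
}

#' Kaiser–Meyer–Olkin measure of sampling adequacy
#'
#' \eqn{KMO = \sum_{i \ne j} r_{ij}^2 \big/ (\sum_{i \ne j} r_{ij}^2 +
#' \sum_{i \ne j} a_{ij}^2)}, where the \eqn{a_{ij}} are anti-image
#' partial correlations obtained from the inverse correlation matrix.
#' Values near 1 support factor extraction; for two variables the
#' partial correlation equals the correlation, so KMO is identically
#' 0.5.
#'
#' @param corr An `hm_corr` object or correlation matrix.
#' @return KMO value in `[0, 1]`; `NA` with a warning if both sums
#'   vanish (near-identity matrix).
#' @export
kmo <- function(corr) {
  corr <- .as_corr(corr)
  R <- corr$r
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-12 * max(ev)) {
    stop("correlation matrix is numerically singular (condition number ",
         format(max(ev) / max(min(ev), .Machine$double.eps), digits = 3),
         ")", call. = FALSE)
  }
  S <- solve(R)
  D <- diag(1 / sqrt(diag(S)))
  A <- -D %*% S %*% D          # anti-image partial correlations (off-diag)
  off <- upper.tri(R)
  r2 <- sum(R[off]^2)
  a2 <- sum(A[off]^2)
  if (r2 + a2 < 1e-12) {
    warning("correlations are all ~0; KMO is undefined (0/0)", call. = FALSE)
    return(NA_real_)
  }
  r2 / (r2 + a2)
}

#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix differs from the identity:
#' \eqn{\chi^2 = -\big(n - 1 - (2p + 5)/6\big) \ln \det R} on
#' \eqn{p(p-1)/2} degrees of freedom.
#'
#' @param corr An `hm_corr` object (uses its `n`) or correlation matrix.
#' @param n Sample count; required if `corr` carries none.
#' @return List with `chi2`, `df`, `p_value`.
#' @export
bartlett_sphericity <- function(corr, n = NULL) {
  corr <- .as_corr(corr)
  if (is.null(n)) n <- corr$n
  p <- length(corr$elements)
  if (is.na(n) || n <= p) {
    stop("Bartlett's test needs n greater than the number of variables",
         call. = FALSE)
  }
  detR <- det(corr$r)
  chi2 <- max(0, -(n - 1 - (2 * p + 5) / 6) * log(detR))
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Correlation PCA with varimax rotation
#'
#' Eigen-decomposes the correlation matrix (so element scales, which
#' span three orders of magnitude, do not dominate), retains components
#' by the Kaiser rule (eigenvalue > 1) or a fixed count, and varimax-
#' rotates the retained loadings with Kaiser normalization. Loadings are
#' \eqn{v_k \sqrt{\lambda_k}}; each column's sign is set so its largest
#' absolute loading is positive.
#'
#' @param corr An `hm_corr` object or correlation matrix.
#' @param retain `"kaiser"` or a fixed number of components.
#' @param eps Varimax convergence tolerance (default 1e-8).
#' @return Object of class `hm_pca`: `eigenvalues`, `variance_pct`,
#'   `cumulative_pct`, `n_retained`, `loadings` (unrotated),
#'   `loadings_rotated`, `communalities`, and — when the input carries a
#'   sample count — `kmo` and `bartlett`.
#' @export
pca_varimax <- function(corr, retain = "kaiser", eps = 1e-8) {
  corr <- .as_corr(corr)
  R <- corr$r
  p <- nrow(R)
  e <- eigen(R, symmetric = TRUE)
  ev <- e$values
  if (identical(retain, "kaiser")) {
    k <- sum(ev > 1)
    if (k == 0L) {
      stop("no eigenvalue exceeds 1 (Kaiser rule retains nothing); ",
           "pass retain = <k> to force a fixed count", call. = FALSE)
    }
  } else {
    k <- as.integer(retain)
    stopifnot(k >= 1L, k <= p)
  }
  L <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(ev[seq_len(k)], 0)), k)
  dimnames(L) <- list(corr$elements, paste0("PC", seq_len(k)))
  L <- .fix_signs(L)
  if (k >= 2L) {
    # Kaiser normalization done here so zero-communality rows stay finite
    sc <- sqrt(rowSums(L^2))
    sc[sc < 1e-12] <- 1
    rot <- stats::varimax(L / sc, normalize = FALSE, eps = eps)
    Lr <- .fix_signs(unclass(rot$loadings) * sc)
  } else {
    Lr <- L
  }
  dimnames(Lr) <- dimnames(L)
  out <- list(eigenvalues = ev,
              variance_pct = ev / p * 100,
              cumulative_pct = cumsum(ev / p * 100),
              n_retained = k,
              loadings = L,
              loadings_rotated = Lr,
              communalities = rowSums(L^2),
              rotated_ss_pct = colSums(Lr^2) / p * 100)
  if (!is.na(corr$n)) {
    out$kmo <- kmo(corr)
    out$bartlett <- bartlett_sphericity(corr)
  }
  structure(out, class = "hm_pca")
}

.fix_signs <- function(L) {
  flip <- apply(L, 2L, function(col) sign(col[which.max(abs(col))]))
  sweep(L, 2L, ifelse(flip == 0, 1, flip), "*")
}

#' @export
print.hm_pca <- function(x, ...) {
  cat("Correlation PCA:", x$n_retained, "component(s) retained",
      sprintf("(%.1f%% cumulative variance)\n",
              x$cumulative_pct[x$n_retained]))
  if (!is.null(x$kmo)) {
    cat(sprintf("KMO %.2f; Bartlett chi2 %.1f (df %d, p %.3g)\n", x$kmo,
                x$bartlett$chi2, x$bartlett$df, x$bartlett$p_value))
  }
  cat("Rotated loadings:\n")
  print(round(x$loadings_rotated, 2))
  invisible(x)
}

#' Hierarchical clustering of elements
#'
#' Agglomerates the six elements on a correlation-based distance
#' (`1 - r`, so perfectly co-varying elements merge at height 0) or on
#' Euclidean distance between standardized concentration profiles,
#' with a configurable linkage (default average).
#'
#' @param x Samples data frame or an `hm_corr` object (correlation
#'   distance only).
#' @param distance `"correlation"` (default) or `"euclidean"`.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @param k Number of flat clusters to cut (default 3).
#' @return Object of class `hm_clust`: `tree` (hclust), `clusters`
#'   (named membership vector), `order` (leaf order for heat maps),
#'   `heights`.
#' @export
cluster_elements <- function(x, distance = c("correlation", "euclidean"),
                             linkage = "average", k = 3) {
  distance <- match.arg(distance)
  if (distance == "euclidean") {
    stopifnot(is.data.frame(x))
    d <- stats::dist(t(scale(as.matrix(x[, hm_elements()]))))
  } else {
    corr <- if (is.data.frame(x)) pearson_matrix(x) else .as_corr(x)
    d <- stats::as.dist(1 - corr$r)
  }
  p <- attr(d, "Size")
  stopifnot(p >= 2L, k >= 1L, k <= p)
  tree <- stats::hclust(d, method = linkage)
  structure(list(tree = tree,
                 clusters = stats::cutree(tree, k = k),
                 order = tree$labels[tree$order],
                 heights = tree$height),
            class = "hm_clust")
}

#' Write a correlation matrix as a lower-triangle CSV
#'
#' @param corr An `hm_corr` object.
#' @param path Output path.
#' @export
write_correlation <- function(corr, path) {
  corr <- .as_corr(corr)
  r <- corr$r
  r[upper.tri(r)] <- NA
  utils::write.csv(round(r, 2), path, na = "", row.names = TRUE)
  invisible(path)
}
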