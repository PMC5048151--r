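# Multivariate ratio analysis: isometric size and log-shape space, shape
# PCA, PCA/allometry ratio spectra with bootstrap confidence intervals,
# and the LDA ratio extractor scored by standard distance.

#' Decompose a measurement table into isometric size and shape
#'
#' With `y = ln(values)`, the isometric size of a specimen is the mean of
#' its log-measurements and its shape vector is the zero-sum residual
#' `y - isosize`. The transform is lossless: `shape + isosize` reconstructs
#' the log table exactly, and multiplying all of a specimen's measurements
#' by a constant changes only its isosize.
#'
#' @param table Measurement table with strictly positive values.
#' @return Object of class `log_shape_space`: list with `ids`, `species`,
#'   `isosize` (numeric vector) and `shape` (n x 25 matrix).
#' @export
to_shape_space <- function(table) {
  validate_measurement_table(table, check_positive = FALSE)
  vals <- as.matrix(table[morpho_characters])
  bad <- which(!is.na(vals) & vals <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("nonpositive measurement for specimen ",
         table$specimen_id[bad[1, 1]], ", character ",
         morpho_characters[bad[1, 2]])
  if (anyNA(vals)) stop("shape space requires a complete table")
  y <- log(vals)
  iso <- rowMeans(y)
  structure(list(ids = table$specimen_id, species = table$species,
                 isosize = iso, shape = y - iso),
            class = "log_shape_space")
}

#' @export
print.log_shape_space <- function(x, ...) {
  cat("<log_shape_space> ", length(x$ids), " specimens x ",
      ncol(x$shape), " characters\n", sep = "")
  invisible(x)
}

.fix_sign <- function(v) {
  if (v[which.max(abs(v))] < 0) -v else v
}

.shape_eigen <- function(shape) {
  e <- eigen(cov(shape), symmetric = TRUE)
  tol <- max(e$values) * 1e-10
  nz <- sum(e$values > tol)
  vectors <- apply(e$vectors, 2, .fix_sign)
  list(values = pmax(e$values, 0), vectors = vectors, nonzero = nz)
}

#' Principal component analysis of shape
#'
#' Eigen-decomposition of the covariance matrix of the zero-sum shape
#' vectors. Because shape vectors live in the zero-sum hyperplane, at most
#' p - 1 eigenvalues are nonzero and every eigenvector with nonzero
#' eigenvalue itself sums to zero. Percent variance is reported over the
#' nonzero spectrum and sums to 100. Eigenvector signs are fixed so that
#' the largest-magnitude component is positive.
#'
#' @param space A [to_shape_space()] result.
#' @return List with `values`, `vectors` (columns are PCs), `percent`
#'   (length = number of nonzero eigenvalues), `scores`, `nonzero`.
#' @export
shape_pca <- function(space) {
  stopifnot(inherits(space, "log_shape_space"))
  n <- nrow(space$shape)
  if (n < 3L) stop("shape PCA needs at least 3 specimens")
  e <- .shape_eigen(space$shape)
  nzv <- e$values[seq_len(e$nonzero)]
  ctr <- scale(space$shape, center = TRUE, scale = FALSE)
  list(values = e$values, vectors = e$vectors,
       percent = 100 * nzv / sum(nzv),
       scores = ctr %*% e$vectors, nonzero = e$nonzero)
}

.boot_ci <- function(space, stat_fun, ref, n_boot, seed) {
  if (n_boot < 2L) stop("n_boot must be >= 2")
  n <- nrow(space$shape)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      v <- stat_fun(idx)
      if (sum(v * ref) < 0) v <- -v  # sign alignment to the reference
      v
    }, numeric(length(ref)))
  })
  list(lower = apply(boots, 1, quantile, 0.025, names = FALSE),
       upper = apply(boots, 1, quantile, 0.975, names = FALSE))
}

.spectrum_result <- function(component, loading, ci) {
  df <- data.frame(character = morpho_characters, loading = unname(loading),
                   ci_lower = pmin(ci$lower, loading),
                   ci_upper = pmax(ci$upper, loading))
  df <- df[order(df$loading), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(component = component, spectrum = df), class = "ratio_spectrum")
}

#' @export
print.ratio_spectrum <- function(x, ...) {
  cat("<ratio_spectrum> component ", x$component, "; extremes: ",
      x$spectrum$character[1], " ... ",
      x$spectrum$character[nrow(x$spectrum)], "\n", sep = "")
  invisible(x)
}

#' PCA ratio spectrum
#'
#' Orders the characters by their loadings on a chosen shape principal
#' component. The loading difference `v_i - v_j` is the coefficient of the
#' log-ratio `ln(x_i / x_j)` along the component, so the two characters at
#' opposite ends of the spectrum form the ratio best aligned with it.
#' Confidence intervals come from a nonparametric bootstrap over specimens;
#' each resampled eigenvector is matched to the original by component index
#' and sign-aligned to it (positive dot product) before quantiles are taken.
#'
#' @param space A [to_shape_space()] result.
#' @param component PC index (1-based), at most the nonzero rank.
#' @param n_boot Number of bootstrap resamples (>= 2).
#' @param seed Integer seed for the bootstrap.
#' @return A `ratio_spectrum`: the characters sorted by loading with 95
#'   percent bootstrap CIs.
#' @export
pca_ratio_spectrum <- function(space, component = 1L, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(space, "log_shape_space"))
  e <- .shape_eigen(space$shape)
  if (component > e$nonzero)
    stop("component exceeds the nonzero rank (", e$nonzero, ")")
  ref <- e$vectors[, component]
  ci <- .boot_ci(space, function(idx)
    .shape_eigen(space$shape[idx, , drop = FALSE])$vectors[, component],
    ref, n_boot, seed)
  res <- .spectrum_result(paste0("PC", component), setNames(ref, morpho_characters), ci)
  res
}

.allometry_loadings <- function(shape, iso) {
  vi <- var(iso)
  if (vi <= 0) stop("constant isosize: allometry spectrum undefined")
  drop(cov(shape, iso)) / vi
}

#' Allometry ratio spectrum
#'
#' Each character's loading is the ordinary least-squares slope of its
#' shape variable on isometric size; because the shape variables sum to
#' zero the loadings do too. Characters at opposite ends of the ordering
#' form the most allometric ratio; under isometric growth all loadings
#' vanish. Bootstrap CIs as in [pca_ratio_spectrum()].
#'
#' @inheritParams pca_ratio_spectrum
#' @return A `ratio_spectrum` with component label "allometry".
#' @export
allometry_ratio_spectrum <- function(space, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(space, "log_shape_space"))
  ref <- .allometry_loadings(space$shape, space$isosize)
  ci <- .boot_ci(space, function(idx)
    .allometry_loadings(space$shape[idx, , drop = FALSE], space$isosize[idx]),
    ref, n_boot, seed)
  .spectrum_result("allometry", setNames(ref, morpho_characters), ci)
}

.standard_distance_matrix <- function(sa, sb) {
  # D for every character pair from group means and covariances of shape:
  # r_ij = shape_i - shape_j, D_ij = |mean_a - mean_b| / s_pooled.
  ga <- colMeans(sa); gb <- colMeans(sb)
  na <- nrow(sa); nb <- nrow(sb)
  Sa <- cov(sa); Sb <- cov(sb)
  g <- ga - gb
  dmean <- outer(g, g, "-")                       # mean_a(r) - mean_b(r)
  va <- outer(diag(Sa), diag(Sa), "+") - 2 * Sa   # var_a(r_ij)
  vb <- outer(diag(Sb), diag(Sb), "+") - 2 * Sb
  vp <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  D <- abs(dmean) / sqrt(vp)
  D[!is.finite(D)] <- 0
  diag(D) <- 0
  D
}

.best_pair <- function(D, exclude = integer()) {
  Dm <- D
  Dm[exclude, ] <- -Inf
  Dm[, exclude] <- -Inf
  Dm[lower.tri(Dm, diag = TRUE)] <- -Inf
  idx <- which(Dm == max(Dm), arr.ind = TRUE)[1, ]
  c(idx[["row"]], idx[["col"]])
}

#' LDA ratio extractor
#'
#' Exhaustively scores every unordered character pair (i, j) by the
#' standard distance of its log-ratio `r = ln(x_i / x_j)` between two
#' groups: `D = |mean_a(r) - mean_b(r)| / s_pooled(r)`. The best ratio is
#' the pair with maximal D; the second-best is the maximal pair sharing no
#' character with the best (matching the convention of reporting disjoint
#' ratios). The delta statistic summarizes whether the separation is driven
#' by size or by shape: it is the absolute cosine, in the Mahalanobis
#' geometry of the pooled within-group covariance, between the
#' two-group LDA discriminant computed in full log-measurement space and
#' the isometric direction (1, ..., 1). Pure-size separation gives delta =
#' 1 exactly; delta near 0 means the groups are separated by shape.
#'
#' @param space A [to_shape_space()] result.
#' @param group_a,group_b Disjoint sets of species labels; unions are pooled
#'   into one group each.
#' @return Object of class `lda_ratio_result`: best/second ratio with their
#'   standard distances and per-group observed ratio ranges, the standard
#'   distance along the full LDA axis (`d_full`), and `delta`.
#' @export
lda_ratio_extract <- function(space, group_a, group_b) {
  stopifnot(inherits(space, "log_shape_space"))
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  ia <- space$species %in% group_a
  ib <- space$species %in% group_b
  if (sum(ia) < 3L || sum(ib) < 3L) stop("each group needs >= 3 specimens")
  sa <- space$shape[ia, , drop = FALSE]
  sb <- space$shape[ib, , drop = FALSE]
  D <- .standard_distance_matrix(sa, sb)
  best <- .best_pair(D)
  second <- .best_pair(D, exclude = best)
  ratio_info <- function(pair) {
    ra <- exp(sa[, pair[1]] - sa[, pair[2]])
    rb <- exp(sb[, pair[1]] - sb[, pair[2]])
    list(characters = morpho_characters[pair], D = D[pair[1], pair[2]],
         range_a = range(ra), range_b = range(rb))
  }
  # delta and the full-axis standard distance in log-measurement space
  ya <- sa + space$isosize[ia]
  yb <- sb + space$isosize[ib]
  na <- nrow(ya); nb <- nrow(yb)
  Sp <- ((na - 1) * cov(ya) + (nb - 1) * cov(yb)) / (na + nb - 2)
  dmu <- colMeans(ya) - colMeans(yb)
  Sinv <- tryCatch(solve(Sp), error = function(e) NULL)
  if (is.null(Sinv) || rcond(Sp) < 1e-12) {
    warning("singular pooled covariance; using pseudo-inverse for the LDA axis")
    Sinv <- MASS::ginv(Sp)
  }
  one <- rep(1, length(dmu))
  d2 <- drop(t(dmu) %*% Sinv %*% dmu)
  iso2 <- drop(t(one) %*% Sinv %*% one)
  delta <- if (d2 <= 0 || iso2 <= 0) NA_real_ else
    abs(drop(t(dmu) %*% Sinv %*% one)) / sqrt(d2 * iso2)
  structure(list(
    group_a = group_a, group_b = group_b,
    best = ratio_info(best), second = ratio_info(second),
    D_matrix = D, d_full = sqrt(max(d2, 0)), delta = delta,
    separable = max(D) > 1e-8), class = "lda_ratio_result")
}

#' @export
print.lda_ratio_result <- function(x, ...) {
  cat("<lda_ratio_result> ", paste(x$group_a, collapse = "+"), " vs ",
      paste(x$group_b, collapse = "+"), "\n",
      "  best   ", paste(x$best$characters, collapse = "/"),
      "  D = ", format(x$best$D, digits = 3), "\n",
      "  second ", paste(x$second$characters, collapse = "/"),
      "  D = ", format(x$second$D, digits = 3), "\n",
      "  delta = ", format(x$delta, digits = 3),
      "  D_full = ", format(x$d_full, digits = 3), "\n", sep = "")
  invisible(x)
}
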