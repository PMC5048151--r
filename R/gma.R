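# Landmark geometric morphometrics: TPS I/O, generalized Procrustes
# analysis, PCA and CVA of aligned coordinates, and a covariance-matrix
# correlation permutation test.

#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of the landmarks from their
#' centroid.
#'
#' @param x k x 2 coordinate matrix.
#' @return Non-negative scalar.
#' @export
centroid_size <- function(x) {
  ctr <- sweep(x, 2, colMeans(x))
  sqrt(sum(ctr^2))
}

#' Read landmark configurations from a TPS file
#'
#' Parses the plain-text format written by tps-DIG digitizers: each record
#' is an `LM=k` line followed by k coordinate lines and an `ID=` line
#' (IMAGE= and SCALE= lines are ignored). Every record must have the
#' expected number of landmarks.
#'
#' @param path TPS file path.
#' @param k Required landmark count per record (default 7, the forewing
#'   scheme: submarginal/marginal/postmarginal/stigmal vein ends, wing tip,
#'   posterior margin tip).
#' @return A `landmark_set` (coords k x 2 x n, ids, species = NA).
#' @export
read_tps <- function(path, k = 7L) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  i <- 1L; cfgs <- list(); ids <- character()
  while (i <= length(lines)) {
    if (!grepl("^LM\\s*=", lines[i]))
      stop("line ", i, ": expected LM= record header")
    lm <- as.integer(sub("^LM\\s*=\\s*", "", lines[i]))
    rec_id <- length(cfgs) + 1L
    if (is.na(lm) || lm != k)
      stop("record ", rec_id, ": LM=", lm, " but expected ", k, " landmarks")
    if (i + lm > length(lines)) stop("record ", rec_id, ": truncated file")
    block <- lines[(i + 1L):(i + lm)]
    xy <- suppressWarnings(lapply(strsplit(block, "\\s+"), as.numeric))
    bad <- which(vapply(xy, function(v) length(v) != 2L || anyNA(v), logical(1)))
    if (length(bad))
      stop("malformed coordinate at line ", i + bad[1],
           " (record ", rec_id, ")")
    cfgs[[rec_id]] <- do.call(rbind, xy)
    i <- i + lm + 1L
    id <- NA_character_
    while (i <= length(lines) && !grepl("^LM\\s*=", lines[i])) {
      if (grepl("^ID\\s*=", lines[i])) id <- sub("^ID\\s*=\\s*", "", lines[i])
      i <- i + 1L
    }
    ids[rec_id] <- if (is.na(id)) as.character(rec_id) else id
  }
  structure(list(coords = array(unlist(cfgs), c(k, 2, length(cfgs))),
                 ids = ids, species = rep(NA_character_, length(cfgs)),
                 nuisance = NULL),
            class = "landmark_set")
}

#' Write landmark configurations to a TPS file
#'
#' @param dataset A `landmark_set` (e.g. from [gen_landmarks()] or
#'   [read_tps()]).
#' @param path Output path.
#' @export
write_tps <- function(dataset, path) {
  stopifnot(inherits(dataset, "landmark_set"))
  n <- dim(dataset$coords)[3]
  k <- dim(dataset$coords)[1]
  con <- file(path, "w"); on.exit(close(con))
  for (j in seq_len(n)) {
    writeLines(sprintf("LM=%d", k), con)
    writeLines(sprintf("%.10g %.10g", dataset$coords[, 1, j],
                       dataset$coords[, 2, j]), con)
    writeLines(sprintf("ID=%s", dataset$ids[j]), con)
  }
  invisible(path)
}

# Optimal rotation of x onto target (both centered), reflections excluded.
.opt_rotation <- function(x, target) {
  s <- svd(crossprod(x, target))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u; u[, ncol(u)] <- -u[, ncol(u)]
    R <- u %*% t(s$v)
  }
  R
}

.canonical_frame <- function(aligned, consensus) {
  # Reporting convention: rotate everything so the consensus principal
  # axes coincide with the coordinate axes. Of the two rotations that
  # diagonalize the consensus (theta and theta + pi) pick the one that
  # gives the farthest-out landmark a positive first coordinate.
  M <- crossprod(consensus)
  e <- eigen(M, symmetric = TRUE)
  R <- e$vectors
  if (det(R) < 0) R[, 2] <- -R[, 2]
  rot <- consensus %*% R
  key <- which.max(rowSums(rot^2))
  if (rot[key, 1] < 0) R <- -R
  list(consensus = consensus %*% R,
       aligned = array(apply(aligned, 3, function(x) x %*% R),
                       dim(aligned)))
}

#' Generalized Procrustes analysis
#'
#' Iterative generalized least-squares superimposition: every configuration
#' is centered and scaled to unit centroid size (full Procrustes scaling),
#' then rotated onto the current consensus by the optimal rotation
#' (SVD-based, reflections excluded since wings come from one body side);
#' the consensus is updated as the mean of the aligned configurations,
#' rescaled to unit centroid size. Iteration stops when the consensus
#' root-mean-square change drops below `tol`. The objective (summed squared
#' distance of aligned configurations to their mean) is non-increasing
#' across iterations. The final fit is reported in a canonical frame
#' (consensus principal axes on the coordinate axes) so that the result is
#' invariant to similarity transforms of the input.
#'
#' @param dataset A `landmark_set`.
#' @param tol Convergence tolerance on consensus RMS change (default 1e-10).
#' @param max_iter Iteration cap (default 100; typical data converge in
#'   fewer than 10).
#' @return Object of class `procrustes_fit`: `consensus` (unit centroid
#'   size), `aligned` (k x 2 x n), `centroid_sizes`, `objective` (per
#'   iteration), `iterations`, `converged`, plus the input `ids`/`species`.
#' @export
gpa <- function(dataset, tol = 1e-10, max_iter = 100L) {
  stopifnot(inherits(dataset, "landmark_set"))
  n <- dim(dataset$coords)[3]
  if (n < 2L) stop("GPA needs at least 2 configurations")
  cs <- numeric(n)
  aligned <- dataset$coords
  for (j in seq_len(n)) {
    x <- aligned[, , j]
    x <- sweep(x, 2, colMeans(x))
    cs[j] <- sqrt(sum(x^2))
    if (cs[j] <= 0) stop("configuration ", dataset$ids[j],
                         " is degenerate (all landmarks coincident)")
    aligned[, , j] <- x / cs[j]
  }
  consensus <- aligned[, , 1]
  objective <- numeric()
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (j in seq_len(n))
      aligned[, , j] <- aligned[, , j] %*% .opt_rotation(aligned[, , j], consensus)
    mean_cfg <- apply(aligned, c(1, 2), mean)
    objective[iter] <- sum(apply(aligned, 3, function(x) sum((x - mean_cfg)^2)))
    new_consensus <- mean_cfg / sqrt(sum(mean_cfg^2))
    delta <- sqrt(mean((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) { converged <- TRUE; break }
  }
  frame <- .canonical_frame(aligned, consensus)
  structure(list(consensus = frame$consensus, aligned = frame$aligned,
                 centroid_sizes = cs, objective = objective,
                 iterations = iter, converged = converged,
                 ids = dataset$ids, species = dataset$species),
            class = "procrustes_fit")
}

#' @export
print.procrustes_fit <- function(x, ...) {
  cat("<procrustes_fit> ", dim(x$aligned)[3], " configurations, ",
      x$iterations, " iterations, converged: ", x$converged, "\n", sep = "")
  invisible(x)
}

.flatten_fit <- function(fit) {
  # Vectorized aligned configurations with orthogonal projection onto the
  # tangent plane at the consensus. The projection linearizes the unit-
  # centroid-size constraint, so downstream covariances have rank at most
  # 2k - 4 (2 translation + 1 rotation + 1 scale constraints).
  n <- dim(fit$aligned)[3]
  X <- t(vapply(seq_len(n), function(j) as.vector(fit$aligned[, , j]),
                numeric(prod(dim(fit$aligned)[1:2]))))
  cvec <- as.vector(fit$consensus)
  cvec <- cvec / sqrt(sum(cvec^2))
  X - (X %*% cvec - 1) %*% t(cvec)
}

#' PCA of Procrustes-aligned coordinates
#'
#' Operates on the vectorized aligned configurations (a 2k-vector per
#' specimen). Superimposition removes 2 translation, 1 rotation and 1 scale
#' degree of freedom, so the spectrum has rank at most 2k - 4 and at least
#' 4 numerically-zero eigenvalues. Percent variance is reported over the
#' nonzero eigenvalues and sums to 100.
#'
#' @param fit A [gpa()] result.
#' @return List with `values`, `vectors`, `percent`, `scores`, `nonzero`.
#' @export
landmark_pca <- function(fit) {
  stopifnot(inherits(fit, "procrustes_fit"))
  X <- .flatten_fit(fit)
  if (nrow(X) < 3L) stop("landmark PCA needs at least 3 specimens")
  e <- eigen(cov(X), symmetric = TRUE)
  total <- sum(pmax(e$values, 0))
  # degenerate: variation at the level of floating-point noise relative to
  # the (unit-size) configurations themselves
  if (total <= 1e-16 * max(1, mean(rowSums(X^2))))
    return(list(values = pmax(e$values, 0), vectors = e$vectors,
                percent = numeric(0), scores = NULL, nonzero = 0L,
                degenerate = TRUE))
  tol <- max(e$values) * 1e-10
  nz <- sum(e$values > tol)
  vals <- pmax(e$values, 0)
  ctr <- scale(X, center = TRUE, scale = FALSE)
  list(values = vals, vectors = e$vectors,
       percent = 100 * vals[seq_len(nz)] / sum(vals[seq_len(nz)]),
       scores = ctr %*% e$vectors, nonzero = nz, degenerate = FALSE)
}

#' Canonical variate analysis of aligned landmarks
#'
#' The aligned coordinates are first projected onto the leading principal
#' components (by default as many as the rank of the pooled within-group
#' covariance, which is singular in raw Procrustes coordinates), then the
#' generalized eigenproblem of between-group versus pooled within-group
#' covariance is solved in that subspace. At most g - 1 canonical axes are
#' returned.
#'
#' @param fit A [gpa()] result with species labels.
#' @param groups Optional group labels (defaults to `fit$species`).
#' @param n_keep Number of PCs to keep before the CVA (default: within-
#'   covariance rank).
#' @return List with `values` (canonical eigenvalues), `scores`
#'   (specimens x axes), `groups`, `n_axes`.
#' @export
cva <- function(fit, groups = fit$species, n_keep = NULL) {
  stopifnot(inherits(fit, "procrustes_fit"))
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2L) stop("CVA needs at least 2 groups")
  if (any(tab < 2L)) stop("every group needs at least 2 specimens")
  X <- .flatten_fit(fit)
  g <- length(tab)
  ctr <- scale(X, center = TRUE, scale = FALSE)
  W <- matrix(0, ncol(X), ncol(X))
  for (sp in names(tab)) {
    xs <- X[groups == sp, , drop = FALSE]
    W <- W + crossprod(scale(xs, center = TRUE, scale = FALSE))
  }
  W <- W / (nrow(X) - g)
  ew <- eigen(W, symmetric = TRUE)
  rank_w <- sum(ew$values > max(ew$values) * 1e-8)
  if (is.null(n_keep)) n_keep <- rank_w
  if (any(tab <= n_keep) && n_keep < rank_w)
    stop("every group must have more specimens than n_keep")
  n_keep <- min(n_keep, rank_w)
  P <- ew$vectors[, seq_len(n_keep), drop = FALSE]
  Z <- ctr %*% P
  Wp <- matrix(0, n_keep, n_keep)
  Bp <- matrix(0, n_keep, n_keep)
  for (sp in names(tab)) {
    zs <- Z[groups == sp, , drop = FALSE]
    Wp <- Wp + crossprod(scale(zs, center = TRUE, scale = FALSE))
    d <- colMeans(zs) - colMeans(Z)
    Bp <- Bp + nrow(zs) * tcrossprod(d)
  }
  Wp <- Wp / (nrow(X) - g)
  Bp <- Bp / (g - 1)
  M <- solve(Wp, Bp)
  e <- eigen(M)
  n_axes <- min(g - 1L, n_keep)
  vec <- Re(e$vectors[, seq_len(n_axes), drop = FALSE])
  list(values = Re(e$values[seq_len(n_axes)]),
       scores = Z %*% vec, groups = groups, n_axes = n_axes)
}

.block_offdiag_lower <- function(S, k) {
  # entries S[a, b], a > b, whose row and column belong to different
  # landmarks; coordinate a of the flattened 2k-vector belongs to landmark
  # ((a - 1) %% k) + 1.
  idx <- which(lower.tri(S), arr.ind = TRUE)
  lmk <- function(a) ((a - 1L) %% k) + 1L
  keep <- lmk(idx[, 1]) != lmk(idx[, 2])
  S[idx[keep, , drop = FALSE]]
}

.permute_landmarks <- function(S, perm, k) {
  # apply a landmark permutation jointly to the x and y coordinates
  ord <- c(perm, perm + k)
  S[ord, ord]
}

#' Covariance-matrix correlation permutation test
#'
#' Pearson correlation between the lower-triangle entries of two groups'
#' covariance matrices of aligned coordinates, keeping the landmark block
#' structure but excluding within-landmark (diagonal-block) entries. The
#' null distribution permutes landmark labels (x and y coordinates of a
#' landmark move together) in the second matrix `n_perm` times; identity
#' permutations are redrawn. The p-value is
#' `(1 + #permuted >= observed) / (n_perm + 1)`.
#'
#' @param fit A [gpa()] result.
#' @param group_a,group_b Species labels defining the two groups (>= 3
#'   specimens each).
#' @param n_perm Number of permutations (>= 99 for usable resolution).
#' @param seed Integer seed.
#' @return List with `correlation`, `p_value`, `n_perm`.
#' @export
covmat_correlation_test <- function(fit, group_a, group_b, n_perm = 999L,
                                    seed = 1L) {
  stopifnot(inherits(fit, "procrustes_fit"))
  if (n_perm < 99L) stop("n_perm must be >= 99 (p-value resolution)")
  X <- .flatten_fit(fit)
  k <- dim(fit$aligned)[1]
  xa <- X[fit$species %in% group_a, , drop = FALSE]
  xb <- X[fit$species %in% group_b, , drop = FALSE]
  if (nrow(xa) < 3L || nrow(xb) < 3L) stop("each group needs >= 3 specimens")
  Sa <- cov(xa); Sb <- cov(xb)
  obs <- cor(.block_offdiag_lower(Sa, k), .block_offdiag_lower(Sb, k))
  perm_stats <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      repeat {
        perm <- sample.int(k)
        if (any(perm != seq_len(k))) break
      }
      cor(.block_offdiag_lower(Sa, k),
          .block_offdiag_lower(.permute_landmarks(Sb, perm, k), k))
    }, numeric(1))
  })
  list(correlation = obs,
       p_value = (1 + sum(perm_stats >= obs)) / (n_perm + 1),
       n_perm = n_perm)
}
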