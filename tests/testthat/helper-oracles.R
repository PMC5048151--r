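# Independent oracles used across the suite. Each deliberately re-derives
# its quantity from first principles, on a different code path from the
# package implementation.

# Direct-formula K2P: explicit per-site loop, no shared helpers.
oracle_k2p <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  ts <- 0L; tv <- 0L; n <- 0L
  pur <- c("A", "G")
  for (i in seq_along(a)) {
    if (!(a[i] %in% c("A", "C", "G", "T"))) next
    if (!(b[i] %in% c("A", "C", "G", "T"))) next
    n <- n + 1L
    if (a[i] == b[i]) next
    if ((a[i] %in% pur) == (b[i] %in% pur)) ts <- ts + 1L else tv <- tv + 1L
  }
  P <- ts / n; Q <- tv / n
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

oracle_p_dist <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  mean(a[ok] != b[ok])
}

# Studentized-range upper tail by direct numerical integration:
# P(Q > q) with g groups and df error degrees of freedom.
oracle_ptukey_upper <- function(q, g, df) {
  inner <- function(s) {
    f <- function(z) g * dnorm(z) * (pnorm(z) - pnorm(z - q * s))^(g - 1)
    integrate(f, -Inf, Inf, rel.tol = 1e-9)$value
  }
  dens_s <- function(s)
    2 * (df / 2)^(df / 2) / gamma(df / 2) * s^(df - 1) * exp(-df * s^2 / 2)
  outer_f <- function(s) vapply(s, function(si) dens_s(si) * inner(si), numeric(1))
  1 - integrate(outer_f, 0, Inf, rel.tol = 1e-8)$value
}

# Exhaustive standard-distance scan over all character pairs, raw loops.
oracle_ratio_scan <- function(shape_a, shape_b) {
  p <- ncol(shape_a)
  best <- c(NA, NA); best_d <- -Inf
  D <- matrix(0, p, p)
  for (i in seq_len(p - 1)) for (j in seq((i + 1), p)) {
    ra <- shape_a[, i] - shape_a[, j]
    rb <- shape_b[, i] - shape_b[, j]
    na <- length(ra); nb <- length(rb)
    sp <- sqrt(((na - 1) * var(ra) + (nb - 1) * var(rb)) / (na + nb - 2))
    d <- if (sp > 0) abs(mean(ra) - mean(rb)) / sp else 0
    D[i, j] <- D[j, i] <- d
    if (d > best_d) { best_d <- d; best <- c(i, j) }
  }
  list(best = best, best_d = best_d, D = D)
}

# Closed-form two-shape full Procrustes superimposition (reflection
# excluded): returns the aligned second shape and the mean shape.
oracle_opa2 <- function(x1, x2) {
  ctr <- function(x) sweep(x, 2, colMeans(x))
  x1 <- ctr(x1); x1 <- x1 / sqrt(sum(x1^2))
  x2 <- ctr(x2); x2 <- x2 / sqrt(sum(x2^2))
  s <- svd(crossprod(x2, x1))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) { u <- s$u; u[, 2] <- -u[, 2]; R <- u %*% t(s$v) }
  x2r <- x2 %*% R
  m <- (x1 + x2r) / 2
  list(aligned2 = x2r, mean = m / sqrt(sum(m^2)))
}

# Rotation-invariant RMS difference between two centered shapes.
procrustes_rms <- function(a, b) {
  s <- svd(crossprod(a, b))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) { u <- s$u; u[, 2] <- -u[, 2]; R <- u %*% t(s$v) }
  sqrt(mean((a %*% R - b)^2))
}

# Brute-force pure-diagnostic scan over positions x species.
oracle_diag_scan <- function(seqs, partition) {
  m <- unclass(seqs)
  sp_of <- partition[rownames(m)]
  species <- sort(unique(unname(sp_of)))
  rows <- list()
  for (pos in seq_len(ncol(m))) {
    for (s in species) {
      inside <- m[sp_of == s, pos]
      outside <- m[sp_of != s, pos]
      inside <- inside[inside %in% c("A", "C", "G", "T")]
      outside <- outside[outside %in% c("A", "C", "G", "T")]
      if (length(unique(inside)) == 1L && length(inside) > 0 &&
          !(inside[1] %in% outside))
        rows[[length(rows) + 1L]] <- data.frame(species = s, position = pos,
                                                state = inside[1])
    }
  }
  if (!length(rows)) return(data.frame(species = character(),
                                       position = integer(),
                                       state = character()))
  res <- do.call(rbind, rows)
  res <- res[order(res$species, res$position), ]
  rownames(res) <- NULL
  res
}

# Random unrooted binary tree with strictly positive branch lengths and its
# additive (cophenetic) matrix; the tree itself is the topology oracle.
random_additive <- function(n_taxa, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n_taxa, rooted = FALSE,
                     br = function(k) runif(k, 0.1, 1))
    list(tree = tr, d = ape::cophenetic.phylo(tr))
  })
}
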