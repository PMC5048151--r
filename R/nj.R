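# Neighbor-joining tree construction and column-bootstrap support.

.split_key <- function(leaves, n) {
  side <- if (1L %in% leaves) setdiff(seq_len(n), leaves) else leaves
  paste(sort(side), collapse = ",")
}

# Canonical NJ on a distance matrix. Returns the recursive node structure,
# the internal-edge splits (canonical keys over taxon indices), and labels.
.nj_core <- function(d, labels) {
  n <- nrow(d)
  nodes <- lapply(seq_len(n), function(i)
    list(leaf = i, leaves = i))
  splits <- character()
  clamp_pair <- function(bi, bj) {
    # negative branch clamped to 0, deficit moved to the sister edge
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- max(bi + bj, 0); bj <- 0 }
    c(bi, bj)
  }
  while (length(nodes) > 3L) {
    r <- nrow(d)
    R <- rowSums(d)
    Q <- (r - 2) * d - outer(R, R, "+")
    Q[lower.tri(Q, diag = TRUE)] <- Inf
    qmin <- min(Q)
    cand <- which(Q == qmin, arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    bi <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    bj <- d[i, j] - bi
    b <- clamp_pair(bi, bj)
    merged <- list(children = list(nodes[[i]], nodes[[j]]), lens = b,
                   leaves = sort(c(nodes[[i]]$leaves, nodes[[j]]$leaves)))
    merged$key <- .split_key(merged$leaves, n)
    splits <- c(splits, merged$key)
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    nodes <- c(nodes[keep], list(merged))
  }
  dv <- c(d[1, 2], d[1, 3], d[2, 3])
  a <- (dv[1] + dv[2] - dv[3]) / 2
  b <- (dv[1] + dv[3] - dv[2]) / 2
  cc <- (dv[2] + dv[3] - dv[1]) / 2
  root <- list(children = nodes, lens = pmax(c(a, b, cc), 0), root = TRUE)
  list(root = root, splits = splits, labels = labels, n = n)
}

.render_newick <- function(node, labels, supports = NULL, threshold = 0) {
  rec <- function(nd) {
    if (!is.null(nd$leaf)) return(labels[nd$leaf])
    parts <- vapply(seq_along(nd$children), function(i)
      sprintf("%s:%.15g", rec(nd$children[[i]]), nd$lens[i]), character(1))
    lbl <- ""
    if (!is.null(supports) && !is.null(nd$key) && !is.null(supports[[nd$key]])) {
      s <- supports[[nd$key]]
      if (s >= threshold) lbl <- format(s, digits = 4)
    }
    paste0("(", paste(parts, collapse = ","), ")", lbl)
  }
  paste0(rec(node), ";")
}

.validate_dist <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm) || !isSymmetric(unname(dm), tol = 1e-8))
    stop("distance matrix must be square and symmetric")
  if (any(diag(dm) != 0)) stop("distance matrix must have a zero diagonal")
  if (any(dm < 0)) stop("negative distances are not allowed")
  if (anyNA(dm)) stop("distance matrix contains undefined entries")
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <- paste0("t", seq_len(nrow(dm)))
  dm
}

#' Neighbor-joining tree
#'
#' Canonical NJ on a symmetric distance matrix (Q-matrix criterion, ties
#' broken by the smallest index pair). Branch lengths follow the standard
#' NJ formulas; a negative length is clamped to zero with the deficit moved
#' to its sister edge so that the path length between the joined nodes is
#' preserved. On an additive matrix the generating topology and branch
#' lengths are recovered exactly.
#'
#' @param dm Symmetric numeric matrix with zero diagonal, n >= 3, taxon
#'   names as dimnames.
#' @return An unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(dm) {
  dm <- .validate_dist(dm)
  if (nrow(dm) < 3L) stop("NJ needs at least 3 taxa")
  res <- .nj_core(dm, rownames(dm))
  ape::read.tree(text = .render_newick(res$root, res$labels))
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds
#' the NJ tree on each replicate, and scores every internal edge of the
#' full-data tree by the percentage of replicates containing the same
#' bipartition. Supports are attached as internal node labels; values below
#' `threshold` are omitted from the labels (but all are returned).
#' Replicates whose distance matrix is undefined (saturation) are dropped
#' and counted; losing more than 10 percent triggers a warning.
#'
#' @param seqs [aligned_sequences] object.
#' @param metric `"k2p"` or `"p"`.
#' @param n_reps Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param threshold Label reporting threshold in percent (default 75).
#' @param partition Optional specimen id -> species map; required when
#'   `collapse = TRUE`.
#' @param collapse Collapse to within-species haplotypes before the
#'   analysis (the haplotype-based mode).
#' @return Object of class `nj_bootstrap`: `tree` (phylo with node
#'   labels), `supports` (named numeric vector keyed by canonical
#'   bipartition of tip labels), `n_reps_used`, `n_dropped`.
#' @export
bootstrap_support <- function(seqs, metric = c("k2p", "p"), n_reps = 1000L,
                              seed = 1L, threshold = 75, partition = NULL,
                              collapse = FALSE) {
  metric <- match.arg(metric)
  if (ncol(seqs) < 2L) stop("alignment too short to bootstrap")
  if (collapse) {
    if (is.null(partition)) stop("collapse = TRUE requires a partition")
    seqs <- collapse_haplotypes(seqs, partition)$seqs
  }
  m <- unclass(seqs)
  d <- dist_matrix(aligned_sequences(m), metric)
  if (anyNA(d)) stop("full-data distance matrix has undefined entries")
  main <- .nj_core(d, rownames(m))
  counts <- setNames(numeric(length(main$splits)), main$splits)
  dropped <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(n_reps)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      db <- tryCatch(
        suppressWarnings(dist_matrix(aligned_sequences(m[, cols, drop = FALSE]),
                                     metric)),
        error = function(e) NULL)
      if (is.null(db) || anyNA(db)) { dropped <- dropped + 1L; next }
      rep_splits <- .nj_core(db, rownames(m))$splits
      hit <- intersect(names(counts), rep_splits)
      counts[hit] <- counts[hit] + 1
    }
  })
  used <- n_reps - dropped
  if (used == 0L) stop("all bootstrap replicates were dropped")
  if (dropped > 0.1 * n_reps)
    warning("more than 10% of replicates dropped (saturation)")
  support <- 100 * counts / used
  tree <- ape::read.tree(text = .render_newick(
    main$root, main$labels, supports = as.list(support), threshold = threshold))
  # re-key supports by tip labels for convenient lookup
  keyed <- setNames(unname(support), vapply(names(support), function(k) {
    idx <- as.integer(strsplit(k, ",")[[1]])
    paste(sort(main$labels[idx]), collapse = ",")
  }, character(1)))
  structure(list(tree = tree, supports = keyed, labels = main$labels,
                 n_reps_used = used, n_dropped = dropped,
                 threshold = threshold),
            class = "nj_bootstrap")
}

#' @export
print.nj_bootstrap <- function(x, ...) {
  cat("<nj_bootstrap> ", length(x$supports), " internal edges, ",
      x$n_reps_used, " replicates used (", x$n_dropped, " dropped)\n", sep = "")
  invisible(x)
}

#' Support of the bipartition separating a set of tips
#'
#' @param bs An [bootstrap_support()] result.
#' @param tips Character vector of tip labels on one side of the split.
#' @return Support percentage, or `NA` if the full-data tree has no such
#'   edge.
#' @export
split_support <- function(bs, tips) {
  stopifnot(inherits(bs, "nj_bootstrap"))
  all_tips <- bs$labels
  side <- if (all_tips[1] %in% tips) setdiff(all_tips, tips) else tips
  key <- paste(sort(side), collapse = ",")
  if (!key %in% names(bs$supports)) return(NA_real_)
  unname(bs$supports[[key]])
}
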