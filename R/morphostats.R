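# Per-character descriptive statistics and Tukey HSD post-hoc comparisons.

.char_cols <- function(table) intersect(morpho_characters, names(table))

#' Per-species, per-character boxplot statistics
#'
#' Median, quartiles and whisker bounds for every species x character cell.
#' The whiskers are the 2.5th and 97.5th percentiles, so that they cover
#' 95 percent of the distribution (rather than the more common 1.5 IQR
#' rule). Missing values are dropped per character and the drop is logged
#' with a message.
#'
#' @param table Measurement table (see [validate_measurement_table()]).
#' @return data.frame with columns `species`, `character`, `n`, `median`,
#'   `q1`, `q3`, `whisker_lo`, `whisker_hi`.
#' @export
summarize_characters <- function(table) {
  validate_measurement_table(table)
  out <- list()
  for (ch in .char_cols(table)) {
    v <- table[[ch]]
    if (anyNA(v))
      message("summarize_characters: dropping ", sum(is.na(v)),
              " missing value(s) in ", ch)
    for (sp in unique(table$species)) {
      x <- v[table$species == sp & !is.na(v)]
      if (!length(x)) next
      q <- quantile(x, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        species = sp, character = ch, n = length(x),
        median = q[3], q1 = q[2], q3 = q[4],
        whisker_lo = q[1], whisker_hi = q[5])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tukey HSD pairwise species comparisons per character
#'
#' For every character, all unordered species pairs are compared with
#' Tukey's honestly-significant-difference test at a family-wise confidence
#' level of `1 - alpha`. Unequal group sizes use the Tukey-Kramer form: the
#' interval half-width is `q/sqrt(2) * s_pooled * sqrt(1/n_i + 1/n_j)` with
#' `q` the studentized-range quantile for `g` groups and `N - g` error
#' degrees of freedom. A pair is significant exactly when the adjusted
#' p-value falls below `alpha`, equivalently when the simultaneous interval
#' excludes zero.
#'
#' @param table Measurement table.
#' @param alpha Family-wise error rate, default 0.05.
#' @return data.frame with one row per character x species pair: `character`,
#'   `group1`, `group2`, `diff`, `lwr`, `upr`, `p_adj`, `significant`.
#' @export
tukey_hsd <- function(table, alpha = 0.05) {
  validate_measurement_table(table)
  species <- unique(table$species)
  if (length(species) < 2L) stop("need at least two species")
  chars <- .char_cols(table)
  grp_all <- factor(table$species)
  prs <- combn(sort(levels(grp_all)), 2)
  np <- ncol(prs)
  nr <- length(chars) * np
  res <- data.frame(character = rep(chars, each = np),
                    group1 = rep(prs[1, ], length(chars)),
                    group2 = rep(prs[2, ], length(chars)),
                    diff = numeric(nr), lwr = numeric(nr), upr = numeric(nr),
                    p_adj = numeric(nr), significant = logical(nr))
  row <- 0L
  for (ch in chars) {
    v <- table[[ch]]
    keep <- !is.na(v)
    if (any(!keep))
      message("tukey_hsd: dropping ", sum(!keep), " missing value(s) in ", ch)
    x <- v[keep]; grp <- grp_all[keep]
    ns <- tabulate(grp)
    names(ns) <- levels(grp)
    if (any(ns < 2L))
      stop("character ", ch, ": every species needs >= 2 specimens")
    g <- length(ns); N <- length(x)
    means <- vapply(split(x, grp), mean, numeric(1))
    vars <- vapply(split(x, grp), var, numeric(1))
    s2 <- sum((ns - 1) * vars) / (N - g)
    if (s2 <= 0)
      stop("character ", ch, ": zero within-group variance in all groups")
    df <- N - g
    qcrit <- qtukey(1 - alpha, g, df)
    d <- means[prs[2, ]] - means[prs[1, ]]
    se <- sqrt(s2 * (1 / ns[prs[1, ]] + 1 / ns[prs[2, ]]) / 2)
    padj <- ptukey(abs(d) / se, g, df, lower.tail = FALSE)
    idx <- row + seq_len(np)
    res$diff[idx] <- d
    res$lwr[idx] <- d - qcrit * se
    res$upr[idx] <- d + qcrit * se
    res$p_adj[idx] <- padj
    res$significant[idx] <- padj < alpha
    row <- row + np
  }
  res
}
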