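# Distance- and character-based DNA barcode analysis.

.valid_base <- function(x) x %in% c("A", "C", "G", "T")
.is_purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)

.pair_counts <- function(a, b) {
  ok <- .valid_base(a) & .valid_base(b)   # pairwise deletion of N / gaps
  n <- sum(ok)
  if (n == 0L) stop("no comparable sites between the two sequences")
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  ts <- diff & (.is_purine[a] == .is_purine[b])
  list(n = n, ts = sum(ts), tv = sum(diff) - sum(ts))
}

.as_site_vector <- function(x) {
  if (inherits(x, "aligned_seqs")) {
    if (nrow(x) != 1L) stop("expected a single sequence")
    return(unclass(x)[1, ])
  }
  if (is.character(x) && length(x) == 1L) return(strsplit(toupper(x), "")[[1]])
  toupper(as.character(x))
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of differing sites among the sites where both sequences have
#' an unambiguous base (pairwise deletion of N and gaps).
#'
#' @param a,b Sequences of equal length: single strings or character
#'   vectors of sites.
#' @return Scalar in \[0, 1\].
#' @export
p_distance <- function(a, b) {
  a <- .as_site_vector(a); b <- .as_site_vector(b)
  if (length(a) != length(b)) stop("sequences differ in length")
  ct <- .pair_counts(a, b)
  (ct$ts + ct$tv) / ct$n
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' With P and Q the transition and transversion proportions over comparable
#' sites, `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`. Saturated pairs
#' (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) are an error: the distance is
#' undefined.
#'
#' @inheritParams p_distance
#' @return Non-negative scalar.
#' @export
k2p_distance <- function(a, b) {
  a <- .as_site_vector(a); b <- .as_site_vector(b)
  if (length(a) != length(b)) stop("sequences differ in length")
  ct <- .pair_counts(a, b)
  P <- ct$ts / ct$n; Q <- ct$tv / ct$n
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) stop("saturated pair: K2P distance undefined")
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Pairwise distance matrix for an alignment
#'
#' Vectorized computation of all pairwise p or K2P distances under
#' pairwise deletion. Saturated K2P pairs become `NA` with a warning.
#'
#' @param seqs [aligned_sequences] object.
#' @param metric `"k2p"` or `"p"`.
#' @return Symmetric matrix with zero diagonal and specimen ids as
#'   dimnames; `NA` marks undefined pairs.
#' @export
dist_matrix <- function(seqs, metric = c("k2p", "p")) {
  metric <- match.arg(metric)
  m <- unclass(seqs)
  n <- nrow(m)
  IA <- (m == "A") * 1; IC <- (m == "C") * 1
  IG <- (m == "G") * 1; IT <- (m == "T") * 1
  V <- IA + IC + IG + IT                       # valid-site indicator
  comp <- tcrossprod(V)                        # comparable sites per pair
  match_ct <- tcrossprod(IA) + tcrossprod(IC) + tcrossprod(IG) + tcrossprod(IT)
  R <- IA + IG; Y <- IC + IT
  tv <- tcrossprod(R, Y); tv <- tv + t(tv)     # transversions
  ts <- comp - match_ct - tv                   # transitions
  if (any(comp[upper.tri(comp)] == 0))
    stop("some sequence pairs share no comparable sites")
  d <- if (metric == "p") {
    (ts + tv) / comp
  } else {
    P <- ts / comp; Q <- tv / comp
    w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
    sat <- w1 <= 0 | w2 <= 0
    w1[sat] <- NA; w2[sat] <- NA
    if (any(sat[upper.tri(sat)]))
      warning(sum(sat[upper.tri(sat)]), " saturated pair(s): K2P undefined")
    -0.5 * log(w1) - 0.25 * log(w2)
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Collapse identical sequences into haplotypes within species
#'
#' Within each species, sequences that agree at every site where both have
#' an unambiguous base are merged (greedily, in input order) into one
#' haplotype represented by the first member. Identical sequences in
#' different species are never merged.
#'
#' @param seqs [aligned_sequences] object.
#' @param partition Named character vector specimen id -> species.
#' @return List with `seqs` (representatives), `partition` (remapped),
#'   `multiplicity` (named integer vector) and `members` (list of input ids
#'   per haplotype).
#' @export
collapse_haplotypes <- function(seqs, partition) {
  m <- unclass(seqs)
  ids <- rownames(m)
  if (!all(ids %in% names(partition)))
    stop("partition does not cover all sequence ids")
  keep <- character(); members <- list()
  for (sp in unique(partition[ids])) {
    sp_ids <- ids[partition[ids] == sp]
    reps <- character()
    for (id in sp_ids) {
      placed <- FALSE
      for (r in reps) {
        a <- m[r, ]; b <- m[id, ]
        ok <- .valid_base(a) & .valid_base(b)
        if (all(a[ok] == b[ok])) {
          members[[r]] <- c(members[[r]], id); placed <- TRUE; break
        }
      }
      if (!placed) { reps <- c(reps, id); members[[id]] <- id }
    }
    keep <- c(keep, reps)
  }
  out <- aligned_sequences(m[keep, , drop = FALSE])
  list(seqs = out, partition = partition[keep],
       multiplicity = setNames(lengths(members[keep]), keep),
       members = members[keep])
}

.pair_frame <- function(d) {
  idx <- which(upper.tri(d), arr.ind = TRUE)
  data.frame(i = rownames(d)[idx[, 1]], j = colnames(d)[idx[, 2]],
             dist = d[idx])
}

#' Intra- and interspecific distance summary
#'
#' Means, standard errors (SD of the pairwise values over the square root
#' of the number of pairs), minima and maxima of the pairwise distances
#' within each species and between each species pair. Species with fewer
#' than two members get no intra row (noted via message); undefined
#' pairwise distances are excluded and counted.
#'
#' @inheritParams collapse_haplotypes
#' @param metric `"k2p"` or `"p"`.
#' @return Object of class `distance_summary`: list with `intra` and
#'   `inter` data.frames, `metric` and `n_undefined`.
#' @export
distance_summary <- function(seqs, partition, metric = c("k2p", "p")) {
  metric <- match.arg(metric)
  d <- dist_matrix(seqs, metric)
  pf <- .pair_frame(d)
  n_undef <- sum(is.na(pf$dist))
  if (n_undef) message("distance_summary: ", n_undef, " undefined pair(s) excluded")
  pf <- pf[!is.na(pf$dist), , drop = FALSE]
  pf$sp_i <- unname(partition[pf$i]); pf$sp_j <- unname(partition[pf$j])
  stat_row <- function(v) data.frame(n_pairs = length(v), mean = mean(v),
                                     se = if (length(v) > 1) sd(v) / sqrt(length(v)) else 0,
                                     min = min(v), max = max(v))
  intra <- list(); inter <- list()
  species <- sort(unique(unname(partition)))
  for (sp in species) {
    v <- pf$dist[pf$sp_i == sp & pf$sp_j == sp]
    if (!length(v)) {
      message("distance_summary: species ", sp,
              " has < 2 members; intra statistics omitted")
      next
    }
    intra[[length(intra) + 1L]] <- cbind(data.frame(species = sp), stat_row(v))
  }
  for (p in seq_len(choose(length(species), 2))) {
    pair <- combn(species, 2)[, p]
    v <- pf$dist[(pf$sp_i == pair[1] & pf$sp_j == pair[2]) |
                 (pf$sp_i == pair[2] & pf$sp_j == pair[1])]
    inter[[length(inter) + 1L]] <- cbind(
      data.frame(species_1 = pair[1], species_2 = pair[2]), stat_row(v))
  }
  structure(list(intra = do.call(rbind, intra), inter = do.call(rbind, inter),
                 metric = metric, n_undefined = n_undef),
            class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  cat("<distance_summary> metric:", x$metric, "\n")
  print(x$intra); print(x$inter)
  invisible(x)
}

#' Barcode gap
#'
#' Compares the maximum intraspecific distance with the minimum
#' interspecific distance; a barcode gap exists when the former is strictly
#' smaller than the latter. Both extremes are reported with the specimen
#' pairs that realize them.
#'
#' @inheritParams distance_summary
#' @return List with `max_intra`, `min_inter`, `gap` (logical), and the
#'   realizing pairs `max_intra_pair`, `min_inter_pair`.
#' @export
barcode_gap <- function(seqs, partition, metric = c("k2p", "p")) {
  metric <- match.arg(metric)
  if (length(unique(unname(partition))) < 2L) stop("need >= 2 species")
  d <- dist_matrix(seqs, metric)
  pf <- .pair_frame(d)
  pf <- pf[!is.na(pf$dist), , drop = FALSE]
  same <- unname(partition[pf$i]) == unname(partition[pf$j])
  if (!any(same) || !any(!same)) stop("need both intra- and interspecific pairs")
  wi <- which(same)[which.max(pf$dist[same])]
  wo <- which(!same)[which.min(pf$dist[!same])]
  list(max_intra = pf$dist[wi], min_inter = pf$dist[wo],
       gap = pf$dist[wi] < pf$dist[wo],
       max_intra_pair = c(pf$i[wi], pf$j[wi]),
       min_inter_pair = c(pf$i[wo], pf$j[wo]),
       metric = metric)
}

#' Pure diagnostic barcode characters
#'
#' A position/state pair is a pure (simple) diagnostic for a species when
#' every member of that species carries the state at the position and no
#' specimen of any other species does. Members with an ambiguous base at a
#' position are ignored there, but a species polymorphic at a position
#' (two or more unambiguous states) is never pure there; its observed state
#' set is reported in the per-position context. Positions are 1-based
#' alignment coordinates. All-gap columns are skipped and counted.
#'
#' @inheritParams collapse_haplotypes
#' @return Object of class `diagnostic_table`: `diagnostics` data.frame
#'   (`species`, `position`, `state`), `context` data.frame with the full
#'   species x state sets at every variable position, and
#'   `n_skipped_columns`.
#' @export
pure_diagnostic_characters <- function(seqs, partition) {
  m <- unclass(seqs)
  ids <- rownames(m)
  if (!all(ids %in% names(partition)))
    stop("partition does not cover all sequence ids")
  sp_of <- partition[ids]
  species <- sort(unique(unname(sp_of)))
  diag_rows <- list(); ctx_rows <- list(); skipped <- 0L
  for (pos in seq_len(ncol(m))) {
    col <- m[, pos]
    ok <- .valid_base(col)
    if (!any(ok)) { skipped <- skipped + 1L; next }
    states_by_sp <- lapply(species, function(s)
      sort(unique(col[ok & sp_of == s])))
    names(states_by_sp) <- species
    all_states <- unlist(states_by_sp, use.names = FALSE)
    if (length(unique(all_states)) < 2L) next
    for (s in species) {
      st <- states_by_sp[[s]]
      ctx_rows[[length(ctx_rows) + 1L]] <- data.frame(
        position = pos, species = s,
        states = paste(st, collapse = "/"))
      if (length(st) != 1L) next                       # polymorphic or absent
      others <- unlist(states_by_sp[setdiff(species, s)], use.names = FALSE)
      if (!(st %in% others))
        diag_rows[[length(diag_rows) + 1L]] <- data.frame(
          species = s, position = pos, state = st)
    }
  }
  if (skipped) message("pure_diagnostic_characters: skipped ", skipped,
                       " column(s) with no unambiguous base")
  empty <- data.frame(species = character(), position = integer(),
                      state = character())
  diagnostics <- if (length(diag_rows)) do.call(rbind, diag_rows) else empty
  diagnostics <- diagnostics[order(diagnostics$species, diagnostics$position), ,
                             drop = FALSE]
  rownames(diagnostics) <- NULL
  structure(list(diagnostics = diagnostics,
                 context = if (length(ctx_rows)) do.call(rbind, ctx_rows) else NULL,
                 n_skipped_columns = skipped),
            class = "diagnostic_table")
}

#' @export
print.diagnostic_table <- function(x, ...) {
  cat("<diagnostic_table> ", nrow(x$diagnostics),
      " pure diagnostic character(s)\n", sep = "")
  print(x$diagnostics)
  invisible(x)
}
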