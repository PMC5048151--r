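# Synthetic three-species data generator.
#
# All three artifacts (measurement table, landmark configurations, aligned
# sequences) are drawn from a single `scenario` object so that planted
# structure is consistent across stages. Random draws are made per artifact
# and per species from seeds derived from the scenario seed by fixed
# offsets, so adding a species to a scenario never perturbs the draws of
# the species already present.

.artifact_offsets <- c(measurements = 101L, landmarks = 202L, sequences = 303L)

.species_seed <- function(scenario, artifact, i) {
  base <- as.integer(scenario$seed) %% 1000000L
  base * 1000L + .artifact_offsets[[artifact]] + i
}

#' Species model for the synthetic generator
#'
#' Describes one species' statistical signature across the three data types:
#' lognormal measurement variation with allometric slopes, a mean landmark
#' configuration, and species-fixed diagnostic substitutions plus a
#' within-species polymorphism rate.
#'
#' @param name Species label.
#' @param mu_log Numeric vector of mean log-measurements, one per character
#'   in [morpho_characters] order (log-mm).
#' @param allometric_slope Per-character slope of log-measurement on
#'   log-size; all slopes equal means isometric growth.
#' @param size_sd Standard deviation of specimen log-size (>= 0).
#' @param mean_shape k x 2 matrix of mean landmark coordinates.
#' @param diag_positions Named integer-keyed map of species-fixed states:
#'   a character vector of nucleotides named by 1-based alignment position,
#'   e.g. `c("14" = "G")`.
#' @param poly_rate Per-site within-species polymorphism probability in
#'   \[0, 1\].
#' @param kappa Transition/transversion rate ratio (> 0).
#' @return An object of class `species_model`.
#' @export
species_model <- function(name, mu_log, allometric_slope = rep(1, length(mu_log)),
                          size_sd = 0.1, mean_shape = NULL,
                          diag_positions = character(), poly_rate = 0,
                          kappa = 4) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!all(is.finite(mu_log)) || !all(is.finite(allometric_slope)))
    stop("non-finite model parameters in species '", name, "'")
  if (length(allometric_slope) != length(mu_log))
    stop("mu_log and allometric_slope must have the same length")
  if (!is.finite(size_sd) || size_sd < 0)
    stop("size_sd must be a finite non-negative scalar")
  if (!is.null(mean_shape)) {
    mean_shape <- as.matrix(mean_shape)
    if (ncol(mean_shape) != 2L) stop("mean_shape must be a k x 2 matrix")
    if (centroid_size(mean_shape) <= 0)
      stop("mean_shape is degenerate (centroid size 0)")
  }
  if (length(diag_positions)) {
    if (is.null(names(diag_positions)))
      stop("diag_positions must be named by alignment position")
    pos <- as.integer(names(diag_positions))
    if (anyNA(pos) || any(pos < 1L)) stop("diag_positions must have positive integer names")
    if (anyDuplicated(pos)) stop("duplicated diag positions in species '", name, "'")
    if (!all(diag_positions %in% c("A", "C", "G", "T")))
      stop("diag states must be in {A,C,G,T}")
  }
  if (!is.finite(poly_rate) || poly_rate < 0 || poly_rate > 1)
    stop("poly_rate must lie in [0, 1]")
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be > 0")
  structure(list(name = name, mu_log = mu_log,
                 allometric_slope = allometric_slope, size_sd = size_sd,
                 mean_shape = mean_shape, diag_positions = diag_positions,
                 poly_rate = poly_rate, kappa = kappa),
            class = "species_model")
}

#' Scenario: a fully specified synthetic world
#'
#' Bundles the species models, per-species sample sizes, the shared ancestral
#' sequence and the master seed. The constructor validates that planted
#' diagnostic substitutions do not conflict between species (no two species
#' planted with the same state at the same position) and that every planted
#' position lies inside the alignment.
#'
#' @param species List of [species_model] objects.
#' @param n_per_species Integer vector (recycled or named by species) of
#'   specimens per species; at least 2 each.
#' @param ancestor_seq Single DNA string over A/C/G/T.
#' @param seed Integer master seed.
#' @return An object of class `scenario`.
#' @export
scenario <- function(species, n_per_species, ancestor_seq, seed = 1L) {
  stopifnot(is.list(species), length(species) >= 1L)
  if (!all(vapply(species, inherits, logical(1), "species_model")))
    stop("species must be a list of species_model objects")
  nms <- vapply(species, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicated species names")
  n_per_species <- rep_len(as.integer(n_per_species), length(species))
  if (any(n_per_species < 2L))
    stop("n_per_species must be >= 2 for every species")
  ancestor_seq <- toupper(ancestor_seq)
  anc <- strsplit(ancestor_seq, "")[[1]]
  if (!all(anc %in% c("A", "C", "G", "T")))
    stop("ancestor_seq must be over {A,C,G,T}")
  L <- length(anc)
  planted <- list()
  for (sp in species) {
    if (!length(sp$diag_positions)) next
    pos <- as.integer(names(sp$diag_positions))
    if (any(pos > L)) stop("diag position beyond alignment length in '", sp$name, "'")
    for (k in seq_along(pos)) {
      key <- as.character(pos[k])
      st <- unname(sp$diag_positions[k])
      if (!is.null(planted[[key]]) && st %in% planted[[key]])
        stop("conflicting diag_positions: state ", st, " at position ", key,
             " planted for more than one species")
      planted[[key]] <- c(planted[[key]], st)
    }
  }
  structure(list(species = species, n_per_species = n_per_species,
                 ancestor = anc, seed = as.integer(seed)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario> ", length(x$species), " species, n = ",
      paste(x$n_per_species, collapse = "/"),
      ", alignment length ", length(x$ancestor),
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

.specimen_ids <- function(scenario) {
  nms <- vapply(scenario$species, `[[`, character(1), "name")
  unlist(lapply(seq_along(nms), function(i)
    sprintf("%s_%03d", nms[i], seq_len(scenario$n_per_species[i]))),
    use.names = FALSE)
}

#' Species labels of every generated specimen
#'
#' @param scenario A [scenario].
#' @return Named character vector mapping specimen id to species label.
#' @export
scenario_partition <- function(scenario) {
  nms <- vapply(scenario$species, `[[`, character(1), "name")
  setNames(rep(nms, scenario$n_per_species), .specimen_ids(scenario))
}

#' Generate a synthetic measurement table
#'
#' For each specimen a log-size `s ~ Normal(0, size_sd)` is drawn; character
#' `c` then takes the value `exp(mu_log[c] + slope[c] * s + eps)` with
#' `eps ~ Normal(0, sigma_resid)`. All values are strictly positive by
#' construction and the draw is deterministic given the scenario seed.
#'
#' @param scenario A [scenario] whose species carry `mu_log` of length 25.
#' @param sigma_resid Residual SD on the log scale; default 0.05, a small
#'   relative measurement error typical of linear morphometrics.
#' @return A data.frame with columns `specimen_id`, `species` and the 25
#'   characters of [morpho_characters].
#' @export
gen_measurements <- function(scenario, sigma_resid = 0.05) {
  stopifnot(inherits(scenario, "scenario"))
  if (!is.finite(sigma_resid) || sigma_resid < 0)
    stop("sigma_resid must be finite and non-negative")
  p <- length(morpho_characters)
  out <- vector("list", length(scenario$species))
  for (i in seq_along(scenario$species)) {
    sp <- scenario$species[[i]]
    if (length(sp$mu_log) != p)
      stop("species '", sp$name, "' needs mu_log of length ", p)
    n <- scenario$n_per_species[i]
    vals <- withr::with_seed(.species_seed(scenario, "measurements", i), {
      s <- rnorm(n, 0, sp$size_sd)
      eps <- matrix(rnorm(n * p, 0, sigma_resid), n, p)
      exp(matrix(sp$mu_log, n, p, byrow = TRUE) + outer(s, sp$allometric_slope) + eps)
    })
    colnames(vals) <- morpho_characters
    out[[i]] <- data.frame(specimen_id = sprintf("%s_%03d", sp$name, seq_len(n)),
                           species = sp$name, vals,
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Generate synthetic landmark configurations
#'
#' Each configuration is the species mean shape plus iid isotropic Gaussian
#' noise per coordinate, then pushed through a random similarity transform:
#' rotation uniform on \[0, 2 pi), translation uniform in \[-1, 1\]^2, scale
#' log-uniform in \[0.5, 2\]. The nuisance parameters are recorded in the
#' result for test introspection; generalized Procrustes analysis must
#' remove them exactly.
#'
#' @param scenario A [scenario] whose species carry a `mean_shape`.
#' @param noise_sd Isotropic landmark noise SD (>= 0), in mean-shape units.
#' @return An object of class `landmark_set`: list with `coords`
#'   (k x 2 x n array), `ids`, `species`, and a `nuisance` data.frame.
#' @export
gen_landmarks <- function(scenario, noise_sd = 0.01) {
  stopifnot(inherits(scenario, "scenario"))
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  coords <- list(); nuis <- list()
  for (i in seq_along(scenario$species)) {
    sp <- scenario$species[[i]]
    if (is.null(sp$mean_shape))
      stop("species '", sp$name, "' has no mean_shape")
    k <- nrow(sp$mean_shape)
    n <- scenario$n_per_species[i]
    res <- withr::with_seed(.species_seed(scenario, "landmarks", i), {
      cfg <- array(NA_real_, c(k, 2, n))
      theta <- runif(n, 0, 2 * pi)
      tx <- runif(n, -1, 1); ty <- runif(n, -1, 1)
      sc <- exp(runif(n, log(0.5), log(2)))
      for (j in seq_len(n)) {
        x <- sp$mean_shape + matrix(rnorm(2 * k, 0, noise_sd), k, 2)
        R <- matrix(c(cos(theta[j]), sin(theta[j]),
                      -sin(theta[j]), cos(theta[j])), 2, 2)
        cfg[, , j] <- sc[j] * x %*% R +
          matrix(c(tx[j], ty[j]), k, 2, byrow = TRUE)
      }
      list(cfg = cfg, theta = theta, tx = tx, ty = ty, sc = sc)
    })
    coords[[i]] <- res$cfg
    nuis[[i]] <- data.frame(species = sp$name, theta = res$theta,
                            tx = res$tx, ty = res$ty, scale = res$sc)
  }
  cfg <- array(unlist(coords), c(nrow(scenario$species[[1]]$mean_shape), 2,
                                 sum(scenario$n_per_species)))
  structure(list(coords = cfg, ids = .specimen_ids(scenario),
                 species = unname(scenario_partition(scenario)),
                 nuisance = do.call(rbind, nuis)),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> ", dim(x$coords)[3], " configurations of ",
      dim(x$coords)[1], " landmarks\n", sep = "")
  invisible(x)
}

.transition <- c(A = "G", G = "A", C = "T", T = "C")
.transversions <- list(A = c("C", "T"), G = c("C", "T"),
                       C = c("A", "G"), T = c("A", "G"))

#' Generate a synthetic aligned sequence set
#'
#' Each specimen receives the ancestor sequence with its species'
#' diagnostic substitutions applied, after which every remaining site is
#' independently mutated with probability `poly_rate`; a mutation is a
#' transition with odds `kappa` : 1 against a transversion (the two possible
#' transversions being equally likely).
#'
#' @param scenario A [scenario].
#' @return List with `seqs` (an [aligned_sequences] object) and `partition`
#'   (named character vector specimen id -> species).
#' @export
gen_sequences <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  L <- length(scenario$ancestor)
  rows <- list()
  for (i in seq_along(scenario$species)) {
    sp <- scenario$species[[i]]
    base <- scenario$ancestor
    dpos <- as.integer(names(sp$diag_positions))
    if (length(dpos)) base[dpos] <- unname(sp$diag_positions)
    n <- scenario$n_per_species[i]
    free <- setdiff(seq_len(L), dpos)
    rows[[i]] <- withr::with_seed(.species_seed(scenario, "sequences", i), {
      m <- matrix(base, n, L, byrow = TRUE)
      if (sp$poly_rate > 0 && length(free)) {
        for (j in seq_len(n)) {
          hit <- free[runif(length(free)) < sp$poly_rate]
          if (!length(hit)) next
          is_ts <- runif(length(hit)) < sp$kappa / (sp$kappa + 1)
          cur <- m[j, hit]
          new <- character(length(hit))
          new[is_ts] <- .transition[cur[is_ts]]
          if (any(!is_ts)) {
            pick <- runif(sum(!is_ts)) < 0.5
            tv <- vapply(seq_along(cur[!is_ts]), function(q)
              .transversions[[cur[!is_ts][q]]][1 + pick[q]], character(1))
            new[!is_ts] <- tv
          }
          m[j, hit] <- new
        }
      }
      m
    })
  }
  m <- do.call(rbind, rows)
  rownames(m) <- .specimen_ids(scenario)
  list(seqs = aligned_sequences(m), partition = scenario_partition(scenario))
}

#' Ground-truth pure diagnostics of a scenario
#'
#' Computes, from the species base sequences (ancestor plus planted
#' substitutions, before polymorphism), the per-species pure diagnostic map
#' that [pure_diagnostic_characters()] must recover when `poly_rate` is 0:
#' a position/state pair is pure for a species when its base state at that
#' position occurs in no other species.
#'
#' @param scenario A [scenario].
#' @return data.frame with columns `species`, `position`, `state`.
#' @export
planted_diagnostics <- function(scenario) {
  base <- lapply(scenario$species, function(sp) {
    b <- scenario$ancestor
    dpos <- as.integer(names(sp$diag_positions))
    if (length(dpos)) b[dpos] <- unname(sp$diag_positions)
    b
  })
  nms <- vapply(scenario$species, `[[`, character(1), "name")
  states <- do.call(rbind, base)  # species x L
  out <- list()
  for (pos in which(apply(states, 2, function(col) length(unique(col)) > 1L))) {
    col <- states[, pos]
    uniq <- names(which(table(col) == 1L))
    for (s in which(col %in% uniq))
      out[[length(out) + 1L]] <- data.frame(species = nms[s], position = pos,
                                            state = col[s])
  }
  if (!length(out))
    return(data.frame(species = character(), position = integer(),
                      state = character()))
  res <- do.call(rbind, out)
  res <- res[order(res$species, res$position), , drop = FALSE]
  rownames(res) <- NULL
  res
}
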