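# Fixture builders shared across test files.

p_chars <- cryptax::morpho_characters

# Measurement table from a matrix of log-values (rows = specimens).
make_meas_table <- function(logvals, species, ids = NULL) {
  logvals <- as.matrix(logvals)
  stopifnot(ncol(logvals) == 25L)
  colnames(logvals) <- p_chars
  if (is.null(ids)) ids <- sprintf("s%03d", seq_len(nrow(logvals)))
  data.frame(specimen_id = ids, species = species, exp(logvals),
             stringsAsFactors = FALSE)
}

# Random-lognormal two/three group table with optional per-character shifts.
make_group_table <- function(n_per_group, shifts = list(), sd = 0.05,
                             seed = 1) {
  groups <- names(n_per_group)
  withr::with_seed(seed, {
    rows <- lapply(groups, function(g) {
      lv <- matrix(rnorm(n_per_group[[g]] * 25, 0, sd), ncol = 25)
      if (!is.null(shifts[[g]])) {
        sh <- shifts[[g]]
        idx <- match(names(sh), p_chars)
        lv[, idx] <- lv[, idx] + rep(unname(sh), each = nrow(lv))
      }
      lv
    })
    make_meas_table(do.call(rbind, rows),
                   rep(groups, unlist(n_per_group)))
  })
}

# Minimal two-species scenario for sequence-level tests.
tiny_scenario <- function(seed = 1, poly_rate = 0, n = c(3L, 3L, 3L),
                          L = 60) {
  withr::with_seed(seed + 999, {
    anc <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
  })
  anc_chars <- strsplit(anc, "")[[1]]
  pick_state <- function(pos) setdiff(c("A", "C", "G", "T"), anc_chars[pos])
  mu <- log(rep(0.1, 25))
  shape <- matrix(c(0, 0, 1, 0, 1, 1, 0.5, 1.5, 0.2, 0.8, 0.9, 0.1,
                    0.4, 0.6), ncol = 2)
  diag_for <- function(shared_state, own_pos) {
    states <- vapply(own_pos, function(p) pick_state(p)[1], character(1))
    setNames(c(shared_state, states), c("5", own_pos))
  }
  sp <- list(
    cryptax::species_model("alpha", mu, mean_shape = shape,
                           diag_positions = diag_for(pick_state(5)[1],
                                                     c(8, 12, 20, 28)),
                           poly_rate = poly_rate),
    cryptax::species_model("beta", mu, mean_shape = shape,
                           diag_positions = diag_for(pick_state(5)[2],
                                                     c(33, 36, 40, 44)),
                           poly_rate = poly_rate),
    cryptax::species_model("gamma", mu, mean_shape = shape,
                           diag_positions = diag_for(pick_state(5)[3],
                                                     c(47, 50, 54, 58)),
                           poly_rate = poly_rate))
  cryptax::scenario(sp, n_per_species = n, ancestor_seq = anc, seed = seed)
}

# Landmark set built directly from a list of k x 2 matrices.
make_landmark_set <- function(configs, species = NULL, ids = NULL) {
  k <- nrow(configs[[1]])
  n <- length(configs)
  if (is.null(ids)) ids <- sprintf("s%03d", seq_len(n))
  if (is.null(species)) species <- rep("sp", n)
  structure(list(coords = array(unlist(configs), c(k, 2, n)),
                 ids = ids, species = species, nuisance = NULL),
            class = "landmark_set")
}

# Apply a random similarity transform (rotation, translation, scale > 0).
random_similarity <- function(x, seed) {
  withr::with_seed(seed, {
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    sc <- exp(runif(1, log(0.5), log(2)))
    tr <- runif(2, -5, 5)
    sc * x %*% R + matrix(tr, nrow(x), 2, byrow = TRUE)
  })
}

seq_set <- function(...) {
  cryptax::aligned_sequences(c(...))
}
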