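# Default three-species scenario.
#
# The default world mirrors the structure of the Encyrtus sasakii complex:
# three species whose linear measurements overlap broadly but differ in a
# handful of body ratios, whose wing shapes differ subtly at a few
# landmarks, and whose COI sequences carry species-fixed diagnostic states
# on a shared 557-site background with low within-species polymorphism.
# Sample sizes (17/48/55) follow the published per-species COI sample
# counts. Effect sizes on the measurement side are chosen so that the best
# discriminating ratios reach standard distances in the low single digits,
# the regime reported for this complex.

# Species-fixed COI states (1-based positions within the 557-site matrix).
.diag_sasakii <- c(
  "14" = "G", "32" = "G", "122" = "A", "224" = "G", "227" = "G",
  "233" = "A", "245" = "G", "254" = "A", "266" = "A", "271" = "A",
  "281" = "G", "284" = "T", "290" = "G", "320" = "G", "335" = "A",
  "431" = "G", "443" = "A", "467" = "A", "470" = "G", "494" = "G")
.diag_eulecaniumiae <- c(
  "14" = "A", "47" = "G", "53" = "G", "68" = "A", "134" = "A",
  "203" = "G", "236" = "G", "266" = "G", "281" = "A", "341" = "A",
  "461" = "A", "470" = "A", "533" = "A")
.diag_rhodococcusiae <- c(
  "14" = "T", "26" = "A", "102" = "A", "149" = "A", "161" = "C",
  "176" = "G", "215" = "G", "266" = "T", "269" = "A", "281" = "T",
  "389" = "A", "446" = "A", "468" = "C", "470" = "T", "521" = "T",
  "530" = "G")

# Baseline mean measurements (mm) for a ~1.5 mm encyrtid female, in
# morpho_characters order.
.base_measurements_mm <- c(
  CL = 0.25, CW = 0.10, F1L = 0.050, F1W = 0.040, F2L = 0.050,
  F2W = 0.045, F3L = 0.055, F3W = 0.050, F4L = 0.055, F4W = 0.055,
  F5L = 0.055, F5W = 0.060, F6L = 0.055, F6W = 0.065, FT = 0.45,
  HT = 0.55, MT = 0.60, MTS = 0.25, OV = 0.55, PL = 0.12,
  PVL = 0.050, PW = 0.055, SL = 0.20, SVL = 0.15, SW = 0.050)

# Mild allometry on ovipositor and mid tibial spur; all else isometric.
.base_slopes <- setNames(rep(1, 25), morpho_characters)
.base_slopes[["OV"]] <- 1.2
.base_slopes[["MTS"]] <- 0.8

# Per-species shifts on the log scale for a few ratio-defining characters.
.shift_sasakii <- c(F2L = 0.10, PVL = -0.06)
.shift_eulecaniumiae <- c(SL = 0.08, F1W = -0.08, F3W = 0.08)
.shift_rhodococcusiae <- c(F5W = 0.10, OV = -0.06, F3W = -0.08)

.apply_shift <- function(mu, shift) {
  mu[names(shift)] <- mu[names(shift)] + shift
  mu
}

# Mean forewing shapes: seven landmarks tracing submarginal, marginal,
# postmarginal and stigmal veins plus the wing tip and posterior margin.
.base_wing <- matrix(c(
  0.00,  0.10,
  0.45,  0.22,
  0.70,  0.25,
  0.95,  0.24,
  0.80,  0.18,
  1.25,  0.05,
  0.60, -0.12), ncol = 2, byrow = TRUE)

.wing_sasakii <- .base_wing
.wing_eulecaniumiae <- local({
  w <- .base_wing
  w[4, ] <- w[4, ] + c(0.03, 0.01)
  w[6, ] <- w[6, ] + c(-0.02, 0.02)
  w
})
.wing_rhodococcusiae <- local({
  w <- .base_wing
  w[2, ] <- w[2, ] + c(0.00, 0.02)
  w[5, ] <- w[5, ] + c(-0.02, -0.02)
  w[7, ] <- w[7, ] + c(0.03, -0.01)
  w
})

#' Bundled synthetic ancestral COI sequence
#'
#' Returns the fixed pseudo-random 557-nt ancestor stored with the package
#' (a synthetic stand-in, not a real accession). At every alignment position
#' where exactly one default species carries a planted diagnostic state the
#' ancestor holds the state shared by the other two species, so the planted
#' diagnostic map of [default_scenario()] is exactly its recoverable pure
#' diagnostic map.
#'
#' @return Single DNA string of length 557.
#' @export
default_ancestor <- function() {
  path <- system.file("extdata", "ancestor_coi_synthetic.fasta",
                      package = "cryptax")
  if (path == "") stop("bundled ancestor sequence not found")
  unname(as.character(read_alignment_fasta(path)$seqs))
}

#' The default three-species scenario
#'
#' A synthetic world with three species ("sasakii", "eulecaniumiae",
#' "rhodococcusiae"), sample sizes 17/48/55, broadly overlapping lognormal
#' measurements with a few ratio-defining shifts, subtly distinct wing
#' shapes, and COI sequences with planted species-fixed diagnostics over a
#' shared 557-site ancestor.
#'
#' @param seed Master seed for all generated artifacts.
#' @param poly_rate Per-site within-species polymorphism probability;
#'   default 0.006 gives mean intraspecific distances near 1 percent,
#'   matching the order of magnitude seen in this complex.
#' @param kappa Transition/transversion odds; default 4, typical for
#'   insect mitochondrial COI.
#' @return A [scenario].
#' @export
default_scenario <- function(seed = 1L, poly_rate = 0.006, kappa = 4) {
  mu <- log(.base_measurements_mm)
  sp <- list(
    species_model("sasakii", .apply_shift(mu, .shift_sasakii),
                  allometric_slope = .base_slopes, size_sd = 0.1,
                  mean_shape = .wing_sasakii, diag_positions = .diag_sasakii,
                  poly_rate = poly_rate, kappa = kappa),
    species_model("eulecaniumiae", .apply_shift(mu, .shift_eulecaniumiae),
                  allometric_slope = .base_slopes, size_sd = 0.1,
                  mean_shape = .wing_eulecaniumiae,
                  diag_positions = .diag_eulecaniumiae,
                  poly_rate = poly_rate, kappa = kappa),
    species_model("rhodococcusiae", .apply_shift(mu, .shift_rhodococcusiae),
                  allometric_slope = .base_slopes, size_sd = 0.1,
                  mean_shape = .wing_rhodococcusiae,
                  diag_positions = .diag_rhodococcusiae,
                  poly_rate = poly_rate, kappa = kappa))
  scenario(sp, n_per_species = c(17L, 48L, 55L),
           ancestor_seq = default_ancestor(), seed = seed)
}
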