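# Configuration-driven orchestration of the full analysis: synthetic data
# (or user files) -> morphometric statistics -> MRA -> GMA -> barcoding,
# with per-stage outputs and one machine-readable JSON summary.

.default_params <- function() {
  list(alpha = 0.05, n_boot = 200L, n_perm = 999L, n_reps = 200L,
       metric = "k2p", tol = 1e-10, sigma_resid = 0.05, noise_sd = 0.01,
       collapse = TRUE, bootstrap_threshold = 75, poly_rate = 0.006,
       kappa = 4)
}

#' Assemble a pipeline run configuration
#'
#' A configuration either names the bundled `"default"` scenario (synthetic
#' data generated on the fly) or points at user files (measurements CSV,
#' TPS landmarks, aligned FASTA, partition CSV). Seeds are always explicit;
#' there is no wall-clock seeding anywhere in the pipeline.
#'
#' @param scenario `"default"` to generate synthetic data, or `NULL` when
#'   using file inputs.
#' @param inputs Named list of file paths (`measurements`, `tps`, `fasta`,
#'   `partition`) for the stages you enable.
#' @param stages Named logical list enabling `morpho`, `mra`, `gma`,
#'   `barcode`.
#' @param params Stage parameters overriding the defaults (`alpha`,
#'   `n_boot`, `n_perm`, `n_reps`, `metric`, `tol`, `sigma_resid`,
#'   `noise_sd`, `collapse`, `bootstrap_threshold`, `poly_rate`, `kappa`).
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return List of class `run_config`.
#' @export
run_config <- function(scenario = "default", inputs = list(),
                       stages = list(), params = list(), seed = 1L,
                       out_dir = tempfile("cryptax_run_")) {
  st <- list(morpho = TRUE, mra = TRUE, gma = TRUE, barcode = TRUE)
  st[names(stages)] <- stages
  pr <- .default_params()
  unknown <- setdiff(names(params), names(pr))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  pr[names(params)] <- params
  cfg <- list(scenario = scenario, inputs = inputs, stages = st,
              params = pr, seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "run_config"
  .validate_config(cfg)
  cfg
}

.validate_config <- function(cfg) {
  gen <- identical(cfg$scenario, "default")
  need <- function(stage, what) {
    if (isTRUE(cfg$stages[[stage]]) && !gen && is.null(cfg$inputs[[what]]))
      stop("stage '", stage, "' enabled but input '", what, "' missing")
  }
  need("morpho", "measurements"); need("mra", "measurements")
  need("gma", "tps")
  need("barcode", "fasta")
  if ((isTRUE(cfg$stages$mra) || isTRUE(cfg$stages$barcode)) && !gen &&
      is.null(cfg$inputs$partition) && is.null(cfg$inputs$fasta))
    stop("mra/barcode need a partition")
  invisible(cfg)
}

#' Read a pipeline configuration from a JSON file
#'
#' @param path JSON file with any of the fields of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw[intersect(names(raw),
    c("scenario", "inputs", "stages", "params", "seed", "out_dir"))])
}

.stage_log <- function(state, stage, files) {
  hashes <- vapply(files, function(f) unname(tools::md5sum(f)), character(1))
  c(state, sprintf("stage=%s file=%s md5=%s", stage, basename(files), hashes))
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order (generate, morphometrics, MRA, GMA,
#' barcode), writes per-stage CSV/Newick outputs plus a top-level
#' `summary.json` into the output directory, and returns the summary.
#' Identical configurations produce byte-identical summaries. A stage
#' failure aborts with a stage-scoped error and leaves a `STALE` marker
#' file listing the partial outputs.
#'
#' @param config A [run_config()] result, or a path to a JSON config file.
#' @param out_dir Optional override of the configured output directory.
#' @param seed Optional override of the configured seed.
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (!is.null(out_dir)) config$out_dir <- out_dir
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  written <- character(); log_lines <- character()
  summary <- list(seed = config$seed, stages = list())
  pr <- config$params

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c("stale partial outputs:", written), out("STALE"))
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  meas <- land <- seqs <- part <- NULL
  if (identical(config$scenario, "default")) {
    run_stage("datagen", {
      scn <- default_scenario(seed = config$seed, poly_rate = pr$poly_rate,
                              kappa = pr$kappa)
      meas <- gen_measurements(scn, sigma_resid = pr$sigma_resid)
      land <- gen_landmarks(scn, noise_sd = pr$noise_sd)
      sq <- gen_sequences(scn)
      seqs <- sq$seqs; part <- sq$partition
      write_measurements_csv(meas, out("measurements.csv"))
      write_tps(land, out("landmarks.tps"))
      write_alignment_fasta(seqs, out("alignment.fasta"), partition = part)
      write_partition_csv(part, out("partition.csv"))
      written <- c(written, out(c("measurements.csv", "landmarks.tps",
                                  "alignment.fasta", "partition.csv")))
    })
    summary$stages$datagen <- list(n_specimens = nrow(meas))
  } else {
    if (!is.null(config$inputs$measurements))
      meas <- read_measurements_csv(config$inputs$measurements)
    if (!is.null(config$inputs$tps)) {
      land <- read_tps(config$inputs$tps)
    }
    if (!is.null(config$inputs$fasta)) {
      fa <- read_alignment_fasta(config$inputs$fasta)
      seqs <- fa$seqs; part <- fa$partition
    }
    if (!is.null(config$inputs$partition))
      part <- read_partition_csv(config$inputs$partition)
    if (!is.null(land) && !is.null(part) && all(land$ids %in% names(part)))
      land$species <- unname(part[land$ids])
  }
  log_lines <- .stage_log(log_lines, "inputs", written)

  if (isTRUE(config$stages$morpho) && !is.null(meas)) {
    run_stage("morpho", {
      cs <- summarize_characters(meas)
      tk <- tukey_hsd(meas, alpha = pr$alpha)
      write.csv(cs, out("character_summaries.csv"), row.names = FALSE)
      write.csv(tk, out("tukey_comparisons.csv"), row.names = FALSE)
      written <- c(written, out(c("character_summaries.csv",
                                   "tukey_comparisons.csv")))
      sig <- tk[tk$significant, c("character", "group1", "group2")]
      rownames(sig) <- NULL
      summary$stages$morpho <- list(
        n_significant = nrow(sig), significant_pairs = sig)
    })
  }

  if (isTRUE(config$stages$mra) && !is.null(meas)) {
    run_stage("mra", {
      space <- to_shape_space(meas)
      pca <- shape_pca(space)
      sp1 <- pca_ratio_spectrum(space, 1L, n_boot = pr$n_boot,
                                seed = config$seed + 11L)
      sp2 <- pca_ratio_spectrum(space, 2L, n_boot = pr$n_boot,
                                seed = config$seed + 12L)
      al <- allometry_ratio_spectrum(space, n_boot = pr$n_boot,
                                     seed = config$seed + 13L)
      spectra <- rbind(cbind(component = sp1$component, sp1$spectrum),
                       cbind(component = sp2$component, sp2$spectrum),
                       cbind(component = al$component, al$spectrum))
      write.csv(spectra, out("ratio_spectra.csv"), row.names = FALSE)
      species <- sort(unique(meas$species))
      comps <- list()
      for (p in seq_len(ncol(combn(species, 2)))) {
        pair <- combn(species, 2)[, p]
        comps[[length(comps) + 1L]] <- list(a = pair[1], b = pair[2])
      }
      if (length(species) > 2L)
        for (s in species)
          comps[[length(comps) + 1L]] <- list(a = s, b = setdiff(species, s))
      lda_rows <- lapply(comps, function(cmp) {
        r <- lda_ratio_extract(space, cmp$a, cmp$b)
        data.frame(
          group_a = paste(cmp$a, collapse = "+"),
          group_b = paste(cmp$b, collapse = "+"),
          best_ratio = paste(r$best$characters, collapse = "/"),
          best_D = r$best$D,
          second_ratio = paste(r$second$characters, collapse = "/"),
          second_D = r$second$D, d_full = r$d_full, delta = r$delta)
      })
      lda_df <- do.call(rbind, lda_rows)
      write.csv(lda_df, out("lda_ratios.csv"), row.names = FALSE)
      written <- c(written, out(c("ratio_spectra.csv", "lda_ratios.csv")))
      summary$stages$mra <- list(
        percent_pc1 = pca$percent[1], percent_pc2 = pca$percent[2],
        lda = lda_df)
    })
  }

  if (isTRUE(config$stages$gma) && !is.null(land)) {
    run_stage("gma", {
      fit <- gpa(land, tol = pr$tol)
      pca <- landmark_pca(fit)
      aligned <- data.frame(
        specimen_id = rep(fit$ids, each = dim(fit$aligned)[1]),
        landmark = rep(seq_len(dim(fit$aligned)[1]), length(fit$ids)),
        x = as.vector(fit$aligned[, 1, ]), y = as.vector(fit$aligned[, 2, ]))
      write.csv(aligned, out("aligned_landmarks.csv"), row.names = FALSE)
      written <- c(written, out("aligned_landmarks.csv"))
      gma_sum <- list(percent_pc1 = pca$percent[1],
                      percent_pc2 = pca$percent[2],
                      iterations = fit$iterations, converged = fit$converged)
      if (!all(is.na(fit$species)) && length(unique(fit$species)) > 1L) {
        cv <- cva(fit)
        scores <- data.frame(specimen_id = fit$ids, species = fit$species,
                             cv1 = cv$scores[, 1],
                             cv2 = if (cv$n_axes > 1) cv$scores[, 2] else NA_real_)
        write.csv(scores, out("cva_scores.csv"), row.names = FALSE)
        written <- c(written, out("cva_scores.csv"))
        gma_sum$cva_eigenvalues <- cv$values
      }
      summary$stages$gma <- gma_sum
    })
  }

  if (isTRUE(config$stages$barcode) && !is.null(seqs)) {
    run_stage("barcode", {
      if (is.null(part)) stop("barcode stage needs a partition")
      hap <- collapse_haplotypes(seqs, part)
      ds <- distance_summary(hap$seqs, hap$partition, metric = pr$metric)
      gap <- barcode_gap(seqs, part, metric = pr$metric)
      bs <- bootstrap_support(seqs, metric = pr$metric, n_reps = pr$n_reps,
                              seed = config$seed + 21L,
                              threshold = pr$bootstrap_threshold,
                              partition = part, collapse = pr$collapse)
      dt <- pure_diagnostic_characters(seqs, part)
      write.csv(ds$intra, out("distances_intra.csv"), row.names = FALSE)
      write.csv(ds$inter, out("distances_inter.csv"), row.names = FALSE)
      write.csv(dt$diagnostics, out("diagnostics.csv"), row.names = FALSE)
      ape::write.tree(bs$tree, out("nj_tree.nwk"))
      written <- c(written, out(c("distances_intra.csv", "distances_inter.csv",
                                   "diagnostics.csv", "nj_tree.nwk")))
      clade_support <- vapply(sort(unique(unname(part))), function(s) {
        tips <- if (pr$collapse) names(hap$partition)[hap$partition == s]
                else names(part)[part == s]
        split_support(bs, tips)
      }, numeric(1))
      summary$stages$barcode <- list(
        n_haplotypes = nrow(hap$seqs),
        intra = ds$intra, inter = ds$inter,
        max_intra = gap$max_intra, min_inter = gap$min_inter,
        barcode_gap = gap$gap,
        clade_support = as.list(clade_support),
        n_diagnostics = nrow(dt$diagnostics),
        diagnostics = dt$diagnostics,
        newick = ape::write.tree(bs$tree))
    })
  }

  log_lines <- .stage_log(log_lines, "outputs", written)
  writeLines(log_lines, out("run.log"))
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Command-line entry point
#'
#' Implements `cryptax <generate|morpho|mra|gma|barcode|all> --config FILE
#' --out DIR [--seed N]` plus `--version`. Used by the `cryptax` script in
#' `inst/exec`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
cryptax_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if ("--version" %in% args) {
    cat("cryptax", as.character(utils::packageVersion("cryptax")), "\n")
    return(invisible(0L))
  }
  usage <- "usage: cryptax <generate|morpho|mra|gma|barcode|all> [--config FILE] [--out DIR] [--seed N]"
  if (!length(args)) { cat(usage, "\n"); return(invisible(1L)) }
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i[1] < length(args)) args[i[1] + 1L] else default
  }
  cfg <- if (!is.null(opt("--config"))) read_run_config(opt("--config"))
         else run_config()
  stages <- switch(cmd,
    generate = list(morpho = FALSE, mra = FALSE, gma = FALSE, barcode = FALSE),
    morpho = list(mra = FALSE, gma = FALSE, barcode = FALSE),
    mra = list(morpho = FALSE, gma = FALSE, barcode = FALSE),
    gma = list(morpho = FALSE, mra = FALSE, barcode = FALSE),
    barcode = list(morpho = FALSE, mra = FALSE, gma = FALSE),
    all = list(),
    { cat(usage, "\n"); return(invisible(1L)) })
  cfg$stages[names(stages)] <- stages
  run_pipeline(cfg, out_dir = opt("--out"),
               seed = if (!is.null(opt("--seed"))) as.integer(opt("--seed")))
  invisible(0L)
}
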