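# Containers and file formats: aligned sequences (FASTA via ape),
# measurement tables and partitions (CSV).

#' Aligned DNA sequences
#'
#' A thin container around a specimen x site character matrix over
#' \{A,C,G,T,N,-\}. All sequences must have equal length and unique ids.
#'
#' @param x Named character vector of equal-length strings, or a character
#'   matrix with one row per specimen (rownames = ids).
#' @return Object of class `aligned_seqs` (character matrix).
#' @export
aligned_sequences <- function(x) {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x))) stop("sequences must be named by specimen id")
    L <- unique(nchar(x))
    if (length(L) != 1L) stop("sequences differ in length")
    m <- matrix(toupper(unlist(strsplit(x, ""), use.names = FALSE)),
                nrow = length(x), ncol = L, byrow = TRUE)
    rownames(m) <- names(x)
  } else if (is.matrix(x)) {
    m <- toupper(x)
    if (is.null(rownames(m))) stop("matrix must have rownames (specimen ids)")
  } else stop("cannot interpret input as aligned sequences")
  if (anyDuplicated(rownames(m))) stop("duplicated specimen ids")
  bad <- setdiff(unique(as.vector(m)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad))
    stop("alignment contains characters outside {A,C,G,T,N,-}: ",
         paste(bad, collapse = ", "))
  class(m) <- c("aligned_seqs", class(m))
  m
}

#' @export
as.character.aligned_seqs <- function(x, ...) {
  setNames(apply(unclass(x), 1, paste, collapse = ""), rownames(x))
}

#' @export
print.aligned_seqs <- function(x, ...) {
  cat("<aligned_seqs> ", nrow(x), " sequences x ", ncol(x), " sites\n", sep = "")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Headers of the form `id|species` populate the returned partition;
#' otherwise the partition is `NULL`.
#'
#' @param path FASTA file path.
#' @return List with `seqs` ([aligned_sequences]) and `partition` (named
#'   character vector or `NULL`).
#' @export
read_alignment_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  m <- toupper(do.call(rbind, as.character(dna)))
  hdr <- names(dna)
  part <- NULL
  if (all(grepl("|", hdr, fixed = TRUE))) {
    bits <- strsplit(hdr, "|", fixed = TRUE)
    ids <- vapply(bits, `[[`, character(1), 1L)
    part <- setNames(vapply(bits, `[[`, character(1), 2L), ids)
    rownames(m) <- ids
  } else rownames(m) <- hdr
  list(seqs = aligned_sequences(m), partition = part)
}

#' Write aligned sequences as FASTA
#'
#' When a partition is supplied, headers take the `id|species` form used
#' throughout the pipeline.
#'
#' @param seqs [aligned_sequences] object.
#' @param path Output path.
#' @param partition Optional named character vector specimen id -> species.
#' @export
write_alignment_fasta <- function(seqs, path, partition = NULL) {
  s <- as.character(seqs)
  if (!is.null(partition)) {
    if (!all(names(s) %in% names(partition)))
      stop("partition does not cover all sequence ids")
    names(s) <- paste0(names(s), "|", partition[names(s)])
  }
  dna <- ape::as.DNAbin(strsplit(tolower(s), ""))
  ape::write.FASTA(dna, path)
  invisible(path)
}

#' Read / write a measurement table
#'
#' The CSV dialect written by the generator: columns `specimen_id`,
#' `species`, then the 25 characters of [morpho_characters].
#'
#' @param path CSV file path.
#' @return data.frame in measurement-table layout.
#' @export
read_measurements_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_measurement_table(df)
  df
}

#' @rdname read_measurements_csv
#' @param table Measurement data.frame.
#' @export
write_measurements_csv <- function(table, path) {
  validate_measurement_table(table)
  out <- table
  # 17 significant digits: values survive a write/read round trip bit-exactly
  for (ch in morpho_characters) out[[ch]] <- sprintf("%.17g", table[[ch]])
  write.csv(out, path, row.names = FALSE, quote = c(1L, 2L))
  invisible(path)
}

#' Validate the measurement-table schema
#'
#' Checks for the id/species columns and the 25 known character columns and
#' for strictly positive values; unknown extra columns raise a schema error.
#'
#' @param table data.frame to check.
#' @param check_positive Also require strictly positive values (default).
#' @return The table, invisibly.
#' @export
validate_measurement_table <- function(table, check_positive = TRUE) {
  need <- c("specimen_id", "species", morpho_characters)
  missing <- setdiff(need, names(table))
  if (length(missing))
    stop("measurement table lacks columns: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(table), need)
  if (length(extra))
    stop("unknown character columns: ", paste(extra, collapse = ", "))
  if (check_positive) {
    vals <- as.matrix(table[morpho_characters])
    if (any(vals[is.finite(vals)] <= 0))
      stop("measurement values must be strictly positive")
  }
  invisible(table)
}

#' Read / write a specimen partition
#'
#' Two-column CSV (`specimen_id`, `species`).
#'
#' @param path CSV file path.
#' @return Named character vector specimen id -> species.
#' @export
read_partition_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("specimen_id", "species") %in% names(df)))
    stop("partition CSV needs columns specimen_id, species")
  setNames(df$species, df$specimen_id)
}

#' @rdname read_partition_csv
#' @param partition Named character vector specimen id -> species.
#' @export
write_partition_csv <- function(partition, path) {
  write.csv(data.frame(specimen_id = names(partition),
                       species = unname(partition)),
            path, row.names = FALSE)
  invisible(path)
}
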