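#' @import data.table
#' @importFrom stats coef lm sd setNames cor cor.test t.test p.adjust pt
#'   qnorm runif rnorm rlnorm quantile
#' @importFrom utils head tail
NULL

# Average residue masses (g/mol) of the 20 standard amino acids; protein MW is
# the residue sum plus one water (18.0153).
AA_AVERAGE_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)

AA_MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

WATER_AVERAGE_MASS <- 18.0153
WATER_MONO_MASS <- 18.010565

#' Molecular weight of a protein sequence
#'
#' Sums residue masses over the sequence and adds one water. Average masses
#' are the default, as is conventional for protein-level quantities such as
#' proteome mass; monoisotopic masses are available for peptide-level work.
#'
#' @param sequence Amino-acid string over the 20-letter alphabet.
#' @param monoisotopic Use monoisotopic instead of average residue masses.
#' @return Molecular weight in g/mol.
#' @export
protein_mw <- function(sequence, monoisotopic = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  masses <- if (monoisotopic) AA_MONO_MASS else AA_AVERAGE_MASS
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(aa), names(masses))
  if (length(bad) > 0)
    stop("illegal residue(s) in sequence: ", paste(bad, collapse = ", "))
  sum(masses[aa]) + if (monoisotopic) WATER_MONO_MASS else WATER_AVERAGE_MASS
}

#' Read a FASTA file of protein sequences
#'
#' Records are identified by the first whitespace-delimited token of the
#' header. Molecular weights are computed from the sequence composition.
#'
#' @param path Path to a FASTA file.
#' @param monoisotopic Passed to [protein_mw()].
#' @return `data.frame` with columns `protein_id`, `sequence`,
#'   `molecular_weight`, in file order.
#' @export
read_fasta <- function(path, monoisotopic = FALSE) {
  aas <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aas), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as.character(aas)
  if (any(!nzchar(seqs)))
    stop("empty sequence for record(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  mw <- vapply(seq_along(seqs), function(i) {
    tryCatch(protein_mw(seqs[i], monoisotopic),
             error = function(e) stop("record '", ids[i], "': ",
                                      conditionMessage(e), call. = FALSE))
  }, numeric(1))
  data.frame(protein_id = ids, sequence = unname(seqs),
             molecular_weight = mw, stringsAsFactors = FALSE)
}

#' Write protein sequences as FASTA
#'
#' @param sequences `data.frame` with `protein_id` and `sequence`.
#' @param path Output path.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::AAStringSet(setNames(sequences$sequence,
                                        sequences$protein_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a tab-separated table with schema checking
#'
#' Empty cells and `NA` become missing values. The header must contain every
#' column named in `required`; rows with a deviating field count are reported
#' with their line number.
#'
#' @param path Path to a tab-separated file with a header line.
#' @param required Character vector of required column names.
#' @return `data.frame`.
#' @export
read_table_checked <- function(path, required = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty file (no header): ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  missing_cols <- setdiff(required, header)
  if (length(missing_cols) > 0)
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) > 0) {
    nf <- lengths(strsplit(body, "\t", fixed = TRUE))
    # a trailing empty field is legal: strsplit drops it
    bad <- which(nf > length(header) | nf < length(header) - 1L)
    if (length(bad) > 0)
      stop("malformed row at line ", bad[1] + 1L, " of ", path,
           ": expected ", length(header), " fields, found ", nf[bad[1]])
  }
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("", "NA"), check.names = FALSE)
  df
}

#' Write a table as tab-separated text
#'
#' Missing values are written as empty cells so that
#' [read_table_checked()] round-trips them.
#'
#' @param x `data.frame`.
#' @param path Output path.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Default pipeline configuration
#'
#' All tunable thresholds of the pipeline with their default values:
#' dilution-series acceptance criteria (`r2_min`, `slope_range`,
#' `intercept_range`, `min_points`), replicate-presence and outlier rules
#' (`min_replicates`, `outlier_pct_max`), the replicate-variation exclusion
#' (`cv_max`), label-free model parameters (`top_fragments`, `model_grid`,
#' iBAQ digest parameters), bootstrap settings, and k_app flux filters.
#'
#' @param ... Named overrides of individual defaults. Unknown names are an
#'   error.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # dilution-series calibration acceptance
    r2_min = 0.95,
    slope_range = c(0.95, 1.05),
    intercept_range = c(-0.1, 0.1),
    min_points = 3L,
    # anchor peptide filters
    min_replicates = 3L,
    outlier_pct_max = 50,
    cv_max = 0.5,
    # label-free quantification
    top_fragments = 5L,
    min_peptides = 2L,
    model_grid = c("top1", "top2", "top3", "top5", "iBAQ", "all_pep_sum"),
    ibaq_missed_cleavages = 0L,
    ibaq_length_range = c(7L, 30L),
    n_boot = 100L,
    fe_aggregate = "arithmetic",
    report_anchor_sil = TRUE,
    # flux integration
    flux_fraction_min = 0.001,
    alpha = 0.05,
    # allocation
    allocation_weight = "mass",
    stoich_tolerance_fold = 1.5,
    seed = 1L)
  dots <- list(...)
  if (length(dots) > 0) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown) > 0 || is.null(names(dots)) || any(!nzchar(names(dots))))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  cfg
}
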