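#' Read a probeset-by-sample expression matrix
#'
#' Reads a tab-delimited expression matrix of raw fluorescent units (RFU).
#' The first column holds probeset identifiers; the header row holds sample
#' identifiers. Values must be non-negative and complete (no missing values:
#' impute upstream if needed).
#'
#' @param path Path to a TSV file with header `probeset_id\t<sample ids...>`.
#' @return A numeric matrix with probeset ids as rownames and sample ids as
#'   colnames.
#' @export
read_expression_matrix <- function(path) {
  ap_check(file.exists(path), paste0("file not found: ", path),
           "format_error")
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ap_check(ncol(df) >= 2,
           "matrix file needs a probeset id column plus >=1 sample column",
           "format_error")
  ids <- as.character(df[[1L]])
  ap_check(!anyNA(ids) && all(nzchar(ids)), "empty probeset id", "format_error")
  ap_check(!anyDuplicated(ids),
           paste0("duplicate probeset ids: ",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")),
           "format_error")
  samples <- colnames(df)[-1L]
  ap_check(all(nzchar(samples)), "empty sample id in header", "format_error")
  ap_check(!anyDuplicated(samples),
           paste0("duplicate sample ids: ",
                  paste(unique(samples[duplicated(samples)]), collapse = ", ")),
           "format_error")
  m <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(mode(m) <- "numeric")
  ap_check(!anyNA(m), "missing or non-numeric expression value", "value_error")
  ap_check(all(m >= 0), "negative expression value (RFU must be >= 0)",
           "value_error")
  rownames(m) <- ids
  m
}

#' Read a sample-to-compartment table
#'
#' @param path Path to a TSV with header `sample_id\tcompartment`.
#' @return A data.frame with columns `sample_id` and `compartment`.
#'   Compartment order of first appearance is preserved downstream.
#' @export
read_sample_table <- function(path) {
  ap_check(file.exists(path), paste0("file not found: ", path),
           "format_error")
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  ap_check(all(c("sample_id", "compartment") %in% colnames(df)),
           "sample table needs columns sample_id and compartment",
           "format_error")
  df <- df[, c("sample_id", "compartment")]
  ap_check(all(nzchar(df$sample_id)) && all(nzchar(df$compartment)) &&
             !anyNA(df$sample_id) && !anyNA(df$compartment),
           "empty sample or compartment label", "format_error")
  ap_check(!anyDuplicated(df$sample_id),
           paste0("duplicate sample ids in sample table: ",
                  paste(unique(df$sample_id[duplicated(df$sample_id)]),
                        collapse = ", ")),
           "format_error")
  df
}

#' Read and cross-validate an expression matrix and its sample table
#'
#' @param matrix_path Path to the expression matrix TSV.
#' @param sample_table_path Path to the sample table TSV.
#' @return A list with elements `matrix` and `samples`. Every sample in the
#'   matrix is guaranteed to appear in the table.
#' @export
read_expression_data <- function(matrix_path, sample_table_path) {
  m <- read_expression_matrix(matrix_path)
  s <- read_sample_table(sample_table_path)
  missing <- setdiff(colnames(m), s$sample_id)
  ap_check(length(missing) == 0L,
           paste0("matrix samples absent from sample table: ",
                  paste(missing, collapse = ", ")),
           "consistency_error")
  list(matrix = m, samples = s)
}

#' Average replicate samples into compartment-level profiles
#'
#' Each compartment's profile is the arithmetic mean of its samples'
#' columns. Compartments are ordered as first encountered in the sample
#' table, so reports follow the user's layout rather than alphabetical
#' order.
#'
#' @param m Expression matrix (probesets x samples), as from
#'   [read_expression_matrix()].
#' @param samples Sample table, as from [read_sample_table()].
#' @return A numeric matrix of mean signal, probesets x compartments.
#' @export
aggregate_by_compartment <- function(m, samples) {
  ap_check(is.matrix(m) && is.numeric(m), "m must be a numeric matrix",
           "value_error")
  use <- samples[samples$sample_id %in% colnames(m), , drop = FALSE]
  missing <- setdiff(colnames(m), samples$sample_id)
  ap_check(length(missing) == 0L,
           paste0("matrix samples absent from sample table: ",
                  paste(missing, collapse = ", ")),
           "consistency_error")
  comps <- unique(use$compartment)
  ap_check(length(comps) >= 1L, "no compartment has any sample",
           "consistency_error")
  prof <- vapply(comps, function(cc) {
    ids <- use$sample_id[use$compartment == cc]
    ap_check(length(ids) >= 1L,
             paste0("compartment with zero samples: ", cc),
             "consistency_error")
    rowMeans(m[, ids, drop = FALSE])
  }, numeric(nrow(m)))
  prof <- matrix(prof, nrow = nrow(m),
                 dimnames = list(rownames(m), comps))
  prof
}

#' Write / read a compartment profile losslessly
#'
#' Values are serialised with 17 significant digits so that a write/read
#' round trip reproduces doubles bit-exactly.
#'
#' @param profile Probeset x compartment matrix.
#' @param path Output TSV path.
#' @return `path`, invisibly (writer); the profile matrix (reader).
#' @export
write_compartment_profile <- function(profile, path) {
  txt <- matrix(sprintf("%.17g", profile), nrow = nrow(profile),
                dimnames = dimnames(profile))
  df <- data.frame(probeset_id = rownames(profile), txt,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_compartment_profile
#' @export
read_compartment_profile <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1L]])
  m
}
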