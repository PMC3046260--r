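# Classification of in situ hybridisation (SISH) expression patterns
# into the five validation categories used when comparing tissue-section
# staining against a microarray-predicted target compartment.

.detected_calls <- c("detected", "weak", "present", "strong")
.pattern_levels <- c("specific", "enriched", "ubiquitous",
                     "not_detected", "non_specific")

#' Classify one gene's SISH pattern against its predicted compartment
#'
#' Graded calls (`weak`/`present`/`strong`) collapse to "detected";
#' `not_detected` means no signal. The label is:
#' * `specific` — detected in the target compartment only (validated
#'   anchor gene);
#' * `enriched` — detected in the target and at least one other, but not
#'   all, compartments (marker gene);
#' * `ubiquitous` — detected in every annotated compartment;
#' * `not_detected` — no detectable signal anywhere;
#' * `non_specific` — detected somewhere, but not in the target.
#'
#' The classifier only sees the compartments present in `calls`; a gene
#' expressed in an unannotated structure must be encoded by the caller as
#' an extra compartment key.
#'
#' @param calls Named character vector: compartment -> call, calls in
#'   `not_detected`, `detected`, `weak`, `present`, `strong`.
#' @param target Target compartment; must be a name of `calls`.
#' @return One of the five labels, as a length-1 character.
#' @export
classify_pattern <- function(calls, target) {
  ap_check(length(calls) >= 1L && !is.null(names(calls)) &&
             all(nzchar(names(calls))),
           "calls must be a non-empty named vector", "value_error")
  ap_check(!anyDuplicated(names(calls)), "duplicate compartment in calls",
           "value_error")
  ap_check(target %in% names(calls),
           paste0("target compartment not annotated: ", target),
           "lookup_error")
  bad <- setdiff(calls, c(.detected_calls, "not_detected"))
  ap_check(length(bad) == 0L,
           paste0("unknown call values: ", paste(bad, collapse = ", ")),
           "value_error")
  det <- names(calls)[calls %in% .detected_calls]
  if (length(det) == 0L) return("not_detected")
  if (!(target %in% det)) return("non_specific")
  if (length(det) == length(calls)) return("ubiquitous")
  if (length(det) == 1L) return("specific")
  "enriched"
}

#' Read a SISH annotation table
#'
#' @param path TSV with columns `gene_id`, `target_compartment`, then one
#'   column per compartment holding calls.
#' @return Data.frame in the same layout, validated.
#' @export
read_sish_annotations <- function(path) {
  ap_check(file.exists(path), paste0("file not found: ", path),
           "format_error")
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  ap_check(all(c("gene_id", "target_compartment") %in% colnames(df)) &&
             ncol(df) >= 3L,
           "annotation table needs gene_id, target_compartment and >=1 compartment column",
           "format_error")
  ap_check(!anyDuplicated(df$gene_id), "duplicate gene ids", "format_error")
  df
}

#' Classify every gene in an annotation table
#'
#' @param annotations Data.frame from [read_sish_annotations()].
#' @return Data.frame `gene_id`, `target_compartment`, `label`.
#' @export
classify_annotations <- function(annotations) {
  comp_cols <- setdiff(colnames(annotations),
                       c("gene_id", "target_compartment"))
  labels <- vapply(seq_len(nrow(annotations)), function(i) {
    calls <- unlist(annotations[i, comp_cols, drop = FALSE])
    names(calls) <- comp_cols
    classify_pattern(calls, annotations$target_compartment[i])
  }, character(1))
  data.frame(gene_id = annotations$gene_id,
             target_compartment = annotations$target_compartment,
             label = labels, stringsAsFactors = FALSE)
}

#' Summarise validation outcomes
#'
#' Counts and percentages (1 decimal) per label, plus the combined
#' validation rate: the percentage of genes classified `specific` or
#' `enriched` (the bioinformatic prediction was confirmed at least in
#' part).
#'
#' @param labels Character vector of pattern labels.
#' @return A `validation_summary`: list with `table` (label, count,
#'   percent), `total` and `combined_validated_percent`.
#' @export
validation_summary <- function(labels) {
  ap_check(length(labels) >= 1L, "need >= 1 label", "value_error")
  bad <- setdiff(labels, .pattern_levels)
  ap_check(length(bad) == 0L,
           paste0("unknown labels: ", paste(bad, collapse = ", ")),
           "value_error")
  total <- length(labels)
  counts <- vapply(.pattern_levels, function(l) sum(labels == l), integer(1))
  tab <- data.frame(label = .pattern_levels,
                    count = unname(counts),
                    percent = round(100 * unname(counts) / total, 1),
                    stringsAsFactors = FALSE)
  combined <- round(100 * (counts[["specific"]] + counts[["enriched"]]) /
                      total, 1)
  structure(list(table = tab, total = total,
                 combined_validated_percent = combined),
            class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat("SISH validation summary (", x$total, " genes)\n", sep = "")
  print(x$table, row.names = FALSE)
  cat("Combined specific + enriched:", x$combined_validated_percent, "%\n")
  invisible(x)
}

#' Write classification results
#'
#' @param classified Data.frame from [classify_annotations()].
#' @param dir Output directory.
#' @export
write_classification <- function(classified, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(classified, file.path(dir, "pattern_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  s <- validation_summary(classified$label)
  jsonlite::write_json(
    list(total = s$total,
         counts = as.list(stats::setNames(s$table$count, s$table$label)),
         percent = as.list(stats::setNames(s$table$percent, s$table$label)),
         combined_validated_percent = s$combined_validated_percent),
    file.path(dir, "validation_summary.json"), auto_unbox = TRUE)
  invisible(dir)
}
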