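#' Median signal across the other compartments
#'
#' For a target compartment, the reference level is the median of the
#' compartment mean signals over all *other* compartments (the target is
#' excluded). With an even count the mean of the two central values is
#' used (standard median).
#'
#' @param profile Probeset x compartment matrix of mean signal (RFU).
#' @param probeset Probeset id (rowname of `profile`).
#' @param target Target compartment (colname of `profile`).
#' @return The median of the other compartments' means, in RFU.
#' @export
median_other <- function(profile, probeset, target) {
  ap_check(probeset %in% rownames(profile),
           paste0("unknown probeset: ", probeset), "lookup_error")
  ap_check(target %in% colnames(profile),
           paste0("unknown compartment: ", target), "lookup_error")
  ap_check(ncol(profile) >= 2L, "need >= 2 compartments", "value_error")
  stats::median(profile[probeset, setdiff(colnames(profile), target)])
}

#' Linear fold-change against the median of the other compartments
#'
#' `raw / median_other`, on the linear RFU scale. When the reference
#' median is zero the ratio is `Inf` for a positive signal and defined as
#' 1 when both are zero (no evidence of enrichment either way).
#'
#' @param raw Target-compartment mean signal (RFU), vectorised.
#' @param median_other Median of the other compartments' means (RFU).
#' @return Dimensionless ratio(s).
#' @export
fold_change <- function(raw, median_other) {
  ap_check(is.numeric(raw) && is.numeric(median_other) && !anyNA(raw) &&
             !anyNA(median_other), "inputs must be numeric and non-missing",
           "value_error")
  ap_check(all(raw >= 0) && all(median_other >= 0),
           "signals must be >= 0", "value_error")
  ifelse(median_other > 0, raw / median_other, ifelse(raw > 0, Inf, 1))
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Tests equality of group means without assuming equal variances
#' (Welch's F with Satterthwaite-type denominator degrees of freedom).
#' Groups must each contain at least two values with positive variance;
#' a zero-variance group makes the statistic undefined and raises a
#' degenerate-input error rather than silently jittering the data.
#'
#' @param groups List of numeric vectors, one per group.
#' @return List with `statistic` (F), `df1`, `df2` and `p.value`.
#' @export
welch_anova <- function(groups) {
  ap_check(is.list(groups) && length(groups) >= 2L,
           "need >= 2 groups", "value_error")
  n <- lengths(groups)
  ap_check(all(n >= 2L), "each group needs >= 2 values", "value_error")
  v <- vapply(groups, stats::var, numeric(1))
  ap_check(all(v > 0),
           "zero-variance group: Welch ANOVA undefined for degenerate input",
           "degenerate_input_error")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep.int(seq_along(groups), n))
  ht <- stats::oneway.test(x ~ g, var.equal = FALSE)
  list(statistic = unname(ht$statistic),
       df1 = unname(ht$parameter[["num df"]]),
       df2 = unname(ht$parameter[["denom df"]]),
       p.value = unname(ht$p.value))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values in the input order, each >= its p-value.
#' @export
bh_adjust <- function(p) {
  ap_check(is.numeric(p) && length(p) >= 1L && !anyNA(p),
           "p-values must be numeric and non-missing", "value_error")
  ap_check(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]", "value_error")
  stats::p.adjust(p, method = "BH")
}

#' Per-probeset compartment-specificity statistics
#'
#' For every (probeset, compartment) pair computes the target-compartment
#' mean signal ("raw"), the median over the other compartments, the linear
#' fold-change, a Welch ANOVA p-value over the replicate groups of all
#' compartments (one test per probeset) and its Benjamini-Hochberg
#' q-value (corrected across probesets).
#'
#' Probesets whose replicate groups include a zero-variance group are
#' handled according to `degenerate`: `"resolve"` (default) assigns the
#' limiting p-value (0 if any group means differ, 1 if the probeset is
#' flat), which keeps noise-free synthetic data usable; `"error"`
#' propagates the degenerate-input error from [welch_anova()].
#'
#' @param m Expression matrix (probesets x samples).
#' @param samples Sample table (`sample_id`, `compartment`).
#' @param degenerate How to treat zero-variance replicate groups.
#' @param log2_fold Also report a `log2_fold_change` column.
#' @return A data.frame with one row per probeset x compartment:
#'   `probeset_id`, `compartment`, `raw`, `median_other`, `fold_change`,
#'   `p_anova`, `q_bh`.
#' @export
compute_specificity_stats <- function(m, samples,
                                      degenerate = c("resolve", "error"),
                                      log2_fold = FALSE) {
  degenerate <- match.arg(degenerate)
  profile <- aggregate_by_compartment(m, samples)
  comps <- colnames(profile)
  ap_check(length(comps) >= 2L, "need >= 2 compartments", "value_error")

  group_cols <- lapply(comps, function(cc)
    samples$sample_id[samples$compartment == cc & samples$sample_id %in% colnames(m)])
  pvals <- vapply(rownames(m), function(p) {
    groups <- lapply(group_cols, function(ids) m[p, ids])
    v <- vapply(groups, stats::var, numeric(1))
    if (any(lengths(groups) < 2L)) {
      ap_stop("each compartment needs >= 2 replicate samples for the ANOVA",
              "value_error")
    }
    if (any(v <= 0)) {
      if (degenerate == "error") {
        ap_stop(paste0("zero-variance replicate group for probeset ", p),
                "degenerate_input_error")
      }
      mu <- vapply(groups, mean, numeric(1))
      return(if (max(mu) - min(mu) > 0) 0 else 1)
    }
    welch_anova(groups)$p.value
  }, numeric(1))
  qvals <- bh_adjust(pvals)

  med_other <- vapply(seq_along(comps), function(j)
    apply(profile[, -j, drop = FALSE], 1L, stats::median),
    numeric(nrow(profile)))

  out <- do.call(rbind, lapply(seq_along(comps), function(j) {
    data.frame(probeset_id = rownames(profile),
               compartment = comps[j],
               raw = profile[, j],
               median_other = med_other[, j],
               fold_change = fold_change(profile[, j], med_other[, j]),
               p_anova = unname(pvals),
               q_bh = unname(qvals),
               row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  if (log2_fold) out$log2_fold_change <- log2(out$fold_change)
  out
}

#' Write specificity statistics as TSV
#'
#' @param stats Data.frame from [compute_specificity_stats()].
#' @param path Output path.
#' @export
write_specificity_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Concordance between computed and printed fold-changes
#'
#' Published tables round fold-changes to the precision they print
#' (sometimes one decimal, sometimes whole numbers). This audit helper
#' recomputes `raw / median_other`, rounds it to the number of decimals
#' each printed value carries, and flags agreement within `tol`.
#'
#' @param raw Target-compartment mean signals (RFU).
#' @param median_other Reference medians (RFU).
#' @param printed Fold-changes as printed.
#' @param tol Tolerated absolute deviation at the printed precision.
#' @return Logical vector: does each computed fold reproduce the printed
#'   one?
#' @export
printed_fold_concordance <- function(raw, median_other, printed, tol = 0.2) {
  computed <- fold_change(raw, median_other)
  decimals <- vapply(printed, function(x) {
    s <- sub("0+$", "", sub("^[^.]*\\.?", "", format(x, trim = TRUE)))
    nchar(s)
  }, integer(1))
  rounded <- round(computed, decimals)
  abs(rounded - printed) <= tol + 1e-9
}
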