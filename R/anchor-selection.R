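#' Selection thresholds for the anchor-gene cascade
#'
#' Bundles every threshold of the candidate-anchor selection cascade:
#' significance (BH q below `p_threshold`), minimum fold-change against
#' the median of the other compartments (`fold_min`, strict), minimum raw
#' signal (`raw_min`, strict), the ranking preference for low reference
#' medians (`median_max`: candidates at or above it sink to the bottom of
#' their list and are flagged, but are not discarded), the
#' cross-expression exclusion threshold (`cross_fold_exclude`: a
#' candidate expressed at or above this fold in any other compartment is
#' dropped) and optional per-compartment fold overrides (by default the
#' early proximal tubule, EPT, requires a 10-fold difference to keep its
#' candidate list tractable).
#'
#' @param p_threshold Significance cut applied to BH-adjusted q-values.
#' @param fold_min Minimum fold-change (strict `>`).
#' @param raw_min Minimum raw signal in RFU (strict `>`).
#' @param median_max Ranking preference ceiling for `median_other` (RFU).
#' @param cross_fold_exclude Fold level in a non-target compartment that
#'   disqualifies a candidate (`>=`).
#' @param per_compartment_fold_min Named numeric vector of fold overrides.
#' @return A `selection_config` object (validated list).
#' @export
selection_config <- function(p_threshold = 0.01,
                             fold_min = 2,
                             raw_min = 100,
                             median_max = 200,
                             cross_fold_exclude = 2,
                             per_compartment_fold_min = c(EPT = 10)) {
  cfg <- list(p_threshold = p_threshold, fold_min = fold_min,
              raw_min = raw_min, median_max = median_max,
              cross_fold_exclude = cross_fold_exclude,
              per_compartment_fold_min = per_compartment_fold_min)
  ap_check(all(vapply(cfg[1:5], function(x)
    is.numeric(x) && length(x) == 1L && x > 0, logical(1))),
    "all thresholds must be single positive numbers", "value_error")
  ap_check(fold_min >= 1, "fold_min must be >= 1", "value_error")
  if (length(per_compartment_fold_min)) {
    ap_check(is.numeric(per_compartment_fold_min) &&
               !is.null(names(per_compartment_fold_min)) &&
               all(nzchar(names(per_compartment_fold_min))),
             "per_compartment_fold_min must be a named numeric vector",
             "value_error")
    ap_check(all(per_compartment_fold_min >= fold_min),
             "per-compartment overrides must be >= fold_min", "value_error")
  }
  structure(cfg, class = "selection_config")
}

#' Load a selection configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the [selection_config()]
#'   arguments.
#' @return A `selection_config` object.
#' @export
read_selection_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(selection_config))
  bad <- setdiff(names(raw), known)
  ap_check(length(bad) == 0L,
           paste0("unknown selection config keys: ",
                  paste(bad, collapse = ", ")), "format_error")
  if (!is.null(raw$per_compartment_fold_min)) {
    raw$per_compartment_fold_min <- unlist(raw$per_compartment_fold_min)
  }
  do.call(selection_config, raw)
}

effective_fold_min <- function(compartment, cfg) {
  ov <- cfg$per_compartment_fold_min
  out <- rep(cfg$fold_min, length(compartment))
  hit <- match(compartment, names(ov))
  out[!is.na(hit)] <- ov[hit[!is.na(hit)]]
  out
}

#' Apply the primary selection filters
#'
#' Retains statistics rows with `q_bh < p_threshold`,
#' `fold_change > fold_min` (or the compartment's override) and
#' `raw > raw_min`. All inequalities on fold and raw signal are strict,
#' so boundary rows (e.g. raw exactly at the floor) are excluded.
#'
#' @param stats Data.frame of per-probeset statistics with columns
#'   `probeset_id`, `compartment`, `raw`, `median_other`, `fold_change`,
#'   `q_bh`.
#' @param cfg A [selection_config()].
#' @return The retained rows (possibly zero).
#' @export
apply_filters <- function(stats, cfg = selection_config()) {
  need <- c("probeset_id", "compartment", "raw", "fold_change", "q_bh")
  ap_check(all(need %in% colnames(stats)),
           paste0("stats must have columns: ", paste(need, collapse = ", ")),
           "format_error")
  ap_check(!anyNA(stats$q_bh), "q_bh must be populated before filtering",
           "value_error")
  fmin <- effective_fold_min(stats$compartment, cfg)
  keep <- stats$q_bh < cfg$p_threshold &
    stats$fold_change > fmin &
    stats$raw > cfg$raw_min
  stats[keep, , drop = FALSE]
}

#' Drop candidates expressed in more than one compartment
#'
#' A candidate is excluded when its fold-change computed with any
#' non-target compartment as the target reaches
#' `cfg$cross_fold_exclude`. This enforces absolute restriction: a
#' probeset enriched in two compartments is dropped from both lists.
#'
#' @param candidates Filtered statistics rows (see [apply_filters()]).
#' @param profile Probeset x compartment mean-signal matrix covering all
#'   candidates.
#' @param cfg A [selection_config()].
#' @return The retained candidate rows.
#' @export
exclude_cross_expressed <- function(candidates, profile,
                                    cfg = selection_config()) {
  if (nrow(candidates) == 0L) return(candidates)
  ap_check(all(candidates$probeset_id %in% rownames(profile)),
           "profile must cover all candidates", "consistency_error")
  comps <- colnames(profile)
  keep <- vapply(seq_len(nrow(candidates)), function(i) {
    p <- candidates$probeset_id[i]
    tgt <- candidates$compartment[i]
    for (cc in setdiff(comps, tgt)) {
      fc <- fold_change(profile[p, cc],
                        stats::median(profile[p, setdiff(comps, cc)]))
      if (fc >= cfg$cross_fold_exclude) return(FALSE)
    }
    TRUE
  }, logical(1))
  candidates[keep, , drop = FALSE]
}

#' Rank one compartment's candidates
#'
#' Candidates are ranked ascending by the reference median (quieter
#' background first); rows whose `median_other` is at or above
#' `cfg$median_max` are flagged (`high_median`) and sink below all
#' unflagged rows. Ties break by descending raw signal, then probeset id.
#'
#' @param candidates Candidate rows from a single compartment.
#' @param cfg A [selection_config()].
#' @return The candidates with `high_median` flag and `rank` 1..n.
#' @export
rank_candidates <- function(candidates, cfg = selection_config()) {
  ap_check(length(unique(candidates$compartment)) <= 1L,
           "rank_candidates expects candidates from one compartment",
           "value_error")
  if (nrow(candidates) == 0L) {
    candidates$high_median <- logical(0)
    candidates$rank <- integer(0)
    return(candidates)
  }
  candidates$high_median <- candidates$median_other >= cfg$median_max
  ord <- order(candidates$high_median, candidates$median_other,
               -candidates$raw, candidates$probeset_id)
  out <- candidates[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Full candidate-anchor selection cascade
#'
#' Runs the complete pipeline: aggregate replicates into compartment
#' profiles, compute specificity statistics (Welch ANOVA + BH), apply the
#' significance/fold/raw filters, exclude cross-expressed probesets, and
#' rank the survivors per compartment.
#'
#' @param m Expression matrix (probesets x samples).
#' @param samples Sample table.
#' @param cfg A [selection_config()].
#' @param degenerate Passed to [compute_specificity_stats()].
#' @return An `anchor_selection` object: list with `candidates` (named
#'   list of ranked data.frames, one per compartment, profile order),
#'   `stats`, `profile` and `config`.
#' @export
select_candidates <- function(m, samples, cfg = selection_config(),
                              degenerate = "resolve") {
  profile <- aggregate_by_compartment(m, samples)
  stats <- compute_specificity_stats(m, samples, degenerate = degenerate)
  filtered <- apply_filters(stats, cfg)
  kept <- exclude_cross_expressed(filtered, profile, cfg)
  comps <- colnames(profile)
  per_comp <- lapply(comps, function(cc)
    rank_candidates(kept[kept$compartment == cc, , drop = FALSE], cfg))
  names(per_comp) <- comps
  structure(list(candidates = per_comp, stats = stats,
                 profile = profile, config = cfg),
            class = "anchor_selection")
}

#' @export
print.anchor_selection <- function(x, ...) {
  counts <- vapply(x$candidates, nrow, integer(1))
  cat("Candidate anchor selection across", length(counts), "compartments\n")
  cat("Candidates per compartment:\n")
  for (cc in names(counts)) cat(sprintf("  %-6s %d\n", cc, counts[cc]))
  invisible(x)
}

#' Candidate counts per compartment
#'
#' @param sel An `anchor_selection` object.
#' @return Named integer vector of list lengths.
#' @export
candidate_counts <- function(sel) {
  vapply(sel$candidates, nrow, integer(1))
}

#' Write selection results to a directory
#'
#' One TSV per compartment plus a JSON summary of counts.
#'
#' @param sel An `anchor_selection` object.
#' @param dir Output directory (created if absent).
#' @export
write_selection <- function(sel, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (cc in names(sel$candidates)) {
    utils::write.table(sel$candidates[[cc]],
                       file.path(dir, paste0("candidates_", cc, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(as.list(candidate_counts(sel)),
                       file.path(dir, "candidate_counts.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
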