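# End-to-end orchestration: candidate selection -> (optional pattern
# classification) -> probe mapping -> template selection -> primer
# design -> in-silico PCR, with a machine-readable run report.

#' Design riboprobes for a set of probesets
#'
#' For each probeset in `probes`: map its oligo probes onto the
#' transcript set, pick the best-covered transcript (ties resolved 3',
#' see [rank_probesets()]), select a 500-800 bp 3'-biased template
#' spanning the probes, design a T7-tagged primer pair, and verify
#' specificity by in-silico PCR against the whole transcript set.
#' Probesets failing a stage (coverage below threshold, infeasible
#' template or design) are reported in `failures` with the failing stage
#' and reason rather than aborting the batch.
#'
#' @param probes Probe table (see [read_probe_table()]).
#' @param transcripts `DNAStringSet` or named character vector.
#' @param constraints A [primer_constraints()].
#' @param allow_antisense Search both probe orientations.
#' @param min_coverage Required probeset coverage on the chosen
#'   transcript.
#' @param max_product In-silico PCR product cap (bp).
#' @return List with `designs` (one row per successful probeset: template
#'   and primer details plus the amplicon count), `amplicons` (all
#'   predicted products) and `failures`.
#' @export
design_riboprobes <- function(probes, transcripts,
                              constraints = primer_constraints(),
                              allow_antisense = TRUE,
                              min_coverage = 0.8,
                              max_product = 4000L) {
  ts <- as_transcript_set(transcripts)
  hits <- map_probes(probes, ts, allow_antisense = allow_antisense)
  cov <- probeset_coverage(hits, probes)
  designs <- list()
  amplicons <- list()
  failures <- list()
  fail <- function(psid, stage, message) {
    failures[[length(failures) + 1L]] <<- data.frame(
      probeset_id = psid, stage = stage, reason = conditionMessage(message),
      stringsAsFactors = FALSE)
  }
  for (psid in unique(probes$probeset_id)) {
    pc <- cov[cov$probeset_id == psid, , drop = FALSE]
    if (nrow(pc) == 0L) {
      fail(psid, "probe_mapping",
           simpleCondition("no probe of this probeset maps to any transcript"))
      next
    }
    best <- rank_probesets(pc)[1L, ]
    h <- hits[hits$probeset_id == psid &
                hits$transcript_id == best$transcript_id, , drop = FALSE]
    tmpl <- tryCatch(
      select_template(ts, h, probeset_size = best$probeset_size,
                      min_coverage = min_coverage),
      anchorprobe_error = function(e) e)
    if (inherits(tmpl, "condition")) { fail(psid, "template_selection", tmpl); next }
    # The primer-search window extends the template (3'-preferring) up to
    # one maximum product length, so the scan has slack; the amplicon is
    # still required to contain the probe span inside the template.
    L <- Biostrings::width(ts)[match(tmpl$transcript_id, names(ts))]
    target <- min(L, constraints$product_max)
    ext <- max(0L, target - (tmpl$end - tmpl$start))
    w_end <- min(L, tmpl$end + ext)
    w_start <- max(0L, tmpl$start - (ext - (w_end - tmpl$end)))
    span <- c(max(min(h$start), tmpl$start), min(max(h$end), tmpl$end))
    region_seq <- substr(as.character(ts[[tmpl$transcript_id]]),
                         w_start + 1L, w_end)
    pair <- tryCatch(
      design_primers(region_seq, constraints, offset = w_start,
                     contain = span - w_start),
      anchorprobe_error = function(e) e)
    if (inherits(pair, "condition")) { fail(psid, "primer_design", pair); next }
    amp <- insilico_pcr(pair, ts, max_product = max_product)
    if (nrow(amp) > 0L) {
      amp <- cbind(probeset_id = psid, amp, stringsAsFactors = FALSE)
      amplicons[[length(amplicons) + 1L]] <- amp
    }
    designs[[length(designs) + 1L]] <- data.frame(
      probeset_id = psid,
      transcript_id = tmpl$transcript_id,
      coverage_fraction = best$coverage_fraction,
      template_start = tmpl$start, template_end = tmpl$end,
      covered_probe_count = tmpl$covered_probe_count,
      forward_seq = pair$forward_seq,
      reverse_core_seq = pair$reverse_core_seq,
      reverse_tagged_seq = pair$reverse_tagged_seq,
      forward_tm = pair$forward_tm, reverse_tm = pair$reverse_tm,
      forward_gc = pair$forward_gc, reverse_gc = pair$reverse_gc,
      product_start = pair$product_start, product_end = pair$product_end,
      product_length = pair$product_length,
      n_amplicons = nrow(amp),
      stringsAsFactors = FALSE)
  }
  empty_fail <- data.frame(probeset_id = character(0), stage = character(0),
                           reason = character(0), stringsAsFactors = FALSE)
  list(designs = if (length(designs)) do.call(rbind, designs) else NULL,
       amplicons = if (length(amplicons)) do.call(rbind, amplicons) else NULL,
       failures = if (length(failures)) do.call(rbind, failures) else empty_fail)
}

#' Load and validate a run configuration
#'
#' @param path YAML file with keys: `matrix`, `samples`, `probes`,
#'   `transcripts` (paths; the first two mandatory), optional
#'   `annotations`, `out_dir`, nested `selection` and `primers` blocks
#'   (mirroring [selection_config()] / [primer_constraints()]),
#'   `allow_antisense`, `min_coverage`, `max_product`.
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  ap_check(file.exists(path), paste0("config not found: ", path),
           "format_error")
  cfg <- yaml::read_yaml(path)
  for (key in c("matrix", "samples")) {
    ap_check(!is.null(cfg[[key]]), paste0("config key missing: ", key),
             "format_error")
  }
  for (key in c("matrix", "samples", "probes", "transcripts", "annotations")) {
    if (!is.null(cfg[[key]])) {
      ap_check(file.exists(cfg[[key]]),
               paste0("path for '", key, "' does not exist: ", cfg[[key]]),
               "format_error")
    }
  }
  cfg$selection <- if (is.null(cfg$selection)) selection_config() else {
    if (!is.null(cfg$selection$per_compartment_fold_min)) {
      cfg$selection$per_compartment_fold_min <-
        unlist(cfg$selection$per_compartment_fold_min)
    }
    do.call(selection_config, cfg$selection)
  }
  cfg$primers <- if (is.null(cfg$primers)) primer_constraints() else
    do.call(primer_constraints, cfg$primers)
  if (is.null(cfg$allow_antisense)) cfg$allow_antisense <- TRUE
  if (is.null(cfg$min_coverage)) cfg$min_coverage <- 0.8
  if (is.null(cfg$max_product)) cfg$max_product <- 4000L
  if (is.null(cfg$out_dir)) cfg$out_dir <- "anchorprobe_run"
  cfg
}

#' Run the full anchor-to-riboprobe pipeline
#'
#' Selection cascade, optional SISH pattern classification, then
#' riboprobe design for every probeset in the probe table that was
#' selected as a candidate in any compartment (or for all probesets if
#' no candidate matches the probe table). Writes per-stage TSVs and a
#' JSON run report into `cfg$out_dir`; the report records every
#' threshold actually applied, counts per stage, and per-probeset design
#' failures with reasons. Errors are re-signalled with the failing
#' stage's name in the message.
#'
#' @param cfg Config list from [read_run_config()], or a path to one.
#' @return The run report, invisibly.
#' @export
run_end_to_end <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stage <- function(name, expr) {
    tryCatch(expr, anchorprobe_error = function(e) {
      ap_stop(paste0("[", name, "] ", conditionMessage(e)),
              class(e)[1L] |> sub(pattern = "^anchorprobe_", replacement = ""))
    })
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = list(
    selection = unclass(cfg$selection),
    primers = unclass(cfg$primers),
    allow_antisense = cfg$allow_antisense,
    min_coverage = cfg$min_coverage,
    max_product = cfg$max_product))

  dat <- stage("expression_io",
               read_expression_data(cfg$matrix, cfg$samples))
  ap_check(nrow(dat$matrix) > 0L, "[expression_io] empty expression matrix",
           "value_error")
  sel <- stage("anchor_selection",
               select_candidates(dat$matrix, dat$samples, cfg$selection))
  write_selection(sel, file.path(cfg$out_dir, "selection"))
  report$candidate_counts <- as.list(candidate_counts(sel))
  selected <- unique(unlist(lapply(sel$candidates, `[[`, "probeset_id")))

  if (!is.null(cfg$annotations)) {
    ann <- stage("pattern_classification",
                 read_sish_annotations(cfg$annotations))
    classified <- stage("pattern_classification", classify_annotations(ann))
    write_classification(classified, file.path(cfg$out_dir, "classification"))
    s <- validation_summary(classified$label)
    report$validation <- list(
      total = s$total,
      combined_validated_percent = s$combined_validated_percent)
  }

  if (!is.null(cfg$probes) && !is.null(cfg$transcripts)) {
    probes <- stage("probe_mapping", read_probe_table(cfg$probes))
    ts <- stage("probe_mapping", read_transcripts(cfg$transcripts))
    in_probes <- intersect(selected, unique(probes$probeset_id))
    use <- if (length(in_probes))
      probes[probes$probeset_id %in% in_probes, , drop = FALSE] else probes
    rb <- stage("primer_design",
                design_riboprobes(use, ts, cfg$primers,
                                  allow_antisense = cfg$allow_antisense,
                                  min_coverage = cfg$min_coverage,
                                  max_product = cfg$max_product))
    if (!is.null(rb$designs)) {
      utils::write.table(rb$designs,
                         file.path(cfg$out_dir, "riboprobe_designs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_bed(data.frame(transcript_id = rb$designs$transcript_id,
                           start = rb$designs$product_start,
                           end = rb$designs$product_end,
                           probeset_id = rb$designs$probeset_id),
                file.path(cfg$out_dir, "riboprobe_products.bed"))
    }
    if (!is.null(rb$amplicons)) {
      utils::write.table(rb$amplicons,
                         file.path(cfg$out_dir, "insilico_amplicons.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    report$riboprobes <- list(
      probesets_considered = length(unique(use$probeset_id)),
      designed = if (is.null(rb$designs)) 0L else nrow(rb$designs),
      failures = if (nrow(rb$failures)) rb$failures else NULL)
  }

  jsonlite::write_json(report, file.path(cfg$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}
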