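# Seed-deterministic synthetic-data generators with recorded ground
# truth, emulating the structure of a compartmental expression atlas
# (replicated arrays over 11 microdissected kidney compartments, rare
# compartment-restricted probesets) and a small transcriptome carrying
# planted probesets. Plus the bundled 37-row anchor-gene reference table.

#' Default compartment codes
#'
#' The 11 midgestation kidney compartments used as fixture defaults:
#' cap mesenchyme (CM), medullary/cortical interstitium (MI, CI),
#' ureteric tip (UT), cortical/medullary collecting duct (CCD, MCD),
#' renal vesicle (RV), S-shaped body (SSB), early proximal tubule (EPT),
#' loop of Henle (LoH) and renal corpuscle (RC).
#' @export
kidney_compartments <- function() {
  c("CM", "MI", "CI", "UT", "CCD", "MCD", "RV", "SSB", "EPT", "LoH", "RC")
}

default_planted <- function(fold = 20) {
  data.frame(probeset_id = paste0("anchor_", c("EPT", "UT", "MCD", "RV", "LoH")),
             compartment = c("EPT", "UT", "MCD", "RV", "LoH"),
             fold = fold, stringsAsFactors = FALSE)
}

#' Generate a synthetic expression matrix with planted anchors
#'
#' Background probesets fluctuate around a constant level (Gaussian
#' noise, truncated at zero, on the RFU scale); each planted probeset is
#' raised to `level x fold` in its target compartment only. The default
#' background level of 50 RFU sits below the 100 RFU raw-signal filter so
#' background is doubly excluded; raise it to stress the fold filter
#' alone.
#'
#' @param n_compartments Number of compartments (taken from
#'   [kidney_compartments()], in order).
#' @param replicates Arrays per compartment.
#' @param n_background Background probesets.
#' @param planted Data.frame `probeset_id`, `compartment`, `fold`
#'   (folds > 1); default plants 5 anchors at fold 20 in EPT, UT, MCD,
#'   RV, LoH.
#' @param background_level Background mean signal (RFU).
#' @param noise_sd Gaussian noise standard deviation (RFU).
#' @param seed Integer seed; generation is fully reproducible.
#' @return List `matrix`, `samples`, `truth` (planted table, levels and
#'   seed).
#' @export
generate_expression_fixture <- function(n_compartments = 11L,
                                        replicates = 3L,
                                        n_background = 200L,
                                        planted = default_planted(),
                                        background_level = 50,
                                        noise_sd = 5,
                                        seed = 1L) {
  ap_check(n_compartments >= 2L && n_compartments <= 11L,
           "n_compartments must be in 2..11", "value_error")
  ap_check(replicates >= 2L, "need >= 2 replicates per compartment",
           "value_error")
  ap_check(n_background >= 0L, "n_background must be >= 0", "value_error")
  comps <- kidney_compartments()[seq_len(n_compartments)]
  ap_check(all(planted$compartment %in% comps),
           "planted compartments must be among the fixture compartments",
           "value_error")
  ap_check(all(planted$fold >= 1), "planted folds must be >= 1",
           "value_error")
  ap_check(!anyDuplicated(planted$probeset_id), "duplicate planted ids",
           "value_error")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  samples <- data.frame(
    sample_id = paste0(rep(comps, each = replicates), "_r",
                       rep(seq_len(replicates), length(comps))),
    compartment = rep(comps, each = replicates),
    stringsAsFactors = FALSE)
  ids <- c(sprintf("bg_%03d_at", seq_len(n_background)), planted$probeset_id)
  n_row <- length(ids)
  n_col <- nrow(samples)
  mu <- matrix(background_level, nrow = n_row, ncol = n_col,
               dimnames = list(ids, samples$sample_id))
  for (i in seq_len(nrow(planted))) {
    cols <- samples$sample_id[samples$compartment == planted$compartment[i]]
    mu[planted$probeset_id[i], cols] <- background_level * planted$fold[i]
  }
  noise <- if (noise_sd > 0)
    matrix(stats::rnorm(n_row * n_col, 0, noise_sd), n_row, n_col)
  else matrix(0, n_row, n_col)
  m <- pmax(mu + noise, 0)
  dimnames(m) <- dimnames(mu)
  list(matrix = m, samples = samples,
       truth = list(planted = planted, background_level = background_level,
                    noise_sd = noise_sd, seed = seed))
}

#' Write an expression fixture to disk
#'
#' Emits `matrix.tsv`, `samples.tsv` and `truth.json`, readable by
#' [read_expression_data()]. Deterministic: the same fixture writes
#' byte-identical files.
#'
#' @param fix List from [generate_expression_fixture()].
#' @param dir Output directory.
#' @export
write_expression_fixture <- function(fix, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  df <- data.frame(probeset_id = rownames(fix$matrix),
                   matrix(sprintf("%.17g", fix$matrix),
                          nrow = nrow(fix$matrix),
                          dimnames = dimnames(fix$matrix)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, file.path(dir, "matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fix$samples, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(fix$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic transcriptome with planted probesets
#'
#' Random transcripts (uniform base composition) each at least 1 kb long;
#' for each planted probeset, 11 non-overlapping 25-mers are copied from
#' positions near the 3' end of its transcript (within a window ending
#' about 100 nt from the end, so template selection exercises the
#' 3'-extension path). Optionally the first `n_antisense` probes per set
#' are stored reverse-complemented, as expression-array probes may be
#' antisense to the mRNA.
#'
#' @param n_transcripts Number of transcripts.
#' @param length_range Min/max transcript length (>= 1000 nt).
#' @param n_probesets Planted probesets (one per transcript; must be
#'   <= `n_transcripts`).
#' @param probes_per_set Probes per probeset.
#' @param n_antisense Probes per set stored as reverse complements.
#' @param seed Integer seed.
#' @return List `transcripts` (`DNAStringSet`), `probes` (probe table)
#'   and `truth` (planted coordinates, 0-based half-open, with
#'   orientation).
#' @export
generate_transcript_fixture <- function(n_transcripts = 6L,
                                        length_range = c(1500L, 3000L),
                                        n_probesets = 3L,
                                        probes_per_set = 11L,
                                        n_antisense = 2L,
                                        seed = 1L) {
  ap_check(length_range[1L] >= 1000L, "transcript lengths must be >= 1000 nt",
           "value_error")
  ap_check(n_probesets <= n_transcripts,
           "need at least one transcript per planted probeset", "value_error")
  ap_check(n_antisense <= probes_per_set, "n_antisense > probes_per_set",
           "value_error")
  slot <- 40L  # probe slot width; >= 25 + jitter keeps probes non-overlapping
  window <- probes_per_set * slot
  ap_check(length_range[1L] >= window + 150L,
           "transcripts too short to place the probe window", "value_error")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  lens <- sample(length_range[1L]:length_range[2L], n_transcripts,
                 replace = TRUE)
  tids <- sprintf("tx_%02d", seq_len(n_transcripts))
  seqs <- vapply(lens, random_dna, character(1))
  names(seqs) <- tids

  probes <- list()
  truth <- list()
  for (j in seq_len(n_probesets)) {
    psid <- sprintf("ps%02d_at", j)
    tid <- tids[j]
    L <- lens[j]
    base <- L - 100L - window   # window sits ~100 nt from the 3' end
    starts0 <- base + (seq_len(probes_per_set) - 1L) * slot +
      sample(0:(slot - 26L), probes_per_set, replace = TRUE)
    for (i in seq_len(probes_per_set)) {
      s0 <- starts0[i]
      sub <- substr(seqs[[tid]], s0 + 1L, s0 + 25L)
      antis <- i <= n_antisense
      probes[[length(probes) + 1L]] <- data.frame(
        probeset_id = psid, probe_index = i - 1L,
        sequence = if (antis) reverse_complement(sub) else sub,
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        probeset_id = psid, probe_index = i - 1L, transcript_id = tid,
        start = s0, end = s0 + 25L,
        orientation = if (antis) "antisense" else "sense",
        stringsAsFactors = FALSE)
    }
  }
  probes <- do.call(rbind, probes)
  truth <- do.call(rbind, truth)
  list(transcripts = Biostrings::DNAStringSet(seqs),
       probes = probes,
       truth = list(planted = truth, lengths = stats::setNames(lens, tids),
                    seed = seed))
}

#' Write a transcript fixture to disk
#'
#' Emits `transcripts.fa`, `probes.tsv` and `truth.json`, readable by
#' [read_transcripts()] and [read_probe_table()].
#'
#' @param fix List from [generate_transcript_fixture()].
#' @param dir Output directory.
#' @export
write_transcript_fixture <- function(fix, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Biostrings::writeXStringSet(fix$transcripts,
                              file.path(dir, "transcripts.fa"))
  utils::write.table(fix$probes, file.path(dir, "probes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(fix$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' The bundled 37-row anchor-gene reference table
#'
#' Loads the published final anchor-gene list (37 probesets across 6
#' kidney compartments: 25 EPT, 5 MCD, 4 RC and one each for LoH, RV and
#' UT) with each probeset's raw target-compartment signal, the median
#' signal over the other compartments, and the fold-change as printed in
#' the source table (`fold_change_printed`). Because the published
#' fold-change column is rounded (several rows to whole numbers), the
#' returned `fold_change` is recomputed as `raw / median_other` so that
#' the statistics invariants hold; compare against
#' `fold_change_printed` to audit the printed values. `p_anova`/`q_bh`
#' are `NA`: the underlying arrays are not bundled, so significance must
#' be supplied by the caller when filtering this table.
#'
#' @return Data.frame with columns `probeset_id`, `gene_symbol`,
#'   `compartment`, `raw`, `median_other`, `fold_change`,
#'   `fold_change_printed`, `p_anova`, `q_bh`.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_anchor_genes.tsv",
                      package = "anchorprobe", mustWork = TRUE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$fold_change <- fold_change(df$raw, df$median_other)
  df$p_anova <- NA_real_
  df$q_bh <- NA_real_
  df[, c("probeset_id", "gene_symbol", "compartment", "raw", "median_other",
         "fold_change", "fold_change_printed", "p_anova", "q_bh")]
}
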