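# Mapping of 25-mer expression-array oligo probes onto transcript
# sequences, probeset coverage and riboprobe template selection. All
# coordinates are 0-based half-open (BED convention) in transcript space.

PROBE_LENGTH <- 25L

#' Read an oligo probe table
#'
#' @param path TSV with columns `probeset_id`, `probe_index` (0-based
#'   within the probeset) and `sequence` (25-mer over A/C/G/T).
#' @return Validated data.frame.
#' @export
read_probe_table <- function(path) {
  ap_check(file.exists(path), paste0("file not found: ", path),
           "format_error")
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ap_check(all(c("probeset_id", "probe_index", "sequence") %in% colnames(df)),
           "probe table needs probeset_id, probe_index, sequence",
           "format_error")
  df$probe_index <- as.integer(df$probe_index)
  validate_probes(df)
  df
}

validate_probes <- function(probes) {
  ap_check(all(nchar(probes$sequence) == PROBE_LENGTH),
           "probe sequences must be exactly 25 nt", "value_error")
  ap_check(all(grepl("^[ACGT]+$", probes$sequence)),
           "probe sequences must be over A/C/G/T", "value_error")
  ap_check(!anyDuplicated(probes[, c("probeset_id", "probe_index")]),
           "duplicate (probeset, probe_index)", "format_error")
  invisible(TRUE)
}

#' Read transcript sequences from FASTA
#'
#' @param path FASTA file; record ids are the first whitespace-delimited
#'   token of each header.
#' @return A [Biostrings::DNAStringSet] with unique non-empty records.
#' @export
read_transcripts <- function(path) {
  ap_check(file.exists(path), paste0("file not found: ", path),
           "format_error")
  ts <- Biostrings::readDNAStringSet(path)
  names(ts) <- sub("\\s.*$", "", names(ts))
  ap_check(length(ts) >= 1L, "no transcripts in FASTA", "format_error")
  ap_check(!anyDuplicated(names(ts)), "duplicate transcript ids",
           "format_error")
  ap_check(all(Biostrings::width(ts) > 0L), "empty transcript sequence",
           "format_error")
  ts
}

as_transcript_set <- function(ts) {
  if (is.character(ts)) {
    ap_check(!is.null(names(ts)) && !anyDuplicated(names(ts)),
             "transcripts must be uniquely named", "format_error")
    ts <- Biostrings::DNAStringSet(ts)
  }
  ap_check(methods::is(ts, "DNAStringSet"),
           "transcripts must be a DNAStringSet or named character vector",
           "value_error")
  ts
}

#' Map oligo probes onto transcripts by exact matching
#'
#' Each probe (and, with `allow_antisense`, its reverse complement) is
#' searched as an exact substring of every transcript; expression-array
#' probes may be antisense to the mRNA, so both orientations are searched
#' by default and the orientation is reported. All occurrences are
#' returned, ordered by transcript id, start, probe index.
#'
#' @param probes Probe table (see [read_probe_table()]).
#' @param transcripts A `DNAStringSet` or named character vector.
#' @param allow_antisense Also search each probe's reverse complement.
#' @return Data.frame of hits: `probeset_id`, `probe_index`,
#'   `transcript_id`, `start`, `end` (0-based half-open), `orientation`
#'   (`sense`/`antisense`).
#' @export
map_probes <- function(probes, transcripts, allow_antisense = TRUE) {
  validate_probes(probes)
  ts <- as_transcript_set(transcripts)
  rows <- vector("list", nrow(probes) * 2L)
  k <- 0L
  collect <- function(i, pattern, orientation) {
    mi <- Biostrings::vmatchPattern(pattern, ts)
    starts <- Biostrings::startIndex(mi)   # list of 1-based start vectors
    hit_t <- which(lengths(starts) > 0L)
    if (length(hit_t) == 0L) return(NULL)
    do.call(rbind, lapply(hit_t, function(j) {
      s1 <- starts[[j]]
      data.frame(probeset_id = probes$probeset_id[i],
                 probe_index = probes$probe_index[i],
                 transcript_id = names(ts)[j],
                 start = s1 - 1L,
                 end = s1 - 1L + PROBE_LENGTH,
                 orientation = orientation,
                 stringsAsFactors = FALSE)
    }))
  }
  for (i in seq_len(nrow(probes))) {
    pat <- Biostrings::DNAString(probes$sequence[i])
    k <- k + 1L
    rows[[k]] <- collect(i, pat, "sense")
    if (allow_antisense) {
      k <- k + 1L
      rows[[k]] <- collect(i, Biostrings::reverseComplement(pat), "antisense")
    }
  }
  hits <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(hits)) {
    hits <- data.frame(probeset_id = character(0), probe_index = integer(0),
                       transcript_id = character(0), start = integer(0),
                       end = integer(0), orientation = character(0),
                       stringsAsFactors = FALSE)
  }
  hits <- hits[order(hits$transcript_id, hits$start, hits$probe_index,
                     hits$orientation), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Fraction of a probeset's probes with at least one hit
#'
#' @param hits Hit rows for one probeset on one transcript.
#' @param probeset_size Number of probes in the probeset (typically 11).
#' @return Distinct hit probe indices divided by `probeset_size`.
#' @export
coverage_fraction <- function(hits, probeset_size) {
  ap_check(is.numeric(probeset_size) && probeset_size >= 1,
           "probeset_size must be >= 1", "value_error")
  length(unique(hits$probe_index)) / probeset_size
}

#' Per (probeset, transcript) mapping summaries
#'
#' @param hits Hit table from [map_probes()].
#' @param probes The probe table (defines each probeset's size).
#' @return Data.frame: `probeset_id`, `transcript_id`, `n_probes_hit`,
#'   `probeset_size`, `coverage_fraction`, `span_start`, `span_end`.
#' @export
probeset_coverage <- function(hits, probes) {
  sizes <- tapply(probes$probe_index, probes$probeset_id,
                  function(x) length(unique(x)))
  if (nrow(hits) == 0L) {
    return(data.frame(probeset_id = character(0), transcript_id = character(0),
                      n_probes_hit = integer(0), probeset_size = integer(0),
                      coverage_fraction = numeric(0), span_start = integer(0),
                      span_end = integer(0), stringsAsFactors = FALSE))
  }
  key <- interaction(hits$probeset_id, hits$transcript_id, drop = TRUE)
  out <- do.call(rbind, lapply(split(hits, key), function(h) {
    data.frame(probeset_id = h$probeset_id[1L],
               transcript_id = h$transcript_id[1L],
               n_probes_hit = length(unique(h$probe_index)),
               probeset_size = unname(sizes[[h$probeset_id[1L]]]),
               coverage_fraction = coverage_fraction(
                 h, sizes[[h$probeset_id[1L]]]),
               span_start = min(h$start),
               span_end = max(h$end),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$probeset_id, out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select a 3'-biased riboprobe template region
#'
#' Starting from the smallest interval containing every hit probe, the
#' region is extended to `min_len` preferring extension toward the
#' transcript 3' end (higher coordinates), clipped at the transcript
#' bounds. If the probe span already exceeds `max_len`, the 3'-most
#' `max_len` window maximising the number of fully contained probes is
#' chosen instead. The template must rest on a probeset covered at
#' `min_coverage` (80% of its probes by default).
#'
#' @param transcripts Transcript set containing the target transcript.
#' @param hits Hit rows for one probeset on one transcript.
#' @param probeset_size Number of probes in the probeset.
#' @param min_len,max_len Template length bounds in bp (riboprobes are
#'   designed at 500-800 bp).
#' @param min_coverage Required coverage fraction.
#' @return Data.frame row: `probeset_id`, `transcript_id`, `start`,
#'   `end`, `covered_probe_count`.
#' @export
select_template <- function(transcripts, hits, probeset_size,
                            min_len = 500L, max_len = 800L,
                            min_coverage = 0.8) {
  ts <- as_transcript_set(transcripts)
  ap_check(nrow(hits) >= 1L, "no hits to build a template from",
           "coverage_error")
  ap_check(length(unique(hits$transcript_id)) == 1L &&
             length(unique(hits$probeset_id)) == 1L,
           "hits must come from one probeset on one transcript",
           "value_error")
  cov <- coverage_fraction(hits, probeset_size)
  if (cov < min_coverage) {
    ap_stop(sprintf(
      "probeset coverage %.3f below required %.2f on transcript %s",
      cov, min_coverage, hits$transcript_id[1L]), "coverage_error")
  }
  tid <- hits$transcript_id[1L]
  ap_check(tid %in% names(ts), paste0("unknown transcript: ", tid),
           "lookup_error")
  L <- Biostrings::width(ts)[match(tid, names(ts))]
  if (L < min_len) {
    ap_stop(sprintf("transcript %s is %d nt, shorter than min_len %d",
                    tid, L, min_len), "length_error")
  }
  span_start <- min(hits$start)
  span_end <- max(hits$end)
  if (span_end - span_start > max_len) {
    # 3'-most max_len window maximising fully contained probes
    starts <- 0:(L - max_len)
    counts <- vapply(starts, function(s) {
      inside <- hits$start >= s & hits$end <= s + max_len
      length(unique(hits$probe_index[inside]))
    }, integer(1))
    best <- max(counts)
    s <- max(starts[counts == best])
    region <- c(s, s + max_len)
  } else {
    region <- c(span_start, span_end)
    deficit <- min_len - (region[2L] - region[1L])
    if (deficit > 0L) {
      region[2L] <- min(L, region[2L] + deficit)           # extend 3' first
      deficit <- min_len - (region[2L] - region[1L])
      if (deficit > 0L) region[1L] <- max(0L, region[1L] - deficit)
    }
  }
  inside <- hits$start >= region[1L] & hits$end <= region[2L]
  data.frame(probeset_id = hits$probeset_id[1L],
             transcript_id = tid,
             start = as.integer(region[1L]),
             end = as.integer(region[2L]),
             covered_probe_count = length(unique(hits$probe_index[inside])),
             stringsAsFactors = FALSE)
}

#' Rank alternative probeset mappings for one locus
#'
#' Where several probesets interrogate the same locus, prefer the one
#' with the highest transcript coverage, then the one whose probe span
#' reaches furthest toward the 3' end, then probeset id.
#'
#' @param mappings Data.frame from [probeset_coverage()].
#' @return The same rows, ordered best-first.
#' @export
rank_probesets <- function(mappings) {
  ap_check(nrow(mappings) >= 1L, "need >= 1 mapping", "value_error")
  ord <- order(-mappings$coverage_fraction, -mappings$span_end,
               mappings$probeset_id)
  out <- mappings[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write intervals as BED (transcript space)
#'
#' @param regions Data.frame with `transcript_id`, `start`, `end` and
#'   optionally a name column given by `name_col`.
#' @param path Output path.
#' @param name_col Column used for the BED name field.
#' @export
write_bed <- function(regions, path, name_col = "probeset_id") {
  nm <- if (name_col %in% colnames(regions)) regions[[name_col]] else "."
  bed <- data.frame(regions$transcript_id, regions$start, regions$end, nm)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
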