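# Self-contained primer-pair search for riboprobe amplicons (500-800 bp
# products, reverse primer carrying a T7 promoter tag so the amplicon can
# template antisense RNA synthesis) and brute-force in-silico PCR for
# specificity checking.

#' Reverse complement of a DNA sequence
#'
#' @param seq Character scalar over A/C/G/T/N.
#' @return The reverse complement, as a character scalar.
#' @export
reverse_complement <- function(seq) {
  ap_check(is.character(seq) && length(seq) == 1L && !is.na(seq),
           "seq must be a single string", "value_error")
  ap_check(grepl("^[ACGTN]*$", seq),
           "sequence must be over A/C/G/T/N", "value_error")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Wallace-rule melting temperature
#'
#' `Tm = 2(A+T) + 4(G+C)` degrees Celsius — the classic salt-free rule of
#' thumb for short oligos, chosen for hand-verifiability. Deterministic
#' and monotone in GC content at fixed length; swap in another rule via
#' the `tm_fun` argument of [design_primers()] if a nearest-neighbor
#' model is preferred.
#'
#' @param seq Character scalar over A/C/G/T, length >= 10.
#' @return Melting temperature in degrees Celsius.
#' @export
melting_temperature <- function(seq) {
  ap_check(is.character(seq) && length(seq) == 1L && !is.na(seq),
           "seq must be a single string", "value_error")
  ap_check(grepl("^[ACGT]+$", seq), "sequence must be over A/C/G/T",
           "value_error")
  ap_check(nchar(seq) >= 10L, "sequence must be >= 10 nt for a Tm estimate",
           "value_error")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  gc <- sum(chars %in% c("G", "C"))
  2 * (length(chars) - gc) + 4 * gc
}

#' GC content in percent
#'
#' @param seq Character scalar over A/C/G/T.
#' @return `100 * (G + C) / length`.
#' @export
gc_content <- function(seq) {
  ap_check(is.character(seq) && length(seq) == 1L && !is.na(seq) &&
             nzchar(seq), "seq must be a non-empty string", "value_error")
  ap_check(grepl("^[ACGT]+$", seq), "sequence must be over A/C/G/T",
           "value_error")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  100 * sum(chars %in% c("G", "C")) / length(chars)
}

#' Primer design constraints
#'
#' Defaults follow common wet-lab practice for riboprobe amplicons:
#' 500-800 bp product, 18-27 nt primers, Tm window 52-68 C around an
#' optimum of 60 C, 40-60% GC, homopolymer runs capped at 4, and the
#' canonical T7 promoter `TAATACGACTCACTATAGGG` prepended to the reverse
#' primer.
#'
#' @param product_min,product_max Product length bounds (bp).
#' @param primer_len_min,primer_len_max Primer length bounds (nt).
#' @param tm_min,tm_opt,tm_max Melting-temperature bounds/optimum (C),
#'   computed on the core primer (the tag does not anneal in the first
#'   cycles and is excluded).
#' @param gc_min,gc_max GC-content bounds (percent, inclusive).
#' @param max_homopolymer Longest tolerated single-base run.
#' @param t7_tag Promoter sequence prepended to the reverse primer.
#' @return A `primer_constraints` object.
#' @export
primer_constraints <- function(product_min = 500L, product_max = 800L,
                               primer_len_min = 18L, primer_len_max = 27L,
                               tm_min = 52, tm_opt = 60, tm_max = 68,
                               gc_min = 40, gc_max = 60,
                               max_homopolymer = 4L,
                               t7_tag = "TAATACGACTCACTATAGGG") {
  ap_check(product_min <= product_max && primer_len_min <= primer_len_max &&
             tm_min <= tm_opt && tm_opt <= tm_max && gc_min <= gc_max,
           "constraint ranges must satisfy min <= opt <= max", "value_error")
  ap_check(product_min > 0 && primer_len_min > 0 && max_homopolymer >= 1,
           "constraints must be positive", "value_error")
  ap_check(grepl("^[ACGT]*$", t7_tag), "t7_tag must be over A/C/G/T",
           "value_error")
  structure(list(product_min = as.integer(product_min),
                 product_max = as.integer(product_max),
                 primer_len_min = as.integer(primer_len_min),
                 primer_len_max = as.integer(primer_len_max),
                 tm_min = tm_min, tm_opt = tm_opt, tm_max = tm_max,
                 gc_min = gc_min, gc_max = gc_max,
                 max_homopolymer = as.integer(max_homopolymer),
                 t7_tag = t7_tag),
            class = "primer_constraints")
}

#' Load primer constraints from a YAML file
#'
#' @param path YAML file with keys mirroring [primer_constraints()].
#' @return A `primer_constraints` object.
#' @export
read_primer_constraints <- function(path) {
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), names(formals(primer_constraints)))
  ap_check(length(bad) == 0L,
           paste0("unknown primer constraint keys: ",
                  paste(bad, collapse = ", ")), "format_error")
  do.call(primer_constraints, raw)
}

# Candidate primer sites within a template: one row per (start0, len)
# satisfying Tm, GC and homopolymer constraints. Validity of a reverse
# primer equals validity of the template substring it anneals to (GC and
# base-pair counts are strand-symmetric, a homopolymer run complements
# to a homopolymer run), so both strands share this table.
primer_candidate_sites <- function(chars, cns, tm_fun = NULL) {
  L <- length(chars)
  is_gc <- chars %in% c("G", "C")
  cum_gc <- c(0L, cumsum(is_gc))
  k <- cns$max_homopolymer
  same <- rep(FALSE, L)  # same[i]: chars[i-k..i] identical (run > k ends at i)
  if (L > k) {
    eq <- chars[-1L] == chars[-L]          # eq[i] <=> chars[i+1]==chars[i]
    run <- Reduce(function(acc, e) if (e) acc + 1L else 0L, eq,
                  accumulate = TRUE)       # run[i]: equal steps ending at i+1
    same[which(run >= k) + 1L] <- TRUE
  }
  cum_same <- c(0L, cumsum(same))
  out <- list()
  for (len in cns$primer_len_min:cns$primer_len_max) {
    if (len > L) next
    s <- seq_len(L - len + 1L)             # 1-based starts
    gc_n <- cum_gc[s + len] - cum_gc[s]
    if (is.null(tm_fun)) {
      tm <- 2 * (len - gc_n) + 4 * gc_n
    } else {
      tm <- vapply(s, function(si)
        tm_fun(paste(chars[si:(si + len - 1L)], collapse = "")), numeric(1))
    }
    gc_pct <- 100 * gc_n / len
    # homopolymer: run of > k inside [s, s+len-1] <=> some "same" flag in
    # (s+k-1, s+len-1]
    hp_bad <- if (len > k) {
      (cum_same[s + len] - cum_same[s + k - 1L + 1L]) > 0L
    } else rep(FALSE, length(s))
    ok <- tm >= cns$tm_min & tm <= cns$tm_max &
      gc_pct >= cns$gc_min & gc_pct <= cns$gc_max & !hp_bad
    if (any(ok)) {
      out[[length(out) + 1L]] <-
        data.frame(start0 = s[ok] - 1L, len = len, tm = tm[ok])
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start0 = integer(0), len = integer(0),
                      tm = numeric(0)))
  }
  do.call(rbind, out)
}

#' Design a primer pair on a riboprobe template
#'
#' Performs a deterministic search over all (forward start, forward
#' length, reverse end, reverse length) combinations inside the template,
#' discarding candidates violating the Tm/GC/homopolymer constraints, and
#' returns the pair minimising
#' `|Tm_fwd - tm_opt| + |Tm_rev - tm_opt| + |Tm_fwd - Tm_rev|`.
#' Ties break by larger product end (3' preference), then shorter
#' product, then shorter forward and reverse primers. The reverse primer
#' is emitted with the T7 tag prepended (`reverse_tagged_seq`); Tm and GC
#' are reported for the cores.
#'
#' @param template Template region sequence (character scalar or
#'   `DNAString`).
#' @param constraints A [primer_constraints()] object.
#' @param offset Added to reported product coordinates (use the template
#'   region's start to report in transcript space).
#' @param tm_fun Optional alternative melting-temperature function
#'   (character scalar in, degrees C out); defaults to the Wallace rule.
#' @param contain Optional 0-based half-open interval (relative to the
#'   template) that the product must fully contain — used by the
#'   riboprobe pipeline to force the amplicon over the probe span.
#' @return A `primer_pair` object (list; see fields in the source/print
#'   method).
#' @export
design_primers <- function(template, constraints = primer_constraints(),
                           offset = 0L, tm_fun = NULL, contain = NULL) {
  if (methods::is(template, "DNAString") ||
      methods::is(template, "DNAStringSet")) {
    template <- as.character(template)[1L]
  }
  ap_check(is.character(template) && length(template) == 1L,
           "template must be a single sequence", "value_error")
  template <- toupper(template)
  ap_check(grepl("^[ACGTN]+$", template),
           "template must be over A/C/G/T/N", "value_error")
  cns <- constraints
  L <- nchar(template)
  if (L < cns$product_min) {
    ap_stop(sprintf(
      "template of %d bp cannot yield a product of >= %d bp", L,
      cns$product_min), "design_failure_error")
  }
  chars <- strsplit(template, "", fixed = TRUE)[[1L]]
  # N is never a valid primer base: treat windows containing N as invalid
  # by mapping N to a fake char that breaks GC bounds? Simpler: mask via
  # pre-scan below.
  sites <- primer_candidate_sites(chars, cns, tm_fun)
  if (nrow(sites) > 0L && any(chars == "N")) {
    npos <- which(chars == "N")
    has_n <- vapply(seq_len(nrow(sites)), function(i)
      any(npos > sites$start0[i] & npos <= sites$start0[i] + sites$len[i]),
      logical(1))
    sites <- sites[!has_n, , drop = FALSE]
  }
  if (nrow(sites) == 0L) {
    ap_stop("no primer site satisfies the Tm/GC/homopolymer constraints",
            "design_failure_error")
  }
  # forward primers are indexed by their start; reverse primers by the
  # product end they define (site end). For each (tm, position) keep the
  # shortest primer (final tie-break).
  best_len_by <- function(pos, len, tm) {
    o <- order(tm, pos, len)
    d <- data.frame(pos = pos[o], len = len[o], tm = tm[o])
    d[!duplicated(d[, c("tm", "pos")]), , drop = FALSE]
  }
  fwd <- best_len_by(sites$start0, sites$len, sites$tm)
  rev <- best_len_by(sites$start0 + sites$len, sites$len, sites$tm)
  if (!is.null(contain)) {
    ap_check(length(contain) == 2L && contain[1L] >= 0 &&
               contain[2L] <= L && contain[1L] <= contain[2L],
             "contain must be a 0-based half-open interval inside the template",
             "value_error")
    fwd <- fwd[fwd$pos <= contain[1L], , drop = FALSE]
    rev <- rev[rev$pos >= contain[2L], , drop = FALSE]
    if (nrow(fwd) == 0L || nrow(rev) == 0L) {
      ap_stop("no valid primer site flanks the required probe-span interval",
              "design_failure_error")
    }
  }

  tms <- sort(unique(sites$tm))
  combos <- expand.grid(ftm = tms, rtm = tms)
  combos$score <- abs(combos$ftm - cns$tm_opt) + abs(combos$rtm - cns$tm_opt) +
    abs(combos$ftm - combos$rtm)
  found <- NULL
  for (ci in order(combos$score)) {
    sc <- combos$score[ci]
    if (!is.null(found) && sc > found$score) break
    fs_all <- sort(fwd$pos[fwd$tm == combos$ftm[ci]])
    re_all <- sort(rev$pos[rev$tm == combos$rtm[ci]], decreasing = TRUE)
    if (length(fs_all) == 0L || length(re_all) == 0L) next
    for (re in re_all) {
      lo <- re - cns$product_max
      hi <- re - cns$product_min
      idx <- findInterval(hi, fs_all)
      if (idx >= 1L && fs_all[idx] >= lo) {
        fs <- fs_all[idx]
        cand <- list(score = sc, fs = fs, re = re,
                     ftm = combos$ftm[ci], rtm = combos$rtm[ci])
        better <- is.null(found) ||
          cand$score < found$score ||
          (cand$score == found$score &&
             (cand$re > found$re ||
                (cand$re == found$re && cand$fs > found$fs)))
        if (better) found <- cand
        break
      }
    }
  }
  if (is.null(found)) {
    ap_stop(sprintf(
      paste0("no primer pair yields a %d-%d bp product (valid sites: %d); ",
             "the product-size constraint is binding"),
      cns$product_min, cns$product_max, nrow(sites)),
      "design_failure_error")
  }
  flen <- min(fwd$len[fwd$tm == found$ftm & fwd$pos == found$fs])
  rlen <- min(rev$len[rev$tm == found$rtm & rev$pos == found$re])
  fwd_seq <- substr(template, found$fs + 1L, found$fs + flen)
  rev_site <- substr(template, found$re - rlen + 1L, found$re)
  rev_core <- reverse_complement(rev_site)
  structure(list(
    forward_seq = fwd_seq,
    reverse_core_seq = rev_core,
    reverse_tagged_seq = paste0(cns$t7_tag, rev_core),
    forward_tm = melting_temperature(fwd_seq),
    reverse_tm = melting_temperature(rev_core),
    forward_gc = gc_content(fwd_seq),
    reverse_gc = gc_content(rev_core),
    product_start = as.integer(offset + found$fs),
    product_end = as.integer(offset + found$re),
    product_length = as.integer(found$re - found$fs),
    t7_tag = cns$t7_tag), class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat("Primer pair (", x$product_length, " bp product at [",
      x$product_start, ", ", x$product_end, "))\n", sep = "")
  cat(sprintf("  forward: %s (Tm %.0f C, GC %.1f%%)\n",
              x$forward_seq, x$forward_tm, x$forward_gc))
  cat(sprintf("  reverse: %s (core Tm %.0f C, GC %.1f%%)\n",
              x$reverse_tagged_seq, x$reverse_tm, x$reverse_gc))
  invisible(x)
}

#' In-silico PCR against a transcript set
#'
#' Brute-force amplicon prediction: every exact sense occurrence of the
#' forward primer is paired with every exact downstream occurrence of the
#' reverse core primer's reverse complement on the same transcript, in
#' convergent, non-overlapping orientation, with product length capped at
#' `max_product`. Exact matching (0 mismatches) of the full primers,
#' including their 3' ends, is required.
#'
#' @param pair A `primer_pair` (or list with `forward_seq` and
#'   `reverse_core_seq`).
#' @param transcripts A `DNAStringSet` or named character vector.
#' @param max_product Largest product reported (bp).
#' @return Data.frame of predicted amplicons: `transcript_id`, `start`,
#'   `end` (0-based half-open), `length`.
#' @export
insilico_pcr <- function(pair, transcripts, max_product = 4000L) {
  ts <- as_transcript_set(transcripts)
  fwd <- Biostrings::DNAString(pair$forward_seq)
  rev_site <- Biostrings::reverseComplement(
    Biostrings::DNAString(pair$reverse_core_seq))
  flen <- length(fwd)
  rlen <- length(rev_site)
  f_idx <- Biostrings::startIndex(Biostrings::vmatchPattern(fwd, ts))
  r_idx <- Biostrings::startIndex(Biostrings::vmatchPattern(rev_site, ts))
  rows <- list()
  for (j in seq_along(ts)) {
    fs <- f_idx[[j]]
    rs <- r_idx[[j]]
    if (length(fs) == 0L || length(rs) == 0L) next
    for (f1 in fs) {
      for (r1 in rs) {
        start0 <- f1 - 1L
        end0 <- r1 - 1L + rlen
        if (r1 - 1L >= start0 + flen && end0 - start0 <= max_product) {
          rows[[length(rows) + 1L]] <-
            data.frame(transcript_id = names(ts)[j], start = start0,
                       end = end0, length = end0 - start0,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$transcript_id, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}
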