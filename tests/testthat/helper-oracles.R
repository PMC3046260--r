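# Independent oracles, coded straight from textbook formulas and naive
# enumeration. Deliberately share no code with the package internals.

# Welch's heteroscedastic F: w_i = n_i/s_i^2, weighted grand mean,
# F = [sum w_i (xbar_i - xbar_w)^2 / (k-1)] / [1 + 2(k-2)/(k^2-1) * Lambda],
# Lambda = sum (1 - w_i/sum(w))^2 / (n_i - 1), df1 = k-1,
# df2 = (k^2-1)/(3*Lambda), p = upper tail of F.
oracle_welch <- function(groups) {
  k <- length(groups)
  n <- vapply(groups, length, numeric(1))
  xbar <- vapply(groups, mean, numeric(1))
  s2 <- vapply(groups, function(x) sum((x - mean(x))^2) / (length(x) - 1),
               numeric(1))
  w <- n / s2
  xw <- sum(w * xbar) / sum(w)
  lambda <- sum((1 - w / sum(w))^2 / (n - 1))
  f <- (sum(w * (xbar - xw)^2) / (k - 1)) /
    (1 + 2 * (k - 2) / (k^2 - 1) * lambda)
  df1 <- k - 1
  df2 <- (k^2 - 1) / (3 * lambda)
  list(statistic = f, df1 = df1, df2 = df2,
       p.value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j) * n / j, capped
# at 1, returned in input order.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- numeric(n)
  running <- Inf
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    q_sorted[i] <- min(running, 1)
  }
  out <- numeric(n)
  out[o] <- q_sorted
  out
}

oracle_revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# Naive O(n*m) exact substring scan of every probe (and optionally its
# reverse complement) against every transcript, via fixed-string gregexpr.
oracle_map <- function(probes, seqs, allow_antisense = TRUE) {
  rows <- list()
  find_all <- function(pattern, subject) {
    hits <- integer(0)
    from <- 1L
    repeat {
      i <- regexpr(pattern, substr(subject, from, nchar(subject)),
                   fixed = TRUE)
      if (i == -1L) break
      hits <- c(hits, from + i - 1L)
      from <- from + i  # allow overlapping occurrences
    }
    hits
  }
  for (i in seq_len(nrow(probes))) {
    for (tid in names(seqs)) {
      for (ori in c("sense", if (allow_antisense) "antisense")) {
        pat <- if (ori == "sense") probes$sequence[i] else
          oracle_revcomp(probes$sequence[i])
        for (s1 in find_all(pat, seqs[[tid]])) {
          rows[[length(rows) + 1L]] <- data.frame(
            probeset_id = probes$probeset_id[i],
            probe_index = probes$probe_index[i],
            transcript_id = tid, start = s1 - 1L, end = s1 - 1L + 25L,
            orientation = ori, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) return(NULL)
  out <- do.call(rbind, rows)
  out <- out[order(out$transcript_id, out$start, out$probe_index,
                   out$orientation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exhaustive position-pair enumeration for in-silico PCR.
oracle_ispcr <- function(fwd, rev_core, seqs, max_product = 4000L) {
  rev_site <- oracle_revcomp(rev_core)
  rows <- list()
  for (tid in names(seqs)) {
    subject <- seqs[[tid]]
    n <- nchar(subject)
    flen <- nchar(fwd); rlen <- nchar(rev_site)
    for (f1 in seq_len(max(0L, n - flen + 1L))) {
      if (substr(subject, f1, f1 + flen - 1L) != fwd) next
      for (r1 in seq_len(max(0L, n - rlen + 1L))) {
        if (substr(subject, r1, r1 + rlen - 1L) != rev_site) next
        start0 <- f1 - 1L
        end0 <- r1 - 1L + rlen
        if (r1 - 1L >= start0 + flen && end0 - start0 <= max_product) {
          rows[[length(rows) + 1L]] <- data.frame(
            transcript_id = tid, start = start0, end = end0,
            length = end0 - start0, stringsAsFactors = FALSE)
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

# Exhaustive fixed-length window scan for template selection: among all
# windows of length `len` containing every hit interval, pick the one
# maximising (covered probes, end coordinate).
oracle_template_window <- function(hits, transcript_len, len) {
  best <- NULL
  for (s in 0:(transcript_len - len)) {
    e <- s + len
    if (all(hits$start >= s & hits$end <= e)) {
      covered <- length(unique(hits$probe_index))
      if (is.null(best) || covered > best$covered || e > best$end) {
        best <- list(start = s, end = e, covered = covered)
      }
    }
  }
  best
}
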