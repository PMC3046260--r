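test_that("planted substrings are found in both orientations", {
  set.seed(31)
  tx <- random_seq(400)
  probe_sense <- substr(tx, 101, 125)
  probe_anti <- reverse_complement(substr(tx, 41, 65))
  probes <- data.frame(probeset_id = "ps1", probe_index = 0:1,
                       sequence = c(probe_sense, probe_anti))
  hits <- map_probes(probes, c(t1 = tx))
  sense <- hits[hits$orientation == "sense", ]
  anti <- hits[hits$orientation == "antisense", ]
  expect_true(any(sense$start == 100 & sense$end == 125 &
                    sense$probe_index == 0))
  expect_true(any(anti$start == 40 & anti$end == 65 & anti$probe_index == 1))
  # antisense search can be disabled
  hits_sense <- map_probes(probes, c(t1 = tx), allow_antisense = FALSE)
  expect_false(any(hits_sense$probe_index == 1))
})

test_that("fixture probes map exactly at the recorded truth coordinates", {
  tf <- generate_transcript_fixture(seed = 2)
  hits <- map_probes(tf$probes, tf$transcripts)
  truth <- tf$truth$planted
  key <- function(d) d[order(d$probeset_id, d$probe_index),
                       c("probeset_id", "probe_index", "transcript_id",
                         "start", "end", "orientation")]
  expect_identical(key(hits), key(truth), ignore_attr = TRUE)

  # every reported hit re-extracts to the probe (or its reverse complement)
  seqs <- as.character(tf$transcripts)
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    sub <- substr(seqs[[h$transcript_id]], h$start + 1, h$end)
    probe <- tf$probes$sequence[tf$probes$probeset_id == h$probeset_id &
                                  tf$probes$probe_index == h$probe_index]
    expect_identical(sub,
                     if (h$orientation == "sense") probe
                     else reverse_complement(probe))
  }
})

test_that("mapping agrees with a naive exhaustive scan", {
  set.seed(77)
  seqs <- setNames(vapply(1:6, function(i) random_seq(800), character(1)),
                   paste0("t", 1:6))
  # plant a few probes, include a duplicate occurrence across transcripts
  probes <- data.frame(
    probeset_id = "psx", probe_index = 0:3,
    sequence = c(substr(seqs[[1]], 50, 74),
                 reverse_complement(substr(seqs[[2]], 300, 324)),
                 substr(seqs[[3]], 700, 724),
                 random_seq(25)))
  seqs[["t4"]] <- paste0(substr(seqs[[4]], 1, 100), substr(seqs[[1]], 50, 74),
                         substr(seqs[[4]], 126, 800))
  got <- map_probes(probes, seqs)
  want <- oracle_map(probes, seqs)
  expect_identical(got, want, ignore_attr = TRUE)
})

test_that("coverage fraction counts distinct probes against the threshold", {
  hits <- data.frame(probe_index = c(0:8, 3, 4))   # 9 distinct of 11
  expect_equal(coverage_fraction(hits, 11), 9 / 11)
  expect_true(coverage_fraction(hits, 11) >= 0.8)
  expect_false(coverage_fraction(data.frame(probe_index = 0:7), 11) >= 0.8)
  expect_equal(coverage_fraction(data.frame(probe_index = 0:10), 11), 1)
})

test_that("template selection extends 3' and matches the window oracle", {
  set.seed(55)
  tx <- random_seq(3000)
  # probes spanning [1000, 1400)
  starts <- seq(1000L, 1375L, length.out = 11L)
  hits <- data.frame(probeset_id = "ps1", probe_index = 0:10,
                     transcript_id = "t1",
                     start = as.integer(starts),
                     end = as.integer(starts) + 25L,
                     orientation = "sense")
  hits$end[11] <- 1400L; hits$start[11] <- 1375L
  tmpl <- select_template(c(t1 = tx), hits, probeset_size = 11)
  expect_equal(tmpl$end - tmpl$start, 500)
  expect_true(tmpl$start <= 1000 && tmpl$end >= 1400)
  expect_equal(tmpl$covered_probe_count, 11)
  want <- oracle_template_window(hits, 3000, 500)
  expect_equal(c(tmpl$start, tmpl$end), c(want$start, want$end))

  # span exactly min_len: region equals the span
  hits2 <- hits
  hits2$start[1] <- 900L; hits2$end[1] <- 925L
  expect_equal(unlist(select_template(c(t1 = tx), hits2,
                                      probeset_size = 11)[c("start", "end")]),
               c(start = 900, end = 1400))
})

test_that("template selection enforces coverage and length preconditions", {
  tx <- random_seq(400, seed = 66)
  hits <- data.frame(probeset_id = "ps1", probe_index = 0:10,
                     transcript_id = "t1",
                     start = seq(10L, 310L, by = 30L),
                     end = seq(35L, 335L, by = 30L),
                     orientation = "sense")
  expect_error(select_template(c(t1 = tx), hits, probeset_size = 11),
               class = "anchorprobe_length_error")
  few <- hits[1:8, ]   # 8/11 probes < 80%
  expect_error(select_template(c(t1 = random_seq(2000, seed = 67)), few,
                               probeset_size = 11),
               class = "anchorprobe_coverage_error")
})

test_that("oversized probe spans fall back to the best 3'-most window", {
  tx <- random_seq(3000, seed = 68)
  starts <- as.integer(seq(500L, 2400L, length.out = 11L))
  hits <- data.frame(probeset_id = "ps1", probe_index = 0:10,
                     transcript_id = "t1", start = starts,
                     end = starts + 25L, orientation = "sense")
  tmpl <- select_template(c(t1 = tx), hits, probeset_size = 11)
  expect_equal(tmpl$end - tmpl$start, 800)
  # exhaustive scan: max covered probes, then 3'-most start
  best_n <- 0L; best_s <- 0L
  for (s in 0:(3000 - 800)) {
    n <- sum(hits$start >= s & hits$end <= s + 800)
    if (n > best_n || (n == best_n && s > best_s)) { best_n <- n; best_s <- s }
  }
  expect_equal(tmpl$start, best_s)
  expect_equal(tmpl$covered_probe_count, best_n)
})

test_that("probeset ranking prefers coverage then 3' span position", {
  maps <- data.frame(
    probeset_id = c("a", "b", "c"),
    transcript_id = "t1",
    n_probes_hit = c(9, 11, 11),
    probeset_size = 11,
    coverage_fraction = c(9 / 11, 1, 1),
    span_start = c(0, 100, 900),
    span_end = c(400, 2000, 2800))
  ranked <- rank_probesets(maps)
  expect_identical(ranked$probeset_id, c("c", "b", "a"))
  expect_identical(rank_probesets(maps[2, ])$probeset_id, "b")
})
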