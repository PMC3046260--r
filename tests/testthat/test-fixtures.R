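test_that("expression fixture is seed-deterministic down to the files", {
  f1 <- generate_expression_fixture(seed = 4)
  f2 <- generate_expression_fixture(seed = 4)
  expect_identical(f1$matrix, f2$matrix)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_expression_fixture(f1, d1)
  write_expression_fixture(f2, d2)
  for (f in c("matrix.tsv", "samples.tsv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # a different seed changes the data
  expect_false(identical(generate_expression_fixture(seed = 5)$matrix,
                         f1$matrix))
  # written files are readable by the I/O layer
  dat <- read_expression_data(file.path(d1, "matrix.tsv"),
                              file.path(d1, "samples.tsv"))
  expect_identical(dat$matrix, f1$matrix)
})

test_that("expression fixture honours its structural parameters", {
  fix <- generate_expression_fixture(n_compartments = 7, replicates = 4,
                                     n_background = 50,
                                     planted = data.frame(
                                       probeset_id = "a1",
                                       compartment = "UT", fold = 12),
                                     seed = 6)
  expect_identical(dim(fix$matrix), c(51L, 28L))
  expect_identical(length(unique(fix$samples$compartment)), 7L)
  expect_true(all(fix$matrix >= 0))
  expect_error(generate_expression_fixture(
    planted = data.frame(probeset_id = "x", compartment = "XX", fold = 5)),
    class = "anchorprobe_value_error")
})

test_that("planted-anchor recovery is monotone in effect size and noise", {
  recov <- function(fold, noise_sd) {
    planted <- data.frame(probeset_id = paste0("a", 1:5),
                          compartment = c("EPT", "UT", "MCD", "RV", "LoH"),
                          fold = fold)
    fix <- generate_expression_fixture(planted = planted, noise_sd = noise_sd,
                                       n_background = 50, seed = 8)
    sel <- select_candidates(fix$matrix, fix$samples)
    hits <- sum(vapply(seq_len(nrow(planted)), function(i)
      planted$probeset_id[i] %in%
        sel$candidates[[planted$compartment[i]]]$probeset_id, logical(1)))
    hits / nrow(planted)
  }
  expect_true(recov(20, 5) >= recov(3, 5))
  expect_true(recov(20, 5) >= recov(20, 40))
})

test_that("transcript fixture is deterministic and internally consistent", {
  t1 <- generate_transcript_fixture(seed = 10)
  t2 <- generate_transcript_fixture(seed = 10)
  expect_identical(as.character(t1$transcripts), as.character(t2$transcripts))
  expect_identical(t1$probes, t2$probes)
  expect_identical(nrow(t1$probes), 33L)

  # planted coordinates re-extract to the probe sequences
  seqs <- as.character(t1$transcripts)
  tr <- t1$truth$planted
  for (i in seq_len(nrow(tr))) {
    sub <- substr(seqs[[tr$transcript_id[i]]], tr$start[i] + 1, tr$end[i])
    probe <- t1$probes$sequence[t1$probes$probeset_id == tr$probeset_id[i] &
                                  t1$probes$probe_index == tr$probe_index[i]]
    expect_identical(probe, if (tr$orientation[i] == "sense") sub
                     else reverse_complement(sub))
  }

  dir <- withr::local_tempdir()
  write_transcript_fixture(t1, dir)
  back_ts <- read_transcripts(file.path(dir, "transcripts.fa"))
  expect_identical(as.character(back_ts), as.character(t1$transcripts))
  back_p <- read_probe_table(file.path(dir, "probes.tsv"))
  expect_identical(back_p, t1$probes)
})

test_that("partially planted probesets fail the coverage threshold", {
  tf <- generate_transcript_fixture(seed = 12)
  probes8 <- tf$probes[tf$probes$probeset_id == "ps01_at" &
                         tf$probes$probe_index < 8, ]
  hits <- map_probes(probes8, tf$transcripts)
  expect_equal(coverage_fraction(hits, 11), 8 / 11)
  expect_error(select_template(tf$transcripts, hits, probeset_size = 11),
               class = "anchorprobe_coverage_error")
})

test_that("the bundled anchor table matches its published structure", {
  t1 <- load_table1_fixture()
  expect_identical(nrow(t1), 37L)
  expect_identical(sum(t1$compartment == "EPT"), 25L)
  expect_identical(sort(unique(t1$compartment)),
                   c("EPT", "LoH", "MCD", "RC", "RV", "UT"))
  ace <- t1[t1$gene_symbol == "Ace", ]
  expect_equal(ace$raw, 916.2)
  expect_equal(ace$median_other, 74.5)
  expect_equal(ace$fold_change_printed, 12.3)
  expect_equal(round(ace$fold_change, 1), 12.3)
  # one probeset appears in exactly one compartment list
  expect_false(anyDuplicated(t1$probeset_id) > 0)
})
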