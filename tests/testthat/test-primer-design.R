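test_that("reverse complement is correct and involutive", {
  expect_identical(reverse_complement("ACGT"), "ACGT")
  expect_identical(reverse_complement("AAAA"), "TTTT")
  expect_identical(reverse_complement("ACGTN"), "NACGT")
  expect_error(reverse_complement("ACGU"), class = "anchorprobe_value_error")
  set.seed(12)
  for (i in 1:20) {
    x <- random_seq(sample(10:60, 1))
    expect_identical(reverse_complement(reverse_complement(x)), x)
    expect_identical(reverse_complement(x), oracle_revcomp(x))
  }
})

test_that("Wallace-rule Tm and GC content match hand evaluation", {
  half_gc <- paste0(strrep("GC", 5), strrep("AT", 5))  # 20-mer, 10 G/C
  expect_equal(melting_temperature(half_gc), 60)
  expect_equal(melting_temperature(strrep("AT", 10)), 40)
  # swapping one A for G raises Tm by exactly 2
  expect_equal(melting_temperature(paste0("G", substr(half_gc, 2, 20))) -
                 melting_temperature(paste0("A", substr(half_gc, 2, 20))), 2)
  expect_error(melting_temperature("ACGTACG"),
               class = "anchorprobe_value_error")

  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("ACGT"), 50)
  expect_error(gc_content(""), class = "anchorprobe_value_error")
})

test_that("design on a random region satisfies every constraint", {
  cns <- primer_constraints()
  set.seed(91)
  region <- random_seq(700)
  pair <- design_primers(region, cns)
  expect_true(pair$product_length >= 500 && pair$product_length <= 800)
  expect_true(pair$forward_tm >= cns$tm_min && pair$forward_tm <= cns$tm_max)
  expect_true(pair$reverse_tm >= cns$tm_min && pair$reverse_tm <= cns$tm_max)
  expect_true(pair$forward_gc >= cns$gc_min && pair$forward_gc <= cns$gc_max)
  expect_true(pair$reverse_gc >= cns$gc_min && pair$reverse_gc <= cns$gc_max)
  expect_false(grepl("A{5}|C{5}|G{5}|T{5}", pair$forward_seq))
  expect_false(grepl("A{5}|C{5}|G{5}|T{5}", pair$reverse_core_seq))
  expect_identical(pair$reverse_tagged_seq,
                   paste0(cns$t7_tag, pair$reverse_core_seq))
  # reverse core is the reverse complement of the template's product end
  expect_identical(pair$reverse_core_seq,
                   reverse_complement(substr(region,
                                             pair$product_end -
                                               nchar(pair$reverse_core_seq) + 1,
                                             pair$product_end)))
  expect_equal(pair$product_length, pair$product_end - pair$product_start)
  # determinism
  expect_identical(design_primers(region, cns), pair)
})

test_that("infeasible regions fail with a design-failure error", {
  expect_error(design_primers(random_seq(300, seed = 92)),
               class = "anchorprobe_design_failure_error")
  expect_error(design_primers(strrep("A", 600)),
               class = "anchorprobe_design_failure_error")
})

test_that("in-silico PCR round-trips a designed pair to one amplicon", {
  set.seed(93)
  tx <- random_seq(2500)
  region <- substr(tx, 1001, 1700)
  pair <- design_primers(region, offset = 1000L)
  amp <- insilico_pcr(pair, c(t1 = tx))
  expect_identical(nrow(amp), 1L)
  expect_equal(amp$length, pair$product_length)
  expect_equal(amp$start, pair$product_start)
  expect_equal(amp$end, pair$product_end)

  # a duplicated template is flagged by two amplicons
  amp2 <- insilico_pcr(pair, c(t1 = tx, t2 = tx))
  expect_identical(nrow(amp2), 2L)
  expect_identical(sort(unique(amp2$transcript_id)), c("t1", "t2"))
})

test_that("in-silico PCR agrees with exhaustive position-pair enumeration", {
  set.seed(94)
  base <- random_seq(600)
  fwd <- substr(base, 21, 40)
  rev_core <- reverse_complement(substr(base, 481, 500))
  seqs <- c(src = base)
  # transcripts with repeated primer sites, partial sites, reversed sites
  seqs[["dup"]] <- paste0(base, base)
  seqs[["fwd_only"]] <- paste0(random_seq(100), fwd, random_seq(100))
  seqs[["noise"]] <- random_seq(700)
  pair <- list(forward_seq = fwd, reverse_core_seq = rev_core)
  got <- insilico_pcr(pair, seqs, max_product = 4000)
  want <- oracle_ispcr(fwd, rev_core, seqs, max_product = 4000)
  expect_identical(got, want, ignore_attr = TRUE)
  # product cap honoured
  capped <- insilico_pcr(pair, seqs, max_product = 500)
  expect_true(all(capped$length <= 500))
  expect_identical(capped, oracle_ispcr(fwd, rev_core, seqs, 500),
                   ignore_attr = TRUE)
})

test_that("a pluggable Tm rule changes the scoring input deterministically", {
  set.seed(95)
  region <- random_seq(700)
  gc_based <- function(s) 64.9 + 41 * (gc_content(s) / 100 - 16.4 / nchar(s))
  pair <- design_primers(region, tm_fun = gc_based)
  expect_true(pair$product_length >= 500 && pair$product_length <= 800)
  expect_identical(design_primers(region, tm_fun = gc_based), pair)
})
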