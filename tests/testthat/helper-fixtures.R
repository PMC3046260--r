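# Small in-code fixture builders shared across test files.

# Write a matrix + sample table pair to temp TSVs; returns the two paths.
write_matrix_files <- function(m, samples,
                               dir = withr::local_tempdir(
                                 .local_envir = parent.frame())) {
  mp <- file.path(dir, "matrix.tsv")
  sp <- file.path(dir, "samples.tsv")
  df <- data.frame(probeset_id = rownames(m), m, check.names = FALSE)
  write.table(df, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(samples, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  list(matrix = mp, samples = sp)
}

tiny_matrix <- function() {
  m <- matrix(c(10, 20, 30, 40), nrow = 2, byrow = TRUE,
              dimnames = list(c("p1", "p2"), c("s1", "s2")))
  samples <- data.frame(sample_id = c("s1", "s2"),
                        compartment = c("A", "B"),
                        stringsAsFactors = FALSE)
  list(m = m, samples = samples)
}

# Profile with one quiet target column and a controllable other-median.
profile_with_median <- function(target_value, others) {
  m <- matrix(c(target_value, others), nrow = 1,
              dimnames = list("p1", c("A", paste0("o", seq_along(others)))))
  m
}

# A statistics row in the shape apply_filters() expects.
stats_row <- function(probeset_id = "p1", compartment = "A", raw = 500,
                      median_other = 50, q_bh = 1e-4) {
  data.frame(probeset_id = probeset_id, compartment = compartment,
             raw = raw, median_other = median_other,
             fold_change = anchorprobe::fold_change(raw, median_other),
             p_anova = q_bh, q_bh = q_bh, stringsAsFactors = FALSE)
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
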