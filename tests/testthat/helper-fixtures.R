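# small programmatic fixtures shared across test files

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

toy_count_table <- function() {
  write_lines_tmp(c(
    "gene\tTG-30-1\tTG-30-2\tTG-30-3\tTG-30-4",
    "g1\t10\t12\t9\t11",
    "g2\t0\t1\t0\t2",
    "g3\t100\t90\t110\t95",
    "__no_feature\t5\t7\t3\t4",
    "__ambiguous\t1\t0\t0\t2"))
}

toy_design_table <- function() {
  write_lines_tmp(c(
    "sample\tgroup",
    paste0("vehicle-", 1:4, "\tvehicle"),
    paste0("GTN-30-", 1:4, "\tGTN-30"),
    paste0("GTN-90-", 1:4, "\tGTN-90")))
}

toy_gmt <- function() {
  write_lines_tmp(c(
    "SetA\tdesc A\tg1\tg2\tg3",
    "SetB\tdesc B\tg2\tg4",
    "SetC\t\tg5\tg6\tg7\tg8"), ext = ".gmt")
}

random_count_matrix <- function(n_genes = 30, n_samples = 6, seed = 1,
                                lambda = 50) {
  set.seed(seed)
  counts <- matrix(rpois(n_genes * n_samples, lambda), n_genes, n_samples,
                   dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                   sprintf("s%02d", seq_len(n_samples))))
  count_matrix(counts)
}

random_expression_matrix <- function(n_genes = 10, n_samples = 6, seed = 1) {
  set.seed(seed)
  expression_matrix(
    matrix(rnorm(n_genes * n_samples, 5, 2), n_genes, n_samples,
           dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                           sprintf("s%02d", seq_len(n_samples)))),
    "test")
}

# per-gene one-way ANOVA F via the standard linear-model machinery;
# independent oracle for gene_f_statistics
oracle_f <- function(values, groups) {
  apply(values, 1, function(x) {
    stats::oneway.test(x ~ g, data.frame(x = x, g = groups),
                       var.equal = TRUE)$statistic
  })
}
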