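test_that("size factors follow the median-of-ratios construction", {
  # identical columns share the reference exactly
  cm <- count_matrix(matrix(c(3L, 7L, 3L, 7L), 2, 2,
                            dimnames = list(c("g1", "g2"), c("s1", "s2"))))
  expect_equal(unname(size_factors(cm)), c(1, 1))

  # hand computation: per-gene geometric means sqrt(8), sqrt(32);
  # every ratio in column 1 is 1/sqrt(2), in column 2 sqrt(2)
  cm2 <- count_matrix(matrix(c(2L, 4L, 4L, 8L), 2, 2,
                             dimnames = list(c("g1", "g2"), c("s1", "s2"))))
  expect_equal(unname(size_factors(cm2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
})

test_that("size factors are gene-order invariant and scale equivariant", {
  cm <- random_count_matrix(n_genes = 40, seed = 11)
  sf <- size_factors(cm)

  shuffled <- count_matrix(unclass(cm)[sample(nrow(cm)), ])
  expect_equal(size_factors(shuffled), sf)

  # scaling one library by c multiplies its factor relative to the others
  # by c (the absolute factors also shift through the geometric reference)
  scaled <- unclass(cm)
  scaled[, 3] <- scaled[, 3] * 4L
  sf2 <- size_factors(count_matrix(scaled))
  expect_equal(unname(sf2[3] / sf2[1]), unname(4 * sf[3] / sf[1]),
               tolerance = 1e-10)
})

test_that("size factors match the reference median-of-ratios implementation", {
  cm <- random_count_matrix(n_genes = 60, n_samples = 8, seed = 5)
  ref <- DESeq2::estimateSizeFactorsForMatrix(unclass(cm))
  expect_equal(unname(size_factors(cm)), unname(ref), tolerance = 1e-12)
})

test_that("no gene covering all samples is an explicit error", {
  counts <- matrix(c(0L, 5L, 3L, 0L), 2, 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(size_factors(count_matrix(counts)), "pseudo-reference")
})

test_that("the log transform normalizes, tags, and maps zeros to zero", {
  cm <- count_matrix(matrix(c(0L, 8L, 0L, 8L), 2, 2,
                            dimnames = list(c("g1", "g2"), c("s1", "s2"))))
  em <- vst_log(cm)  # identical columns, factors 1
  expect_s3_class(em, "expression_matrix")
  expect_match(attr(em, "transform_tag"), "log2")
  expect_equal(unname(em["g1", ]), c(0, 0))
  expect_equal(unname(em["g2", ]), c(log2(9), log2(9)))
  expect_true(all(em >= 0))

  expect_error(vst_log(cm, pseudocount = 0), "positive")
  expect_error(vst_log(cm, pseudocount = -1), "positive")
})

test_that("transform is monotone within a sample and stable under library scaling", {
  cm <- random_count_matrix(n_genes = 50, n_samples = 6, seed = 3)
  em <- vst_log(cm)
  for (j in seq_len(ncol(cm))) {
    expect_identical(order(em[, j]), order(unclass(cm)[, j]))
  }

  # doubling one library rescales all normalized counts by the common
  # geometric-reference factor 2^(1/n); sample-to-sample contrasts survive
  doubled <- unclass(cm)
  doubled[, 2] <- doubled[, 2] * 2L
  cm2 <- count_matrix(doubled)
  norm1 <- sweep(unclass(cm), 2, size_factors(cm), "/")
  norm2 <- sweep(unclass(cm2), 2, size_factors(cm2), "/")
  expect_equal(norm2, norm1 * 2^(1 / ncol(cm)), tolerance = 1e-10)
  # and the log-scale column moves by at most that common shift
  em2 <- vst_log(cm2)
  expect_lt(max(abs(em2[, 2] - em[, 2])), 1 / ncol(cm) + 0.01)
})

test_that("sample distances are Euclidean and match a brute-force oracle", {
  em <- expression_matrix(matrix(c(0, 0, 3, 4), 2, 2,
                                 dimnames = list(c("g1", "g2"),
                                                 c("s1", "s2"))), "test")
  d <- sample_distances(em)
  expect_equal(d["s1", "s2"], 5)
  expect_equal(diag(d), c(s1 = 0, s2 = 0))

  for (seed in 1:5) {
    em <- random_expression_matrix(10, 6, seed = seed)
    d <- sample_distances(em)
    brute <- matrix(0, 6, 6)
    for (i in 1:6) for (j in 1:6) {
      brute[i, j] <- sqrt(sum((em[, i] - em[, j])^2))
    }
    expect_equal(unname(d), brute, tolerance = 1e-12)
    expect_equal(d, t(d))
  }

  same <- expression_matrix(matrix(1, 3, 2,
                                   dimnames = list(paste0("g", 1:3),
                                                   c("a", "b"))), "test")
  expect_equal(sample_distances(same)["a", "b"], 0)
})

outlier_fixture <- function(seed = 9, displaced = "s05", shift = 40) {
  set.seed(seed)
  values <- matrix(rnorm(20 * 6, 5, 0.3), 20, 6,
                   dimnames = list(sprintf("g%02d", 1:20),
                                   sprintf("s%02d", 1:6)))
  values[, displaced] <- values[, displaced] + shift
  expression_matrix(values, "test")
}

test_that("a displaced sample is flagged and removal clears the report", {
  em <- outlier_fixture()
  report <- detect_outliers(sample_distances(em))
  expect_identical(report$flagged, "s05")
  expect_true(all(report$isolation >= 0))
  expect_match(report$dendrogram_newick, "s05")

  # no further outliers after exclusion
  rest <- sample_distances(em[, colnames(em) != "s05"])
  expect_length(detect_outliers(rest)$flagged, 0)
})

test_that("mutually equidistant samples produce no flags", {
  # 4 points of a regular simplex: all pairwise distances equal
  values <- diag(4) * 3
  dimnames(values) <- list(paste0("g", 1:4), paste0("s", 1:4))
  report <- detect_outliers(sample_distances(expression_matrix(values, "t")))
  expect_length(report$flagged, 0)
})

test_that("outlier detection is invariant to sample order", {
  em <- outlier_fixture(seed = 21)
  dm <- sample_distances(em)
  perm <- c(4, 2, 6, 1, 5, 3)
  report1 <- detect_outliers(dm)
  report2 <- detect_outliers(dm[perm, perm])
  expect_identical(sort(report1$flagged), sort(report2$flagged))
  expect_equal(report1$isolation[order(names(report1$isolation))],
               report2$isolation[order(names(report2$isolation))])
})

test_that("outlier report rejects bad multipliers and serializes to JSON", {
  dm <- sample_distances(outlier_fixture())
  expect_error(detect_outliers(dm, multiplier = 0), "positive")
  expect_error(detect_outliers(dm, multiplier = -2), "positive")

  json <- outlier_report_json(detect_outliers(dm))
  parsed <- jsonlite::fromJSON(json)
  expect_identical(parsed$flagged, "s05")
  expect_identical(parsed$linkage, "average")
})
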