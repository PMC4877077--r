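test_that("simulated counts are reproducible non-negative integers", {
  a <- simulate_counts(n_genes = 100, group_sizes = c(3, 3, 3), seed = 5)
  b <- simulate_counts(n_genes = 100, group_sizes = c(3, 3, 3), seed = 5)
  expect_identical(unclass(a$counts), unclass(b$counts))
  expect_true(all(a$counts >= 0))
  expect_identical(storage.mode(unclass(a$counts)), "integer")
  expect_identical(attr(a$design, "n_i"),
                   c(vehicle = 3L, `GTN-30` = 3L, `GTN-90` = 3L))

  c2 <- simulate_counts(n_genes = 100, group_sizes = c(3, 3, 3), seed = 6)
  expect_false(identical(unclass(a$counts), unclass(c2$counts)))
})

test_that("regenerating from the recorded truth seed reproduces the data", {
  sim <- simulate_dataset("spiked", seed = 17, n_genes = 300, n_sets = 10,
                          size_range = c(5, 15))
  again <- simulate_counts(n_genes = 300, group_sizes = c(4, 4, 4),
                           shifts = sim$truth$shifts, seed = sim$truth$seed)
  expect_identical(unclass(sim$counts), unclass(again$counts))
})

test_that("group-mean shifts act multiplicatively on the spiked group", {
  gene_ids <- sprintf("gene%05d", 1:2000)
  shifts <- matrix(0, 2000, 2, dimnames = list(gene_ids, c("a", "b")))
  shifts[1:500, "b"] <- 2  # 4-fold
  sim <- simulate_counts(n_genes = 2000, group_sizes = c(40, 40),
                         group_names = c("a", "b"),
                         base_mean_range = c(100, 100), dispersion = 0.05,
                         size_factor_range = c(1, 1), shifts = shifts,
                         seed = 3)
  counts <- unclass(sim$counts)
  in_b <- sim$design$group == "b"
  ratio_shifted <- mean(counts[1:500, in_b]) / mean(counts[1:500, !in_b])
  ratio_null <- mean(counts[501:2000, in_b]) / mean(counts[501:2000, !in_b])
  expect_equal(ratio_shifted, 4, tolerance = 0.1)
  expect_equal(ratio_null, 1, tolerance = 0.05)
})

test_that("dispersion controls the coefficient of variation", {
  base <- list(n_genes = 200, group_sizes = c(30, 30),
               group_names = c("a", "b"), base_mean_range = c(200, 200),
               size_factor_range = c(1, 1), seed = 8)
  cv <- function(dispersion) {
    counts <- unclass(do.call(simulate_counts,
                              c(base, dispersion = dispersion))$counts)
    mean(apply(counts, 1, sd) / rowMeans(counts))
  }
  expect_lt(cv(0.01), cv(0.5))
  # NB limit: var = mu + phi mu^2, cv ~ sqrt(1/mu + phi)
  expect_equal(cv(0.01), sqrt(1 / 200 + 0.01), tolerance = 0.1)
})

test_that("gene-set simulation records spike truth exactly", {
  universe <- sprintf("gene%05d", 1:500)
  gs <- simulate_gene_sets(universe, n_sets = 12, size_range = c(5, 20),
                           n_spiked = 2, spike_shift = 1.5,
                           group_names = c("a", "b", "c"),
                           spike_groups = "c", seed = 4)
  expect_length(gs$sets, 12)
  expect_identical(gs$spiked_sets, c("set001", "set002"))
  spiked_genes <- unique(unlist(gs$sets[gs$spiked_sets]))
  expect_true(all(gs$shifts[spiked_genes, "c"] == 1.5))
  other <- setdiff(universe, spiked_genes)
  expect_true(all(gs$shifts[other, ] == 0))
  expect_true(all(gs$shifts[, c("a", "b")] == 0))

  gs0 <- simulate_gene_sets(universe, n_sets = 5, size_range = c(5, 10),
                            n_spiked = 0, seed = 4)
  expect_true(all(gs0$shifts == 0))
  expect_length(gs0$spiked_sets, 0)
})

test_that("infeasible simulation parameters are rejected", {
  expect_error(simulate_counts(n_genes = 10, base_mean_range = c(10, 1),
                               seed = 1), "base_mean_range")
  expect_error(simulate_counts(n_genes = 10, size_factor_range = c(-1, 2),
                               seed = 1), "size_factor_range")
  expect_error(simulate_counts(n_genes = 10, dispersion = 0, seed = 1))
  expect_error(simulate_gene_sets(letters, size_range = c(5, 100), seed = 1),
               "universe")
  expect_error(simulate_gene_sets(letters, n_sets = 3, n_spiked = 4,
                                  size_range = c(2, 5), seed = 1))
})
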