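derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + i * 1000003) %% 2147483629L)
}

#' Permutation null distribution of standardized enrichment scores
#'
#' For each of `n_permutations` uniform shuffles of the group-label vector
#' (which preserves the group sizes), recomputes every gene's f-statistic and
#' every set's standardized enrichment score. Each permutation uses a seed
#' derived deterministically from `rng_seed` and the permutation index, so
#' results are reproducible and independent of how permutations might be
#' chunked across workers.
#'
#' @param em an [expression_matrix].
#' @param design a [sample_design].
#' @param sets a [gene_set_collection]; every set must have at least one
#'   member in the matrix's gene universe.
#' @param expressed logical per-gene vector passed to [gene_f_statistics()].
#' @param n_permutations number of label permutations (default 1000).
#' @param n_random_sets random sets per standardization (default 1000).
#' @param rng_seed integer seed.
#' @param reuse_random_sets if `TRUE`, the random gene-set memberships used
#'   for standardization are drawn once per target set and reused across
#'   permutations (their scores are still recomputed under each permuted
#'   statistic); if `FALSE` (default) they are redrawn in every permutation.
#' @param standardize_method `"sample"` (default) or `"exhaustive"`; the
#'   latter enumerates all subsets of each set's size and is only feasible
#'   on tiny gene universes.
#' @param f_cap cap for infinite F (see [gene_f_statistics()]).
#' @return numeric matrix, `n_permutations` x `length(sets)`, of
#'   standardized null scores with set names as column names.
#' @export
permutation_null <- function(em, design, sets, expressed = NULL,
                             n_permutations = 1000, n_random_sets = 1000,
                             rng_seed = 1, reuse_random_sets = FALSE,
                             standardize_method = c("sample", "exhaustive"),
                             f_cap = 1e12) {
  standardize_method <- match.arg(standardize_method)
  genes <- rownames(em)
  member_idx <- lapply(sets, function(m) {
    idx <- match(unique(m), genes)
    idx[!is.na(idx)]
  })
  if (any(lengths(member_idx) == 0)) {
    stop("set(s) with no member in the gene universe: ",
         paste(names(sets)[lengths(member_idx) == 0], collapse = ", "),
         call. = FALSE)
  }
  sizes <- lengths(member_idx)
  N <- length(genes)
  n <- nrow(design)

  reuse_idx <- NULL
  if (reuse_random_sets && standardize_method == "sample") {
    set.seed(derive_seed(rng_seed, 0))
    reuse_idx <- lapply(sizes, function(m)
      random_set_index_matrix(N, m, n_random_sets))
  }

  null_scores <- matrix(NA_real_, n_permutations, length(sets),
                        dimnames = list(NULL, names(sets)))
  for (b in seq_len(n_permutations)) {
    set.seed(derive_seed(rng_seed, b))
    perm_design <- sample_design(design$sample,
                                 design$group[sample.int(n)])
    f_b <- gene_f_statistics(em, perm_design, expressed, f_cap)$f
    for (s in seq_along(member_idx)) {
      raw_b <- mean(f_b[member_idx[[s]]])
      null_b <- if (standardize_method == "exhaustive") {
        random_set_scores(f_b, sizes[s], method = "exhaustive")
      } else if (reuse_random_sets) {
        null_scores_from_index(f_b, reuse_idx[[s]])
      } else {
        random_set_scores(f_b, sizes[s], n_random_sets)
      }
      null_scores[b, s] <- standardize_against(raw_b, null_b)
    }
  }
  null_scores
}

#' Nominal permutation p-value
#'
#' One-sided upper-tail p-value with the add-one correction,
#' `p = (1 + #\{null >= observed\}) / (B + 1)`, so that `p` is always in
#' `(0, 1]` and never exactly zero.
#'
#' @param observed observed standardized enrichment score.
#' @param null_scores numeric vector of permutation null scores.
#' @return p-value in `(0, 1]`.
#' @export
nominal_p <- function(observed, null_scores) {
  if (length(null_scores) == 0) stop("empty null distribution", call. = FALSE)
  (1 + sum(null_scores >= observed)) / (length(null_scores) + 1)
}

#' Pooled (global-null) permutation p-value
#'
#' Same add-one upper-tail formula as [nominal_p()], evaluated against the
#' permutation scores pooled across all gene sets. Pooling yields a common
#' global null, which is what the downstream q-value computation adjusts.
#'
#' @param observed observed standardized enrichment score.
#' @param pooled_null numeric vector of null scores pooled across sets.
#' @return p-value in `(0, 1]`.
#' @export
pooled_p <- function(observed, pooled_null) {
  if (length(pooled_null) == 0) stop("empty pooled null", call. = FALSE)
  (1 + sum(pooled_null >= observed)) / (length(pooled_null) + 1)
}
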