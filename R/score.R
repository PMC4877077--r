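#' Raw enrichment score of one gene set
#'
#' The mean f-statistic over the set's members that are present in the gene
#' universe of the statistics; members absent from the universe are ignored
#' in both the mean and the reported size.
#'
#' @param stats a `gene_level_stats` from [gene_f_statistics()].
#' @param members character vector of member gene identifiers.
#' @return list with `score` (mean f) and `size_in_universe`; `score` is
#'   `NA` with size 0 when no member is present.
#' @export
raw_set_score <- function(stats, members) {
  idx <- match(unique(members), stats$gene)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) {
    return(list(score = NA_real_, size_in_universe = 0L))
  }
  list(score = mean(stats$f[idx]), size_in_universe = length(idx))
}

#' Null scores of random gene sets of a given size
#'
#' Draws `n_random` gene sets of exactly `size` genes uniformly without
#' replacement from the universe and returns their mean-f scores, or
#' enumerates all `choose(N, size)` subsets when `method = "exhaustive"`.
#' Sampling falls back to complete enumeration whenever the subset space is
#' no larger than `n_random`, where enumeration is exact and cheaper.
#'
#' @param f numeric vector of per-gene f-statistics (the universe).
#' @param size set size to draw.
#' @param n_random number of random sets (ignored for exhaustive).
#' @param method `"sample"` (default) or `"exhaustive"`.
#' @return numeric vector of null scores.
#' @export
random_set_scores <- function(f, size, n_random = 1000,
                              method = c("sample", "exhaustive")) {
  method <- match.arg(method)
  N <- length(f)
  if (size < 1 || size > N) {
    stop("set size ", size, " outside universe of ", N, " genes",
         call. = FALSE)
  }
  # when the subset space is no larger than the requested number of draws,
  # complete enumeration is cheaper and exact, and the sampled estimator
  # converges to it; fall back automatically (exact-test practice)
  if (method == "exhaustive" || lchoose(N, size) <= log(n_random)) {
    if (size == N) return(mean(f))
    return(utils::combn(N, size, FUN = function(i) mean(f[i])))
  }
  idx <- random_set_index_matrix(N, size, n_random)
  null_scores_from_index(f, idx)
}

# size x n_random matrix of gene indices, one random set per column
random_set_index_matrix <- function(N, size, n_random) {
  vapply(seq_len(n_random), function(i) sample.int(N, size),
         integer(size))
}

# mean f per column of an index matrix (size x n_random)
null_scores_from_index <- function(f, idx) {
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1)
  .colMeans(f[idx], nrow(idx), ncol(idx))
}

#' Standardize a raw enrichment score against random gene sets
#'
#' Centers and scales the raw score by the mean and sample standard
#' deviation of the scores of random gene sets of identical size drawn from
#' the full gene universe (unexpressed genes included, with `f = 0`). A
#' degenerate null (standard deviation zero, e.g. constant f) yields a
#' standardized score of 0.
#'
#' @param raw raw mean-f score of the set.
#' @param size number of set members in the universe.
#' @param stats a `gene_level_stats`, or a numeric vector of f values.
#' @param n_random number of random sets (default 1000).
#' @param method `"sample"` or `"exhaustive"` (see [random_set_scores()]).
#' @return the standardized enrichment score.
#' @export
standardize_score <- function(raw, size, stats, n_random = 1000,
                              method = c("sample", "exhaustive")) {
  f <- if (is.data.frame(stats)) stats$f else as.numeric(stats)
  null_scores <- random_set_scores(f, size, n_random, method)
  standardize_against(raw, null_scores)
}

standardize_against <- function(raw, null_scores) {
  s <- stats::sd(null_scores)
  if (!is.finite(s) || s == 0) return(0)
  (raw - mean(null_scores)) / s
}
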