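#' Per-gene one-way ANOVA f-statistics
#'
#' For each gene, computes the one-way ANOVA F over the design's groups:
#' \deqn{f = \frac{n-k}{k-1} \cdot
#'   \frac{\sum_i n_i (\bar x_i - \bar x)^2}
#'        {\sum_i \sum_j (x_{ij} - \bar x_i)^2}}
#' where `k` is the number of groups, `n_i` and `x̄_i` the size and mean of
#' group `i`, and `n` and `x̄` the total sample count and grand mean. The
#' f-statistic of unexpressed genes is set to zero. Degenerate genes are
#' handled explicitly: zero between- and within-group variation gives
#' `f = 0`; positive between- with zero within-group variation gives the
#' finite cap `f_cap` so that set-level means and standard deviations stay
#' finite.
#'
#' @param em an [expression_matrix] (genes x samples).
#' @param design a [sample_design]; its samples must all be columns of `em`.
#' @param expressed logical per-gene vector; genes with `FALSE` get `f = 0`.
#'   Default: all genes treated as expressed.
#' @param f_cap finite value substituted for an infinite F (default 1e12).
#' @return a `gene_level_stats`: data frame with columns `gene`, `f`,
#'   `expressed`.
#' @export
gene_f_statistics <- function(em, design, expressed = NULL, f_cap = 1e12) {
  if (!all(design$sample %in% colnames(em))) {
    stop("design samples missing from expression matrix: ",
         paste(setdiff(design$sample, colnames(em)), collapse = ", "),
         call. = FALSE)
  }
  x <- unclass(em)[, design$sample, drop = FALSE]
  g <- factor(design$group, levels = unique(design$group))
  n <- ncol(x)
  k <- nlevels(g)
  if (n <= k) {
    stop("need more samples than groups (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  }
  if (is.null(expressed)) expressed <- rep(TRUE, nrow(x))
  if (length(expressed) != nrow(x)) {
    stop("`expressed` must have one entry per gene", call. = FALSE)
  }

  n_i <- tabulate(g, nbins = k)
  # group means via one matrix product; grand mean over all samples
  weights <- model_matrix_groups(g) # n x k, column i has 1/n_i in group i
  gm <- x %*% weights                         # genes x k
  grand <- rowMeans(x)
  between <- as.vector((gm - grand)^2 %*% n_i)
  within <- rowSums((x - gm[, as.integer(g), drop = FALSE])^2)

  # sums of squares below (1e-10 x rms value)^2 per sample are fp noise,
  # not variation: without this guard a gene that is constant within groups
  # can yield an arbitrary ratio of rounding errors
  tol <- n * 1e-20 * rowMeans(x^2)
  f <- ((n - k) / (k - 1)) * between / within
  f[within <= tol & between > tol] <- f_cap     # zero within, real between
  f[between <= tol] <- 0                        # no between-group variation
  f[!is.finite(f)] <- f_cap
  f[!expressed] <- 0
  f[f > f_cap] <- f_cap

  structure(data.frame(gene = rownames(x), f = f,
                       expressed = as.logical(expressed),
                       stringsAsFactors = FALSE),
            class = c("gene_level_stats", "data.frame"))
}

model_matrix_groups <- function(g) {
  k <- nlevels(g)
  n <- length(g)
  n_i <- tabulate(g, nbins = k)
  m <- matrix(0, n, k)
  m[cbind(seq_len(n), as.integer(g))] <- 1 / n_i[as.integer(g)]
  m
}

#' Default expressed-gene rule
#'
#' A gene is treated as expressed when its total raw count across all samples
#' meets `min_total`; the default (1) means genes with all-zero counts are
#' unexpressed and receive `f = 0`.
#'
#' @param cm a [count_matrix].
#' @param min_total minimum total count across samples (default 1).
#' @return logical vector, one entry per gene.
#' @export
expressed_genes <- function(cm, min_total = 1) {
  rowSums(unclass(cm)) >= min_total
}
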