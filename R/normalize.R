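#' Median-of-ratios library size factors
#'
#' The standard median-of-ratios normalization: per-gene geometric means form
#' a pseudo-reference sample; each sample's factor is the median across genes
#' (restricted to genes with a positive geometric mean, i.e. nonzero counts
#' in every sample) of the count / reference ratio.
#'
#' @param cm a [count_matrix].
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(cm) {
  counts <- unclass(cm)
  storage.mode(counts) <- "double"
  # geometric mean in log space; genes with any zero drop out via -Inf
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use)) {
    stop("no gene has nonzero counts in every sample; ",
         "consider a pseudo-reference fallback", call. = FALSE)
  }
  factors <- apply(counts[use, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - log_geo[use]))
  })
  stats::setNames(factors, colnames(cm))
}

#' Log-scale variance-stabilizing transform of counts
#'
#' Divides each sample's counts by its median-of-ratios size factor and takes
#' `log2(normalized count + pseudocount)`. This is a deliberately simple
#' homoscedastic expression estimate: the enrichment statistic only requires
#' per-gene expression values on a roughly variance-stabilized log scale, not
#' a specific shrinkage-based transform, and the tag records exactly what was
#' applied.
#'
#' @param cm a [count_matrix].
#' @param pseudocount positive real added before taking logs (default 1).
#' @return an [expression_matrix] with `transform_tag`
#'   `"log2(count/sizefactor + <pseudocount>)"`.
#' @export
vst_log <- function(cm, pseudocount = 1) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 ||
      !is.finite(pseudocount) || pseudocount <= 0) {
    stop("`pseudocount` must be a single positive number", call. = FALSE)
  }
  sf <- size_factors(cm)
  counts <- unclass(cm)
  storage.mode(counts) <- "double"
  values <- log2(sweep(counts, 2, sf, "/") + pseudocount)
  expression_matrix(values,
                    sprintf("log2(count/sizefactor + %g)", pseudocount))
}

#' Pairwise Euclidean distances between samples
#'
#' @param em an [expression_matrix] (or any numeric genes x samples matrix).
#' @return symmetric numeric matrix of distances with zero diagonal, sample
#'   ids as dimnames.
#' @export
sample_distances <- function(em) {
  if (ncol(em) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(!is.finite(em))) stop("expression values must be finite",
                                call. = FALSE)
  as.matrix(stats::dist(t(unclass(em)), method = "euclidean"))
}

#' Flag outlying samples from a distance matrix
#'
#' Builds an average-linkage dendrogram for manual review and flags sample
#' `s` when its nearest-neighbor distance exceeds `multiplier` times the
#' median nearest-neighbor distance over all samples. This turns the usual
#' look-at-the-dendrogram QC step into an explicit, reproducible rule while
#' still exporting the tree.
#'
#' @param dm symmetric distance matrix from [sample_distances()].
#' @param multiplier positive isolation threshold multiplier (default 2).
#' @return an `outlier_report`: list with `flagged` (character), `isolation`
#'   (named nearest-neighbor distances), `threshold`, `multiplier`,
#'   `linkage`, and `dendrogram_newick`.
#' @export
detect_outliers <- function(dm, multiplier = 2) {
  if (!is.numeric(multiplier) || length(multiplier) != 1 ||
      !is.finite(multiplier) || multiplier <= 0) {
    stop("`multiplier` must be a single positive number", call. = FALSE)
  }
  dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop("need at least 3 samples", call. = FALSE)
  ids <- rownames(dm)
  off <- dm
  diag(off) <- NA_real_
  isolation <- apply(off, 1, min, na.rm = TRUE)
  threshold <- multiplier * stats::median(isolation)
  flagged <- ids[isolation > threshold]

  hc <- stats::hclust(stats::as.dist(dm), method = "average")
  newick <- ape::write.tree(ape::as.phylo(hc))

  structure(list(flagged = flagged,
                 isolation = stats::setNames(isolation, ids),
                 threshold = threshold,
                 multiplier = multiplier,
                 linkage = "average",
                 dendrogram_newick = newick),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("outlier_report (average-linkage QC)\n")
  if (length(x$flagged) == 0) {
    cat("  no samples flagged\n")
  } else {
    cat("  flagged:",
        paste(sprintf("%s (nn = %.3g)", x$flagged, x$isolation[x$flagged]),
              collapse = ", "), "\n")
  }
  cat(sprintf("  threshold: nearest-neighbor distance > %.4g (%g x median)\n",
              x$threshold, x$multiplier))
  cat("  dendrogram:", x$dendrogram_newick, "\n")
  invisible(x)
}

#' Serialize an outlier report as JSON
#'
#' @param report an `outlier_report`.
#' @return a JSON string.
#' @export
outlier_report_json <- function(report) {
  jsonlite::toJSON(list(flagged = report$flagged,
                        isolation = as.list(report$isolation),
                        threshold = report$threshold,
                        multiplier = report$multiplier,
                        linkage = report$linkage,
                        dendrogram_newick = report$dendrogram_newick),
                   auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
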