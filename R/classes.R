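#' Construct a count matrix
#'
#' A `count_matrix` is an integer matrix of read counts with genes in rows and
#' samples in columns, as produced by merging per-sample htseq-count output.
#' Gene and sample identifiers must be unique and counts non-negative
#' integers; htseq-count bookkeeping rows (identifiers starting with `"__"`)
#' are not allowed inside a valid object.
#'
#' @param counts numeric matrix, genes x samples, with `dimnames` giving gene
#'   and sample identifiers.
#' @return an integer matrix of class `count_matrix`.
#' @export
count_matrix <- function(counts) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix", call. = FALSE)
  gene_ids <- rownames(counts)
  sample_ids <- colnames(counts)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("count matrix needs gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifiers", call. = FALSE)
  }
  if (any(startsWith(gene_ids, "__"))) {
    stop("'__'-prefixed summary rows must be removed before construction",
         call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != floor(counts))) {
    stop("counts must be finite non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  structure(counts, class = c("count_matrix", class(matrix())))
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n", nrow(x), ncol(x)))
  cat("samples:", paste(utils::head(colnames(x), 8), collapse = ", "),
      if (ncol(x) > 8) "..." else "", "\n")
  invisible(x)
}

#' Construct a sample design
#'
#' Maps each sample to exactly one group label, defining the `k >= 2` groups,
#' the per-group sizes `n_i`, and the total sample count `n` used by the
#' f-statistic.
#'
#' @param sample_ids character vector of unique sample identifiers (order is
#'   preserved).
#' @param groups character vector of group labels, one per sample.
#' @return a `sample_design` object: a data frame with columns `sample` and
#'   `group` plus attributes `k`, `n_i` (named integer vector) and `n`.
#' @export
sample_design <- function(sample_ids, groups) {
  sample_ids <- as.character(sample_ids)
  groups <- as.character(groups)
  if (length(sample_ids) != length(groups)) {
    stop("`sample_ids` and `groups` must have equal length", call. = FALSE)
  }
  if (length(sample_ids) == 0) stop("design is empty", call. = FALSE)
  if (anyDuplicated(sample_ids)) {
    stop("sample listed more than once: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(groups) || any(!nzchar(groups))) {
    stop("every sample needs a non-empty group label", call. = FALSE)
  }
  n_i <- table(factor(groups, levels = unique(groups)))
  if (length(n_i) < 2) {
    stop("need at least 2 groups, got ", length(n_i), call. = FALSE)
  }
  out <- data.frame(sample = sample_ids, group = groups,
                    stringsAsFactors = FALSE)
  structure(out,
            k = length(n_i),
            n_i = stats::setNames(as.integer(n_i), names(n_i)),
            n = length(sample_ids),
            class = c("sample_design", "data.frame"))
}

#' @export
print.sample_design <- function(x, ...) {
  n_i <- attr(x, "n_i")
  cat(sprintf("sample_design: n = %d samples in k = %d groups\n",
              attr(x, "n"), attr(x, "k")))
  cat(paste(sprintf("  %s: %d", names(n_i), n_i), collapse = "\n"), "\n")
  invisible(x)
}

#' Construct a gene set collection
#'
#' Named, non-empty sets of gene identifiers with optional free-text
#' descriptions, as read from a GMT file.
#'
#' @param sets named list of character vectors of member gene identifiers.
#' @param descriptions optional character vector of descriptions, one per set.
#' @return a `gene_set_collection`: the named list with a `descriptions`
#'   attribute.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("`sets` must be a named list", call. = FALSE)
  }
  if (anyDuplicated(names(sets))) {
    stop("duplicate set name: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "),
         call. = FALSE)
  }
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (any(lengths(sets) == 0)) stop("every set must be non-empty", call. = FALSE)
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  if (length(descriptions) != length(sets)) {
    stop("one description per set required", call. = FALSE)
  }
  structure(sets,
            descriptions = stats::setNames(as.character(descriptions),
                                           names(sets)),
            class = c("gene_set_collection", "list"))
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, sizes %d-%d\n",
              length(x), min(lengths(x)), max(lengths(x))))
  invisible(x)
}

#' @export
`[.gene_set_collection` <- function(x, i) {
  gene_set_collection(unclass(x)[i], attr(x, "descriptions")[i])
}

#' Construct an expression matrix
#'
#' Real-valued transformed expression values with the same shape and
#' identifiers as the source count matrix. `transform_tag` records the
#' provenance of the transform applied.
#'
#' @param values numeric genes x samples matrix with dimnames.
#' @param transform_tag character label describing the transform.
#' @return a numeric matrix of class `expression_matrix` with attribute
#'   `transform_tag`.
#' @export
expression_matrix <- function(values, transform_tag = "unspecified") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and sample colnames",
         call. = FALSE)
  }
  if (any(!is.finite(values))) stop("all values must be finite", call. = FALSE)
  structure(values, transform_tag = as.character(transform_tag)[1],
            class = c("expression_matrix", class(matrix())))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples [%s]\n",
              nrow(x), ncol(x), attr(x, "transform_tag")))
  invisible(x)
}
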