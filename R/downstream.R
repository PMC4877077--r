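#' Classify temporal response patterns from two log2 fold changes
#'
#' Assigns each gene a quadrant from the signs of its log2 fold changes at
#' two post-treatment time points (x = first, y = second):
#' \itemize{
#'   \item `(+, +)` quadrant I, `sustained_up`
#'   \item `(-, +)` quadrant II, `transient_down_up`
#'   \item `(-, -)` quadrant III, `sustained_down`
#'   \item `(+, -)` quadrant IV, `transient_up_down`
#' }
#' An exact zero in either coordinate lies on a quadrant boundary and is
#' reported as unclassified (`NA` quadrant) rather than silently assigned.
#'
#' @param lfc_t1 numeric vector, log2 fold change at the first time point.
#' @param lfc_t2 numeric vector, log2 fold change at the second time point.
#' @param gene_id optional gene identifiers.
#' @return data frame with columns `gene` (if given), `lfc_t1`, `lfc_t2`,
#'   `quadrant` (factor `I`-`IV`, `NA` on a boundary), `label`.
#' @export
classify_quadrant <- function(lfc_t1, lfc_t2, gene_id = NULL) {
  if (length(lfc_t1) != length(lfc_t2)) {
    stop("`lfc_t1` and `lfc_t2` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(lfc_t1)) || any(!is.finite(lfc_t2))) {
    stop("log fold changes must be finite", call. = FALSE)
  }
  quadrant <- rep(NA_character_, length(lfc_t1))
  quadrant[lfc_t1 > 0 & lfc_t2 > 0] <- "I"
  quadrant[lfc_t1 < 0 & lfc_t2 > 0] <- "II"
  quadrant[lfc_t1 < 0 & lfc_t2 < 0] <- "III"
  quadrant[lfc_t1 > 0 & lfc_t2 < 0] <- "IV"
  labels <- c(I = "sustained_up", II = "transient_down_up",
              III = "sustained_down", IV = "transient_up_down")
  label <- ifelse(is.na(quadrant), "unclassified", labels[quadrant])
  out <- data.frame(lfc_t1 = lfc_t1, lfc_t2 = lfc_t2,
                    quadrant = factor(quadrant, levels = c("I", "II", "III", "IV")),
                    label = label, stringsAsFactors = FALSE)
  if (!is.null(gene_id)) out <- cbind(gene = as.character(gene_id), out)
  out
}

#' qPCR relative copy number
#'
#' Converts a threshold cycle to a relative copy number using the primer
#' efficiency: `(1 + E/100)^(-Ct)`. `E` is in percent (100 = perfect
#' doubling per cycle); an efficiency of at most 1 triggers a warning since
#' it suggests the value was passed as a fraction rather than a percentage.
#'
#' @param E primer efficiency in percent, in `(0, 100]`.
#' @param Ct threshold cycle, non-negative.
#' @return relative copy number, vectorized over inputs.
#' @export
qpcr_relative_copy_number <- function(E, Ct) {
  if (any(!is.finite(E)) || any(E <= 0) || any(E > 100)) {
    stop("primer efficiency E must be in (0, 100] percent", call. = FALSE)
  }
  if (any(E <= 1)) {
    warning("E <= 1: efficiencies are expected in percent ",
            "(e.g. 90, not 0.9)", call. = FALSE)
  }
  if (any(!is.finite(Ct)) || any(Ct < 0)) {
    stop("Ct must be a non-negative threshold cycle", call. = FALSE)
  }
  (1 + E / 100)^(-Ct)
}

#' Normalize a target gene's copy number to a reference gene
#'
#' Standard reference-gene normalization (e.g. to a housekeeping gene such
#' as Hprt1): the target relative copy number divided by the reference's.
#'
#' @param target relative copy number of the target gene.
#' @param reference relative copy number of the reference gene (> 0).
#' @return normalized expression ratio.
#' @export
normalize_to_reference <- function(target, reference) {
  if (any(!is.finite(reference)) || any(reference <= 0)) {
    stop("reference copy number must be positive", call. = FALSE)
  }
  target / reference
}
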