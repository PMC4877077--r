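#' Parameters for a GSANOVA run
#'
#' @param n_random_sets random gene sets per standardization (default 1000).
#' @param n_permutations group-label permutations (default 1000).
#' @param q_cutoff q-value threshold for calling a set enriched (default
#'   0.25).
#' @param rng_seed integer seed controlling every source of randomness.
#' @param pi0_method pi0 estimator for [qvalues()]: `"fixed_one"` or
#'   `"storey_smoother"`.
#' @param min_set_size,max_set_size optional filters on set size in the gene
#'   universe (default: no filtering).
#' @param reuse_random_sets reuse standardization set memberships across
#'   permutations for speed (see [permutation_null()]; default `FALSE`).
#' @param f_cap finite substitute for an infinite F (default 1e12).
#' @param min_total_count expressed-gene rule: minimum total raw count
#'   (default 1, i.e. only all-zero genes are unexpressed).
#' @param pseudocount pseudocount for [vst_log()] (default 1).
#' @return a `gsanova_params` list.
#' @export
gsanova_params <- function(n_random_sets = 1000, n_permutations = 1000,
                           q_cutoff = 0.25, rng_seed = 1,
                           pi0_method = c("fixed_one", "storey_smoother"),
                           min_set_size = NULL, max_set_size = NULL,
                           reuse_random_sets = FALSE, f_cap = 1e12,
                           min_total_count = 1, pseudocount = 1) {
  pi0_method <- match.arg(pi0_method)
  stopifnot(n_random_sets >= 1, n_permutations >= 1,
            q_cutoff > 0, q_cutoff <= 1, f_cap > 0)
  structure(list(n_random_sets = as.integer(n_random_sets),
                 n_permutations = as.integer(n_permutations),
                 q_cutoff = q_cutoff,
                 rng_seed = as.integer(rng_seed),
                 pi0_method = pi0_method,
                 min_set_size = min_set_size,
                 max_set_size = max_set_size,
                 reuse_random_sets = isTRUE(reuse_random_sets),
                 f_cap = f_cap,
                 min_total_count = min_total_count,
                 pseudocount = pseudocount),
            class = "gsanova_params")
}

#' Run the full GSANOVA pipeline
#'
#' Transforms counts to log-scale expression estimates, computes per-gene
#' one-way ANOVA f-statistics across the design's groups, scores each gene
#' set by its mean f, standardizes against random sets of identical size,
#' builds a permutation null of standardized scores, and reports nominal
#' (per-set) and pooled (global-null) p-values, q-values computed from the
#' pooled p-values, and a significance call at `q < q_cutoff`.
#'
#' @param cm a [count_matrix].
#' @param design a [sample_design].
#' @param sets a [gene_set_collection]. Sets with no member in the gene
#'   universe (or outside the size filters) are skipped with a warning and
#'   recorded in the result's `skipped` element.
#' @param params a [gsanova_params].
#' @return a `gsanova_result`: list with `table` (one row per tested set,
#'   sorted by q-value then pooled p), `skipped` (named character vector of
#'   skip reasons), `params`, `null_scores` (permutations x sets), and
#'   `stats` (the observed `gene_level_stats`).
#' @export
run_gsanova <- function(cm, design, sets, params = gsanova_params()) {
  stopifnot(inherits(params, "gsanova_params"))
  if (!all(design$sample %in% colnames(cm))) {
    stop("design samples missing from count matrix: ",
         paste(setdiff(design$sample, colnames(cm)), collapse = ", "),
         call. = FALSE)
  }

  em <- vst_log(cm, params$pseudocount)
  expressed <- expressed_genes(cm, params$min_total_count)
  stats_obs <- gene_f_statistics(em, design, expressed, params$f_cap)

  sizes <- vapply(sets, function(m)
    raw_set_score(stats_obs, m)$size_in_universe, integer(1))
  skipped <- character(0)
  skip <- sizes == 0
  if (!is.null(params$min_set_size)) {
    skip <- skip | (sizes > 0 & sizes < params$min_set_size)
  }
  if (!is.null(params$max_set_size)) {
    skip <- skip | sizes > params$max_set_size
  }
  if (any(skip)) {
    reasons <- ifelse(sizes[skip] == 0, "no members in gene universe",
                      sprintf("size %d outside [%s, %s]", sizes[skip],
                              params$min_set_size %||% 1,
                              params$max_set_size %||% "Inf"))
    skipped <- stats::setNames(reasons, names(sets)[skip])
    warning("skipping ", sum(skip), " gene set(s): ",
            paste(names(sets)[skip], collapse = ", "), call. = FALSE)
  }
  kept <- sets[!skip]
  if (length(kept) == 0) {
    stop("no gene set survives filtering", call. = FALSE)
  }

  # observed raw and standardized scores
  set.seed(derive_seed(params$rng_seed, -1))
  raw <- numeric(length(kept))
  z <- numeric(length(kept))
  for (s in seq_along(kept)) {
    rs <- raw_set_score(stats_obs, kept[[s]])
    raw[s] <- rs$score
    z[s] <- standardize_score(rs$score, rs$size_in_universe, stats_obs,
                              params$n_random_sets)
  }

  null_scores <- permutation_null(
    em, design, kept, expressed,
    n_permutations = params$n_permutations,
    n_random_sets = params$n_random_sets,
    rng_seed = params$rng_seed,
    reuse_random_sets = params$reuse_random_sets,
    f_cap = params$f_cap)

  p_nom <- vapply(seq_along(kept),
                  function(s) nominal_p(z[s], null_scores[, s]), numeric(1))
  pooled <- as.vector(null_scores)
  p_pool <- vapply(z, function(zi) pooled_p(zi, pooled), numeric(1))
  q <- qvalues(p_pool, params$pi0_method)

  tab <- data.frame(set_name = names(kept),
                    set_size = sizes[!skip],
                    raw_score = raw,
                    standardized_score = z,
                    p_nominal = p_nom,
                    p_pooled = p_pool,
                    q_value = q,
                    significant = q < params$q_cutoff,
                    stringsAsFactors = FALSE, row.names = NULL)
  tab <- tab[order(tab$q_value, tab$p_pooled), ]
  rownames(tab) <- NULL

  structure(list(table = tab, skipped = skipped, params = params,
                 null_scores = null_scores, stats = stats_obs),
            class = "gsanova_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gsanova_result <- function(x, ...) {
  cat(sprintf("gsanova_result: %d sets tested, %d significant at q < %g\n",
              nrow(x$table), sum(x$table$significant),
              x$params$q_cutoff))
  if (length(x$skipped)) cat("  skipped:", length(x$skipped), "set(s)\n")
  print(utils::head(x$table, 10))
  invisible(x)
}
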