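#' Simulate a negative-binomial count matrix
#'
#' Draws `count_gj ~ NB(mean = s_j * mu_g * 2^shift[g, group(j)],
#' dispersion)` with per-gene base means log-uniform on `base_mean_range`
#' and per-sample library-size factors uniform on `size_factor_range`. The
#' default design emulates a small-n three-group treatment time course
#' (vehicle / 30 min / 90 min, 4 animals per group).
#'
#' @param n_genes number of genes (default 12000).
#' @param group_sizes integer vector of samples per group (default
#'   `c(4, 4, 4)`).
#' @param group_names group labels (default vehicle / GTN-30 / GTN-90).
#' @param base_mean_range positive range for log-uniform per-gene base means
#'   (default `c(1, 1000)`).
#' @param dispersion common NB dispersion; variance is
#'   `mu + dispersion * mu^2` (default 0.1).
#' @param size_factor_range range for uniform per-sample size factors
#'   (default `c(0.7, 1.4)`).
#' @param shifts optional `n_genes x k` matrix of log2 group-mean shifts
#'   (rownames = gene ids, colnames = group names); default all zero.
#' @param seed integer seed.
#' @return list with `counts` ([count_matrix]), `design`
#'   ([sample_design]), and `truth` (base means, shifts, dispersion, size
#'   factors, seed).
#' @export
simulate_counts <- function(n_genes = 12000, group_sizes = c(4, 4, 4),
                            group_names = c("vehicle", "GTN-30", "GTN-90"),
                            base_mean_range = c(1, 1000), dispersion = 0.1,
                            size_factor_range = c(0.7, 1.4), shifts = NULL,
                            seed = 1) {
  stopifnot(n_genes >= 1, all(group_sizes >= 1),
            length(group_names) == length(group_sizes),
            dispersion > 0)
  if (length(base_mean_range) != 2 || any(base_mean_range <= 0) ||
      base_mean_range[1] > base_mean_range[2]) {
    stop("invalid `base_mean_range`", call. = FALSE)
  }
  if (length(size_factor_range) != 2 || any(size_factor_range <= 0) ||
      size_factor_range[1] > size_factor_range[2]) {
    stop("invalid `size_factor_range`", call. = FALSE)
  }
  k <- length(group_sizes)
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  if (is.null(shifts)) {
    shifts <- matrix(0, n_genes, k, dimnames = list(gene_ids, group_names))
  }
  stopifnot(nrow(shifts) == n_genes, ncol(shifts) == k)

  group_of <- rep(group_names, group_sizes)
  sample_ids <- unlist(lapply(seq_len(k), function(i)
    paste0(group_names[i], "-", seq_len(group_sizes[i]))))
  n <- length(sample_ids)

  set.seed(seed)
  base_mean <- exp(stats::runif(n_genes, log(base_mean_range[1]),
                                log(base_mean_range[2])))
  sf <- stats::runif(n, size_factor_range[1], size_factor_range[2])
  group_idx <- match(group_of, group_names)
  mu <- outer(base_mean, sf) * 2^shifts[, group_idx, drop = FALSE]
  counts <- matrix(stats::rnbinom(n_genes * n, mu = mu, size = 1 / dispersion),
                   n_genes, n, dimnames = list(gene_ids, sample_ids))

  list(counts = count_matrix(counts),
       design = sample_design(sample_ids, group_of),
       truth = list(base_means = stats::setNames(base_mean, gene_ids),
                    shifts = shifts,
                    dispersion = dispersion,
                    size_factors = stats::setNames(sf, sample_ids),
                    seed = seed))
}

#' Simulate a gene-set collection with optional spiked sets
#'
#' Draws `n_sets` gene sets (membership sampled uniformly without
#' replacement from the universe; overlap between sets is allowed) with
#' sizes uniform on `size_range`. The first `n_spiked` sets are "spiked":
#' their member genes are assigned a log2 group-mean shift of `spike_shift`
#' in the `spike_groups` columns of the returned truth matrix, ready to be
#' passed to [simulate_counts()].
#'
#' @param universe character vector of gene identifiers.
#' @param n_sets number of sets (default 200).
#' @param size_range inclusive range of set sizes (default `c(10, 60)`).
#' @param n_spiked number of spiked sets (default 0).
#' @param spike_shift log2 shift given to spiked members (default 1).
#' @param group_names group labels for the shift matrix.
#' @param spike_groups group(s) receiving the shift (default: the last
#'   group, mimicking a late-time-point response).
#' @param spike_size optional exact size for the spiked sets.
#' @param seed integer seed.
#' @return list with `sets` ([gene_set_collection]), `shifts`
#'   (universe x groups log2 matrix), `spiked_sets` (names), `seed`.
#' @export
simulate_gene_sets <- function(universe, n_sets = 200, size_range = c(10, 60),
                               n_spiked = 0, spike_shift = 1,
                               group_names = c("vehicle", "GTN-30", "GTN-90"),
                               spike_groups = utils::tail(group_names, 1),
                               spike_size = NULL, seed = 1) {
  N <- length(universe)
  stopifnot(n_sets >= 1, n_spiked >= 0, n_spiked <= n_sets)
  if (length(size_range) != 2 || size_range[1] < 1 ||
      size_range[1] > size_range[2] || size_range[2] > N) {
    stop("`size_range` must lie within the universe size", call. = FALSE)
  }
  if (!is.null(spike_size) && (spike_size < 1 || spike_size > N)) {
    stop("`spike_size` outside the universe size", call. = FALSE)
  }
  stopifnot(all(spike_groups %in% group_names))

  set.seed(seed)
  sizes <- sample(seq(size_range[1], size_range[2]), n_sets, replace = TRUE)
  spiked_idx <- seq_len(n_spiked)
  if (!is.null(spike_size)) sizes[spiked_idx] <- spike_size
  members <- lapply(sizes, function(m) sample(universe, m))
  set_names <- sprintf("set%03d", seq_len(n_sets))
  names(members) <- set_names

  shifts <- matrix(0, N, length(group_names),
                   dimnames = list(universe, group_names))
  for (s in spiked_idx) {
    shifts[members[[s]], spike_groups] <- spike_shift
  }
  desc <- ifelse(seq_len(n_sets) %in% spiked_idx, "spiked", "null")

  list(sets = gene_set_collection(members, desc),
       shifts = shifts,
       spiked_sets = set_names[spiked_idx],
       seed = seed)
}

#' Simulate a complete dataset with known truth
#'
#' Convenience wrapper tying [simulate_gene_sets()] and [simulate_counts()]
#' together. Preset `"null"` has no group-mean shifts anywhere; preset
#' `"spiked"` gives one gene set of `spike_size` members a `spike_shift`
#' log2 shift in the last group.
#'
#' @param preset `"null"` or `"spiked"`.
#' @param seed integer seed (sub-seeds for sets and counts are derived from
#'   it).
#' @param n_genes,group_sizes,n_sets,size_range,dispersion see
#'   [simulate_counts()] and [simulate_gene_sets()].
#' @param spike_shift,spike_size spiked-set parameters (defaults 1.0 log2
#'   units, 30 genes).
#' @return list with `counts`, `design`, `sets`, `truth` (including
#'   `spiked_sets`).
#' @export
simulate_dataset <- function(preset = c("null", "spiked"), seed = 1,
                             n_genes = 12000, group_sizes = c(4, 4, 4),
                             n_sets = 200, size_range = c(10, 60),
                             dispersion = 0.1, spike_shift = 1,
                             spike_size = 30) {
  preset <- match.arg(preset)
  group_names <- c("vehicle", "GTN-30", "GTN-90")[seq_along(group_sizes)]
  if (length(group_sizes) > 3) {
    group_names <- c(group_names, paste0("group", seq(4, length(group_sizes))))
  }
  universe <- sprintf("gene%05d", seq_len(n_genes))
  gs <- simulate_gene_sets(universe, n_sets = n_sets, size_range = size_range,
                           n_spiked = if (preset == "spiked") 1 else 0,
                           spike_shift = spike_shift,
                           group_names = group_names,
                           spike_size = spike_size,
                           seed = derive_seed(seed, 101))
  sim <- simulate_counts(n_genes = n_genes, group_sizes = group_sizes,
                         group_names = group_names, dispersion = dispersion,
                         shifts = gs$shifts, seed = derive_seed(seed, 102))
  truth <- c(sim$truth, list(spiked_sets = gs$spiked_sets,
                             preset = preset, master_seed = seed))
  list(counts = sim$counts, design = sim$design, sets = gs$sets,
       truth = truth)
}
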