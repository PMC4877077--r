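split_tsv_lines <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- nzchar(lines)
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE),
       lineno = which(keep))
}

#' Read a merged htseq-count-style count table
#'
#' Reads a tab-separated table with one row per gene: first column the gene
#' identifier, remaining columns integer read counts, and a header row of
#' sample names (with or without a leading gene-id column name).
#' htseq-count bookkeeping rows (`__no_feature`, `__ambiguous`, ...) are
#' dropped with a message; the order of the remaining genes is preserved.
#'
#' @param path path to the TSV file.
#' @return a [count_matrix].
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  parsed <- split_tsv_lines(path)
  fields <- parsed$fields
  lineno <- parsed$lineno
  if (length(fields) < 2) stop("count table has no data rows", call. = FALSE)

  header <- fields[[1]]
  body <- fields[-1]
  body_lineno <- lineno[-1]
  width <- lengths(body)
  if (length(unique(width)) != 1) {
    bad <- body_lineno[which(width != width[1])[1]]
    stop("malformed line ", bad, ": inconsistent number of columns",
         call. = FALSE)
  }
  ncol_body <- width[1]
  if (ncol_body < 2) {
    stop("malformed line ", body_lineno[1],
         ": need a gene id plus at least one count column", call. = FALSE)
  }
  sample_ids <- if (length(header) == ncol_body) header[-1]
                else if (length(header) == ncol_body - 1) header
                else stop("malformed line ", lineno[1],
                          ": header width does not match data rows",
                          call. = FALSE)

  gene_ids <- vapply(body, `[`, character(1), 1L)
  count_fields <- lapply(body, `[`, -1L)
  ok <- vapply(count_fields,
               function(f) all(grepl("^[0-9]+$", f)), logical(1))
  if (!all(ok)) {
    bad <- body_lineno[which(!ok)[1]]
    stop("malformed line ", bad,
         ": count fields must be non-negative integers", call. = FALSE)
  }
  counts <- do.call(rbind, lapply(count_fields, as.numeric))
  rownames(counts) <- gene_ids
  colnames(counts) <- sample_ids

  summary_rows <- startsWith(gene_ids, "__")
  if (any(summary_rows)) {
    message("dropped ", sum(summary_rows), " '__'-prefixed summary row(s): ",
            paste(gene_ids[summary_rows], collapse = ", "))
    counts <- counts[!summary_rows, , drop = FALSE]
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- unique(rownames(counts)[duplicated(rownames(counts))])
    stop("duplicate gene id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  count_matrix(counts)
}

#' Write a count matrix as a merged TSV table
#'
#' Inverse of [read_count_table()]: first column `gene`, then one column per
#' sample.
#'
#' @param cm a [count_matrix].
#' @param path output path.
#' @export
write_count_table <- function(cm, path) {
  df <- data.frame(gene = rownames(cm), cm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge per-sample htseq-count files into one count matrix
#'
#' Each input is a two-column, headerless TSV (gene id, count) as written by
#' htseq-count for a single sample. All files must cover exactly the same
#' genes; rows are joined on gene id using the first file's order.
#'
#' @param paths character vector of per-sample file paths.
#' @param sample_ids sample names, one per file (default: file base names
#'   without extension).
#' @return a [count_matrix].
#' @export
merge_count_files <- function(paths,
                              sample_ids = tools::file_path_sans_ext(basename(paths))) {
  if (length(paths) < 1) stop("no input files", call. = FALSE)
  if (length(sample_ids) != length(paths)) {
    stop("one sample id per file required", call. = FALSE)
  }
  read_one <- function(path) {
    parsed <- split_tsv_lines(path)
    width <- lengths(parsed$fields)
    if (any(width != 2)) {
      stop("malformed line ", parsed$lineno[which(width != 2)[1]], " in ",
           path, ": expected 2 tab-separated fields", call. = FALSE)
    }
    genes <- vapply(parsed$fields, `[`, character(1), 1L)
    vals <- vapply(parsed$fields, `[`, character(1), 2L)
    if (!all(grepl("^[0-9]+$", vals))) {
      stop("malformed line ",
           parsed$lineno[which(!grepl("^[0-9]+$", vals))[1]], " in ", path,
           ": count fields must be non-negative integers", call. = FALSE)
    }
    stats::setNames(as.numeric(vals), genes)
  }
  cols <- lapply(paths, read_one)
  genes <- names(cols[[1]])
  for (i in seq_along(cols)[-1]) {
    if (!identical(sort(names(cols[[i]])), sort(genes))) {
      stop("gene universe of ", paths[i], " does not match ", paths[1],
           call. = FALSE)
    }
  }
  counts <- vapply(cols, function(col) col[genes], numeric(length(genes)))
  dimnames(counts) <- list(genes, sample_ids)
  summary_rows <- startsWith(genes, "__")
  if (any(summary_rows)) {
    message("dropped ", sum(summary_rows), " '__'-prefixed summary row(s): ",
            paste(genes[summary_rows], collapse = ", "))
    counts <- counts[!summary_rows, , drop = FALSE]
  }
  count_matrix(counts)
}

#' Read a sample design table
#'
#' Two-column TSV (`sample`, `group`) with a header row, mapping each sample
#' to its group label. Samples may be excluded (e.g. QC outliers) via
#' `exclude`.
#'
#' @param path path to the TSV file.
#' @param exclude character vector of sample ids to drop after reading.
#' @return a [sample_design].
#' @export
read_design <- function(path, exclude = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  parsed <- split_tsv_lines(path)
  fields <- parsed$fields
  if (length(fields) < 2) stop("design file has no data rows", call. = FALSE)
  width <- lengths(fields)
  if (any(width != 2)) {
    stop("malformed line ", parsed$lineno[which(width != 2)[1]],
         ": expected 2 tab-separated fields", call. = FALSE)
  }
  body <- fields[-1]
  samples <- vapply(body, `[`, character(1), 1L)
  groups <- vapply(body, `[`, character(1), 2L)
  keep <- !(samples %in% exclude)
  sample_design(samples[keep], groups[keep])
}

#' Write a sample design table
#'
#' @param design a [sample_design].
#' @param path output path.
#' @export
write_design <- function(design, path) {
  utils::write.table(data.frame(sample = design$sample, group = design$group),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Broad-dialect GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`, at least one member per
#' set. Duplicate members within a line are dropped with a warning.
#'
#' @param path path to the GMT file.
#' @return a [gene_set_collection] preserving file order.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  parsed <- split_tsv_lines(path)
  fields <- parsed$fields
  if (length(fields) == 0) stop("empty GMT file", call. = FALSE)
  width <- lengths(fields)
  if (any(width < 3)) {
    stop("malformed line ", parsed$lineno[which(width < 3)[1]],
         ": GMT lines need name, description and at least one member",
         call. = FALSE)
  }
  names_ <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(names_)) {
    stop("duplicate set name: ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "),
         call. = FALSE)
  }
  descriptions <- vapply(fields, `[`, character(1), 2L)
  members <- lapply(fields, `[`, -(1:2))
  n_dup <- vapply(members, function(m) sum(duplicated(m)), integer(1))
  if (any(n_dup > 0)) {
    warning("dropped duplicate members within set(s): ",
            paste(names_[n_dup > 0], collapse = ", "), call. = FALSE)
    members <- lapply(members, unique)
  }
  gene_set_collection(stats::setNames(members, names_), descriptions)
}

#' Write gene sets in GMT format
#'
#' @param sets a [gene_set_collection].
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[[i]], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write an enrichment result table
#'
#' Tab-separated with columns `set_name`, `set_size`, `raw_score`,
#' `standardized_score`, `p_nominal`, `p_pooled`, `q_value`, `significant`,
#' sorted ascending by q-value then pooled p-value.
#'
#' @param results a `gsanova_result` (see [run_gsanova()]) or its table.
#' @param path output path.
#' @export
write_enrichment_table <- function(results, path) {
  tab <- if (inherits(results, "gsanova_result")) results$table else results
  if (!is.data.frame(tab) || nrow(tab) == 0) {
    stop("results are empty", call. = FALSE)
  }
  cols <- c("set_name", "set_size", "raw_score", "standardized_score",
            "p_nominal", "p_pooled", "q_value", "significant")
  if (!all(cols %in% names(tab))) {
    stop("results table is missing columns: ",
         paste(setdiff(cols, names(tab)), collapse = ", "), call. = FALSE)
  }
  tab <- tab[order(tab$q_value, tab$p_pooled), cols]
  ok <- tryCatch({
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok),
                        call. = FALSE)
  invisible(path)
}
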