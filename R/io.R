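#' Read and write the pipeline's plain-text formats
#'
#' Counts are TSV with the miRNA id in the first column and one column per
#' sample; sample metadata is a two-column TSV (`sample_id`, `condition`);
#' mature lengths a two-column TSV (`mirna_id`, `length_nt`); target tables a
#' three-column TSV (`mirna_id`, `gene_id`, `score`) in the miRDB flat-file
#' convention; gene sets use GMT (name, description, then one gene per
#' field).
#'
#' @param counts_file,samples_file,lengths_file paths to the three count
#'   TSVs.
#' @return `read_count_matrix` returns a [count_matrix].
#' @name mircross_io
NULL

#' @rdname mircross_io
#' @export
read_count_matrix <- function(counts_file, samples_file, lengths_file) {
  cts <- utils::read.delim(counts_file, check.names = FALSE)
  mat <- as.matrix(cts[, -1, drop = FALSE])
  storage.mode(mat) <- "integer"
  rownames(mat) <- cts[[1]]
  smp <- utils::read.delim(samples_file)
  if (!all(colnames(mat) %in% smp$sample_id))
    stop("samples file missing entries for: ",
         paste(setdiff(colnames(mat), smp$sample_id), collapse = ", "))
  cond <- smp$condition[match(colnames(mat), smp$sample_id)]
  len <- utils::read.delim(lengths_file)
  if (!all(rownames(mat) %in% len$mirna_id))
    stop("lengths file missing entries for some miRNAs")
  count_matrix(mat, cond, len$length_nt[match(rownames(mat), len$mirna_id)])
}

#' @rdname mircross_io
#' @param cm a [count_matrix]; `dir` an output directory.
#' @param dir output directory (created if needed).
#' @export
write_count_matrix <- function(cm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(mirna_id = rownames(cm$counts), cm$counts,
               check.names = FALSE),
    file.path(dir, "counts.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = colnames(cm$counts),
               condition = as.character(cm$condition)),
    file.path(dir, "samples.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(mirna_id = rownames(cm$counts), length_nt = cm$lengths),
    file.path(dir, "lengths.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}

#' @rdname mircross_io
#' @param file path to a targets TSV (`mirna_id`, `gene_id`, `score`).
#' @param score_bounds admissible score range, miRDB convention `[50, 100]`.
#' @export
read_target_table <- function(file, score_bounds = c(50, 100)) {
  tt <- utils::read.delim(file)
  target_table(tt, score_bounds = score_bounds)
}

#' Validate a target table
#'
#' @param df data.frame with columns `mirna_id`, `gene_id`, `score`.
#' @param score_bounds admissible score range (default miRDB's `[50, 100]`).
#' @return The validated data.frame with class `target_table`.
#' @export
target_table <- function(df, score_bounds = c(50, 100)) {
  need <- c("mirna_id", "gene_id", "score")
  if (!all(need %in% names(df)))
    stop("target table needs columns: ", paste(need, collapse = ", "))
  df <- df[need]
  if (anyDuplicated(df[c("mirna_id", "gene_id")]))
    stop("duplicate (mirna_id, gene_id) pairs in target table")
  if (any(df$score < score_bounds[1] | df$score > score_bounds[2]))
    stop("target scores outside [", score_bounds[1], ", ",
         score_bounds[2], "]")
  class(df) <- c("target_table", "data.frame")
  df
}

#' @rdname mircross_io
#' @export
write_target_table <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname mircross_io
#' @export
read_gmt <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    gene_set(f[1], f[-(1:2)])
  })
  names(sets) <- vapply(sets, function(s) s$name, character(1))
  sets
}

#' @rdname mircross_io
#' @param sets a list of [gene_set] objects (or a single one).
#' @export
write_gmt <- function(sets, file) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s)
    paste(c(s$name, "na", s$genes), collapse = "\t"), character(1))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname mircross_io
#' @export
read_id_list <- function(file) {
  ids <- readLines(file)
  ids[nzchar(ids)]
}

#' @rdname mircross_io
#' @param ids character vector of identifiers to write, one per line.
#' @export
write_id_list <- function(ids, file) {
  if (inherits(ids, "gene_set")) ids <- ids$genes
  writeLines(ids, file)
  invisible(file)
}
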