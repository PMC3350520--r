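# TSV dialect shared by all stages: probe matrices carry probe_id and
# transcript_id as the first two columns, designs are (sample_id, group),
# networks are SIF or two-column TSV edge lists.

#' Write a probe matrix as TSV (plus a companion design file)
#'
#' @param pm a `probe_matrix`.
#' @param path output path for the matrix TSV. Columns: probe_id,
#'   transcript_id, then one column per sample.
#' @param design_path output path for the design TSV (sample_id, group);
#'   default replaces the matrix file extension with `.design.tsv`.
#' @return invisibly, `c(path, design_path)`.
#' @export
write_probe_matrix <- function(pm, path,
                               design_path = sub("\\.tsv$", ".design.tsv", path)) {
  stopifnot(inherits(pm, "probe_matrix"))
  df <- data.frame(probe_id = rownames(pm$values),
                   transcript_id = pm$transcript_of,
                   pm$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_design(data.frame(sample_id = colnames(pm$values),
                          group = pm$group_of,
                          stringsAsFactors = FALSE),
               design_path)
  invisible(c(path, design_path))
}

#' Read a probe matrix written by [write_probe_matrix()]
#' @param path matrix TSV path.
#' @param design_path design TSV path.
#' @return a `probe_matrix`.
#' @export
read_probe_matrix <- function(path,
                              design_path = sub("\\.tsv$", ".design.tsv", path)) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "transcript_id") %in% names(df)[1:2]))
    stop("probe matrix TSV must start with columns probe_id, transcript_id: ", path)
  design <- read_design(design_path)
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(vals) <- df$probe_id
  samples <- colnames(vals)
  missing <- setdiff(samples, design$sample_id)
  if (length(missing))
    stop("samples absent from design: ", paste(missing, collapse = ", "))
  grp <- design$group[match(samples, design$sample_id)]
  probe_matrix(vals, df$transcript_id, grp)
}

write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(d)))
    stop("design TSV must have columns sample_id, group: ", path)
  d
}

#' Write a transcript-level expression matrix as TSV
#' @param em an `expression_matrix`.
#' @param path output path; first column `transcript_id`, then samples.
#' @param design_path companion design TSV path.
#' @return invisibly, the paths written.
#' @export
write_expression_matrix <- function(em, path,
                                    design_path = sub("\\.tsv$", ".design.tsv", path)) {
  stopifnot(inherits(em, "expression_matrix"))
  df <- data.frame(transcript_id = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_design(data.frame(sample_id = colnames(em$values),
                          group = em$group_of, stringsAsFactors = FALSE),
               design_path)
  invisible(c(path, design_path))
}

#' Read a transcript-level expression matrix
#' @param path matrix TSV path (first column transcript_id).
#' @param design_path design TSV path.
#' @return an `expression_matrix`.
#' @export
read_expression_matrix <- function(path,
                                   design_path = sub("\\.tsv$", ".design.tsv", path)) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "transcript_id")
    stop("expression TSV must start with column transcript_id: ", path)
  design <- read_design(design_path)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$transcript_id
  grp <- design$group[match(colnames(vals), design$sample_id)]
  if (anyNA(grp)) stop("samples absent from design: ", path)
  expression_matrix(vals, grp)
}

# TSV writer with "# key: value" metadata header lines, used for DE tables
# and other stage outputs so every file records its provenance.
write_annotated_tsv <- function(df, path, metadata = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(metadata))
    writeLines(sprintf("# %s: %s", names(metadata),
                       vapply(metadata, as.character, "")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_annotated_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
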