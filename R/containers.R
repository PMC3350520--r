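#' Probe-level expression container
#'
#' Holds log2-scale probe intensities together with the probe-to-transcript
#' grouping and the sample-to-group design. This is the unit of input for
#' [quantile_normalize()] and [median_polish_summarize()].
#'
#' @param values numeric matrix, probes x samples, log2 intensities. Must have
#'   row and column names.
#' @param transcript_of character vector mapping each probe (row) to its
#'   transcript id; length `nrow(values)`.
#' @param group_of character vector of group labels, one per sample (column);
#'   length `ncol(values)`.
#' @return An object of class `probe_matrix`: a list with elements `values`,
#'   `transcript_of` (named by probe id) and `group_of` (named by sample id).
#' @export
probe_matrix <- function(values, transcript_of, group_of) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have probe row names and sample column names")
  if (anyNA(values) || any(!is.finite(values)))
    stop("'values' contains missing or non-finite entries")
  if (length(transcript_of) != nrow(values))
    stop("'transcript_of' must have one entry per probe")
  if (length(group_of) != ncol(values))
    stop("'group_of' must have one entry per sample")
  names(transcript_of) <- rownames(values)
  names(group_of) <- colnames(values)
  structure(
    list(values = values,
         transcript_of = as.character(transcript_of),
         group_of = as.character(group_of)),
    names = c("values", "transcript_of", "group_of"),
    class = "probe_matrix"
  )
}

#' Transcript-level expression container
#'
#' @param values numeric matrix, transcripts x samples, log2 scale, with row
#'   and column names.
#' @param group_of character vector of group labels, one per sample.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, group_of) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have transcript row names and sample column names")
  if (any(!is.finite(values)))
    stop("'values' contains non-finite entries")
  if (length(group_of) != ncol(values))
    stop("'group_of' must have one entry per sample")
  names(group_of) <- colnames(values)
  structure(list(values = values, group_of = as.character(group_of)),
            class = "expression_matrix")
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat(sprintf("probe_matrix: %d probes x %d samples, %d transcripts, groups: %s\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$transcript_of)),
              paste(unique(x$group_of), collapse = ", ")))
  invisible(x)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d transcripts x %d samples, groups: %s\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$group_of), collapse = ", ")))
  invisible(x)
}

#' @export
dim.probe_matrix <- function(x) dim(x$values)

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Signature set: up- and down-regulated transcript ids for one contrast
#'
#' @param name character label for the signature.
#' @param up,down character vectors of transcript ids; must be disjoint.
#' @return An object of class `signature_set`.
#' @export
signature_set <- function(name, up = character(), down = character()) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  if (length(intersect(up, down)))
    stop("up and down sets must be disjoint")
  structure(list(name = name, up = up, down = down), class = "signature_set")
}

#' All transcript ids in a signature
#' @param sig a `signature_set`.
#' @return character vector of transcript ids (up then down).
#' @export
signature_ids <- function(sig) c(sig$up, sig$down)

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set '%s': %d up, %d down\n",
              x$name, length(x$up), length(x$down)))
  invisible(x)
}
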