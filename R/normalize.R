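# Transcript-level expression from probe-level data: quantile normalization
# across samples followed by median-polish summarization of the probes of
# each transcript. This mirrors the normalization + summarization steps of
# the RMA workflow; background adjustment is intentionally out of scope
# (inputs are assumed background-clean, as the synthetic generator produces).

#' Quantile normalization across sample columns
#'
#' Forces every column to share one empirical distribution: after
#' normalization each column's sorted values equal the across-column mean of
#' sorted values, while within-column rank order is preserved. Ties share the
#' mean of the reference values at their rank positions.
#'
#' @param x a `probe_matrix`, `expression_matrix`, or plain numeric matrix.
#' @param ... unused.
#' @return object of the same type with normalized values. A single-column
#'   input is returned unchanged with a warning.
#' @export
quantile_normalize <- function(x, ...) UseMethod("quantile_normalize")

#' @export
quantile_normalize.matrix <- function(x, ...) {
  if (ncol(x) < 2) {
    warning("quantile_normalize: fewer than 2 columns; returning input unchanged")
    return(x)
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' @export
quantile_normalize.probe_matrix <- function(x, ...) {
  x$values <- quantile_normalize(x$values)
  x
}

#' @export
quantile_normalize.expression_matrix <- function(x, ...) {
  x$values <- quantile_normalize(x$values)
  x
}

#' Median-polish summarization of probes to transcripts
#'
#' For each transcript, fits the additive model
#' `value ~ overall + probe_effect + sample_effect` by iterated median sweeps
#' (rows first) and reports `overall + sample_effect` as the transcript's
#' summarized log2 signal — the robust two-way fit used by RMA.
#'
#' @param pm a `probe_matrix`.
#' @param tol convergence tolerance on the relative change in the sum of
#'   absolute residuals (default 1e-6).
#' @param max_iter maximum sweep iterations per transcript (default 20).
#' @return an `expression_matrix` with one row per transcript, ordered by
#'   transcript id.
#' @export
median_polish_summarize <- function(pm, tol = 1e-6, max_iter = 20L) {
  stopifnot(inherits(pm, "probe_matrix"))
  bad <- !is.finite(pm$values)
  if (any(bad)) {
    probe <- rownames(pm$values)[which(rowSums(bad) > 0)[1]]
    stop("non-finite intensity for probe ", probe)
  }
  tx <- sort(unique(pm$transcript_of))
  rows_of <- split(seq_len(nrow(pm$values)), pm$transcript_of)
  out <- matrix(NA_real_, length(tx), ncol(pm$values),
                dimnames = list(tx, colnames(pm$values)))
  n_nonconv <- 0L
  for (t in tx) {
    block <- pm$values[rows_of[[t]], , drop = FALSE]
    if (nrow(block) == 1L) {
      out[t, ] <- block[1, ]  # single probe: the probe row is the summary
    } else {
      fit <- withCallingHandlers(
        stats::medpolish(block, eps = tol, maxiter = max_iter,
                         trace.iter = FALSE, na.rm = FALSE),
        warning = function(w) {
          if (grepl("did not converge", conditionMessage(w))) {
            n_nonconv <<- n_nonconv + 1L
            invokeRestart("muffleWarning")
          }
        })
      out[t, ] <- fit$overall + fit$col
    }
  }
  if (n_nonconv > 0L)
    warning(sprintf("median polish hit max_iter = %d for %d of %d transcripts",
                    max_iter, n_nonconv, length(tx)))
  expression_matrix(out, pm$group_of)
}
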