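# Treatment counter-regulation analysis. Counter-regulation means a treatment
# moves a transcript in the direction opposite its disease-associated change:
# treatment down-regulates genes up-regulated in disease vs control, and vice
# versa. The procedure: (1) build per-transcript fold-change profiles over
# [disease vs control, treatment_i vs disease] for the disease-signature
# transcripts; (2) K-means the profiles into bins; (3) keep bins whose
# centroid shows strict sign opposition between the disease and every
# treatment component; (4) apply the per-gene magnitude/significance filter
# (|FC| > 2, p < 0.05 for treatment vs disease, opposite sign).

#' Build the fold-change profile matrix over the disease signature
#'
#' @param de_tables named list of `de_table`s, disease contrast first, then
#'   one per treatment (treatment vs disease).
#' @param signature a [signature_set()] of disease-signature transcripts.
#' @return numeric matrix, rows = signature transcripts, columns = log2 fold
#'   changes per contrast (disease first), with contrast names as column
#'   names. Empty signature gives a 0-row matrix.
#' @export
build_fc_profiles <- function(de_tables, signature) {
  stopifnot(is.list(de_tables), length(de_tables) >= 2,
            !is.null(names(de_tables)), inherits(signature, "signature_set"))
  ids <- signature_ids(signature)
  prof <- matrix(NA_real_, length(ids), length(de_tables),
                 dimnames = list(ids, names(de_tables)))
  for (nm in names(de_tables)) {
    tab <- de_tables[[nm]]
    hit <- match(ids, tab$transcript_id)
    if (anyNA(hit))
      stop("signature transcripts missing from DE table '", nm, "': ",
           paste(ids[is.na(hit)], collapse = ", "))
    prof[, nm] <- tab$log2fc[hit]
  }
  prof
}

#' K-means binning of fold-change profiles
#'
#' Euclidean K-means on the raw log2 fold-change columns (all contrasts share
#' the log2 scale, so no standardization), best of `n_restarts` by total
#' within-bin sum of squares, deterministic given `seed`.
#'
#' @param profiles matrix from [build_fc_profiles()].
#' @param k number of bins (default 20).
#' @param seed integer seed.
#' @param n_restarts random restarts (default 50).
#' @return list of class `bin_assignment` with `bin` (named integer vector),
#'   `centroids` (k x n_contrasts), `inertia`, `k`, `seed`.
#' @export
kmeans_bins <- function(profiles, k = 20L, seed = 1L, n_restarts = 50L) {
  if (k > nrow(profiles))
    stop("k = ", k, " exceeds the ", nrow(profiles),
         " profiled transcripts; choose a smaller k")
  distinct <- unique(profiles)
  if (k > nrow(distinct))
    stop("k = ", k, " exceeds the ", nrow(distinct),
         " distinct profiles; choose a smaller k")
  set.seed(seed)
  if (k == nrow(distinct)) {
    # saturated case: every distinct profile is its own centroid, inertia 0
    fit <- stats::kmeans(profiles, centers = distinct, iter.max = 100)
  } else {
    fit <- stats::kmeans(profiles, centers = k, nstart = n_restarts,
                         iter.max = 100)
  }
  structure(list(bin = stats::setNames(fit$cluster, rownames(profiles)),
                 centroids = unname(fit$centers),
                 inertia = fit$tot.withinss,
                 k = as.integer(k), seed = as.integer(seed)),
            class = "bin_assignment")
}

#' Select counter-regulated bins by centroid sign opposition
#'
#' A bin is selected iff its centroid's disease component (column 1) and every
#' treatment component have strictly opposite signs; a zero component fails
#' the strict rule.
#'
#' @param bins a `bin_assignment`.
#' @return integer vector of selected bin indices.
#' @export
select_counterreg_bins <- function(bins) {
  stopifnot(inherits(bins, "bin_assignment"))
  ce <- bins$centroids
  sel <- apply(ce, 1, function(v)
    v[1] != 0 && all(v[-1] != 0) && all(sign(v[-1]) == -sign(v[1])))
  which(sel)
}

#' Classify counter-regulation of single genes from signed fold changes
#'
#' A gene is counter-regulated by a treatment iff the treatment fold change
#' has the sign opposite to the disease fold change, `|FC| > fc_thr`, and the
#' treatment p-value is `< p_thr`. `status_all` is TRUE when every treatment
#' counter-regulates the gene.
#'
#' @param fc_disease signed fold change disease vs control (vector of genes).
#' @param fc_treatments matrix (genes x treatments) or vector of signed fold
#'   changes treatment vs disease.
#' @param p_treatments matching matrix/vector of p-values, or NULL when the
#'   inputs are already significance-filtered (e.g. published tables that
#'   print fold changes for genes pre-selected at p < 0.05).
#' @param fc_thr fold-change threshold (default 2, strict `>`).
#' @param p_thr p-value threshold (default 0.05, strict `<`).
#' @param fc_tol measurement tolerance on the fold changes: values within
#'   `fc_tol` of the threshold pass. Default 0 (strict). Use half the printed
#'   least significant digit (e.g. 0.05 for one-decimal tables) when
#'   classifying rounded published values.
#' @return list with `status` (genes x treatments logical matrix) and
#'   `status_all` (logical vector).
#' @export
classify_counter_regulation <- function(fc_disease, fc_treatments,
                                        p_treatments = NULL,
                                        fc_thr = 2, p_thr = 0.05,
                                        fc_tol = 0) {
  fc_treatments <- as.matrix(fc_treatments)
  stopifnot(length(fc_disease) == nrow(fc_treatments),
            all(abs(fc_disease) >= 1), all(abs(fc_treatments) >= 1))
  if (is.null(p_treatments)) {
    p_ok <- matrix(TRUE, nrow(fc_treatments), ncol(fc_treatments))
  } else {
    p_treatments <- as.matrix(p_treatments)
    stopifnot(identical(dim(p_treatments), dim(fc_treatments)))
    p_ok <- p_treatments < p_thr
  }
  opposite <- sign(fc_treatments) == -sign(fc_disease)
  big <- abs(fc_treatments) + fc_tol > fc_thr
  status <- opposite & big & p_ok
  dimnames(status) <- dimnames(fc_treatments)
  list(status = status, status_all = apply(status, 1, all))
}

#' Counter-regulated signatures per treatment and their intersection
#'
#' Combines bin selection with the per-gene filter: a transcript is
#' counter-regulated by a treatment iff it sits in a selected bin (when
#' `bin_filter = TRUE`) and passes [classify_counter_regulation()] for that
#' treatment, with p-value `min(p_up, p_down)` from the treatment DE table.
#'
#' @param profiles matrix from [build_fc_profiles()].
#' @param bins a `bin_assignment` over `profiles` (ignored when
#'   `bin_filter = FALSE`).
#' @param de_tables named list of `de_table`s, disease first (as in
#'   [build_fc_profiles()]).
#' @param fc_thr,p_thr thresholds of the gene-level filter.
#' @param bin_filter apply the K-means bin selection before the gene-level
#'   filter (default TRUE). With FALSE the pure gene-level filter is used.
#' @return list with `per_treatment` (named list of [signature_set()]s),
#'   `all` (signature_set counter-regulated by every treatment), and `table`
#'   (a data.frame sorted by disease fold change ascending, with per-treatment
#'   fold changes, p-values, bin and status columns).
#' @export
counterreg_signature <- function(profiles, bins, de_tables,
                                 fc_thr = 2, p_thr = 0.05, bin_filter = TRUE) {
  stopifnot(nrow(profiles) == 0 || !is.null(rownames(profiles)))
  treatments <- names(de_tables)[-1]
  ids <- rownames(profiles)
  if (!length(ids)) {
    empty <- signature_set("counter-regulated (all treatments)")
    return(list(per_treatment = stats::setNames(
                  lapply(treatments, function(t) signature_set(t)), treatments),
                all = empty,
                table = data.frame(transcript_id = character())))
  }
  disease_tab <- de_tables[[1]]
  fc_d <- disease_tab$signed_fc[match(ids, disease_tab$transcript_id)]
  fc_t <- sapply(treatments, function(trt) {
    tab <- de_tables[[trt]]
    tab$signed_fc[match(ids, tab$transcript_id)]
  })
  p_t <- sapply(treatments, function(trt) {
    tab <- de_tables[[trt]]
    pmin(tab$p_up, tab$p_down)[match(ids, tab$transcript_id)]
  })
  fc_t <- matrix(fc_t, nrow = length(ids),
                 dimnames = list(ids, treatments))
  p_t <- matrix(p_t, nrow = length(ids), dimnames = list(ids, treatments))

  cls <- classify_counter_regulation(fc_d, fc_t, p_t,
                                     fc_thr = fc_thr, p_thr = p_thr)
  in_bin <- if (bin_filter) {
    sel <- select_counterreg_bins(bins)
    bins$bin[ids] %in% sel
  } else rep(TRUE, length(ids))

  status <- cls$status & in_bin
  per_treatment <- stats::setNames(lapply(treatments, function(trt) {
    hit <- status[, trt]
    signature_set(paste0("counter-regulated by ", trt),
                  up = ids[hit & fc_t[, trt] > 0],
                  down = ids[hit & fc_t[, trt] < 0])
  }), treatments)
  all_hit <- apply(status, 1, all)
  sig_all <- signature_set("counter-regulated (all treatments)",
                           up = ids[all_hit & fc_d < 0],
                           down = ids[all_hit & fc_d > 0])

  tab <- data.frame(transcript_id = ids,
                    fc_disease = fc_d,
                    stringsAsFactors = FALSE)
  for (trt in treatments) {
    tab[[paste0("fc_", trt)]] <- fc_t[, trt]
    tab[[paste0("p_", trt)]] <- p_t[, trt]
  }
  tab$bin <- if (bin_filter) unname(bins$bin[ids]) else NA_integer_
  for (trt in treatments) tab[[paste0("status_", trt)]] <- status[, trt]
  tab$status_all <- all_hit
  tab <- tab[order(tab$fc_disease), , drop = FALSE]
  rownames(tab) <- NULL
  list(per_treatment = per_treatment, all = sig_all, table = tab)
}
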