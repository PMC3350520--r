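# Two-group differential expression by the rank-product statistic. For each
# of the k = n1 x n2 between-group sample pairs, all transcripts are ranked by
# the pairwise log2 difference (rank 1 = most up, respectively most down); the
# rank product is the geometric mean of a transcript's ranks across pairs,
# computed in log space. Significance comes from a permutation null of
# uniformly random rank assignments per pairwise comparison, pooled across
# transcripts and permutations.

#' Signed fold change from two log2 group means
#'
#' Converts a log2 difference to the symmetric linear-scale convention used in
#' gene-expression tables: the ratio `r = 2^(num - den)` is reported as `r`
#' when `r >= 1` and as `-1/r` otherwise, so magnitude is symmetric about
#' +1/-1 and `signed_fc = +1` when the means are equal.
#'
#' @param mean_log2_num,mean_log2_den log2 group means (vectorized).
#' @return numeric vector of signed fold changes, |value| >= 1.
#' @export
signed_fold_change <- function(mean_log2_num, mean_log2_den) {
  stopifnot(all(is.finite(mean_log2_num)), all(is.finite(mean_log2_den)))
  r <- 2^(mean_log2_num - mean_log2_den)
  ifelse(r >= 1, r, -1 / r)
}

contrast_indices <- function(em, numerator, denominator) {
  if (identical(numerator, denominator))
    stop("contrast groups must be distinct")
  idx_num <- which(em$group_of == numerator)
  idx_den <- which(em$group_of == denominator)
  if (!length(idx_num)) stop("group absent from design: ", numerator)
  if (!length(idx_den)) stop("group absent from design: ", denominator)
  list(num = idx_num, den = idx_den)
}

# log-scale rank products for both directions; ranks use the average-rank tie
# convention. Returns a list with log_rp_up / log_rp_down (natural log).
rank_product_log <- function(em, numerator, denominator) {
  ix <- contrast_indices(em, numerator, denominator)
  G <- nrow(em$values)
  k <- length(ix$num) * length(ix$den)
  log_up <- numeric(G); log_down <- numeric(G)
  for (i in ix$num) for (j in ix$den) {
    d <- em$values[, i] - em$values[, j]
    r_down <- rank(d, ties.method = "average")   # most-down difference -> rank 1
    r_up <- rank(-d, ties.method = "average")    # most-up difference -> rank 1
    log_up <- log_up + log(r_up)
    log_down <- log_down + log(r_down)
  }
  list(log_rp_up = log_up / k, log_rp_down = log_down / k, k = k, G = G)
}

#' Rank products for one two-group contrast
#'
#' @param em an `expression_matrix`.
#' @param numerator,denominator group labels (numerator vs denominator, e.g.
#'   disease vs control).
#' @return data.frame with columns `transcript_id`, `rp_up`, `rp_down`; rank
#'   products lie in `[1, G]` where `G` is the number of transcripts.
#' @export
rank_product <- function(em, numerator, denominator) {
  rp <- rank_product_log(em, numerator, denominator)
  data.frame(transcript_id = rownames(em$values),
             rp_up = exp(rp$log_rp_up),
             rp_down = exp(rp$log_rp_down),
             stringsAsFactors = FALSE)
}

# Draw the pooled permutation null of log rank products: n_perm independent
# replicates, each assigning uniformly random ranks (a random permutation of
# 1..G) to the transcripts in each of the k pairwise comparisons. Returns a
# sorted vector of n_perm * G null log rank products.
null_log_rp <- function(G, k, n_perm) {
  out <- numeric(n_perm * G)
  for (b in seq_len(n_perm)) {
    acc <- numeric(G)
    for (j in seq_len(k)) acc <- acc + log(sample.int(G))
    out[((b - 1) * G + 1):(b * G)] <- acc / k
  }
  sort(out)
}

#' Permutation p-values for observed rank products
#'
#' The null pools rank products across all transcripts and permutations:
#' `p = (1 + #null <= observed) / (1 + n_perm * G)`, so p lies in (0, 1] and
#' is monotone in the observed rank product.
#'
#' @param em an `expression_matrix`.
#' @param numerator,denominator group labels of the contrast.
#' @param n_perm number of random permutations (default 100).
#' @param seed integer seed for the permutation draws.
#' @return data.frame with columns `transcript_id`, `p_up`, `p_down`.
#' @export
permutation_pvalues <- function(em, numerator, denominator,
                                n_perm = 100L, seed = 1L) {
  stopifnot(n_perm >= 1)
  rp <- rank_product_log(em, numerator, denominator)
  set.seed(seed)
  null_sorted <- null_log_rp(rp$G, rp$k, n_perm)
  # tiny eps absorbs float jitter so exact rank ties count as <=
  eps <- 1e-9
  p_of <- function(obs)
    (1 + findInterval(obs + eps, null_sorted)) / (1 + n_perm * rp$G)
  data.frame(transcript_id = rownames(em$values),
             p_up = p_of(rp$log_rp_up),
             p_down = p_of(rp$log_rp_down),
             stringsAsFactors = FALSE)
}

#' Full rank-product differential-expression table for one contrast
#'
#' Combines group-mean log2 fold changes (signed fold change on the linear
#' scale), rank products in both directions, permutation p-values and the
#' significance call at the stated thresholds.
#'
#' @param em an `expression_matrix`.
#' @param numerator,denominator group labels (numerator vs denominator).
#' @param n_perm permutations for the null (default 100).
#' @param seed integer seed.
#' @param fc_thr,p_thr thresholds for the significance flag: significant iff
#'   `|signed_fc| > fc_thr` and `min(p_up, p_down) <= p_thr`.
#' @return a `de_table`: data.frame with columns `transcript_id`, `log2fc`,
#'   `signed_fc`, `rp_up`, `rp_down`, `p_up`, `p_down`, `significant`, with
#'   attributes `contrast`, `n_permutations`, `seed`.
#' @export
rankprod_de <- function(em, numerator, denominator, n_perm = 100L, seed = 1L,
                        fc_thr = 2, p_thr = 0.05) {
  ix <- contrast_indices(em, numerator, denominator)
  mean_num <- rowMeans(em$values[, ix$num, drop = FALSE])
  mean_den <- rowMeans(em$values[, ix$den, drop = FALSE])
  log2fc <- mean_num - mean_den
  rp <- rank_product(em, numerator, denominator)
  pv <- permutation_pvalues(em, numerator, denominator, n_perm, seed)
  tab <- data.frame(transcript_id = rp$transcript_id,
                    log2fc = unname(log2fc),
                    signed_fc = unname(signed_fold_change(mean_num, mean_den)),
                    rp_up = rp$rp_up, rp_down = rp$rp_down,
                    p_up = pv$p_up, p_down = pv$p_down,
                    stringsAsFactors = FALSE)
  tab$significant <- abs(tab$signed_fc) > fc_thr &
    pmin(tab$p_up, tab$p_down) <= p_thr
  structure(tab,
            contrast = c(numerator = numerator, denominator = denominator),
            n_permutations = as.integer(n_perm), seed = as.integer(seed),
            class = c("de_table", "data.frame"))
}

#' Extract the differential-expression signature from a DE table
#'
#' A transcript enters the signature iff `|signed_fc| > fc_thr` and
#' `min(p_up, p_down) <= p_thr`; its direction is the sign of the signed fold
#' change.
#'
#' @param tab a `de_table` from [rankprod_de()].
#' @param fc_thr fold-change threshold (default 2, strict `>`).
#' @param p_thr p-value threshold (default 0.05, inclusive `<=`).
#' @param name signature label.
#' @return a [signature_set()].
#' @export
de_signature <- function(tab, fc_thr = 2, p_thr = 0.05, name = "DE signature") {
  stopifnot(fc_thr > 0, p_thr > 0)
  sel <- abs(tab$signed_fc) > fc_thr & pmin(tab$p_up, tab$p_down) <= p_thr
  signature_set(name,
                up = tab$transcript_id[sel & tab$signed_fc > 0],
                down = tab$transcript_id[sel & tab$signed_fc < 0])
}

#' Write a DE table as annotated TSV
#' @param tab a `de_table`.
#' @param path output path; metadata (contrast, permutations, seed) is written
#'   as `#`-prefixed header lines.
#' @return invisibly, `path`.
#' @export
write_de_table <- function(tab, path) {
  ct <- attr(tab, "contrast")
  write_annotated_tsv(as.data.frame(tab), path, metadata = list(
    contrast = paste0(ct["numerator"], "_vs_", ct["denominator"]),
    n_permutations = attr(tab, "n_permutations"),
    seed = attr(tab, "seed")))
}
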