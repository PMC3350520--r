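# helper: run the sim through normalization + all three DE contrasts.
# Zero-noise fixtures skip quantile normalization: QN equalizes column
# distributions, which planted group shifts intentionally violate, so the
# exact-recovery limit is a property of summarization + DE + counterreg.
sim_de_tables <- function(sim, n_perm = 60, seed = 5, qn = TRUE) {
  pm <- if (qn) quantile_normalize(sim$probes) else sim$probes
  em <- suppressWarnings(median_polish_summarize(pm))
  list(
    DIA_vs_NOR = rankprod_de(em, "DIA", "NOR", n_perm = n_perm, seed = seed),
    TRT1 = rankprod_de(em, "TRT1", "DIA", n_perm = n_perm, seed = seed + 1),
    TRT2 = rankprod_de(em, "TRT2", "DIA", n_perm = n_perm, seed = seed + 2))
}

test_that("fold-change profiles have the contracted shape and contents", {
  sim <- zero_noise_sim(n = 50, seed = 3)
  de <- sim_de_tables(sim, n_perm = 20, qn = FALSE)
  sig <- de_signature(de[[1]])

  prof <- build_fc_profiles(de, sig)
  expect_identical(colnames(prof), c("DIA_vs_NOR", "TRT1", "TRT2"))
  expect_setequal(rownames(prof), signature_ids(sig))

  # empty signature -> empty matrix, no error
  empty <- build_fc_profiles(de, signature_set("none"))
  expect_identical(dim(empty), c(0L, 3L))

  # single transcript, 2 treatments -> 1 x 3
  one <- build_fc_profiles(de, signature_set("one", up = sig$up[1]))
  expect_identical(dim(one), c(1L, 3L))

  # planted reversed up-gene at zero noise: (+2, -2, -2) in log2 columns
  cr_up <- intersect(sim$truth$counterreg_sets$TRT1,
                     names(sim$truth$de_direction)[sim$truth$de_direction > 0])
  expect_equal(unname(prof[cr_up[1], ]), c(2, -2, -2), tolerance = 1e-10)

  # missing transcript errors with the offending ids
  expect_error(build_fc_profiles(de, signature_set("bad", up = "NOPE1")),
               "NOPE1")
})

test_that("kmeans_bins separates planted clusters and is deterministic", {
  prof <- rbind(matrix(rnorm(60, mean = 2, sd = 0.05), 20, 3),
                matrix(rnorm(60, mean = -2, sd = 0.05), 20, 3))
  rownames(prof) <- paste0("t", 1:40)
  bins <- kmeans_bins(prof, k = 2, seed = 1)
  expect_length(unique(bins$bin[1:20]), 1)
  expect_length(unique(bins$bin[21:40]), 1)
  expect_false(bins$bin[1] == bins$bin[40])

  again <- kmeans_bins(prof, k = 2, seed = 1)
  expect_identical(bins$bin, again$bin)

  # k = number of distinct rows -> inertia 0
  dup <- rbind(a = c(1, 1), b = c(1, 1), c = c(2, 2), d = c(3, 3))
  sat <- kmeans_bins(dup, k = 3, seed = 2)
  expect_equal(sat$inertia, 0)

  expect_error(kmeans_bins(prof, k = 100, seed = 1), "smaller k")
})

test_that("bin selection requires strict centroid sign opposition", {
  fake <- structure(list(
    bin = setNames(1:3, c("a", "b", "c")),
    centroids = rbind(c(2.1, -1.8, -2.2),
                      c(2.1, 0.3, -2.2),
                      c(2.1, 0, -2.2)),
    inertia = 0, k = 3L, seed = 1L), class = "bin_assignment")
  expect_identical(select_counterreg_bins(fake), 1L)
})

test_that("classify_counter_regulation reproduces the published worked rows", {
  # Pck1: disease -9.3, treatments +12.6 / +13.6 -> counter-regulated by both
  pck1 <- classify_counter_regulation(-9.3, cbind(12.6, 13.6),
                                      cbind(0.01, 0.01))
  expect_true(all(pck1$status))
  expect_true(pck1$status_all)

  # Insig1: disease +7.8, treatments -7.2 / -4.3 -> counter-regulated by both
  insig1 <- classify_counter_regulation(7.8, cbind(-7.2, -4.3),
                                        cbind(0.01, 0.01))
  expect_true(insig1$status_all)

  # |FC| > 2 is strict: treatment 1 at +1.5 fails, so status_all is FALSE
  mid <- classify_counter_regulation(-4, cbind(1.5, 3), cbind(0.01, 0.01))
  expect_identical(unname(mid$status[1, ]), c(FALSE, TRUE))
  expect_false(mid$status_all)

  # p filter and sign filter
  expect_false(classify_counter_regulation(-4, cbind(3), cbind(0.2))$status_all)
  expect_false(classify_counter_regulation(4, cbind(3), cbind(0.01))$status_all)

  # fc_tol admits values within measurement precision of the threshold
  expect_false(classify_counter_regulation(-3, cbind(2), NULL)$status_all)
  expect_true(classify_counter_regulation(-3, cbind(2), NULL,
                                          fc_tol = 0.05)$status_all)
})

test_that("counterreg signature recovers planted truth exactly at zero noise", {
  sim <- zero_noise_sim(n = 80, seed = 23)
  de <- sim_de_tables(sim, n_perm = 100, qn = FALSE)
  sig <- de_signature(de[[1]])
  expect_setequal(signature_ids(sig), sim$truth$de_ids)

  prof <- build_fc_profiles(de, sig)
  k <- min(6, nrow(unique(prof)))
  bins <- kmeans_bins(prof, k = k, seed = 9)
  cr <- counterreg_signature(prof, bins, de)
  expect_setequal(signature_ids(cr$all), sim$truth$counterreg_sets$TRT1)
  expect_setequal(signature_ids(cr$per_treatment$TRT1),
                  sim$truth$counterreg_sets$TRT1)
})

test_that("counterreg signature obeys its structural invariants", {
  sim <- small_sim(n = 200, seed = 37, frac_de = 0.2, frac_cr = 0.5)
  de <- sim_de_tables(sim, n_perm = 60)
  sig <- de_signature(de[[1]])
  prof <- build_fc_profiles(de, sig)
  bins <- kmeans_bins(prof, k = min(10, nrow(unique(prof))), seed = 4)
  cr <- counterreg_signature(prof, bins, de)

  # subset invariant: counter-regulated signature within the disease signature
  expect_true(all(signature_ids(cr$all) %in% signature_ids(sig)))

  # bin filter only removes genes: binned result subset of pure gene filter
  cr_nobin <- counterreg_signature(prof, bins, de, bin_filter = FALSE)
  expect_true(all(signature_ids(cr$all) %in% signature_ids(cr_nobin$all)))
  for (trt in c("TRT1", "TRT2"))
    expect_true(all(signature_ids(cr$per_treatment[[trt]]) %in%
                      signature_ids(cr_nobin$per_treatment[[trt]])))

  # status_all implies every per-treatment status
  tab <- cr$table
  expect_true(all(!tab$status_all | (tab$status_TRT1 & tab$status_TRT2)))
  # all-treatments set = intersection of per-treatment sets
  expect_setequal(signature_ids(cr$all),
                  intersect(signature_ids(cr$per_treatment$TRT1),
                            signature_ids(cr$per_treatment$TRT2)))
  # report table sorted by disease fold change ascending
  expect_true(!is.unsorted(tab$fc_disease))
})

test_that("infinite fold-change threshold empties the signature", {
  sim <- zero_noise_sim(n = 40, seed = 2)
  de <- sim_de_tables(sim, n_perm = 20, qn = FALSE)
  sig <- de_signature(de[[1]])
  prof <- build_fc_profiles(de, sig)
  bins <- kmeans_bins(prof, k = min(4, nrow(unique(prof))), seed = 1)
  cr <- counterreg_signature(prof, bins, de, fc_thr = Inf)
  expect_length(signature_ids(cr$all), 0)
})
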