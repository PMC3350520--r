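# End-to-end orchestration: normalize -> rank-product DE (all contrasts) ->
# counter-regulation -> network hubs, with deterministic seeding, stage
# logging to stderr and a machine-readable run manifest.

pipeline_defaults <- function() list(
  expression = NA_character_, design = NA_character_, network = NA_character_,
  output_dir = NA_character_,
  fc_thr = 2, p_thr = 0.05, n_permutations = 100L, n_bins = 20L,
  min_network_score = 15, n_networks_to_merge = 7L,
  max_subnetwork_size = 35L, n_top_hubs = 20L,
  universe_size = NA_integer_, bin_filter = TRUE, rng_seed = 1L)

#' Pipeline configuration
#'
#' Either construct programmatically (named arguments override the defaults)
#' or read from a flat `key = value` text file with [read_pipeline_config()].
#' Unknown keys are errors — this catches typos in threshold names.
#'
#' @param ... named fields: `expression`, `design`, `network` (input paths),
#'   `output_dir`, `fc_thr` (2), `p_thr` (0.05), `n_permutations` (100),
#'   `n_bins` (20), `min_network_score` (15), `n_networks_to_merge` (7),
#'   `max_subnetwork_size` (35), `n_top_hubs` (20), `universe_size` (NA =
#'   network node count), `bin_filter` (TRUE), `rng_seed` (1).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  args <- list(...)
  unknown <- setdiff(names(args), names(cfg))
  if (length(unknown))
    stop("unknown pipeline_config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(args)] <- args
  for (f in c("n_permutations", "n_bins", "n_networks_to_merge",
              "max_subnetwork_size", "n_top_hubs", "rng_seed"))
    cfg[[f]] <- as.integer(cfg[[f]])
  for (f in c("fc_thr", "p_thr", "min_network_score"))
    cfg[[f]] <- as.numeric(cfg[[f]])
  cfg$bin_filter <- as.logical(cfg$bin_filter)
  if (cfg$fc_thr <= 0 || cfg$p_thr <= 0) stop("thresholds must be positive")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a flat key = value file
#'
#' Lines are `key = value`; blank lines and `#` comments are ignored.
#' Unknown keys are errors.
#'
#' @param path config file path.
#' @param ... overrides applied after the file is read.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*?)\\s*$",
                                  lines))
  bad <- which(vapply(kv, length, 0L) != 3)
  if (length(bad)) stop("malformed config line: ", lines[bad[1]])
  args <- stats::setNames(lapply(kv, `[[`, 3), vapply(kv, `[[`, "", 2))
  over <- list(...)
  args[names(over)] <- over
  do.call(pipeline_config, args)
}

log_stage <- function(fmt, ...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

#' Run the full pipeline
#'
#' Stages: read inputs -> quantile normalization + median-polish
#' summarization -> rank-product DE for the disease contrast (group 2 vs
#' group 1 of the design) and every treatment contrast (group i vs group 2)
#' -> counter-regulation signatures -> seeded subnetworks, merge, hub
#' ranking. All TSV/SIF artifacts are written under `output_dir` together
#' with `manifest.json` (config snapshot, file checksums, versions).
#'
#' @param config a `pipeline_config` with input paths set.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c("expression", "design", "network")) {
    if (is.na(config[[f]])) stop("config field '", f, "' is required")
    if (!file.exists(config[[f]])) stop("input file not found: ", config[[f]])
  }
  if (is.na(config$output_dir)) stop("config field 'output_dir' is required")
  out <- config$output_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  seed <- config$rng_seed

  log_stage("reading inputs")
  pm <- read_probe_matrix(config$expression, config$design)
  net <- read_edge_list(config$network,
                        universe_size = if (is.na(config$universe_size)) NULL
                                        else config$universe_size)
  groups <- unique(pm$group_of)
  if (length(groups) < 3)
    stop("design needs a control, a disease and at least one treatment group")
  control <- groups[1]; disease <- groups[2]; treatments <- groups[-(1:2)]

  log_stage("normalizing %d probes x %d samples", nrow(pm$values), ncol(pm$values))
  em <- median_polish_summarize(quantile_normalize(pm))
  write_expression_matrix(em, file.path(out, "expression.tsv"))

  contrasts <- c(stats::setNames(list(c(disease, control)),
                                 paste0(disease, "_vs_", control)),
                 stats::setNames(lapply(treatments, function(t) c(t, disease)),
                                 paste0(treatments, "_vs_", disease)))
  de_tables <- list()
  for (i in seq_along(contrasts)) {
    nm <- names(contrasts)[i]
    log_stage("rank-product DE: %s (%d permutations)", nm, config$n_permutations)
    tab <- rankprod_de(em, contrasts[[i]][1], contrasts[[i]][2],
                       n_perm = config$n_permutations, seed = seed + i,
                       fc_thr = config$fc_thr, p_thr = config$p_thr)
    de_tables[[nm]] <- tab
    write_de_table(tab, file.path(out, paste0("de_", nm, ".tsv")))
  }

  log_stage("disease signature")
  sig <- de_signature(de_tables[[1]], config$fc_thr, config$p_thr,
                      name = names(contrasts)[1])
  write_annotated_tsv(
    data.frame(transcript_id = signature_ids(sig),
               direction = rep(c("up", "down"), c(length(sig$up), length(sig$down)))),
    file.path(out, "signature_disease.tsv"),
    metadata = list(contrast = sig$name, fc_thr = config$fc_thr,
                    p_thr = config$p_thr))

  log_stage("counter-regulation: %d signature transcripts, %d bins",
            length(signature_ids(sig)), config$n_bins)
  profiles <- build_fc_profiles(de_tables, sig)
  bins <- NULL
  if (config$bin_filter) {
    if (config$n_bins > nrow(unique(profiles))) {
      warning("n_bins exceeds distinct profiles; disabling bin filter")
      config$bin_filter <- FALSE
    } else {
      bins <- kmeans_bins(profiles, k = config$n_bins, seed = seed)
    }
  }
  cr <- counterreg_signature(profiles, bins, de_tables,
                             fc_thr = config$fc_thr, p_thr = config$p_thr,
                             bin_filter = config$bin_filter)
  write_annotated_tsv(cr$table, file.path(out, "counterreg_table.tsv"),
                      metadata = list(fc_thr = config$fc_thr,
                                      p_thr = config$p_thr,
                                      n_bins = config$n_bins,
                                      bin_filter = config$bin_filter,
                                      seed = seed))

  log_stage("network analysis: %d counter-regulated genes",
            length(signature_ids(cr$all)))
  subnets <- build_seeded_subnetworks(net, cr$all,
                                      max_size = config$max_subnetwork_size)
  write_subnetworks(subnets, file.path(out, "subnetworks.tsv"))
  merged <- merge_top_networks(subnets, net,
                               n_top = config$n_networks_to_merge,
                               min_score = config$min_network_score)
  write_network_sif(merged, file.path(out, "merged_network.sif"))
  hubs <- rank_hubs(merged, cr$all, n_top = config$n_top_hubs)
  write_annotated_tsv(hubs, file.path(out, "hubs.tsv"),
                      metadata = list(n_top = config$n_top_hubs, seed = seed))

  files <- c("expression.tsv", paste0("de_", names(contrasts), ".tsv"),
             "signature_disease.tsv", "counterreg_table.tsv",
             "subnetworks.tsv", "merged_network.sif", "hubs.tsv")
  manifest <- list(
    config = unclass(config),
    checksums = as.list(tools::md5sum(file.path(out, files))),
    versions = list(counterhub = as.character(utils::packageVersion("counterhub")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", na = "null")
  log_stage("done: %s", out)
  invisible(manifest)
}

#' Deterministic hierarchical-clustering leaf order
#'
#' Average-linkage agglomerative clustering with correlation distance
#' (1 - Pearson), used to order rows or columns of an expression matrix for
#' heatmap export. Items are pre-sorted by id before clustering so the leaf
#' order is invariant to input permutation up to the tie rule.
#'
#' @param em an `expression_matrix` or numeric matrix.
#' @param axis `"rows"` (transcripts) or `"columns"` (samples).
#' @return character vector of ids in leaf order.
#' @export
hierarchical_order <- function(em, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  m <- if (inherits(em, "expression_matrix")) em$values else em
  if (axis == "columns") m <- t(m)
  if (nrow(m) < 2) stop("need at least 2 items on the chosen axis")
  m <- m[order(rownames(m)), , drop = FALSE]
  v <- apply(m, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance row under correlation distance: ",
         rownames(m)[which(v == 0)[1]])
  d <- stats::as.dist(1 - stats::cor(t(m)))
  hc <- stats::hclust(d, method = "average")
  rownames(m)[hc$order]
}

#' Row-standardized matrix in heatmap order
#'
#' Exports the matrix a heatmap plotter needs to reproduce a clustered
#' expression figure: rows centred/scaled to unit variance, rows and columns
#' in [hierarchical_order()].
#'
#' @param em an `expression_matrix`.
#' @param path optional TSV output path.
#' @return the reordered, row-standardized matrix (invisibly when `path` is
#'   given).
#' @export
heatmap_export <- function(em, path = NULL) {
  ro <- hierarchical_order(em, "rows")
  co <- hierarchical_order(em, "columns")
  z <- t(scale(t(em$values)))[ro, co, drop = FALSE]
  if (!is.null(path)) {
    utils::write.table(data.frame(transcript_id = rownames(z), z,
                                  check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(z))
  }
  z
}
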