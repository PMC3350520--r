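# Synthetic-data generator with planted ground truth. Emulates the structure
# of a multi-group oligonucleotide microarray study: log2-scale intensities,
# several probes per transcript with shared probe offsets, a disease group
# shifted for a planted DE subset, and treatment groups in which a planted
# subset of the DE transcripts returns to the control level
# ("counter-regulation").

#' Simulation configuration for the expression generator
#'
#' Defaults state the emulated study design: four groups (control `NOR`,
#' disease `DIA`, two treatments) with 4 replicates each, 11 probes per
#' transcript, a planted effect of |log2 FC| = 2 (4-fold) and Gaussian
#' log2-scale noise with sd 0.25.
#'
#' @param n_transcripts number of transcripts.
#' @param probes_per_transcript probes per transcript (default 11).
#' @param groups named integer vector: replicate count per group, in order.
#'   The first group is the control, the second the disease group, any
#'   further groups are treatments.
#' @param frac_de fraction of transcripts differentially expressed in the
#'   disease vs control contrast.
#' @param frac_counterreg fraction of the DE transcripts whose disease shift
#'   is reversed (returned toward the control mean) in every treatment group.
#' @param effect_log2fc planted absolute log2 fold change of DE transcripts.
#' @param noise_sd per-observation Gaussian noise sd on the log2 scale;
#'   0 is allowed and gives the exact zero-noise limit.
#' @param probe_effect_sd sd of the per-probe additive offset (drawn once per
#'   probe and shared across samples, the additive model median polish fits).
#' @param baseline_mean,baseline_sd mean/sd of per-transcript baseline
#'   abundance on the log2 scale.
#' @param reversal_magnitude fraction of the disease shift undone in treated
#'   groups for reversed transcripts; 1 = full return to the control mean.
#' @param rng_seed integer seed; all randomness flows from it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 2000,
                       probes_per_transcript = 11,
                       groups = c(NOR = 4L, DIA = 4L, TRT1 = 4L, TRT2 = 4L),
                       frac_de = 0.10,
                       frac_counterreg = 0.5,
                       effect_log2fc = 2,
                       noise_sd = 0.25,
                       probe_effect_sd = 0.5,
                       baseline_mean = 8,
                       baseline_sd = 1.5,
                       reversal_magnitude = 1,
                       rng_seed = 1L) {
  chk <- function(ok, field, msg) if (!ok) stop("invalid sim_config field '",
                                                field, "': ", msg)
  chk(is.numeric(n_transcripts) && n_transcripts >= 1, "n_transcripts", ">= 1 required")
  chk(is.numeric(probes_per_transcript) && probes_per_transcript >= 1,
      "probes_per_transcript", ">= 1 required")
  chk(length(groups) >= 2 && !is.null(names(groups)) && all(nzchar(names(groups))),
      "groups", "at least two named groups required")
  chk(all(groups >= 2), "groups", "replicate counts must be >= 2")
  chk(frac_de >= 0 && frac_de <= 1, "frac_de", "must be in [0,1]")
  chk(frac_counterreg >= 0 && frac_counterreg <= 1, "frac_counterreg", "must be in [0,1]")
  chk(effect_log2fc >= 0, "effect_log2fc", "must be >= 0")
  chk(noise_sd >= 0, "noise_sd", "must be >= 0")
  chk(probe_effect_sd >= 0, "probe_effect_sd", "must be >= 0")
  chk(reversal_magnitude >= 0 && reversal_magnitude <= 1,
      "reversal_magnitude", "must be in [0,1]")
  chk(is.numeric(rng_seed) && length(rng_seed) == 1, "rng_seed", "single integer required")
  structure(list(n_transcripts = as.integer(n_transcripts),
                 probes_per_transcript = as.integer(probes_per_transcript),
                 groups = vapply(groups, as.integer, 1L),
                 frac_de = frac_de, frac_counterreg = frac_counterreg,
                 effect_log2fc = effect_log2fc, noise_sd = noise_sd,
                 probe_effect_sd = probe_effect_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 reversal_magnitude = reversal_magnitude,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' Simulate probe-level expression with planted ground truth
#'
#' Model: `log2 intensity = baseline(transcript) + probe_offset + group_shift
#' + noise`. Planted DE transcripts are shifted by `+/- effect_log2fc` in the
#' disease group relative to control; planted counter-regulated transcripts
#' have that shift undone (by `reversal_magnitude`) in every treatment group,
#' i.e. the treatment-vs-disease change has the opposite sign of the
#' disease-vs-control change. Non-reversed DE transcripts retain their disease
#' shift under treatment.
#'
#' @param config a [sim_config()].
#' @return list with elements `probes` (a [probe_matrix()]) and `truth`, a
#'   list of class `sim_truth` with fields `de_ids`, `de_direction` (named
#'   +1/-1), `counterreg_sets` (per-treatment list of transcript ids, all
#'   subsets of `de_ids`) and `rng_seed`.
#' @export
simulate_expression <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  n <- config$n_transcripts
  ppt <- config$probes_per_transcript
  tx <- sprintf("TX%05d", seq_len(n))
  groups <- config$groups
  grp_labels <- rep(names(groups), groups)
  sample_ids <- paste0(grp_labels, "_", unlist(lapply(groups, seq_len)))
  n_samp <- length(sample_ids)

  baseline <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
  n_de <- round(config$frac_de * n)
  de_ids <- if (n_de > 0) sort(sample(tx, n_de)) else character()
  de_dir <- stats::setNames(sample(c(-1, 1), n_de, replace = TRUE), de_ids)
  n_cr <- round(config$frac_counterreg * n_de)
  cr_ids <- if (n_cr > 0) sort(sample(de_ids, n_cr)) else character()
  treatments <- names(groups)[-(1:2)]
  counterreg_sets <- stats::setNames(rep(list(cr_ids), length(treatments)),
                                     treatments)

  # per-transcript shift for each group: control 0; disease +/-effect for DE;
  # treatments keep the disease shift except for reversed transcripts
  shift <- matrix(0, n, length(groups), dimnames = list(tx, names(groups)))
  if (n_de > 0) {
    shift[de_ids, 2L] <- de_dir * config$effect_log2fc
    for (trt in treatments) {
      shift[de_ids, trt] <- de_dir * config$effect_log2fc
      if (length(cr_ids))
        shift[cr_ids, trt] <- shift[cr_ids, trt] -
          config$reversal_magnitude * de_dir[cr_ids] * config$effect_log2fc
    }
  }

  probe_ids <- paste0(rep(tx, each = ppt), "_p", sprintf("%02d", seq_len(ppt)))
  probe_offset <- stats::rnorm(n * ppt, 0, config$probe_effect_sd)
  base_probe <- rep(baseline, each = ppt) + probe_offset
  shift_probe <- shift[rep(seq_len(n), each = ppt), match(grp_labels, names(groups)),
                       drop = FALSE]
  noise <- matrix(stats::rnorm(n * ppt * n_samp, 0, config$noise_sd),
                  n * ppt, n_samp)
  vals <- base_probe + shift_probe + noise
  dimnames(vals) <- list(probe_ids, sample_ids)

  pm <- probe_matrix(vals, rep(tx, each = ppt), grp_labels)
  truth <- structure(list(de_ids = de_ids, de_direction = de_dir,
                          counterreg_sets = counterreg_sets,
                          rng_seed = config$rng_seed),
                     class = "sim_truth")
  list(probes = pm, truth = truth)
}

#' Network simulation configuration
#'
#' @param n_background_nodes number of non-signature background genes.
#' @param background_degree_param target mean degree of the background
#'   Erdos-Renyi wiring over signature + background nodes.
#' @param hub_target_fraction fraction of signature genes wired to the
#'   planted hub.
#' @param hub_name symbol used for the planted hub node.
#' @param rng_seed integer seed.
#' @return validated list of class `net_sim_config`.
#' @export
net_sim_config <- function(n_background_nodes = 500,
                           background_degree_param = 4,
                           hub_target_fraction = 0.5,
                           hub_name = "HUB1",
                           rng_seed = 1L) {
  chk <- function(ok, field, msg) if (!ok) stop("invalid net_sim_config field '",
                                                field, "': ", msg)
  chk(n_background_nodes >= 0, "n_background_nodes", "must be >= 0")
  chk(background_degree_param >= 0, "background_degree_param", "must be >= 0")
  chk(hub_target_fraction >= 0 && hub_target_fraction <= 1,
      "hub_target_fraction", "must be in [0,1]")
  chk(is.character(hub_name) && nzchar(hub_name), "hub_name", "non-empty string")
  structure(list(n_background_nodes = as.integer(n_background_nodes),
                 background_degree_param = background_degree_param,
                 hub_target_fraction = hub_target_fraction,
                 hub_name = hub_name, rng_seed = as.integer(rng_seed)),
            class = "net_sim_config")
}

#' Simulate an interaction network with a planted hub
#'
#' Builds an undirected simple graph over the signature genes plus background
#' nodes: background wiring is Erdos-Renyi with the stated mean degree, and a
#' single designated hub is attached to `round(hub_target_fraction *
#' length(sig_genes))` signature genes. The hub is made the unique
#' maximum-degree node by construction (background edges of any competitor
#' are dropped).
#'
#' @param sig_genes nonempty character vector of signature gene symbols.
#' @param config a [net_sim_config()].
#' @return list with elements `network` (an `interaction_network`), `hub`
#'   (hub symbol), `hub_targets` (signature genes wired to the hub) and
#'   `hub_target_fraction` (realized fraction).
#' @export
simulate_network <- function(sig_genes, config = net_sim_config()) {
  stopifnot(inherits(config, "net_sim_config"))
  sig_genes <- unique(as.character(sig_genes))
  if (!length(sig_genes)) stop("'sig_genes' must be nonempty")
  set.seed(config$rng_seed)
  hub <- config$hub_name
  if (hub %in% sig_genes) stop("hub_name collides with a signature gene")
  bg <- if (config$n_background_nodes > 0)
    sprintf("BG%05d", seq_len(config$n_background_nodes)) else character()
  nodes <- c(sig_genes, bg)

  n_attach <- round(config$hub_target_fraction * length(sig_genes))
  if (n_attach < 1) {
    warning("hub_target_fraction x |sig_genes| < 1; attaching hub to 1 gene")
    n_attach <- 1L
  }
  hub_targets <- sort(sample(sig_genes, n_attach))

  # background wiring: G(n, p) over non-hub nodes at the stated mean degree
  nn <- length(nodes)
  edge_df <- data.frame(V1 = character(), V2 = character(),
                        stringsAsFactors = FALSE)
  if (nn >= 2 && config$background_degree_param > 0) {
    p <- min(1, config$background_degree_param / (nn - 1))
    pairs <- utils::combn(nn, 2)
    keep <- stats::runif(ncol(pairs)) < p
    edge_df <- data.frame(V1 = nodes[pairs[1, keep]], V2 = nodes[pairs[2, keep]],
                          stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    d = rbind(edge_df,
              data.frame(V1 = hub, V2 = hub_targets, stringsAsFactors = FALSE)),
    directed = FALSE,
    vertices = data.frame(name = c(nodes, hub), stringsAsFactors = FALSE))
  g <- igraph::simplify(g)

  # enforce unique maximum degree at the hub: drop background edges of any
  # node that reaches the hub's degree (edges to the hub itself are kept, so
  # with hub degree 1 uniqueness is unattainable and flagged instead)
  hub_deg <- igraph::degree(g, hub)
  repeat {
    deg <- igraph::degree(g)
    rival <- names(deg)[deg >= hub_deg & names(deg) != hub]
    if (!length(rival)) break
    dropped <- FALSE
    for (r in rival) {
      eid <- as.integer(igraph::incident(g, r))
      end <- igraph::ends(g, eid)
      drop_n <- igraph::degree(g, r) - hub_deg + 1L
      cand <- eid[end[, 1] != hub & end[, 2] != hub]
      if (!length(cand)) next
      dropped <- TRUE
      g <- igraph::delete_edges(g, cand[seq_len(min(drop_n, length(cand)))])
    }
    if (!dropped) {
      warning("hub degree too small for a unique maximum (degenerate graph)")
      break
    }
  }

  list(network = interaction_network(g),
       hub = hub,
       hub_targets = hub_targets,
       hub_target_fraction = n_attach / length(sig_genes))
}

#' Write simulation truth tables as TSV
#' @param truth a `sim_truth`.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_sim_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  de_path <- file.path(dir, "truth_de.tsv")
  utils::write.table(
    data.frame(transcript_id = truth$de_ids,
               direction = unname(truth$de_direction[truth$de_ids])),
    de_path, sep = "\t", quote = FALSE, row.names = FALSE)
  cr_path <- file.path(dir, "truth_counterreg.tsv")
  cr <- do.call(rbind, lapply(names(truth$counterreg_sets), function(trt)
    if (length(truth$counterreg_sets[[trt]]))
      data.frame(treatment = trt, transcript_id = truth$counterreg_sets[[trt]])
    else NULL))
  if (is.null(cr)) cr <- data.frame(treatment = character(),
                                    transcript_id = character())
  utils::write.table(cr, cr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(de_path, cr_path))
}
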