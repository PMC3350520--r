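# Network stage: an open, documented surrogate for proprietary
# knowledge-base network tools. Subnetworks are grown greedily around
# signature seeds over a user-supplied interaction graph, scored by the
# hypergeometric (Fisher exact) enrichment of signature genes among their
# members, merged, and mined for focus hubs by degree of connectivity.

#' Interaction network container
#'
#' An undirected simple graph of gene symbols plus the size of the gene
#' universe used as the denominator of enrichment tests.
#'
#' @param graph an igraph undirected graph (simplified on construction), or a
#'   two-column character matrix/data.frame of edges.
#' @param universe_size number of genes eligible for subnetwork membership in
#'   the enrichment null; defaults to the node count.
#' @return object of class `interaction_network` with elements `graph` and
#'   `universe_size`.
#' @export
interaction_network <- function(graph, universe_size = NULL) {
  if (!igraph::is_igraph(graph)) {
    graph <- igraph::graph_from_data_frame(as.data.frame(graph),
                                           directed = FALSE)
  }
  if (igraph::is_directed(graph)) graph <- igraph::as_undirected(graph)
  graph <- igraph::simplify(graph)
  if (is.null(universe_size)) universe_size <- igraph::vcount(graph)
  if (universe_size < igraph::vcount(graph))
    stop("universe_size smaller than the node count")
  structure(list(graph = graph, universe_size = as.integer(universe_size)),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network: %d nodes, %d edges (universe %d)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$universe_size))
  invisible(x)
}

#' Node symbols of an interaction network
#' @param net an `interaction_network`.
#' @return character vector of node names.
#' @export
network_nodes <- function(net) igraph::V(net$graph)$name

#' Read an interaction network from a SIF or two-column TSV edge list
#'
#' SIF lines are `nodeA<TAB>relation<TAB>nodeB [nodeC ...]`; the relation
#' label is ignored (edges are undirected and unlabeled). TSV lines are
#' `nodeA<TAB>nodeB`. Symbols are case-preserving; duplicate edges (either
#' orientation) are collapsed and self-loops dropped with a message.
#'
#' @param path file path.
#' @param format `"sif"`, `"tsv"`, or `"auto"` (by extension, default).
#' @param universe_size optional enrichment universe override.
#' @return an `interaction_network`.
#' @export
read_edge_list <- function(path, format = c("auto", "sif", "tsv"),
                           universe_size = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("network file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sif = "sif", tsv = "tsv", txt = "tsv",
                     stop("cannot infer network format from extension '",
                          ext, "'; pass format explicitly"))
  }
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  from <- character(); to <- character()
  for (i in seq_along(lines)) {
    tok <- strsplit(lines[i], "[\t ]+")[[1]]
    tok <- tok[nzchar(tok)]
    if (format == "sif") {
      if (length(tok) == 1) next            # isolated node, allowed by SIF
      if (length(tok) < 3)
        stop("malformed SIF line ", line_no[i], ": ", lines[i])
      from <- c(from, rep(tok[1], length(tok) - 2))
      to <- c(to, tok[3:length(tok)])
    } else {
      if (length(tok) != 2)
        stop("malformed TSV edge line ", line_no[i], ": ", lines[i])
      from <- c(from, tok[1]); to <- c(to, tok[2])
    }
  }
  self <- from == to
  if (any(self))
    message("read_edge_list: dropped ", sum(self), " self-loop(s)")
  net <- interaction_network(cbind(from[!self], to[!self]))
  if (!is.null(universe_size)) net$universe_size <- as.integer(universe_size)
  net
}

#' Write a network as SIF
#' @param net an `interaction_network`.
#' @param path output path; each edge is written once as
#'   `nodeA<TAB>interacts<TAB>nodeB` with endpoints in sorted order.
#' @return invisibly, `path`.
#' @export
write_network_sif <- function(net, path) {
  e <- igraph::as_edgelist(net$graph)
  if (nrow(e)) {
    e <- t(apply(e, 1, sort))
    e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  }
  writeLines(if (nrow(e)) paste(e[, 1], "interacts", e[, 2], sep = "\t")
             else character(), path)
  invisible(path)
}

#' Score a subnetwork by hypergeometric signature enrichment
#'
#' `p` is the upper-tail probability of observing at least the realized
#' number of signature genes among `|members|` draws (without replacement)
#' from a universe of `universe_size` genes containing the signature genes
#' present in the network; the score is `-log10(p)`, so higher = more
#' significantly enriched.
#'
#' @param members character vector of subnetwork member nodes.
#' @param signature character vector of signature gene symbols (or a
#'   [signature_set()]).
#' @param net the parent `interaction_network`.
#' @return numeric score, >= 0.
#' @export
score_subnetwork <- function(members, signature, net) {
  if (inherits(signature, "signature_set")) signature <- signature_ids(signature)
  nodes <- network_nodes(net)
  m <- length(intersect(signature, nodes))  # signature genes in the universe
  size <- length(members)
  x <- length(intersect(members, signature))
  N <- net$universe_size
  if (size > N || m > N || x > min(m, size))
    stop("inconsistent counts: |subnet| = ", size, ", |signature| = ", m,
         ", overlap = ", x, ", universe = ", N)
  p <- stats::phyper(x - 1, m, N - m, size, lower.tail = FALSE)
  max(0, -log10(p))
}

#' Grow signature-seeded subnetworks
#'
#' Repeats until every signature gene present in the network is assigned:
#' seed a new subnetwork at the unassigned signature gene of highest degree,
#' then greedily add connected candidates until `max_size` members or no
#' connected candidate remains. Candidate priority: unassigned signature
#' genes first (the subnetworks are built around the signature), then most
#' edges into the current member set, then lexicographic. Non-signature
#' connector ("white") nodes are only recruited when no signature gene is
#' connected; they may appear in several subnetworks, while each signature
#' gene belongs to at most one.
#'
#' @param net an `interaction_network`.
#' @param signature a [signature_set()] or character vector of gene symbols.
#' @param max_size maximum members per subnetwork (default 35).
#' @return list of subnetworks, each a list with `members`,
#'   `n_signature_members`, `score`; ordered by score descending (ties by
#'   more signature members, then by seed symbol).
#' @export
build_seeded_subnetworks <- function(net, signature, max_size = 35L) {
  if (inherits(signature, "signature_set")) signature <- signature_ids(signature)
  if (igraph::vcount(net$graph) == 0) stop("network is empty")
  nodes <- network_nodes(net)
  sig_in <- intersect(signature, nodes)
  if (!length(sig_in)) {
    warning("no signature gene present in the network")
    return(list())
  }
  deg <- igraph::degree(net$graph)
  adj <- igraph::adjacent_vertices(net$graph, igraph::V(net$graph))
  adj <- lapply(adj, function(v) nodes[as.integer(v)])
  names(adj) <- nodes

  assigned <- character()
  subnets <- list()
  unassigned <- sig_in[order(-deg[sig_in], sig_in)]
  while (length(unassigned)) {
    seed <- unassigned[1]
    members <- seed
    repeat {
      if (length(members) >= max_size) break
      cand <- setdiff(unique(unlist(adj[members], use.names = FALSE)), members)
      # signature genes already claimed by an earlier subnetwork stay out
      cand <- cand[!(cand %in% sig_in) | !(cand %in% assigned)]
      if (!length(cand)) break
      sig_cand <- cand[cand %in% sig_in]
      if (length(sig_cand)) cand <- sig_cand
      n_edges <- vapply(cand, function(v) sum(adj[[v]] %in% members), 0L)
      best <- sort(cand[n_edges == max(n_edges)])
      members <- c(members, best[1])
    }
    new_sig <- intersect(members, sig_in)
    assigned <- c(assigned, new_sig)
    unassigned <- setdiff(unassigned, new_sig)
    subnets[[length(subnets) + 1]] <- list(
      seed = seed,
      members = sort(members),
      n_signature_members = length(new_sig),
      score = score_subnetwork(members, sig_in, net))
  }
  ord <- order(-vapply(subnets, `[[`, 0, "score"),
               -vapply(subnets, `[[`, 0L, "n_signature_members"),
               vapply(subnets, `[[`, "", "seed"))
  subnets[ord]
}

#' Merge the top-scoring subnetworks into one network
#'
#' Keeps subnetworks with `score >= min_score`, takes the `n_top` best by
#' score, and returns the parent-network subgraph induced on the union of
#' their members.
#'
#' @param subnets list from [build_seeded_subnetworks()].
#' @param net the parent `interaction_network`.
#' @param n_top number of top networks to merge (default 7).
#' @param min_score score threshold (default 15).
#' @return an `interaction_network` (the merged subgraph; the enrichment
#'   universe is inherited from the parent). Empty with a warning when no
#'   subnetwork passes.
#' @export
merge_top_networks <- function(subnets, net, n_top = 7L, min_score = 15) {
  scores <- vapply(subnets, `[[`, 0, "score")
  keep <- subnets[scores >= min_score]
  if (!length(keep)) {
    warning("no subnetwork reaches min_score = ", min_score)
    return(interaction_network(igraph::make_empty_graph(0, directed = FALSE),
                               universe_size = net$universe_size))
  }
  keep <- keep[order(-vapply(keep, `[[`, 0, "score"),
                     -vapply(keep, `[[`, 0L, "n_signature_members"),
                     vapply(keep, `[[`, "", "seed"))]
  keep <- keep[seq_len(min(n_top, length(keep)))]
  members <- sort(unique(unlist(lapply(keep, `[[`, "members"))))
  sub <- igraph::induced_subgraph(net$graph, members)
  interaction_network(sub, universe_size = net$universe_size)
}

#' Rank focus hubs by degree of connectivity in the merged network
#'
#' Degree of connectivity is the number of distinct interaction partners a
#' node has within the merged network. The signature-connection fraction is
#' the percentage of signature genes present in the merged network adjacent
#' to the node.
#'
#' @param merged an `interaction_network` (e.g. from [merge_top_networks()]).
#' @param signature a [signature_set()] or character vector of gene symbols.
#' @param n_top number of top hubs to report (default 20); `Inf` for all.
#' @return data.frame (class `hub_table`) with columns `node`, `degree`,
#'   `signature_fraction` (percent) and `rank` (1..N, degree descending, ties
#'   lexicographic).
#' @export
rank_hubs <- function(merged, signature, n_top = 20L) {
  if (inherits(signature, "signature_set")) signature <- signature_ids(signature)
  nodes <- network_nodes(merged)
  if (!length(nodes)) stop("merged network is empty")
  deg <- igraph::degree(merged$graph)
  sig_m <- intersect(signature, nodes)
  frac <- if (length(sig_m)) {
    vapply(nodes, function(v) {
      nb <- igraph::neighbors(merged$graph, v)$name
      100 * length(intersect(nb, sig_m)) / length(sig_m)
    }, 0)
  } else stats::setNames(rep(NA_real_, length(nodes)), nodes)
  ord <- order(-deg[nodes], nodes)
  tab <- data.frame(node = nodes[ord],
                    degree = unname(deg[nodes][ord]),
                    signature_fraction = unname(frac[nodes][ord]),
                    rank = seq_along(nodes),
                    stringsAsFactors = FALSE)
  tab <- utils::head(tab, n_top)
  rownames(tab) <- NULL
  class(tab) <- c("hub_table", "data.frame")
  tab
}

#' Write subnetwork membership and scores as TSV
#' @param subnets list from [build_seeded_subnetworks()].
#' @param path output path; one row per (subnetwork, member).
#' @return invisibly, `path`.
#' @export
write_subnetworks <- function(subnets, path) {
  df <- do.call(rbind, lapply(seq_along(subnets), function(i) {
    s <- subnets[[i]]
    data.frame(subnetwork = i, seed = s$seed, score = s$score,
               n_signature_members = s$n_signature_members,
               member = s$members, stringsAsFactors = FALSE)
  }))
  if (is.null(df)) df <- data.frame(subnetwork = integer(), seed = character(),
                                    score = numeric(),
                                    n_signature_members = integer(),
                                    member = character())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
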