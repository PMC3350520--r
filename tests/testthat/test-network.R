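test_that("edge-list readers honor the format contracts", {
  d <- withr::local_tempdir()
  sif <- file.path(d, "net.sif")
  writeLines(c("TNF\tinteracts\tNFKB1",
               "NFKB1\tinteracts\tTNF",      # duplicate, other orientation
               "TNF\tinteracts\tTNF",        # self-loop
               "IL6\tinteracts\tTNF\tSTAT3"  # multi-target SIF line
  ), sif)
  expect_message(net <- read_edge_list(sif), "1 self-loop")
  expect_setequal(network_nodes(net), c("TNF", "NFKB1", "IL6", "STAT3"))
  expect_equal(igraph::ecount(net$graph), 3)  # TNF-NFKB1, IL6-TNF, IL6-STAT3
  expect_false(igraph::any_loop(net$graph))

  tsv <- file.path(d, "net.tsv")
  writeLines(c("A\tB", "B\tA", "A\tC"), tsv)
  net2 <- read_edge_list(tsv)
  expect_equal(igraph::ecount(net2$graph), 2)

  writeLines(c("A\tB", "oops"), tsv)
  expect_error(read_edge_list(tsv), "line 2")
  writeLines("A\tinteracts", sif)
  expect_error(read_edge_list(sif), "line 1")
  expect_error(read_edge_list(file.path(d, "nope.sif")), "not found")
})

test_that("SIF writer round-trips through the reader", {
  net <- star_network()
  d <- withr::local_tempdir()
  p <- file.path(d, "out.sif")
  write_network_sif(net, p)
  back <- read_edge_list(p)
  expect_setequal(network_nodes(back), network_nodes(net))
  expect_equal(igraph::ecount(back$graph), igraph::ecount(net$graph))
})

test_that("subnetwork score matches the exhaustive combinatorial oracle", {
  # universe 20, signature 5, subnet exactly the 5 signature genes:
  # p = 1 / choose(20, 5)
  nodes <- sprintf("N%02d", 1:20)
  ring <- interaction_network(cbind(nodes, nodes[c(2:20, 1)]))
  sig <- nodes[1:5]
  s <- score_subnetwork(nodes[1:5], sig, ring)
  expect_equal(s, -log10(1 / choose(20, 5)), tolerance = 1e-9)

  # exhaustive enumeration over all draws for several configurations
  for (cfg in list(c(N = 12, m = 4, n = 6, x = 2), c(N = 20, m = 5, n = 8, x = 3),
                   c(N = 25, m = 10, n = 5, x = 4))) {
    N <- cfg[["N"]]; m <- cfg[["m"]]; n <- cfg[["n"]]; x <- cfg[["x"]]
    p_exhaustive <- sum(vapply(x:min(m, n), function(i)
      choose(m, i) * choose(N - m, n - i), 0)) / choose(N, n)
    big <- interaction_network(
      igraph::make_ring(N), universe_size = N)
    igraph::V(big$graph)$name <- sprintf("V%02d", 1:N)
    members <- c(sprintf("V%02d", 1:x),                 # x signature members
                 sprintf("V%02d", (m + 1):(m + n - x))) # rest non-signature
    sigv <- sprintf("V%02d", 1:m)
    expect_equal(score_subnetwork(members, sigv, big),
                 -log10(p_exhaustive), tolerance = 1e-9)
  }
})

test_that("score is ~0 for null overlap and monotone in dilution", {
  nodes <- sprintf("N%02d", 1:20)
  net <- interaction_network(cbind(nodes, nodes[c(2:20, 1)]))
  sig <- nodes[1:5]
  expect_lt(score_subnetwork(nodes[10:14], sig, net), 0.5)
  # adding a non-signature node never increases the score
  s1 <- score_subnetwork(c(nodes[1:3], nodes[10]), sig, net)
  s2 <- score_subnetwork(c(nodes[1:3], nodes[10:11]), sig, net)
  expect_lte(s2, s1)
  expect_error(score_subnetwork(rep(nodes, 2), sig, net), "inconsistent")
})

test_that("seeded growth covers the signature and absorbs connectors", {
  # star of 10 signature leaves around one non-signature center
  leaves <- sprintf("S%02d", 1:10)
  net <- star_network("WHITE", leaves)
  subs <- build_seeded_subnetworks(net, leaves, max_size = 11)
  expect_length(subs, 1)
  expect_setequal(subs[[1]]$members, c("WHITE", leaves))
  expect_equal(subs[[1]]$n_signature_members, 10)

  # isolated signature node forms a singleton subnetwork
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(c("LONER", "A", "B")) + igraph::edges(c("A", "B"))
  net2 <- interaction_network(g)
  subs2 <- build_seeded_subnetworks(net2, "LONER")
  expect_length(subs2, 1)
  expect_identical(subs2[[1]]$members, "LONER")
  expect_equal(subs2[[1]]$n_signature_members, 1)

  # no signature gene in the graph -> empty list with warning
  expect_warning(out <- build_seeded_subnetworks(net2, "ZZZ"), "no signature")
  expect_length(out, 0)
})

test_that("every signature gene lands in exactly one subnetwork", {
  sig <- sprintf("G%03d", 1:60)
  ns <- simulate_network(sig, net_sim_config(n_background_nodes = 120,
                                             hub_target_fraction = 0.4,
                                             rng_seed = 31))
  subs <- build_seeded_subnetworks(ns$network, sig, max_size = 20)
  counts <- table(unlist(lapply(subs, function(s) intersect(s$members, sig))))
  expect_setequal(names(counts), sig)
  expect_true(all(counts == 1))
  expect_true(all(vapply(subs, function(s) length(s$members) <= 20, TRUE)))
})

test_that("merging follows union arithmetic and the score filter", {
  nodes <- sprintf("N%02d", 1:30)
  net <- interaction_network(cbind(nodes, nodes[c(2:30, 1)]))
  mk <- function(members, score) list(seed = members[1], members = members,
                                      n_signature_members = length(members),
                                      score = score)
  # disjoint union
  m1 <- merge_top_networks(list(mk(nodes[1:10], 20), mk(nodes[11:18], 18)),
                           net, n_top = 7, min_score = 15)
  expect_equal(igraph::vcount(m1$graph), 18)
  # overlap: sizes 10 and 8 sharing 3 nodes -> 15
  m2 <- merge_top_networks(list(mk(nodes[1:10], 20), mk(nodes[8:15], 18)),
                           net, n_top = 7, min_score = 15)
  expect_equal(igraph::vcount(m2$graph), 15)
  # idempotence: a subnetwork merged with itself
  m3 <- merge_top_networks(list(mk(nodes[1:10], 20), mk(nodes[1:10], 20)),
                           net, n_top = 7, min_score = 15)
  expect_setequal(network_nodes(m3), nodes[1:10])
  # score filter and n_top
  m4 <- merge_top_networks(list(mk(nodes[1:10], 20), mk(nodes[11:18], 3)),
                           net, n_top = 7, min_score = 15)
  expect_setequal(network_nodes(m4), nodes[1:10])
  expect_warning(m5 <- merge_top_networks(list(mk(nodes[1:5], 2)), net),
                 "min_score")
  expect_equal(igraph::vcount(m5$graph), 0)
})

test_that("hub ranking reports degree, fraction and gapless ranks", {
  leaves <- sprintf("S%02d", 1:9)
  net <- star_network("C", leaves)
  hubs <- rank_hubs(net, leaves)
  expect_identical(hubs$node[1], "C")
  expect_equal(hubs$degree[1], 9)
  expect_equal(hubs$signature_fraction[1], 100)
  expect_identical(hubs$rank, seq_len(nrow(hubs)))

  # hub adjacent to 6 of 12 signature genes present -> 50%
  sig12 <- sprintf("S%02d", 1:12)
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(c("H", sig12)) +
    igraph::edges(as.vector(rbind("H", sig12[1:6]))) +
    igraph::edges(c("S07", "S08", "S09", "S10", "S11", "S12"))
  h2 <- rank_hubs(interaction_network(g), sig12)
  expect_equal(h2$signature_fraction[h2$node == "H"], 50)
})

test_that("hub ranking is invariant to node relabeling", {
  sig <- sprintf("G%02d", 1:25)
  ns <- simulate_network(sig, net_sim_config(n_background_nodes = 40,
                                             hub_target_fraction = 0.6,
                                             rng_seed = 77))
  hubs <- rank_hubs(ns$network, sig, n_top = Inf)
  # relabel every node with a prefix; ranking must map along
  g2 <- ns$network$graph
  igraph::V(g2)$name <- paste0("x_", igraph::V(g2)$name)
  hubs2 <- rank_hubs(interaction_network(g2), paste0("x_", sig), n_top = Inf)
  expect_identical(paste0("x_", hubs$node), hubs2$node)
  expect_equal(hubs$degree, hubs2$degree)
  expect_equal(hubs$signature_fraction, hubs2$signature_fraction)
})

test_that("planted hub is recovered at rank 1 through the full network path", {
  for (seed in c(7, 8, 9)) {
    sig <- sprintf("G%03d", 1:100)
    ns <- simulate_network(sig, net_sim_config(n_background_nodes = 300,
                                               hub_target_fraction = 0.53,
                                               rng_seed = seed))
    subs <- build_seeded_subnetworks(ns$network, sig)
    # hub sits in the top-scoring subnetwork
    expect_true(ns$hub %in% subs[[1]]$members)
    merged <- merge_top_networks(subs, ns$network, n_top = 7, min_score = 15)
    hubs <- rank_hubs(merged, sig)
    expect_identical(hubs$node[1], ns$hub)
    # on the planted graph the wiring fraction is exact
    full <- rank_hubs(ns$network, sig)
    expect_identical(full$node[1], ns$hub)
    expect_equal(full$signature_fraction[1], 53)
  }
})
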