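write_edges <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}

test_that("edge-list loading merges orientations, thresholds, and drops loops", {
  path <- write_edges(c("protein1 protein2 combined_score",
                        "A B 700", "B A 900", "A A 950", "B C 150", "C D 700"))
  g <- load_network(path, min_score = 400)
  expect_equal(igraph::ecount(g), 2L)  # A-B merged, loop and low-score gone
  ab <- igraph::E(g)[igraph::V(g)["A"] %--% igraph::V(g)["B"]]
  expect_equal(ab$score, 900)         # max of the two orientations
  expect_warning(empty <- load_network(write_edges(character(0))), "empty")
  expect_equal(igraph::vcount(empty), 0L)
  expect_error(load_network(write_edges(c("A B 700", "A B"))), "line 2")
  expect_error(load_network(write_edges("A B x")), "line 1")
})

test_that("edge lists round-trip through the STRING-style writer", {
  cfg <- small_config(network_model = "planted_hub", n_planted_hubs = 1L)
  net <- generate_network(cfg)
  path <- tempfile()
  write_network(net$network, path)
  g2 <- load_network(path, min_score = 0)
  expect_equal(igraph::ecount(g2), igraph::ecount(net$network))
  expect_setequal(igraph::V(g2)$name, igraph::V(net$network)$name[
    igraph::degree(net$network) > 0])
})

test_that("eigenvector centrality matches the star and complete-graph closed forms", {
  star <- igraph::make_star(4, mode = "undirected")
  igraph::V(star)$name <- c("hub", "l1", "l2", "l3")
  cent <- eigenvector_centrality(star)
  expect_equal(unname(cent["hub"]), 1 / sqrt(2), tolerance = 1e-8)
  expect_equal(unname(cent[c("l1", "l2", "l3")]), rep(1 / sqrt(6), 3),
               tolerance = 1e-8)
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  expect_equal(as.numeric(eigenvector_centrality(k4)), rep(0.5, 4),
               tolerance = 1e-8)
})

test_that("centrality is unit-norm, non-negative, label-invariant, and agrees with igraph", {
  set.seed(21)
  g <- igraph::sample_gnp(60, 0.08)
  igraph::V(g)$name <- sprintf("v%02d", 1:60)
  cent <- eigenvector_centrality(g)
  expect_true(all(cent >= 0))
  expect_equal(sum(cent^2), 1, tolerance = 1e-10)
  # independent route: igraph's solver, rescaled to unit Euclidean norm
  ref <- igraph::eigen_centrality(g)$vector
  ref <- ref / sqrt(sum(ref^2))
  expect_equal(as.numeric(cent), as.numeric(ref[names(cent)]), tolerance = 1e-6)
  # relabeling nodes permutes but does not change values
  perm <- sample(60)
  g2 <- igraph::permute(g, perm)
  cent2 <- eigenvector_centrality(g2)
  expect_equal(cent2[names(cent)], cent, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("a planted hub attains the maximum centrality", {
  cfg <- synthetic_config(n_proteins_total = 100L, n_detected = 30L,
                          network_model = "planted_hub", n_planted_hubs = 1L,
                          seed = 8L)
  net <- generate_network(cfg)
  cent <- eigenvector_centrality(net$network)
  expect_equal(names(which.max(cent)), net$truth$hub_ids)
})

test_that("the calibrated subnetwork keeps full-network centrality values exactly", {
  set.seed(13)
  g <- igraph::sample_gnp(40, 0.1)
  igraph::V(g)$name <- sprintf("p%02d", 1:40)
  cent <- eigenvector_centrality(g)
  ids <- sample(igraph::V(g)$name, 15)
  calib <- calibrated_subnetwork(g, cent, ids)
  expect_identical(as.numeric(calib$centrality),
                   as.numeric(cent[names(calib$centrality)]))
  expect_setequal(igraph::V(calib$subnetwork)$name, ids)
  # full subset returns the whole network
  all_sub <- calibrated_subnetwork(g, cent, igraph::V(g)$name)
  expect_equal(igraph::ecount(all_sub$subnetwork), igraph::ecount(g))
  # unknown ids are reported and dropped; empty intersection errors
  expect_message(dropped <- calibrated_subnetwork(g, cent, c(ids[1], "zzz")),
                 "absent")
  expect_equal(dropped$missing_ids, "zzz")
  expect_error(calibrated_subnetwork(g, cent, "zzz"), "no detected ids")
})

test_that("detected hubs raise the subnetwork mean centrality above the full mean", {
  cfg <- synthetic_config(n_proteins_total = 200L, n_detected = 40L,
                          network_model = "planted_hub", n_planted_hubs = 3L,
                          seed = 4L)
  net <- generate_network(cfg)
  cent <- eigenvector_centrality(net$network)
  calib <- calibrated_subnetwork(net$network, cent, detected_ids(cfg))
  expect_gt(mean(calib$centrality), mean(cent))
})

test_that("Louvain recovers the exhaustive modularity optimum on two bridged cliques", {
  g <- two_cliques_graph()
  oracle <- exhaustive_best_partition(g)
  part <- louvain_partition(g, seed = 1)
  expect_equal(canonical_partition(part$membership),
               canonical_partition(oracle$membership))
  expect_equal(part$modularity, oracle$modularity, tolerance = 1e-12)
  expect_equal(part$n_communities, 2L)
})

test_that("Louvain is deterministic, bounded below by singletons, and guards edge cases", {
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  expect_equal(louvain_partition(k5, seed = 0)$n_communities, 1L)
  g <- two_cliques_graph()
  p1 <- louvain_partition(g, seed = 3)
  p2 <- louvain_partition(g, seed = 3)
  expect_identical(p1, p2)
  singleton_q <- igraph::modularity(g, seq_len(igraph::vcount(g)))
  expect_gte(p1$modularity, singleton_q)
  expect_error(louvain_partition(igraph::make_empty_graph(3, directed = FALSE)),
               "edgeless")
})

test_that("only the largest connected component is partitioned", {
  g <- two_cliques_graph()
  g <- igraph::add_vertices(g, 3)
  igraph::V(g)$name <- paste0("m", 1:11)
  g <- igraph::add_edges(g, c("m9", "m10", "m10", "m11", "m9", "m11"))
  part <- louvain_partition(g, seed = 0)
  expect_equal(sort(names(part$membership)), paste0("m", 1:8))
})

test_that("community centrality profiles summarize each community's distribution", {
  g <- two_cliques_graph()
  cent <- eigenvector_centrality(g)
  part <- louvain_partition(g, seed = 0)
  prof <- community_centrality_profile(part, cent)
  expect_equal(nrow(prof), 2L)
  expect_equal(sum(prof$n), 8L)
  # the bridged clique holds the global maximum
  expect_equal(max(prof$max), max(cent))
  single <- community_centrality_profile(
    stats::setNames(rep(1L, 8), names(cent)), cent)
  expect_equal(single$max, max(cent))
  expect_equal(single$n, 8L)
})

test_that("membership counts partition the signed proteins by community, age and sign", {
  ref <- reference_table()
  membership <- stats::setNames(ref$community, ref$gene_name)
  old <- stats::setNames(ref$old_sign, ref$gene_name)
  young <- stats::setNames(ref$young_sign, ref$gene_name)
  counts <- membership_upset(membership, old, young)
  msr_old_loss <- counts$count[counts$community == "Metabolic stress response" &
                                 counts$age == "old" & !is.na(counts$sign) &
                                 counts$sign == -1L]
  expect_equal(msr_old_loss, 4L)
  # disjointness: per-age counts total the number of signed proteins
  for (age in c("old", "young")) {
    sub <- counts[counts$age == age & !is.na(counts$sign), ]
    expect_equal(sum(sub$count), nrow(ref))
  }
  # all-zero signs concentrate every count in the zero cell
  zeros <- stats::setNames(rep(0L, nrow(ref)), ref$gene_name)
  z <- membership_upset(membership, zeros, zeros)
  expect_true(all(z$count[!is.na(z$sign) & z$sign != 0L] == 0L))
})
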