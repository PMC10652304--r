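# Shared fixtures and independent oracles, built in code at test time.

# Two 4-cliques joined by a single bridge edge; the canonical case where the
# modularity optimum is exactly the pair of cliques.
two_cliques_graph <- function() {
  g <- igraph::disjoint_union(igraph::make_full_graph(4),
                              igraph::make_full_graph(4))
  g <- igraph::add_edges(g, c(1, 5))
  igraph::V(g)$name <- paste0("n", 1:8)
  g
}

# Exhaustive modularity maximization over all set partitions of the nodes,
# enumerated as restricted-growth strings. Independent of the Louvain path.
exhaustive_best_partition <- function(g) {
  n <- igraph::vcount(g)
  best_q <- -Inf
  best <- NULL
  rg <- integer(n)          # restricted-growth string, 1-based
  recurse <- function(i, max_label) {
    if (i > n) {
      q <- igraph::modularity(g, rg)
      if (q > best_q) {
        best_q <<- q
        best <<- rg
      }
      return(invisible())
    }
    for (lab in seq_len(max_label + 1L)) {
      rg[i] <<- lab
      recurse(i + 1L, max(max_label, lab))
    }
  }
  recurse(1L, 0L)
  list(membership = stats::setNames(best, igraph::V(g)$name),
       modularity = best_q)
}

# Canonical form of a partition label vector: labels renumbered by first
# appearance, so two partitions are equal iff their canonical forms are.
canonical_partition <- function(membership) {
  membership <- membership[order(names(membership))]
  as.integer(factor(membership, levels = unique(membership)))
}

# Minimal four-arm evidence table with explicit quantities.
toy_evidence <- function() {
  expand_rows <- function(pid, site, mod, cond, quantities) {
    data.frame(protein_id = pid, site = site, modification = mod,
               condition = cond, replicate = seq_along(quantities),
               quantity = quantities, stringsAsFactors = FALSE)
  }
  rbind(
    expand_rows("P1", 10L, "HNE", "vehicle", c(10, 10)),
    expand_rows("P1", 10L, "HNE", "treated", c(5, 5)),
    expand_rows("P1", 42L, "4-ONE", "vehicle", c(20, 20)),
    expand_rows("P1", 42L, "4-ONE", "treated", c(20, 20)),
    expand_rows("P2", 3L, "GlyGly", "vehicle", c(8, 8)),
    expand_rows("P2", 3L, "GlyGly", "treated", c(12, 12))
  )
}

toy_pair <- c(vehicle = "vehicle", treated = "treated")

# Small synthetic config that keeps generator-based tests fast.
small_config <- function(..., seed = 42L) {
  synthetic_config(n_proteins_total = 60L, n_detected = 20L,
                   length_range = c(50L, 300L), n_replicates = 3L,
                   baseline_mean = 1000, seed = seed, ...)
}

# Reference top-20 score table bundled with the package.
reference_table <- function() css_reference_table()
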