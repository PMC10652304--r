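#' Load a STRING-style interaction edge list
#'
#' Reads a whitespace- or tab-separated three-column file
#' (`protein1 protein2 combined_score`, scores on the 0-1000 STRING scale)
#' into an undirected [igraph] graph. An optional header line is detected and
#' skipped. Self-loops are removed; edges listed in both orientations (or
#' repeated) are merged keeping the maximum score; edges scoring below
#' `min_score` are dropped.
#'
#' @param path Path to the edge-list file.
#' @param min_score Minimum combined score to retain an edge (default 400,
#'   STRING's "medium confidence").
#' @return An undirected igraph graph with edge attribute `score`.
#' @export
load_network <- function(path, min_score = 400) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty edge list: returning an empty network")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  first <- fields[[1L]]
  has_header <- length(first) == 3L &&
    grepl("score|protein", first[3L], ignore.case = TRUE)
  if (has_header) fields <- fields[-1L]
  bad <- which(vapply(fields, length, integer(1)) != 3L)
  if (length(bad)) {
    stop("malformed edge-list line ", bad[1L] + has_header,
         ": expected 3 fields, got ", length(fields[[bad[1L]]]))
  }
  score <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
  if (anyNA(score)) {
    stop("malformed edge-list line ",
         which(is.na(score))[1L] + has_header, ": non-numeric score")
  }
  edges <- data.frame(
    from = vapply(fields, `[`, character(1), 1L),
    to = vapply(fields, `[`, character(1), 2L),
    score = score, stringsAsFactors = FALSE
  )
  edges <- edges[edges$score >= min_score & edges$from != edges$to, , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  # merge duplicate undirected edges, keeping the maximum confidence
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = list(score = "max"))
}

#' Write a network as a STRING-style edge list
#'
#' @param network An igraph graph, optionally with a `score` edge attribute
#'   (missing scores are written as 999).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  el <- igraph::as_edgelist(network)
  score <- igraph::edge_attr(network, "score") %||% rep(999, nrow(el))
  writeLines(c("protein1 protein2 combined_score",
               sprintf("%s %s %d", el[, 1L], el[, 2L], as.integer(round(score)))),
             path)
  invisible(path)
}

#' Whole-network eigenvector centrality
#'
#' Scores every protein by the dominant eigenvector of the (unweighted)
#' adjacency matrix: a protein is central when its interaction partners are
#' themselves central. The computation runs on the full graph in one pass —
#' the dominant eigenvector is carried by the largest-spectral-radius
#' (in practice the largest) connected component, and nodes outside it
#' receive centralities that decay to zero — so all values share one scale.
#'
#' Computed by power iteration on the shifted adjacency A + I (the shift
#' leaves eigenvectors unchanged but guarantees convergence on bipartite-like
#' graphs, whose extreme eigenvalues tie in magnitude), started from the
#' uniform vector so the returned sign is non-negative. The vector is
#' normalized to unit Euclidean norm.
#'
#' @param network An igraph graph with at least one node.
#' @param tol Convergence tolerance on the max absolute change per iteration.
#' @param max_iter Maximum number of power iterations.
#' @return A named numeric vector (class `ox_centrality`) of centralities with
#'   attribute `scale = "full_network"`; non-negative, unit L2 norm.
#' @export
eigenvector_centrality <- function(network, tol = 1e-10, max_iter = 1000L) {
  n <- igraph::vcount(network)
  if (n == 0L) stop("empty network")
  a <- igraph::as_adjacency_matrix(network, sparse = TRUE)
  a <- (a > 0) * 1  # unweighted
  x <- rep(1 / sqrt(n), n)
  for (iter in seq_len(max_iter)) {
    x_new <- as.numeric(a %*% x) + x
    x_new <- x_new / sqrt(sum(x_new^2))
    if (max(abs(x_new - x)) < tol) {
      x <- x_new
      names(x) <- igraph::V(network)$name %||% as.character(seq_len(n))
      return(structure(x, scale = "full_network", class = "ox_centrality"))
    }
    x <- x_new
  }
  stop("eigenvector centrality did not converge in ", max_iter,
       " iterations; increase max_iter")
}

#' Calibrated detected-protein subnetwork
#'
#' Induces the subgraph on the experimentally detected proteins and carries
#' the full-network eigenvector centralities onto it unchanged, so the
#' subnetwork's values remain numerically calibrated to the centrality scale
#' of the whole proteome (no recomputation, exact equality). Detected ids
#' absent from the network are reported and dropped.
#'
#' @param network The full igraph graph.
#' @param centrality Full-network centralities from
#'   [eigenvector_centrality()].
#' @param detected_ids Character vector of detected protein ids.
#' @return A list with `subnetwork` (igraph) and `centrality` (named vector,
#'   attribute `scale = "subnetwork_calibrated"`), plus `missing_ids`.
#' @export
calibrated_subnetwork <- function(network, centrality, detected_ids) {
  nodes <- igraph::V(network)$name
  missing_ids <- setdiff(detected_ids, nodes)
  keep <- intersect(detected_ids, nodes)
  if (!length(keep)) stop("no detected ids present in the network")
  if (length(missing_ids)) {
    message(length(missing_ids), " detected id(s) absent from the network; dropped")
  }
  sub <- igraph::induced_subgraph(network, keep)
  sub_cent <- centrality[igraph::V(sub)$name]
  attr(sub_cent, "scale") <- "subnetwork_calibrated"
  class(sub_cent) <- "ox_centrality"
  list(subnetwork = sub, centrality = sub_cent, missing_ids = missing_ids)
}

#' Louvain community partition of the largest connected component
#'
#' Runs Louvain modularity optimization on the largest connected component of
#' the (sub)network; nodes outside that component receive no label. Edges are
#' treated as unweighted. Deterministic under a fixed seed.
#'
#' @param subnetwork An igraph graph with at least one edge.
#' @param seed Integer seed (Louvain's node sweep order is randomized).
#' @param resolution Modularity resolution parameter (1 = classic
#'   modularity).
#' @return A list of class `ox_partition` with `membership` (named integer
#'   vector over the largest component), `modularity`, `seed`, `resolution`,
#'   `n_communities`.
#' @export
louvain_partition <- function(subnetwork, seed = 0L, resolution = 1.0) {
  if (igraph::ecount(subnetwork) == 0L) stop("cannot partition an edgeless network")
  comp <- igraph::components(subnetwork)
  lcc_nodes <- which(comp$membership == which.max(comp$csize))
  lcc <- igraph::induced_subgraph(subnetwork, lcc_nodes)
  lcc <- strip_weights(lcc)
  set.seed(seed)
  cl <- igraph::cluster_louvain(lcc, resolution = resolution)
  membership <- igraph::membership(cl)
  out <- stats::setNames(as.integer(membership), igraph::V(lcc)$name)
  structure(
    list(membership = out,
         modularity = igraph::modularity(lcc, membership),
         seed = as.integer(seed), resolution = resolution,
         n_communities = length(unique(out))),
    class = "ox_partition"
  )
}

# Louvain must see an unweighted graph: strip any 'weight' edge attribute so
# confidence scores never act as weights.
strip_weights <- function(g) {
  if ("weight" %in% igraph::edge_attr_names(g)) {
    g <- igraph::delete_edge_attr(g, "weight")
  }
  g
}

#' Per-community centrality profile
#'
#' Distribution summaries (count, quartiles, max) of eigenvector centrality
#' within each community.
#'
#' @param partition An `ox_partition` (or named membership vector).
#' @param centrality Named centrality vector covering the partitioned nodes.
#' @return A data.frame with one row per community: `community`, `n`, `min`,
#'   `q25`, `median`, `q75`, `max`.
#' @export
community_centrality_profile <- function(partition, centrality) {
  membership <- if (inherits(partition, "ox_partition")) partition$membership else partition
  stopifnot(all(names(membership) %in% names(centrality)))
  vals <- split(as.numeric(centrality[names(membership)]), membership)
  rows <- lapply(names(vals), function(com) {
    q <- stats::quantile(vals[[com]], c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(community = com, n = length(vals[[com]]),
               min = q[1], q25 = q[2], median = q[3], q75 = q[4], max = q[5],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Community-by-age-by-sign membership counts
#'
#' Counts, for every (community, age, sign) combination, the proteins whose
#' net PTM change in that age's treatment carries that sign — the counts
#' behind an UpSet-style set-membership display. Signs are -1 (loss), +1
#' (gain) and 0 (no change); proteins with `NA` sign in a condition are
#' counted under that condition's `no_data` margin.
#'
#' @param partition An `ox_partition`, or a named community-label vector (ids
#'   as names; labels may be arbitrary strings).
#' @param old_signs,young_signs Named vectors of -1/0/+1 (or NA) net signs.
#' @return A data.frame with columns `community`, `age`, `sign`, `count`,
#'   covering every community x age x sign in \{-1, 0, 1\} combination, plus
#'   `no_data` rows where applicable.
#' @export
membership_upset <- function(partition, old_signs, young_signs) {
  membership <- if (inherits(partition, "ox_partition")) partition$membership else partition
  stopifnot(!is.null(names(membership)))
  communities <- sort(unique(as.character(membership)))
  count_one <- function(signs, age) {
    s <- signs[names(membership)]
    rows <- expand.grid(community = communities, age = age,
                        sign = c(-1L, 0L, 1L), stringsAsFactors = FALSE)
    rows$count <- mapply(function(com, sg) {
      sum(as.character(membership) == com & !is.na(s) & s == sg)
    }, rows$community, rows$sign)
    nd <- data.frame(community = communities, age = age, sign = NA_integer_,
                     count = vapply(communities, function(com) {
                       sum(as.character(membership) == com & is.na(s))
                     }, integer(1)), stringsAsFactors = FALSE)
    nd <- nd[nd$count > 0L, , drop = FALSE]
    rbind(rows, nd)
  }
  out <- rbind(count_one(old_signs, "old"), count_one(young_signs, "young"))
  rownames(out) <- NULL
  out
}
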