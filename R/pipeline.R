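#' Run the full oxidation-sensitivity analysis chain
#'
#' Orchestrates every stage over one dataset: load/threshold the interaction
#' network; whole-network eigenvector centrality; calibrated detected-protein
#' subnetwork; Louvain partition of its largest connected component;
#' per-protein and per-modification PTM change tables, grand sums and sign
#' censuses for each age's condition pair; young-vs-old and
#' centrality-vs-change correlations; electrostatic stability table and
#' susceptibility map; composite sensitivity scores, upper-percentile subset,
#' community summary and the ranked top-k report. All randomized stages
#' (Louvain sweep order, bootstrap resampling) are governed by `seed`, so a
#' rerun with identical inputs is byte-identical.
#'
#' Inputs may be file paths (FASTA, STRING-style edge list, evidence/LFQ CSV)
#' or the in-memory objects produced by [simulate_dataset()].
#'
#' @param fasta Proteome FASTA path, named character vector or AAStringSet.
#' @param edges Edge-list path or an igraph graph.
#' @param evidence PTM evidence CSV path or data.frame.
#' @param lfq Optional LFQ CSV path or data.frame.
#' @param out_dir Optional directory for the report bundle (TSV/JSON files
#'   plus a run manifest with the seed and a parameter hash).
#' @param condition_pairs Named list of `c(vehicle =, treated =)` pairs, one
#'   per age group; defaults to the standard four-arm design.
#' @param min_score Edge confidence threshold (used when `edges` is a path).
#' @param seed Seed for Louvain and bootstraps.
#' @param resolution Louvain resolution.
#' @param zero_tolerance Zero band for net signs (percent).
#' @param n_boot Bootstrap resamples for correlations.
#' @param scored_set `"ptm_mapped"` (score only proteins with PTM evidence;
#'   default) or `"network"` (score every subnetwork protein).
#' @param percentile Upper CSS percentile reported (default 50).
#' @param top_k Rows in the ranked summary (default 20).
#' @return A list of class `ox_pipeline_result` with elements `network`,
#'   `centrality`, `subnetwork`, `partition`, `ptm` (per-age change tables,
#'   grand sums, censuses), `correlations`, `stability`, `map`, `scores`,
#'   `top`, `communities`, `summary`, `manifest`.
#' @export
run_pipeline <- function(fasta, edges, evidence, lfq = NULL, out_dir = NULL,
                         condition_pairs = list(
                           young = c(vehicle = "young-vehicle", treated = "young-treated"),
                           old = c(vehicle = "old-vehicle", treated = "old-treated")
                         ),
                         min_score = 400, seed = 0L, resolution = 1.0,
                         zero_tolerance = 1e-9, n_boot = 1000L,
                         scored_set = c("ptm_mapped", "network"),
                         percentile = 50, top_k = 20L) {
  scored_set <- match.arg(scored_set)

  if (is.character(evidence)) {
    evidence <- utils::read.csv(evidence, stringsAsFactors = FALSE)
  }
  check_evidence(evidence)
  if (is.character(lfq)) lfq <- utils::read.csv(lfq, stringsAsFactors = FALSE)

  # --- network stage ---
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(name, " stage failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  network <- stage("network", {
    g <- if (igraph::is_igraph(edges)) edges else load_network(edges, min_score)
    if (igraph::vcount(g) == 0L) stop("empty network")
    g
  })
  centrality <- stage("network", eigenvector_centrality(network))
  detected <- sort(unique(evidence$protein_id))
  calib <- stage("network", calibrated_subnetwork(network, centrality, detected))
  partition <- stage("network", louvain_partition(calib$subnetwork, seed = seed,
                                                  resolution = resolution))

  # --- PTM stage: per-age change tables, sums, censuses ---
  ptm <- stage("ptm", lapply(condition_pairs, function(pair) {
    by_protein <- ptm_change_table(evidence, pair, by = "protein",
                                   zero_tolerance = zero_tolerance)
    by_modification <- ptm_change_table(evidence, pair, by = "modification",
                                        zero_tolerance = zero_tolerance)
    list(by_protein = by_protein,
         by_modification = by_modification,
         grand_sum_protein = grand_sum(by_protein),
         grand_sum_modification = grand_sum(by_modification),
         census = sign_census(by_protein, zero_tolerance))
  }))

  # --- correlations: young vs old change; centrality vs change per age ---
  correlations <- list()
  signs <- list()
  change_of <- function(age) {
    tab <- ptm[[age]]$by_protein
    stats::setNames(tab$pct_change_per_site, tab$id)
  }
  ages <- names(condition_pairs)
  for (age in ages) {
    ch <- change_of(age)
    signs[[age]] <- stats::setNames(
      sign_of(ch, zero_tolerance), names(ch))
    shared <- intersect(names(ch), names(calib$centrality))
    if (length(shared) >= 3L) {
      correlations[[paste0("centrality_vs_", age)]] <-
        correlate(ch[shared], as.numeric(calib$centrality[shared]),
                  n_boot = n_boot, seed = seed)
    }
  }
  if (length(ages) >= 2L) {
    a <- change_of(ages[1]); b <- change_of(ages[2])
    shared <- intersect(names(a), names(b))
    if (length(shared) >= 3L) {
      correlations[[paste(ages[1], "vs", ages[2], sep = "_")]] <-
        correlate(a[shared], b[shared], n_boot = n_boot, seed = seed)
    }
  }

  # --- LFQ overlay ---
  overlay <- NULL
  if (!is.null(lfq)) {
    overlay <- lapply(ages, function(age) {
      overlay_lfq(ptm[[age]]$by_protein,
                  lfq_log2_ratio(lfq, condition_pairs[[age]]))
    })
    names(overlay) <- ages
  }

  # --- stability stage ---
  stability <- stage("stability", stability_table(fasta))
  map <- stage("stability", proteome_map(fasta))

  # --- scoring stage ---
  p_set <- switch(scored_set,
    ptm_mapped = detected,
    network = igraph::V(calib$subnetwork)$name
  )
  old_signs <- signs[["old"]] %||% signs[[ages[length(ages)]]]
  young_signs <- signs[["young"]] %||% signs[[ages[1]]]
  scores <- stage("scoring", compute_scores(
    stability, calib$centrality, partition = partition,
    old_signs = old_signs, young_signs = young_signs, scored_set = p_set))
  top <- top_percentile(scores, percentile)
  communities <- community_summary(scores)
  summary_tab <- summary_table(scores, top_k)

  manifest <- list(
    seed = as.integer(seed),
    parameters = list(min_score = min_score, resolution = resolution,
                      zero_tolerance = zero_tolerance, n_boot = n_boot,
                      scored_set = scored_set, percentile = percentile,
                      top_k = top_k),
    n_network_nodes = igraph::vcount(network),
    n_network_edges = igraph::ecount(network),
    n_detected = length(detected),
    n_scored = nrow(scores)
  )
  manifest$parameter_hash <- hash_object(manifest)

  result <- structure(
    list(network = network, centrality = centrality,
         subnetwork = calib$subnetwork,
         subnetwork_centrality = calib$centrality,
         partition = partition, ptm = ptm, correlations = correlations,
         overlay = overlay, stability = stability, map = map,
         scores = scores, top = top, communities = communities,
         summary = summary_tab, manifest = manifest),
    class = "ox_pipeline_result"
  )
  if (!is.null(out_dir)) write_report_bundle(result, out_dir)
  result
}

# Stable md5 of an R object via its canonical JSON serialization.
hash_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write the pipeline report bundle
#'
#' Serializes every stage's table under `out_dir`: per-age PTM change tables,
#' centrality and partition exports, the stability and score tables, the
#' ranked summary, a JSON of grand sums / censuses / correlations, and the
#' run manifest.
#'
#' @param result An `ox_pipeline_result`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (age in names(result$ptm)) {
    write_tsv(result$ptm[[age]]$by_protein,
              file.path(out_dir, paste0("ptm_change_protein_", age, ".tsv")))
    write_tsv(result$ptm[[age]]$by_modification,
              file.path(out_dir, paste0("ptm_change_modification_", age, ".tsv")))
  }
  write_tsv(data.frame(protein_id = names(result$centrality),
                       centrality = as.numeric(result$centrality)),
            file.path(out_dir, "centrality_full.tsv"))
  write_tsv(data.frame(protein_id = names(result$partition$membership),
                       community = as.integer(result$partition$membership)),
            file.path(out_dir, "louvain_partition.tsv"))
  write_tsv(result$stability, file.path(out_dir, "stability.tsv"))
  write_tsv(result$map$table, file.path(out_dir, "susceptibility_map.tsv"))
  write_tsv(result$scores, file.path(out_dir, "scores.tsv"))
  write_tsv(result$summary, file.path(out_dir, "summary_top.tsv"))
  write_tsv(result$communities, file.path(out_dir, "community_summary.tsv"))
  summary_json <- list(
    grand_sums = lapply(result$ptm, function(p)
      list(by_protein = p$grand_sum_protein,
           by_modification = p$grand_sum_modification)),
    censuses = lapply(result$ptm, function(p) as.list(p$census)),
    correlations = lapply(result$correlations, unclass),
    modularity = result$partition$modularity,
    n_communities = result$partition$n_communities
  )
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
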