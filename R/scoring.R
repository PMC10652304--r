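#' Min-max normalization
#'
#' Rescales values linearly so the minimum maps to 0 and the maximum to 1.
#' Invariant under positive affine transformations of the input, which is
#' what makes the downstream composite score independent of the raw units of
#' its two ingredients.
#'
#' @param values Numeric vector with at least 2 distinct finite values.
#' @return `(values - min) / (max - min)`.
#' @export
minmax <- function(values) {
  stopifnot(is.numeric(values), all(is.finite(values)))
  rng <- range(values)
  if (rng[1] == rng[2]) stop("all values equal: min-max normalization degenerate")
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Composite sensitivity scores
#'
#' Integrates folding-destabilization susceptibility and network influence
#' into a per-protein ranking. Over the scored set P, the raw sensitivity
#' score is the product of the min-max normalized susceptibility
#' \eqn{|\Delta\Delta G|} and the min-max normalized eigenvector centrality
#' E; the composite sensitivity score (CSS) is that product min-max
#' normalized once more, so the top-ranked protein always scores exactly 1
#' and the bottom exactly 0:
#' \deqn{RSS = \mathrm{minmax}_P(\Delta\Delta G) \cdot \mathrm{minmax}_P(E),
#'       \qquad CSS = \mathrm{minmax}_P(RSS)}
#'
#' The scored set defaults to the proteins having both a susceptibility and a
#' calibrated centrality (intersected with `scored_set` when given, e.g. to
#' restrict to PTM-mapped proteins). Community labels and net PTM signs are
#' annotations carried through when provided.
#'
#' @param stability A data.frame with `protein_id` and `susceptibility`
#'   (see [stability_table()]).
#' @param centrality Named centrality vector (full-network calibrated).
#' @param partition Optional `ox_partition` or named community-label vector.
#' @param old_signs,young_signs Optional named -1/0/+1 net-sign vectors.
#' @param scored_set Optional character vector restricting P.
#' @param gene_names Optional named vector mapping protein ids to gene names.
#' @return A data.frame of class `ox_scores`, one row per protein in P,
#'   ordered by CSS descending then protein id: `protein_id`, `gene_name`,
#'   `community`, `e`, `ddg`, `e_norm`, `ddg_norm`, `rss`, `css`,
#'   `old_sign`, `young_sign`.
#' @export
compute_scores <- function(stability, centrality, partition = NULL,
                           old_signs = NULL, young_signs = NULL,
                           scored_set = NULL, gene_names = NULL) {
  stopifnot(all(c("protein_id", "susceptibility") %in% names(stability)))
  p <- intersect(stability$protein_id, names(centrality))
  if (!is.null(scored_set)) p <- intersect(p, scored_set)
  if (length(p) < 2L) stop("scored set must contain at least 2 proteins")

  ddg <- stats::setNames(stability$susceptibility, stability$protein_id)[p]
  e <- as.numeric(centrality[p])
  ddg_norm <- minmax(as.numeric(ddg))
  e_norm <- minmax(e)
  rss <- ddg_norm * e_norm
  css <- minmax(rss)

  membership <- if (inherits(partition, "ox_partition")) partition$membership else partition
  pick <- function(v) if (is.null(v)) rep(NA, length(p)) else unname(v[p])
  out <- data.frame(
    protein_id = p,
    gene_name = as.character(pick(gene_names)),
    community = as.character(pick(membership)),
    e = e, ddg = as.numeric(ddg),
    e_norm = e_norm, ddg_norm = ddg_norm,
    rss = rss, css = css,
    old_sign = as.integer(pick(old_signs)),
    young_sign = as.integer(pick(young_signs)),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$css, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ox_scores", "data.frame")
  out
}

#' Upper-percentile subset of scored proteins
#'
#' Rows with CSS at or above the given empirical percentile of CSS over the
#' scored set. Cutoff ties are inclusive, so float-equal proteins are never
#' dropped; ordering is stable (CSS descending, then protein id).
#'
#' @param rows An `ox_scores` table.
#' @param percentile Percentile in `[0, 100]`; 50 keeps the upper half.
#' @return The qualifying rows, stably ordered.
#' @export
top_percentile <- function(rows, percentile = 50) {
  stopifnot(percentile >= 0, percentile <= 100)
  cutoff <- stats::quantile(rows$css, percentile / 100, names = FALSE)
  out <- rows[rows$css >= cutoff, , drop = FALSE]
  out <- out[order(-out$css, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-community score summary
#'
#' CSS sums, member counts and membership fractions per community — the
#' community-level weight census of the composite score. Unlabeled proteins
#' (NA community) are excluded; fractions are over the labeled proteins and
#' sum to 1.
#'
#' @param rows An `ox_scores` table with a `community` column.
#' @return A data.frame with `community`, `css_sum`, `n`, `fraction`, ordered
#'   by decreasing `css_sum`.
#' @export
community_summary <- function(rows) {
  rows <- rows[!is.na(rows$community), , drop = FALSE]
  if (!nrow(rows)) stop("no community labels present")
  pieces <- split(rows, rows$community)
  out <- data.frame(
    community = names(pieces),
    css_sum = vapply(pieces, function(d) sum(d$css), numeric(1)),
    n = vapply(pieces, nrow, integer(1)),
    stringsAsFactors = FALSE
  )
  out$fraction <- out$n / sum(out$n)
  out <- out[order(-out$css_sum), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ranked summary report of the top-scoring proteins
#'
#' The headline table of the analysis: the `top_k` proteins by CSS with their
#' community labels and net PTM signs, CSS rounded to 2 decimals for display
#' (`css` retains full precision in the `css_full` column).
#'
#' @param rows An `ox_scores` table.
#' @param top_k Number of rows to report (all rows if larger than the set).
#' @return A data.frame with `rank`, `protein_id`, `gene_name`, `community`,
#'   `old_sign`, `young_sign`, `css` (2 dp) and `css_full`.
#' @export
summary_table <- function(rows, top_k = 20L) {
  out <- rows[seq_len(min(top_k, nrow(rows))), , drop = FALSE]
  data.frame(
    rank = seq_len(nrow(out)),
    protein_id = out$protein_id,
    gene_name = out$gene_name,
    community = out$community,
    old_sign = out$old_sign,
    young_sign = out$young_sign,
    css = round(out$css, 2),
    css_full = out$css,
    stringsAsFactors = FALSE
  )
}

#' Bundled top-20 composite-sensitivity reference table
#'
#' The published ranking of the twenty highest composite sensitivity scores
#' from a mass-spectrometry study of senolytic-treated osteoarthritic mouse
#' knee cartilage — simultaneously the top 20 and the upper 50th CSS
#' percentile of that study's scored set. Columns: `gene_name`,
#' `protein_name`, `uniprot_id`, `community` (Louvain community label),
#' `old_sign` / `young_sign` (net direction of the oxidative PTM change upon
#' treatment: -1 loss, 0 none, +1 gain) and `css` (2 dp).
#'
#' Used as a fixture for census and membership operations; the underlying
#' raw intensities are not redistributable, so CSS values here are display
#' precision only.
#'
#' @return A 20-row data.frame.
#' @export
css_reference_table <- function() {
  path <- system.file("extdata", "css_top20_reference.tsv", package = "oxsens",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
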