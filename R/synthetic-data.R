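#' Configuration for the synthetic study generator
#'
#' One object holding every knob of the synthetic data that stands in for a
#' real study: proteome size and charge composition, interaction-network
#' model, the experimental design (conditions x replicates), planted
#' per-protein PTM effects, and the count-noise model. Defaults emulate a
#' two-age senolytic study: four conditions (vehicle/treated x young/old),
#' spectral-count-like site quantities with Poisson noise, a whole proteome
#' an order of magnitude larger than the detected set, and planted effects
#' skewed toward PTM loss in the old treated condition and PTM gain in the
#' young — the asymmetry the downstream census and correlation analyses are
#' designed to expose.
#'
#' @param n_proteins_total Proteins in the full proteome / network.
#' @param n_detected Size of the experimentally detected subset (the first
#'   `n_detected` protein ids); must not exceed `n_proteins_total`.
#' @param length_range Integer `[min, max]` sequence length in residues.
#' @param charge_fraction_ranges List with elements `positive` (Arg/Lys),
#'   `negative` (Asp/Glu) and `variable` (His), each a `[min, max]` fraction
#'   range in `[0, 1]` (a single number is a degenerate range). The range
#'   maxima must sum to at most 1.
#' @param network_model `"preferential_attachment"` or `"planted_hub"`.
#' @param n_planted_hubs Number of planted hub proteins (the first ids);
#'   must be smaller than `n_proteins_total`.
#' @param extreme_hubs When TRUE, planted hub proteins are also drawn at the
#'   extremes of the sequence model (maximum length, maximum positive and
#'   minimum negative charge fractions), making them simultaneously the most
#'   network-central and the most destabilization-susceptible proteins — the
#'   configuration whose recovery at the top of the composite ranking is the
#'   pipeline's end-to-end truth check.
#' @param conditions Condition labels; the default four-arm design is
#'   `young-vehicle, young-treated, old-vehicle, old-treated`.
#' @param n_replicates Technical replicates per condition (>= 1).
#' @param effect_table Optional data.frame `protein_id, effect_young,
#'   effect_old` of planted signed percent changes in PTM per site for the
#'   treated vs vehicle comparison; when NULL, effects are drawn for the
#'   detected set with `prob_negative_old` / `prob_negative_young`.
#' @param prob_negative_old,prob_negative_young Probability that a drawn
#'   effect is a loss, in the old and young comparisons (defaults 0.7 and
#'   0.2, mirroring loss-dominated old and gain-dominated young responses).
#' @param baseline_mean Mean vehicle-condition site quantity (counts).
#' @param noise_model `"poisson"` (counts) or `"lognormal"`.
#' @param noise_scale Noise dial: 0 means exact expectations (no noise); for
#'   the lognormal model it is the log-scale sigma; for Poisson any positive
#'   value switches sampling on.
#' @param lfq_sigma Log-scale sigma of LFQ replicate noise.
#' @param seed Integer seed; every generator call is deterministic in
#'   (config, seed).
#' @return A list of class `ox_synthetic_config`.
#' @export
synthetic_config <- function(n_proteins_total = 2000L,
                             n_detected = 500L,
                             length_range = c(50L, 1500L),
                             charge_fraction_ranges = list(
                               positive = c(0.08, 0.16),
                               negative = c(0.08, 0.16),
                               variable = c(0.01, 0.04)
                             ),
                             network_model = c("preferential_attachment", "planted_hub"),
                             n_planted_hubs = 0L,
                             extreme_hubs = FALSE,
                             conditions = c("young-vehicle", "young-treated",
                                            "old-vehicle", "old-treated"),
                             n_replicates = 3L,
                             effect_table = NULL,
                             prob_negative_old = 0.7,
                             prob_negative_young = 0.2,
                             baseline_mean = 1000,
                             noise_model = c("poisson", "lognormal"),
                             noise_scale = 1,
                             lfq_sigma = 0.1,
                             seed = 1L) {
  network_model <- match.arg(network_model)
  noise_model <- match.arg(noise_model)
  as_range <- function(r) if (length(r) == 1L) c(r, r) else sort(r[1:2])
  charge_fraction_ranges <- lapply(charge_fraction_ranges, as_range)
  stopifnot(
    n_proteins_total >= 3L,
    n_detected >= 1L, n_detected <= n_proteins_total,
    n_replicates >= 1L,
    length_range[1] >= 1L, length_range[1] <= length_range[2],
    all(unlist(charge_fraction_ranges) >= 0),
    all(unlist(charge_fraction_ranges) <= 1),
    baseline_mean > 0, noise_scale >= 0, lfq_sigma >= 0
  )
  if (sum(vapply(charge_fraction_ranges, max, numeric(1))) > 1) {
    stop("infeasible charge fractions: class maxima sum to more than 1")
  }
  if (n_planted_hubs >= n_proteins_total) {
    stop("n_planted_hubs must be smaller than n_proteins_total")
  }
  structure(
    list(n_proteins_total = as.integer(n_proteins_total),
         n_detected = as.integer(n_detected),
         length_range = as.integer(length_range),
         charge_fraction_ranges = charge_fraction_ranges,
         network_model = network_model,
         n_planted_hubs = as.integer(n_planted_hubs),
         extreme_hubs = isTRUE(extreme_hubs),
         conditions = conditions,
         n_replicates = as.integer(n_replicates),
         effect_table = effect_table,
         prob_negative_old = prob_negative_old,
         prob_negative_young = prob_negative_young,
         baseline_mean = baseline_mean,
         noise_model = noise_model,
         noise_scale = noise_scale,
         lfq_sigma = lfq_sigma,
         seed = as.integer(seed) %% .Machine$integer.max),
    class = "ox_synthetic_config"
  )
}

protein_ids <- function(config) sprintf("SYN%05d", seq_len(config$n_proteins_total))

#' @rdname synthetic_config
#' @param config An `ox_synthetic_config`.
#' @export
detected_ids <- function(config) protein_ids(config)[seq_len(config$n_detected)]

hub_ids <- function(config) {
  if (config$n_planted_hubs == 0L) character(0)
  else protein_ids(config)[seq_len(config$n_planted_hubs)]
}

# Residues outside the three charge classes (20 standard minus R,K,D,E,H).
NEUTRAL_AA <- c("A", "C", "F", "G", "I", "L", "M", "N", "P",
                "Q", "S", "T", "V", "W", "Y")

#' Generate a synthetic proteome
#'
#' Draws one sequence per protein with controlled charge composition: length
#' uniform over `length_range`, per-class fractions uniform over their
#' configured ranges, realized class counts equal to `round(N * fraction)`.
#' Charged positions are filled uniformly from their class pools (R/K, D/E,
#' H) and the remainder uniformly from the 15 non-charged standard residues;
#' residue order is then shuffled (the downstream model is composition-only,
#' so positions are labels). Deterministic in the config seed.
#'
#' @param config An [synthetic_config()] object.
#' @param fasta Optional path: write the proteome as FASTA.
#' @return A list with `records` (named character vector of sequences) and
#'   `truth` (data.frame of planted per-protein class counts).
#' @export
generate_proteome <- function(config, fasta = NULL) {
  set.seed(config$seed)
  ids <- protein_ids(config)
  fr <- config$charge_fraction_ranges
  n <- config$n_proteins_total
  len_pool <- seq(config$length_range[1], config$length_range[2])
  lens <- len_pool[sample.int(length(len_pool), n, replace = TRUE)]
  f_pos <- stats::runif(n, fr$positive[1], fr$positive[2])
  f_neg <- stats::runif(n, fr$negative[1], fr$negative[2])
  f_var <- stats::runif(n, fr$variable[1], fr$variable[2])
  if (config$extreme_hubs && config$n_planted_hubs > 0L) {
    i <- seq_len(config$n_planted_hubs)
    lens[i] <- config$length_range[2]
    f_pos[i] <- fr$positive[2]
    f_neg[i] <- fr$negative[1]
    f_var[i] <- fr$variable[2]
  }
  c_pos <- round(lens * f_pos)
  c_neg <- round(lens * f_neg)
  c_var <- round(lens * f_var)
  records <- vapply(seq_len(n), function(i) {
    n_rest <- lens[i] - c_pos[i] - c_neg[i] - c_var[i]
    aa <- c(sample(c("R", "K"), c_pos[i], replace = TRUE),
            sample(c("D", "E"), c_neg[i], replace = TRUE),
            rep("H", c_var[i]),
            sample(NEUTRAL_AA, n_rest, replace = TRUE))
    paste(sample(aa), collapse = "")
  }, character(1))
  names(records) <- ids
  truth <- data.frame(protein_id = ids, n_residues = lens,
                      c_positive = c_pos, c_negative = c_neg, c_variable = c_var,
                      stringsAsFactors = FALSE)
  if (!is.null(fasta)) {
    Biostrings::writeXStringSet(Biostrings::AAStringSet(records), fasta)
  }
  list(records = records, truth = truth)
}

#' Generate a synthetic interaction network
#'
#' Builds a scale-free-like undirected network over the whole synthetic
#' proteome by preferential attachment; under the `planted_hub` model the
#' first `n_planted_hubs` proteins are additionally wired to a large random
#' node subset until each reaches at least ten times the median degree, so
#' their identity as dominant influence centers is guaranteed by
#' construction. Edge confidence scores are uniform integers on the 400-1000
#' STRING scale. Deterministic in the config seed.
#'
#' @param config An [synthetic_config()] object.
#' @param path Optional path: write a STRING-style edge list.
#' @return A list with `network` (igraph, edge attribute `score`) and `truth`
#'   (list with `hub_ids`).
#' @export
generate_network <- function(config, path = NULL) {
  set.seed(config$seed + 1L)
  n <- config$n_proteins_total
  ids <- protein_ids(config)
  hubs <- if (config$network_model == "planted_hub") hub_ids(config) else character(0)
  # a sparser preferential-attachment backbone under the planted-hub model
  # keeps the median degree low enough that a 10x-median hub is attainable
  m <- if (length(hubs)) 1L else min(3L, n - 1L)
  g <- igraph::sample_pa(n, power = 1, m = m, directed = FALSE)
  igraph::V(g)$name <- ids
  attach_to <- function(g, h, target) {
    current <- igraph::neighbors(g, h)$name
    want <- setdiff(ids, c(h, current))
    extra <- want[sample.int(length(want),
                             min(length(want), target - length(current)))]
    if (length(extra)) g <- igraph::add_edges(g, rbind(h, extra))
    g
  }
  for (h in hubs) {
    med <- stats::median(igraph::degree(g))
    target <- min(max(ceiling(10 * med) + 2L, ceiling(0.5 * n)), n - 1L)
    g <- attach_to(g, h, target)
  }
  # wiring hubs raises everyone else's degree, so top up until each hub
  # clears ten times the final median
  for (iter in seq_len(10L)) {
    deg <- igraph::degree(g)
    med <- stats::median(deg)
    lacking <- hubs[deg[hubs] < 10 * med]
    if (!length(lacking)) break
    for (h in lacking) {
      g <- attach_to(g, h, min(ceiling(10 * med) + 2L, n - 1L))
    }
  }
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  igraph::E(g)$score <- sample(400:1000, igraph::ecount(g), replace = TRUE)
  if (!is.null(path)) write_network(g, path)
  list(network = g, truth = list(hub_ids = hubs))
}

# Draw or pass through the planted effect table for the detected proteins.
planted_effects <- function(config) {
  if (!is.null(config$effect_table)) {
    et <- config$effect_table
    stopifnot(all(c("protein_id", "effect_young", "effect_old") %in% names(et)))
    if (!all(et$protein_id %in% protein_ids(config))) {
      stop("effect_table contains protein ids outside the proteome")
    }
    return(et)
  }
  ids <- detected_ids(config)
  draw <- function(p_neg) {
    neg <- stats::runif(length(ids)) < p_neg
    ifelse(neg, -stats::runif(length(ids), 5, 60), stats::runif(length(ids), 5, 40))
  }
  data.frame(protein_id = ids,
             effect_young = draw(config$prob_negative_young),
             effect_old = draw(config$prob_negative_old),
             stringsAsFactors = FALSE)
}

apply_noise <- function(expected, noise_model, noise_scale) {
  if (noise_scale == 0) return(expected)
  if (noise_model == "poisson") {
    stats::rpois(length(expected), expected)
  } else {
    # mean-preserving lognormal: E[exp(N(-s^2/2, s))] = 1
    expected * stats::rlnorm(length(expected), -noise_scale^2 / 2, noise_scale)
  }
}

#' Generate site-level PTM evidence with planted effects
#'
#' Emits one evidence row per (protein, site, modification, condition,
#' replicate). Each detected protein carries 1-4 modified sites at positions
#' drawn uniformly without replacement along its sequence, with modification
#' labels drawn from an AGE/ALE-style vocabulary. Vehicle-condition
#' quantities have expectation equal to the site baseline; treated-condition
#' expectations are `baseline * (1 + effect/100)` with the planted
#' age-specific effect. Noise follows the configured model; `noise_scale = 0`
#' yields the exact expectations, so planted effects are recoverable exactly.
#' Deterministic in the config seed.
#'
#' @param config An [synthetic_config()] object.
#' @param proteome Output of [generate_proteome()] (site positions are drawn
#'   within each sequence's length).
#' @param path Optional path: write the evidence CSV
#'   (`protein_id,site,modification,condition,replicate,quantity`).
#' @return A list with `evidence` (data.frame) and `truth` (the planted
#'   effect table with net signs).
#' @export
generate_ptm_evidence <- function(config, proteome, path = NULL) {
  set.seed(config$seed + 2L)
  effects <- planted_effects(config)
  if (config$baseline_mean <= 0) stop("baseline quantities must be positive")
  mods <- c("4-ONE", "HNE", "carboxymethyl", "carboxyethyl",
            "G-H1", "GlyGly", "mono-oxidation", "di-oxidation")
  vehicle <- grep("vehicle", config$conditions, value = TRUE)
  lens <- stats::setNames(nchar(proteome$records), names(proteome$records))
  rows <- lapply(seq_len(nrow(effects)), function(i) {
    pid <- effects$protein_id[i]
    n_sites <- sample(1:4, 1L)
    sites <- sample.int(lens[[pid]], min(n_sites, lens[[pid]]))
    site_mods <- sample(mods, length(sites), replace = TRUE)
    baseline <- config$baseline_mean * stats::runif(length(sites), 0.5, 1.5)
    per_cond <- lapply(config$conditions, function(cond) {
      eff <- if (cond %in% vehicle) 0
        else if (startsWith(cond, "young")) effects$effect_young[i]
        else effects$effect_old[i]
      expected <- rep(baseline * (1 + eff / 100), each = config$n_replicates)
      data.frame(
        protein_id = pid,
        site = rep(sites, each = config$n_replicates),
        modification = rep(site_mods, each = config$n_replicates),
        condition = cond,
        replicate = rep(seq_len(config$n_replicates), times = length(sites)),
        quantity = apply_noise(expected, config$noise_model, config$noise_scale),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, per_cond)
  })
  evidence <- do.call(rbind, rows)
  rownames(evidence) <- NULL
  truth <- effects
  truth$sign_young <- as.integer(sign(truth$effect_young))
  truth$sign_old <- as.integer(sign(truth$effect_old))
  if (!is.null(path)) utils::write.csv(evidence, path, row.names = FALSE, quote = FALSE)
  list(evidence = evidence, truth = truth)
}

#' Generate label-free quantification (LFQ) abundance data
#'
#' Per-protein, per-condition, per-replicate relative abundances with planted
#' treated-vs-vehicle fold changes and mean-preserving lognormal replicate
#' noise (`lfq_sigma = 0` gives exact expectations). Fold changes default to
#' lognormal draws around 1 (sdlog 0.5) per age.
#'
#' @param config An [synthetic_config()] object.
#' @param proteome Output of [generate_proteome()].
#' @param fold_changes Optional data.frame `protein_id, fc_young, fc_old` of
#'   planted fold changes (> 0).
#' @param path Optional path: write the LFQ CSV.
#' @return A list with `lfq` (data.frame `protein_id, condition, replicate,
#'   intensity`) and `truth` (the fold-change table).
#' @export
generate_lfq <- function(config, proteome, fold_changes = NULL, path = NULL) {
  set.seed(config$seed + 3L)
  ids <- detected_ids(config)
  if (is.null(fold_changes)) {
    fold_changes <- data.frame(
      protein_id = ids,
      fc_young = stats::rlnorm(length(ids), 0, 0.5),
      fc_old = stats::rlnorm(length(ids), 0, 0.5),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(fold_changes$protein_id %in% protein_ids(config)),
            all(fold_changes$fc_young > 0), all(fold_changes$fc_old > 0))
  base <- stats::setNames(stats::rlnorm(nrow(fold_changes), log(1e6), 1),
                          fold_changes$protein_id)
  vehicle <- grep("vehicle", config$conditions, value = TRUE)
  rows <- lapply(config$conditions, function(cond) {
    fc <- if (cond %in% vehicle) rep(1, nrow(fold_changes))
      else if (startsWith(cond, "young")) fold_changes$fc_young
      else fold_changes$fc_old
    expected <- rep(base * fc, each = config$n_replicates)
    data.frame(
      protein_id = rep(fold_changes$protein_id, each = config$n_replicates),
      condition = cond,
      replicate = rep(seq_len(config$n_replicates), times = nrow(fold_changes)),
      intensity = if (config$lfq_sigma == 0) expected else
        expected * stats::rlnorm(length(expected),
                                 -config$lfq_sigma^2 / 2, config$lfq_sigma),
      stringsAsFactors = FALSE
    )
  })
  lfq <- do.call(rbind, rows)
  rownames(lfq) <- NULL
  if (!is.null(path)) utils::write.csv(lfq, path, row.names = FALSE, quote = FALSE)
  list(lfq = lfq, truth = fold_changes)
}

#' Per-protein log2 LFQ ratios
#'
#' Condition means over replicates, then `log2(treated / vehicle)` per
#' protein for one age's condition pair.
#'
#' @param lfq An LFQ data.frame from [generate_lfq()] (columns `protein_id`,
#'   `condition`, `replicate`, `intensity`).
#' @param condition_pair Named vector with `vehicle` and `treated` labels.
#' @return A data.frame `protein_id, log2_ratio`.
#' @export
lfq_log2_ratio <- function(lfq, condition_pair) {
  mean_of <- function(cond) {
    d <- lfq[lfq$condition == cond, , drop = FALSE]
    tapply(d$intensity, d$protein_id, mean)
  }
  mv <- mean_of(condition_pair[["vehicle"]])
  mt <- mean_of(condition_pair[["treated"]])
  ids <- sort(intersect(names(mv), names(mt)))
  data.frame(protein_id = ids,
             log2_ratio = log2(as.numeric(mt[ids]) / as.numeric(mv[ids])),
             stringsAsFactors = FALSE)
}

#' Generate and write a complete synthetic dataset bundle
#'
#' Runs all four generators and writes the standard file formats under
#' `out_dir`: `proteome.fasta`, `network_edges.txt` (STRING-style),
#' `ptm_evidence.csv`, `lfq.csv` and `truth.json`. Re-running with the same
#' config produces byte-identical files.
#'
#' @param config An [synthetic_config()] object.
#' @param out_dir Output directory (created if needed); NULL keeps everything
#'   in memory only.
#' @return A list with `proteome`, `network`, `ptm`, `lfq`, `truth` and
#'   `paths`.
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(fasta = file.path(out_dir, "proteome.fasta"),
                  edges = file.path(out_dir, "network_edges.txt"),
                  evidence = file.path(out_dir, "ptm_evidence.csv"),
                  lfq = file.path(out_dir, "lfq.csv"),
                  truth = file.path(out_dir, "truth.json"))
  }
  proteome <- generate_proteome(config, fasta = paths$fasta)
  network <- generate_network(config, path = paths$edges)
  ptm <- generate_ptm_evidence(config, proteome, path = paths$evidence)
  lfq <- generate_lfq(config, proteome, path = paths$lfq)
  truth <- list(
    detected_ids = detected_ids(config),
    hub_ids = network$truth$hub_ids,
    charge_composition = proteome$truth,
    ptm_effects = ptm$truth,
    lfq_fold_changes = lfq$truth
  )
  if (!is.null(paths)) {
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  }
  list(proteome = proteome, network = network, ptm = ptm, lfq = lfq,
       truth = truth, paths = paths)
}
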