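test_that("degenerate fraction ranges force exact class counts", {
  cfg <- synthetic_config(n_proteins_total = 10L, n_detected = 5L,
                          length_range = c(50L, 50L),
                          charge_fraction_ranges = list(positive = 0.2,
                                                        negative = 0.1,
                                                        variable = 0.04),
                          seed = 1L)
  prot <- generate_proteome(cfg)
  for (s in prot$records) {
    comp <- count_charges(s)
    expect_equal(comp$c_positive, 10L)
    expect_equal(comp$c_negative, 5L)
    expect_equal(comp$c_variable, 2L)
    expect_equal(comp$n_residues, 50L)
  }
})

test_that("the proteome generator is deterministic and id-complete", {
  cfg <- small_config()
  f1 <- tempfile(fileext = ".fasta")
  f2 <- tempfile(fileext = ".fasta")
  p1 <- generate_proteome(cfg, fasta = f1)
  p2 <- generate_proteome(cfg, fasta = f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(p1$records, p2$records)
  expect_equal(length(p1$records), cfg$n_proteins_total)
  expect_false(anyDuplicated(names(p1$records)) > 0)
  # realized counts match the recorded truth
  i <- 7L
  comp <- count_charges(p1$records[[i]])
  expect_equal(comp$c_positive, p1$truth$c_positive[i])
  expect_equal(comp$c_negative, p1$truth$c_negative[i])
  expect_equal(comp$c_variable, p1$truth$c_variable[i])
})

test_that("infeasible configurations are rejected", {
  expect_error(synthetic_config(charge_fraction_ranges = list(
    positive = 0.6, negative = 0.5, variable = 0.1)), "infeasible")
  expect_error(synthetic_config(n_proteins_total = 10L, n_detected = 11L))
  expect_error(synthetic_config(n_proteins_total = 10L, n_detected = 5L,
                                n_planted_hubs = 10L),
               "n_planted_hubs")
  expect_error(synthetic_config(n_proteins_total = 2L))
  expect_error(synthetic_config(n_replicates = 0L))
})

test_that("generated networks are simple, deterministic, and plant real hubs", {
  cfg <- small_config(network_model = "planted_hub", n_planted_hubs = 2L)
  n1 <- generate_network(cfg)
  n2 <- generate_network(cfg)
  expect_identical(igraph::as_edgelist(n1$network), igraph::as_edgelist(n2$network))
  g <- n1$network
  expect_false(igraph::any_loop(g))
  expect_false(igraph::any_multiple(g))
  deg <- igraph::degree(g)
  for (h in n1$truth$hub_ids) {
    expect_gte(deg[[h]], 10 * stats::median(deg))
  }
  # smallest admissible case stays connected under preferential attachment
  tiny <- generate_network(synthetic_config(n_proteins_total = 3L, n_detected = 3L,
                                            seed = 2L))
  expect_true(igraph::is_connected(tiny$network))
})

test_that("zero-noise evidence carries exact planted expectations", {
  cfg <- small_config(noise_scale = 0, effect_table = data.frame(
    protein_id = "SYN00001", effect_young = 0, effect_old = -50,
    stringsAsFactors = FALSE))
  prot <- generate_proteome(cfg)
  ev <- generate_ptm_evidence(cfg, prot)$evidence
  one <- ev[ev$site == ev$site[1] & ev$modification == ev$modification[1], ]
  v <- one$quantity[one$condition == "old-vehicle"][1]
  t_ <- one$quantity[one$condition == "old-treated"][1]
  expect_equal(t_ / v, 0.5)  # treated = vehicle x (1 + effect/100)
  y <- one$quantity[one$condition == "young-treated"][1]
  expect_equal(y, v)         # null young effect
  # truth records the planted signs
  truth <- generate_ptm_evidence(cfg, prot)$truth
  expect_equal(truth$sign_old, -1L)
  expect_equal(truth$sign_young, 0L)
})

test_that("effect tables referencing unknown proteins are rejected", {
  cfg <- small_config(effect_table = data.frame(
    protein_id = "NOPE", effect_young = 1, effect_old = 1))
  prot <- generate_proteome(small_config())
  expect_error(generate_ptm_evidence(cfg, prot), "outside the proteome")
})

test_that("Poisson-noise estimates concentrate around the planted effect", {
  base_cfg <- function(seed) {
    synthetic_config(n_proteins_total = 3L, n_detected = 1L,
                     length_range = c(100L, 100L), n_replicates = 3L,
                     baseline_mean = 1000, noise_model = "poisson",
                     effect_table = data.frame(protein_id = "SYN00001",
                                               effect_young = -50,
                                               effect_old = -50),
                     seed = seed)
  }
  pair <- c(vehicle = "old-vehicle", treated = "old-treated")
  hits <- vapply(1:50, function(s) {
    cfg <- base_cfg(s)
    prot <- generate_proteome(cfg)
    ev <- generate_ptm_evidence(cfg, prot)$evidence
    est <- ptm_change_table(ev, pair)$pct_change_per_site
    abs(est - (-50)) <= 10
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("LFQ ratios recover planted fold changes and reject them under noise", {
  fc <- data.frame(protein_id = c("SYN00001", "SYN00002"),
                   fc_young = c(2, 1), fc_old = c(4, 1),
                   stringsAsFactors = FALSE)
  cfg <- small_config(lfq_sigma = 0)
  prot <- generate_proteome(cfg)
  lfq <- generate_lfq(cfg, prot, fold_changes = fc)$lfq
  young <- lfq_log2_ratio(lfq, c(vehicle = "young-vehicle", treated = "young-treated"))
  expect_equal(young$log2_ratio[young$protein_id == "SYN00001"], 1)
  expect_equal(young$log2_ratio[young$protein_id == "SYN00002"], 0)
  old <- lfq_log2_ratio(lfq, c(vehicle = "old-vehicle", treated = "old-treated"))
  expect_equal(old$log2_ratio[old$protein_id == "SYN00001"], 2)

  # scaled-down power check: sigma 0.1, 4-fold change, n = 3 -> t-test rejects
  rejections <- vapply(1:50, function(s) {
    cfg_s <- small_config(lfq_sigma = 0.1, seed = s)
    prot_s <- generate_proteome(cfg_s)
    l <- generate_lfq(cfg_s, prot_s, fold_changes = fc)$lfq
    one <- l[l$protein_id == "SYN00001" &
               l$condition %in% c("old-vehicle", "old-treated"), ]
    p <- stats::t.test(log(one$intensity[one$condition == "old-treated"]),
                       log(one$intensity[one$condition == "old-vehicle"]))$p.value
    p < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.9)
})

test_that("dataset bundles are byte-identical across reruns and truth-linked", {
  cfg <- small_config(network_model = "planted_hub", n_planted_hubs = 1L)
  d1 <- file.path(tempdir(), "bundle1")
  d2 <- file.path(tempdir(), "bundle2")
  b1 <- simulate_dataset(cfg, d1)
  b2 <- simulate_dataset(cfg, d2)
  for (f in c("proteome.fasta", "network_edges.txt", "ptm_evidence.csv",
              "lfq.csv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # every truth entry refers to a generated protein
  ids <- names(b1$proteome$records)
  expect_true(all(b1$truth$ptm_effects$protein_id %in% ids))
  expect_true(all(b1$truth$hub_ids %in% ids))
  expect_true(all(b1$truth$lfq_fold_changes$protein_id %in% ids))
  unlink(c(d1, d2), recursive = TRUE)
})
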