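test_that("generators are pure functions of the configuration", {
  cfg <- tiny_cfg(noise_sd = 0.15, seed = 9)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a, b)
  expect_identical(simulate_repertoire(cfg)$records, simulate_repertoire(cfg)$records)
  expect_identical(simulate_peaks(cfg, simulate_gene_models(cfg))$peaks,
                   simulate_peaks(cfg, simulate_gene_models(cfg))$peaks)
})

test_that("noiseless expression hits the planted fold factors exactly", {
  cfg <- simulation_config(n_genes = 100, n_signature_up = 10, n_signature_down = 5,
                           signature_effect_up = c(2, 2),
                           signature_effect_down = c(0.4, 0.4),
                           n_biased_inkt = 2, n_biased_gdnkt = 2, n_common = 2,
                           n_discordant = 1, n_dp_changed = 5, n_enrichment_set = 5,
                           n_target_genes_with_peaks = 5, n_offsignature_targets = 1,
                           n_correlated_pos = 3, n_correlated_neg = 3,
                           noise_sd = 0, seed = 2)
  sim <- simulate_expression(cfg)
  m <- as.matrix(sim$expression[-1])
  rownames(m) <- sim$expression$gene_id
  sm <- sim$samples
  ref <- rowMeans(m[, sm$sample_id[sm$role == "ref_ab"]])
  inkt <- rowMeans(m[, sm$sample_id[sm$role == "inkt_wt"]])
  ratio <- inkt / ref
  expect_equal(unname(ratio[sim$truth$signature_up]),
               rep(2, 10), tolerance = 1e-12)
  expect_equal(unname(ratio[sim$truth$signature_down]),
               rep(0.4, 5), tolerance = 1e-12)
  # the anchor and correlated genes perturb the pooled reference through
  # their planted WT-DP pattern; everything else sits exactly at ratio 1
  dp_patterned <- c(sim$truth$anchor, sim$truth$correlated_pos,
                    sim$truth$correlated_neg)
  background <- setdiff(rownames(m), c(sim$truth$signature_up,
                                       sim$truth$signature_down, dp_patterned))
  expect_equal(unname(ratio[background]), rep(1, length(background)),
               tolerance = 1e-12)
  # dp-patterned genes can never leak into the dual-gated signature:
  # their gamma-delta lineage ratio is exactly 1
  gd <- rowMeans(m[, sm$sample_id[sm$role == "gdnkt_wt"]]) /
    rowMeans(m[, sm$sample_id[sm$role == "ref_gd"]])
  expect_equal(unname(gd[dp_patterned]), rep(1, length(dp_patterned)),
               tolerance = 1e-12)
  expect_true(all(m > 0))
  # planted signature recovered exactly and exclusively
  smap <- sim$samples
  expr <- sim$expression
  fc_i <- fold_change(expr, smap, unique(smap$population[smap$role == "inkt_wt"]),
                      unique(smap$population[smap$role == "ref_ab"]), pseudocount = 0)
  fc_g <- fold_change(expr, smap, unique(smap$population[smap$role == "gdnkt_wt"]),
                      unique(smap$population[smap$role == "ref_gd"]), pseudocount = 0)
  sig <- derive_signature(fc_i, fc_g)
  expect_identical(sort(sig$gene_id[sig$direction == "up"]), sim$truth$signature_up)
  expect_identical(sort(sig$gene_id[sig$direction == "down"]), sim$truth$signature_down)
})

test_that("planted peaks annotate back to their intended categories and decoys filter out", {
  cfg <- tiny_cfg(seed = 3)
  models <- simulate_gene_models(cfg)
  pk <- simulate_peaks(cfg, models)
  sig_peaks <- filter_significant_peaks(pk$peaks)
  expect_true(all(startsWith(sig_peaks$name, "peak_") |
                    startsWith(sig_peaks$name, "far_")))
  ann <- annotate_peaks(sig_peaks, models)
  planted <- dplyr::inner_join(ann, pk$truth, by = c(name = "peak_name"))
  expect_equal(planted$gene_id.x, planted$gene_id.y)
  expect_equal(planted$category.x, planted$category.y)
  far <- ann[startsWith(ann$name, "far_"), ]
  expect_true(all(far$category == "unassigned"))
  targets <- call_tf_targets(ann)
  expect_setequal(targets, unique(pk$truth$gene_id))
})

test_that("zero planted targets yield no called targets", {
  cfg <- tiny_cfg(seed = 4)
  models <- simulate_gene_models(cfg)
  pk <- simulate_peaks(cfg, models, target_genes = character(0))
  expect_equal(nrow(pk$truth), 0)
  ann <- annotate_peaks(filter_significant_peaks(pk$peaks), models)
  expect_equal(call_tf_targets(ann[startsWith(ann$name, "peak_"), ]), character(0))
})

test_that("repertoire planting matches the null, enrichment and productivity contracts", {
  base_cfg <- tiny_cfg(seed = 11)
  # enrichment factor 1: mean frequencies equal across genotypes within error
  null_cfg <- simulation_config(
    n_genes = base_cfg$n_genes, noise_sd = 0, seed = 11,
    repertoire = repertoire_config(mice_per_genotype = 3, reads_per_mouse = 20000,
                                   j18_enrichment = 1)
  )
  sim <- simulate_repertoire(null_cfg)
  u <- j_usage(sim$records, v_call = "TRAV11")
  f18 <- u |> dplyr::filter(j_call == "TRAJ18") |>
    dplyr::group_by(genotype) |> dplyr::summarise(f = mean(frequency))
  p0 <- 1 / length(null_cfg$repertoire$j_segments)
  expect_true(all(abs(f18$f - p0) < 4 * sqrt(p0 * (1 - p0) / 10000 / 3)))
  # productive fraction 1 -> all junctions in-frame and stop-free
  all_prod <- simulation_config(
    n_genes = 200, seed = 12,
    repertoire = repertoire_config(mice_per_genotype = 2, reads_per_mouse = 600,
                                   productive_fraction = 1))
  recs <- simulate_repertoire(all_prod)$records
  expect_true(all(nchar(recs$junction) %% 3 == 0))
  expect_true(all(classify_productivity(recs$junction) == "productive"))
  # planted 3x enrichment at 20,000 reads/mouse: estimated ratio within 10% of 3
  enr <- simulation_config(n_genes = 200, seed = 13,
                           repertoire = repertoire_config(mice_per_genotype = 3,
                                                          reads_per_mouse = 20000))
  ue <- j_usage(simulate_repertoire(enr)$records, v_call = "TRAV11")
  fe <- ue |> dplyr::filter(j_call == "TRAJ18") |>
    dplyr::group_by(genotype) |> dplyr::summarise(f = mean(frequency))
  ratio <- fe$f[fe$genotype == "LDKO"] / fe$f[fe$genotype == "WT"]
  expect_lt(abs(ratio - 3) / 3, 0.10)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_genes = 10, n_signature_up = 20),
               "exceed")
  expect_error(simulation_config(n_signature_up = 30, n_signature_down = 0,
                                 n_biased_inkt = 31, n_biased_gdnkt = 0,
                                 n_common = 0, n_discordant = 0),
               "exceed the planted signature")
  expect_error(simulation_config(signature_effect_up = c(1.2, 3)), "1.5 gate")
  expect_error(simulation_config(dysregulation_effect = c(1.5, 3)), "2 gate")
  expect_error(repertoire_config(j_usage_baseline = rep(0.5, 3)), "simplex")
  expect_error(repertoire_config(j18_enrichment = -1), "> 0")
})

test_that("simulated files parse back through the package readers losslessly", {
  sim <- simulate_all(tiny_cfg(noise_sd = 0.1, seed = 14))
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  ex <- read_expression(paths[["expression"]], paths[["sample_map"]])
  expect_equal(ex$expression, sim$expression, tolerance = 1e-12)
  expect_equal(ex$samples, sim$samples)
  models <- read_gene_models(paths[["gene_models"]])
  expect_equal(dplyr::arrange(models, gene_id),
               dplyr::arrange(sim$gene_models, gene_id))
  peaks <- read_peaks(paths[["peaks"]])
  expect_equal(peaks[c("chrom", "start", "end", "name")],
               sim$peaks[c("chrom", "start", "end", "name")])
  expect_equal(read_rearrangements(paths[["rearrangements"]]), sim$rearrangements)
  expect_equal(read_gmt(paths[["gene_sets"]]), sim$gene_sets)
  truth <- read_truth(paths[["truth"]])
  expect_equal(truth$signature_up, sim$truth$signature_up)
  expect_equal(truth$dysregulated, sim$truth$dysregulated)
  expect_equal(truth$targets, sim$truth$targets)
  expect_equal(truth$repertoire$j18_frequency, sim$truth$repertoire$j18_frequency)
  expect_equal(truth$correlated_pos, sim$truth$correlated_pos)
})
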