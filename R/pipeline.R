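innate_config_defaults <- function() {
  list(
    sim = NULL,                       # simulation_config(); seeded from `seed`
    up_thresh = 1.5,
    down_thresh = 0.6,
    strict_signature = TRUE,
    dysreg_threshold = 2,
    strict_dysreg = TRUE,
    bias_delta = 1,
    p_max = 1e-5,
    score_dialect = "minus10log10",
    windows = default_windows(),
    correlation_cutoff = 0.7,
    anchor_gene = "Zbtb16",
    n_permutations = 1000,
    weight_exponent = 1,
    unchanged_threshold = 2,
    pseudocount = 1,
    min_max_expr = 1,
    literature_genes = innate_literature_genes,
    tf_name = "Tcf3",
    j_v_call = "TRAV11",
    j_call_of_interest = "TRAJ18",
    j_bins = default_j_bins(),
    seed = 1L
  )
}

#' Pipeline configuration
#'
#' Collects every threshold of the analysis in one validated object:
#' the 1.5x/0.6x dual signature gates, the 2x dysregulation gate and
#' its strictness, the lineage-bias delta, peak windows / score dialect
#' / p-value cutoff, the 0.7 dual correlation cutoff, the permutation
#' count, the unchanged-universe band, pseudocounts and filters.
#' Unknown keys are rejected and a fully-defaulted configuration is
#' valid.  `seed` drives both the synthetic-data generator and the
#' permutation test.
#'
#' @param ... Named overrides of the defaults (see
#'   [innate_config_defaults values][run_innate_pipeline()] docs).
#' @return A validated list of class `innate_config`.
#' @export
innate_config <- function(...) {
  defaults <- innate_config_defaults()
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown) > 0 || (length(override) > 0 && is.null(names(override)))) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, override)
  cfg$seed <- as.integer(cfg$seed)
  if (is.null(cfg$sim)) cfg$sim <- simulation_config(seed = cfg$seed)
  if (cfg$up_thresh <= 1) abort("`up_thresh` must be > 1.")
  if (cfg$down_thresh <= 0 || cfg$down_thresh >= 1) abort("`down_thresh` must be in (0, 1).")
  if (cfg$dysreg_threshold <= 1) abort("`dysreg_threshold` must be > 1.")
  if (cfg$bias_delta < 0) abort("`bias_delta` must be >= 0.")
  if (cfg$p_max <= 0 || cfg$p_max >= 1) abort("`p_max` must be in (0, 1).")
  if (cfg$correlation_cutoff <= 0 || cfg$correlation_cutoff > 1) {
    abort("`correlation_cutoff` must be in (0, 1].")
  }
  if (cfg$n_permutations < 1) abort("`n_permutations` must be >= 1.")
  if (cfg$pseudocount < 0) abort("`pseudocount` must be >= 0.")
  structure(cfg, class = "innate_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror [innate_config()] arguments; the optional `sim`
#' block mirrors [simulation_config()] and its `repertoire` sub-block
#' mirrors [repertoire_config()].
#'
#' @param path YAML file.
#' @return An `innate_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path) %||% list()
  if (!is.null(y$sim)) {
    simargs <- y$sim
    if (!is.null(simargs$repertoire)) {
      simargs$repertoire <- do.call(repertoire_config, simargs$repertoire)
    }
    y$sim <- do.call(simulation_config, simargs)
  }
  do.call(innate_config, y)
}

#' Run the full innate-signature analysis pipeline
#'
#' Executes simulate -> expression I/O and filtering -> signature
#' derivation -> dysregulation grouping -> peak annotation and target
#' calling -> network assembly/export -> anchor correlation -> weighted
#' enrichment with permutation null -> repertoire analysis, all from
#' the files written under `out_dir/inputs` (every stage consumes what
#' the readers parsed back, so the file round trip is part of the run).
#' A manifest JSON records the seed, every threshold in force and
#' per-stage counts; a rerun with the same configuration is
#' byte-identical.
#'
#' @param config An [innate_config()].
#' @param out_dir Output directory; inputs go to `out_dir/inputs`,
#'   results to `out_dir/results`.
#' @return Invisibly, a list with every intermediate result (`sim`,
#'   `signature`, `grouped`, `annotations`, `targets`, `network`,
#'   `correlation`, `enrichment`, `usage`, `bins`, `comparison`, `pca`,
#'   `manifest`, `paths`).
#' @export
run_innate_pipeline <- function(config = innate_config(), out_dir) {
  stopifnot(inherits(config, "innate_config"))
  inputs_dir <- file.path(out_dir, "inputs")
  results_dir <- file.path(out_dir, "results")
  dir.create(results_dir, recursive = TRUE, showWarnings = FALSE)

  sim <- simulate_all(config$sim)
  in_paths <- write_simulation(sim, inputs_dir)

  ex <- read_expression(in_paths[["expression"]], in_paths[["sample_map"]])
  sm <- ex$samples
  expr <- filter_low_quality(ex$expression, config$min_max_expr)
  pops_of <- function(role) unique(sm$population[sm$role == role])

  fc_inkt_wt <- fold_change(expr, sm, pops_of("inkt_wt"), pops_of("ref_ab"),
                            config$pseudocount, contrast = "iNKT_WT vs ref_ab")
  fc_gd_wt <- fold_change(expr, sm, pops_of("gdnkt_wt"), pops_of("ref_gd"),
                          config$pseudocount, contrast = "gdNKT_WT vs ref_gd")
  sig <- derive_signature(fc_inkt_wt, fc_gd_wt, config$up_thresh,
                          config$down_thresh, config$strict_signature) |>
    augment_with_literature(config$literature_genes)

  fc_inkt_mut <- fold_change(expr, sm, pops_of("inkt_mut"), pops_of("inkt_wt"),
                             config$pseudocount, contrast = "iNKT mutant vs WT")
  fc_gd_mut <- fold_change(expr, sm, pops_of("gdnkt_mut"), pops_of("gdnkt_wt"),
                           config$pseudocount, contrast = "gdNKT mutant vs WT")
  grouped <- intersect_signature(call_dysregulated(fc_inkt_mut, config$dysreg_threshold,
                                                   config$strict_dysreg),
                                 call_dysregulated(fc_gd_mut, config$dysreg_threshold,
                                                   config$strict_dysreg),
                                 sig) |>
    classify_groups(config$bias_delta)

  peaks <- read_peaks(in_paths[["peaks"]])
  sig_peaks <- filter_significant_peaks(peaks, config$p_max, config$score_dialect)
  models <- read_gene_models(in_paths[["gene_models"]])
  annotations <- annotate_peaks(sig_peaks, models, config$windows)
  targets <- call_tf_targets(annotations, expr$gene_id)

  interactions <- read_interactions(in_paths[["interactions"]])
  network <- build_network(grouped, targets, config$tf_name, interactions)
  write_network(network, results_dir)

  dp_samples <- sm$sample_id[sm$dp_family]
  correlation <- correlate_with_anchor(expr, config$anchor_gene, dp_samples,
                                       config$correlation_cutoff)

  wt_dp <- unique(sm$population[sm$dp_family & sm$genotype == "WT"])
  fc_dp <- fold_change(expr, sm, pops_of("dp_mut"), wt_dp, config$pseudocount,
                       contrast = "mutant DP vs WT DP")
  universe <- unchanged_universe(fc_dp, config$unchanged_threshold)
  ranked <- rank_by_class_ratio(expr,
                                sm$sample_id[sm$role == "dp_mut_pta"],
                                sm$sample_id[sm$role == "dp_mut"],
                                config$pseudocount, genes = universe)
  gene_sets <- read_gmt(in_paths[["gene_sets"]])
  enrichment <- purrr::imap(gene_sets, function(set, nm) {
    permutation_test(ranked, set, config$n_permutations,
                     config$weight_exponent, seed = config$seed + 11L,
                     set_name = nm)
  })

  records <- read_rearrangements(in_paths[["rearrangements"]])
  usage <- j_usage(records, v_call = config$j_v_call)
  bins <- bin_proximal_distal(usage, config$j_bins)
  genos <- config$sim$repertoire$genotypes
  comparison <- compare_genotypes(usage, genos[["wt"]], genos[["mutant"]],
                                  config$j_call_of_interest)
  pca <- pca_samples(expr, scale = "linear", pseudocount = config$pseudocount)

  out <- list(
    signature = sig, grouped = grouped,
    fold_changes = dplyr::bind_rows(fc_inkt_wt, fc_gd_wt, fc_inkt_mut,
                                    fc_gd_mut, fc_dp),
    annotations = annotations, targets = tibble(gene_id = targets),
    correlation = correlation, ranked = ranked,
    enrichment_report = purrr::map_dfr(enrichment, tidy_gsea_row),
    usage = usage, bins = bins, comparison = comparison,
    pca_scores = pca$scores
  )
  for (nm in names(out)) {
    readr::write_tsv(out[[nm]], file.path(results_dir, paste0(nm, ".tsv")),
                     progress = FALSE)
  }

  manifest <- list(
    package = "innatesig",
    version = as.character(utils::packageVersion("innatesig")),
    seed = config$seed,
    thresholds = list(
      up_thresh = config$up_thresh, down_thresh = config$down_thresh,
      strict_signature = config$strict_signature,
      dysreg_threshold = config$dysreg_threshold,
      strict_dysreg = config$strict_dysreg, bias_delta = config$bias_delta,
      p_max = config$p_max, score_dialect = config$score_dialect,
      windows = config$windows,
      correlation_cutoff = config$correlation_cutoff,
      n_permutations = config$n_permutations,
      weight_exponent = config$weight_exponent,
      permutation_type = "gene-set",
      unchanged_threshold = config$unchanged_threshold,
      pseudocount = config$pseudocount, min_max_expr = config$min_max_expr,
      j_bins = config$j_bins
    ),
    counts = c(list(
      n_genes_input = nrow(ex$expression), n_genes_filtered = nrow(expr),
      n_signature_derived = sum(sig$source == "derived"),
      n_signature_total = nrow(sig),
      n_dysregulated_signature = nrow(grouped),
      n_significant_peaks = nrow(sig_peaks), n_peaks_input = nrow(peaks),
      n_targets = length(targets),
      n_network_nodes = nrow(network$nodes),
      n_network_edges = nrow(network$edges),
      n_unchanged_universe = length(universe),
      n_correlated_pos = sum(correlation$klass == "positive"),
      n_correlated_neg = sum(correlation$klass == "negative"),
      n_reads = nrow(records)
    ), group_counts(grouped))
  )
  jsonlite::write_json(manifest, file.path(results_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(sim = sim, expression = expr, samples = sm,
                 signature = sig, grouped = grouped,
                 annotations = annotations, targets = targets,
                 network = network, correlation = correlation,
                 universe = universe, ranked = ranked,
                 enrichment = enrichment, usage = usage, bins = bins,
                 comparison = comparison, pca = pca, manifest = manifest,
                 paths = list(inputs = in_paths, results = results_dir)))
}

tidy_gsea_row <- function(x) {
  tibble(set_name = x$set_name, es = x$es, nes = x$nes, p_perm = x$p_perm,
         n_perm = x$n_perm, n_hits = x$n_hits,
         n_leading_edge = length(x$leading_edge))
}
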