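#' Default simulated cell populations
#'
#' Thymocyte populations emulating the structure of the real study
#' design: five conventional alpha-beta reference populations (DN3a,
#' DN3b, DN4, DP, CD4SP), a conventional gamma-delta reference (Tgd),
#' wild-type and mutant innate-like populations (iNKT and gamma-delta
#' NKT), and a DP family (WT, Id-deficient, Id- and pTa-deficient) used
#' for the anchor-correlation and enrichment analyses.
#'
#' @param n_rep Replicates per population (default 2).
#' @return Tibble with columns `population`, `n_rep`, `role`,
#'   `genotype`, `dp_family`.
#' @export
default_populations <- function(n_rep = 2) {
  tibble(
    population = c("DN3a", "DN3b", "DN4", "DP", "CD4SP", "Tgd",
                   "iNKT_WT", "gdNKT_WT", "iNKT_LDKO", "gdNKT_Id3KO",
                   "DP_LDKO", "DP_LDKO_pTa"),
    n_rep = n_rep,
    role = c(rep("ref_ab", 5), "ref_gd", "inkt_wt", "gdnkt_wt",
             "inkt_mut", "gdnkt_mut", "dp_mut", "dp_mut_pta"),
    genotype = c(rep("WT", 8), "LDKO", "Id3KO", "LDKO", "LDKO_pTa"),
    dp_family = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
                  FALSE, FALSE, TRUE, TRUE)
  )
}

#' Repertoire simulation settings
#'
#' @param genotypes Named length-2 character vector `c(wt = , mutant = )`.
#' @param mice_per_genotype Mice per genotype (default 3).
#' @param reads_per_mouse Total reads per mouse, split evenly across the
#'   V segments (default 20000).
#' @param v_calls Named vector mapping common V-alpha names to TRAV
#'   calls; the `Va14` entry receives the planted J-alpha-18 enrichment.
#' @param j_segments TRAJ segments in play.
#' @param j_usage_baseline Baseline usage simplex over `j_segments`
#'   (default uniform); must sum to 1 within 1e-9.
#' @param j18_enrichment Multiplicative J-alpha-18 enrichment planted in
#'   mutant V-alpha-14 reads before renormalization (default 3).
#' @param productive_fraction Expected fraction of productive junctions
#'   (default 0.75).
#' @return Named list of settings.
#' @export
repertoire_config <- function(genotypes = c(wt = "WT", mutant = "LDKO"),
                              mice_per_genotype = 3,
                              reads_per_mouse = 20000,
                              v_calls = c(Va14 = "TRAV11", Va8 = "TRAV8-1"),
                              j_segments = paste0("TRAJ", c(2, 5, 7, 9, 11, 12,
                                13, 15, 16, 17, 18, 21, 22, 23, 24, 26, 27, 30,
                                31, 32, 33, 34, 35, 37, 38, 39, 40, 42, 43, 45,
                                48, 49, 50, 52, 53, 56, 57, 58)),
                              j_usage_baseline = NULL,
                              j18_enrichment = 3,
                              productive_fraction = 0.75) {
  if (length(genotypes) != 2 || is.null(names(genotypes))) {
    abort("`genotypes` must be a named length-2 vector c(wt=, mutant=).")
  }
  mice_per_genotype <- assert_count(mice_per_genotype, "mice_per_genotype", 1)
  reads_per_mouse <- assert_count(reads_per_mouse, "reads_per_mouse", 1)
  j_usage_baseline <- j_usage_baseline %||%
    rep(1 / length(j_segments), length(j_segments))
  if (length(j_usage_baseline) != length(j_segments) ||
      abs(sum(j_usage_baseline) - 1) > 1e-9 || any(j_usage_baseline < 0)) {
    abort("`j_usage_baseline` must be a simplex over `j_segments` (sum 1 within 1e-9).")
  }
  if (j18_enrichment <= 0) abort("`j18_enrichment` must be > 0.")
  if (!"TRAJ18" %in% j_segments) abort("`j_segments` must include TRAJ18.")
  if (productive_fraction < 0 || productive_fraction > 1) {
    abort("`productive_fraction` must be in [0, 1].")
  }
  list(genotypes = genotypes, mice_per_genotype = mice_per_genotype,
       reads_per_mouse = reads_per_mouse, v_calls = v_calls,
       j_segments = j_segments, j_usage_baseline = j_usage_baseline,
       j18_enrichment = j18_enrichment,
       productive_fraction = productive_fraction)
}

#' Simulation settings with planted ground truth
#'
#' Defines the synthetic study: population-structured expression with
#' planted concordant signature genes, planted lineage-biased / common /
#' discordant dysregulation inside the signature, an anchor gene
#' (`Zbtb16`) with planted positively and negatively correlated gene
#' blocks across the DP-family samples, a planted enrichment gene set
#' upregulated in the pTa-deficient mutant DP samples, ChIP peaks
#' planted in defined region categories, and a multinomial TCR-alpha
#' repertoire with planted J-alpha-18 enrichment.
#'
#' @param n_genes Number of background genes (an extra `Zbtb16` anchor
#'   row is always added).
#' @param populations Population design tibble ([default_populations()]).
#' @param n_signature_up,n_signature_down Planted concordant signature
#'   genes per direction.
#' @param signature_effect_up Fold-factor range for planted up genes
#'   (entirely above the 1.5 gate).
#' @param signature_effect_down Fold-factor range for planted down genes
#'   (entirely below the 0.6 gate).
#' @param n_biased_inkt,n_biased_gdnkt,n_common,n_discordant Planted
#'   dysregulation classes (drawn from the signature genes; their sum
#'   must not exceed the signature size).
#' @param dysregulation_effect Fold-factor magnitude range (entirely
#'   above the 2 gate).
#' @param n_dp_changed Genes planted as changed in mutant DP versus WT
#'   DP (excluded from the unchanged enrichment universe).
#' @param n_enrichment_set Genes of the planted enrichment set,
#'   upregulated by `enrichment_boost` only in the pTa-deficient mutant
#'   DP samples.
#' @param enrichment_boost Fold boost of the enrichment-set genes.
#' @param n_target_genes_with_peaks Planted regulator target genes drawn
#'   from the dysregulated signature genes (topped up from other genes
#'   if needed).
#' @param n_offsignature_targets Additional planted targets outside the
#'   signature.
#' @param peak_category_mix Proportions over the five region categories.
#' @param n_correlated_pos,n_correlated_neg Planted anchor-correlated
#'   genes.
#' @param repertoire Settings from [repertoire_config()].
#' @param noise_sd Log2-scale lognormal dispersion of baselines and
#'   per-sample noise (0 = noiseless).
#' @param seed RNG seed; all generators are pure functions of the
#'   configuration.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 600,
                              populations = default_populations(),
                              n_signature_up = 40, n_signature_down = 20,
                              signature_effect_up = c(1.8, 3.5),
                              signature_effect_down = c(0.2, 0.5),
                              n_biased_inkt = 8, n_biased_gdnkt = 8,
                              n_common = 10, n_discordant = 4,
                              dysregulation_effect = c(5.5, 9),
                              n_dp_changed = 25,
                              n_enrichment_set = 15,
                              enrichment_boost = 2,
                              n_target_genes_with_peaks = 20,
                              n_offsignature_targets = 5,
                              peak_category_mix = c(promoter = 0.35,
                                                    `enhancer-window` = 0.2,
                                                    intragenic = 0.25,
                                                    downstream = 0.1,
                                                    intergenic = 0.1),
                              n_correlated_pos = 12, n_correlated_neg = 8,
                              repertoire = repertoire_config(),
                              noise_sd = 0.15,
                              seed = 20180405) {
  n_genes <- assert_count(n_genes, "n_genes", 1)
  for (nm in c("n_signature_up", "n_signature_down", "n_biased_inkt",
               "n_biased_gdnkt", "n_common", "n_discordant", "n_dp_changed",
               "n_enrichment_set", "n_target_genes_with_peaks",
               "n_offsignature_targets", "n_correlated_pos",
               "n_correlated_neg")) {
    assign(nm, assert_count(get(nm), nm))
  }
  signature_effect_up <- assert_range(signature_effect_up, "signature_effect_up")
  signature_effect_down <- assert_range(signature_effect_down, "signature_effect_down")
  dysregulation_effect <- assert_range(dysregulation_effect, "dysregulation_effect")
  if (signature_effect_up[1] <= 1.5) abort("`signature_effect_up` must lie above the 1.5 gate.")
  if (signature_effect_down[2] >= 0.6 || signature_effect_down[1] <= 0) {
    abort("`signature_effect_down` must lie in (0, 0.6).")
  }
  if (dysregulation_effect[1] <= 2) abort("`dysregulation_effect` must lie above the 2 gate.")
  n_sig <- n_signature_up + n_signature_down
  n_dys <- n_biased_inkt + n_biased_gdnkt + n_common + n_discordant
  if (n_dys > n_sig) abort("planted dysregulation classes exceed the planted signature size.")
  n_planted <- n_sig + n_dp_changed + n_enrichment_set + n_correlated_pos + n_correlated_neg
  if (n_planted > n_genes) abort("planted gene classes exceed `n_genes`.")
  if (abs(sum(peak_category_mix) - 1) > 1e-9 || any(peak_category_mix < 0) ||
      !setequal(names(peak_category_mix), peak_categories)) {
    abort("`peak_category_mix` must be a named simplex over the five region categories.")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (enrichment_boost <= 1) abort("`enrichment_boost` must be > 1.")
  structure(list(
    n_genes = n_genes, populations = populations,
    n_signature_up = n_signature_up, n_signature_down = n_signature_down,
    signature_effect_up = signature_effect_up,
    signature_effect_down = signature_effect_down,
    n_biased_inkt = n_biased_inkt, n_biased_gdnkt = n_biased_gdnkt,
    n_common = n_common, n_discordant = n_discordant,
    dysregulation_effect = dysregulation_effect,
    n_dp_changed = n_dp_changed, n_enrichment_set = n_enrichment_set,
    enrichment_boost = enrichment_boost,
    n_target_genes_with_peaks = n_target_genes_with_peaks,
    n_offsignature_targets = n_offsignature_targets,
    peak_category_mix = peak_category_mix,
    n_correlated_pos = n_correlated_pos, n_correlated_neg = n_correlated_neg,
    repertoire = repertoire, noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "simulation_config")
}

# log2 multipliers of the anchor gene across the DP family; low in WT DP,
# equally high in both mutant DP conditions so that no other planted
# condition effect reaches the +/-0.7 dual correlation cutoff
anchor_pattern <- c(DP = 0.5, DP_LDKO = 2, DP_LDKO_pTa = 2)

#' Simulate a population-structured expression matrix
#'
#' Baselines are lognormal on the log2 scale (mean 3, sd `noise_sd`,
#' i.e. FPKM-like strictly positive values around 8); per-sample
#' multiplicative lognormal noise has the same dispersion.  Planted
#' effects are applied as population-level fold factors (see
#' [simulation_config()]).
#'
#' @param cfg A `simulation_config`.
#' @param seed Optional seed override.
#' @return List with `expression` (tibble), `samples` (sample map) and
#'   `truth` (planted labels).
#' @export
simulate_expression <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  pops <- cfg$populations
  withr::with_seed(as.integer(seed %||% (cfg$seed + 1L)), {
    ids <- c(sprintf("gene_%04d", seq_len(cfg$n_genes)), "Zbtb16")
    n_tot <- length(ids)
    anchor <- "Zbtb16"
    pool <- seq_len(cfg$n_genes)
    take <- function(n) {
      picked <- sample(pool, n)
      pool <<- setdiff(pool, picked)
      picked
    }
    up_idx <- take(cfg$n_signature_up)
    down_idx <- take(cfg$n_signature_down)
    sig_idx <- c(up_idx, down_idx)
    dys_idx <- sample(sig_idx, cfg$n_biased_inkt + cfg$n_biased_gdnkt +
                        cfg$n_common + cfg$n_discordant)
    dys_class <- rep(c("biased_inkt", "biased_gdnkt", "common", "discordant"),
                     times = c(cfg$n_biased_inkt, cfg$n_biased_gdnkt,
                               cfg$n_common, cfg$n_discordant))
    dp_changed_idx <- take(cfg$n_dp_changed)
    enrich_idx <- take(cfg$n_enrichment_set)
    pos_idx <- take(cfg$n_correlated_pos)
    neg_idx <- take(cfg$n_correlated_neg)

    f_sig <- numeric(n_tot)
    f_sig[up_idx] <- runif(cfg$n_signature_up, cfg$signature_effect_up[1],
                           cfg$signature_effect_up[2])
    f_sig[down_idx] <- runif(cfg$n_signature_down, cfg$signature_effect_down[1],
                             cfg$signature_effect_down[2])

    mag <- runif(length(dys_idx), cfg$dysregulation_effect[1],
                 cfg$dysregulation_effect[2])
    updown <- sample(c(1, -1), length(dys_idx), replace = TRUE)
    d_main <- mag^updown
    d_inkt <- rep(1, n_tot)
    d_gd <- rep(1, n_tot)
    d_inkt[dys_idx] <- ifelse(dys_class %in% c("biased_inkt", "common", "discordant"),
                              d_main, 1)
    d_gd[dys_idx] <- ifelse(dys_class == "biased_gdnkt", d_main,
                     ifelse(dys_class == "common", d_main,
                     ifelse(dys_class == "discordant", 1 / d_main, 1)))

    mult <- matrix(1, n_tot, nrow(pops), dimnames = list(ids, pops$population))
    innate_wt <- pops$population[pops$role %in% c("inkt_wt", "gdnkt_wt")]
    mult[sig_idx, innate_wt] <- f_sig[sig_idx]
    mult[, pops$population[pops$role == "inkt_mut"]] <-
      mult[, pops$population[pops$role == "inkt_wt"]] * d_inkt
    mult[, pops$population[pops$role == "gdnkt_mut"]] <-
      mult[, pops$population[pops$role == "gdnkt_wt"]] * d_gd

    d_dp <- runif(cfg$n_dp_changed, cfg$dysregulation_effect[1],
                  cfg$dysregulation_effect[2]) ^
      sample(c(1, -1), cfg$n_dp_changed, replace = TRUE)
    mult[dp_changed_idx, "DP_LDKO"] <- d_dp
    mult[enrich_idx, "DP_LDKO_pTa"] <- cfg$enrichment_boost
    mult[anchor, names(anchor_pattern)] <- anchor_pattern
    a_pos <- 2^runif(cfg$n_correlated_pos, -1, 1)
    a_neg <- 2^runif(cfg$n_correlated_neg, -1, 1)
    mult[pos_idx, names(anchor_pattern)] <-
      outer(a_pos, anchor_pattern)
    mult[neg_idx, names(anchor_pattern)] <-
      outer(a_neg, 1 / anchor_pattern)

    samples <- purrr::pmap_dfr(pops, function(population, n_rep, role,
                                              genotype, dp_family) {
      tibble(sample_id = paste0(population, "_r", seq_len(n_rep)),
             population = population, genotype = genotype,
             replicate = seq_len(n_rep), role = role, dp_family = dp_family)
    })
    baseline <- 2^rnorm(n_tot, 3, cfg$noise_sd)
    vals <- baseline * mult[, samples$population, drop = FALSE] *
      2^matrix(rnorm(n_tot * nrow(samples), 0, cfg$noise_sd), n_tot)
    colnames(vals) <- samples$sample_id

    truth <- list(
      anchor = anchor,
      signature_up = sort(ids[up_idx]),
      signature_down = sort(ids[down_idx]),
      dysregulated = tibble(
        gene_id = ids[dys_idx],
        class = dys_class,
        log2fc_inkt = log2(d_inkt[dys_idx]),
        log2fc_gdnkt = log2(d_gd[dys_idx]),
        expected_group = dplyr::recode(dys_class,
                                       biased_inkt = "iNKT-biased",
                                       biased_gdnkt = "gdNKT-biased",
                                       common = "common",
                                       discordant = "discordant")
      ) |> dplyr::arrange(gene_id),
      dp_changed = sort(ids[dp_changed_idx]),
      enrichment_set = sort(ids[enrich_idx]),
      correlated_pos = sort(ids[pos_idx]),
      correlated_neg = sort(ids[neg_idx])
    )
    list(expression = dplyr::bind_cols(tibble(gene_id = ids),
                                       as_tibble(vals, .name_repair = "minimal")),
         samples = samples, truth = truth)
  })
}

#' Simulate gene models
#'
#' One model per gene (including the anchor), laid out every 500 kb
#' across three chromosomes with random strand and 10-30 kb length, so
#' that every region category is realizable without neighbor collisions.
#'
#' @inheritParams simulate_expression
#' @return Gene-model tibble (same layout as [read_gene_models()]).
#' @export
simulate_gene_models <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  withr::with_seed(as.integer(seed %||% (cfg$seed + 2L)), {
    ids <- c(sprintf("gene_%04d", seq_len(cfg$n_genes)), "Zbtb16")
    n <- length(ids)
    per_chrom <- ceiling(n / 3)
    chrom <- paste0("chr", (seq_len(n) - 1) %/% per_chrom + 1)
    slot <- (seq_len(n) - 1) %% per_chrom
    start <- 200000 + slot * 500000
    len <- sample(10000:30000, n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    end <- start + len
    tibble(gene_id = ids, chrom = chrom, strand = strand,
           start = start, end = end,
           tss = ifelse(strand == "+", start, end),
           tes = ifelse(strand == "+", end, start))
  })
}

# deterministic in-window placement for a planted (gene, category) peak
place_peak <- function(models, gene, category, windows, half_width = 100) {
  wins <- gene_windows(models[models$gene_id == gene, , drop = FALSE], windows)
  row <- wins[wins$category == category, ]
  center <- if (category == "intergenic") {
    span_s <- row$wstart + windows$intergenic_horizon
    span_s - round(0.75 * windows$intergenic_horizon)
  } else {
    round((row$wstart + row$wend) / 2)
  }
  c(start = center - half_width, end = center + half_width)
}

#' Simulate ChIP peaks with planted region categories
#'
#' Every planted target gene receives one significant peak placed wholly
#' inside its drawn category window (scores 55-150 on the MACS 1.4
#' `-10*log10(p)` scale, i.e. p < 1e-5); sub-threshold decoy peaks and
#' significant far-intergenic peaks beyond every horizon are also
#' emitted.  A planted placement whose annotation would not round-trip
#' is re-drawn as a promoter peak with a message (cannot happen under
#' the default layout).
#'
#' @inheritParams simulate_expression
#' @param gene_models Gene-model tibble from [simulate_gene_models()].
#' @param target_genes Character vector of genes to plant peaks on (the
#'   pipeline draws them from the dysregulated signature; default: a
#'   random sample).
#' @param windows Window configuration.
#' @return List with `peaks` (tibble) and `truth` (tibble `gene_id`,
#'   `category`, `peak_name`).
#' @export
simulate_peaks <- function(cfg, gene_models, target_genes = NULL,
                           windows = default_windows(), seed = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  withr::with_seed(as.integer(seed %||% (cfg$seed + 3L)), {
    n_t <- cfg$n_target_genes_with_peaks + cfg$n_offsignature_targets
    target_genes <- target_genes %||% sample(gene_models$gene_id, n_t)
    cats <- sample(names(cfg$peak_category_mix), length(target_genes),
                   replace = TRUE, prob = cfg$peak_category_mix)
    empty_peaks <- tibble(chrom = character(), start = integer(),
                          end = integer(), gene_id = character(),
                          category = character(), name = character(),
                          score = numeric())
    planted <- empty_peaks[0, ]
    if (length(target_genes) > 0) planted <- purrr::map2_dfr(target_genes, cats, function(g, cat) {
      pos <- place_peak(gene_models, g, cat, windows)
      m <- gene_models[gene_models$gene_id == g, ]
      tibble(chrom = m$chrom, start = pos[["start"]], end = pos[["end"]],
             gene_id = g, category = cat)
    })
    # verify each planted peak annotates back to its intended label
    chk <- annotate_peaks(tibble(chrom = planted$chrom, start = planted$start,
                                 end = planted$end,
                                 name = as.character(seq_len(nrow(planted))),
                                 score = 100),
                          gene_models, windows)
    bad <- which(chk$gene_id != planted$gene_id | chk$category != planted$category)
    if (length(bad) > 0) {
      inform(sprintf("simulate_peaks: %d unrealizable placement(s) re-drawn as promoter peaks.",
                     length(bad)))
      for (i in bad) {
        pos <- place_peak(gene_models, planted$gene_id[i], "promoter", windows)
        planted$start[i] <- pos[["start"]]
        planted$end[i] <- pos[["end"]]
        planted$category[i] <- "promoter"
      }
    }
    planted$name <- sprintf("peak_%04d", seq_len(nrow(planted)))
    planted$score <- runif(nrow(planted), 55, 150)

    n_decoy <- max(10L, length(target_genes))
    decoy_genes <- sample(gene_models$gene_id, n_decoy, replace = TRUE)
    decoy_cats <- sample(names(cfg$peak_category_mix), n_decoy, replace = TRUE,
                         prob = cfg$peak_category_mix)
    decoys <- purrr::map2_dfr(decoy_genes, decoy_cats, function(g, cat) {
      pos <- place_peak(gene_models, g, cat, windows)
      m <- gene_models[gene_models$gene_id == g, ]
      tibble(chrom = m$chrom, start = pos[["start"]] + 10L,
             end = pos[["end"]] + 10L, gene_id = g, category = cat)
    })
    decoys$name <- sprintf("decoy_%04d", seq_len(nrow(decoys)))
    decoys$score <- runif(nrow(decoys), 5, 49)

    far <- gene_models |>
      dplyr::group_by(chrom) |>
      dplyr::summarise(pos = max(end) + 60000 + windows$enhancer_length +
                         windows$intergenic_horizon, .groups = "drop") |>
      dplyr::mutate(start = pos, end = pos + 200,
                    name = sprintf("far_%02d", dplyr::row_number()),
                    score = 100, gene_id = NA_character_,
                    category = "unassigned") |>
      dplyr::select(chrom, start, end, gene_id, category, name, score)

    peaks <- dplyr::bind_rows(planted, decoys, far) |>
      dplyr::select(chrom, start, end, name, score)
    truth <- dplyr::select(planted, gene_id, category, peak_name = name) |>
      dplyr::arrange(gene_id)
    list(peaks = peaks, truth = truth)
  })
}

codon_table <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}
stop_codons <- c("TAA", "TAG", "TGA")

# vectorized junction construction: stop-free in-frame codons for
# productive reads; a frameshift or an in-frame stop (50/50) otherwise
make_junctions <- function(n, productive_fraction) {
  if (n == 0) return(character(0))
  sense <- setdiff(codon_table(), stop_codons)
  k <- sample(4:6, n, replace = TRUE)
  mat <- matrix(sample(sense, n * 6, replace = TRUE), nrow = n)
  jx <- substr(do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE)),
               1, 3 * k)
  productive <- runif(n) < productive_fraction
  nonp <- which(!productive)
  shift <- nonp[runif(length(nonp)) < 0.5]
  stopped <- setdiff(nonp, shift)
  if (length(shift) > 0) {
    jx[shift] <- substr(jx[shift], 1,
                        3 * k[shift] - sample(1:2, length(shift), replace = TRUE))
  }
  if (length(stopped) > 0) {
    pos <- floor(runif(length(stopped)) * k[stopped]) + 1
    substr(jx[stopped], 3 * (pos - 1) + 1, 3 * pos) <-
      sample(stop_codons, length(stopped), replace = TRUE)
  }
  jx
}

#' Simulate a TCR-alpha rearrangement table
#'
#' Reads are drawn multinomially per mouse and V segment from the
#' baseline J-usage simplex; mutant-genotype V-alpha-14 reads have their
#' TRAJ18 probability multiplied by the planted enrichment factor and
#' renormalized.  Junctions hit the configured productive fraction in
#' expectation.
#'
#' @inheritParams simulate_expression
#' @return List with `records` (AIRR-style tibble) and `truth` (planted
#'   per-genotype V-alpha-14 TRAJ18 frequencies and the productive
#'   fraction).
#' @export
simulate_repertoire <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  rc <- cfg$repertoire
  withr::with_seed(as.integer(seed %||% (cfg$seed + 4L)), {
    p_base <- rc$j_usage_baseline
    j18 <- which(rc$j_segments == "TRAJ18")
    p_enr <- p_base
    p_enr[j18] <- p_enr[j18] * rc$j18_enrichment
    p_enr <- p_enr / sum(p_enr)
    per_v <- rc$reads_per_mouse %/% length(rc$v_calls)
    grid <- tidyr::expand_grid(
      genotype_key = names(rc$genotypes),
      mouse = seq_len(rc$mice_per_genotype),
      v_name = names(rc$v_calls)
    )
    records <- purrr::pmap_dfr(grid, function(genotype_key, mouse, v_name) {
      genotype <- rc$genotypes[[genotype_key]]
      p <- if (genotype_key == "mutant" && v_name == "Va14") p_enr else p_base
      counts <- as.vector(rmultinom(1, per_v, p))
      tibble(subject_id = paste0(genotype, "_m", mouse),
             genotype = genotype,
             v_call = rc$v_calls[[v_name]],
             j_call = rep(rc$j_segments, counts))
    })
    records <- records |>
      dplyr::mutate(junction = make_junctions(dplyr::n(), rc$productive_fraction),
                    sequence_id = sprintf("read_%07d", dplyr::row_number())) |>
      dplyr::select(sequence_id, subject_id, genotype, v_call, j_call, junction)
    truth <- list(
      j18_frequency = list(wt = p_base[j18], mutant = p_enr[j18]),
      j18_enrichment_planted = rc$j18_enrichment,
      j18_frequency_ratio = p_enr[j18] / p_base[j18],
      productive_fraction = rc$productive_fraction
    )
    list(records = records, truth = truth)
  })
}

#' Simulate a typed interaction table
#'
#' Random typed pairs among the given genes plus a few rows touching
#' genes outside the node universe (dropped during network assembly).
#'
#' @param genes Character vector of genes to draw pairs from.
#' @param n_edges Number of in-universe edges.
#' @param n_outside Rows with an endpoint outside `genes`.
#' @param seed RNG seed.
#' @return Interaction tibble (`gene_a`, `gene_b`, `type`).
#' @export
simulate_interactions <- function(genes, n_edges = 30, n_outside = 3, seed = 1) {
  withr::with_seed(as.integer(seed), {
    pairs <- t(replicate(n_edges, sample(genes, 2)))
    inside <- tibble(gene_a = pairs[, 1], gene_b = pairs[, 2],
                     type = sample(interaction_types, n_edges, replace = TRUE))
    outside <- tibble(gene_a = sample(genes, n_outside, replace = TRUE),
                      gene_b = paste0("EXT_", seq_len(n_outside)),
                      type = sample(interaction_types, n_outside, replace = TRUE))
    dplyr::bind_rows(inside, outside)
  })
}

#' Run the whole generator
#'
#' Produces every pipeline input with a merged truth manifest.  Planted
#' regulator targets are drawn from the dysregulated signature genes
#' (plus `n_offsignature_targets` genes outside the signature).
#'
#' @inheritParams simulate_expression
#' @return List with `expression`, `samples`, `gene_models`, `peaks`,
#'   `rearrangements`, `interactions`, `gene_sets` and `truth`.
#' @export
simulate_all <- function(cfg = simulation_config()) {
  ex <- simulate_expression(cfg)
  models <- simulate_gene_models(cfg)
  dys <- ex$truth$dysregulated$gene_id
  targets <- withr::with_seed(cfg$seed + 5L, {
    n_main <- min(cfg$n_target_genes_with_peaks, length(dys))
    main <- sample(dys, n_main)
    off_pool <- setdiff(models$gene_id,
                        c(ex$truth$signature_up, ex$truth$signature_down,
                          ex$truth$anchor))
    extra_n <- cfg$n_offsignature_targets +
      (cfg$n_target_genes_with_peaks - n_main)
    c(main, sample(off_pool, extra_n))
  })
  pk <- simulate_peaks(cfg, models, target_genes = targets)
  rep_sim <- simulate_repertoire(cfg)
  interactions <- simulate_interactions(if (length(dys) >= 2) dys else models$gene_id,
                                        seed = cfg$seed + 6L)
  truth <- ex$truth
  truth$targets <- pk$truth
  truth$target_genes <- sort(unique(pk$truth$gene_id))
  truth$repertoire <- rep_sim$truth
  list(expression = ex$expression, samples = ex$samples, gene_models = models,
       peaks = pk$peaks, rearrangements = rep_sim$records,
       interactions = interactions,
       gene_sets = list(innate_program = truth$enrichment_set),
       truth = truth, config = cfg)
}

#' Write all simulated inputs to a directory
#'
#' Emits expression TSV, sample-map TSV, gene-model GTF, BED6 peaks,
#' AIRR-style rearrangement TSV, interaction TSV, GMT gene sets and the
#' truth manifest as JSON; every file parses back through the package's
#' own readers.
#'
#' @param sim Output of [simulate_all()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    sample_map = file.path(dir, "sample_map.tsv"),
    gene_models = file.path(dir, "gene_models.gtf"),
    peaks = file.path(dir, "peaks.bed"),
    rearrangements = file.path(dir, "rearrangements.tsv"),
    interactions = file.path(dir, "interactions.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    truth = file.path(dir, "truth.json")
  )
  write_expression(sim$expression, paths[["expression"]])
  readr::write_tsv(sim$samples, paths[["sample_map"]], progress = FALSE)
  write_gene_models(sim$gene_models, paths[["gene_models"]])
  write_peaks(sim$peaks, paths[["peaks"]])
  write_rearrangements(sim$rearrangements, paths[["rearrangements"]])
  readr::write_tsv(sim$interactions, paths[["interactions"]], progress = FALSE)
  write_gmt(sim$gene_sets, paths[["gene_sets"]])
  write_truth(sim$truth, paths[["truth"]])
  invisible(paths)
}

#' Read and write the truth manifest
#'
#' @param truth Truth manifest list.
#' @param path JSON path.
#' @return `read_truth()` returns the manifest with tabular components
#'   restored as tibbles; the round trip is lossless.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  truth <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (nm in intersect(c("dysregulated", "targets"), names(truth))) {
    truth[[nm]] <- as_tibble(truth[[nm]])
  }
  truth
}
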