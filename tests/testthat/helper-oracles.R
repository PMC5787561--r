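# Independent brute-force oracles, deliberately written in a naive style
# so they share no code path with the implementation.

# average ranks computed from first principles
oracle_rank <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  num / den
}

oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_rank(x), oracle_rank(y))
}

# exhaustive (peak, gene, category) scan with independently re-derived
# window arithmetic; 0-based half-open throughout
oracle_annotate_one <- function(pstart, pend, pchrom, models, windows) {
  cat_order <- c("promoter", "intragenic", "downstream", "enhancer-window",
                 "intergenic")
  best <- NULL
  for (gi in seq_len(nrow(models))) {
    g <- models[gi, ]
    if (g$chrom != pchrom) next
    if (g$strand == "+") {
      prom <- c(g$tss - windows$promoter_radius, g$tss + windows$promoter_radius)
      body <- c(g$tss, g$tes)
      down <- c(g$tes, g$tes + windows$downstream_length)
      enh <- c(prom[1] - windows$enhancer_length, prom[1])
    } else {
      prom <- c(g$tss - windows$promoter_radius, g$tss + windows$promoter_radius)
      body <- c(g$tes, g$tss)
      down <- c(g$tes - windows$downstream_length, g$tes)
      enh <- c(prom[2], prom[2] + windows$enhancer_length)
    }
    span <- c(min(prom[1], body[1], down[1], enh[1]),
              max(prom[2], body[2], down[2], enh[2]))
    inter <- c(span[1] - windows$intergenic_horizon,
               span[2] + windows$intergenic_horizon)
    wins <- list(promoter = prom, intragenic = body, downstream = down,
                 `enhancer-window` = enh, intergenic = inter)
    gene_cat <- NA_character_
    for (cat in cat_order) {
      w <- wins[[cat]]
      w[1] <- max(w[1], 0)
      if (w[2] > w[1] && pstart < w[2] && pend > w[1]) {
        gene_cat <- cat
        break
      }
    }
    if (is.na(gene_cat)) next
    mid <- floor((pstart + pend - 1) / 2)
    dist <- (mid - g$tss) * (if (g$strand == "+") 1 else -1)
    cand <- list(gene_id = g$gene_id, category = gene_cat,
                 priority = match(gene_cat, cat_order), dist = dist)
    if (is.null(best) ||
        cand$priority < best$priority ||
        (cand$priority == best$priority && abs(cand$dist) < abs(best$dist)) ||
        (cand$priority == best$priority && abs(cand$dist) == abs(best$dist) &&
         cand$gene_id < best$gene_id)) {
      best <- cand
    }
  }
  if (is.null(best)) {
    list(gene_id = NA_character_, category = "unassigned", dist = NA_real_)
  } else {
    best
  }
}

# translate-and-scan productivity oracle with an explicit codon map
oracle_productivity <- function(junction) {
  stops <- c("TAA", "TAG", "TGA")
  vapply(junction, function(j) {
    if (grepl("N", j, fixed = TRUE)) return("undetermined")
    if (nchar(j) %% 3 != 0 || nchar(j) < 3) return("nonproductive")
    for (i in seq(1, nchar(j) - 2, by = 3)) {
      if (substr(j, i, i + 2) %in% stops) return("nonproductive")
    }
    "productive"
  }, character(1), USE.NAMES = FALSE)
}

# plain-loop weighted KS running sum
oracle_es <- function(scores, is_hit, w = 1) {
  n <- length(scores)
  sw <- sum(abs(scores[is_hit])^w)
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (is_hit[i]) {
      run <- run + if (sw == 0) 1 / sum(is_hit) else abs(scores[i])^w / sw
    } else {
      run <- run - 1 / (n - sum(is_hit))
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# small, fast study configuration used by most tests
tiny_cfg <- function(noise_sd = 0, seed = 1, ...) {
  simulation_config(
    n_genes = 150, n_signature_up = 12, n_signature_down = 6,
    n_biased_inkt = 3, n_biased_gdnkt = 3, n_common = 3, n_discordant = 2,
    n_dp_changed = 8, n_enrichment_set = 6,
    n_target_genes_with_peaks = 8, n_offsignature_targets = 2,
    n_correlated_pos = 5, n_correlated_neg = 4,
    repertoire = repertoire_config(mice_per_genotype = 2, reads_per_mouse = 2000),
    noise_sd = noise_sd, seed = seed, ...
  )
}

random_fc_table <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(gene_id = sprintf("g%03d", seq_len(n)), contrast = "a vs b",
                   fc = 2^stats::rnorm(n, 0, 1.2)) |>
      dplyr::mutate(log2fc = log2(fc))
  })
}
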