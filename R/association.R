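#' Classify genes by correlation with an anchor gene
#'
#' Computes Pearson's r and Spearman's rho (average ranks on ties)
#' between every gene and the anchor gene across the selected samples,
#' then applies the dual rule: `positive` requires *both* coefficients
#' >= `cutoff`, `negative` requires both <= `-cutoff` (inclusive), all
#' other defined pairs are `none`, and genes with zero variance are
#' `undefined`.  Values are log2-transformed by default, matching the
#' convention of computing downstream statistics on log2 expression.
#'
#' @param expr Expression tibble.
#' @param anchor_gene Gene id of the anchor (e.g. `Zbtb16`).
#' @param samples Optional character vector of sample ids to use
#'   (default: all samples); at least 3 are required.
#' @param cutoff Dual correlation cutoff (default 0.7, inclusive).
#' @param log2_input Log2-transform linear values first (default TRUE).
#' @param pseudocount Offset for the log2 transform (default 0; values
#'   must then be strictly positive).
#' @return Tibble with columns `gene_id`, `pearson_r`, `spearman_rho`,
#'   `klass`.
#' @export
correlate_with_anchor <- function(expr, anchor_gene, samples = NULL,
                                  cutoff = 0.7, log2_input = TRUE,
                                  pseudocount = 0) {
  m <- expr_values(expr)
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(m))
    if (length(missing) > 0) abort(sprintf("unknown sample(s): %s", paste(missing, collapse = ", ")))
    m <- m[, samples, drop = FALSE]
  }
  if (ncol(m) < 3) abort("correlation needs at least 3 samples.")
  if (!anchor_gene %in% rownames(m)) abort(sprintf("anchor gene '%s' not in the matrix.", anchor_gene))
  if (log2_input) {
    if (any(m + pseudocount <= 0)) abort("non-positive values under log2 transform; raise `pseudocount`.")
    m <- log2(m + pseudocount)
  }
  x <- m[anchor_gene, ]
  if (sd(x) == 0) abort("anchor gene has zero variance across the selected samples.")
  sds <- apply(m, 1, sd)
  pearson <- suppressWarnings(as.vector(cor(t(m), x)))
  ranks <- t(apply(m, 1, rank))
  spearman <- suppressWarnings(as.vector(cor(t(ranks), rank(x))))
  pearson[sds == 0] <- NA_real_
  spearman[sds == 0] <- NA_real_
  klass <- dplyr::case_when(
    is.na(pearson) | is.na(spearman) ~ "undefined",
    pearson >= cutoff & spearman >= cutoff ~ "positive",
    pearson <= -cutoff & spearman <= -cutoff ~ "negative",
    TRUE ~ "none"
  )
  tibble(gene_id = rownames(m), pearson_r = pearson,
         spearman_rho = spearman, klass = klass)
}

#' Rank genes by the log2 ratio of two sample classes
#'
#' The ranking metric of the enrichment analysis:
#' `score = log2((mean_a + eps) / (mean_b + eps))`, genes sorted by
#' decreasing score with lexicographic gene id breaking ties.
#'
#' @param expr Expression tibble (linear scale).
#' @param class_a_samples,class_b_samples Sample id vectors for the two
#'   classes (both non-empty).
#' @param pseudocount Positive offset (default 1).
#' @param genes Optional gene universe to restrict the ranking to.
#' @return Tibble with columns `gene_id`, `score`, ordered best-first.
#' @export
rank_by_class_ratio <- function(expr, class_a_samples, class_b_samples,
                                pseudocount = 1, genes = NULL) {
  if (length(class_a_samples) == 0 || length(class_b_samples) == 0) {
    abort("both sample classes must be non-empty.")
  }
  m <- expr_values(expr)
  if (!is.null(genes)) m <- m[rownames(m) %in% genes, , drop = FALSE]
  score <- log2((rowMeans(m[, class_a_samples, drop = FALSE]) + pseudocount) /
                  (rowMeans(m[, class_b_samples, drop = FALSE]) + pseudocount))
  tibble(gene_id = rownames(m), score = unname(score)) |>
    dplyr::arrange(dplyr::desc(score), gene_id)
}

#' Genes unchanged between two conditions
#'
#' The comparison universe of the enrichment analysis: genes whose fold
#' change lies within `[1/threshold, threshold]` (inclusive).
#'
#' @param fc Fold-change table.
#' @param threshold Band edge (> 1, default 2).
#' @return Character vector of gene ids.
#' @export
unchanged_universe <- function(fc, threshold = 2) {
  if (threshold <= 1) abort("`threshold` must be > 1.")
  fc$gene_id[fc$fc >= 1 / threshold & fc$fc <= threshold]
}

# core weighted Kolmogorov-Smirnov running sum; ranked scores + hit mask
compute_es <- function(scores, hits, weight_exponent = 1) {
  n <- length(scores)
  n_hit <- sum(hits)
  w <- abs(scores)^weight_exponent
  sw <- sum(w[hits])
  inc <- numeric(n)
  inc[hits] <- if (sw == 0) 1 / n_hit else w[hits] / sw
  dec <- numeric(n)
  dec[!hits] <- 1 / (n - n_hit)
  running <- cumsum(inc - dec)
  peak <- which.max(abs(running))
  list(es = running[peak], running = running, peak = peak)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list top to bottom: the running sum increases by
#' `|score|^w / sum_set |score|^w` at each gene-set hit and decreases by
#' `1/(N - N_hit)` at each miss; the enrichment score (ES) is the signed
#' extremum of the running sum.  If the hit weights sum to zero, hits
#' fall back to uniform increments so the ES bounds are preserved.
#'
#' @param ranked Ranked tibble from [rank_by_class_ratio()] (columns
#'   `gene_id`, `score`); re-sorted defensively with the same tie-break.
#' @param gene_set Character vector; must intersect the ranked list and
#'   must not cover it entirely.
#' @param weight_exponent Weight exponent `w` (1 = weighted, 0 =
#'   classic unweighted KS statistic).
#' @return List of class `innate_es` with elements `es`, `peak`
#'   (extremum position) and `running` (tibble: `position`, `gene_id`,
#'   `hit`, `running`).
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  ranked <- dplyr::arrange(ranked, dplyr::desc(score), gene_id)
  hits <- ranked$gene_id %in% gene_set
  if (!any(hits)) abort("gene set does not intersect the ranked list.")
  if (all(hits)) abort("gene set covers the whole ranked universe.")
  res <- compute_es(ranked$score, hits, weight_exponent)
  structure(list(es = res$es, peak = res$peak,
                 running = tibble(position = seq_len(nrow(ranked)),
                                  gene_id = ranked$gene_id, hit = hits,
                                  running = res$running)),
            class = "innate_es")
}

#' Gene-set permutation test for the enrichment score
#'
#' Builds the null distribution from `n_perm` random gene sets of the
#' same size drawn from the ranked universe (gene-set permutation;
#' phenotype permutation is degenerate with two samples per class).
#' `p_perm = (1 + #{same-sign nulls with |ES_null| >= |ES|}) /
#' (1 + #same-sign nulls)` and `NES = ES / mean(|ES_null| same sign)`.
#'
#' @inheritParams enrichment_score
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; results are seed-reproducible.
#' @param set_name Label carried into the result.
#' @return Object of class `innate_gsea`: list with `set_name`, `es`,
#'   `nes`, `p_perm`, `n_perm`, `n_hits`, `leading_edge`, `running`
#'   (as in [enrichment_score()]) and `es_null`.  Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
permutation_test <- function(ranked, gene_set, n_perm = 1000,
                             weight_exponent = 1, seed = 1,
                             set_name = "gene_set") {
  obs <- enrichment_score(ranked, gene_set, weight_exponent)
  ranked <- dplyr::arrange(ranked, dplyr::desc(score), gene_id)
  n <- nrow(ranked)
  k <- sum(obs$running$hit)
  es_null <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) {
      hits <- logical(n)
      hits[sample.int(n, k)] <- TRUE
      compute_es(ranked$score, hits, weight_exponent)$es
    }, numeric(1))
  })
  same <- es_null[sign(es_null) == sign(obs$es)]
  p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
  nes <- if (length(same) > 0) obs$es / mean(abs(same)) else NA_real_
  le <- if (obs$es >= 0) {
    obs$running$gene_id[obs$running$hit & obs$running$position <= obs$peak]
  } else {
    obs$running$gene_id[obs$running$hit & obs$running$position >= obs$peak]
  }
  structure(list(set_name = set_name, es = obs$es, nes = nes, p_perm = p,
                 n_perm = n_perm, n_hits = k, leading_edge = le,
                 running = obs$running, es_null = es_null),
            class = "innate_gsea")
}

#' @export
print.innate_gsea <- function(x, ...) {
  cat(sprintf("<innate_gsea> set '%s': ES = %.3f, NES = %.3f, p = %.4g (%d permutations, %d hits)\n",
              x$set_name, x$es, x$nes, x$p_perm, x$n_perm, x$n_hits))
  invisible(x)
}
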