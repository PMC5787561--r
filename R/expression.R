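#' Read a gene-by-sample expression matrix
#'
#' Reads a TSV whose first column is `gene_id` and whose remaining columns
#' are one sample each (FPKM or microarray intensity, linear scale unless
#' stated otherwise downstream).  If a sample map is supplied, every
#' expression column must be covered by it; unmapped samples are rejected.
#'
#' @param path Path to the expression TSV.
#' @param sample_map_path Optional path to a sample map TSV with at least
#'   columns `sample_id` and `population` (see [read_sample_map()]).
#' @return A list with elements `expression` (tibble, first column
#'   `gene_id`) and `samples` (the sample map tibble, or `NULL`).
#' @export
read_expression <- function(path, sample_map_path = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) abort("expression TSV must have a gene id column plus >=1 sample column.")
  names(raw)[1] <- "gene_id"
  dup <- raw$gene_id[duplicated(raw$gene_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicated gene id(s) in %s: %s", path,
                  paste(unique(dup), collapse = ", ")))
  }
  vals <- raw[-1]
  for (j in seq_along(vals)) {
    x <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(x) & !is.na(vals[[j]]) & vals[[j]] != "NA")
    if (length(bad) > 0) {
      abort(sprintf("non-numeric value '%s' at row %d, column '%s' of %s",
                    vals[[j]][bad[1]], bad[1], names(vals)[j], path))
    }
    vals[[j]] <- x
  }
  expr <- dplyr::bind_cols(raw["gene_id"], vals)
  samples <- NULL
  if (!is.null(sample_map_path)) {
    samples <- read_sample_map(sample_map_path)
    missing <- setdiff(sample_cols(expr), samples$sample_id)
    if (length(missing) > 0) {
      abort(sprintf("sample(s) not covered by the sample map: %s",
                    paste(missing, collapse = ", ")))
    }
  }
  list(expression = expr, samples = samples)
}

#' Write an expression matrix to TSV
#'
#' @param expr Expression tibble (first column `gene_id`).
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  stopifnot(names(expr)[1] == "gene_id")
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}

#' Read a sample map
#'
#' A sample map assigns each expression column to a cell population and,
#' optionally, genotype / replicate / pipeline-role metadata.
#'
#' @param path TSV with at least columns `sample_id` and `population`.
#' @return A tibble.
#' @export
read_sample_map <- function(path) {
  sm <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "population")
  if (!all(need %in% names(sm))) {
    abort(sprintf("sample map must contain columns %s", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(sm$sample_id)) abort("duplicated sample_id in sample map.")
  sm
}

#' Drop low-quality genes
#'
#' Retains genes whose maximum expression across all samples reaches
#' `min_max_expr` (linear scale).  Gene order is preserved and the filter
#' is idempotent.
#'
#' @param expr Expression tibble on the linear scale.
#' @param min_max_expr Expressed-gene floor (default 1, i.e. max FPKM >= 1).
#' @return Filtered expression tibble.
#' @export
filter_low_quality <- function(expr, min_max_expr = 1) {
  m <- expr_values(expr)
  keep <- apply(m, 1, max) >= min_max_expr
  out <- expr[keep, , drop = FALSE]
  if (nrow(out) == 0) warn("all genes removed by the low-quality filter.")
  out
}

#' Per-gene mean expression over one or more populations
#'
#' Pools every sample belonging to the named populations and takes the
#' arithmetic mean per gene on the linear scale (each sample weighted
#' equally).  Set `weighting = "population"` to average population means
#' instead.
#'
#' @param expr Expression tibble (linear scale).
#' @param sample_map Sample map tibble covering the expression columns.
#' @param populations Character vector of population labels.
#' @param weighting `"pooled"` (default) or `"population"`.
#' @return Tibble with columns `gene_id`, `mean_expr`.
#' @export
population_mean <- function(expr, sample_map, populations,
                            weighting = c("pooled", "population")) {
  weighting <- match.arg(weighting)
  check_populations(sample_map, populations)
  m <- expr_values(expr)
  if (weighting == "pooled") {
    ids <- sample_map$sample_id[sample_map$population %in% populations]
    mu <- rowMeans(m[, ids, drop = FALSE])
  } else {
    per_pop <- vapply(populations, function(p) {
      ids <- sample_map$sample_id[sample_map$population == p]
      rowMeans(m[, ids, drop = FALSE])
    }, numeric(nrow(m)))
    mu <- rowMeans(as.matrix(per_pop))
  }
  tibble(gene_id = expr$gene_id, mean_expr = unname(mu))
}

#' Linear fold change between population groups
#'
#' Computes `fc = (mean_num + eps) / (mean_den + eps)` per gene on the
#' linear scale, where each mean pools all samples of the listed
#' populations.  `log2fc` is `log2(fc)`.
#'
#' @param expr Expression tibble (linear scale).
#' @param sample_map Sample map tibble.
#' @param numerator,denominator Population labels forming the contrast.
#' @param pseudocount Non-negative `eps` added to both means; must be
#'   positive if any denominator mean can be zero (default 1, the usual
#'   FPKM practice; use 0 for floored microarray intensities).
#' @param contrast Optional contrast label; defaults to
#'   `"<num> vs <den>"`.
#' @param weighting Passed to [population_mean()].
#' @return Tibble with columns `gene_id`, `contrast`, `fc`, `log2fc`.
#' @export
fold_change <- function(expr, sample_map, numerator, denominator,
                        pseudocount = 1, contrast = NULL,
                        weighting = "pooled") {
  if (pseudocount < 0) abort("`pseudocount` must be >= 0.")
  num <- population_mean(expr, sample_map, numerator, weighting)$mean_expr
  den <- population_mean(expr, sample_map, denominator, weighting)$mean_expr
  if (pseudocount == 0 && any(den == 0)) {
    abort("zero denominator mean with pseudocount = 0; supply a positive pseudocount.")
  }
  fc <- (num + pseudocount) / (den + pseudocount)
  contrast <- contrast %||% paste(paste(numerator, collapse = "+"), "vs",
                                  paste(denominator, collapse = "+"))
  tibble(gene_id = expr$gene_id, contrast = contrast, fc = fc, log2fc = log2(fc))
}

#' Principal component analysis of samples
#'
#' Samples are projected on principal components of the gene-centered
#' log2 expression matrix (no unit-variance scaling), grouping samples by
#' overall transcriptome similarity.
#'
#' @param expr Expression tibble.
#' @param scale Scale of the stored values: `"linear"` values are
#'   transformed as `log2(x + pseudocount)` first, `"log2"` values are
#'   used as-is.
#' @param pseudocount Offset used for the log2 transform of linear values.
#' @return An object of class `innate_pca`: list with `scores` (tibble,
#'   one row per sample), `explained_variance` (fractions, non-increasing)
#'   and `sdev`.  Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
pca_samples <- function(expr, scale = c("linear", "log2"), pseudocount = 1) {
  scale <- match.arg(scale)
  m <- expr_values(expr)
  if (ncol(m) < 2) abort("PCA needs at least 2 samples.")
  if (scale == "linear") m <- log2(m + pseudocount)
  fit <- prcomp(t(m), center = TRUE, scale. = FALSE)
  ev <- fit$sdev^2
  frac <- if (sum(ev) > 0) ev / sum(ev) else ev
  scores <- as_tibble(fit$x, .name_repair = "minimal")
  scores <- dplyr::bind_cols(tibble(sample_id = colnames(m)), scores)
  structure(list(scores = scores, explained_variance = frac, sdev = fit$sdev),
            class = "innate_pca")
}

#' @export
print.innate_pca <- function(x, ...) {
  cat(sprintf("<innate_pca> %d samples, %d components; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), length(x$explained_variance),
              100 * x$explained_variance[1],
              100 * (x$explained_variance[2] %||% NA_real_)))
  invisible(x)
}
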