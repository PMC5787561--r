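#' Default region-category windows
#'
#' Window sizes (bp) used to assign a ChIP peak to a gene region
#' category.  Promoter = TSS +/- `promoter_radius`; intragenic = gene
#' body; downstream = `downstream_length` past the TES; enhancer-window =
#' `enhancer_length` upstream of the promoter edge; intergenic = within
#' `intergenic_horizon` beyond all other windows of the nearest gene.
#' All windows are strand-aware and configurable.
#'
#' @param promoter_radius,downstream_length,enhancer_length,intergenic_horizon
#'   Window sizes in bp.
#' @return Named list of window sizes.
#' @export
default_windows <- function(promoter_radius = 2000, downstream_length = 10000,
                            enhancer_length = 50000, intergenic_horizon = 100000) {
  w <- list(promoter_radius = promoter_radius,
            downstream_length = downstream_length,
            enhancer_length = enhancer_length,
            intergenic_horizon = intergenic_horizon)
  if (any(unlist(w) < 0)) abort("window sizes must be >= 0.")
  w
}

peak_categories <- c("promoter", "intragenic", "downstream", "enhancer-window",
                     "intergenic")

#' Per-gene category windows
#'
#' Expands gene models into one interval per (gene, category) under the
#' window configuration, on 0-based half-open coordinates.  Category
#' priority (1 = highest) is promoter > intragenic > downstream >
#' enhancer-window > intergenic.
#'
#' @param models Gene-model tibble from [read_gene_models()] (columns
#'   `gene_id`, `chrom`, `strand`, `tss`, `tes`).
#' @param windows Window configuration from [default_windows()].
#' @return Tibble with columns `gene_id`, `chrom`, `strand`, `tss`,
#'   `category`, `priority`, `wstart`, `wend`.
#' @export
gene_windows <- function(models, windows = default_windows()) {
  plus <- models$strand == "+"
  if (any(models$tss == models$tes)) abort("gene models must have TSS != TES.")
  if (any(plus & models$tss > models$tes) || any(!plus & models$tss < models$tes)) {
    abort("strand-inconsistent gene model: expected TSS < TES on '+', TSS > TES on '-'.")
  }
  r <- windows$promoter_radius
  prom_s <- models$tss - r
  prom_e <- models$tss + r
  body_s <- pmin(models$tss, models$tes)
  body_e <- pmax(models$tss, models$tes)
  down_s <- ifelse(plus, models$tes, models$tes - windows$downstream_length)
  down_e <- ifelse(plus, models$tes + windows$downstream_length, models$tes)
  enh_s <- ifelse(plus, prom_s - windows$enhancer_length, prom_e)
  enh_e <- ifelse(plus, prom_s, prom_e + windows$enhancer_length)
  span_s <- pmin(prom_s, body_s, down_s, enh_s)
  span_e <- pmax(prom_e, body_e, down_e, enh_e)
  base <- dplyr::select(models, gene_id, chrom, strand, tss)
  mk <- function(cat, pr, s, e) dplyr::mutate(base, category = cat, priority = pr,
                                              wstart = s, wend = e)
  out <- dplyr::bind_rows(
    mk("promoter", 1L, prom_s, prom_e),
    mk("intragenic", 2L, body_s, body_e),
    mk("downstream", 3L, down_s, down_e),
    mk("enhancer-window", 4L, enh_s, enh_e),
    mk("intergenic", 5L, span_s - windows$intergenic_horizon,
       span_e + windows$intergenic_horizon)
  )
  out$wstart <- pmax(out$wstart, 0)
  out[out$wend > out$wstart, , drop = FALSE]
}

#' Filter ChIP peaks by significance
#'
#' Decodes the BED score column into a p-value under the declared dialect
#' and keeps peaks with `p < p_max` (strict).  MACS 1.4-style files encode
#' `-10*log10(p)` (dialect `"minus10log10"`, the default); newer callers
#' emit `-log10(p)` (`"minuslog10"`).
#'
#' @param peaks Peak tibble (columns `chrom`, `start`, `end`, `name`,
#'   `score`).
#' @param p_max Significance threshold (default `1e-5`).
#' @param dialect Score encoding; must be declared explicitly or left at
#'   the documented default.
#' @return Filtered peak tibble.
#' @export
filter_significant_peaks <- function(peaks, p_max = 1e-5,
                                     dialect = c("minus10log10", "minuslog10")) {
  dialect <- match.arg(dialect)
  if (any(peaks$score < 0)) abort("peak scores must be >= 0.")
  p <- switch(dialect,
              minus10log10 = 10^(-peaks$score / 10),
              minuslog10 = 10^(-peaks$score))
  peaks[p < p_max, , drop = FALSE]
}

#' Assign peaks to genes and region categories
#'
#' For every peak, each gene's category is the highest-priority window
#' (promoter > intragenic > downstream > enhancer-window > intergenic)
#' sharing at least one base with the peak; among genes the winner
#' minimizes first category priority, then |distance to TSS| (signed,
#' strand-aware, from the peak midpoint), with remaining ties broken by
#' lexicographic gene id.  Peaks overlapping no window are `unassigned`.
#'
#' @param peaks Peak tibble (0-based half-open `start`/`end`).
#' @param models Gene-model tibble.
#' @param windows Window configuration from [default_windows()].
#' @return The peak tibble with columns `gene_id`, `category`,
#'   `tss_distance` appended (input row order preserved).
#' @export
annotate_peaks <- function(peaks, models, windows = default_windows()) {
  wins <- gene_windows(models, windows)
  ann <- tibble(gene_id = NA_character_, category = "unassigned",
                tss_distance = NA_real_, .rows = nrow(peaks))
  if (nrow(peaks) > 0 && nrow(wins) > 0) {
    gr_p <- GenomicRanges::GRanges(peaks$chrom,
                                   IRanges::IRanges(peaks$start + 1L, peaks$end))
    gr_w <- GenomicRanges::GRanges(wins$chrom,
                                   IRanges::IRanges(wins$wstart + 1L, wins$wend))
    ov <- GenomicRanges::findOverlaps(gr_p, gr_w, ignore.strand = TRUE)
    if (length(ov) > 0) {
      hit <- tibble(peak_idx = S4Vectors::queryHits(ov),
                    win_idx = S4Vectors::subjectHits(ov))
      mid <- floor((peaks$start + peaks$end - 1) / 2)
      best <- hit |>
        dplyr::bind_cols(wins[hit$win_idx, c("gene_id", "category", "priority",
                                             "tss", "strand")]) |>
        dplyr::group_by(peak_idx, gene_id) |>
        dplyr::slice_min(priority, n = 1, with_ties = FALSE) |>
        dplyr::ungroup() |>
        dplyr::mutate(tss_distance = (mid[peak_idx] - tss) *
                        ifelse(strand == "+", 1, -1)) |>
        dplyr::arrange(peak_idx, priority, abs(tss_distance), gene_id) |>
        dplyr::distinct(peak_idx, .keep_all = TRUE)
      ann$gene_id[best$peak_idx] <- best$gene_id
      ann$category[best$peak_idx] <- best$category
      ann$tss_distance[best$peak_idx] <- best$tss_distance
    }
  }
  dplyr::bind_cols(peaks, ann)
}

#' Call transcription-factor target genes
#'
#' A gene is a target when at least one (significant) peak annotation
#' assigns it any of the five named region categories; the result is
#' intersected with the expression gene universe when supplied.
#'
#' @param annotations Annotated peak tibble from [annotate_peaks()],
#'   computed on significance-filtered peaks.
#' @param gene_universe Optional character vector restricting the calls.
#' @return Sorted character vector of target gene ids.
#' @export
call_tf_targets <- function(annotations, gene_universe = NULL) {
  targets <- unique(annotations$gene_id[annotations$category %in% peak_categories])
  targets <- targets[!is.na(targets)]
  if (!is.null(gene_universe)) targets <- intersect(targets, gene_universe)
  sort(targets)
}

#' Read and write BED6 peak files
#'
#' @param path File path.
#' @return `read_peaks()` returns a tibble with columns `chrom`, `start`,
#'   `end`, `name`, `score`, `strand` (0-based half-open coordinates).
#' @export
read_peaks <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr),
         name = gr$name %||% paste0("peak_", seq_along(gr)),
         score = as.numeric(gr$score),
         strand = as.character(GenomicRanges::strand(gr)))
}

#' @rdname read_peaks
#' @param peaks Peak tibble.
#' @export
write_peaks <- function(peaks, path) {
  strand <- if ("strand" %in% names(peaks)) peaks$strand else rep("*", nrow(peaks))
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L, peaks$end),
                               strand = strand)
  gr$name <- peaks$name
  gr$score <- peaks$score
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read gene models from GTF or BED12
#'
#' GTF input (1-based closed) is converted to the package's internal
#' 0-based half-open convention; the TSS is the strand-aware 5' end
#' (so TSS > TES on the minus strand).
#'
#' @param path File path.
#' @param format `"gtf"` or `"bed"` (BED12/BED6 with the gene id in the
#'   name field).
#' @return Tibble with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `tss`, `tes`.
#' @export
read_gene_models <- function(path, format = c("gtf", "bed")) {
  format <- match.arg(format)
  gr <- rtracklayer::import(path, format = format)
  if (format == "gtf") {
    if ("type" %in% names(S4Vectors::mcols(gr)) && any(gr$type == "gene")) {
      gr <- gr[gr$type == "gene"]
    }
    ids <- gr$gene_id
  } else {
    ids <- gr$name
  }
  if (anyDuplicated(ids)) abort("duplicated gene id in gene models.")
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-"))) abort("gene models must be stranded (+/-).")
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  tibble(gene_id = ids,
         chrom = as.character(GenomicRanges::seqnames(gr)),
         strand = strand, start = start0, end = end0,
         tss = ifelse(strand == "+", start0, end0),
         tes = ifelse(strand == "+", end0, start0))
}

#' @rdname read_gene_models
#' @param models Gene-model tibble.
#' @export
write_gene_models <- function(models, path) {
  gr <- GenomicRanges::GRanges(models$chrom,
                               IRanges::IRanges(models$start + 1L, models$end),
                               strand = models$strand)
  gr$source <- "innatesig"
  gr$type <- "gene"
  gr$gene_id <- models$gene_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
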