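#' Call per-gene dysregulation from a mutant-vs-wild-type fold change
#'
#' A gene is `up` when its linear fold change exceeds `threshold`
#' (default 2), `down` when it falls below `1/threshold`, and `none`
#' otherwise.  Strict inequalities by default; `strict = FALSE` makes the
#' gates inclusive ("at least twofold").
#'
#' @param fc Fold-change table from [fold_change()].
#' @param threshold Linear fold-change gate (> 1).
#' @param strict Strict (default) or inclusive comparison.
#' @return Tibble with columns `gene_id`, `direction`, `fc`, `log2fc`.
#' @export
call_dysregulated <- function(fc, threshold = 2, strict = TRUE) {
  if (threshold <= 1) abort("`threshold` must be > 1.")
  gt <- if (strict) `>` else `>=`
  lt <- if (strict) `<` else `<=`
  fc |>
    dplyr::mutate(direction = dplyr::case_when(
      gt(fc, threshold) ~ "up",
      lt(fc, 1 / threshold) ~ "down",
      TRUE ~ "none"
    )) |>
    dplyr::select(gene_id, direction, fc, log2fc)
}

#' Intersect dysregulation calls with the innate-like signature
#'
#' Retains signature genes that are dysregulated in at least one mutant
#' innate lineage.  Signature genes absent from the expression universe
#' are excluded with a message.  The returned table carries the counts as
#' attributes `n_signature` and `n_retained`.
#'
#' @param calls_inkt,calls_gdnkt Direction calls from
#'   [call_dysregulated()] for the mutant iNKT and mutant gamma-delta NKT
#'   contrasts (against their wild-type counterparts).
#' @param sig Signature tibble (derived + literature).
#' @return Grouped-gene tibble with columns `gene_id`, `in_signature`,
#'   `dir_inkt`, `dir_gdnkt`, `log2fc_inkt`, `log2fc_gdnkt`, `group`
#'   (unset, `NA`); one row per retained gene.
#' @export
intersect_signature <- function(calls_inkt, calls_gdnkt, sig) {
  universe <- intersect(calls_inkt$gene_id, calls_gdnkt$gene_id)
  absent <- setdiff(sig$gene_id, universe)
  if (length(absent) > 0) {
    inform(sprintf("intersect_signature: %d signature gene(s) absent from the expression universe were excluded.",
                   length(absent)))
  }
  out <- tibble(gene_id = intersect(sig$gene_id, universe)) |>
    dplyr::left_join(dplyr::select(calls_inkt, gene_id, dir_inkt = direction,
                                   log2fc_inkt = log2fc), by = "gene_id") |>
    dplyr::left_join(dplyr::select(calls_gdnkt, gene_id, dir_gdnkt = direction,
                                   log2fc_gdnkt = log2fc), by = "gene_id") |>
    dplyr::filter(dir_inkt != "none" | dir_gdnkt != "none") |>
    dplyr::mutate(in_signature = TRUE, group = NA_character_) |>
    dplyr::select(gene_id, in_signature, dir_inkt, dir_gdnkt,
                  log2fc_inkt, log2fc_gdnkt, group) |>
    dplyr::arrange(gene_id)
  attr(out, "n_signature") <- length(unique(sig$gene_id))
  attr(out, "n_retained") <- nrow(out)
  out
}

#' Classify dysregulated signature genes into lineage groups
#'
#' Formalizes the biased/common grouping: a gene dysregulated in both
#' lineages in the same direction is `common` when the absolute log2
#' fold changes differ by less than `bias_delta`, and biased toward the
#' lineage with the larger |log2FC| otherwise; a gene dysregulated in one
#' lineage only is biased toward that lineage; opposite directions give
#' `discordant`.  `bias_delta = 1` (a twofold gap) is this package's
#' operational definition of a "significantly larger" fold change and is
#' always echoed in pipeline metadata.
#'
#' @param grouped Output of [intersect_signature()].
#' @param bias_delta Minimum |log2FC| gap declaring lineage bias.
#' @return The same tibble with `group` filled with one of
#'   `iNKT-biased`, `gdNKT-biased`, `common`, `discordant`.
#' @export
classify_groups <- function(grouped, bias_delta = 1) {
  if (bias_delta < 0) abort("`bias_delta` must be >= 0.")
  grouped |>
    dplyr::mutate(
      gap = abs(log2fc_inkt) - abs(log2fc_gdnkt),
      group = dplyr::case_when(
        dir_inkt == "none" & dir_gdnkt == "none" ~ "none",
        dir_inkt != "none" & dir_gdnkt == "none" ~ "iNKT-biased",
        dir_inkt == "none" & dir_gdnkt != "none" ~ "gdNKT-biased",
        dir_inkt != dir_gdnkt ~ "discordant",
        gap >= bias_delta ~ "iNKT-biased",
        -gap >= bias_delta ~ "gdNKT-biased",
        TRUE ~ "common"
      )
    ) |>
    dplyr::select(-gap)
}

#' Summarize group counts
#'
#' @param grouped Classified grouped-gene tibble.
#' @return Named list of counts (retained total plus one entry per group).
#' @export
group_counts <- function(grouped) {
  counts <- as.list(table(grouped$group))
  c(list(n_retained = nrow(grouped)), counts)
}
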