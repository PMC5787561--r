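#' Read and write AIRR-style rearrangement tables
#'
#' Minimum columns: `sequence_id`, `subject_id`, `genotype`, `v_call`,
#' `j_call`, `junction` (nucleotides over A/C/G/T/N).
#'
#' @param path File path (TSV).
#' @return `read_rearrangements()` returns a tibble.
#' @export
read_rearrangements <- function(path) {
  rec <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sequence_id", "subject_id", "genotype", "v_call", "j_call", "junction")
  if (!all(need %in% names(rec))) {
    abort(sprintf("rearrangement table must contain columns %s",
                  paste(need, collapse = ", ")))
  }
  if (any(grepl("[^ACGTN]", rec$junction))) {
    abort("junction sequences must be over the alphabet A/C/G/T/N.")
  }
  geno <- dplyr::distinct(rec, subject_id, genotype)
  if (anyDuplicated(geno$subject_id)) {
    abort("each subject must map to exactly one genotype.")
  }
  rec
}

#' @rdname read_rearrangements
#' @param records Rearrangement tibble.
#' @export
write_rearrangements <- function(records, path) {
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}

#' Classify V-J junction productivity
#'
#' A junction is `productive` when its length is divisible by 3 and its
#' frame-0 translation under the standard codon table contains no stop
#' codon; otherwise it is `nonproductive` (frameshift or in-frame stop).
#' Junctions containing N are `undetermined` and are excluded from
#' productive/non-productive splits.  This frame-and-stop rule
#' approximates the junction functionality call of germline-alignment
#' tools.
#'
#' @param junction Character vector of junction nucleotide sequences.
#' @return Character vector over `productive`, `nonproductive`,
#'   `undetermined`.
#' @export
classify_productivity <- function(junction) {
  if (any(grepl("[^ACGTN]", junction))) {
    abort("junctions must be over the alphabet A/C/G/T/N.")
  }
  out <- rep("nonproductive", length(junction))
  has_n <- grepl("N", junction, fixed = TRUE)
  out[has_n] <- "undetermined"
  if (any(has_n)) {
    inform(sprintf("classify_productivity: %d junction(s) containing N marked undetermined.",
                   sum(has_n)))
  }
  inframe <- which(!has_n & nchar(junction) %% 3 == 0 & nchar(junction) >= 3)
  if (length(inframe) > 0) {
    aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(junction[inframe])))
    out[inframe[!grepl("*", aa, fixed = TRUE)]] <- "productive"
  }
  out
}

#' Per-mouse J-segment usage
#'
#' Computes the frequency of each `j_call` among the reads of each
#' (subject, v_call) stratum, optionally restricted to one V segment
#' and/or one productivity class.
#'
#' @param records Rearrangement tibble.
#' @param v_call Optional V segment (exact match) to restrict to.
#' @param productivity Optional `"productive"` or `"nonproductive"`;
#'   junction productivity is computed on the fly and `undetermined`
#'   reads are always excluded from such splits.
#' @return Usage tibble with columns `subject_id`, `genotype`, `v_call`,
#'   `j_call`, `n`, `total`, `frequency`; frequencies sum to 1 per
#'   (subject, v_call).
#' @export
j_usage <- function(records, v_call = NULL, productivity = NULL) {
  rec <- records
  if (!is.null(v_call)) rec <- rec[rec$v_call %in% v_call, , drop = FALSE]
  if (!is.null(productivity)) {
    rec <- rec[classify_productivity(rec$junction) == productivity, , drop = FALSE]
  }
  if (nrow(rec) == 0) abort("no reads left after filtering.")
  dropped <- setdiff(unique(records$subject_id), unique(rec$subject_id))
  if (length(dropped) > 0) {
    warn(sprintf("j_usage: subject(s) with zero reads after filtering omitted: %s",
                 paste(dropped, collapse = ", ")))
  }
  rec |>
    dplyr::count(subject_id, genotype, v_call, j_call, name = "n") |>
    dplyr::group_by(subject_id, v_call) |>
    dplyr::mutate(total = sum(n), frequency = n / total) |>
    dplyr::ungroup() |>
    dplyr::arrange(subject_id, v_call, j_call)
}

#' Default proximal/middle/distal J-segment bins
#'
#' TRAJ numbering decreases 5' to 3' across the J-alpha cluster, so
#' high-numbered segments are rearranged first (proximal).  Default:
#' proximal = TRAJ >= 43, middle = TRAJ 22-42, distal = TRAJ <= 21.
#'
#' @return Named list of inclusive `c(lo, hi)` TRAJ-number ranges.
#' @export
default_j_bins <- function() {
  list(distal = c(1, 21), middle = c(22, 42), proximal = c(43, 61))
}

#' Aggregate J usage into proximal/middle/distal mass
#'
#' @param usage Usage tibble from [j_usage()].
#' @param bins Named list of inclusive TRAJ-number ranges partitioning
#'   the observed segments (default [default_j_bins()]).
#' @return Tibble with columns `subject_id`, `genotype`, `v_call`,
#'   `bin`, `mass`; masses sum to 1 per (subject, v_call).
#' @export
bin_proximal_distal <- function(usage, bins = default_j_bins()) {
  jnum <- suppressWarnings(as.integer(sub("^TRAJ", "", usage$j_call)))
  if (any(is.na(jnum))) {
    abort(sprintf("j_call not parseable as TRAJ<number>: %s",
                  paste(unique(usage$j_call[is.na(jnum)]), collapse = ", ")))
  }
  bin <- rep(NA_character_, length(jnum))
  for (b in names(bins)) {
    bin[jnum >= bins[[b]][1] & jnum <= bins[[b]][2]] <- b
  }
  if (any(is.na(bin))) {
    abort(sprintf("J segment(s) outside all bins: %s",
                  paste(unique(usage$j_call[is.na(bin)]), collapse = ", ")))
  }
  usage |>
    dplyr::mutate(bin = factor(bin, levels = names(bins))) |>
    dplyr::group_by(subject_id, genotype, v_call, bin, .drop = FALSE) |>
    dplyr::summarise(mass = sum(frequency), .groups = "drop") |>
    dplyr::mutate(bin = as.character(bin))
}

#' Compare a J-segment frequency between genotypes
#'
#' Two-sample pooled-variance (Student) t-test on per-mouse frequencies
#' of one J segment, two-tailed, with `n_a + n_b - 2` degrees of
#' freedom.  Mice without any read for the segment contribute a
#' frequency of 0.
#'
#' @param usage Usage tibble from [j_usage()].
#' @param genotype_a,genotype_b Genotype labels to compare.
#' @param j_call J segment of interest (default `TRAJ18`, the invariant
#'   iNKT J segment).
#' @param v_call Optional V segment restriction.
#' @return One-row tibble: `j_call`, `statistic`, `df`, `p_value`,
#'   `mean_a`, `mean_b`, `n_a`, `n_b`, `genotype_a`, `genotype_b`.
#' @export
compare_genotypes <- function(usage, genotype_a, genotype_b,
                              j_call = "TRAJ18", v_call = NULL) {
  u <- usage
  if (!is.null(v_call)) u <- u[u$v_call %in% v_call, , drop = FALSE]
  per_mouse <- u |>
    dplyr::group_by(subject_id, genotype) |>
    dplyr::summarise(frequency = sum(frequency[j_call == !!j_call]),
                     .groups = "drop")
  a <- per_mouse$frequency[per_mouse$genotype == genotype_a]
  b <- per_mouse$frequency[per_mouse$genotype == genotype_b]
  if (length(a) < 2 || length(b) < 2) {
    abort("need at least 2 mice per genotype for the t-test.")
  }
  if (sd(c(a, b)) == 0) {
    tt <- list(statistic = c(t = 0), parameter = c(df = length(a) + length(b) - 2),
               p.value = 1)
  } else {
    tt <- t.test(a, b, var.equal = TRUE)
  }
  tibble(j_call = j_call,
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b),
         n_a = length(a), n_b = length(b),
         genotype_a = genotype_a, genotype_b = genotype_b)
}
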