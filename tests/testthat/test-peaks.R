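random_models <- function(n, seed, chroms = c("chrA", "chrB")) {
  withr::with_seed(seed, {
    start <- sample(0:2000000, n)
    len <- sample(5000:40000, n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    tibble::tibble(gene_id = sprintf("g%03d", seq_len(n)),
                   chrom = sample(chroms, n, replace = TRUE),
                   strand = strand, start = start, end = start + len,
                   tss = ifelse(strand == "+", start, start + len),
                   tes = ifelse(strand == "+", start + len, start))
  })
}

random_peaks <- function(n, seed, chroms = c("chrA", "chrB")) {
  withr::with_seed(seed, {
    s <- sample(0:2200000, n, replace = TRUE)
    tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                   start = s, end = s + sample(50:1000, n, replace = TRUE),
                   name = sprintf("p%04d", seq_len(n)),
                   score = stats::runif(n, 0, 200))
  })
}

test_that("significance filtering decodes both score dialects with a strict cutoff", {
  pk <- tibble::tibble(chrom = "c", start = c(0, 100, 200), end = c(50, 150, 250),
                       name = c("a", "b", "c"), score = c(51, 50, 49))
  kept <- filter_significant_peaks(pk)  # -10*log10(p): 51 <=> p = 10^-5.1
  expect_equal(kept$name, "a")
  pk2 <- tibble::tibble(chrom = "c", start = 0, end = 10, name = "d", score = 6)
  expect_equal(nrow(filter_significant_peaks(pk2, dialect = "minuslog10")), 1)
  expect_equal(nrow(filter_significant_peaks(pk2, dialect = "minus10log10")), 0)
  expect_error(filter_significant_peaks(pk, dialect = "macs"), "arg")
})

test_that("category windows are assigned by the documented priority for simple cases", {
  m <- tibble::tibble(gene_id = "g1", chrom = "c", strand = "+",
                      start = 100000, end = 120000, tss = 100000, tes = 120000)
  ann <- function(s, e) {
    annotate_peaks(tibble::tibble(chrom = "c", start = s, end = e, name = "p",
                                  score = 100), m)
  }
  expect_equal(ann(99950, 100050)$category, "promoter")   # spans the TSS
  expect_equal(ann(110000, 110100)$category, "intragenic")
  expect_equal(ann(125000, 125100)$category, "downstream")
  expect_equal(ann(70000, 70100)$category, "enhancer-window")  # 30 kb upstream
  expect_equal(ann(147000, 147100)$category, "intergenic")
  expect_equal(ann(400000, 400100)$category, "unassigned")
  expect_true(is.na(ann(400000, 400100)$gene_id))
})

test_that("annotation equals the exhaustive brute-force scan on random inputs", {
  models <- random_models(20, seed = 31)
  peaks <- random_peaks(300, seed = 32)
  got <- annotate_peaks(peaks, models)
  for (i in seq_len(nrow(peaks))) {
    o <- oracle_annotate_one(peaks$start[i], peaks$end[i], peaks$chrom[i],
                             models, default_windows())
    expect_identical(got$category[i], o$category)
    expect_identical(got$gene_id[i], o$gene_id)
    if (!is.na(o$gene_id)) expect_equal(got$tss_distance[i], o$dist)
  }
})

test_that("annotation is strand-symmetric under coordinate reflection", {
  models <- random_models(12, seed = 41, chroms = "chrA")
  peaks <- random_peaks(150, seed = 42, chroms = "chrA")
  L <- 3000000
  mirror_models <- models |>
    dplyr::mutate(strand = ifelse(strand == "+", "-", "+"),
                  start2 = L - end, end2 = L - start) |>
    dplyr::mutate(start = start2, end = end2,
                  tss = ifelse(strand == "+", start, end),
                  tes = ifelse(strand == "+", end, start)) |>
    dplyr::select(-start2, -end2)
  mirror_peaks <- peaks |>
    dplyr::mutate(start2 = L - end, end2 = L - start) |>
    dplyr::mutate(start = start2, end = end2) |>
    dplyr::select(-start2, -end2)
  a1 <- annotate_peaks(peaks, models)
  a2 <- annotate_peaks(mirror_peaks, mirror_models)
  expect_equal(a2$category, a1$category)
  expect_equal(a2$gene_id, a1$gene_id)
})

test_that("annotation is independent of peak order and shrinking windows never assigns more", {
  models <- random_models(15, seed = 51)
  peaks <- random_peaks(200, seed = 52)
  a1 <- annotate_peaks(peaks, models)
  perm <- withr::with_seed(53, sample(nrow(peaks)))
  a2 <- annotate_peaks(peaks[perm, ], models)
  expect_equal(a2[order(perm), ]$category, a1$category)
  small <- default_windows(promoter_radius = 500, downstream_length = 2000,
                           enhancer_length = 10000, intergenic_horizon = 20000)
  a3 <- annotate_peaks(peaks, models, small)
  expect_true(all(!(a1$category == "unassigned" & a3$category != "unassigned")))
})

test_that("target calling requires a named-category annotation from a significant peak", {
  models <- tibble::tibble(gene_id = c("gA", "gB"), chrom = "c", strand = "+",
                           start = c(1e5, 9e5), end = c(1.2e5, 9.2e5),
                           tss = c(1e5, 9e5), tes = c(1.2e5, 9.2e5))
  peaks <- tibble::tibble(chrom = "c", start = c(99950, 2.5e6), end = c(100050, 2.5e6 + 100),
                          name = c("on_gA", "nowhere"), score = c(100, 100))
  ann <- annotate_peaks(peaks, models)
  expect_equal(call_tf_targets(ann), "gA")
  expect_equal(call_tf_targets(ann, gene_universe = "gB"), character(0))
  expect_equal(call_tf_targets(ann[0, ]), character(0))
})

test_that("peak and gene-model files round-trip through BED and GTF", {
  peaks <- random_peaks(20, seed = 61)
  pb <- withr::local_tempfile(fileext = ".bed")
  write_peaks(peaks, pb)
  back <- read_peaks(pb)
  expect_equal(back[c("chrom", "start", "end", "name")],
               peaks[c("chrom", "start", "end", "name")])
  expect_equal(back$score, peaks$score, tolerance = 1e-6)

  models <- random_models(10, seed = 62)
  pg <- withr::local_tempfile(fileext = ".gtf")
  write_gene_models(models, pg)
  mback <- read_gene_models(pg)
  expect_equal(dplyr::arrange(mback, gene_id), dplyr::arrange(models, gene_id))
})
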