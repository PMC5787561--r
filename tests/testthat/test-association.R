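expr_from <- function(m, genes = sprintf("g%02d", seq_len(nrow(m)))) {
  colnames(m) <- colnames(m) %||% paste0("s", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(gene_id = genes),
                   tibble::as_tibble(m, .name_repair = "minimal"))
}

test_that("anchor correlation reproduces brute-force coefficients and the dual rule", {
  m <- withr::with_seed(71, matrix(2^stats::rnorm(6 * 30, 3, 1), nrow = 30))
  expr <- expr_from(m)
  out <- correlate_with_anchor(expr, "g01", log2_input = TRUE)
  lg <- log2(m)
  for (i in seq_len(30)) {
    expect_equal(out$pearson_r[i], oracle_pearson(lg[i, ], lg[1, ]), tolerance = 1e-10)
    expect_equal(out$spearman_rho[i], oracle_spearman(lg[i, ], lg[1, ]), tolerance = 1e-10)
  }
  klass_oracle <- ifelse(out$pearson_r >= 0.7 & out$spearman_rho >= 0.7, "positive",
                  ifelse(out$pearson_r <= -0.7 & out$spearman_rho <= -0.7, "negative",
                         "none"))
  expect_equal(out$klass, klass_oracle)
  expect_equal(out$klass[1], "positive")  # anchor against itself
  expect_equal(out$pearson_r[1], 1)
})

test_that("affine transforms, zero variance and the both-must-pass rule behave as documented", {
  anchor <- c(1, 2, 4, 8, 3, 6)
  m <- rbind(anchor = anchor, lin = 2 * anchor + 3, flat = rep(5, 6))
  expr <- expr_from(m, genes = c("anchor", "lin", "flat"))
  out <- correlate_with_anchor(expr, "anchor", log2_input = FALSE)
  expect_equal(out$pearson_r[out$gene_id == "lin"], 1, tolerance = 1e-12)
  expect_equal(out$klass[out$gene_id == "lin"], "positive")
  expect_equal(out$klass[out$gene_id == "flat"], "undefined")
  expect_error(correlate_with_anchor(expr_from(rbind(rep(1, 6)), genes = "a"), "a",
                                     log2_input = FALSE), "zero variance")
  expect_error(correlate_with_anchor(expr, "anchor", samples = c("s1", "s2")),
               "at least 3")
  # r passes, rho fails -> none; constructed via a monotone-breaking outlier
  y <- c(1.0, 2.2, 2.9, 4.2, 2.0, 9.0)
  x <- c(1, 2, 3, 4, 5, 6)
  stopifnot(oracle_pearson(x, y) >= 0.7, abs(oracle_spearman(x, y)) < 0.7)
  m2 <- rbind(a = x, g = y)
  out2 <- correlate_with_anchor(expr_from(m2, c("a", "g")), "a", log2_input = FALSE)
  expect_equal(out2$klass[2], "none")
})

test_that("class-ratio ranking recomputes scores and breaks ties lexicographically", {
  m <- withr::with_seed(72, matrix(stats::runif(40, 0, 50), nrow = 10))
  expr <- expr_from(m)
  ranked <- rank_by_class_ratio(expr, c("s1", "s2"), c("s3", "s4"))
  manual <- log2((rowMeans(m[, 1:2]) + 1) / (rowMeans(m[, 3:4]) + 1))
  expect_equal(ranked$score,
               unname(sort(manual, decreasing = TRUE)), tolerance = 1e-12)
  # (4+1)/(2+1) == (9+1)/(5+1): equal scores, ordered lexicographically
  tied <- expr_from(matrix(c(4, 4, 2, 2, 9, 9, 5, 5), nrow = 2, byrow = TRUE),
                    genes = c("zz", "aa"))
  r2 <- rank_by_class_ratio(tied, c("s1", "s2"), c("s3", "s4"))
  expect_equal(r2$score[1], r2$score[2])
  expect_equal(r2$gene_id, c("aa", "zz"))
  expect_error(rank_by_class_ratio(expr, character(0), "s1"), "non-empty")
})

test_that("the unchanged universe is the inclusive fold-change band", {
  fc <- random_fc_table(200, 73)
  got <- unchanged_universe(fc, 2)
  expect_setequal(got, fc$gene_id[fc$fc >= 0.5 & fc$fc <= 2])
  expect_true("x" %in% unchanged_universe(
    tibble::tibble(gene_id = "x", fc = 1, log2fc = 0), 2))
  expect_false("x" %in% unchanged_universe(
    tibble::tibble(gene_id = "x", fc = 2.5, log2fc = log2(2.5)), 2))
})

test_that("the running-sum enrichment score matches a hand-computed worked example", {
  # 5 genes with equal |score|; set = top gene: inc 1 at position 1 then
  # -1/4 per miss -> running 1, .75, .5, .25, 0; ES = 1
  ranked <- tibble::tibble(gene_id = paste0("g", 1:5), score = c(2, 2, 2, 2, 2))
  es <- enrichment_score(ranked, "g1")
  expect_equal(es$es, 1)
  expect_equal(es$running$running, c(1, 0.75, 0.5, 0.25, 0))
  # graded scores 4,3,2,1,0 and set {g1, g3}: weights 4/6 and 2/6
  ranked2 <- tibble::tibble(gene_id = paste0("g", 1:5), score = c(4, 3, 2, 1, 0))
  es2 <- enrichment_score(ranked2, c("g1", "g3"))
  expect_equal(es2$running$running,
               c(4 / 6, 4 / 6 - 1 / 3, 4 / 6 - 1 / 3 + 2 / 6,
                 4 / 6 - 1 / 3 + 2 / 6 - 1 / 3, 0), tolerance = 1e-12)
  expect_equal(es2$es, 2 / 3, tolerance = 1e-12)
  # bottom-ranked gene with score 0 at w=1: uniform fallback keeps |ES| <= 1
  es3 <- enrichment_score(ranked2, "g5")
  expect_equal(es3$es, -1)
  expect_error(enrichment_score(ranked2, "zzz"), "does not intersect")
  expect_error(enrichment_score(ranked2, ranked2$gene_id), "whole ranked universe")
})

test_that("random-input ES agrees with the plain-loop oracle and the complement rule at w=0", {
  withr::with_seed(81, {
    for (rep in 1:20) {
      n <- sample(10:60, 1)
      ranked <- tibble::tibble(gene_id = sprintf("g%03d", 1:n),
                               score = sort(stats::rnorm(n), decreasing = TRUE))
      set <- sample(ranked$gene_id, sample(2:(n - 2), 1))
      es <- enrichment_score(ranked, set)
      expect_equal(es$es, oracle_es(ranked$score, ranked$gene_id %in% set),
                   tolerance = 1e-12)
      expect_lte(abs(es$es), 1 + 1e-12)
    }
  })
  ranked <- tibble::tibble(gene_id = sprintf("g%03d", 1:30),
                           score = seq(3, -3, length.out = 30))
  set <- sprintf("g%03d", c(1, 4, 9, 16, 25))
  es_a <- enrichment_score(ranked, set, weight_exponent = 0)
  es_b <- enrichment_score(ranked, setdiff(ranked$gene_id, set), weight_exponent = 0)
  expect_equal(es_a$es, -es_b$es, tolerance = 1e-12)
})

test_that("the ES implementation agrees with an established GSEA statistic", {
  skip_if_not_installed("fgsea")
  ranked <- withr::with_seed(91, tibble::tibble(
    gene_id = sprintf("g%03d", 1:100),
    score = sort(stats::rnorm(100, 0, 2), decreasing = TRUE)
  ))
  set <- sprintf("g%03d", c(2, 5, 8, 11, 17, 40, 90))
  es <- enrichment_score(ranked, set)$es
  stats_vec <- stats::setNames(ranked$score, ranked$gene_id)
  ref <- fgsea::calcGseaStat(stats_vec, selectedStats = match(set, names(stats_vec)),
                             gseaParam = 1)
  expect_equal(es, ref, tolerance = 1e-6)
})

test_that("the permutation test is seed-stable, detects a planted top set, and p-values are valid", {
  ranked <- withr::with_seed(92, tibble::tibble(
    gene_id = sprintf("g%03d", 1:120),
    score = sort(stats::rnorm(120, 0, 1.5), decreasing = TRUE)
  ))
  planted <- ranked$gene_id[1:20]
  r1 <- permutation_test(ranked, planted, n_perm = 1000, seed = 7)
  r2 <- permutation_test(ranked, planted, n_perm = 1000, seed = 7)
  expect_identical(r1, r2)
  expect_lte(r1$p_perm, 0.01)
  expect_gt(r1$es, 0)
  expect_gt(r1$p_perm, 0)
  expect_lte(r1$p_perm, 1)
  expect_true(all(r1$leading_edge %in% planted))
  r3 <- permutation_test(ranked, planted, n_perm = 1000, seed = 8)
  expect_false(identical(r1$es_null, r3$es_null))
  expect_equal(r1$es, r3$es)  # observed ES does not depend on the seed
})
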