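# internal helpers shared across modules

assert_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

assert_range <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 2L || any(is.na(x)) || x[1] > x[2] ||
      x[1] < lower || x[2] > upper) {
    abort(sprintf("`%s` must be a numeric range c(lo, hi) within [%s, %s].",
                  name, format(lower), format(upper)))
  }
  as.numeric(x)
}

# gene x sample values of a wide expression tibble as a numeric matrix
expr_values <- function(expr) {
  if (!is.data.frame(expr) || names(expr)[1] != "gene_id") {
    abort("expression table must be a data frame whose first column is `gene_id`.")
  }
  m <- as.matrix(expr[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- expr$gene_id
  m
}

sample_cols <- function(expr) setdiff(names(expr), "gene_id")

check_populations <- function(sample_map, populations) {
  known <- unique(sample_map$population)
  bad <- setdiff(populations, known)
  if (length(bad) > 0) {
    abort(sprintf("unknown population(s) %s; known populations: %s",
                  paste0("'", bad, "'", collapse = ", "),
                  paste(known, collapse = ", ")))
  }
  invisible(TRUE)
}
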