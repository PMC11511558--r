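# Small in-code fixtures shared across test files.

toy_study <- function(n_genes = 6, n_subjects = 4, seed = 42) {
  set.seed(seed)
  timepoints <- c("V1D0", "V1D7", "V2D0", "V2D7")
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  meta <- data.frame(
    sample_id = as.vector(t(outer(subjects, timepoints, paste, sep = "_"))),
    subject = rep(subjects, each = 4),
    group = rep(c("HD", "HC"), length.out = n_subjects)[rep(seq_len(n_subjects), each = 4)],
    timepoint = rep(timepoints, n_subjects))
  expr <- matrix(rnorm(n_genes * nrow(meta)), n_genes,
                 dimnames = list(sprintf("G%03d", seq_len(n_genes)), meta$sample_id))
  expression_study(expr, meta)
}

write_toy_gmt <- function(path, sets = list(M1 = c("A", "B", "C"),
                                            M2 = c("C", "D", "E", "F"),
                                            M3 = c("G", "H"))) {
  writeLines(vapply(names(sets), function(id)
    paste(c(id, "desc", sets[[id]]), collapse = "\t"), character(1)), path)
  path
}

# Brute-force Pearson correlation of two vectors, written independently of
# stats::cor for oracle comparisons.
pearson_brute <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Brute-force BH step-up.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- prev
  }
  q
}

# Brute-force GSEA enrichment score by walking the full ranked list.
es_brute <- function(scores, in_set, exponent = 1) {
  N <- length(scores)
  w <- abs(scores)^exponent
  wh <- w * in_set
  if (sum(wh) == 0) wh <- as.numeric(in_set)
  inc <- wh / sum(wh)
  dec <- (!in_set) / (N - sum(in_set))
  running <- cumsum(inc - dec)
  running[which.max(abs(running))]
}
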