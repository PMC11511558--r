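test_that("regulatory network TSV round-trips and rejects bad input", {
  set.seed(81)
  w <- matrix(rnorm(6), 2, 3, dimnames = list(c("TF1", "TF2"), c("G1", "G2", "G3")))
  net <- regulatory_network(w)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_regulatory_network(net, path)
  back <- read_regulatory_network(path)
  expect_equal(back$weights, w)
  expect_equal(back$tf_names, c("TF1", "TF2"))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tf\tG1\tG2", "TF1\t1\tx"), bad)
  expect_error(read_regulatory_network(bad), "non-numeric")
  expect_error(regulatory_network(matrix(1, 1, 2, dimnames = list("TF1", c("G1", "G1")))),
               "duplicate gene")
})

test_that("prior+correlation builder behaves on planted cases", {
  set.seed(82)
  n <- 400
  expr <- rbind(TFA = rnorm(n), GX = rnorm(n))
  expr <- rbind(expr, GDUP = expr["TFA", ])
  colnames(expr) <- paste0("s", seq_len(n))
  meta <- data.frame(sample_id = colnames(expr), subject = colnames(expr),
                     group = "HC", timepoint = "V1D0")
  study <- expression_study(expr, meta)
  prior <- matrix(c(0, 1), 1, 2, dimnames = list("TFA", c("GX", "GDUP")))
  net <- build_prior_network(prior, study)
  expect_lt(abs(net$weights["TFA", "GX"]), 0.15)       # independent: ~0
  expect_equal(net$weights["TFA", "GDUP"], 2)          # r = 1 plus prior 1
  net2 <- build_prior_network(prior, study)
  expect_identical(net$weights, net2$weights)
  bad <- matrix(0, 1, 1, dimnames = list("NOPE", "GX"))
  expect_error(build_prior_network(bad, study), "NOPE")
})

test_that("regulatory difference is elementwise, order-normalized and antisymmetric", {
  set.seed(83)
  w <- matrix(rnorm(12), 3, 4, dimnames = list(paste0("TF", 1:3), paste0("G", 1:4)))
  a <- regulatory_network(w)
  shuffled <- w[c(2, 1, 3), c(3, 1, 2, 4)]
  b <- regulatory_network(shuffled)
  expect_equal(regulatory_difference(a, b), regulatory_difference(a, a))
  expect_true(all(regulatory_difference(a, a) == 0))
  w2 <- w; w2["TF2", "G3"] <- w2["TF2", "G3"] + 5
  d <- regulatory_difference(regulatory_network(w2), a)
  expect_equal(sum(d != 0), 1)
  expect_equal(d["TF2", "G3"], 5)
  expect_equal(regulatory_difference(a, regulatory_network(w2)), -d)
  bad <- regulatory_network(matrix(0, 3, 4, dimnames = list(paste0("TF", 1:3),
                                                            paste0("X", 1:4))))
  expect_error(regulatory_difference(a, bad), "differ")
})

test_that("gene ranking honors the aggregation rules and tie-breaks", {
  d <- matrix(0, 2, 3, dimnames = list(c("TFA", "TFB"), c("G1", "G2", "G3")))
  d["TFA", "G1"] <- -5
  ranked <- rank_gene_targets(d)
  expect_equal(ranked$gene[3], "G1")
  expect_equal(ranked$score[3], -5)
  # sum aggregation cancels opposite edges
  d2 <- matrix(c(3, -3), 2, 1, dimnames = list(c("TFA", "TFB"), "G1"))
  expect_equal(rank_gene_targets(d2, "sum")$score, 0)
  # |value| tie across TFs resolves to the lexicographically larger TF
  d3 <- matrix(c(4, -4), 2, 1, dimnames = list(c("TFA", "TFB"), "G1"))
  expect_equal(rank_gene_targets(d3)$score, -4)
})

test_that("planted dysregulated genes occupy the ranking extremes", {
  pair <- generate_regulatory_pair(8, 60, 10, effect = 5, seed = 84, sign = "both")
  tr <- pair$truth$regulatory_truth
  ranked <- rank_gene_targets(regulatory_difference(pair$hd, pair$hc))
  up <- tr$gene[tr$sign > 0]
  down <- tr$gene[tr$sign < 0]
  expect_setequal(head(ranked$gene, length(up)), up)
  expect_setequal(tail(ranked$gene, length(down)), down)
})

test_that("enrichment score matches the hand-traced toy and the brute-force walk", {
  ranked <- data.frame(gene = c("g1", "g2", "g3", "g4", "g5"),
                       score = c(3, 2, 1, -1, -2))
  res <- preranked_gsea(ranked, list(TOP = c("g1", "g2")), n_perm = 200, seed = 1)
  expect_equal(res$es, 1.0)
  expect_setequal(attr(res, "leading_edges")$TOP, c("g1", "g2"))
  # independent full-walk oracle over random sets
  set.seed(85)
  scores <- sort(rnorm(40), decreasing = TRUE)
  genes <- sprintf("g%02d", 1:40)
  for (k in c(3, 7, 15)) {
    in_set <- genes %in% sample(genes, k)
    res_k <- preranked_gsea(data.frame(gene = genes, score = scores),
                            setNames(list(genes[in_set]), "S"),
                            n_perm = 100, seed = 2)
    expect_equal(res_k$es, es_brute(scores, in_set), tolerance = 1e-12)
  }
})

test_that("enrichment agrees with an independent implementation on clean rankings", {
  skip_if_not_installed("fgsea")
  set.seed(86)
  genes <- sprintf("g%03d", 1:100)
  scores <- sort(rnorm(100, sd = 2), decreasing = TRUE)
  names(scores) <- genes
  sets <- list(A = sample(genes, 10), B = sample(genes, 25))
  mine <- preranked_gsea(data.frame(gene = genes, score = scores), sets,
                         n_perm = 200, seed = 3)
  ref <- suppressWarnings(fgsea::fgsea(sets, scores, nPermSimple = 500,
                                       gseaParam = 1))
  expect_equal(mine$es[match(ref$pathway, mine$set)], ref$ES, tolerance = 1e-6)
})

test_that("permutation p respects the (b+1)/(n+1) floor and degenerate sets are skipped", {
  ranked <- data.frame(gene = sprintf("g%02d", 1:30),
                       score = seq(5, -5, length.out = 30))
  res <- preranked_gsea(ranked, list(S = sprintf("g%02d", 1:5)), n_perm = 150, seed = 4)
  expect_gte(res$p, 1 / 151)
  expect_warning(
    res2 <- preranked_gsea(ranked, list(ALL = ranked$gene, S = sprintf("g%02d", 1:5)),
                           n_perm = 150, seed = 4),
    "whole ranked list")
  expect_equal(res2$set, "S")
  expect_warning(
    preranked_gsea(ranked, list(S = sprintf("g%02d", 1:5), NONE = "zzz"),
                   n_perm = 150, seed = 4),
    "no genes")
})

test_that("negating scores and reversing rank order negates the ES", {
  set.seed(87)
  genes <- sprintf("g%02d", 1:25)
  scores <- sort(rnorm(25), decreasing = TRUE)
  set <- sample(genes, 6)
  a <- preranked_gsea(data.frame(gene = genes, score = scores),
                      list(S = set), n_perm = 100, seed = 5)
  b <- preranked_gsea(data.frame(gene = rev(genes), score = rev(-scores)),
                      list(S = set), n_perm = 100, seed = 5)
  expect_equal(a$es, -b$es, tolerance = 1e-12)
})

test_that("top dysregulated edge report is sorted and restricted to the gene set", {
  set.seed(88)
  d <- matrix(rnorm(30), 5, 6, dimnames = list(paste0("TF", 1:5), paste0("G", 1:6)))
  rep_edges <- top_dysregulated_edges(d, c("G1", "G2"), n_top = 4)
  expect_equal(nrow(rep_edges), 4)
  expect_true(all(rep_edges$gene %in% c("G1", "G2")))
  expect_true(all(diff(abs(rep_edges$difference)) <= 0))
})
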