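make_net <- function(r_mat, n, scope = "g") {
  structure(list(r = r_mat, n_samples = n, scope = scope,
                 module_order = rownames(r_mat)), class = "CoexpressionNetwork")
}

sym_net <- function(rs, n, ids = NULL) {
  k <- (1 + sqrt(1 + 8 * length(rs))) / 2
  m <- diag(k)
  m[upper.tri(m)] <- rs
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  ids <- ids %||% paste0("M", seq_len(k))
  dimnames(m) <- list(ids, ids)
  make_net(m, n)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("fisher_z matches arctanh, is odd, clamps r = 1 and rejects |r| > 1", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  expect_equal(fisher_z(-0.9), -fisher_z(0.9))
  expect_warning(z1 <- fisher_z(1), "clamped")
  expect_equal(z1, atanh(1 - 1e-7))
  expect_error(fisher_z(1.01), "not a correlation")
})

test_that("standardized z-difference reproduces the closed form", {
  net_hd <- sym_net(0.5, 48)
  net_hc <- sym_net(0.8, 76)
  d <- z_difference_network(net_hd, net_hc)
  expect_equal(d$z_diff, -2.898, tolerance = 1e-3)
  expect_equal(d$p, 0.00375, tolerance = 1e-3)
  # brute closed form
  expect_equal(d$z_diff, (atanh(0.5) - atanh(0.8)) / sqrt(1 / 45 + 1 / 73),
               tolerance = 1e-12)
})

test_that("literal mode treats the raw z difference as a normal deviate", {
  r_hd <- tanh(1.96); r_hc <- tanh(0)
  d <- z_difference_network(sym_net(r_hd, 48), sym_net(r_hc, 76), mode = "literal")
  expect_equal(d$z_diff, 1.96, tolerance = 1e-10)
  expect_equal(d$p, 0.05, tolerance = 1e-3)
})

test_that("identical networks give zero differences, p = 1, all unchanged", {
  net <- sym_net(c(0.3, -0.2, 0.6), 40)
  d <- z_difference_network(net, net)
  expect_equal(d$z_diff, rep(0, 3))
  expect_equal(d$p, rep(1, 3))
  expect_equal(d$class, rep("unchanged", 3))
})

test_that("swapping group order negates z_diff and preserves p and q", {
  set.seed(71)
  a <- sym_net(runif(6, -0.8, 0.8), 48)
  b <- sym_net(runif(6, -0.8, 0.8), 76)
  d1 <- z_difference_network(a, b)
  d2 <- z_difference_network(b, a)
  expect_equal(d1$z_diff, -d2$z_diff)
  expect_equal(d1$p, d2$p)
  expect_equal(d1$q, d2$q)
})

test_that("mismatched module sets are rejected", {
  a <- sym_net(0.5, 48, c("M1", "M2"))
  b <- sym_net(0.5, 76, c("M1", "MX"))
  expect_error(z_difference_network(a, b), "module sets")
})

test_that("edge classification assigns the six differential classes correctly", {
  expect_equal(classify_edge(0.3, 0.6, TRUE), "pos_weaker_hd")
  expect_equal(classify_edge(-0.2, 0.4, TRUE), "discordant_neg_hd")
  expect_equal(classify_edge(0.9, 0.1, FALSE), "unchanged")
  expect_equal(classify_edge(0.7, 0.2, TRUE), "pos_stronger_hd")
  expect_equal(classify_edge(-0.2, -0.5, TRUE), "neg_weaker_hd")
  expect_equal(classify_edge(-0.6, -0.1, TRUE), "neg_stronger_hd")
  expect_equal(classify_edge(0.4, -0.3, TRUE), "discordant_pos_hd")
})

test_that("the six classes plus unchanged are exhaustive and mutually exclusive", {
  grid <- expand.grid(r_hd = seq(-0.9, 0.9, by = 0.1),
                      r_hc = seq(-0.9, 0.9, by = 0.1),
                      sig = c(TRUE, FALSE))
  labels <- classify_edge(grid$r_hd, grid$r_hc, grid$sig)
  valid <- c("pos_weaker_hd", "pos_stronger_hd", "neg_weaker_hd",
             "neg_stronger_hd", "discordant_pos_hd", "discordant_neg_hd",
             "unchanged")
  expect_true(all(labels %in% valid))
  expect_equal(length(labels), nrow(grid))  # exactly one label per combination
  expect_true(all(labels[!grid$sig] == "unchanged"))
  sig_rows <- grid$sig & grid$r_hd != 0 & grid$r_hc != 0
  expect_true(all(labels[sig_rows] != "unchanged"))
  # zero-correlation tie rule goes to the discordant branch
  expect_equal(classify_edge(0, 0.5, TRUE), "discordant_neg_hd")
  expect_equal(classify_edge(0, -0.5, TRUE), "discordant_pos_hd")
})

test_that("family summaries use the n-choose-2 and cross-product denominators", {
  # 5 modules: family F has 3 (M1..M3), family G has 2 (M4, M5)
  set.seed(72)
  rs_hd <- runif(10, 0.1, 0.4)
  rs_hc <- runif(10, 0.5, 0.9)
  net_hd <- sym_net(rs_hd, 48, paste0("M", 1:5))
  net_hc <- sym_net(rs_hc, 76, paste0("M", 1:5))
  d <- z_difference_network(net_hd, net_hc, alpha = 0.9)
  fams <- c(M1 = "F", M2 = "F", M3 = "F", M4 = "G", M5 = "G")
  intra <- family_edge_summary(d, fams, "intra")
  expect_equal(unique(intra$denominator[intra$family == "F"]), 3)
  expect_equal(unique(intra$denominator[intra$family == "G"]), 1)
  inter <- family_edge_summary(d, fams, "inter")
  expect_equal(unique(inter$denominator[inter$family == "F"]), 3 * 2)
  pw <- family_edge_summary(d, fams, "pairwise")
  expect_equal(unique(pw$denominator), 6)
  # percentages are count / denominator
  expect_equal(intra$percentage, 100 * intra$count / intra$denominator)
  # intra + pairwise counts partition the significant edges
  n_sig <- sum(d$class != "unchanged")
  expect_equal(sum(intra$count) + sum(pw$count), n_sig)
})

test_that("single-module families get NA intra percentages", {
  net_hd <- sym_net(c(0.1, 0.1, 0.1), 48, paste0("M", 1:3))
  net_hc <- sym_net(c(0.8, 0.8, 0.8), 76, paste0("M", 1:3))
  d <- z_difference_network(net_hd, net_hc)
  fams <- c(M1 = "F", M2 = "F", M3 = "Lone")
  intra <- family_edge_summary(d, fams, "intra")
  expect_true(all(is.na(intra$percentage[intra$family == "Lone"])))
  expect_equal(unique(intra$denominator[intra$family == "Lone"]), 0)
})

test_that("median edge weight respects sign, mask, and symmetry", {
  rs <- tanh(c(0.2, 0.5, -0.3))
  net <- sym_net(rs, 10, paste0("M", 1:3))
  expect_equal(median_edge_weight(net, "positive"), 0.35, tolerance = 1e-9)
  expect_equal(median_edge_weight(net, "negative"), -0.3, tolerance = 1e-9)
  all_neg <- sym_net(tanh(c(-0.2, -0.5, -0.3)), 10)
  expect_true(is.na(median_edge_weight(all_neg, "positive")))
  mask <- data.frame(module_a = "M1", module_b = "M2")
  expect_equal(median_edge_weight(net, "positive", mask), 0.2, tolerance = 1e-9)
  # mask order must not matter
  mask_rev <- data.frame(module_a = "M2", module_b = "M1")
  expect_equal(median_edge_weight(net, "positive", mask_rev), 0.2, tolerance = 1e-9)
})

test_that("median-edge comparison reproduces the pooled t and its invariances", {
  res <- compare_median_edges(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))
  expect_equal(res$t, -3.674, tolerance = 1e-3)
  expect_equal(res$p, 0.0213, tolerance = 1e-3)
  expect_equal(res$df, 4)
  scaled <- compare_median_edges(2 * c(0.1, 0.2, 0.3), 2 * c(0.4, 0.5, 0.6))
  expect_equal(scaled$t, res$t, tolerance = 1e-12)
  same <- compare_median_edges(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(compare_median_edges(0.5, c(1, 2)), ">= 2")
})

test_that("significant co-expression edges agree with cor.test and pick the right sign", {
  set.seed(73)
  values <- matrix(rnorm(4 * 30), 4, dimnames = list(paste0("M", 1:4), paste0("s", 1:30)))
  values[2, ] <- values[1, ] + rnorm(30, sd = 0.4)   # strong positive pair
  values[4, ] <- -values[3, ] + rnorm(30, sd = 0.4)  # strong negative pair
  net <- make_net(cor(t(values)), 30)
  edges <- significant_edges(net, alpha = 0.05, sign = "any")
  # oracle: cor.test p-values
  for (i in seq_len(nrow(edges))) {
    ct <- cor.test(values[edges$module_a[i], ], values[edges$module_b[i], ])
    expect_equal(edges$p[i], ct$p.value, tolerance = 1e-9)
  }
  pos <- significant_edges(net, sign = "positive")
  expect_true(all(pos$r > 0))
  expect_true(any(pos$module_a == "M1" & pos$module_b == "M2"))
  neg <- significant_edges(net, sign = "negative")
  expect_true(any(neg$module_a == "M3" & neg$module_b == "M4"))
})

test_that("edge concordance counts shared directions", {
  hd <- sym_net(c(0.5, -0.4, 0.3), 48, paste0("M", 1:3))
  hc <- sym_net(c(0.7, -0.2, -0.3), 76, paste0("M", 1:3))
  edges <- data.frame(module_a = c("M1", "M1", "M2"), module_b = c("M2", "M3", "M3"))
  cc <- edge_concordance(hd, hc, edges)
  expect_equal(cc$n_edges, 3)
  expect_equal(cc$n_both_positive, 1)
  expect_equal(cc$n_both_negative, 1)
  expect_equal(cc$pct_concordant, 100 * 2 / 3)
})
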