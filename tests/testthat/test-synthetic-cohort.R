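test_that("identical seeds give bit-identical cohorts", {
  a <- generate_cohort(n_subjects_per_group = c(4, 4), n_modules = 6,
                       genes_per_module = 5, seed = 7)
  b <- generate_cohort(n_subjects_per_group = c(4, 4), n_modules = 6,
                       genes_per_module = 5, seed = 7)
  expect_identical(a$study$expr, b$study$expr)
  expect_identical(a$truth$eigensignals, b$truth$eigensignals)
  c <- generate_cohort(n_subjects_per_group = c(4, 4), n_modules = 6,
                       genes_per_module = 5, seed = 8)
  expect_false(identical(a$study$expr, c$study$expr))
})

test_that("cohort dimensions, metadata and truth invariants hold", {
  sim <- generate_cohort(n_subjects_per_group = c(5, 6), n_modules = 12,
                         genes_per_module = 7, seed = 1)
  expect_equal(dim(sim$study$expr), c(12 * 7, (5 + 6) * 4))
  expect_equal(sum(sim$study$metadata$group == "HD"), 20)
  expect_setequal(unique(sim$study$metadata$timepoint),
                  c("V1D0", "V1D7", "V2D0", "V2D7"))
  for (m in sim$truth$coupling_matrix_by_group) {
    expect_equal(m, t(m))
    expect_equal(unname(diag(m)), rep(1, 12))
  }
  mult <- sim$truth$group_coupling_multiplier
  expect_true(mult > 0 && mult <= 1)
})

test_that("planted multiplier scales within-family latent correlations", {
  # large cohort so Monte-Carlo error on the latent correlations is small
  sim <- generate_cohort(n_subjects_per_group = c(150, 150), n_modules = 12,
                         genes_per_module = 2, coupling = 0.7,
                         hd_multiplier = 0.5, timepoint_effect_sd = 0,
                         seed = 11)
  meta <- sim$study$metadata
  lat <- sim$truth$latent_factors
  fam <- sim$truth$family_assignments
  same_fam_cor <- function(group) {
    cc <- cor(t(lat[, meta$sample_id[meta$group == group]]))
    mask <- outer(fam, fam, "==") & upper.tri(cc)
    mean(cc[mask])
  }
  expect_equal(same_fam_cor("HC"), 0.7, tolerance = 0.05)
  expect_equal(same_fam_cor("HD"), 0.35, tolerance = 0.05)
  # HD-like group's median positive eigensignal correlation is lower
  med_pos <- function(group) {
    cc <- cor(t(lat[, meta$sample_id[meta$group == group]]))
    v <- cc[upper.tri(cc)]
    median(v[v > 0])
  }
  expect_lt(med_pos("HD"), med_pos("HC"))
})

test_that("with multiplier 1 the groups are statistically exchangeable", {
  sim <- generate_cohort(n_subjects_per_group = c(8, 8), n_modules = 12,
                         genes_per_module = 4, hd_multiplier = 1, seed = 3)
  meta <- sim$study$metadata
  lat <- sim$truth$latent_factors
  ch <- cor(t(lat[, meta$sample_id[meta$group == "HD"]]))
  cc <- cor(t(lat[, meta$sample_id[meta$group == "HC"]]))
  fam <- sim$truth$family_assignments
  mask <- outer(fam, fam, "==") & upper.tri(ch)
  # same generating correlation: difference of family-edge means is small
  expect_equal(mean(ch[mask]), mean(cc[mask]), tolerance = 0.15)
})

test_that("generator rejects invalid arguments", {
  expect_error(generate_cohort(n_subjects_per_group = c(2, 19)), ">= 4 subjects")
  expect_error(generate_cohort(coupling = 1.2), "coupling")
  expect_error(generate_cohort(hd_multiplier = 0), "hd_multiplier")
  expect_error(generate_cohort(coupling = 1, hd_multiplier = 1), "< 1")
  expect_error(generate_cohort(noise_sd = 0), "noise_sd")
  expect_error(generate_cohort(n_modules = 0), "dimensions")
})

test_that("regulatory pair plants exactly the requested edge differences", {
  pair <- generate_regulatory_pair(5, 40, 10, effect = 5, seed = 2)
  d <- pair$hd$weights[sort(pair$hd$tf_names), sort(pair$hd$gene_names)] -
    pair$hc$weights[sort(pair$hc$tf_names), sort(pair$hc$gene_names)]
  expect_equal(sum(d != 0), 10)
  tr <- pair$truth$regulatory_truth
  expect_equal(sort(abs(d[cbind(tr$tf, tr$gene)])), rep(5, 10))
  expect_equal(unname(sign(d[cbind(tr$tf, tr$gene)])), tr$sign)
  # effect = 0 leaves the matrices equal
  p0 <- generate_regulatory_pair(5, 40, 10, effect = 0, seed = 2)
  expect_equal(p0$hd$weights, p0$hc$weights)
  # determinism
  p2 <- generate_regulatory_pair(5, 40, 10, effect = 5, seed = 2)
  expect_identical(pair$hd$weights, p2$hd$weights)
  expect_error(generate_regulatory_pair(5, 40, 10, effect = -1), "non-negative")
  expect_error(generate_regulatory_pair(2, 3, 7, effect = 1), "exceeds")
})

test_that("mixture truth rows are simplex points and noiseless bulk is exact", {
  S <- diag(4) * 3 + 1
  dimnames(S) <- list(paste0("G", 1:4), paste0("T", 1:4))
  mix <- generate_mixtures(S, 30, rep(2, 4), noise_sd = 0, seed = 5)
  pr <- mix$truth$mixture_truth
  expect_equal(unname(rowSums(pr)), rep(1, 30))
  expect_true(all(pr >= 0))
  expect_equal(unname(mix$study$expr), unname(S %*% t(pr)))
  expect_true(all(mix$study$expr >= 0))
  expect_error(generate_mixtures(S - 5, 3, rep(1, 4)), "non-negative")
  expect_error(generate_mixtures(S, 3, rep(1, 3)), "length")
})

test_that("synthetic reference plants recoverable markers", {
  ref <- generate_reference(celltypes = c("A", "B", "C"), markers_per_type = 5,
                            n_background = 20, cells_per_type = 4, seed = 9)
  expect_equal(dim(ref$expr), c(3 * 5 + 20, 12))
  expect_true(all(ref$expr >= 0))
  expect_equal(ref$labels, rep(c("A", "B", "C"), each = 4))
  means_a <- rowMeans(ref$expr[, ref$labels == "A"])
  expect_true(all(means_a[ref$marker_truth$A] > 3))
})
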