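BTM_FAMILIES <- c("B cells", "cell cycle", "DC/APC", "IFN type I",
                  "Myeloid/Inflamm", "T/NK cells")

# Orientation of each family on the global immune-activity factor: innate
# activity (DC/APC, IFN type I, Myeloid/Inflamm) and cell cycle move
# together, adaptive lymphocyte families (B cells, T/NK cells) against
# them, so cross-family edges include negative co-expression as in real
# blood transcriptomes.
FAMILY_SIGNS <- c("B cells" = -1, "cell cycle" = 1, "DC/APC" = 1,
                  "IFN type I" = 1, "Myeloid/Inflamm" = 1, "T/NK cells" = -1)

#' Generate a synthetic vaccine-response cohort with ground truth
#'
#' Simulates the statistical structure the downstream analysis assumes: a
#' hierarchical latent-factor model in which each sample has one global
#' immune-activity factor and one factor per BTM family, each module's
#' eigensignal mixes the global factor, its family factor and a
#' module-unique component, and genes load on their module's eigensignal
#' plus i.i.d. Gaussian noise. The latent Pearson correlation between
#' same-family module eigensignals is `coupling` in the control-like group
#' and `coupling * hd_multiplier` in the HD-like group (weakened
#' coregulation); modules in different families correlate at half that
#' strength through the global factor, positively between families with
#' the same orientation on it and negatively between innate-oriented and
#' adaptive-oriented families, so interfamily and negative coregulation
#' are weakened too. Module activity shifts additively across the four
#' timepoints; the shifts are drawn per family (co-regulated modules move
#' together over the vaccine course) and are shared by both groups, giving
#' the timepoint ANOVA a real effect that does not differ between groups.
#'
#' Defaults mirror the study design the pipeline targets: 12 HD-like vs 19
#' control subjects, each with complete `V1D0, V1D7, V2D0, V2D7` series,
#' and eight modules in each of the six BTM families (a deliberately
#' reduced network relative to the full BTM catalogue, sized so that the
#' planted group contrast is recoverable at this scale).
#'
#' @param n_subjects_per_group integer pair `(HD, HC)`; both >= 4.
#' @param n_modules number of modules (assigned round-robin to six BTM
#'   families).
#' @param genes_per_module genes per module.
#' @param coupling within-family latent correlation in `[0, 1]` for the
#'   control group.
#' @param hd_multiplier factor in `(0, 1]` applied to `coupling` in the
#'   HD-like group (`coupling * hd_multiplier < 1`).
#' @param noise_sd gene-level Gaussian noise sd.
#' @param timepoint_effect_sd sd of the module-by-timepoint additive
#'   shifts (0 disables the timepoint effect).
#' @param subject_effect_sd sd of per-subject, per-module random
#'   intercepts (between-subject baseline variation; cancels in
#'   within-subject correlations but exercises the ANOVA's subject
#'   blocking).
#' @param seed integer; identical seeds give bit-identical output.
#' @return List with `study` (an [expression_study()]), `truth`
#'   (`SyntheticTruth`: module/family assignments, per-group coupling
#'   matrices, the multiplier, timepoint effects, the planted latent
#'   factors and per-sample eigensignals, gene loadings, and the seed) and
#'   `btms` (the matching [btm_collection()]).
#' @export
generate_cohort <- function(n_subjects_per_group = c(12L, 19L),
                            n_modules = 48L, genes_per_module = 15L,
                            coupling = 0.7, hd_multiplier = 0.5,
                            noise_sd = 0.5, timepoint_effect_sd = 0.3,
                            subject_effect_sd = 0.3, seed = 1L) {
  if (any(n_subjects_per_group < 4L)) stop("need >= 4 subjects per group")
  if (n_modules < 1L || genes_per_module < 1L) stop("non-positive dimensions")
  if (coupling < 0 || coupling > 1) stop("coupling must lie in [0, 1]")
  if (hd_multiplier <= 0 || hd_multiplier > 1) stop("hd_multiplier must lie in (0, 1]")
  if (coupling * hd_multiplier >= 1) stop("coupling * hd_multiplier must be < 1")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (timepoint_effect_sd < 0) stop("timepoint_effect_sd must be non-negative")
  if (subject_effect_sd < 0) stop("subject_effect_sd must be non-negative")

  timepoints <- c("V1D0", "V1D7", "V2D0", "V2D7")
  groups <- c("HD", "HC")
  n_sub <- stats::setNames(as.integer(n_subjects_per_group), groups)
  module_ids <- sprintf("M%02d", seq_len(n_modules))
  fam_of <- stats::setNames(rep(BTM_FAMILIES, length.out = n_modules), module_ids)
  gene_ids <- as.vector(vapply(module_ids, function(m)
    sprintf("%sG%03d", m, seq_len(genes_per_module)), character(genes_per_module)))
  gene_module <- stats::setNames(rep(module_ids, each = genes_per_module), gene_ids)

  subjects <- c(sprintf("HD%02d", seq_len(n_sub["HD"])),
                sprintf("HC%02d", seq_len(n_sub["HC"])))
  metadata <- data.frame(
    sample_id = as.vector(t(outer(subjects, timepoints, paste, sep = "_"))),
    subject = rep(subjects, each = length(timepoints)),
    group = rep(c(rep("HD", n_sub["HD"]), rep("HC", n_sub["HC"])),
                each = length(timepoints)),
    timepoint = rep(timepoints, times = length(subjects)),
    stringsAsFactors = FALSE)

  rho <- c(HD = coupling * hd_multiplier, HC = coupling)
  out <- with_seed(child_seed(seed, "cohort"), {
    fams <- unique(fam_of)
    fam_eff <- matrix(stats::rnorm(length(fams) * length(timepoints), 0, timepoint_effect_sd),
                      nrow = length(fams),
                      dimnames = list(fams, timepoints))
    tp_eff <- fam_eff[fam_of, , drop = FALSE]
    rownames(tp_eff) <- module_ids
    loadings <- stats::setNames(stats::runif(length(gene_ids), 0.5, 1), gene_ids)
    n_samples <- nrow(metadata)
    latent <- matrix(0, n_modules, n_samples,
                     dimnames = list(module_ids, metadata$sample_id))
    signs <- FAMILY_SIGNS[fam_of]
    subj_ids <- unique(metadata$subject)
    subj_eff <- matrix(stats::rnorm(n_modules * length(subj_ids), 0, subject_effect_sd),
                       nrow = n_modules, dimnames = list(module_ids, subj_ids))
    for (j in seq_len(n_samples)) {
      g <- metadata$group[j]
      glob <- stats::rnorm(1)
      f_fac <- stats::setNames(stats::rnorm(length(fams)), fams)
      uniq <- stats::rnorm(n_modules)
      latent[, j] <- sqrt(rho[g] / 2) * (signs * glob + f_fac[fam_of]) +
        sqrt(1 - rho[g]) * uniq
    }
    eigensignals <- latent + tp_eff[, metadata$timepoint, drop = FALSE] +
      subj_eff[, metadata$subject, drop = FALSE]
    colnames(eigensignals) <- metadata$sample_id
    expr <- loadings[gene_ids] * eigensignals[gene_module[gene_ids], , drop = FALSE] +
      matrix(stats::rnorm(length(gene_ids) * n_samples, 0, noise_sd),
             length(gene_ids), n_samples)
    rownames(expr) <- gene_ids
    colnames(expr) <- metadata$sample_id
    list(expr = expr, latent = latent, eigensignals = eigensignals,
         tp_eff = tp_eff, loadings = loadings)
  })

  coupling_matrices <- lapply(rho, function(r) {
    same_fam <- outer(fam_of, fam_of, "==")
    sgn <- FAMILY_SIGNS[fam_of]
    m <- ifelse(same_fam, r, (r / 2) * outer(sgn, sgn))
    diag(m) <- 1
    dimnames(m) <- list(module_ids, module_ids)
    m
  })

  truth <- structure(list(
    module_assignments = gene_module,
    family_assignments = fam_of,
    family_signs = FAMILY_SIGNS,
    coupling_matrix_by_group = coupling_matrices,
    group_coupling_multiplier = hd_multiplier,
    timepoint_effects = out$tp_eff,
    latent_factors = out$latent,
    eigensignals = out$eigensignals,
    gene_loadings = out$loadings,
    regulatory_truth = NULL,
    mixture_truth = NULL,
    seed = seed), class = "SyntheticTruth")

  list(study = expression_study(out$expr, metadata), truth = truth,
       btms = btm_collection(split(gene_ids, gene_module), fam_of))
}

#' Generate a pair of regulatory networks with planted differences
#'
#' Draws one TF-by-gene base weight matrix shared by both groups, then
#' shifts `n_dysregulated` edges (one per target gene when possible) by
#' `effect` in the HD-like network. Edge signs follow `sign`:
#' `"negative"` models weakened targeting in the HD-like group (difference
#' HD - HC is negative), `"positive"` strengthened targeting, `"both"`
#' a random mix.
#'
#' @param n_tfs,n_genes matrix dimensions.
#' @param n_dysregulated number of shifted edges
#'   (`<= n_tfs * n_genes`).
#' @param effect non-negative shift magnitude.
#' @param seed RNG seed.
#' @param sign `"both"`, `"positive"` or `"negative"`.
#' @return List with `hd`, `hc` ([regulatory_network()]s) and `truth`
#'   (`SyntheticTruth` whose `regulatory_truth` records the shifted edges,
#'   their signs and the target genes).
#' @export
generate_regulatory_pair <- function(n_tfs, n_genes, n_dysregulated,
                                     effect, seed = 1L,
                                     sign = c("both", "positive", "negative")) {
  sign <- match.arg(sign)
  if (effect < 0) stop("effect must be non-negative")
  if (n_dysregulated > n_tfs * n_genes) stop("n_dysregulated exceeds the edge count")
  tfs <- sprintf("TF%03d", seq_len(n_tfs))
  genes <- sprintf("TG%04d", seq_len(n_genes))
  out <- with_seed(child_seed(seed, "regulatory"), {
    base <- matrix(stats::rnorm(n_tfs * n_genes), n_tfs, n_genes,
                   dimnames = list(tfs, genes))
    if (n_dysregulated <= n_genes) {
      g_idx <- sample.int(n_genes, n_dysregulated)
      t_idx <- sample.int(n_tfs, n_dysregulated, replace = TRUE)
      cells <- cbind(t_idx, g_idx)
    } else {
      flat <- sample.int(n_tfs * n_genes, n_dysregulated)
      cells <- cbind((flat - 1L) %% n_tfs + 1L, (flat - 1L) %/% n_tfs + 1L)
    }
    signs <- switch(sign,
                    both = sample(c(-1, 1), n_dysregulated, replace = TRUE),
                    positive = rep(1, n_dysregulated),
                    negative = rep(-1, n_dysregulated))
    hd <- base
    hd[cells] <- hd[cells] + signs * effect
    list(base = base, hd = hd, cells = cells, signs = signs)
  })
  truth <- structure(list(
    regulatory_truth = data.frame(
      tf = tfs[out$cells[, 1]], gene = genes[out$cells[, 2]],
      sign = out$signs, effect = effect),
    seed = seed), class = "SyntheticTruth")
  list(hd = regulatory_network(out$hd), hc = regulatory_network(out$base),
       truth = truth)
}

#' Generate bulk mixtures of known cell-type proportions
#'
#' Draws sample proportions from a Dirichlet distribution and forms
#' `bulk = signature %*% proportions + noise`, truncated at zero so
#' expression stays non-negative.
#'
#' @param signature a [build_signature()] result or non-negative
#'   gene-by-type matrix.
#' @param n_samples number of bulk samples.
#' @param dirichlet_alpha positive vector, one entry per cell type.
#' @param noise_sd non-negative Gaussian noise sd.
#' @param seed RNG seed.
#' @param metadata optional metadata data.frame; by default samples
#'   alternate between HD and HC at a single timepoint.
#' @return List with `study` (an [expression_study()] whose expression is
#'   the mixed bulk) and `truth` (`SyntheticTruth` with `mixture_truth`,
#'   the sample-by-celltype proportion matrix).
#' @export
generate_mixtures <- function(signature, n_samples, dirichlet_alpha,
                              noise_sd = 0, seed = 1L, metadata = NULL) {
  S <- if (inherits(signature, "SignatureMatrix")) signature$values else signature
  if (any(S < 0)) stop("signature must be non-negative")
  if (length(dirichlet_alpha) != ncol(S)) {
    stop("dirichlet_alpha length must equal the number of cell types")
  }
  if (any(dirichlet_alpha <= 0)) stop("dirichlet_alpha must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  out <- with_seed(child_seed(seed, "mixtures"), {
    gm <- matrix(stats::rgamma(n_samples * ncol(S), shape = dirichlet_alpha,
                               rate = 1),
                 nrow = n_samples, byrow = TRUE)
    props <- gm / rowSums(gm)
    bulk <- S %*% t(props)
    if (noise_sd > 0) {
      bulk <- pmax(bulk + matrix(stats::rnorm(length(bulk), 0, noise_sd),
                                 nrow(bulk)), 0)
    }
    list(props = props, bulk = bulk)
  })
  dimnames(out$props) <- list(sample_ids, colnames(S))
  colnames(out$bulk) <- sample_ids
  if (is.null(metadata)) {
    metadata <- data.frame(sample_id = sample_ids, subject = sample_ids,
                           group = rep(c("HD", "HC"), length.out = n_samples),
                           timepoint = "V1D0", stringsAsFactors = FALSE)
  }
  truth <- structure(list(mixture_truth = out$props, seed = seed),
                     class = "SyntheticTruth")
  list(study = expression_study(out$bulk, metadata), truth = truth)
}

#' The 16 immune cell populations resolved by the deconvolution stage
#' @export
IMMUNE_CELL_TYPES <- c("CD4 T", "CD14+ monocytes", "Naive CD8 T", "CD8 T",
                       "CD16+ monocytes", "NK", "cDC2", "B", "pDC", "HPCs",
                       "Platelets", "NK T", "Plasmablasts", "Tregs",
                       "Naive B", "cDC1")

#' Generate a labeled single-cell-like reference for signature construction
#'
#' Each cell type gets a block of planted marker genes whose mean
#' expression is elevated by `marker_effect` over a shared baseline, plus
#' background genes expressed uniformly; cells add non-negative
#' (zero-truncated Gaussian) noise. Deliberately simple: enough structure
#' for [build_signature()] to find the planted markers and for mixtures of
#' the resulting signature to be identifiable.
#'
#' @param celltypes character vector of type labels (default the 16
#'   immune populations in `IMMUNE_CELL_TYPES`).
#' @param markers_per_type planted marker genes per type.
#' @param n_background shared background genes.
#' @param cells_per_type cells simulated per type.
#' @param baseline baseline mean expression.
#' @param marker_effect additive elevation of a marker in its own type.
#' @param noise_sd cell-level noise sd.
#' @param seed RNG seed.
#' @return List with `expr` (gene-by-cell matrix), `labels` (cell-type per
#'   column) and `marker_truth` (named list of planted markers per type).
#' @export
generate_reference <- function(celltypes = IMMUNE_CELL_TYPES,
                               markers_per_type = 20L, n_background = 100L,
                               cells_per_type = 30L, baseline = 1,
                               marker_effect = 4, noise_sd = 0.5, seed = 1L) {
  k <- length(celltypes)
  if (k < 2L) stop("need >= 2 cell types")
  marker_ids <- lapply(seq_len(k), function(i)
    sprintf("MK%02d_%03d", i, seq_len(markers_per_type)))
  names(marker_ids) <- celltypes
  genes <- c(unlist(marker_ids), sprintf("BG%04d", seq_len(n_background)))
  labels <- rep(celltypes, each = cells_per_type)
  mean_mat <- matrix(baseline, length(genes), k,
                     dimnames = list(genes, celltypes))
  for (i in seq_len(k)) mean_mat[marker_ids[[i]], i] <- baseline + marker_effect
  expr <- with_seed(child_seed(seed, "reference"), {
    e <- mean_mat[, rep(seq_len(k), each = cells_per_type), drop = FALSE] +
      matrix(stats::rnorm(length(genes) * k * cells_per_type, 0, noise_sd),
             length(genes))
    pmax(e, 0)
  })
  colnames(expr) <- sprintf("CELL%04d", seq_along(labels))
  list(expr = expr, labels = labels, marker_truth = marker_ids)
}

#' Write synthetic truth as JSON
#'
#' @param truth a `SyntheticTruth`.
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null", pretty = TRUE)
  invisible(path)
}
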