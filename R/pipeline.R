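default_config <- function() {
  list(
    paths = list(expression = NULL, metadata = NULL, gmt = NULL,
                 family_map = NULL, regulatory_hd = NULL, regulatory_hc = NULL,
                 reference_expr = NULL, reference_labels = NULL),
    thresholds = list(anova_q = 0.05, jaccard = 0.2, alpha = 0.05,
                      n_perm = 1000L),
    modes = list(zdiff_mode = "standardized", aggregation = "signed_extreme",
                 edge_mask = "coexpression_significant", eigengene_scope = "group"),
    seed = 1L)
}

#' Validate a pipeline configuration
#'
#' Reads a YAML or JSON configuration (or takes a list), fills defaults,
#' rejects unknown keys and enforces value ranges. Returns a typed
#' `RunConfig` or stops with an enumerated error list.
#'
#' @param config path to a YAML/JSON file, or a (possibly partial) list.
#' @return `RunConfig` list: `paths`, `thresholds`, `modes`, `seed`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
    if (is.null(config)) config <- list()
  }
  def <- default_config()
  errs <- character()
  bad_top <- setdiff(names(config), names(def))
  if (length(bad_top)) errs <- c(errs, paste("unknown keys:", paste(bad_top, collapse = ", ")))
  for (section in c("paths", "thresholds", "modes")) {
    bad <- setdiff(names(config[[section]]), names(def[[section]]))
    if (length(bad)) {
      errs <- c(errs, paste0("unknown ", section, " keys: ", paste(bad, collapse = ", ")))
    }
    for (k in intersect(names(config[[section]]), names(def[[section]]))) {
      def[[section]][[k]] <- config[[section]][[k]]
    }
  }
  if (!is.null(config$seed)) def$seed <- config$seed
  th <- def$thresholds
  if (!is.numeric(th$alpha) || th$alpha <= 0 || th$alpha > 1) {
    errs <- c(errs, "alpha must be in (0, 1]")
  }
  if (!is.numeric(th$anova_q) || th$anova_q <= 0 || th$anova_q > 1) {
    errs <- c(errs, "anova_q must be in (0, 1]")
  }
  if (!is.numeric(th$jaccard) || th$jaccard < 0 || th$jaccard > 1) {
    errs <- c(errs, "jaccard must be in [0, 1]")
  }
  if (!is.numeric(th$n_perm) || th$n_perm < 1) errs <- c(errs, "n_perm must be >= 1")
  if (!def$modes$zdiff_mode %in% c("standardized", "literal")) {
    errs <- c(errs, "zdiff_mode must be 'standardized' or 'literal'")
  }
  if (!def$modes$aggregation %in% c("signed_extreme", "sum")) {
    errs <- c(errs, "aggregation must be 'signed_extreme' or 'sum'")
  }
  if (!def$modes$edge_mask %in% c("coexpression_significant", "group_significant", "all")) {
    errs <- c(errs, "edge_mask must be 'coexpression_significant', 'group_significant' or 'all'")
  }
  if (!def$modes$eigengene_scope %in% c("group", "pooled")) {
    errs <- c(errs, "eigengene_scope must be 'group' or 'pooled'")
  }
  if (!is.numeric(def$seed) || is.na(def$seed)) errs <- c(errs, "seed must be an integer")
  for (k in c("expression", "metadata", "gmt")) {
    p <- def$paths[[k]]
    if (!is.null(p) && !file.exists(p)) {
      errs <- c(errs, paste0("paths$", k, " does not exist: ", p))
    }
  }
  if (length(errs)) stop("invalid configuration:\n  - ",
                         paste(errs, collapse = "\n  - "), call. = FALSE)
  structure(def, class = "RunConfig")
}

#' Run the full differential co-expression pipeline
#'
#' Executes the stages in dependency order: per-group eigengene
#' extraction, timepoint-ANOVA node selection with Jaccard redundancy
#' filtering, group and single-subject networks, the Fisher-Z difference
#' network with family summaries, per-subject median-edge comparisons,
#' then — when the respective inputs are configured — the
#' regulatory-difference ranking with preranked enrichment, and signature
#' deconvolution with rank-sum comparisons. All stage outputs are written
#' as TSV/JSON under `out_dir`, along with a `manifest.json` recording the
#' configuration, its hash, the seed and the package version. With
#' `demo = TRUE` (or no expression path), a synthetic cohort is generated
#' with the configured seed so the pipeline runs end to end
#' self-contained.
#'
#' @param config a `RunConfig` from [validate_config()] (or a list/path,
#'   validated on the fly).
#' @param out_dir output directory, created if absent.
#' @param demo generate a synthetic cohort instead of reading inputs.
#' @return Invisibly, a list with the main in-memory results (`selection`,
#'   `networks`, `difference`, `family_summaries`, `medians`,
#'   `median_tests`, optionally `enrichment`, `proportions`,
#'   `proportion_tests`, and `manifest`).
#' @export
run_pipeline <- function(config = list(), out_dir, demo = FALSE) {
  cfg <- if (inherits(config, "RunConfig")) config else validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  reg_truth <- NULL
  if (demo || is.null(cfg$paths$expression)) {
    sim <- stage("simulate", generate_cohort(seed = cfg$seed))
    study <- sim$study
    btms <- sim$btms
    write_expression_study(study, file.path(out_dir, "expression.tsv"),
                           file.path(out_dir, "metadata.tsv"))
    write_gmt(btms, file.path(out_dir, "modules.gmt"))
    write_family_map(btms, file.path(out_dir, "families.tsv"))
  } else {
    study <- stage("load", read_expression_study(cfg$paths$expression, cfg$paths$metadata))
    fam <- if (!is.null(cfg$paths$family_map)) read_family_map(cfg$paths$family_map)
    btms <- stage("load", read_gmt(cfg$paths$gmt, fam))
  }

  groups <- sort(unique(study$metadata$group))
  if (length(groups) != 2L) stop("pipeline expects exactly two groups, got: ",
                                 paste(groups, collapse = ", "))
  g_hd <- if ("HD" %in% groups) "HD" else groups[1]
  g_hc <- setdiff(groups, g_hd)[1]

  eig <- stage("eigengenes",
               eigengenes_by_group(study, btms, scope = cfg$modes$eigengene_scope))
  if (cfg$modes$eigengene_scope == "pooled") eig <- list(HD = eig$pooled, HC = eig$pooled)[c(1, 2)] |>
    stats::setNames(c(g_hd, g_hc))
  combined <- combine_group_eigengenes(eig, study$metadata)
  write_tsv_matrix(combined, file.path(out_dir, "eigengenes.tsv"), "module")

  sel <- stage("select", select_modules(combined, study$metadata, btms,
                                        q_threshold = cfg$thresholds$anova_q,
                                        jaccard_threshold = cfg$thresholds$jaccard))
  utils::write.table(sel$candidates, file.path(out_dir, "selection.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  nodes <- if (length(sel$retained) >= 3L) sel$retained else rownames(combined)

  nets <- stage("networks", lapply(
    stats::setNames(c(g_hd, g_hc), c(g_hd, g_hc)),
    function(g) {
      v <- eig[[g]]$values[nodes, , drop = FALSE]
      group_network(v, study$metadata, g)
    }))
  for (g in names(nets)) {
    write_network(nets[[g]], file.path(out_dir, paste0("network_", g, ".tsv")),
                  file.path(out_dir, paste0("edges_", g, ".tsv")))
  }

  diffnet <- stage("compare", z_difference_network(
    nets[[g_hd]], nets[[g_hc]], alpha = cfg$thresholds$alpha,
    mode = cfg$modes$zdiff_mode))
  write_difference_network(diffnet, file.path(out_dir, "difference_network.tsv"))
  fams <- btms$families
  summaries <- lapply(stats::setNames(c("intra", "inter", "pairwise"),
                                      c("intra", "inter", "pairwise")),
                      function(lv) family_edge_summary(diffnet, fams, lv))
  for (lv in names(summaries)) {
    utils::write.table(summaries[[lv]], file.path(out_dir, paste0("family_", lv, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  across <- across_group_network(eig, study$metadata, modules = nodes)
  concord <- edge_concordance(nets[[g_hd]], nets[[g_hc]],
                              significant_edges(across, cfg$thresholds$alpha))
  jsonlite::write_json(concord, file.path(out_dir, "edge_concordance.json"),
                       auto_unbox = TRUE, digits = NA)
  mask <- switch(cfg$modes$edge_mask,
    coexpression_significant = list(
      positive = significant_edges(across, cfg$thresholds$alpha, "positive"),
      negative = significant_edges(across, cfg$thresholds$alpha, "negative")),
    group_significant = {
      sig <- diffnet[diffnet$class != "unchanged", c("module_a", "module_b")]
      if (nrow(sig)) sig else NULL
    },
    all = NULL)
  medians <- stage("medians", subject_median_table(eig, study$metadata,
                                                   modules = nodes, edge_mask = mask))
  utils::write.table(medians, file.path(out_dir, "subject_medians.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  med_tests <- list(
    positive = compare_median_edges(medians$median_pos[medians$group == g_hd],
                                    medians$median_pos[medians$group == g_hc]),
    negative = compare_median_edges(medians$median_neg[medians$group == g_hd],
                                    medians$median_neg[medians$group == g_hc]))
  jsonlite::write_json(med_tests, file.path(out_dir, "median_edge_tests.json"),
                       auto_unbox = TRUE, digits = NA)

  enrichment <- NULL
  if (!is.null(cfg$paths$regulatory_hd) && !is.null(cfg$paths$regulatory_hc)) {
    reg_hd <- stage("regdiff", read_regulatory_network(cfg$paths$regulatory_hd))
    reg_hc <- stage("regdiff", read_regulatory_network(cfg$paths$regulatory_hc))
    rd <- regulatory_difference(reg_hd, reg_hc)
    ranked <- rank_gene_targets(rd, aggregation = cfg$modes$aggregation)
    utils::write.table(ranked, file.path(out_dir, "ranked_targets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    enrichment <- stage("regdiff", preranked_gsea(
      ranked, btms, n_perm = cfg$thresholds$n_perm,
      seed = child_seed(cfg$seed, "gsea")))
    utils::write.table(as.data.frame(enrichment), file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  proportions <- NULL
  prop_tests <- NULL
  if (!is.null(cfg$paths$reference_expr)) {
    ref <- stage("deconvolve", read_tsv_matrix(cfg$paths$reference_expr))
    labels <- utils::read.delim(cfg$paths$reference_labels, stringsAsFactors = FALSE)
    sig <- stage("deconvolve", build_signature(ref, labels[[2]]))
    proportions <- stage("deconvolve", estimate_proportions(study$expr, sig))
    write_tsv_matrix(proportions, file.path(out_dir, "proportions.tsv"), "sample_id")
    prop_tests <- compare_proportions(proportions, study$metadata,
                                      groups = c(g_hd, g_hc))
    utils::write.table(prop_tests, file.path(out_dir, "proportion_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  manifest <- list(
    package = "btmdcnet",
    version = as.character(utils::packageVersion("btmdcnet")),
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    groups = list(hd = g_hd, hc = g_hc),
    n_modules_retained = length(nodes),
    stages = c("eigengenes", "select", "networks", "compare", "medians",
               if (!is.null(enrichment)) "regdiff",
               if (!is.null(proportions)) "deconvolve"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(selection = sel, networks = nets, difference = diffnet,
                 family_summaries = summaries, medians = medians,
                 median_tests = med_tests, enrichment = enrichment,
                 proportions = proportions, proportion_tests = prop_tests,
                 manifest = manifest))
}
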