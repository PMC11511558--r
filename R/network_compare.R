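#' Fisher Z transformation
#'
#' `z = arctanh(r)`, the variance-stabilizing transform of a Pearson
#' correlation. Correlations of exactly +/-1 are clamped to
#' `+/-(1 - 1e-7)` with a warning so the transform stays finite.
#'
#' @param r numeric vector of correlations, `|r| <= 1`.
#' @return Fisher Z values.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| > 1 is not a correlation")
  clamp <- !is.na(r) & abs(r) >= 1
  if (any(clamp)) {
    warning(sprintf("%d correlation(s) of +/-1 clamped before Fisher Z", sum(clamp)))
    r[clamp] <- sign(r[clamp]) * (1 - 1e-7)
  }
  atanh(r)
}

#' Six-class taxonomy of a differential edge
#'
#' Classifies each edge of an HD-vs-HC comparison by the signs and relative
#' magnitudes of its two correlations: positively co-expressed in both but
#' weaker/stronger in HD; negatively co-expressed in both but
#' weaker/stronger in HD; or discordant, positive/negative in HD. Edges
#' that are not significantly different are `unchanged`. An exact zero in
#' one group is assigned to the discordant branch implied by the sign of
#' the nonzero member; a zero in both groups stays `unchanged`.
#'
#' @param r_hd,r_hc numeric vectors of correlations (recycled).
#' @param significant logical vector.
#' @return Character vector of labels in
#'   `pos_weaker_hd, pos_stronger_hd, neg_weaker_hd, neg_stronger_hd,
#'    discordant_pos_hd, discordant_neg_hd, unchanged`.
#' @export
classify_edge <- function(r_hd, r_hc, significant) {
  n <- max(length(r_hd), length(r_hc), length(significant))
  r_hd <- rep_len(r_hd, n); r_hc <- rep_len(r_hc, n)
  significant <- rep_len(significant, n)
  out <- character(n)
  for (i in seq_len(n)) {
    a <- r_hd[i]; b <- r_hc[i]
    out[i] <- if (!isTRUE(significant[i]) || is.na(a) || is.na(b)) {
      "unchanged"
    } else if (a > 0 && b > 0) {
      if (abs(a) < abs(b)) "pos_weaker_hd" else "pos_stronger_hd"
    } else if (a < 0 && b < 0) {
      if (abs(a) < abs(b)) "neg_weaker_hd" else "neg_stronger_hd"
    } else if (a > 0) {
      "discordant_pos_hd"
    } else if (a < 0) {
      "discordant_neg_hd"
    } else if (b > 0) {
      # r_hd exactly 0: discordant branch by the sign of the nonzero member
      "discordant_neg_hd"
    } else if (b < 0) {
      "discordant_pos_hd"
    } else {
      "unchanged"
    }
  }
  out
}

#' Fisher-Z difference network between two group networks
#'
#' Applies the Fisher Z transformation to each network's edges and
#' subtracts the control (HC) network from the HD network. In the default
#' `standardized` mode the difference is divided by its standard error
#' `sqrt(1/(n_hd - 3) + 1/(n_hc - 3))` (the classical two-correlation
#' z-test); in `literal` mode the raw difference `z_hd - z_hc` is treated
#' directly as a standard normal deviate. Two-sided normal p-values are
#' FDR-adjusted (Benjamini-Hochberg) across all finite edges and each edge
#' gets a six-class label ([classify_edge()]); edges with `q >= alpha` are
#' `unchanged`, and the TSV export writes 0 for their difference.
#'
#' @param net_hd,net_hc `CoexpressionNetwork`s on the same module set.
#' @param alpha edge significance level on the FDR q (default 0.05).
#' @param mode `"standardized"` or `"literal"`.
#' @return `DifferenceNetwork`: a data.frame with one row per unordered
#'   module pair (`module_a < module_b`) and columns `r_hd, r_hc, z_hd,
#'   z_hc, z_diff, p, q, class, n_hd, n_hc`; attributes `alpha`, `mode`.
#' @export
z_difference_network <- function(net_hd, net_hc, alpha = 0.05,
                                 mode = c("standardized", "literal")) {
  mode <- match.arg(mode)
  if (!setequal(net_hd$module_order, net_hc$module_order)) {
    stop("module sets differ between the two networks")
  }
  ord <- net_hd$module_order
  r_hd <- net_hd$r[ord, ord]
  r_hc <- net_hc$r[ord, ord]
  n_hd <- net_hd$n_samples; n_hc <- net_hc$n_samples
  if (n_hd < 4L || n_hc < 4L) stop("need n >= 4 samples per network")
  idx <- which(upper.tri(r_hd), arr.ind = TRUE)
  edges <- data.frame(module_a = ord[idx[, 1]], module_b = ord[idx[, 2]],
                      r_hd = r_hd[idx], r_hc = r_hc[idx])
  edges$z_hd <- suppressWarnings(fisher_z(edges$r_hd))
  edges$z_hc <- suppressWarnings(fisher_z(edges$r_hc))
  se <- if (mode == "standardized") sqrt(1 / (n_hd - 3) + 1 / (n_hc - 3)) else 1
  edges$z_diff <- (edges$z_hd - edges$z_hc) / se
  edges$p <- 2 * stats::pnorm(-abs(edges$z_diff))
  ok <- is.finite(edges$p)
  edges$q <- NA_real_
  edges$q[ok] <- fdr_adjust(edges$p[ok])
  edges$class <- classify_edge(edges$r_hd, edges$r_hc,
                               !is.na(edges$q) & edges$q < alpha)
  edges$n_hd <- n_hd
  edges$n_hc <- n_hc
  structure(edges, alpha = alpha, mode = mode, class = c("DifferenceNetwork", "data.frame"))
}

#' Write a difference network as long-form TSV
#'
#' Non-significant (`unchanged`) edges are exported with a difference of 0,
#' matching the convention that only significant differences carry signal.
#'
#' @param diff a `DifferenceNetwork`.
#' @param path output TSV.
#' @return Invisibly, `path`.
#' @export
write_difference_network <- function(diff, path) {
  out <- as.data.frame(diff)
  out$z_diff_export <- ifelse(out$class == "unchanged", 0, out$z_diff)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Family-level summary of differential edges
#'
#' Counts differential edges by class within a family (`intra`), between a
#' family and all other modules (`inter`), or pairwise between families
#' (`pairwise`), and divides by the number of possible edges: `n*(n-1)/2`
#' within a family of `n` nodes, `n_f*(N - n_f)` for a family against the
#' rest of an `N`-node network, and `n_f*n_g` for a family pair.
#'
#' @param diff a `DifferenceNetwork`.
#' @param families named character vector (module -> family); modules
#'   without a label count as `"other"`.
#' @param level `"intra"`, `"inter"` or `"pairwise"`.
#' @return `FamilySummary` data.frame, long form: family (or
#'   family_a/family_b), class, count, denominator, percentage (NA when the
#'   denominator is 0).
#' @export
family_edge_summary <- function(diff, families, level = c("intra", "inter", "pairwise")) {
  level <- match.arg(level)
  mods <- unique(c(diff$module_a, diff$module_b))
  fam <- stats::setNames(rep("other", length(mods)), mods)
  known <- intersect(names(families), mods)
  fam[known] <- families[known]
  classes <- c("pos_weaker_hd", "pos_stronger_hd", "neg_weaker_hd",
               "neg_stronger_hd", "discordant_pos_hd", "discordant_neg_hd")
  fa <- fam[diff$module_a]
  fb <- fam[diff$module_b]
  fam_levels <- sort(unique(fam))
  sizes <- table(factor(fam, levels = fam_levels))
  N <- length(mods)
  count_classes <- function(sel) {
    vapply(classes, function(cl) sum(sel & diff$class == cl, na.rm = TRUE), numeric(1))
  }
  rows <- list()
  if (level == "intra") {
    for (f in fam_levels) {
      n_f <- sizes[[f]]
      denom <- n_f * (n_f - 1) / 2
      cnt <- count_classes(fa == f & fb == f)
      rows[[f]] <- data.frame(family = f, class = classes, count = cnt,
                              denominator = denom,
                              percentage = if (denom > 0) 100 * cnt / denom else NA_real_)
    }
  } else if (level == "inter") {
    for (f in fam_levels) {
      n_f <- sizes[[f]]
      denom <- n_f * (N - n_f)
      cnt <- count_classes(xor(fa == f, fb == f))
      rows[[f]] <- data.frame(family = f, class = classes, count = cnt,
                              denominator = denom,
                              percentage = if (denom > 0) 100 * cnt / denom else NA_real_)
    }
  } else {
    for (i in seq_along(fam_levels)) {
      for (j in seq_len(i - 1L)) {
        f <- fam_levels[j]; g <- fam_levels[i]
        denom <- sizes[[f]] * sizes[[g]]
        cnt <- count_classes((fa == f & fb == g) | (fa == g & fb == f))
        rows[[paste(f, g, sep = "|")]] <-
          data.frame(family_a = f, family_b = g, class = classes, count = cnt,
                     denominator = denom,
                     percentage = if (denom > 0) 100 * cnt / denom else NA_real_)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, level = level, class = c("FamilySummary", "data.frame"))
}

#' Across-group co-expression network
#'
#' Pearson network over all samples of both groups pooled, each sample
#' contributing its own group's eigengene extraction. Used to define which
#' edges are significantly co-expressed at all (independent of the group
#' difference), and to summarize how concordant the two groups' signs are
#' on those edges.
#'
#' @param eig_list per-group `EigengeneMatrix` list
#'   ([eigengenes_by_group()]).
#' @param metadata study metadata.
#' @param modules optional module subset.
#' @return A `CoexpressionNetwork` with `scope = "across-group"`.
#' @export
across_group_network <- function(eig_list, metadata, modules = NULL) {
  values <- combine_group_eigengenes(eig_list, metadata)
  if (!is.null(modules)) values <- values[modules, , drop = FALSE]
  pearson_network(values, scope = "across-group")
}

#' Significantly co-expressed edges of a network
#'
#' Tests each edge's correlation against zero with the exact t reference
#' (`t = r * sqrt((n-2)/(1-r^2))`, `df = n - 2`), BH-adjusts across edges,
#' and returns those with `q < alpha`, optionally restricted by sign.
#'
#' @param net a `CoexpressionNetwork`.
#' @param alpha FDR threshold (default 0.05).
#' @param sign `"any"`, `"positive"` or `"negative"`.
#' @return data.frame `module_a`, `module_b`, `r`, `p`, `q`.
#' @export
significant_edges <- function(net, alpha = 0.05, sign = c("any", "positive", "negative")) {
  sign <- match.arg(sign)
  edges <- as_edge_list(net)
  n <- net$n_samples
  if (n < 4L) stop("need n >= 4 samples for edge significance")
  r <- pmin(pmax(edges$r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  edges$p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  ok <- is.finite(edges$p)
  edges$q <- NA_real_
  edges$q[ok] <- fdr_adjust(edges$p[ok])
  keep <- !is.na(edges$q) & edges$q < alpha
  keep <- keep & switch(sign, any = TRUE, positive = edges$r > 0,
                        negative = edges$r < 0)
  out <- edges[keep, c("module_a", "module_b", "r", "p", "q"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Concordance of edge directions between two group networks
#'
#' Restricted to a set of (typically significantly co-expressed) edges,
#' counts how many have the same correlation sign in both groups, split
#' into concordant-positive and concordant-negative.
#'
#' @param net_hd,net_hc `CoexpressionNetwork`s on the same modules.
#' @param edges data.frame with `module_a`, `module_b` (e.g. from
#'   [significant_edges()]).
#' @return List: `n_edges`, `n_concordant`, `pct_concordant`,
#'   `n_both_positive`, `n_both_negative`.
#' @export
edge_concordance <- function(net_hd, net_hc, edges) {
  r_hd <- net_hd$r[cbind(edges$module_a, edges$module_b)]
  r_hc <- net_hc$r[cbind(edges$module_a, edges$module_b)]
  both_pos <- r_hd > 0 & r_hc > 0
  both_neg <- r_hd < 0 & r_hc < 0
  n <- nrow(edges)
  list(n_edges = n, n_concordant = sum(both_pos | both_neg),
       pct_concordant = if (n) 100 * sum(both_pos | both_neg) / n else NA_real_,
       n_both_positive = sum(both_pos), n_both_negative = sum(both_neg))
}

#' Median Fisher-Z edge weight of a network
#'
#' Fisher-Z-transforms the network's (upper-triangle) edges, optionally
#' restricts them to a mask of module pairs, keeps those of the requested
#' sign, and returns their median. Used per subject to summarize
#' single-subject networks; an empty subset yields NA.
#'
#' @param net a `CoexpressionNetwork`.
#' @param sign `"positive"` or `"negative"` (sign of the edge's Z value).
#' @param edge_mask optional data.frame with columns `module_a`, `module_b`
#'   naming the unordered pairs to keep (e.g. edges significant in the
#'   group-level difference analysis).
#' @return Median Fisher Z, or NA if no edge qualifies.
#' @export
median_edge_weight <- function(net, sign = c("positive", "negative"),
                               edge_mask = NULL) {
  sign <- match.arg(sign)
  edges <- as_edge_list(net)
  if (!is.null(edge_mask)) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
    edges <- edges[key(edges$module_a, edges$module_b) %in%
                     key(edge_mask$module_a, edge_mask$module_b), , drop = FALSE]
  }
  z <- suppressWarnings(fisher_z(edges$r))
  z <- z[is.finite(z)]
  z <- if (sign == "positive") z[z > 0] else z[z < 0]
  if (!length(z)) return(NA_real_)
  stats::median(z)
}

#' Compare per-subject median edge weights between groups
#'
#' Two-sample pooled-variance Student's t-test (two-sided) of median edge
#' weights, HD values first so a negative t means weaker in HD.
#'
#' @param hd_values,hc_values numeric vectors (NA dropped; >= 2 each).
#' @return List with `t`, `df`, `p`, and group means.
#' @export
compare_median_edges <- function(hd_values, hc_values) {
  x <- hd_values[!is.na(hd_values)]
  y <- hc_values[!is.na(hc_values)]
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 non-NA values per group")
  if (stats::sd(c(x, y)) == 0) {
    return(list(t = 0, df = length(x) + length(y) - 2, p = 1,
                mean_hd = mean(x), mean_hc = mean(y)))
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       mean_hd = mean(x), mean_hc = mean(y))
}

#' Per-subject median edge weight table
#'
#' Builds each subject's network, computes its median positive and negative
#' Fisher-Z edge weights (optionally restricted to a mask), and returns a
#' tidy table ready for [compare_median_edges()].
#'
#' @param eig_list per-group `EigengeneMatrix` list
#'   ([eigengenes_by_group()]).
#' @param metadata study metadata.
#' @param modules optional module subset (e.g. the selected network nodes).
#' @param edge_mask optional pair mask, see [median_edge_weight()]; either
#'   one data.frame applied to both signs, or a list with elements
#'   `positive` and `negative` (e.g. the significantly positively and
#'   negatively co-expressed edges from [significant_edges()]).
#' @return data.frame: subject, group, median_pos, median_neg.
#' @export
subject_median_table <- function(eig_list, metadata, modules = NULL,
                                 edge_mask = NULL) {
  if (!is.null(edge_mask) && is.data.frame(edge_mask)) {
    edge_mask <- list(positive = edge_mask, negative = edge_mask)
  }
  subjects <- unique(metadata[, c("subject", "group")])
  rows <- lapply(seq_len(nrow(subjects)), function(i) {
    g <- subjects$group[i]
    values <- eig_list[[g]]$values
    if (!is.null(modules)) values <- values[modules, , drop = FALSE]
    net <- subject_network(values, metadata, subjects$subject[i])
    data.frame(subject = subjects$subject[i], group = g,
               median_pos = median_edge_weight(net, "positive", edge_mask$positive),
               median_neg = median_edge_weight(net, "negative", edge_mask$negative))
  })
  do.call(rbind, rows)
}
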