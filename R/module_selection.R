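#' Timepoint ANOVA for one eigengene
#'
#' Tests the main effect of timepoint on a module eigengene in a repeated
#' measures design: fixed effects of group and timepoint with a per-subject
#' random intercept. For the balanced complete design (every subject
#' measured at every timepoint) this p-value is computed from the
#' numerically equivalent subject-blocked two-way ANOVA, i.e. the F-test
#' for timepoint in `lm(eigengene ~ subject + timepoint)`; the
#' between-subject group effect is absorbed by the subject blocks.
#'
#' @param eigengene numeric vector, one value per sample.
#' @param metadata data.frame with `sample_id`, `subject`, `group`,
#'   `timepoint` aligned to `eigengene` (by names if present, else by
#'   position).
#' @return List with `p` (timepoint main-effect p-value), `f` (F statistic),
#'   `df` (numerator/denominator degrees of freedom) and `flagged`
#'   (TRUE when the response is degenerate, in which case `p = 1`).
#' @export
timepoint_anova <- function(eigengene, metadata) {
  if (!is.null(names(eigengene)) && all(metadata$sample_id %in% names(eigengene))) {
    eigengene <- eigengene[metadata$sample_id]
  }
  if (length(eigengene) != nrow(metadata)) {
    stop("eigengene length does not match metadata rows")
  }
  tab <- table(metadata$subject)
  if (any(tab < 2L)) stop("every subject needs >= 2 timepoints")
  if (stats::sd(eigengene) == 0) {
    return(list(p = 1, f = 0, df = c(NA_real_, NA_real_), flagged = TRUE))
  }
  d <- data.frame(y = as.numeric(eigengene),
                  subject = factor(metadata$subject),
                  timepoint = factor(metadata$timepoint))
  fit <- stats::lm(y ~ subject + timepoint, data = d)
  an <- stats::anova(fit)
  i <- which(rownames(an) == "timepoint")
  list(p = an[i, "Pr(>F)"], f = an[i, "F value"],
       df = c(an[i, "Df"], an["Residuals", "Df"]), flagged = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH q-values; thin validated wrapper over [stats::p.adjust()].
#'
#' @param p_values numeric vector of p-values in `[0, 1]`; NA/NaN rejected.
#' @return q-values in `[0, 1]`, same order as input.
#' @export
fdr_adjust <- function(p_values) {
  if (any(is.na(p_values))) stop("NA/NaN p-values not allowed")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Jaccard index of two gene sets
#'
#' @param a,b non-empty character vectors.
#' @return `|a n b| / |a u b|` in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) || !length(b)) stop("empty gene set")
  length(intersect(a, b)) / length(union(a, b))
}

#' Remove redundant modules by pairwise Jaccard overlap
#'
#' Candidate modules overlapping with Jaccard index above `threshold` are
#' deduplicated: for each offending pair only the module with the larger
#' number of member genes is retained. Pairs are processed greedily in
#' descending Jaccard order (ties broken by module id, lexicographically);
#' a pair is skipped if either member was already dropped; equal-sized pairs
#' drop the lexicographically later id. The procedure is idempotent.
#'
#' @param btms a [btm_collection()].
#' @param candidates character vector of candidate module ids (default all).
#' @param threshold Jaccard cutoff (default 0.2; overlaps strictly above it
#'   trigger removal).
#' @return List with `retained` (character vector, input order) and
#'   `removed_pairs` (data.frame kept / dropped / jaccard).
#' @export
filter_overlapping <- function(btms, candidates = NULL, threshold = 0.2) {
  candidates <- candidates %||% names(btms$modules)
  if (!length(candidates)) stop("no candidate modules")
  missing <- setdiff(candidates, names(btms$modules))
  if (length(missing)) stop("unknown modules: ", paste(missing, collapse = ", "))
  pairs <- if (length(candidates) >= 2L) t(utils::combn(candidates, 2L)) else
    matrix(character(), ncol = 2)
  if (nrow(pairs)) {
    jc <- apply(pairs, 1, function(p) jaccard(btms$modules[[p[1]]], btms$modules[[p[2]]]))
    over <- which(jc > threshold)
    ord <- over[order(-jc[over], pairs[over, 1], pairs[over, 2])]
  } else {
    ord <- integer()
    jc <- numeric()
  }
  dropped <- character()
  removed <- data.frame(kept = character(), dropped = character(), jaccard = numeric())
  for (i in ord) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    if (a %in% dropped || b %in% dropped) next
    na <- length(btms$modules[[a]]); nb <- length(btms$modules[[b]])
    loser <- if (na > nb) b else if (nb > na) a else max(a, b)
    winner <- if (loser == a) b else a
    dropped <- c(dropped, loser)
    removed <- rbind(removed, data.frame(kept = winner, dropped = loser, jaccard = jc[i]))
  }
  list(retained = setdiff(candidates, dropped), removed_pairs = removed)
}

#' Select BTM network nodes
#'
#' Runs the timepoint ANOVA per module eigengene, FDR-corrects across
#' modules, keeps modules with `q < q_threshold` as candidates, and removes
#' redundant candidates with [filter_overlapping()].
#'
#' @param eig module-by-sample eigengene matrix (see
#'   [combine_group_eigengenes()]).
#' @param metadata study metadata.
#' @param btms a [btm_collection()].
#' @param q_threshold FDR cutoff on the timepoint effect (default 0.05).
#' @param jaccard_threshold overlap cutoff (default 0.2).
#' @return `SelectionResult`: list with `candidates` (data.frame module, p,
#'   q, flagged, candidate), `retained`, `removed_pairs`.
#' @export
select_modules <- function(eig, metadata, btms, q_threshold = 0.05,
                           jaccard_threshold = 0.2) {
  res <- lapply(rownames(eig), function(m) timepoint_anova(eig[m, ], metadata))
  p <- vapply(res, `[[`, numeric(1), "p")
  q <- fdr_adjust(p)
  cand <- data.frame(module = rownames(eig), p = p, q = q,
                     flagged = vapply(res, `[[`, logical(1), "flagged"),
                     candidate = q < q_threshold)
  keep <- cand$module[cand$candidate]
  if (!length(keep)) {
    return(structure(list(candidates = cand, retained = character(),
                          removed_pairs = data.frame()), class = "SelectionResult"))
  }
  filt <- filter_overlapping(btms, keep, jaccard_threshold)
  structure(list(candidates = cand, retained = filt$retained,
                 removed_pairs = filt$removed_pairs), class = "SelectionResult")
}

#' @export
print.SelectionResult <- function(x, ...) {
  cat("SelectionResult:", sum(x$candidates$candidate), "of",
      nrow(x$candidates), "modules pass the timepoint-effect FDR;",
      length(x$retained), "retained after overlap filtering\n")
  invisible(x)
}
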