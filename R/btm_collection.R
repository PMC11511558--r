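#' Construct a BTMCollection
#'
#' Blood transcription modules (BTMs) are curated sets of co-expressed blood
#' genes used both as gene sets and as network nodes. A `BTMCollection`
#' stores module membership plus a module-to-family taxonomy (B cells,
#' cell cycle, DC/APC, IFN type I, Myeloid/Inflamm, T/NK cells, other).
#'
#' @param modules named list of character vectors (gene symbols); names are
#'   module ids.
#' @param families named character vector mapping module id to family label;
#'   modules absent from the map get family `"other"`.
#' @return An object of class `BTMCollection`.
#' @export
btm_collection <- function(modules, families = NULL) {
  if (!length(modules)) stop("empty module collection")
  if (is.null(names(modules)) || any(names(modules) == "") ||
      anyDuplicated(names(modules))) {
    stop("modules must have unique non-empty names")
  }
  modules <- lapply(modules, function(g) {
    g <- unique(toupper(as.character(g)))
    if (!length(g)) stop("empty module not allowed")
    g
  })
  fam <- rep("other", length(modules))
  names(fam) <- names(modules)
  if (!is.null(families)) {
    known <- intersect(names(families), names(modules))
    fam[known] <- as.character(families[known])
  }
  structure(list(modules = modules, families = fam), class = "BTMCollection")
}

#' @export
print.BTMCollection <- function(x, ...) {
  sizes <- lengths(x$modules)
  cat("BTMCollection:", length(x$modules), "modules,",
      "gene-set sizes", min(sizes), "-", max(sizes), "\n")
  cat("  families:", paste(sprintf("%s (%d)", names(table(x$families)),
                                   as.integer(table(x$families))), collapse = ", "), "\n")
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Each GMT line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Gene
#' symbols are uppercased and deduplicated within a set.
#'
#' @param path GMT file.
#' @param families optional named character vector (module -> family) merged
#'   into the collection.
#' @return A [btm_collection()].
#' @export
read_gmt <- function(path, families = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  modules <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields", i))
    }
    genes <- unique(toupper(fields[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop(sprintf("GMT line %d: set '%s' has no genes", i, fields[1]))
    ids[i] <- fields[1]
    modules[[i]] <- genes
  }
  names(modules) <- ids
  btm_collection(modules, families)
}

#' Write gene sets to a GMT file
#'
#' @param btms a `BTMCollection`.
#' @param path output path.
#' @param descriptions optional named character vector of set descriptions
#'   (defaults to the family label).
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(btms, path, descriptions = NULL) {
  lines <- vapply(names(btms$modules), function(id) {
    desc <- if (!is.null(descriptions) && id %in% names(descriptions)) {
      descriptions[[id]]
    } else {
      btms$families[[id]]
    }
    paste(c(id, desc, btms$modules[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a module-to-family map
#'
#' @param path TSV with columns `module_id` and `family`.
#' @return Named character vector (module id -> family label).
#' @export
read_family_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("module_id", "family") %in% colnames(df))) {
    stop("family map must have columns module_id and family")
  }
  stats::setNames(as.character(df$family), as.character(df$module_id))
}

#' Write a module-to-family map
#'
#' @param btms a `BTMCollection`.
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_family_map <- function(btms, path) {
  utils::write.table(
    data.frame(module_id = names(btms$families), family = unname(btms$families)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
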