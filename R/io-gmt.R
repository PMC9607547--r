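#' Gene set collection
#'
#' A named list of gene-symbol vectors with one description per set, as
#' carried by GMT files (e.g. MSigDB C2). Empty sets and duplicate set
#' names are rejected; duplicate members within a set are deduplicated.
#'
#' @param sets Named list of character vectors.
#' @param description Character vector of per-set descriptions (recycled
#'   from `""` when absent).
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  if (anyDuplicated(names(sets)))
    stop("duplicate set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  dup <- vapply(sets, anyDuplicated, integer(1)) > 0
  if (any(dup)) {
    warning("duplicate members deduplicated in set(s): ",
            paste(names(sets)[dup], collapse = ", "))
    sets <- lapply(sets, unique)
  }
  if (any(lengths(sets) == 0)) stop("empty gene set not allowed")
  if (is.null(description)) description <- rep("", length(sets))
  description <- setNames(rep_len(as.character(description), length(sets)),
                          names(sets))
  structure(list(sets = sets, description = description),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "sets, sizes",
      min(lengths(x$sets)), "-", max(lengths(x$sets)), "\n")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read a GMT gene-set file
#'
#' Tab-separated, one set per line: name, description, members...
#' Lines with fewer than three fields are a parse error naming the line.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop("malformed GMT line ", short[1], ": fewer than 3 tab-separated fields")
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  desc <- vapply(fields, `[[`, character(1), 2)
  gene_set_collection(sets, desc)
}

#' Write a GMT gene-set file
#'
#' Inverse of [read_gmt()]; round-trips are lossless.
#'
#' @param collection A [gene_set_collection()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$description[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
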