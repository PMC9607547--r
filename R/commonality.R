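#' Restrict DE tables to a biotype
#'
#' @param de_tables Named list of per-series [run_de()] tables (or a single
#'   such table).
#' @param annotation A [tx_annotation()].
#' @param biotype `"lncRNA"`, `"protein_coding"` or `"other"`.
#' @return The tables with only transcripts of the requested biotype;
#'   all other columns untouched.
#' @export
filter_biotype <- function(de_tables, annotation, biotype = "lncRNA") {
  stopifnot(biotype %in% .BIOTYPES)
  map <- setNames(annotation$transcripts$biotype,
                  annotation$transcripts$transcript_id)
  one <- function(tab) tab[!is.na(map[tab$transcript_id]) &
                           map[tab$transcript_id] == biotype, , drop = FALSE]
  if (is.data.frame(de_tables)) one(de_tables) else lapply(de_tables, one)
}

#' Direction-aware commonality table
#'
#' One row per (DE transcript, series): the membership substrate for upset
#' counts and the at-least-k selection.
#'
#' @param de_tables Named list of per-series [run_de()] tables.
#' @return data.frame of class `commonality_table` with columns
#'   `transcript_id`, `series_id`, `direction`, `log2FC`.
#' @export
commonality_table <- function(de_tables) {
  rows <- lapply(de_tables, function(tab)
    tab[tab$is_DE, c("transcript_id", "series_id", "direction", "log2FC")])
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(transcript_id = character(), series_id = character(),
                      direction = character(), log2FC = numeric(),
                      stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  if (anyDuplicated(tab[, c("transcript_id", "series_id")]))
    stop("duplicate (transcript, series) rows in DE input")
  class(tab) <- c("commonality_table", "data.frame")
  tab
}

#' Upset-style exclusive intersection counts
#'
#' Each DE transcript is counted in exactly one cell: the exact set of
#' series in which it is DE in the requested direction. The cell counts
#' therefore partition the DE transcripts and sum to the number of
#' distinct DE transcripts in that direction.
#'
#' @param table A [commonality_table()].
#' @param direction `"up"` or `"down"`.
#' @return data.frame with columns `subset` (series IDs joined by `+`),
#'   `direction`, `count`, sorted by decreasing count.
#' @export
upset_counts <- function(table, direction = c("up", "down")) {
  direction <- match.arg(direction)
  tab <- table[table$direction == direction, , drop = FALSE]
  if (!nrow(tab))
    return(data.frame(subset = character(), direction = character(),
                      count = integer(), stringsAsFactors = FALSE))
  key <- vapply(split(tab$series_id, tab$transcript_id),
                function(s) paste(sort(s), collapse = "+"), character(1))
  cnt <- table(key)
  out <- data.frame(subset = names(cnt), direction = direction,
                    count = as.integer(cnt), stringsAsFactors = FALSE)
  out[order(-out$count, out$subset), , drop = FALSE]
}

#' Select isoforms DE in at least k series
#'
#' Membership counts series where the transcript is DE in either direction
#' (a transcript may be up in some series and down in others; mixed
#' directions are preserved); set `direction_specific = TRUE` to require
#' the k-series membership within a single direction instead.
#'
#' @param table A [commonality_table()].
#' @param k_min Minimum number of series (default 4).
#' @param n_series Total number of series (bounds check only).
#' @param direction_specific Count memberships per direction (default
#'   `FALSE`).
#' @return List with `selected` (character vector of transcript IDs,
#'   sorted), `membership` (data.frame `transcript_id`, `n_series`) and
#'   `detail` (the selected rows of `table`).
#' @export
select_common <- function(table, k_min = 4, n_series = NULL,
                          direction_specific = FALSE) {
  if (!is.null(n_series) && (k_min < 1 || k_min > n_series))
    stop("k_min must be in 1..n_series")
  if (!nrow(table))
    return(list(selected = character(),
                membership = data.frame(transcript_id = character(),
                                        n_series = integer()),
                detail = table))
  if (direction_specific) {
    key <- paste(table$transcript_id, table$direction, sep = "\r")
    n <- table(key)
    hits <- unique(sub("\r.*", "", names(n)[n >= k_min]))
  } else {
    n <- table(table$transcript_id)
    hits <- names(n)[n >= k_min]
  }
  n_all <- table(table$transcript_id)
  list(selected = sort(hits),
       membership = data.frame(transcript_id = names(n_all),
                               n_series = as.integer(n_all),
                               stringsAsFactors = FALSE),
       detail = table[table$transcript_id %in% hits, , drop = FALSE])
}
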