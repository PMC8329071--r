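#' Genomic interval tables
#'
#' Intervals are represented throughout the package as plain data frames with
#' columns `id`, `chrom`, `start`, `end`. Coordinates are uniformly 0-based
#' half-open internally: a base at position `p` is covered by `[start, end)`
#' iff `start <= p < end`. Published 1-based inclusive coordinates are
#' converted at the I/O boundary only.
#'
#' @param id character vector of feature identifiers.
#' @param chrom character vector of chromosome names (matched as exact
#'   strings; `"chr5"` and `"5"` are different chromosomes).
#' @param start,end integer-like vectors; `0 <= start < end`.
#' @return A `data.frame` with columns `id`, `chrom`, `start`, `end`.
#' @examples
#' genomic_intervals("a", "chr1", 100, 200)
#' @export
genomic_intervals <- function(id, chrom, start, end) {
  x <- data.frame(
    id = as.character(id), chrom = as.character(chrom),
    start = as.numeric(start), end = as.numeric(end),
    stringsAsFactors = FALSE
  )
  validate_intervals(x)
  x
}

validate_intervals <- function(x, what = "interval") {
  stopifnot(all(c("id", "chrom", "start", "end") %in% names(x)))
  if (any(is.na(x$start)) || any(is.na(x$end))) {
    stop(what, ": missing coordinates")
  }
  bad <- which(x$start < 0 | x$start >= x$end)
  if (length(bad)) {
    stop(sprintf("%s: start >= end (or start < 0) at row %d", what, bad[1]))
  }
  invisible(x)
}

#' Read an interval table (BED-like)
#'
#' Reads a tab-separated file with at least three columns
#' (chrom, start, end) and an optional fourth id column. Rows lacking an id
#' get auto-generated ids `row1`, `row2`, ... in file order.
#'
#' @param path path to a tab-separated file without header.
#' @param convention coordinate convention of the file: `"bed0"` (0-based
#'   half-open, the BED standard) or `"onebased_inclusive"` (as printed in
#'   most publications, e.g. `chr5:140660415-141580433`).
#' @param chrom_prefix `"asis"` (default) keeps chromosome names untouched;
#'   `"add"` prepends `"chr"` where missing; `"strip"` removes a leading
#'   `"chr"`.
#' @return interval data frame (see [genomic_intervals()]), 0-based half-open,
#'   input order preserved.
#' @export
read_intervals <- function(path, convention = c("bed0", "onebased_inclusive"),
                           chrom_prefix = c("asis", "add", "strip")) {
  convention <- match.arg(convention)
  chrom_prefix <- match.arg(chrom_prefix)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) {
    return(genomic_intervals(character(), character(), numeric(), numeric()))
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          colClasses = list(character = 1))
  if (ncol(dt) < 3) stop("interval file needs >= 3 columns: ", path)
  chrom <- normalize_chrom(as.character(dt[[1]]), chrom_prefix)
  start <- suppressWarnings(as.numeric(dt[[2]]))
  end <- suppressWarnings(as.numeric(dt[[3]]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("malformed row at line ", bad[1], " in ", path)
  if (convention == "onebased_inclusive") start <- start - 1
  bad <- which(start < 0 | start >= end)
  if (length(bad)) stop("start >= end at line ", bad[1], " in ", path)
  id <- if (ncol(dt) >= 4) as.character(dt[[4]]) else paste0("row", seq_len(nrow(dt)))
  id[is.na(id) | id == ""] <- paste0("row", which(is.na(id) | id == ""))
  genomic_intervals(id, chrom, start, end)
}

#' Write an interval table
#'
#' Inverse of [read_intervals()]: converts internal 0-based half-open
#' coordinates back to the requested convention.
#'
#' @param x interval data frame.
#' @inheritParams read_intervals
#' @export
write_intervals <- function(x, path,
                            convention = c("bed0", "onebased_inclusive")) {
  convention <- match.arg(convention)
  validate_intervals(x)
  start <- x$start
  if (convention == "onebased_inclusive") start <- start + 1
  out <- data.table::data.table(x$chrom, format_coord(start),
                                format_coord(x$end), x$id)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

normalize_chrom <- function(chrom, mode = c("asis", "add", "strip")) {
  mode <- match.arg(mode)
  if (mode == "add") {
    no <- !startsWith(chrom, "chr")
    chrom[no] <- paste0("chr", chrom[no])
  } else if (mode == "strip") {
    chrom <- sub("^chr", "", chrom)
  }
  chrom
}

#' Read TAD segments
#'
#' Reads a TAD segmentation as a BED-like file and validates that TADs on the
#' same chromosome do not overlap. Every downstream TAD statistic assumes a
#' partition, so overlap is an error, not a warning.
#'
#' @inheritParams read_intervals
#' @return interval data frame of TADs, sorted as in the file.
#' @export
read_tads <- function(path, convention = c("bed0", "onebased_inclusive"),
                      chrom_prefix = c("asis", "add", "strip")) {
  tads <- read_intervals(path, convention, chrom_prefix)
  validate_tads(tads)
  tads
}

validate_tads <- function(tads) {
  if (anyDuplicated(tads$id)) stop("duplicate TAD ids")
  for (ch in unique(tads$chrom)) {
    sub <- tads[tads$chrom == ch, , drop = FALSE]
    o <- order(sub$start)
    s <- sub$start[o]; e <- sub$end[o]
    if (length(s) > 1 && any(s[-1] < e[-length(e)])) {
      stop("overlapping TADs on ", ch)
    }
  }
  invisible(tads)
}

#' Read chromatin contact pairs (BEDPE)
#'
#' Reads anchor pairs from a BEDPE file (chromA, startA, endA, chromB,
#' startB, endB, optional score). Inter-chromosomal pairs are dropped; their
#' count is reported via a message and kept in the `"n_interchrom_dropped"`
#' attribute of the result.
#'
#' @param path path to a BEDPE file (0-based half-open anchors, no header).
#' @return data frame with columns `chrom`, `start_a`, `end_a`, `start_b`,
#'   `end_b`, `score` (`NA` when absent).
#' @export
read_contacts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  empty <- data.frame(chrom = character(), start_a = numeric(),
                      end_a = numeric(), start_b = numeric(),
                      end_b = numeric(), score = numeric(),
                      stringsAsFactors = FALSE)
  attr(empty, "n_interchrom_dropped") <- 0L
  if (file.size(path) == 0) return(empty)
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (nrow(dt) == 0) return(empty)
  if (ncol(dt) < 6) stop("BEDPE needs >= 6 columns: ", path)
  out <- data.frame(
    chrom_a = as.character(dt[[1]]),
    start_a = as.numeric(dt[[2]]), end_a = as.numeric(dt[[3]]),
    chrom_b = as.character(dt[[4]]),
    start_b = as.numeric(dt[[5]]), end_b = as.numeric(dt[[6]]),
    score = if (ncol(dt) >= 7) suppressWarnings(as.numeric(dt[[7]])) else NA_real_,
    stringsAsFactors = FALSE
  )
  if (any(!is.na(out$score) & out$score < 0)) stop("negative contact score")
  intra <- out$chrom_a == out$chrom_b
  n_drop <- sum(!intra)
  if (n_drop > 0) {
    message(n_drop, " inter-chromosomal contact pair(s) dropped")
  }
  out <- out[intra, , drop = FALSE]
  bad <- which(out$start_a < 0 | out$start_a >= out$end_a |
                 out$start_b < 0 | out$start_b >= out$end_b)
  if (length(bad)) stop("malformed anchor at retained row ", bad[1])
  out <- data.frame(chrom = out$chrom_a,
                    out[, c("start_a", "end_a", "start_b", "end_b", "score")],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_interchrom_dropped") <- n_drop
  out
}

#' Write contact pairs as BEDPE
#' @param contacts data frame as returned by [read_contacts()].
#' @param path output path.
#' @export
write_contacts <- function(contacts, path) {
  out <- data.table::data.table(
    contacts$chrom, format_coord(contacts$start_a), format_coord(contacts$end_a),
    contacts$chrom, format_coord(contacts$start_b), format_coord(contacts$end_b),
    ifelse(is.na(contacts$score), ".", format_coord(contacts$score))
  )
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

# Half-open interval tables -> IRanges (1-based closed) for the overlap engine.
as_iranges0 <- function(start, end) IRanges::IRanges(start = start + 1, end = end)

#' Query intervals overlapping a window
#'
#' Half-open overlap semantics: `[0,10)` and `[10,20)` do not overlap.
#' Chromosomes are matched as exact strings; a query on an unseen chromosome
#' returns an empty result.
#'
#' @param targets interval data frame.
#' @param chrom,start,end the query window (0-based half-open).
#' @return character vector of ids of all targets intersecting the query, in
#'   target order.
#' @export
overlap_query <- function(targets, chrom, start, end) {
  validate_intervals(targets)
  stopifnot(length(chrom) == 1, start < end)
  sub <- targets[targets$chrom == chrom, , drop = FALSE]
  if (nrow(sub) == 0) return(character())
  hits <- IRanges::findOverlaps(as_iranges0(start, end),
                                as_iranges0(sub$start, sub$end))
  sub$id[sort(S4Vectors::subjectHits(hits))]
}

# Vectorised overlap of two interval tables; returns data.frame of row
# indices (query_idx, target_idx). Used by aggregation and linking code.
overlap_join <- function(query, targets) {
  out <- vector("list", 0L)
  chroms <- intersect(unique(query$chrom), unique(targets$chrom))
  for (ch in chroms) {
    qi <- which(query$chrom == ch)
    ti <- which(targets$chrom == ch)
    hits <- IRanges::findOverlaps(
      as_iranges0(query$start[qi], query$end[qi]),
      as_iranges0(targets$start[ti], targets$end[ti])
    )
    out[[length(out) + 1L]] <- data.frame(
      query_idx = qi[S4Vectors::queryHits(hits)],
      target_idx = ti[S4Vectors::subjectHits(hits)]
    )
  }
  if (!length(out)) {
    return(data.frame(query_idx = integer(), target_idx = integer()))
  }
  do.call(rbind, out)
}
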