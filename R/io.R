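#' Read a BED file of genomic intervals
#'
#' Parses BED3/BED6 into a tibble of genomic intervals. All coordinates in
#' this package follow the BED convention: 0-based, half-open `[start, end)`.
#' Input row order is preserved.
#'
#' @param path Path to a tab-separated BED file (>= 3 columns, no header).
#' @return A tibble with columns `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- read_nonempty_lines(path)
  if (length(lines) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  bad <- which(ncol < 3L)
  if (length(bad) > 0L) {
    abort(sprintf("malformed BED line %d in '%s': fewer than 3 tab-separated fields",
                  bad[1], path))
  }
  k <- min(ncol)
  get_col <- function(i) vapply(fields, `[[`, character(1), i)
  out <- tibble(
    chrom = get_col(1L),
    start = parse_coord(get_col(2L), path, "start"),
    end   = parse_coord(get_col(3L), path, "end")
  )
  if (k >= 4L) out$name <- get_col(4L)
  if (k >= 5L) {
    sc <- suppressWarnings(as.numeric(get_col(5L)))
    out$score <- sc
  }
  if (k >= 6L) out$strand <- get_col(6L)
  validate_intervals(out, path = path)
  out
}

#' Write genomic intervals as BED
#'
#' @param x Interval tibble (`chrom`, `start`, `end`, optional `name`,
#'   `score`, `strand`).
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  has <- function(col) col %in% names(x)
  cols <- list(x$chrom, format_coord(x$start), format_coord(x$end))
  if (has("name")) cols <- c(cols, list(x$name))
  if (has("score")) {
    if (!has("name")) cols <- c(cols, list(rep(".", nrow(x))))
    cols <- c(cols, list(format(x$score, trim = TRUE, scientific = FALSE)))
  }
  if (has("strand")) {
    while (length(cols) < 5L) cols <- c(cols, list(rep(".", nrow(x))))
    cols <- c(cols, list(x$strand))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(x)
}

#' Read a bedGraph signal track
#'
#' Returns a piecewise-constant coverage track, sorted by (chrom, start),
#' with non-overlapping blocks. Gaps between blocks imply signal 0. Values
#' must be finite and non-negative; overlapping records are an error.
#'
#' @param path Path to a 4-column bedGraph file.
#' @return A track tibble with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  lines <- read_nonempty_lines(path)
  lines <- lines[!startsWith(lines, "track") & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(empty_track())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 4L)
  if (length(bad) > 0L) {
    abort(sprintf("malformed bedGraph line %d in '%s': expected 4 fields", bad[1], path))
  }
  get_col <- function(i) vapply(fields, `[[`, character(1), i)
  x <- tibble(
    chrom = get_col(1L),
    start = parse_coord(get_col(2L), path, "start"),
    end   = parse_coord(get_col(3L), path, "end"),
    value = suppressWarnings(as.numeric(get_col(4L)))
  )
  if (anyNA(x$value)) {
    abort(sprintf("non-numeric value on bedGraph line %d in '%s'",
                  which(is.na(x$value))[1], path))
  }
  if (any(x$value < 0)) {
    abort(sprintf("negative signal value on bedGraph line %d in '%s'",
                  which(x$value < 0)[1], path))
  }
  validate_track(x, path = path)
}

#' Write a signal track as bedGraph
#'
#' Values are written with 6 decimal places, the package's round-trip
#' precision for signal.
#'
#' @param x Track tibble (`chrom`, `start`, `end`, `value`).
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(x)))
  writeLines(
    paste(x$chrom, format_coord(x$start), format_coord(x$end),
          sprintf("%.6f", x$value), sep = "\t"),
    path
  )
  invisible(x)
}

#' Read a feature-by-sample count or expression table
#'
#' Expects a header row of sample names and a first column of feature ids.
#' Duplicated feature ids and non-numeric cells are errors.
#'
#' @param path Path to a tab-separated table.
#' @return A tibble whose first column is `feature` and remaining columns
#'   are numeric sample columns.
#' @export
read_count_table <- function(path) {
  x <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                         colClasses = "character")
  if (ncol(x) < 2L) abort(sprintf("'%s' needs a feature column plus >=1 sample column", path))
  feats <- x[[1L]]
  if (anyDuplicated(feats)) {
    abort(sprintf("duplicated feature id '%s' in '%s'", feats[duplicated(feats)][1], path))
  }
  num <- lapply(seq(2L, ncol(x)), function(j) {
    v <- suppressWarnings(as.numeric(x[[j]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      abort(sprintf("non-numeric cell at row '%s', column '%s' in '%s'",
                    feats[i], names(x)[j], path))
    }
    v
  })
  names(num) <- names(x)[-1L]
  out <- as_tibble(c(list(feature = feats), num))
  out
}

#' Write a feature-by-sample table as TSV
#'
#' @param x Tibble with `feature` first column.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_count_table <- function(x, path) {
  stopifnot(names(x)[1] == "feature")
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

## ---- internal helpers -------------------------------------------------

read_nonempty_lines <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines[nzchar(lines)]
}

parse_coord <- function(x, path, what) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v)) {
    abort(sprintf("malformed line %d in '%s': non-numeric %s '%s'",
                  which(is.na(v))[1], path, what, x[which(is.na(v))[1]]))
  }
  v
}

format_coord <- function(x) format(x, trim = TRUE, scientific = FALSE)

empty_track <- function() {
  tibble(chrom = character(), start = numeric(), end = numeric(), value = numeric())
}

#' Validate an interval tibble against the coordinate invariants
#'
#' Checks 0-based half-open coordinates: `start >= 0`, `end > start`.
#'
#' @param x Interval tibble.
#' @param path Optional source path used in error messages.
#' @return `x`, invisibly.
#' @export
validate_intervals <- function(x, path = NULL) {
  where <- if (is.null(path)) "" else sprintf(" in '%s'", path)
  if (!all(c("chrom", "start", "end") %in% names(x))) {
    abort(sprintf("interval table%s must have chrom/start/end columns", where))
  }
  if (nrow(x) == 0L) return(invisible(x))
  if (any(x$start < 0)) {
    abort(sprintf("line %d%s: negative start", which(x$start < 0)[1], where))
  }
  if (any(x$end <= x$start)) {
    abort(sprintf("line %d%s: end <= start (zero or negative width)",
                  which(x$end <= x$start)[1], where))
  }
  invisible(x)
}

validate_track <- function(x, path = NULL) {
  validate_intervals(x, path)
  x <- arrange(x, .data$chrom, .data$start)
  if (nrow(x) > 1L) {
    same <- x$chrom[-1L] == x$chrom[-nrow(x)]
    if (any(same & x$start[-1L] < x$end[-nrow(x)])) {
      i <- which(same & x$start[-1L] < x$end[-nrow(x)])[1] + 1L
      where <- if (is.null(path)) "" else sprintf(" in '%s'", path)
      abort(sprintf("overlapping bedGraph records near record %d%s", i, where))
    }
  }
  if (!all(is.finite(x$value))) abort("signal values must be finite")
  x
}

## tibble <-> GRanges bridges (internal). GRanges is 1-based closed;
## the +1/-0 shift here is the only place the conversion happens.
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = if ("strand" %in% names(x)) ifelse(x$strand %in% c("+", "-"), x$strand, "*") else "*"
  )
}

granges_to_tibble <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end   = GenomicRanges::end(gr)
  )
}

#' Total area under a signal track
#'
#' Sum over blocks of `value * width`; the bedGraph round-trip preserves
#' this quantity to the write precision.
#'
#' @param x Track tibble.
#' @return A single number.
#' @export
track_area <- function(x) sum(x$value * (x$end - x$start))
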