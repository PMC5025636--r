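#' Read-level filter parameters
#'
#' @param redundancy_threshold Maximum number of reads retained per
#'   identical (chrom, start, strand) key.
#' @param max_mismatch Maximum alignment mismatches (NM tag) retained.
#' @param min_mapq Reads must have mapping quality strictly greater than
#'   this ("better than 20").
#' @return A `filter_params` list.
#' @export
filter_params <- function(redundancy_threshold = 1L,
                          max_mismatch = 1L,
                          min_mapq = 20L) {
  stopifnot(redundancy_threshold >= 1, max_mismatch >= 0, min_mapq >= 0)
  structure(
    list(
      redundancy_threshold = as.integer(redundancy_threshold),
      max_mismatch = as.integer(max_mismatch),
      min_mapq = as.integer(min_mapq)
    ),
    class = "filter_params"
  )
}

#' Load reads from a BED file
#'
#' Accepts BED3 or BED6; with fewer than 6 columns the strand defaults to
#' `"+"` with a warning. Coordinates are 0-based half-open. Records with
#' `start >= end`, or (when `genome` is given) on unknown chromosomes or
#' extending past a chromosome end, are rejected with an informative error.
#'
#' @param path Path to a tab-separated BED file (no header).
#' @param genome Optional genome layout tibble (`chrom`, `length`) to
#'   validate against.
#' @return A read tibble (`chrom`, `start`, `end`, `strand`).
#' @export
load_reads <- function(path, genome = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("BED file not found: %s", path))
  }
  raw <- readr::read_tsv(
    path,
    col_names = FALSE, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(raw) == 0L) {
    return(empty_reads())
  }
  if (ncol(raw) < 3L) {
    abort(sprintf("%s: need at least 3 BED columns, found %d", path, ncol(raw)))
  }
  start <- suppressWarnings(as.integer(raw[[2]]))
  end <- suppressWarnings(as.integer(raw[[3]]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    abort(sprintf("%s: malformed coordinates at line %d", path, bad[1]))
  }
  bad <- which(start >= end)
  if (length(bad) > 0L) {
    abort(sprintf("%s: start >= end at line %d", path, bad[1]))
  }
  if (ncol(raw) >= 6L) {
    strand <- raw[[6]]
    if (!all(strand %in% c("+", "-"))) {
      abort(sprintf("%s: strand column must be '+' or '-'", path))
    }
  } else {
    warn(sprintf("%s: no strand column; assuming '+'", path))
    strand <- rep("+", nrow(raw))
  }
  reads <- tibble(chrom = raw[[1]], start = start, end = end, strand = strand)
  if (!is.null(genome)) {
    unk <- setdiff(unique(reads$chrom), genome$chrom)
    if (length(unk) > 0L) {
      abort(sprintf(
        "%s: unknown chromosome(s): %s", path, paste(unk, collapse = ", ")
      ))
    }
    len <- genome$length[match(reads$chrom, genome$chrom)]
    if (any(reads$end > len)) {
      abort(sprintf("%s: record extends past chromosome end", path))
    }
  }
  reads
}

#' Write intervals as BED
#'
#' Writes BED6 when a `strand` column is present (name = row id, score 0),
#' BED3 otherwise. Records are sorted by (chrom, start).
#'
#' @param x Interval tibble with `chrom`, `start`, `end` and optionally
#'   `strand` and `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- arrange(x, .data$chrom, .data$start)
  if ("strand" %in% names(x)) {
    out <- tibble(
      chrom = x$chrom, start = x$start, end = x$end,
      name = if ("name" %in% names(x)) x$name else sprintf("r%d", seq_len(nrow(x))),
      score = if ("score" %in% names(x)) x$score else 0L,
      strand = x$strand
    )
  } else {
    out <- x |> select(all_of(c("chrom", "start", "end")))
  }
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Remove redundant reads
#'
#' Retains at most `redundancy_threshold` reads per identical
#' (chrom, start, strand) key — the duplicate key appropriate for
#' fixed-length single-end reads. Retention is deterministic: the first
#' occurrences in (chrom, start, strand) sort order are kept, so the result
#' does not depend on input record order.
#'
#' @param reads Read tibble.
#' @param redundancy_threshold Maximum copies retained per key.
#' @return Filtered read tibble.
#' @export
#' @examples
#' r <- tibble::tibble(
#'   chrom = "chr1", start = c(100L, 100L, 100L), end = c(136L, 136L, 136L),
#'   strand = "+"
#' )
#' nrow(filter_redundant(r, 1)) # 1
filter_redundant <- function(reads, redundancy_threshold = 1L) {
  stopifnot(redundancy_threshold >= 1)
  check_reads(reads)
  reads |>
    arrange(.data$chrom, .data$start, .data$strand, .data$end) |>
    group_by(.data$chrom, .data$start, .data$strand) |>
    filter(row_number() <= redundancy_threshold) |>
    ungroup()
}

#' Filter reads on mapping quality and mismatches
#'
#' Keeps records with `mapq` strictly greater than `params$min_mapq` and
#' `nm` (mismatch count) at most `params$max_mismatch`. The input must
#' carry `mapq` and `nm` columns (the simulator's sidecar fields); plain
#' BED input skips this stage.
#'
#' @param reads Read tibble with `mapq` and `nm` columns.
#' @param params A [filter_params()].
#' @return Filtered read tibble.
#' @export
filter_quality <- function(reads, params = filter_params()) {
  assert_cols(reads, c("mapq", "nm"), "quality-filter input")
  reads |>
    filter(.data$mapq > params$min_mapq, .data$nm <= params$max_mismatch)
}
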