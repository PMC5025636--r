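# Internal helpers shared across modules.

# Overlap pairs between two interval tables (0-based half-open columns
# `chrom`, `start`, `end`). Returns a tibble of row indices (query, subject).
# IRanges is 1-based closed; the +1L on start keeps half-open semantics:
# [s, e) in 0-based equals [s+1, e] in 1-based closed.
overlap_pairs <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(tibble(query = integer(), subject = integer()))
  }
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  purrr::map_dfr(chroms, function(ch) {
    ia <- which(a$chrom == ch)
    ib <- which(b$chrom == ch)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = a$start[ia] + 1L, end = a$end[ia]),
      IRanges::IRanges(start = b$start[ib] + 1L, end = b$end[ib])
    )
    tibble(
      query = ia[S4Vectors::queryHits(hits)],
      subject = ib[S4Vectors::subjectHits(hits)]
    )
  })
}

# Width of intersection of two half-open intervals; 0 when disjoint.
intersect_width <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

# Deterministic per-stage seed derived from a master seed. Kept below 2^31.
derive_seed <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage)) %% 1000L
  (as.integer(seed) %% 2000000L) * 1000L + offs
}

assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    abort(sprintf("%s is missing column(s): %s", what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}

check_reads <- function(reads) {
  assert_cols(reads, c("chrom", "start", "end", "strand"), "read set")
  if (any(reads$start >= reads$end)) {
    abort("read set contains records with start >= end")
  }
  invisible(reads)
}

empty_reads <- function() {
  tibble(
    chrom = character(), start = integer(), end = integer(),
    strand = character()
  )
}
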