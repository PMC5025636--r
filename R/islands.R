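#' Island-calling parameters
#'
#' The windowed island caller follows the standard broad-mark
#' parameterization: 200-bp windows, 200-bp fragment shift, effective
#' genome fraction 0.75, and a mark-specific gap — 600 bp for the narrow
#' H3K4me3 mark, 1000 bp for broad H3K27me3 — with islands kept at
#' Benjamini-Hochberg q <= `fdr_q`.
#'
#' @param window_w Window size in bp.
#' @param gap_g Maximum gap bridged between eligible windows, in bp; must
#'   be a multiple of `window_w`. Use [k4_params()] / [k27_params()] for
#'   the per-mark defaults.
#' @param fragment_size Fragment size; tags are read 5' ends shifted by
#'   `fragment_size / 2` toward the 3' end.
#' @param egf Effective genome fraction (mappable proportion).
#' @param window_p0 Poisson upper-tail p-value below which a window is
#'   eligible to seed or extend an island.
#' @param fdr_q FDR threshold on island q-values.
#' @param mode `"with_control"` (Poisson test of island tag count against
#'   the library-size-scaled control count) or `"background_only"`
#'   (against the genome-wide background rate).
#' @return An `island_params` list.
#' @export
island_params <- function(window_w = 200L,
                          gap_g = 600L,
                          fragment_size = 200L,
                          egf = 0.75,
                          window_p0 = 0.2,
                          fdr_q = 0.01,
                          mode = c("with_control", "background_only")) {
  mode <- match.arg(mode)
  stopifnot(
    window_w > 0, gap_g >= 0, gap_g %% window_w == 0,
    fragment_size > 0, egf > 0, egf <= 1,
    window_p0 > 0, window_p0 <= 1, fdr_q > 0, fdr_q < 1
  )
  structure(
    list(
      window_w = as.integer(window_w), gap_g = as.integer(gap_g),
      fragment_size = as.integer(fragment_size), egf = egf,
      window_p0 = window_p0, fdr_q = fdr_q, mode = mode
    ),
    class = "island_params"
  )
}

#' @rdname island_params
#' @param ... Overrides passed to [island_params()].
#' @export
k4_params <- function(...) island_params(gap_g = 600L, ...)

#' @rdname island_params
#' @export
k27_params <- function(...) island_params(gap_g = 1000L, ...)

#' Convert stranded reads to shifted tag positions
#'
#' A tag is the read 5' end shifted by `fragment_size / 2` toward the 3'
#' end: plus-strand reads give `start + fragment_size/2`, minus-strand
#' reads `end - fragment_size/2`. Tags are clipped to `[0, chrom_len)`.
#'
#' @param reads Read tibble.
#' @param genome Genome layout (`chrom`, `length`).
#' @param fragment_size Fragment size in bp.
#' @return Tibble with `chrom`, `tag`.
#' @export
tags_from_reads <- function(reads, genome, fragment_size = 200L) {
  check_reads(reads)
  shift <- fragment_size %/% 2L
  tag <- ifelse(reads$strand == "+", reads$start + shift, reads$end - shift)
  len <- genome$length[match(reads$chrom, genome$chrom)]
  if (anyNA(len)) {
    abort("reads contain chromosomes absent from the genome layout")
  }
  tibble(
    chrom = reads$chrom,
    tag = as.integer(pmax(0L, pmin(tag, len - 1L)))
  )
}

#' Per-window tag counts and background rate
#'
#' Bins tags into fixed non-overlapping windows tiled from coordinate 0
#' (window index `floor(tag / window_w)`; the final partial window is
#' dropped) and computes the expected background tags per window,
#' `lambda_bg = N_tags * window_w / (genome_length * egf)`.
#'
#' @param tags Tibble from [tags_from_reads()].
#' @param genome Genome layout.
#' @param params An [island_params()].
#' @return A list with `counts` (named list of per-chromosome integer
#'   vectors) and `lambda_bg`.
#' @export
window_counts <- function(tags, genome, params = island_params()) {
  w <- params$window_w
  counts <- setNames(
    purrr::map(seq_len(nrow(genome)), function(i) {
      nw <- genome$length[i] %/% w
      t <- tags$tag[tags$chrom == genome$chrom[i]]
      t <- t[t %/% w < nw]
      tabulate(t %/% w + 1L, nbins = nw)
    }),
    genome$chrom
  )
  lambda_bg <- nrow(tags) * w / (sum(genome$length) * params$egf)
  list(counts = counts, lambda_bg = lambda_bg, window_w = w)
}

#' Window eligibility by Poisson upper tail
#'
#' A window with tag count `c >= 1` is eligible iff the upper-tail
#' Poisson probability `P(X >= c | lambda_bg)` is at most
#' `params$window_p0`.
#'
#' @param wv A [window_counts()] result.
#' @param params An [island_params()].
#' @return Named list of per-chromosome logical vectors.
#' @export
eligible_windows <- function(wv, params = island_params()) {
  if (wv$lambda_bg <= 0) {
    abort("degenerate background: lambda_bg is zero (no tags)")
  }
  purrr::map(wv$counts, function(cnt) {
    cnt >= 1L & ppois(cnt - 1L, wv$lambda_bg, lower.tail = FALSE) <= params$window_p0
  })
}

#' Assemble candidate islands from eligible windows
#'
#' Islands are maximal runs of eligible windows in which consecutive
#' eligible windows are separated by at most `gap_g / window_w`
#' ineligible windows. The island spans the first through last eligible
#' window; its score is the sum over its eligible windows of
#' `-ln Poisson(count; lambda_bg)`.
#'
#' @param eligible Output of [eligible_windows()].
#' @param wv The matching [window_counts()] result.
#' @param params An [island_params()].
#' @return Tibble of candidate islands: `chrom`, `start`, `end`, `score`,
#'   `n_windows` (eligible windows), `chip_count` (tags inside the span).
#' @export
assemble_islands <- function(eligible, wv, params = island_params()) {
  w <- wv$window_w
  gap_win <- params$gap_g %/% w
  purrr::map_dfr(names(eligible), function(ch) {
    idx <- which(eligible[[ch]])
    if (length(idx) == 0L) {
      return(NULL)
    }
    grp <- cumsum(c(1L, diff(idx) - 1L > gap_win))
    cnt <- wv$counts[[ch]]
    purrr::map_dfr(split(idx, grp), function(ii) {
      span <- seq(min(ii), max(ii))
      tibble(
        chrom = ch,
        start = as.integer((min(ii) - 1L) * w),
        end = as.integer(max(ii) * w),
        score = sum(-dpois(cnt[ii], wv$lambda_bg, log = TRUE)),
        n_windows = length(ii),
        chip_count = as.integer(sum(cnt[span]))
      )
    })
  })
}

empty_islands <- function() {
  tibble(
    chrom = character(), start = integer(), end = integer(),
    score = double(), n_windows = integer(), chip_count = integer(),
    control_count = integer(), p_value = double(), q_value = double(),
    island_id = character()
  )
}

#' Call enrichment islands from ChIP (and optionally control) reads
#'
#' Full caller: shift reads to tags, count per window, select eligible
#' windows, assemble gapped islands, and test each island's tag count —
#' against the library-size-scaled control count (+1 pseudo-count) in
#' `with_control` mode, or against `lambda_bg * windows_spanned` in
#' `background_only` mode — with Benjamini-Hochberg correction across
#' islands. Islands with q <= `fdr_q` are kept.
#'
#' @param chip_reads Read tibble for the ChIP track.
#' @param genome Genome layout (`chrom`, `length`).
#' @param params An [island_params()]; use [k4_params()] / [k27_params()]
#'   for mark defaults.
#' @param control_reads Optional read tibble for the control (input) track;
#'   required in `with_control` mode.
#' @return A tibble of class `biv_islands`, sorted and non-overlapping:
#'   `chrom`, `start`, `end`, `score`, `n_windows`, `chip_count`,
#'   `control_count`, `p_value`, `q_value`, `island_id`.
#' @export
call_islands <- function(chip_reads, genome, params = island_params(),
                         control_reads = NULL) {
  if (nrow(chip_reads) == 0L) {
    warn("no ChIP reads: returning zero islands")
    return(structure(empty_islands(), class = c("biv_islands", class(empty_islands()))))
  }
  if (params$mode == "with_control" &&
    (is.null(control_reads) || nrow(control_reads) == 0L)) {
    abort("with_control mode requires non-empty control_reads")
  }
  tags <- tags_from_reads(chip_reads, genome, params$fragment_size)
  wv <- window_counts(tags, genome, params)
  elig <- eligible_windows(wv, params)
  cand <- assemble_islands(elig, wv, params)
  if (nrow(cand) == 0L) {
    return(structure(empty_islands(), class = c("biv_islands", class(empty_islands()))))
  }

  if (params$mode == "with_control") {
    ctags <- tags_from_reads(control_reads, genome, params$fragment_size)
    ratio <- nrow(tags) / nrow(ctags)
    cc <- purrr::map_int(seq_len(nrow(cand)), function(i) {
      t <- ctags$tag[ctags$chrom == cand$chrom[i]]
      sum(t >= cand$start[i] & t < cand$end[i])
    })
    cand$control_count <- cc
    lambda <- (cc + 1) * ratio
  } else {
    cand$control_count <- NA_integer_
    lambda <- wv$lambda_bg * (cand$end - cand$start) / params$window_w
  }
  cand$p_value <- ppois(cand$chip_count - 1L, lambda, lower.tail = FALSE)
  cand$q_value <- p.adjust(cand$p_value, method = "BH")
  out <- cand |>
    filter(.data$q_value <= params$fdr_q) |>
    arrange(.data$chrom, .data$start) |>
    mutate(island_id = sprintf("isl_%04d", row_number()))
  attr(out, "params") <- params
  structure(out, class = c("biv_islands", class(out)))
}

#' @export
glance.biv_islands <- function(x, ...) {
  tibble(
    n_islands = nrow(x),
    median_width = if (nrow(x)) median(x$end - x$start) else NA_real_,
    total_span = sum(x$end - x$start),
    median_q = if (nrow(x)) median(x$q_value) else NA_real_
  )
}

#' @export
tidy.biv_islands <- function(x, ...) {
  as_tibble(x) |> mutate(width = .data$end - .data$start)
}
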