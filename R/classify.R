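#' Classify promoters from H3K4me3 and H3K27me3 island calls
#'
#' Each transcript's promoter window is `[tss - radius, tss + radius)`.
#' A promoter is *bivalent* when an H3K4me3 island and an H3K27me3 island
#' both intersect the window and (under the default `"overlap"` rule)
#' also intersect each other; *K4_exclusive* / *K27_exclusive* when only
#' one mark's islands hit; *none* otherwise. Under the looser `"cooccur"`
#' rule, window co-occurrence of both marks suffices for bivalency.
#' Promoters whose marks co-occur in the window without mutual island
#' overlap are flagged `zonal_only` (and classed `none` under the default
#' rule), so the distinction between zonal and overlapping bivalency is
#' never silently dropped.
#'
#' @param genes Gene/transcript table with `transcript_id`, `chrom`,
#'   `tss`, `strand`.
#' @param islands_k4,islands_k27 Island tibbles from [call_islands()].
#' @param radius Half-width of the promoter window in bp (2500 by default;
#'   5000 reproduces the broader "enriched" definition).
#' @param bivalent_rule `"overlap"` (islands must mutually overlap) or
#'   `"cooccur"` (window co-occurrence suffices).
#' @return A tibble of class `biv_calls`: `transcript_id`, `class`
#'   (factor: bivalent, K4_exclusive, K27_exclusive, none), `k4_islands`,
#'   `k27_islands` (comma-collapsed ids), `overlap_bp` (widest mutual
#'   K4xK27 overlap inside the window), `zonal_only`.
#' @export
classify_promoters <- function(genes, islands_k4, islands_k27,
                               radius = 2500L,
                               bivalent_rule = c("overlap", "cooccur")) {
  bivalent_rule <- match.arg(bivalent_rule)
  stopifnot(radius > 0)
  assert_cols(genes, c("transcript_id", "chrom", "tss"), "genes")
  if (anyDuplicated(genes$transcript_id)) {
    abort("duplicate transcript_id in genes")
  }
  win <- tibble(
    chrom = genes$chrom,
    start = pmax(0L, genes$tss - as.integer(radius)),
    end = genes$tss + as.integer(radius)
  )
  h4 <- overlap_pairs(win, islands_k4)
  h27 <- overlap_pairs(win, islands_k27)

  res <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    i4 <- h4$subject[h4$query == i]
    i27 <- h27$subject[h27$query == i]
    k4_hit <- length(i4) > 0L
    k27_hit <- length(i27) > 0L
    ov <- 0L
    if (k4_hit && k27_hit) {
      grid <- expand.grid(a = i4, b = i27)
      ov <- max(intersect_width(
        islands_k4$start[grid$a], islands_k4$end[grid$a],
        islands_k27$start[grid$b], islands_k27$end[grid$b]
      ))
    }
    zonal <- k4_hit && k27_hit && ov == 0L
    cls <- if (k4_hit && k27_hit) {
      if (ov > 0L || bivalent_rule == "cooccur") "bivalent" else "none"
    } else if (k4_hit) {
      "K4_exclusive"
    } else if (k27_hit) {
      "K27_exclusive"
    } else {
      "none"
    }
    id4 <- if (k4_hit) paste(islands_k4$island_id[i4], collapse = ",") else ""
    id27 <- if (k27_hit) paste(islands_k27$island_id[i27], collapse = ",") else ""
    tibble(
      transcript_id = genes$transcript_id[i],
      class = cls, k4_islands = id4, k27_islands = id27,
      overlap_bp = as.integer(ov), zonal_only = zonal
    )
  })
  res$class <- factor(
    res$class,
    levels = c("bivalent", "K4_exclusive", "K27_exclusive", "none")
  )
  structure(res, class = c("biv_calls", class(res)))
}

#' @export
glance.biv_calls <- function(x, ...) {
  as_tibble(x) |>
    count(.data$class, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n")
}

#' Intersection zones of H3K4me3 and H3K27me3 islands
#'
#' Pairwise intersections of the two island sets — the "bivalent zones"
#' whose sizes the overlap-size distribution summarises.
#'
#' @param islands_k4,islands_k27 Island tibbles.
#' @return Tibble of intersection intervals `chrom`, `start`, `end`,
#'   `width`, with the source island indices `k4_idx`, `k27_idx`.
#' @export
overlap_zones <- function(islands_k4, islands_k27) {
  h <- overlap_pairs(islands_k4, islands_k27)
  if (nrow(h) == 0L) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      width = integer(), k4_idx = integer(), k27_idx = integer()
    ))
  }
  tibble(
    chrom = islands_k4$chrom[h$query],
    start = pmax(islands_k4$start[h$query], islands_k27$start[h$subject]),
    end = pmin(islands_k4$end[h$query], islands_k27$end[h$subject]),
    k4_idx = h$query, k27_idx = h$subject
  ) |>
    mutate(width = .data$end - .data$start) |>
    filter(.data$width > 0L) |>
    arrange(.data$chrom, .data$start)
}

#' Strand-oriented island-center offsets from the TSS
#'
#' For every island intersecting a promoter window, records the island
#' center's transcription-oriented offset from the TSS (upstream negative),
#' binned at `bin` bp.
#'
#' @param islands Island tibble.
#' @param genes Gene table with `transcript_id`, `chrom`, `tss`, `strand`.
#' @param flank Promoter window half-width in bp.
#' @param bin Offset bin width in bp.
#' @return Tibble `transcript_id`, `island_idx`, `offset`, `offset_bin`.
#' @export
peak_center_distribution <- function(islands, genes, flank = 5000L, bin = 10L) {
  win <- tibble(
    chrom = genes$chrom,
    start = pmax(0L, genes$tss - as.integer(flank)),
    end = genes$tss + as.integer(flank)
  )
  h <- overlap_pairs(win, islands)
  if (nrow(h) == 0L) {
    return(tibble(
      transcript_id = character(), island_idx = integer(),
      offset = integer(), offset_bin = integer()
    ))
  }
  center <- (islands$start[h$subject] + islands$end[h$subject]) %/% 2L
  sgn <- ifelse(genes$strand[h$query] == "+", 1L, -1L)
  off <- (center - genes$tss[h$query]) * sgn
  tibble(
    transcript_id = genes$transcript_id[h$query],
    island_idx = h$subject,
    offset = as.integer(off),
    offset_bin = as.integer((off %/% bin) * bin)
  )
}
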