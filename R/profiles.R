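# TSS-anchored and enhancer-scaled coverage profiles.

# Extend reads to fragment_size from their 5' ends.
extend_fragments <- function(reads, fragment_size) {
  tibble(
    chrom = reads$chrom,
    start = as.integer(ifelse(reads$strand == "+", reads$start,
      reads$end - fragment_size
    )),
    end = as.integer(ifelse(reads$strand == "+", reads$start + fragment_size,
      reads$end
    ))
  )
}

#' TSS-anchored fragment-coverage matrix
#'
#' Each read is extended to `fragment_size` bp from its 5' end; the value
#' of a bin is the number of extended fragments overlapping it. Rows are
#' transcripts, columns the `2 * flank / bin` bins covering
#' `[-flank, +flank)` around the TSS in transcription orientation
#' (minus-strand rows are column-reversed so upstream is always left).
#' Bin `k` covers `[-flank + k*bin, -flank + (k+1)*bin)`; the TSS is the
#' left edge of the middle bin.
#'
#' @param reads Read tibble.
#' @param genes Gene table with `transcript_id`, `chrom`, `tss`, `strand`.
#' @param flank Half-width of the profiled region in bp.
#' @param bin Bin width in bp; must divide `flank`.
#' @param fragment_size Fragment extension length in bp.
#' @return An object of class `biv_profile_matrix`: a list with `matrix`
#'   (transcripts x bins, rownames = transcript ids), `offsets` (left edge
#'   of each bin relative to the TSS), `flank`, `bin`.
#' @export
tss_profile <- function(reads, genes, flank = 5000L, bin = 10L,
                        fragment_size = 200L) {
  stopifnot(flank %% bin == 0)
  n_bins <- as.integer(2L * flank / bin)
  mat <- matrix(
    0L, nrow = nrow(genes), ncol = n_bins,
    dimnames = list(genes$transcript_id, NULL)
  )
  offsets <- as.integer(seq(-flank, flank - bin, by = bin))
  if (nrow(reads) > 0L) {
    frags <- extend_fragments(reads, fragment_size)
    win <- tibble(
      chrom = genes$chrom,
      start = genes$tss - as.integer(flank),
      end = genes$tss + as.integer(flank)
    )
    h <- overlap_pairs(win, frags)
    if (nrow(h) > 0L) {
      w0 <- win$start[h$query]
      b0 <- pmax(0L, as.integer((frags$start[h$subject] - w0) %/% bin))
      b1 <- pmin(
        n_bins - 1L,
        as.integer((frags$end[h$subject] - 1L - w0) %/% bin)
      )
      ok <- b0 <= b1
      # difference-array accumulation (vectorized), then cumsum per row
      n_g <- nrow(genes)
      cells <- n_g * (n_bins + 1L)
      up <- tabulate(b0[ok] * n_g + h$query[ok], nbins = cells)
      dn <- tabulate((b1[ok] + 1L) * n_g + h$query[ok], nbins = cells)
      inc <- matrix(up - dn, nrow = n_g)
      mat <- t(apply(inc, 1L, cumsum))[, seq_len(n_bins), drop = FALSE]
      dimnames(mat) <- list(genes$transcript_id, NULL)
    }
  }
  flip <- which(genes$strand == "-")
  if (length(flip) > 0L) {
    mat[flip, ] <- mat[flip, rev(seq_len(n_bins)), drop = FALSE]
  }
  structure(
    list(matrix = mat, offsets = offsets, flank = as.integer(flank), bin = as.integer(bin)),
    class = "biv_profile_matrix"
  )
}

#' @export
print.biv_profile_matrix <- function(x, ...) {
  cat(sprintf(
    "<biv_profile_matrix> %d transcripts x %d bins of %d bp ([-%d, %d))\n",
    nrow(x$matrix), ncol(x$matrix), x$bin, x$flank, x$flank
  ))
  invisible(x)
}

#' @export
tidy.biv_profile_matrix <- function(x, ...) {
  as_tibble(x$matrix, .name_repair = ~ as.character(x$offsets)) |>
    mutate(transcript_id = rownames(x$matrix)) |>
    tidyr::pivot_longer(-"transcript_id",
      names_to = "offset", values_to = "coverage",
      names_transform = as.integer
    )
}

#' Average profile over a subset of transcripts
#'
#' Per-bin arithmetic mean of the coverage matrix over the given rows.
#'
#' @param profile A [tss_profile()] result.
#' @param subset Character vector of transcript ids (default: all rows).
#' @return A tibble of class `biv_profile`: `offset`, `value`.
#' @export
average_profile <- function(profile, subset = NULL) {
  m <- profile$matrix
  if (!is.null(subset)) {
    miss <- setdiff(subset, rownames(m))
    if (length(miss) > 0L) {
      abort(sprintf("unknown transcript id(s): %s", paste(utils::head(miss, 3), collapse = ", ")))
    }
    m <- m[subset, , drop = FALSE]
  }
  if (nrow(m) == 0L) {
    abort("cannot average over an empty subset")
  }
  structure(
    tibble(offset = profile$offsets, value = colMeans(m)),
    class = c("biv_profile", class(tibble())),
    bin = profile$bin
  )
}

#' Normalize an average ChIP profile to the matching input profile
#'
#' Element-wise ratio `(chip + pseudocount) / (input + pseudocount)` of two
#' averaged profiles over the same bins (ratio of category means, not mean
#' of per-gene ratios). Sparse tracks such as sequential ChIP yield ratios
#' below 1 genome-wide; the shape, not the absolute level, is informative.
#'
#' @param avg_chip,avg_input `biv_profile` tibbles (`offset`, `value`) on
#'   identical bins.
#' @param pseudocount Small constant keeping zero-input bins finite.
#' @return A `biv_profile` tibble: `offset`, `value` (the ratio).
#' @export
normalize_to_input <- function(avg_chip, avg_input, pseudocount = 0.5) {
  if (nrow(avg_chip) != nrow(avg_input) ||
    !all(avg_chip$offset == avg_input$offset)) {
    abort("chip and input profiles must share identical bins")
  }
  structure(
    tibble(
      offset = avg_chip$offset,
      value = (avg_chip$value + pseudocount) / (avg_input$value + pseudocount)
    ),
    class = c("biv_profile", class(tibble())),
    bin = attr(avg_chip, "bin")
  )
}

#' @export
autoplot.biv_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset, y = .data$value)) +
    ggplot2::geom_line(...) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "distance from TSS (bp)", y = "average coverage") +
    ggplot2::theme_minimal()
}

# Mean per-base fragment depth over arbitrary intervals of one chromosome,
# via run-length coverage of the extended fragments.
interval_mean_depth <- function(frags_chrom, starts, ends, chrom_len) {
  cov <- IRanges::coverage(
    IRanges::IRanges(start = frags_chrom$start + 1L, end = frags_chrom$end),
    width = chrom_len
  )
  v <- IRanges::Views(cov, start = starts + 1L, end = ends)
  IRanges::viewMeans(v)
}

#' Size-scaled enhancer coverage profile
#'
#' Each enhancer body is divided into `n_intervals` equal-width intervals;
#' mean per-base fragment depth is computed per interval, and at 10-bp
#' bins across the `flank` bp on either side. Profiles are averaged over
#' enhancers and, when an input read set is supplied, normalized to the
#' identically computed input profile.
#'
#' @param reads Read tibble.
#' @param enhancers Interval tibble (`chrom`, `start`, `end`).
#' @param genome Genome layout.
#' @param input_reads Optional input read tibble for normalization.
#' @param n_intervals Number of body intervals.
#' @param flank Flanking region width in bp.
#' @param bin Flank bin width in bp.
#' @param fragment_size Fragment extension in bp.
#' @param pseudocount Pseudo-count used in normalization.
#' @return Tibble of class `biv_profile`: `position` (bin label:
#'   `flank_left`, `body`, `flank_right`), `offset` (bin index across the
#'   concatenated profile), `value`.
#' @export
enhancer_profile <- function(reads, enhancers, genome, input_reads = NULL,
                             n_intervals = 10L, flank = 5000L, bin = 10L,
                             fragment_size = 200L, pseudocount = 0.5) {
  wide_enough <- (enhancers$end - enhancers$start) >= n_intervals
  if (!all(wide_enough)) {
    warn(sprintf(
      "skipping %d enhancer(s) narrower than %d bp",
      sum(!wide_enough), n_intervals
    ))
    enhancers <- enhancers[wide_enough, , drop = FALSE]
  }
  if (nrow(enhancers) == 0L) {
    abort("no enhancers wide enough to profile")
  }
  n_flank_bins <- as.integer(flank / bin)

  one_track <- function(rds) {
    frags <- extend_fragments(rds, fragment_size)
    acc <- matrix(0, nrow = nrow(enhancers), ncol = 2L * n_flank_bins + n_intervals)
    for (ch in unique(enhancers$chrom)) {
      ei <- which(enhancers$chrom == ch)
      fc <- frags[frags$chrom == ch, , drop = FALSE]
      clen <- genome$length[match(ch, genome$chrom)]
      fc$start <- pmax(fc$start, 0L)
      fc$end <- pmin(fc$end, clen)
      for (i in ei) {
        s <- enhancers$start[i]
        e <- enhancers$end[i]
        w <- e - s
        body_edges <- s + as.integer(floor((0:n_intervals) * w / n_intervals))
        left_edges <- seq(s - flank, s, by = bin)
        right_edges <- seq(e, e + flank, by = bin)
        starts <- c(
          utils::head(left_edges, -1), utils::head(body_edges, -1),
          utils::head(right_edges, -1)
        )
        ends <- c(left_edges[-1], body_edges[-1], right_edges[-1])
        keep <- starts >= 0L & ends <= clen
        vals <- rep(NA_real_, length(starts))
        if (any(keep)) {
          vals[keep] <- interval_mean_depth(fc, starts[keep], ends[keep], clen)
        }
        acc[i, ] <- vals
      }
    }
    colMeans(acc, na.rm = TRUE)
  }

  chip <- one_track(reads)
  value <- if (is.null(input_reads)) {
    chip
  } else {
    (chip + pseudocount) / (one_track(input_reads) + pseudocount)
  }
  pos <- c(
    rep("flank_left", n_flank_bins), rep("body", n_intervals),
    rep("flank_right", n_flank_bins)
  )
  structure(
    tibble(
      position = pos,
      offset = seq_along(value),
      value = value
    ),
    class = c("biv_profile", class(tibble())),
    bin = bin
  )
}

#' Random genomic intervals matched on width distribution
#'
#' Draws `n` intervals whose width multiset equals that of a sample of the
#' given enhancers, placed uniformly on the genome while avoiding
#' `exclusions`. Deterministic under `seed`.
#'
#' @param genome Genome layout.
#' @param enhancers Interval tibble whose widths are matched.
#' @param n Number of random intervals (widths are sampled with
#'   replacement if `n` exceeds the enhancer count, else without).
#' @param seed Integer seed.
#' @param exclusions Optional interval tibble the placements must avoid.
#' @param max_tries Retry bound per interval before erroring.
#' @return Interval tibble `chrom`, `start`, `end`, sorted.
#' @export
sample_matched_random <- function(genome, enhancers, n = 1000L, seed = 1L,
                                  exclusions = NULL, max_tries = 1000L) {
  widths <- enhancers$end - enhancers$start
  withr::with_seed(as.integer(seed), {
    ws <- sample(widths, n, replace = n > length(widths))
    out <- vector("list", n)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        ci <- sample.int(nrow(genome), 1L, prob = genome$length)
        maxs <- genome$length[ci] - ws[i]
        if (maxs < 1L) next
        s <- as.integer(floor(runif(1) * maxs))
        cand <- tibble(chrom = genome$chrom[ci], start = s, end = s + ws[i])
        if (!is.null(exclusions) &&
          nrow(overlap_pairs(cand, exclusions)) > 0L) {
          next
        }
        out[[i]] <- cand
        placed <- TRUE
        break
      }
      if (!placed) {
        abort(sprintf(
          "could not place interval %d of width %d after %d tries",
          i, ws[i], max_tries
        ))
      }
    }
    bind_rows(out) |> arrange(.data$chrom, .data$start)
  })
}
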