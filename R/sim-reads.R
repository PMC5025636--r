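# Read-set simulation: single ChIP, sequential ChIP, and MNase input.

# Shared emission engine: given per-nucleosome sampling weights plus a
# uniform background weight, draw ~depth reads and emit `read_len`-bp
# records from the 147-bp fragment 5' end on a random strand.
emit_reads <- function(states, weights, genome, config, stage_seed) {
  withr::with_seed(stage_seed, {
    bg_w <- config$bg_rate * sum(genome$length)
    sig_w <- sum(weights)
    tot_w <- bg_w + sig_w
    n_total <- if (tot_w > 0) rpois(1, config$depth) else 0L
    if (n_total == 0L) {
      return(empty_reads())
    }
    n_bg <- rbinom(1, n_total, bg_w / tot_w)
    n_sig <- n_total - n_bg

    frag <- empty_reads()
    if (n_sig > 0L) {
      pick <- sample.int(nrow(states), n_sig, replace = TRUE, prob = weights)
      frag <- tibble(
        chrom = states$chrom[pick],
        fs = states$start[pick],
        fe = states$end[pick]
      )
    }
    bg <- NULL
    if (n_bg > 0L) {
      ch <- sample.int(nrow(genome), n_bg, replace = TRUE, prob = genome$length)
      pos <- floor(runif(n_bg) * (genome$length[ch] - 147L))
      bg <- tibble(
        chrom = genome$chrom[ch],
        fs = as.integer(pos),
        fe = as.integer(pos + 147L)
      )
    }
    frags <- bind_rows(
      if (n_sig > 0L) frag else NULL,
      bg
    )
    strand <- sample(c("+", "-"), nrow(frags), replace = TRUE)
    rl <- config$read_len
    start <- ifelse(strand == "+", frags$fs, frags$fe - rl)
    end <- start + rl
    # clip to chromosome ends
    len <- genome$length[match(frags$chrom, genome$chrom)]
    start <- pmax(0L, pmin(as.integer(start), len - rl))
    end <- pmin(as.integer(end), len)
    tibble(
      chrom = frags$chrom, start = as.integer(start),
      end = as.integer(end), strand = strand
    ) |>
      arrange(.data$chrom, .data$start)
  })
}

#' Simulate a single-mark ChIP-seq read set
#'
#' Samples nucleosome copies carrying the requested mark with capture
#' efficiency `eps1`, plus a uniform background, and emits short single-end
#' reads from the fragment 5' end (the 147-bp nucleosome footprint) on a
#' random strand. The expected total record count is `config$depth`.
#'
#' @param states Nucleosome state table from [sample_chromatin_states()].
#' @param mark One of `"K4"`, `"K27"`, `"H2AZ"`.
#' @param config A [sim_config()].
#' @param genome Genome layout tibble (`chrom`, `length`).
#' @return A read tibble (`chrom`, `start`, `end`, `strand`), BED-sorted.
#' @export
simulate_chip <- function(states, mark, config, genome) {
  frac <- switch(mark,
    K4 = (states$n_both + states$n_k4only) / config$n_cells,
    K27 = (states$n_both + states$n_k27only) / config$n_cells,
    H2AZ = states$n_h2az / config$n_cells,
    abort(sprintf("unknown mark '%s' (expected K4, K27 or H2AZ)", mark))
  )
  emit_reads(
    states, config$eps1 * frac, genome, config,
    derive_seed(config$seed, paste0("chip_", mark))
  )
}

#' Simulate a sequential (re-)ChIP read set
#'
#' Models the H3K27me3-primary, H3K4me3-secondary immunoprecipitation:
#' copies carrying both marks are sampled with weight `eps1 * eps2`;
#' single-marked H3K4me3 copies leak through the primary IP with weight
#' `phi * eps2` (flow-through); H3K27me3-only and unmarked copies
#' contribute nothing beyond the uniform background.
#'
#' @inheritParams simulate_chip
#' @return A read tibble, BED-sorted.
#' @export
simulate_sequential_chip <- function(states, config, genome) {
  w <- config$eps1 * config$eps2 * states$n_both / config$n_cells +
    config$phi * config$eps2 * states$n_k4only / config$n_cells
  emit_reads(states, w, genome, config, derive_seed(config$seed, "seqchip"))
}

#' Simulate an MNase input read set
#'
#' Reads are sampled uniformly over occupied nucleosome copies regardless
#' of marks, so coverage dips inside the nucleosome-depleted region in
#' proportion to `1 - ndr_occupancy`.
#'
#' @inheritParams simulate_chip
#' @return A read tibble, BED-sorted.
#' @export
simulate_input <- function(states, config, genome) {
  if (nrow(states) == 0L) {
    return(empty_reads())
  }
  emit_reads(
    states, states$n_occ / config$n_cells, genome, config,
    derive_seed(config$seed, "input")
  )
}
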