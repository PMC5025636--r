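#' Sample per-cell nucleosome chromatin states around each TSS
#'
#' Tiles phased 147-bp nucleosomes `config$tile_flank` bp either side of
#' every TSS (one phase per promoter, the +1 nucleosome starting at the
#' TSS in transcription orientation) and samples, for a population of
#' `config$n_cells` cells, how many copies of each nucleosome are occupied
#' and which marks they carry.
#'
#' Mark logic by archetype:
#' * `bivalent`: occupied TSS-proximal copies carry both marks with
#'   probability `f_biv`; the remainder carry H3K4me3 alone with
#'   probability `het_k4_frac`, else H3K27me3 alone (cell-population
#'   heterogeneity). Non-proximal copies inside the K4 domain carry
#'   H3K4me3 only; copies in the rest of the (broader, upstream-shifted)
#'   K27 domain carry H3K27me3 only — zonal co-occurrence without
#'   mononucleosome co-occupancy.
#' * `K4_only` / `K27_only`: single-mark domains, every occupied copy
#'   in the domain marked.
#' * `silent_methylated` and `none`: no marks; silent promoters keep full
#'   nucleosome occupancy across the TSS.
#'
#' Occupancy is 1 everywhere except inside the NDR
#' (`[ndr_start, ndr_end)` downstream of the TSS) of bivalent and K4_only
#' promoters, where it is `ndr_occupancy`. H2A.Z is assigned to
#' TSS-proximal copies of CpG-island promoters with a logistic probability
#' increasing in expression rank.
#'
#' @param world A [build_world()] result.
#' @param config A [sim_config()]; defaults to the one stored in `world`.
#'
#' @return A tibble with one row per nucleosome position: `chrom`, `start`,
#'   `end` (147-bp footprint), `transcript_id`, `archetype`, `offset`
#'   (oriented footprint start relative to the TSS), `is_proximal`, and
#'   per-population copy counts `n_occ`, `n_both`, `n_k4only`, `n_k27only`,
#'   `n_h2az`.
#' @export
sample_chromatin_states <- function(world, config = world$config) {
  stopifnot(inherits(world, "biv_world"), inherits(config, "sim_config"))
  genes <- world$genes
  period <- config$nucleosome_len + config$linker_len
  n_tile <- config$tile_flank %/% period
  offsets <- (-n_tile:n_tile) * period # oriented footprint starts

  # expression-rank-based H2A.Z probability for CpG-island promoters
  erank <- (rank(genes$expression, ties.method = "first") - 0.5) / nrow(genes)
  p_h2az <- ifelse(
    !is.na(genes$cpg_density), plogis(6 * (erank - 0.5)), 0.02
  )

  withr::with_seed(derive_seed(config$seed, "states"), {
    per_gene <- purrr::map(seq_len(nrow(genes)), function(k) {
      g <- genes[k, ]
      sgn <- if (g$strand == "+") 1L else -1L
      # genomic footprint start for oriented offset u: [u, u+147) oriented
      gstart <- if (sgn == 1L) g$tss + offsets else g$tss - offsets - 147L
      keep <- gstart >= 0L & gstart + 147L <= world$genome$length[
        match(g$chrom, world$genome$chrom)
      ]
      u <- offsets[keep]
      gstart <- gstart[keep]
      nn <- length(u)

      proximal <- (u + 147L) > -config$proximal_halfwin &
        u < config$proximal_halfwin
      in_ndr <- (u + 147L) > config$ndr_start & u < config$ndr_end
      half4 <- g$k4_span %/% 2L
      in_d4 <- (u + 147L) > -half4 & u < half4
      up27 <- g$k27_span - g$k27_down
      in_d27 <- switch(g$archetype,
        bivalent = (u + 147L) > -up27 & u < g$k27_down,
        K27_only = (u + 147L) > -(g$k27_span %/% 2L) & u < g$k27_span %/% 2L,
        rep(FALSE, nn)
      )

      occ_p <- rep(1, nn)
      if (g$archetype %in% c("bivalent", "K4_only")) {
        occ_p[in_ndr] <- config$ndr_occupancy
      }
      n_occ <- rbinom(nn, config$n_cells, occ_p)

      n_both <- integer(nn)
      n_k4 <- integer(nn)
      n_k27 <- integer(nn)
      if (g$archetype == "bivalent") {
        pr <- which(proximal)
        n_both[pr] <- rbinom(length(pr), n_occ[pr], config$f_biv)
        rest <- n_occ[pr] - n_both[pr]
        n_k4[pr] <- rbinom(length(pr), rest, config$het_k4_frac)
        n_k27[pr] <- rest - n_k4[pr]
        zon4 <- which(in_d4 & !proximal)
        n_k4[zon4] <- n_occ[zon4]
        zon27 <- which(in_d27 & !in_d4 & !proximal)
        n_k27[zon27] <- n_occ[zon27]
      } else if (g$archetype == "K4_only") {
        zon <- which(in_d4 | proximal)
        n_k4[zon] <- n_occ[zon]
      } else if (g$archetype == "K27_only") {
        zon <- which(in_d27)
        n_k27[zon] <- n_occ[zon]
      }

      n_h2az <- integer(nn)
      pr <- which(proximal)
      n_h2az[pr] <- rbinom(length(pr), n_occ[pr], p_h2az[k])

      tibble(
        chrom = g$chrom,
        start = as.integer(gstart),
        end = as.integer(gstart + 147L),
        transcript_id = g$transcript_id,
        archetype = g$archetype,
        offset = as.integer(u),
        is_proximal = proximal,
        n_occ = n_occ, n_both = n_both,
        n_k4only = n_k4, n_k27only = n_k27, n_h2az = n_h2az
      )
    })
    bind_rows(per_gene) |> arrange(.data$chrom, .data$start)
  })
}
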