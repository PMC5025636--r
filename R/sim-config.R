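#' Simulation configuration for the cell-population chromatin model
#'
#' Collects every knob of the synthetic-data generator: how many cells the
#' simulated population has, nucleosome geometry, the nucleosome-depleted
#' region (NDR), the fraction of TSS-proximal nucleosome copies that are
#' truly bivalent, zonal mark-domain geometry, IP capture efficiencies,
#' primary-IP flow-through, background rate and sequencing depth.
#'
#' The model distinguishes *zonal* bivalency (overlapping H3K4me3 and
#' H3K27me3 domains whose individual nucleosome copies carry only one mark)
#' from *mononucleosome* bivalency (both marks on the same copy), which
#' exists only on TSS-proximal nucleosomes at rate `f_biv`. Cells that do
#' not carry the bivalent configuration carry one of the two marks instead
#' (population heterogeneity), split by `het_k4_frac`.
#'
#' @param n_cells Number of cells in the simulated population.
#' @param nucleosome_len Nucleosome footprint, fixed at 147 bp.
#' @param linker_len Linker length in bp; nucleosome phasing period is
#'   `nucleosome_len + linker_len`.
#' @param ndr_start,ndr_end NDR interval in bp relative to the TSS
#'   (transcription-oriented; positive = downstream).
#' @param ndr_occupancy Probability that a nucleosome inside the NDR is
#'   present in a given cell (applies to bivalent and K4_only archetypes;
#'   silent promoters keep full occupancy).
#' @param f_biv Fraction of occupied TSS-proximal nucleosome copies carrying
#'   both H3K4me3 and H3K27me3 at bivalent-archetype promoters.
#' @param het_k4_frac Among non-bivalent TSS-proximal copies at bivalent
#'   promoters, the fraction carrying H3K4me3 (the rest carry H3K27me3).
#' @param zonal_k4_span Length-2 range (bp) from which each gene's H3K4me3
#'   domain width is drawn; the domain is centred on the TSS.
#' @param zonal_k27_extra Length-2 range (bp) added to the K4 width to give
#'   the H3K27me3 domain width, so K27 domains are systematically broader.
#' @param k27_downstream_pad Length-2 range (bp): the K27 domain extends this
#'   far past the downstream edge of the K4 domain; the remainder of its
#'   width lies upstream, producing the upstream-shifted asymmetric K27
#'   distribution.
#' @param proximal_halfwin Nucleosomes whose footprint intersects
#'   `TSS +/- proximal_halfwin` are "TSS-proximal" and subject to the
#'   bivalency/heterogeneity logic.
#' @param tile_flank Nucleosomes are tiled this many bp either side of each
#'   TSS.
#' @param eps1,eps2 Capture efficiencies of the primary and secondary IP.
#' @param phi Flow-through rate: relative weight with which single-marked
#'   H3K4me3 copies are carried through the primary anti-H3K27me3 IP into
#'   the sequential ChIP.
#' @param bg_rate Background sampling weight per bp (on the scale of
#'   per-cell copy fractions); the uniform-Poisson null the island caller
#'   assumes.
#' @param depth Expected number of reads per track.
#' @param read_len Emitted read length (bp), from the fragment 5' end.
#' @param seed Integer master seed; all simulator randomness derives from it.
#'
#' @return An object of class `sim_config` (a named list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, depth = 1e4)
#' cfg$f_biv
sim_config <- function(n_cells = 1000L,
                       nucleosome_len = 147L,
                       linker_len = 53L,
                       ndr_start = 0L,
                       ndr_end = 800L,
                       ndr_occupancy = 0.75,
                       f_biv = 0.8,
                       het_k4_frac = 0.5,
                       zonal_k4_span = c(1000L, 4000L),
                       zonal_k27_extra = c(2500L, 4500L),
                       k27_downstream_pad = c(300L, 800L),
                       proximal_halfwin = 100L,
                       tile_flank = 8000L,
                       eps1 = 0.8,
                       eps2 = 0.8,
                       phi = 0,
                       bg_rate = 1e-4,
                       depth = 2e5,
                       read_len = 36L,
                       seed = 1L) {
  if (nucleosome_len != 147L) {
    abort("nucleosome_len is fixed at 147 bp (mononucleosome footprint)")
  }
  stopifnot(
    n_cells >= 1, linker_len >= 0,
    ndr_occupancy >= 0, ndr_occupancy <= 1,
    f_biv >= 0, f_biv <= 1,
    het_k4_frac >= 0, het_k4_frac <= 1,
    length(zonal_k4_span) == 2, diff(zonal_k4_span) >= 0,
    length(zonal_k27_extra) == 2, length(k27_downstream_pad) == 2,
    eps1 > 0, eps1 <= 1, eps2 > 0, eps2 <= 1,
    phi >= 0, phi < 1,
    bg_rate >= 0, depth >= 0, read_len >= 1
  )
  structure(
    list(
      n_cells = as.integer(n_cells),
      nucleosome_len = 147L,
      linker_len = as.integer(linker_len),
      ndr_start = as.integer(ndr_start),
      ndr_end = as.integer(ndr_end),
      ndr_occupancy = ndr_occupancy,
      f_biv = f_biv,
      het_k4_frac = het_k4_frac,
      zonal_k4_span = as.integer(zonal_k4_span),
      zonal_k27_extra = as.integer(zonal_k27_extra),
      k27_downstream_pad = as.integer(k27_downstream_pad),
      proximal_halfwin = as.integer(proximal_halfwin),
      tile_flank = as.integer(tile_flank),
      eps1 = eps1,
      eps2 = eps2,
      phi = phi,
      bg_rate = bg_rate,
      depth = depth,
      read_len = as.integer(read_len),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf(
    "  cells: %d | f_biv: %.2f | phi: %.2f | eps1/eps2: %.2f/%.2f\n",
    x$n_cells, x$f_biv, x$phi, x$eps1, x$eps2
  ))
  cat(sprintf(
    "  NDR: [%d,%d) occ %.2f | depth: %g | seed: %d\n",
    x$ndr_start, x$ndr_end, x$ndr_occupancy, x$depth, x$seed
  ))
  invisible(x)
}
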