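#' Build a miniature genome, gene models, CpG islands and enhancers
#'
#' Lays out `n_genes` promoters on a small multi-chromosome genome with a
#' guaranteed minimum TSS spacing, assigns each gene an archetype
#' (`bivalent`, `K4_only`, `K27_only`, `silent_methylated`, `none`), draws
#' per-gene zonal mark-domain geometry, expression values, CpG islands
#' (at bivalent, K4_only and silent_methylated promoters), a methylation
#' probe table, and intergenic enhancers, a configurable fraction of which
#' contain a CpG island.
#'
#' All coordinates are 0-based half-open. The result is deterministic for a
#' given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param n_genes Number of genes (one transcript per gene by default).
#' @param n_enhancers Number of intergenic enhancer intervals.
#' @param archetype_mix Named proportions over archetypes; need not sum to 1
#'   (normalized internally).
#' @param spacing Distance in bp between consecutive TSSs on a chromosome.
#'   Must be at least twice `config$tile_flank` plus the widest possible K27
#'   domain so neighbouring islands can never merge.
#' @param cpg_enhancer_frac Fraction of enhancers that receive a CpG island.
#' @param n_chroms Number of chromosomes over which genes are spread.
#'
#' @return A list of class `biv_world` with elements `genome` (chrom,
#'   length), `genes`, `cpg_islands`, `enhancers`, `expression`,
#'   `methylation`, and the `config` used.
#' @export
#' @examples
#' w <- build_world(sim_config(seed = 7), n_genes = 8, n_enhancers = 4)
#' dplyr::count(w$genes, archetype)
build_world <- function(config,
                        n_genes = 200L,
                        n_enhancers = 200L,
                        archetype_mix = c(
                          bivalent = 1, K4_only = 1,
                          K27_only = 1, silent_methylated = 1
                        ),
                        spacing = 30000L,
                        cpg_enhancer_frac = 0.3,
                        n_chroms = 4L) {
  stopifnot(inherits(config, "sim_config"), n_genes >= 1)
  max_k27 <- max(config$zonal_k4_span) + max(config$zonal_k27_extra)
  min_spacing <- 2L * max(config$tile_flank, max_k27)
  if (spacing < min_spacing) {
    abort(sprintf(
      "spacing %d too small: need >= %d so neighbouring domains cannot merge",
      spacing, min_spacing
    ))
  }
  known <- c("bivalent", "K4_only", "K27_only", "silent_methylated", "none")
  if (!all(names(archetype_mix) %in% known)) {
    abort(paste(
      "archetype_mix names must be among:", paste(known, collapse = ", ")
    ))
  }

  withr::with_seed(derive_seed(config$seed, "world"), {
    margin <- 20000L
    per_chrom <- ceiling(n_genes / n_chroms)
    chrom_len <- 2L * margin + per_chrom * spacing
    genome <- tibble(
      chrom = sprintf("chr%d", seq_len(n_chroms)),
      length = chrom_len
    )

    # archetype counts by largest remainder, then shuffled
    p <- archetype_mix / sum(archetype_mix)
    cnt <- floor(p * n_genes)
    rem <- n_genes - sum(cnt)
    if (rem > 0) {
      extra <- order(p * n_genes - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[extra] <- cnt[extra] + 1L
    }
    archetypes <- sample(rep(names(cnt), times = cnt))

    idx <- seq_len(n_genes) - 1L
    chrom_i <- idx %/% per_chrom + 1L
    slot_i <- idx %% per_chrom
    w4 <- round(runif(n_genes, config$zonal_k4_span[1], config$zonal_k4_span[2]))
    w27 <- w4 + round(runif(
      n_genes, config$zonal_k27_extra[1], config$zonal_k27_extra[2]
    ))
    k27_down <- round(w4 / 2) + round(runif(
      n_genes, config$k27_downstream_pad[1], config$k27_downstream_pad[2]
    ))
    expr_mean <- c(
      bivalent = 6, K4_only = 10, K27_only = 4.5,
      silent_methylated = 3.5, none = 7
    )
    genes <- tibble(
      gene_id = sprintf("g%04d", seq_len(n_genes)),
      transcript_id = sprintf("t%04d", seq_len(n_genes)),
      chrom = genome$chrom[chrom_i],
      tss = as.integer(margin + slot_i * spacing + round(runif(n_genes, 0, 2000))),
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      archetype = archetypes,
      expression = rnorm(n_genes, mean = expr_mean[archetypes], sd = 0.8),
      k4_span = as.integer(w4),
      k27_span = as.integer(w27),
      k27_down = as.integer(k27_down)
    )

    # CpG islands at bivalent / K4_only / silent_methylated promoters
    has_cpg <- genes$archetype %in% c("bivalent", "K4_only", "silent_methylated")
    gi <- which(has_cpg)
    cpg_w <- round(runif(length(gi), 600, 1500))
    cpg_center <- genes$tss[gi] + round(runif(length(gi), -300, 300))
    dens_rng <- list(
      bivalent = c(0.08, 0.12), K4_only = c(0.05, 0.10),
      silent_methylated = c(0.06, 0.10)
    )
    dens <- purrr::map_dbl(seq_along(gi), function(k) {
      r <- dens_rng[[genes$archetype[gi[k]]]]
      runif(1, r[1], r[2])
    })
    cpg_prom <- tibble(
      chrom = genes$chrom[gi],
      start = as.integer(pmax(0, cpg_center - cpg_w %/% 2L)),
      end = as.integer(cpg_center + cpg_w %/% 2L),
      density = dens
    )
    genes$cpg_density <- NA_real_
    genes$cpg_density[gi] <- dens

    # enhancers midway between promoters, never inside promoter windows
    enh_slot <- sample(seq_len(n_chroms * per_chrom) - 1L, n_enhancers,
      replace = n_enhancers > n_chroms * per_chrom
    )
    enh_chrom_i <- enh_slot %/% per_chrom + 1L
    enh_w <- round(runif(n_enhancers, 200, 2000))
    enh_center <- margin + (enh_slot %% per_chrom) * spacing +
      spacing %/% 2L + round(runif(n_enhancers, -2000, 2000))
    enh_has_cpg <- runif(n_enhancers) < cpg_enhancer_frac
    enhancers <- tibble(
      chrom = genome$chrom[enh_chrom_i],
      start = as.integer(enh_center - enh_w %/% 2L),
      end = as.integer(enh_center + enh_w %/% 2L),
      name = sprintf("enh%04d", seq_len(n_enhancers)),
      has_cpg = enh_has_cpg
    )
    enh_cpg <- enhancers |>
      filter(.data$has_cpg) |>
      mutate(
        width = .data$end - .data$start,
        cw = pmin(.data$width, as.integer(round(runif(n(), 200, 800)))),
        cs = .data$start + (.data$width - .data$cw) %/% 2L
      )
    cpg_enh <- tibble(
      chrom = enh_cpg$chrom,
      start = as.integer(enh_cpg$cs),
      end = as.integer(enh_cpg$cs + enh_cpg$cw),
      density = runif(nrow(enh_cpg), 0.04, 0.09)
    )
    cpg_islands <- bind_rows(cpg_prom, cpg_enh) |>
      arrange(.data$chrom, .data$start)

    # methylation probe table: silent promoters hypermethylated by design
    meth <- purrr::map_dfr(seq_len(n_genes), function(k) {
      silent <- genes$archetype[k] == "silent_methylated"
      b1 <- if (silent) runif(1, 0.8, 0.95) else runif(1, 0.02, 0.2)
      b2 <- if (silent) runif(1, 0.5, 0.9) else runif(1, 0.02, 0.2)
      tibble(
        transcript_id = genes$transcript_id[k],
        probe_id = sprintf("p%04d_%d", k, 1:2),
        beta = c(b1, b2),
        detect_p = c(runif(1, 0.0005, 0.02), runif(1, 0, 0.1))
      )
    })

    expression <- genes |> select(all_of(c("gene_id", "transcript_id", "expression")))

    structure(
      list(
        genome = genome, genes = genes, cpg_islands = cpg_islands,
        enhancers = enhancers, expression = expression, methylation = meth,
        config = config
      ),
      class = "biv_world"
    )
  })
}

#' @export
print.biv_world <- function(x, ...) {
  cat(sprintf(
    "<biv_world> %d chrom(s), %d genes, %d CpG islands, %d enhancers\n",
    nrow(x$genome), nrow(x$genes), nrow(x$cpg_islands), nrow(x$enhancers)
  ))
  invisible(x)
}
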