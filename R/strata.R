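#' Stratification parameters
#'
#' @param cpg_radius CpG islands within `+/- cpg_radius` bp of a TSS define
#'   CpG-island promoters.
#' @param n_quantiles Number of rank groups (quintiles).
#' @param beta_methylated A promoter with at least one surviving probe at
#'   beta >= this threshold is methylated.
#' @param beta_unmethylated A promoter whose surviving probes are all below
#'   this threshold is unmethylated.
#' @param detect_p_max Probes with detection p-value above this are dropped.
#' @return A `strata_params` list.
#' @export
strata_params <- function(cpg_radius = 1500L, n_quantiles = 5L,
                          beta_methylated = 0.75, beta_unmethylated = 0.25,
                          detect_p_max = 0.05) {
  stopifnot(
    cpg_radius > 0, n_quantiles >= 2,
    beta_unmethylated > 0, beta_unmethylated < beta_methylated,
    beta_methylated < 1, detect_p_max > 0, detect_p_max <= 1
  )
  structure(
    list(
      cpg_radius = as.integer(cpg_radius),
      n_quantiles = as.integer(n_quantiles),
      beta_methylated = beta_methylated,
      beta_unmethylated = beta_unmethylated,
      detect_p_max = detect_p_max
    ),
    class = "strata_params"
  )
}

#' CpG-island status per promoter
#'
#' A transcript is a CpG-island promoter iff any CpG island intersects
#' `[tss - cpg_radius, tss + cpg_radius)` (half-open); its density is the
#' maximum over intersecting islands. A transcript *without* an island
#' whose sibling transcript (same `gene_id`) *has* one is removed from the
#' analysis; single-transcript genes without islands are `non_cpg`.
#'
#' @param genes Gene table with `gene_id`, `transcript_id`, `chrom`, `tss`.
#' @param cpg_islands CpG island tibble (`chrom`, `start`, `end`,
#'   `density`).
#' @param params A [strata_params()].
#' @return Tibble `transcript_id`, `status` (`cpg`, `non_cpg`, `removed`),
#'   `cpg_density` (NA unless `cpg`).
#' @export
assign_cpg_status <- function(genes, cpg_islands, params = strata_params()) {
  assert_cols(genes, c("gene_id", "transcript_id", "chrom", "tss"), "genes")
  win <- tibble(
    chrom = genes$chrom,
    start = pmax(0L, genes$tss - params$cpg_radius),
    end = genes$tss + params$cpg_radius
  )
  h <- overlap_pairs(win, cpg_islands)
  dens <- rep(NA_real_, nrow(genes))
  if (nrow(h) > 0L) {
    agg <- tibble(q = h$query, d = cpg_islands$density[h$subject]) |>
      group_by(.data$q) |>
      summarise(d = max(.data$d), .groups = "drop")
    dens[agg$q] <- agg$d
  }
  res <- tibble(
    gene_id = genes$gene_id,
    transcript_id = genes$transcript_id,
    has_island = !is.na(dens),
    cpg_density = dens
  ) |>
    group_by(.data$gene_id) |>
    mutate(sibling_has = any(.data$has_island)) |>
    ungroup() |>
    mutate(status = dplyr::case_when(
      .data$has_island ~ "cpg",
      .data$sibling_has ~ "removed",
      TRUE ~ "non_cpg"
    )) |>
    select(all_of(c("transcript_id", "status", "cpg_density")))
  res$cpg_density[res$status != "cpg"] <- NA_real_
  res
}

#' Rank-based quantile groups
#'
#' Assigns ids to `n_quantiles` equal-size rank groups (sizes differing by
#' at most 1, with the larger groups at the low end — largest remainder to
#' the lowest groups). Ties are broken by stable id order. Group 1 holds
#' the lowest values.
#'
#' @param values Tibble with columns `id` and `value` (or a named numeric
#'   vector).
#' @param n_quantiles Number of groups.
#' @return Tibble `id`, `value`, `group` (integer 1..n).
#' @export
#' @examples
#' quantile_groups(tibble::tibble(id = letters[1:10], value = 1:10), 5)
quantile_groups <- function(values, n_quantiles = 5L) {
  if (is.numeric(values) && !is.null(names(values))) {
    values <- tibble(id = names(values), value = unname(values))
  }
  assert_cols(values, c("id", "value"), "values")
  n <- nrow(values)
  if (dplyr::n_distinct(values$id) < n_quantiles) {
    abort(sprintf("need at least %d distinct ids, got %d", n_quantiles, n))
  }
  base <- n %/% n_quantiles
  rem <- n %% n_quantiles
  sizes <- base + as.integer(seq_len(n_quantiles) <= rem)
  ord <- order(values$value, values$id)
  grp <- integer(n)
  grp[ord] <- rep(seq_len(n_quantiles), times = sizes)
  values |> mutate(group = grp)
}

#' Methylation class per promoter
#'
#' Probes with `detect_p` above `params$detect_p_max` are dropped. A
#' promoter is `methylated` iff any surviving probe has
#' `beta >= beta_methylated`; else `unmethylated` iff all surviving betas
#' are below `beta_unmethylated`; else `ambiguous`. Promoters with no
#' surviving probes are `no_data`.
#'
#' @param meth Methylation probe tibble: `transcript_id`, `probe_id`,
#'   `beta`, `detect_p`.
#' @param params A [strata_params()].
#' @return Tibble `transcript_id`, `meth_class`.
#' @export
methylation_classes <- function(meth, params = strata_params()) {
  assert_cols(meth, c("transcript_id", "beta", "detect_p"), "methylation table")
  stopifnot(all(meth$beta >= 0 & meth$beta <= 1))
  meth |>
    group_by(.data$transcript_id) |>
    summarise(
      n_pass = sum(.data$detect_p <= params$detect_p_max),
      any_meth = any(.data$beta >= params$beta_methylated &
        .data$detect_p <= params$detect_p_max),
      all_unmeth = all(.data$beta[.data$detect_p <= params$detect_p_max] <
        params$beta_unmethylated),
      .groups = "drop"
    ) |>
    mutate(meth_class = dplyr::case_when(
      .data$n_pass == 0L ~ "no_data",
      .data$any_meth ~ "methylated",
      .data$all_unmeth ~ "unmethylated",
      TRUE ~ "ambiguous"
    )) |>
    select(all_of(c("transcript_id", "meth_class")))
}

#' Expression quintiles per gene
#'
#' One value per gene (maximum over probes when several rows share a
#' gene), delegated to [quantile_groups()] with `n_quantiles` groups.
#'
#' @param expr Tibble with `gene_id` and `expression` (log2 intensities).
#' @param n_quantiles Number of groups (5 for quintiles).
#' @return Tibble `id` (gene id), `value`, `group` (1 = lowest expression).
#' @export
expression_quintiles <- function(expr, n_quantiles = 5L) {
  assert_cols(expr, c("gene_id", "expression"), "expression table")
  per_gene <- expr |>
    group_by(.data$gene_id) |>
    summarise(value = max(.data$expression), .groups = "drop") |>
    dplyr::rename(id = "gene_id")
  quantile_groups(per_gene, n_quantiles)
}

#' Split enhancers by CpG-island overlap
#'
#' @param enhancers Interval tibble.
#' @param cpg_islands CpG island tibble.
#' @return Input tibble with logical column `with_cpg` (>= 1 bp
#'   intersection, half-open semantics).
#' @export
enhancer_cpg_split <- function(enhancers, cpg_islands) {
  h <- overlap_pairs(enhancers, cpg_islands)
  enhancers |> mutate(with_cpg = seq_len(n()) %in% h$query)
}
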