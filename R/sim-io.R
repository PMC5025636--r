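# On-disk representation of a simulated world: plain TSV/BED/YAML.

#' Write simulated world (and optional read sets) to a directory
#'
#' Emits `genes.tsv`, `cpg.bed`, `enhancers.bed`, `expression.tsv`,
#' `methylation.tsv`, a YAML echo of the simulation config
#' (`sim_config.yml`), and one `reads_<track>.bed` per supplied read set.
#' BED records are sorted by (chrom, start); all coordinates 0-based
#' half-open. Files round-trip losslessly through [read_world_tables()] /
#' [load_reads()].
#'
#' @param world A [build_world()] result.
#' @param outdir Output directory (created if needed).
#' @param reads Optional named list of read tibbles, e.g.
#'   `list(k4 = ..., k27 = ..., seqchip = ..., input = ...)`.
#' @return `outdir`, invisibly.
#' @export
emit_tables <- function(world, outdir, reads = NULL) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory: %s", outdir))
  }
  p <- function(f) file.path(outdir, f)
  readr::write_tsv(world$genome, p("genome.tsv"), progress = FALSE)
  readr::write_tsv(world$genes, p("genes.tsv"), progress = FALSE)
  readr::write_tsv(world$expression, p("expression.tsv"), progress = FALSE)
  readr::write_tsv(world$methylation, p("methylation.tsv"), progress = FALSE)
  cpg <- world$cpg_islands |> arrange(.data$chrom, .data$start)
  readr::write_tsv(
    cpg |> mutate(name = sprintf("cpg%04d", row_number()), score = .data$density) |>
      select(all_of(c("chrom", "start", "end", "name", "score"))),
    p("cpg.bed"),
    col_names = FALSE, progress = FALSE
  )
  enh <- world$enhancers |> arrange(.data$chrom, .data$start)
  readr::write_tsv(
    enh |> select(all_of(c("chrom", "start", "end", "name"))),
    p("enhancers.bed"),
    col_names = FALSE, progress = FALSE
  )
  yaml::write_yaml(unclass(world$config), p("sim_config.yml"))
  for (nm in names(reads)) {
    write_bed(reads[[nm]], p(sprintf("reads_%s.bed", nm)))
  }
  invisible(outdir)
}

#' Read back world tables written by [emit_tables()]
#'
#' @param dir Directory written by [emit_tables()].
#' @return A list with `genome`, `genes`, `expression`, `methylation`,
#'   `cpg_islands`, `enhancers`.
#' @export
read_world_tables <- function(dir) {
  p <- function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) abort(sprintf("missing table: %s", path))
    path
  }
  genome <- readr::read_tsv(p("genome.tsv"), show_col_types = FALSE, progress = FALSE)
  genes <- readr::read_tsv(p("genes.tsv"), show_col_types = FALSE, progress = FALSE)
  cpg <- readr::read_tsv(
    p("cpg.bed"),
    col_names = c("chrom", "start", "end", "name", "density"),
    show_col_types = FALSE, progress = FALSE
  )
  enh <- readr::read_tsv(
    p("enhancers.bed"),
    col_names = c("chrom", "start", "end", "name"),
    show_col_types = FALSE, progress = FALSE
  )
  list(
    genome = genome,
    genes = genes,
    expression = readr::read_tsv(p("expression.tsv"), show_col_types = FALSE, progress = FALSE),
    methylation = readr::read_tsv(p("methylation.tsv"), show_col_types = FALSE, progress = FALSE),
    cpg_islands = cpg |> select(-all_of("name")),
    enhancers = enh
  )
}
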