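#' Demo pipeline configuration
#'
#' A self-contained configuration reproducing the package's reference
#' scenario: 200 promoters split evenly over the four archetypes,
#' 2e5 reads per track, `f_biv = 0.8`, no flow-through, island calling
#' against the simulated input, promoter classification at +/-2500 bp.
#'
#' @param seed Master seed for the run.
#' @param n_genes,depth Overrides for quick runs.
#' @return A named list of class `run_config`.
#' @export
demo_config <- function(seed = 1L, n_genes = 200L, depth = 2e5) {
  structure(
    list(
      sim = sim_config(seed = seed, depth = depth, f_biv = 0.8, phi = 0),
      n_genes = as.integer(n_genes),
      n_enhancers = 100L,
      archetype_mix = c(
        bivalent = 1, K4_only = 1, K27_only = 1, silent_methylated = 1
      ),
      dedup = FALSE,
      redundancy_threshold = 1L,
      radius = 2500L,
      flank = 5000L,
      bin = 10L,
      fragment_size = 200L,
      pseudocount = 0.5,
      fdr_q = 0.01,
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Save / load a run configuration as YAML
#'
#' @param config A `run_config` list.
#' @param path YAML file path.
#' @return `path` (save) or the `run_config` (load).
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  x$archetype_mix <- as.list(x$archetype_mix)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  x <- yaml::read_yaml(path)
  x$sim <- do.call(sim_config, x$sim)
  x$archetype_mix <- unlist(x$archetype_mix)
  structure(x, class = "run_config")
}

#' Run the full simulate-call-classify-stratify-profile pipeline
#'
#' Orchestrates the package end to end on simulated data: builds the
#' world, samples chromatin states, simulates the H3K4me3, H3K27me3,
#' H2A.Z, sequential-ChIP and input tracks, optionally removes redundant
#' reads, calls islands per mark against the input, classifies promoters,
#' computes stratifications and input-normalized TSS profiles per class,
#' and writes every artefact plus a `summary.json` and a `manifest.yml`
#' to `outdir`. Reruns with the same config are byte-identical.
#'
#' @param config A [demo_config()]-style `run_config`.
#' @param outdir Output directory.
#' @param quiet Suppress progress messages.
#' @return A list with the in-memory results (`world`, `islands`,
#'   `classes`, `strata`, `profiles`, `summary`), invisibly.
#' @export
run_pipeline <- function(config = demo_config(), outdir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(format(Sys.time(), "%H:%M:%S "), sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  say("simulate: building world (%d genes)", config$n_genes)
  world <- stage("simulate", build_world(
    config$sim,
    n_genes = config$n_genes, n_enhancers = config$n_enhancers,
    archetype_mix = config$archetype_mix
  ))
  states <- stage("simulate", sample_chromatin_states(world))
  reads <- stage("simulate", list(
    k4 = simulate_chip(states, "K4", world$config, world$genome),
    k27 = simulate_chip(states, "K27", world$config, world$genome),
    h2az = simulate_chip(states, "H2AZ", world$config, world$genome),
    seqchip = simulate_sequential_chip(states, world$config, world$genome),
    input = simulate_input(states, world$config, world$genome)
  ))

  if (isTRUE(config$dedup)) {
    say("filter: redundancy threshold %d", config$redundancy_threshold)
    reads <- stage("filter", purrr::map(
      reads, filter_redundant, redundancy_threshold = config$redundancy_threshold
    ))
  }
  emit_tables(world, outdir, reads = reads)

  say("call-islands: K4 (gap 600), K27 (gap 1000), H2AZ")
  islands <- stage("call-islands", list(
    k4 = call_islands(reads$k4, world$genome, k4_params(fdr_q = config$fdr_q),
      control_reads = reads$input
    ),
    k27 = call_islands(reads$k27, world$genome, k27_params(fdr_q = config$fdr_q),
      control_reads = reads$input
    ),
    h2az = call_islands(reads$h2az, world$genome, k4_params(fdr_q = config$fdr_q),
      control_reads = reads$input
    )
  ))
  for (nm in names(islands)) {
    isl <- islands[[nm]]
    write_bed(
      tibble(
        chrom = isl$chrom, start = isl$start, end = isl$end,
        name = isl$island_id,
        score = pmin(1000, round(-10 * log10(pmax(isl$q_value, 1e-100)))),
        strand = rep(".", nrow(isl))
      ),
      file.path(outdir, sprintf("islands.%s.bed", nm))
    )
    readr::write_tsv(as_tibble(isl), file.path(outdir, sprintf("islands.%s.tsv", nm)),
      progress = FALSE
    )
  }

  say("classify: radius %d", config$radius)
  classes <- stage("classify", classify_promoters(
    world$genes, islands$k4, islands$k27,
    radius = config$radius
  ))
  readr::write_tsv(as_tibble(classes), file.path(outdir, "classes.tsv"), progress = FALSE)
  zones <- overlap_zones(islands$k4, islands$k27)

  say("stratify: CpG / expression / methylation")
  strata <- stage("stratify", {
    cpg <- assign_cpg_status(world$genes, world$cpg_islands)
    meth <- methylation_classes(world$methylation)
    eq <- expression_quintiles(
      world$expression |> select(all_of(c("gene_id", "expression")))
    ) |> dplyr::rename(gene_id = "id", expr_group = "group")
    world$genes |>
      select(all_of(c("gene_id", "transcript_id", "archetype"))) |>
      left_join(cpg, by = "transcript_id") |>
      left_join(meth, by = "transcript_id") |>
      left_join(eq |> select(all_of(c("gene_id", "expr_group"))), by = "gene_id")
  })
  readr::write_tsv(strata, file.path(outdir, "strata.tsv"), progress = FALSE)

  say("profile: flank %d, bin %d", config$flank, config$bin)
  profiles <- stage("profile", {
    mats <- purrr::map(reads, tss_profile,
      genes = world$genes,
      flank = config$flank, bin = config$bin,
      fragment_size = config$fragment_size
    )
    cls_sets <- split(classes$transcript_id, classes$class)
    dir.create(file.path(outdir, "profiles"), showWarnings = FALSE)
    out <- list()
    for (cls in names(cls_sets)) {
      ids <- cls_sets[[cls]]
      if (length(ids) == 0L) next
      avg_in <- average_profile(mats$input, ids)
      for (trk in c("k4", "k27", "h2az", "seqchip")) {
        prof <- normalize_to_input(
          average_profile(mats[[trk]], ids), avg_in,
          pseudocount = config$pseudocount
        )
        out[[paste(cls, trk, sep = ".")]] <- prof
        readr::write_tsv(
          prof, file.path(outdir, "profiles", sprintf("%s_%s.tsv", cls, trk)),
          progress = FALSE
        )
      }
    }
    out
  })

  truth <- world$genes$archetype
  called <- as.character(classes$class)
  expected <- c(
    bivalent = "bivalent", K4_only = "K4_exclusive",
    K27_only = "K27_exclusive", silent_methylated = "none", none = "none"
  )[truth]
  summary <- list(
    n_genes = config$n_genes,
    island_counts = purrr::map_int(islands, nrow),
    class_counts = as.list(table(called)),
    archetype_recovery = mean(called == expected),
    overlap_zone_width = if (nrow(zones)) {
      list(
        min = min(zones$width), median = stats::median(zones$width),
        max = max(zones$width)
      )
    } else {
      NULL
    },
    seed = config$seed
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  yaml::write_yaml(
    list(
      config_hash = rlang::hash(config), seed = config$seed,
      package = "bivalseq"
    ),
    file.path(outdir, "manifest.yml")
  )
  say("done: %s", outdir)
  invisible(list(
    world = world, states = states, reads = reads, islands = islands,
    classes = classes, zones = zones, strata = strata, profiles = profiles,
    summary = summary
  ))
}
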