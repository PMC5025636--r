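test_that("CpG status removes island-less siblings of CpG transcripts", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g1", "g2"),
    transcript_id = c("tA", "tB", "tC"),
    chrom = "chr1", tss = c(10000L, 40000L, 80000L)
  )
  cpg <- tibble::tibble(chrom = "chr1", start = 9000L, end = 9500L, density = 0.1)
  s <- assign_cpg_status(genes, cpg)
  expect_equal(s$status, c("cpg", "removed", "non_cpg"))
  expect_equal(s$cpg_density, c(0.1, NA, NA))
})

test_that("CpG intersection uses half-open windows with 1 bp sensitivity", {
  genes <- tibble::tibble(
    gene_id = "g", transcript_id = "t", chrom = "chr1", tss = 10000L
  )
  # window is [8500, 11500); island ending at 8501 overlaps by exactly 1 bp
  touch <- tibble::tibble(chrom = "chr1", start = 8000L, end = 8501L, density = 0.2)
  expect_equal(assign_cpg_status(genes, touch)$status, "cpg")
  # island ending exactly at the window start does not overlap
  miss <- tibble::tibble(chrom = "chr1", start = 8000L, end = 8500L, density = 0.2)
  expect_equal(assign_cpg_status(genes, miss)$status, "non_cpg")
})

test_that("quantile groups are rank-based with stable ties and remainder rule", {
  q <- quantile_groups(tibble::tibble(id = letters[1:10], value = 1:10), 5)
  expect_equal(q$group, rep(1:5, each = 2))

  ties <- quantile_groups(tibble::tibble(id = letters[1:10], value = rep(1, 10)), 5)
  expect_equal(ties$group, rep(1:5, each = 2)) # filled in id order

  q11 <- quantile_groups(tibble::tibble(id = sprintf("i%02d", 1:11), value = 1:11), 5)
  expect_equal(as.integer(table(q11$group)), c(3L, 2L, 2L, 2L, 2L))

  expect_error(quantile_groups(tibble::tibble(id = "a", value = 1), 5), "distinct ids")

  # invariance to monotone transforms of the values
  v <- tibble::tibble(id = sprintf("i%02d", 1:20), value = runif(20))
  expect_equal(
    quantile_groups(v, 5)$group,
    quantile_groups(dplyr::mutate(v, value = exp(3 * value)), 5)$group
  )
})

test_that("methylation classes apply the probe filter before the beta rule", {
  mk <- function(beta, p) {
    tibble::tibble(
      transcript_id = "t", probe_id = sprintf("p%d", seq_along(beta)),
      beta = beta, detect_p = p
    )
  }
  expect_equal(methylation_classes(mk(c(0.8, 0.1), c(0.01, 0.01)))$meth_class, "methylated")
  expect_equal(methylation_classes(mk(c(0.1, 0.2), c(0.01, 0.01)))$meth_class, "unmethylated")
  # poor-signal probe dropped: the beta = 0.8 probe no longer counts
  expect_equal(methylation_classes(mk(c(0.8, 0.1), c(0.2, 0.01)))$meth_class, "unmethylated")
  expect_equal(methylation_classes(mk(c(0.5, 0.1), c(0.01, 0.01)))$meth_class, "ambiguous")
  expect_equal(methylation_classes(mk(0.9, 0.5))$meth_class, "no_data")
  # boundary: beta exactly at 0.75 counts as methylated
  expect_equal(methylation_classes(mk(0.75, 0.01))$meth_class, "methylated")
})

test_that("expression quintiles delegate to quantile_groups on per-gene maxima", {
  expr <- tibble::tibble(
    gene_id = rep(sprintf("g%03d", 1:100), each = 2),
    expression = c(rbind(100:1, 100:1 - 0.5))
  )
  q <- expression_quintiles(expr)
  expect_equal(nrow(q), 100)
  top <- q$id[q$group == 5]
  expect_setequal(top, sprintf("g%03d", 1:20)) # descending values: first 20 highest
  direct <- quantile_groups(
    tibble::tibble(id = sprintf("g%03d", 1:100), value = 100:1), 5
  )
  expect_equal(q$group, direct$group[match(q$id, direct$id)])
})

test_that("enhancer CpG split uses half-open overlap and recovers the simulated rate", {
  enh <- tibble::tibble(
    chrom = "chr1", start = c(100L, 1000L), end = c(500L, 1200L),
    name = c("e1", "e2")
  )
  cpg <- tibble::tibble(chrom = "chr1", start = 200L, end = 300L, density = 0.1)
  s <- enhancer_cpg_split(enh, cpg)
  expect_equal(s$with_cpg, c(TRUE, FALSE))
  # touching but not overlapping (half-open): no hit
  adj <- tibble::tibble(chrom = "chr1", start = 500L, end = 600L, density = 0.1)
  expect_equal(enhancer_cpg_split(enh, adj)$with_cpg, c(FALSE, FALSE))

  w <- build_world(sim_config(seed = 14, depth = 1e4),
    n_genes = 200, n_enhancers = 150, cpg_enhancer_frac = 0.3
  )
  frac <- mean(enhancer_cpg_split(w$enhancers, w$cpg_islands)$with_cpg)
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 150))
})

test_that("stratifications partition the gene set", {
  w <- build_world(sim_config(seed = 15, depth = 1e4), n_genes = 50, n_enhancers = 5)
  s <- assign_cpg_status(w$genes, w$cpg_islands)
  expect_equal(sort(s$transcript_id), sort(w$genes$transcript_id))
  expect_true(all(s$status %in% c("cpg", "non_cpg", "removed")))
  m <- methylation_classes(w$methylation)
  expect_equal(sort(m$transcript_id), sort(unique(w$methylation$transcript_id)))
})
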