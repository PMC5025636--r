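genes_p <- tibble::tibble(
  gene_id = "g1", transcript_id = "t1", chrom = "chr1",
  tss = 20000L, strand = "+"
)
genome_p <- tibble::tibble(chrom = "chr1", length = 50000L)

test_that("a single fragment fills exactly its overlapped bins", {
  r <- mk_reads("chr1", 20000, 20036, "+") # extends to [20000, 20200)
  pm <- tss_profile(r, genes_p)
  v <- pm$matrix[1, ]
  expect_equal(sum(v), 20) # 20 bins of 10 bp
  expect_equal(unname(v[501:520]), rep(1L, 20)) # bins at offsets [0, 200)
  expect_equal(sum(v[1:500]), 0)

  # same read at a minus-strand gene: columns mirrored
  pm2 <- tss_profile(r, dplyr::mutate(genes_p, strand = "-"))
  expect_equal(unname(pm2$matrix[1, ]), rev(unname(pm$matrix[1, ])))

  empty <- tss_profile(mk_reads(character(), integer(), integer(), character()), genes_p)
  expect_true(all(empty$matrix == 0))
})

test_that("binned coverage matches the brute-force per-base oracle", {
  set.seed(12)
  r <- uniform_reads(400, genome_p)
  pm <- tss_profile(r, genes_p, flank = 5000L, bin = 10L)
  frags <- dplyr::mutate(r,
    fs = ifelse(strand == "+", start, end - 200L),
    fe = ifelse(strand == "+", start + 200L, end)
  )
  oracle <- oracle_bin_coverage(frags$fs, frags$fe, 20000L - 5000L, 1000L, 10L)
  expect_equal(unname(pm$matrix[1, ]), oracle)
  # conservation: row sum equals total overlapped-bin count of all fragments
  expect_equal(sum(pm$matrix[1, ]), sum(oracle))
})

test_that("profiles are invariant under genome-wide strand reflection", {
  set.seed(5)
  r <- uniform_reads(500, genome_p)
  g2 <- tibble::tibble(
    gene_id = c("a", "b"), transcript_id = c("a", "b"), chrom = "chr1",
    tss = c(12000L, 30000L), strand = c("+", "-")
  )
  p1 <- average_profile(tss_profile(r, g2))
  # reflect: x -> L - x flips coordinates and strands of reads and genes
  L <- genome_p$length
  r_flip <- tibble::tibble(
    chrom = r$chrom, start = L - r$end, end = L - r$start,
    strand = ifelse(r$strand == "+", "-", "+")
  )
  g_flip <- dplyr::mutate(g2,
    tss = L - tss, strand = ifelse(strand == "+", "-", "+")
  )
  p2 <- average_profile(tss_profile(r_flip, g_flip))
  expect_equal(p1$value, p2$value)
})

test_that("averaging and input normalization follow their contracts", {
  pm <- tss_profile(mk_reads("chr1", 20000, 20036, "+"), genes_p)
  one <- average_profile(pm, "t1")
  expect_equal(one$value, unname(pm$matrix[1, ]))
  expect_error(average_profile(pm, "missing"), "unknown transcript")

  a <- structure(tibble::tibble(offset = 1:4, value = c(2, 2, 2, 2)),
    class = c("biv_profile", class(tibble::tibble()))
  )
  b <- structure(tibble::tibble(offset = 1:4, value = c(2, 2, 2, 0)),
    class = c("biv_profile", class(tibble::tibble()))
  )
  expect_equal(normalize_to_input(a, a)$value, rep(1, 4))
  # chip at a tenth of input depth: ratio approx 0.1
  a10 <- structure(tibble::tibble(offset = 1:4, value = rep(20, 4)),
    class = class(a)
  )
  expect_equal(
    normalize_to_input(a, a10, pseudocount = 0)$value, rep(0.1, 4)
  )
  # zero-input bin stays finite via the pseudocount
  expect_equal(normalize_to_input(a, b)$value[4], (2 + 0.5) / 0.5)
  expect_error(
    normalize_to_input(a, structure(b[1:3, ], class = class(b))),
    "identical bins"
  )
})

test_that("uniform chip and input tracks normalize to 1 at every bin", {
  set.seed(31)
  g <- tibble::tibble(chrom = "chr1", length = 500000L)
  genes <- tibble::tibble(
    gene_id = sprintf("g%d", 1:190), transcript_id = sprintf("t%d", 1:190),
    chrom = "chr1", tss = as.integer(seq(10000, 482500, by = 2500)),
    strand = rep(c("+", "-"), 95)
  )
  chip <- uniform_reads(200000, g)
  input <- uniform_reads(200000, g)
  p <- normalize_to_input(
    average_profile(tss_profile(chip, genes)),
    average_profile(tss_profile(input, genes))
  )
  expect_lt(max(abs(p$value - 1)), 0.05)
})

test_that("enhancer profiles scale bodies into equal intervals", {
  g <- tibble::tibble(chrom = "chr1", length = 100000L)
  enh <- tibble::tibble(chrom = "chr1", start = 40000L, end = 41000L)
  # uniform coverage: flat profile ~1 after self-normalization
  set.seed(8)
  r <- uniform_reads(20000, g)
  p <- enhancer_profile(r, enh, g, input_reads = r)
  expect_equal(nrow(p), 500 + 10 + 500)
  expect_equal(sum(p$position == "body"), 10)
  expect_true(all(abs(p$value - 1) < 1e-12)) # identical tracks cancel exactly

  # coverage only at the body center peaks in the middle intervals
  mid <- mk_reads("chr1", rep(40480, 50), rep(40516, 50), "+")
  p2 <- enhancer_profile(mid, enh, g)
  body <- p2$value[p2$position == "body"]
  expect_equal(which.max(body) %in% 5:6, TRUE)
  expect_true(all(p2$value[p2$position == "flank_left"][1:400] == 0))

  expect_warning(
    enhancer_profile(r, dplyr::bind_rows(
      enh, tibble::tibble(chrom = "chr1", start = 100L, end = 105L)
    ), g),
    "narrower"
  )
})

test_that("matched random intervals preserve widths, seed and exclusions", {
  g <- tibble::tibble(chrom = c("chr1", "chr2"), length = c(200000L, 100000L))
  enh <- tibble::tibble(
    chrom = "chr1", start = c(0L, 100L, 200L), end = c(500L, 1300L, 2200L)
  )
  s1 <- sample_matched_random(g, enh, n = 30, seed = 4)
  s2 <- sample_matched_random(g, enh, n = 30, seed = 4)
  expect_identical(s1, s2)
  expect_true(all((s1$end - s1$start) %in% c(500, 1200, 2000)))
  # without replacement (n = enhancer count): exact width multiset
  s_exact <- sample_matched_random(g, enh, n = 3, seed = 2)
  expect_equal(sort(s_exact$end - s_exact$start), c(500, 1200, 2000))
  # exclusion covering all but one region forces placement inside it
  excl <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(0L, 60000L, 0L), end = c(50000L, 200000L, 100000L)
  )
  s3 <- sample_matched_random(g, enh, n = 10, seed = 9, exclusions = excl)
  expect_true(all(s3$chrom == "chr1" & s3$start >= 50000 & s3$end <= 60000))
})
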