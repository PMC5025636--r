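genome1 <- tibble::tibble(chrom = "chr1", length = 20000L)

test_that("tags are 5'-end positions shifted by half the fragment size", {
  r <- mk_reads("chr1", c(250, 250), c(286, 286), c("+", "-"))
  t <- tags_from_reads(r, genome1, fragment_size = 200L)
  expect_equal(t$tag, c(350L, 186L))
  # clipping at the chromosome end
  r2 <- mk_reads("chr1", 19950, 19986, "+")
  expect_equal(tags_from_reads(r2, genome1)$tag, 19999L)
})

test_that("window counts and background rate follow the SICER formulas", {
  t <- tibble::tibble(chrom = "chr1", tag = c(350L, 399L, 401L))
  wv <- window_counts(t, genome1, island_params(egf = 0.75))
  expect_equal(wv$counts$chr1[2], 2L) # tags 350, 399 in window [200,400)
  expect_equal(wv$counts$chr1[3], 1L)
  expect_equal(sum(wv$counts$chr1), 3L)
  # lambda_bg = N * W / (L * egf): 1000 tags, 2 Mb, egf 0.75 -> 0.13333
  g2 <- tibble::tibble(chrom = "chr1", length = 2000000L)
  set.seed(1)
  t2 <- tibble::tibble(chrom = "chr1", tag = sample.int(2e6, 1000) - 1L)
  wv2 <- window_counts(t2, g2, island_params(egf = 0.75))
  expect_equal(wv2$lambda_bg, 1000 * 200 / (2e6 * 0.75))
})

test_that("window eligibility matches an independent Poisson tail to 1e-9", {
  # lambda = 1, c = 5: tail 0.00366 -> eligible; lambda = 5, c = 5: 0.559 -> not
  expect_lt(abs(oracle_pois_tail(5, 1) - 0.003660), 1e-6)
  expect_gt(oracle_pois_tail(5, 5), 0.2)
  for (lambda in c(0.2, 1, 5)) {
    wv <- list(counts = list(chr1 = 0:20), lambda_bg = lambda, window_w = 200L)
    elig <- eligible_windows(wv, island_params(window_p0 = 0.2))$chr1
    oracle <- vapply(0:20, function(c) {
      c >= 1 && oracle_pois_tail(c, lambda) <= 0.2 + 1e-9
    }, logical(1))
    impl_tail <- ppois(0:20 - 1L, lambda, lower.tail = FALSE)
    orac_tail <- vapply(0:20, oracle_pois_tail, numeric(1), lambda = lambda)
    expect_lt(max(abs(impl_tail - orac_tail)), 1e-9)
    expect_equal(elig, oracle)
  }
  expect_false(eligible_windows(
    list(counts = list(chr1 = c(0L, 0L)), lambda_bg = 5, window_w = 200L)
  )$chr1[1]) # c = 0 never eligible
  expect_error(
    eligible_windows(list(counts = list(chr1 = 0L), lambda_bg = 0)),
    "degenerate"
  )
})

test_that("island assembly merges eligible windows across bounded gaps", {
  mk_wv <- function(n, hot, lambda = 0.5) {
    cnt <- integer(n)
    cnt[hot + 1L] <- 5L
    list(counts = list(chr1 = cnt), lambda_bg = lambda, window_w = 200L)
  }
  wv <- mk_wv(12, c(3, 4, 7))
  elig <- eligible_windows(wv, island_params())
  isl <- assemble_islands(elig, wv, island_params(gap_g = 600L))
  expect_equal(nrow(isl), 1L)
  expect_equal(c(isl$start, isl$end), c(600L, 1600L))

  isl2 <- assemble_islands(
    eligible_windows(mk_wv(12, c(3, 7)), island_params()),
    mk_wv(12, c(3, 7)), island_params(gap_g = 200L)
  )
  expect_equal(nrow(isl2), 2L)

  empty <- assemble_islands(
    list(chr1 = rep(FALSE, 12)), mk_wv(12, integer()), island_params()
  )
  expect_equal(nrow(empty), 0L)
})

test_that("island assembly matches the brute-force run/gap oracle on random fixtures", {
  set.seed(99)
  for (rep in 1:50) {
    n <- sample(20:100, 1)
    lambda <- runif(1, 0.2, 2)
    cnt <- rpois(n, lambda) + rbinom(n, 1, 0.2) * rpois(n, 8)
    wv <- list(
      counts = list(chr1 = cnt), lambda_bg = lambda, window_w = 200L
    )
    gap_win <- sample(0:5, 1)
    params <- island_params(gap_g = gap_win * 200L, window_p0 = 0.2)
    elig <- eligible_windows(wv, params)
    got <- assemble_islands(elig, wv, params)
    want <- oracle_islands(elig$chr1, cnt, lambda, 200L, gap_win)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$n_windows, want$n_windows)
      expect_equal(got$score, want$score, tolerance = 1e-12)
    }
  }
})

test_that("island score never decreases when tags are added inside the island", {
  base <- c(0L, 5L, 6L, 0L, 7L, 0L)
  wv1 <- list(counts = list(chr1 = base), lambda_bg = 0.5, window_w = 200L)
  p <- island_params(gap_g = 600L)
  s1 <- assemble_islands(eligible_windows(wv1, p), wv1, p)$score
  more <- base
  more[3] <- more[3] + 4L
  wv2 <- list(counts = list(chr1 = more), lambda_bg = 0.5, window_w = 200L)
  s2 <- assemble_islands(eligible_windows(wv2, p), wv2, p)$score
  expect_gte(s2, s1)
})

test_that("full caller keeps a strong island and reports Poisson/BH statistics", {
  # 50 chip tags piled in one window vs sparse control scaled to lambda = 5
  chip <- mk_reads("chr1", rep(900, 50), rep(936, 50))
  ctrl <- mk_reads("chr1", seq(100, 19800, length.out = 50), seq(136, 19836, length.out = 50))
  # with 50 chip tags and 50 control tags, ratio 1; island has control 4+1=5
  isl <- call_islands(
    chip, genome1, island_params(mode = "with_control", window_p0 = 0.2),
    control_reads = ctrl
  )
  expect_equal(nrow(isl), 1L)
  expect_equal(isl$chip_count, 50L)
  lambda <- (isl$control_count + 1) * 1
  expect_equal(isl$p_value, ppois(49, lambda, lower.tail = FALSE))
  expect_lt(isl$q_value, 1e-6)

  expect_warning(out <- call_islands(mk_reads(character(), integer(), integer(), character()), genome1), "no ChIP reads")
  expect_equal(nrow(out), 0L)
  expect_error(
    call_islands(chip, genome1, island_params(mode = "with_control")),
    "control_reads"
  )
})

test_that("caller controls type-I error when chip and control share the null", {
  # tag density in the regime of real libraries (lambda_bg < 1 per window)
  set.seed(7)
  g <- tibble::tibble(chrom = "chr1", length = 1000000L)
  kept <- cand <- numeric(5)
  for (i in 1:5) {
    chip <- uniform_reads(3000, g)
    ctrl <- uniform_reads(3000, g)
    wv <- window_counts(tags_from_reads(chip, g), g)
    cand[i] <- nrow(assemble_islands(eligible_windows(wv), wv, island_params()))
    kept[i] <- nrow(call_islands(chip, g, island_params(mode = "with_control"), ctrl))
  }
  bound <- 0.01 * sum(cand) + 3 * sqrt(0.01 * sum(cand))
  expect_lte(sum(kept), bound)
})
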