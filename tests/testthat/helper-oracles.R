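# Independent brute-force oracles and small fixture builders used across
# the test files. Each oracle deliberately takes a different code path
# from the implementation it checks.

# Gapped-run merge oracle: close runs of ineligible windows of length
# <= gap_win that lie between eligible windows, via run-length encoding,
# then trim each run of 1s to its eligible extent.
oracle_islands <- function(eligible, counts, lambda_bg, window_w, gap_win) {
  v <- as.integer(eligible)
  r <- rle(v)
  pos_end <- cumsum(r$lengths)
  pos_start <- pos_end - r$lengths + 1L
  for (k in seq_along(r$values)) {
    internal <- k > 1L && k < length(r$values)
    if (r$values[k] == 0L && internal && r$lengths[k] <= gap_win) {
      v[pos_start[k]:pos_end[k]] <- 1L
    }
  }
  r2 <- rle(v)
  e2 <- cumsum(r2$lengths)
  s2 <- e2 - r2$lengths + 1L
  out <- list()
  for (k in seq_along(r2$values)) {
    if (r2$values[k] == 1L) {
      ii <- s2[k]:e2[k]
      ii <- ii[eligible[ii]] # trim to eligible extent
      out[[length(out) + 1L]] <- data.frame(
        start = (min(ii) - 1L) * window_w,
        end = max(ii) * window_w,
        score = sum(-dpois(counts[ii], lambda_bg, log = TRUE)),
        n_windows = length(ii)
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(
      start = integer(), end = integer(), score = double(),
      n_windows = integer()
    ))
  }
  do.call(rbind, out)
}

# Upper-tail Poisson P(X >= c) by direct pmf summation from first
# principles (log-space terms, no ppois/dpois).
oracle_pois_tail <- function(c, lambda, terms = 3000L) {
  if (c <= 0) {
    return(1)
  }
  k <- seq(c, c + terms)
  sum(exp(k * log(lambda) - lambda - lgamma(k + 1)))
}

# Per-bin fragment-overlap coverage by direct interval checks, O(F * B).
oracle_bin_coverage <- function(frag_start, frag_end, win_start, n_bins, bin) {
  vapply(seq_len(n_bins), function(k) {
    b0 <- win_start + (k - 1L) * bin
    b1 <- b0 + bin
    sum(frag_start < b1 & frag_end > b0)
  }, integer(1))
}

# Tiny deterministic world for unit tests.
tiny_world <- function(seed = 11, n_genes = 8, depth = 2e4, ...) {
  build_world(sim_config(seed = seed, depth = depth, ...),
    n_genes = n_genes, n_enhancers = 6
  )
}

# Hand-built read tibble.
mk_reads <- function(chrom, start, end, strand = "+") {
  tibble::tibble(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    strand = strand
  )
}

# Uniform random reads on a genome (fixed-length, both strands).
uniform_reads <- function(n, genome, read_len = 36L) {
  ch <- sample.int(nrow(genome), n, replace = TRUE, prob = genome$length)
  pos <- floor(runif(n) * (genome$length[ch] - read_len))
  tibble::tibble(
    chrom = genome$chrom[ch], start = as.integer(pos),
    end = as.integer(pos + read_len),
    strand = sample(c("+", "-"), n, replace = TRUE)
  )
}
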