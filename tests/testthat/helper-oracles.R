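# Independent oracles and fixture generators.  These deliberately avoid
# the package's own code paths: scanning is redone per window with an
# explicit position loop, interval intersection by a quadratic scan,
# hypergeometric tails by direct pmf summation over binomial-coefficient
# products.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

random_pwm <- function(L, name = "rnd", tf_class = "other") {
  m <- matrix(stats::rgamma(L * 4, 1), ncol = 4)
  m <- m / rowSums(m)
  cooccupy::pwm(m, name, tf_class = tf_class)
}

oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(seq, NULL)[[1]]]), collapse = "")
}

# Score every window of both strands by explicit per-position lookup.
oracle_scan <- function(seq, pwm, rel_threshold = 0.70,
                        background = rep(0.25, 4)) {
  probs <- pwm$probs
  L <- nrow(probs)
  # per-position attainable bounds on the log-odds scale
  lo <- sum(vapply(seq_len(L), function(j)
    min(log2(probs[j, ] / background)), numeric(1)))
  hi <- sum(vapply(seq_len(L), function(j)
    max(log2(probs[j, ] / background)), numeric(1)))
  score_at <- function(chars, o) {
    s <- 0
    for (j in seq_len(L)) {
      b <- match(chars[o + j], c("A", "C", "G", "T"))
      if (is.na(b)) return(NA_real_)
      s <- s + log2(probs[j, b] / background[b])
    }
    s
  }
  n <- nchar(seq)
  res <- list()
  for (strand in c("+", "-")) {
    s2 <- if (strand == "+") seq else oracle_revcomp(seq)
    chars <- strsplit(s2, NULL)[[1]]
    if (n < L) next
    for (o in 0:(n - L)) {
      sc <- score_at(chars, o)
      if (is.na(sc)) next
      rel <- (sc - lo) / (hi - lo)
      if (rel >= rel_threshold - 1e-12) {
        off <- if (strand == "+") o else n - L - o
        res[[length(res) + 1]] <- data.frame(
          offset = off, strand = strand, log_odds = sc,
          relative_score = min(rel, 1))
      }
    }
  }
  if (!length(res))
    return(data.frame(offset = integer(), strand = character(),
                      log_odds = numeric(), relative_score = numeric()))
  out <- do.call(rbind, res)
  out[order(out$offset, out$strand), ]
}

oracle_intersect <- function(a, b, min_overlap = 1) {
  res <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (ov >= min_overlap)
      res[[length(res) + 1]] <- data.frame(a_index = i, b_index = j,
                                           overlap_bp = ov)
  }
  if (!length(res))
    return(data.frame(a_index = integer(), b_index = integer(),
                      overlap_bp = integer()))
  out <- do.call(rbind, res)
  out[order(out$a_index, out$b_index), ]
}

# Hypergeometric pmf by explicit binomial-coefficient products and its
# upper tail by summation.
oracle_hyper_pmf <- function(N, K, n, j) {
  choose(K, j) * choose(N - K, n - j) / choose(N, n)
}

oracle_hyper_upper <- function(N, K, n, k) {
  js <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(vapply(js, function(j) oracle_hyper_pmf(N, K, n, j), numeric(1)))
}

oracle_fisher_two_sided <- function(a, b, c, d) {
  N <- a + b + c + d; K <- a + c; n <- a + b
  lo <- max(0, n + K - N); hi <- min(K, n)
  pobs <- oracle_hyper_pmf(N, K, n, a)
  ps <- vapply(lo:hi, function(j) oracle_hyper_pmf(N, K, n, j),
               numeric(1))
  sum(ps[ps <= pobs * (1 + 1e-7)])
}

random_intervals <- function(n, chroms = c("chr1", "chr2"),
                             max_pos = 1000) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  width <- sample.int(100, n, replace = TRUE)
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = start, end = start + width,
                 strand = ".")
}

# Mean per-bin coverage by a naive per-base loop over the track rows.
oracle_density_row <- function(track, chrom, summit, flank, bin_size,
                               chrom_len) {
  base_val <- function(pos) {
    if (pos < 0 || pos >= chrom_len) return(NA_real_)
    r <- track[track$chrom == chrom & track$start <= pos &
                 track$end > pos, ]
    if (nrow(r) == 0) 0 else sum(r$value)
  }
  nb <- 2 * flank / bin_size
  out <- numeric(nb)
  for (b in seq_len(nb)) {
    pos <- (summit - flank + (b - 1) * bin_size) + 0:(bin_size - 1)
    v <- vapply(pos, base_val, numeric(1))
    out[b] <- if (all(is.na(v))) 0 else mean(v, na.rm = TRUE)
  }
  out
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
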