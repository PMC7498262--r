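test_that("motif readers parse HOMER and CIS-BP dialects", {
  hom <- write_lines_tmp(c(
    ">AAAA\tmotifA\t5.0",
    "0.97\t0.01\t0.01\t0.01",
    "0.97\t0.01\t0.01\t0.01",
    "0.97\t0.01\t0.01\t0.01",
    "0.97\t0.01\t0.01\t0.01",
    ">CCCC\tmotifB\t5.0",
    "0.01\t0.97\t0.01\t0.01",
    "0.01\t0.97\t0.01\t0.01",
    "0.01\t0.97\t0.01\t0.01",
    "0.01\t0.97\t0.01\t0.01"), ".motif")
  ms <- read_motifs(hom, "homer", tf_class = "sox")
  expect_length(ms, 2)
  expect_equal(consensus(ms[[1]]), "AAAA")
  expect_equal(ms[[2]]$name, "motifB")
  expect_equal(ms[[1]]$tf_class, "sox")
  expect_true(all(abs(rowSums(ms[[1]]$probs) - 1) < 1e-9))

  cis <- write_lines_tmp(c(
    "Pos\tA\tC\tG\tT",
    paste(1:7, "0.1", "0.2", "0.3", "0.4", sep = "\t")), ".txt")
  mc <- read_motifs(cis, "cisbp", tf_class = "tcf")
  expect_length(mc, 1)
  expect_equal(nrow(mc[[1]]$probs), 7)
  expect_equal(mc[[1]]$source, "cisbp")

  bad <- write_lines_tmp(c(">AAAA\tm\t1", "0.2\t0.1\t0.1\t0.1",
                           "0.97\t0.01\t0.01\t0.01",
                           "0.97\t0.01\t0.01\t0.01",
                           "0.97\t0.01\t0.01\t0.01"), ".motif")
  expect_error(read_motifs(bad, "homer"), "sums to")
  expect_error(pwm(matrix(c(-0.1, 0.5, 0.3, 0.3), 4, 4), "x"),
               "negative")
})

test_that("consensus and its reverse complement score relative 1.0", {
  set.seed(5)
  for (i in 1:5) {
    p <- random_pwm(sample(4:10, 1))
    cons <- consensus(p)
    h <- scan_sequence(cons, p)
    plus <- h[h$strand == "+", ]
    expect_equal(nrow(plus), 1)
    expect_equal(plus$offset, 0L)
    expect_equal(plus$relative_score, 1)
    hrc <- scan_sequence(oracle_revcomp(cons), p)
    minus <- hrc[hrc$strand == "-", ]
    expect_equal(minus$relative_score, 1)
    expect_equal(minus$offset, 0L)
  }
})

test_that("scanning equals the brute-force per-window oracle", {
  set.seed(6)
  for (i in 1:10) {
    seq <- random_dna(sample(100:400, 1))
    p <- random_pwm(sample(4:12, 1))
    thr <- sample(c(0.6, 0.7, 0.8), 1)
    got <- as.data.frame(scan_sequence(seq, p, thr))
    ora <- oracle_scan(seq, p, thr)
    expect_equal(nrow(got), nrow(ora))
    if (nrow(got)) {
      rownames(got) <- rownames(ora) <- NULL
      expect_equal(got$offset, ora$offset)
      expect_equal(got$strand, ora$strand)
      expect_equal(got$log_odds, ora$log_odds, tolerance = 1e-9)
      expect_equal(got$relative_score, ora$relative_score,
                   tolerance = 1e-9)
    }
  }
})

test_that("scanning is strand-symmetric and handles N and short input", {
  set.seed(8)
  p <- random_pwm(8)
  seq <- random_dna(300)
  h <- scan_sequence(seq, p, 0.6)
  hrc <- scan_sequence(oracle_revcomp(seq), p, 0.6)
  # a + hit at offset o maps to a - hit at n - L - o on the reverse
  n <- nchar(seq); L <- 8
  mapped <- data.frame(offset = n - L - h$offset,
                       strand = ifelse(h$strand == "+", "-", "+"),
                       log_odds = h$log_odds)
  mapped <- mapped[order(mapped$offset, mapped$strand), ]
  hrc2 <- as.data.frame(hrc[order(hrc$offset, hrc$strand),
                            c("offset", "strand", "log_odds")])
  rownames(mapped) <- rownames(hrc2) <- NULL
  expect_equal(hrc2, mapped, tolerance = 1e-9)
  # windows containing N are excluded
  hN <- scan_sequence(paste0("NNNN", substr(seq, 5, 300)), p, 0.6)
  expect_true(all(hN$offset >= 4))
  expect_equal(nrow(scan_sequence("ACG", p)), 0)
})

test_that("dinucleotide shuffles preserve composition and endpoints", {
  expect_equal(dinucleotide_shuffle("AAAA", n = 3, seed = 1)$shuffles,
               rep("AAAA", 3))
  # ACACAC admits a unique arrangement with its dinucleotide counts
  expect_equal(dinucleotide_shuffle("ACACAC", n = 5, seed = 1)$shuffles,
               rep("ACACAC", 5))
  set.seed(12)
  s <- random_dna(500)
  sh <- dinucleotide_shuffle(s, n = 10, seed = 42, id = "peak1")
  for (x in sh$shuffles) {
    expect_identical(dinucleotide_counts(x), dinucleotide_counts(s))
    expect_equal(substr(x, 1, 1), substr(s, 1, 1))
    expect_equal(substr(x, 500, 500), substr(s, 500, 500))
  }
  # seeded runs are reproducible and keyed streams are order-independent
  again <- dinucleotide_shuffle(s, n = 10, seed = 42, id = "peak1")
  expect_identical(sh$shuffles, again$shuffles)
  other <- dinucleotide_shuffle(s, n = 10, seed = 42, id = "peak2")
  expect_false(identical(sh$shuffles, other$shuffles))
  # shuffles actually move bases around
  expect_gt(length(unique(sh$shuffles)), 1)
  expect_error(dinucleotide_shuffle("ACGX", seed = 1), "A, C, G, T, N")
})

test_that("N runs split the sequence into independently shuffled segments", {
  s <- paste0(random_dna(40), "NNN", random_dna(40))
  sh <- dinucleotide_shuffle(s, n = 5, seed = 3)
  for (x in sh$shuffles) {
    expect_equal(substr(x, 41, 43), "NNN")
    expect_identical(dinucleotide_counts(substr(x, 1, 40)),
                     dinucleotide_counts(substr(s, 1, 40)))
    expect_identical(dinucleotide_counts(substr(x, 44, 83)),
                     dinucleotide_counts(substr(s, 44, 83)))
  }
})

test_that("peak classification labels and deduplicates sites", {
  hit <- function(offset, strand = "+", motif = "m1", class = "sox")
    tibble::tibble(peak_id = "p", motif_name = motif, tf_class = class,
                   offset = offset, strand = strand, log_odds = 1,
                   relative_score = 0.9, width = 8L)
  c1 <- classify_peak(rbind(hit(3), hit(20)), hit(40, class = "tcf"))
  expect_equal(c1$label, "sox_and_tcf")
  expect_equal(c(c1$n_sox_sites, c1$n_tcf_sites), c(2L, 1L))
  c2 <- classify_peak(hit(3)[0, ], hit(3)[0, ])
  expect_equal(c2$label, "neither")
  # same offset/strand from two PWMs of one class counts once
  c3 <- classify_peak(rbind(hit(5, motif = "mA"), hit(5, motif = "mB")),
                      hit(1)[0, ])
  expect_equal(c3$label, "sox_only")
  expect_equal(c3$n_sox_sites, 1L)
})

test_that("motif class enrichment builds the right table and p-value", {
  mk <- function(n, n_with, label = "sox_and_tcf") {
    tibble::tibble(peak_id = as.character(seq_len(n)),
                   label = c(rep(label, n_with),
                             rep("neither", n - n_with)),
                   n_sox_sites = 0L, n_tcf_sites = 0L)
  }
  # the study's headline proportions: 101/191 vs 592/1910
  r <- motif_class_enrichment(mk(191, 101), mk(1910, 592), "sox_and_tcf")
  expect_equal(c(r$a, r$b, r$c, r$d), c(101, 90, 592, 1318))
  expect_equal(r$p_value, oracle_hyper_upper(2101, 101 + 592, 191, 101),
               tolerance = 1e-9)
  expect_lt(r$p_value, 1e-8)
  r2 <- motif_class_enrichment(mk(10, 5), mk(10, 5), "sox_and_tcf")
  expect_equal(r2$odds_ratio, 1)
  expect_gt(r2$p_value, 0.5)
  r3 <- motif_class_enrichment(mk(3, 3), mk(3, 0), "sox_and_tcf")
  expect_equal(r3$p_value, 0.05, tolerance = 1e-12)
  expect_error(motif_class_enrichment(mk(3, 3)[0, ], mk(3, 0),
                                      "sox_and_tcf"), "empty")
})

test_that("motif spacing minimizes center distance across classes", {
  sox <- tibble::tibble(offset = 10, width = 8L)
  tcf <- tibble::tibble(offset = 40, width = 10L)
  r <- motif_spacing(sox, tcf)
  expect_equal(r$min_center_distance, 31)
  expect_true(r$clustered_within)
  r2 <- motif_spacing(sox, tcf[0, ])
  expect_true(is.na(r2$min_center_distance))
  expect_false(r2$clustered_within)
  set.seed(3)
  for (i in 1:5) {
    s <- tibble::tibble(offset = sample(0:140, 5), width = 8L)
    t <- tibble::tibble(offset = sample(0:140, 5), width = 10L)
    expected <- min(abs(outer(s$offset + 4, t$offset + 5, "-")))
    expect_equal(motif_spacing(s, t)$min_center_distance, expected)
  }
})

test_that("motif count summary reports the >threshold fraction", {
  cls <- tibble::tibble(peak_id = letters[1:4],
                        label = "sox_only",
                        n_sox_sites = c(6L, 6L, 1L, 0L),
                        n_tcf_sites = 0L)
  r <- motif_count_summary(cls, threshold = 5)
  expect_equal(r$fraction, 0.5)
  expect_equal(as.integer(r$histogram[c("0", "1", "6")]), c(1L, 1L, 2L))
  empty <- motif_count_summary(cls[0, ])
  expect_true(is.na(empty$fraction))
  bg <- tibble::tibble(peak_id = as.character(1:20), label = "neither",
                       n_sox_sites = 0L, n_tcf_sites = 0L)
  rb <- motif_count_summary(cls, threshold = 5, background = bg)
  expect_equal(rb$background_fraction, 0)
  expect_equal(rb$p_value,
               fisher_exact(2, 2, 0, 20, "greater")$p_value)
})
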