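mk_records <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    tibble::tibble(gene_id = r[[1]], stage = r[[2]],
                   log2_fold_change = as.numeric(r[[3]]),
                   fdr = as.numeric(r[[4]]))))
}

test_that("differential filter applies strict FC and FDR cutoffs", {
  rec <- mk_records(list("g1", "NF10", 1.2, 0.01),
                    list("g2", "NF10", 0.8, 0.001),
                    list("g3", "NF9", 3.0, 0.06),
                    list("g3", "NF12", 3.0, 0.06),
                    list("g4", "NF10.5", -2.0, 0.02))
  out <- filter_differential(rec)
  expect_setequal(out$gene_id, c("g1", "g4"))
  g1 <- out[out$gene_id == "g1", ]
  expect_equal(g1$direction, "up_in_MO")
  expect_equal(g1$stage_class, "early")
  g4 <- out[out$gene_id == "g4", ]
  expect_equal(g4$direction, "down_in_MO")
  expect_equal(g4$stage_class, "late")
  # boundary |log2FC| == 1 is excluded
  b <- filter_differential(mk_records(list("g", "NF9", 1.0, 0.001)))
  expect_equal(nrow(b), 0)
})

test_that("direction comes from the earliest significant stage", {
  rec <- mk_records(list("g", "NF10.5", -3, 0.001),
                    list("g", "NF10", 2, 0.001),
                    list("g", "NF9", 1.5, 0.5))
  out <- filter_differential(rec)
  expect_equal(out$first_stage, "NF10")
  expect_equal(out$direction, "up_in_MO")
  expect_equal(out$stage_class, "early")
})

test_that("differential filter errors on conflicting duplicates, is monotone", {
  dup <- mk_records(list("g", "NF9", 2, 0.01), list("g", "NF9", 3, 0.01))
  expect_error(filter_differential(dup), "conflicting duplicate")
  set.seed(14)
  stages <- c("NF9", "NF10", "NF10.5")
  rec <- do.call(rbind, lapply(sprintf("g%03d", 1:200), function(g)
    tibble::tibble(gene_id = g, stage = stages,
                   log2_fold_change = rnorm(3, 0, 2),
                   fdr = runif(3))))
  strict <- filter_differential(rec, 2, 0.05)$gene_id
  relaxed_fc <- filter_differential(rec, 1.5, 0.05)$gene_id
  relaxed_fdr <- filter_differential(rec, 2, 0.2)$gene_id
  expect_true(all(strict %in% relaxed_fc))
  expect_true(all(strict %in% relaxed_fdr))
})

test_that("spatial enrichment uses the 1.5x-over-mean rule", {
  v <- c(t1 = 3.2, t2 = 1, t3 = 1, t4 = 1, t5 = 1)
  expect_equal(spatial_enrichment(v), "t1")   # mean 1.44, cutoff 2.16
  expect_equal(spatial_enrichment(rep(2, 4)), character(0))
  expect_equal(spatial_enrichment(c(a = 0, b = 0, c = 0, d = 0)),
               character(0))
  expect_error(spatial_enrichment(c(1, -1)), "negative")
  # scale invariance
  set.seed(3)
  for (i in 1:20) {
    p <- stats::setNames(rexp(5), paste0("t", 1:5))
    expect_identical(spatial_enrichment(p), spatial_enrichment(p * 37.5))
  }
  m <- rbind(g1 = v, g2 = rep(1, 5))
  tab <- spatial_enrichment(m)
  expect_equal(tab$n_enriched, c(1L, 0L))
})

test_that("pattern distribution tests agree with their kernels", {
  subset <- rep(c("endo", "meso"), c(30, 10))
  genome <- rep(c("endo", "meso", "ecto"), c(300, 100, 0))
  r <- pattern_distribution_test(subset, genome, "chi_square")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  uni <- rep(c("a", "b", "c", "d"), 25)
  conc <- rep("a", 40)
  r2 <- pattern_distribution_test(conc, uni, "chi_square")
  expect_equal(r2$statistic, 120)
  expect_equal(r2$p_value, stats::pchisq(120, 3, lower.tail = FALSE))
  expect_error(pattern_distribution_test(c("a", "x"), uni, "chi_square"),
               "expected count 0")
  r3 <- pattern_distribution_test(c(1, 2, 3), c(1, 2, 3), "ks")
  expect_equal(r3$statistic, 0)
  expect_equal(r3$p_value, 1)
})

test_that("overlap test matches enumeration and validates inputs", {
  u <- paste0("g", 1:10)
  r <- overlap_test(u, paste0("g", 1:5), paste0("g", 1:5))
  expect_equal(r$p_value, 1 / 252, tolerance = 1e-12)
  r2 <- overlap_test(u, u, paste0("g", 3:7))
  expect_equal(r2$p_value, 1)
  r3 <- overlap_test(u, c("g1", "g2"), c("g2", "g3"))
  expect_equal(r3$k, 1)
  expect_equal(r3$p_value, 1 - 28 / 45, tolerance = 1e-12)
  expect_error(overlap_test(u, c("g1", "gX"), "g2"), "gX")
  set.seed(21)
  for (i in 1:20) {
    N <- sample(10:40, 1)
    uu <- paste0("g", seq_len(N))
    a <- sample(uu, sample.int(N, 1))
    b <- sample(uu, sample.int(N, 1))
    r <- overlap_test(uu, a, b)
    expect_equal(r$p_value,
                 oracle_hyper_upper(N, length(a), length(b), r$k),
                 tolerance = 1e-12)
  }
})

test_that("regulatory categories map directions and partition the input", {
  expect_equal(regulatory_category("down", "down"), "activated_by_both")
  expect_equal(regulatory_category("up", "down"),
               "bcat_activated_sox17_repressed")
  expect_equal(regulatory_category("down", "up"),
               "sox17_activated_bcat_repressed")
  expect_equal(regulatory_category("up_in_MO", "up_in_MO"),
               "repressed_by_both")
  set.seed(2)
  n <- 84
  rs <- tibble::tibble(gene_id = paste0("g", 1:n),
                       direction = sample(c("down_in_MO", "up_in_MO"), n,
                                          replace = TRUE))
  rb <- tibble::tibble(gene_id = paste0("g", 1:n),
                       direction = sample(c("down_in_MO", "up_in_MO"), n,
                                          replace = TRUE))
  cats <- regulatory_categories(rs, rb)
  expect_equal(nrow(cats), n)
  expect_equal(sum(table(cats$category)), n)  # partition: counts sum to n
  expect_false(any(is.na(cats$category)))
})

test_that("direct targets intersect bound and regulated genes", {
  ann <- tibble::tibble(peak_id = c("p1", "p2", "p3"),
                        gene_id = c("g1", "g2", "g2"),
                        distance_to_tss = 0L, feature = "intergenic")
  reg <- tibble::tibble(gene_id = c("g2", "g3"))
  r <- direct_targets(ann, reg, paste0("g", 1:10))
  expect_equal(r$genes, "g2")
  expect_setequal(r$peaks, c("p2", "p3"))
  expect_equal(r$test$p_value, 1 - 28 / 45, tolerance = 1e-12)
  r2 <- direct_targets(ann, tibble::tibble(gene_id = "g9"),
                       paste0("g", 1:10))
  expect_length(r2$genes, 0)
  expect_error(direct_targets(ann, reg, character(0)), "empty universe")
})

test_that("reporter summary normalizes by Renilla and tests vs reference", {
  firefly <- c(10, 12, 8, 40, 44, 36)
  renilla <- c(10, 10, 10, 20, 20, 20)
  cond <- rep(c("empty", "enhancer"), each = 3)
  r <- reporter_summary(firefly, renilla, cond, "empty")
  expect_equal(r$mean_ratio, c(1, 2))
  expect_equal(r$sd_ratio, c(0.2, 0.2))
  ref <- stats::t.test(c(2, 2.2, 1.8), c(1, 1.2, 0.8), var.equal = TRUE)
  en <- r[r$condition == "enhancer", ]
  expect_equal(en$p_vs_reference, ref$p.value, tolerance = 1e-12)
  expect_true(is.na(r$p_vs_reference[r$condition == "empty"]))
  # degenerate zero-variance case is flagged
  d <- reporter_summary(c(1, 1, 2, 2), c(1, 1, 1, 1),
                        rep(c("a", "b"), each = 2), "a")
  expect_true(d$degenerate[d$condition == "b"])
  expect_equal(d$p_vs_reference[d$condition == "b"], 0)
  expect_error(reporter_summary(1:4, c(1, 0, 1, 1),
                                rep(c("a", "b"), each = 2), "a"), "> 0")
})
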