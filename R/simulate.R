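dinuc_names <- function() as.vector(outer(DNA_BASES, DNA_BASES, paste0))

#' Simulate a genome with a specified dinucleotide composition
#'
#' First-order Markov chain whose transition probabilities are derived
#' from the target dinucleotide frequencies, started from the stationary
#' base distribution — the same background model the shuffle null
#' preserves.
#'
#' @param length sequence length in bp (>= 1000).
#' @param dinuc_freqs 16 frequencies summing to 1: either a 4x4 matrix
#'   (row = first base, A C G T order) or a named vector over "AA".."TT"
#'   (names as in [dinucleotide_counts()]).  Default uniform.
#' @param seed integer seed.
#' @param chrom_name chromosome name for the FASTA record.
#' @return `Biostrings::DNAStringSet` with one sequence.
#' @export
simulate_genome <- function(length, dinuc_freqs = NULL, seed = 1,
                            chrom_name = "chrSim") {
  if (length < 1000) stop("length must be >= 1000", call. = FALSE)
  if (is.null(dinuc_freqs)) dinuc_freqs <- rep(1 / 16, 16)
  f <- if (is.matrix(dinuc_freqs)) dinuc_freqs else {
    if (is.null(names(dinuc_freqs))) names(dinuc_freqs) <- dinuc_names()
    matrix(dinuc_freqs[as.vector(outer(DNA_BASES, DNA_BASES, paste0))],
           nrow = 4, dimnames = list(DNA_BASES, DNA_BASES))
  }
  if (abs(sum(f) - 1) > 1e-6 || any(f < 0))
    stop("dinuc_freqs must be nonnegative and sum to 1", call. = FALSE)
  rs <- rowSums(f)
  P <- f
  P[rs > 0, ] <- f[rs > 0, ] / rs[rs > 0]
  P[rs == 0, ] <- 0.25      # unreachable states
  # stationary distribution by power iteration
  pi0 <- if (sum(rs) > 0) rs / sum(rs) else rep(0.25, 4)
  for (i in 1:200) pi0 <- as.vector(pi0 %*% P)
  cum <- t(apply(P, 1, cumsum))
  with_seed(derive_seed(seed, chrom_name), {
    u <- stats::runif(length)
    code <- integer(length)
    code[1] <- min(findInterval(u[1], cumsum(pi0)) + 1L, 4L)
    for (i in 2:length)
      code[i] <- min(findInterval(u[i], cum[code[i - 1L], ],
                                  left.open = TRUE) + 1L, 4L)
    seq <- decode_dna(code)
    out <- Biostrings::DNAStringSet(seq)
    names(out) <- chrom_name
    out
  })
}

# Place k non-overlapping sites in a window by slotting: the window is
# split into k equal slots and each site gets a random offset inside its
# slot, so plants never collide.
.slot_offsets <- function(window, lens) {
  k <- length(lens)
  slot <- window %/% k
  if (any(lens > slot))
    stop("sites do not fit the summit window; reduce site count",
         call. = FALSE)
  vapply(seq_len(k), function(i) {
    (i - 1L) * slot + sample.int(slot - lens[i] + 1L, 1) - 1L
  }, numeric(1))
}

#' Plant motif-site grammars into a genome
#'
#' Creates `n_peaks` peaks of `peak_width` bp (summit at center) and
#' overwrites PWM consensus sequences at recorded offsets inside each
#' 150 bp summit window, according to the per-peak class (both motif
#' classes, one, or neither).  Consensus sites have relative score 1.0,
#' so detection at the usual 0.70 threshold is deterministic; each
#' assembled window is verified to classify exactly as intended (the
#' background is re-shuffled when a spurious site arises), making the
#' truth manifest exact.
#'
#' @param genome `Biostrings::DNAStringSet`; planting happens on the
#'   first sequence.
#' @param n_peaks number of peaks.
#' @param class_fractions fractions over (both, sox_only, tcf_only,
#'   neither) summing to 1; counts are round(n * fraction) with the
#'   remainder assigned to the largest fraction.
#' @param sox_pwm,tcf_pwm "pwm" objects whose consensus is planted.
#' @param n_sox_sites,n_tcf_sites consensus copies planted per window for
#'   the respective class.
#' @param min_gap minimum separation between peaks in bp.
#' @param peak_width peak interval width (default 300).
#' @param window summit-window width for planting (default 150).
#' @param rel_threshold relative-score threshold used for verification.
#' @param positions optional vector of summit positions (0-based); when
#'   NULL, peaks are placed at random with `min_gap` separation.
#' @param seed integer seed.
#' @param max_tries background re-shuffles allowed per window before
#'   erroring.
#' @return list: `peaks` (peak tibble), `genome` (modified
#'   DNAStringSet), `manifest` (truth manifest list).
#' @export
plant_peaks <- function(genome, n_peaks,
                        class_fractions = c(both = 0.5, sox_only = 0.25,
                                            tcf_only = 0, neither = 0.25),
                        sox_pwm, tcf_pwm, n_sox_sites = 3, n_tcf_sites = 2,
                        min_gap = 100L, peak_width = 300L, window = 150L,
                        rel_threshold = 0.70, positions = NULL, seed = 1,
                        max_tries = 100L) {
  stopifnot(inherits(sox_pwm, "pwm"), inherits(tcf_pwm, "pwm"))
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop("class_fractions must sum to 1", call. = FALSE)
  class_names <- c("both", "sox_only", "tcf_only", "neither")
  if (is.null(names(class_fractions))) names(class_fractions) <- class_names
  chrom <- sub("\\s.*$", "", names(genome)[1])
  gchars <- strsplit(toupper(as.character(genome[[1]])), NULL)[[1]]
  glen <- length(gchars)
  half <- window %/% 2L
  counts <- round(n_peaks * class_fractions[class_names])
  counts[which.max(class_fractions[class_names])] <-
    counts[which.max(class_fractions[class_names])] + n_peaks - sum(counts)
  cons_sox <- consensus(sox_pwm); cons_tcf <- consensus(tcf_pwm)
  with_seed(derive_seed(seed, "plant"), {
    if (is.null(positions)) {
      required <- n_peaks * peak_width + (n_peaks + 1L) * min_gap
      if (required > glen)
        stop("peaks do not fit: need ", required, " bp with min_gap ",
             min_gap, ", genome has ", glen, call. = FALSE)
      extra <- glen - required
      cuts <- sort(floor(stats::runif(n_peaks) * extra))
      starts <- min_gap + (seq_len(n_peaks) - 1L) * (peak_width + min_gap) +
        cuts
      summits <- as.integer(starts + peak_width %/% 2L)
    } else {
      if (length(positions) != n_peaks)
        stop("positions must have length n_peaks", call. = FALSE)
      summits <- as.integer(positions)
      starts <- summits - peak_width %/% 2L
      if (any(starts < 0 | starts + peak_width > glen))
        stop("peak outside genome", call. = FALSE)
    }
    classes <- sample(rep(class_names, times = counts))
    scan_class <- function(win_seq) {
      sh <- scan_windows(c(w = win_seq), list(sox_pwm, tcf_pwm),
                         rel_threshold = rel_threshold)
      classify_peak(sh[sh$tf_class == "sox", ], sh[sh$tf_class == "tcf", ],
                    "w")
    }
    manifest_peaks <- vector("list", n_peaks)
    for (i in seq_len(n_peaks)) {
      cls <- classes[i]
      w0 <- summits[i] - half
      sox_off <- integer(0); tcf_off <- integer(0)
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        win <- gchars[(w0 + 1L):(w0 + window)]
        which_sox <- switch(cls, both = , sox_only = n_sox_sites, 0L)
        which_tcf <- switch(cls, both = , tcf_only = n_tcf_sites, 0L)
        lens <- c(rep(nchar(cons_sox), which_sox),
                  rep(nchar(cons_tcf), which_tcf))
        if (length(lens)) {
          offs <- .slot_offsets(window, lens)
          sox_off <- offs[seq_len(which_sox)]
          tcf_off <- offs[which_sox + seq_len(which_tcf)]
          for (o in sox_off)
            win[(o + 1L):(o + nchar(cons_sox))] <-
              strsplit(cons_sox, NULL)[[1]]
          for (o in tcf_off)
            win[(o + 1L):(o + nchar(cons_tcf))] <-
              strsplit(cons_tcf, NULL)[[1]]
        }
        got <- scan_class(paste(win, collapse = ""))
        want_label <- switch(cls, both = "sox_and_tcf", cls)
        if (got$label == want_label &&
            got$n_sox_sites >= which_sox && got$n_tcf_sites >= which_tcf) {
          gchars[(w0 + 1L):(w0 + window)] <- win
          ok <- TRUE
          break
        }
        # spurious background site: re-shuffle the window background
        gchars[(w0 + 1L):(w0 + window)] <-
          .euler_shuffle(gchars[(w0 + 1L):(w0 + window)])
      }
      if (!ok)
        stop("could not assemble a clean window for peak ", i,
             " after ", max_tries, " tries", call. = FALSE)
      manifest_peaks[[i]] <- list(
        peak_id = sprintf("peak%04d", i), class = cls,
        window_start = w0, sox_offsets = as.integer(sox_off),
        tcf_offsets = as.integer(tcf_off))
    }
    peaks <- tibble::tibble(
      chrom = chrom, start = as.integer(starts),
      end = as.integer(starts + peak_width),
      peak_id = sprintf("peak%04d", seq_len(n_peaks)),
      score = 100, strand = ".", summit = summits)
    out_genome <- Biostrings::DNAStringSet(paste(gchars, collapse = ""))
    names(out_genome) <- names(genome)[1]
    manifest <- list(
      seed = seed,
      params = list(n_peaks = n_peaks,
                    class_fractions = as.list(class_fractions),
                    n_sox_sites = n_sox_sites, n_tcf_sites = n_tcf_sites,
                    peak_width = peak_width, window = window,
                    sox_motif = sox_pwm$name, tcf_motif = tcf_pwm$name),
      peaks = manifest_peaks)
    list(peaks = peaks, genome = out_genome, manifest = manifest)
  })
}

#' Simulate a tissue-expression table with known enrichment
#'
#' Baseline TPM is log-normal per gene and shared across tissues; each
#' enriched gene has one assigned tissue multiplied by
#' `enrichment_factor`; optional multiplicative log-normal noise with the
#' given coefficient of variation.
#'
#' @param n_genes number of genes (ignored when `gene_ids` given).
#' @param tissues tissue labels (default five gastrula dissection-style
#'   territories).
#' @param enriched_fraction fraction of genes with an enriched tissue.
#' @param enrichment_factor fold enrichment (> 1).
#' @param noise_cv coefficient of variation of multiplicative noise
#'   (default 0).
#' @param seed integer seed.
#' @param gene_ids optional explicit gene identifiers.
#' @param baseline_meanlog,baseline_sdlog log-normal baseline parameters.
#' @return list: `expression` (genes x tissues matrix of TPM), `truth`
#'   (tibble gene_id, enriched, tissue).
#' @export
simulate_expression <- function(n_genes, tissues = c("endoderm",
                                  "mesoderm", "ectoderm", "organizer",
                                  "ventral"),
                                enriched_fraction = 0.3,
                                enrichment_factor = 3, noise_cv = 0,
                                seed = 1, gene_ids = NULL,
                                baseline_meanlog = log(50),
                                baseline_sdlog = 1) {
  if (enrichment_factor <= 1) stop("enrichment_factor must be > 1",
                                   call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  gene_ids <- gene_ids %||% sprintf("gene%04d", seq_len(n_genes))
  n_genes <- length(gene_ids)
  with_seed(derive_seed(seed, "expr"), {
    base <- stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
    m <- matrix(base, nrow = n_genes, ncol = length(tissues),
                dimnames = list(gene_ids, tissues))
    n_enr <- round(n_genes * enriched_fraction)
    enr_idx <- if (n_enr > 0) sample.int(n_genes, n_enr) else integer(0)
    enr_tissue <- rep(NA_character_, n_genes)
    if (n_enr > 0) {
      enr_tissue[enr_idx] <- sample(tissues, n_enr, replace = TRUE)
      for (i in enr_idx)
        m[i, enr_tissue[i]] <- m[i, enr_tissue[i]] * enrichment_factor
    }
    if (noise_cv > 0) {
      sdl <- sqrt(log(1 + noise_cv^2))
      m <- m * matrix(stats::rlnorm(length(m), -sdl^2 / 2, sdl),
                      nrow = n_genes)
    }
    list(expression = m,
         truth = tibble::tibble(gene_id = gene_ids,
                                enriched = !is.na(enr_tissue),
                                tissue = enr_tissue))
  })
}

#' Simulate a staged differential-expression table with known truth
#'
#' Per gene and stage, replicate log2 abundances are drawn for control
#' and knockdown with the given replicate dispersion; true DE genes carry
#' their effect from a random onset stage onward.  log2FC is the mean
#' log-ratio, p from a two-sample t on log abundances, FDR by
#' Benjamini-Hochberg within stage.
#'
#' @param n_genes number of genes (ignored when `gene_ids` given).
#' @param true_de_fraction fraction of genes truly differential.
#' @param log2fc_mean,log2fc_sd distribution of true |log2FC|.
#' @param reps_per_condition replicates per condition (>= 2).
#' @param dispersion SD of replicate log2 abundances (0 allowed).
#' @param stages stage labels in temporal order.
#' @param seed integer seed.
#' @param gene_ids optional explicit gene identifiers.
#' @param de_genes optional explicit set of truly-DE gene ids (overrides
#'   `true_de_fraction`).
#' @return list: `table` (tibble gene_id, stage, log2_fold_change, fdr),
#'   `truth` (tibble gene_id, is_de, direction, log2fc, onset_stage).
#' @export
simulate_de <- function(n_genes, true_de_fraction = 0.1,
                        log2fc_mean = 2.5, log2fc_sd = 0.5,
                        reps_per_condition = 3, dispersion = 0.25,
                        stages = c("NF9", "NF10", "NF10.5", "NF11",
                                   "NF12"),
                        seed = 1, gene_ids = NULL, de_genes = NULL) {
  if (reps_per_condition < 2) stop("need >= 2 replicates", call. = FALSE)
  if (true_de_fraction < 0 || true_de_fraction > 1)
    stop("true_de_fraction must be in [0, 1]", call. = FALSE)
  gene_ids <- gene_ids %||% sprintf("gene%04d", seq_len(n_genes))
  n_genes <- length(gene_ids)
  with_seed(derive_seed(seed, "de"), {
    if (is.null(de_genes)) {
      n_de <- round(n_genes * true_de_fraction)
      de_idx <- if (n_de > 0) sample.int(n_genes, n_de) else integer(0)
    } else {
      de_idx <- match(de_genes, gene_ids)
      if (any(is.na(de_idx))) stop("de_genes not in gene_ids",
                                   call. = FALSE)
    }
    is_de <- seq_len(n_genes) %in% de_idx
    sign <- ifelse(stats::runif(n_genes) < 0.5, -1, 1)
    mag <- abs(stats::rnorm(n_genes, log2fc_mean, log2fc_sd))
    onset <- sample(seq_along(stages), n_genes, replace = TRUE)
    mu <- stats::rnorm(n_genes, 5, 2)
    rows <- vector("list", length(stages))
    for (si in seq_along(stages)) {
      delta <- ifelse(is_de & si >= onset, sign * mag, 0)
      lfc <- numeric(n_genes); pv <- numeric(n_genes)
      for (g in seq_len(n_genes)) {
        ctrl <- stats::rnorm(reps_per_condition, mu[g], dispersion)
        trt <- stats::rnorm(reps_per_condition, mu[g] + delta[g],
                            dispersion)
        lfc[g] <- mean(trt) - mean(ctrl)
        pv[g] <- t_two_sample(trt, ctrl)$p_value
      }
      rows[[si]] <- tibble::tibble(gene_id = gene_ids,
                                   stage = stages[si],
                                   log2_fold_change = lfc,
                                   fdr = bh_fdr(pv))
    }
    list(table = do.call(rbind, rows),
         truth = tibble::tibble(
           gene_id = gene_ids, is_de = is_de,
           direction = ifelse(sign < 0, "down_in_MO", "up_in_MO"),
           log2fc = ifelse(is_de, sign * mag, 0),
           onset_stage = stages[onset]))
  })
}

#' Synthetic piecewise-constant coverage track
#'
#' Background coverage plus a triangular enrichment peak of the given
#' height and half-width around every summit, discretized in `step` bp
#' runs — a desk-scale stand-in for a ChIP coverage track.
#'
#' @param peaks peak tibble (chrom, summit).
#' @param chrom_sizes named chromosome lengths.
#' @param background baseline coverage (default 1).
#' @param peak_height maximum added coverage at the summit (default 20).
#' @param peak_halfwidth bp from summit to the bump's edge (default 500).
#' @param step run length of the piecewise-constant discretization.
#' @return bedGraph tibble (chrom, start, end, value).
#' @export
simulate_coverage <- function(peaks, chrom_sizes, background = 1,
                              peak_height = 20, peak_halfwidth = 500,
                              step = 50L) {
  out <- lapply(names(chrom_sizes), function(cn) {
    len <- chrom_sizes[[cn]]
    v <- rep(background, len)
    for (s in peaks$summit[peaks$chrom == cn]) {
      lo <- max(s - peak_halfwidth, 0L)
      hi <- min(s + peak_halfwidth, len - 1L)
      pos <- lo:hi
      bump <- peak_height * (1 - abs(pos - s) / peak_halfwidth)
      # discretize to `step` bp plateaus (value at plateau center)
      plat <- (pos - s) %/% step
      bump <- stats::ave(bump, plat, FUN = mean)
      v[pos + 1L] <- v[pos + 1L] + bump
    }
    r <- rle(v)
    ends <- cumsum(r$lengths)
    tibble::tibble(chrom = cn, start = c(0L, ends[-length(ends)]),
                   end = ends, value = r$values)
  })
  do.call(rbind, out)
}

#' Write a truth manifest as JSON
#'
#' @param manifest manifest list (e.g. from [plant_peaks()] or
#'   [simulate_cooccupancy_dataset()]).
#' @param path output path.
#' @export
write_truth_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a truth manifest written by [write_truth_manifest()]
#'
#' @param path JSON path.
#' @return manifest list.
#' @export
read_truth_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE,
                      simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
}

#' Simulate a complete co-occupancy study with ground truth
#'
#' One call that emulates the statistical structure of an integrative
#' ChIP/RNA study at desk scale: a Markov background genome; gene models
#' on a regular grid; peaks planted near a known subset of TSSs with
#' known motif-class grammars; two staged knockdown DE tables whose truly
#' regulated gene sets overlap the bound set by construction; a
#' tissue-expression table with known enrichment; and a synthetic
#' coverage track.  Everything is recorded in the returned manifest.
#'
#' @param seed master integer seed.
#' @param n_genes number of gene models.
#' @param n_peaks number of planted peaks (<= n_genes; each peak is
#'   placed 2 kb upstream of a distinct TSS so the bound gene set is
#'   known exactly).
#' @param class_fractions motif-class mix passed to [plant_peaks()].
#' @param sox_pwm,tcf_pwm PWMs to plant; defaults are bundled
#'   Sox17/Tcf7-style models (see [example_pwms()]).
#' @param n_regulated truly regulated genes per factor.
#' @param gene_spacing bp between consecutive TSSs.
#' @param dispersion,log2fc_mean,log2fc_sd DE simulation parameters
#'   (dispersion 0 gives exact recovery).
#' @param noise_cv expression noise (0 gives exact spatial recovery).
#' @return list: genome, genes, peaks, windows, window_seqs, coverage,
#'   de_sox17, de_bcat, expression, manifest.
#' @export
simulate_cooccupancy_dataset <- function(seed = 1, n_genes = 150,
                                         n_peaks = 60,
                                         class_fractions = c(both = 0.5,
                                           sox_only = 0.25, tcf_only = 0,
                                           neither = 0.25),
                                         sox_pwm = NULL, tcf_pwm = NULL,
                                         n_regulated = 50,
                                         gene_spacing = 6000L,
                                         dispersion = 0,
                                         log2fc_mean = 4, log2fc_sd = 0,
                                         noise_cv = 0) {
  if (n_peaks > n_genes) stop("n_peaks must be <= n_genes", call. = FALSE)
  if (is.null(sox_pwm) || is.null(tcf_pwm)) {
    ex <- example_pwms()
    sox_pwm <- sox_pwm %||% ex$sox
    tcf_pwm <- tcf_pwm %||% ex$tcf
  }
  glen <- (n_genes + 1L) * gene_spacing
  genome <- simulate_genome(glen, seed = seed)
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  tss <- seq_len(n_genes) * gene_spacing
  genes <- tibble::tibble(
    gene_id = gene_ids, chrom = names(genome)[1], tss = as.integer(tss),
    strand = "+", span_start = as.integer(tss),
    span_end = as.integer(tss + 2000L),
    exons = lapply(tss, function(t)
      cbind(start = as.integer(t), end = as.integer(t + 400L))))
  bound_idx <- with_seed(derive_seed(seed, "bound"),
                         sort(sample.int(n_genes, n_peaks)))
  summits <- as.integer(tss[bound_idx] - 2000L)
  planted <- plant_peaks(genome, n_peaks,
                         class_fractions = class_fractions,
                         sox_pwm = sox_pwm, tcf_pwm = tcf_pwm,
                         positions = summits, seed = seed)
  bound_genes <- gene_ids[bound_idx]
  reg <- with_seed(derive_seed(seed, "reg"), {
    list(sox = sample(gene_ids, n_regulated),
         bcat = sample(gene_ids, n_regulated))
  })
  de_sox <- simulate_de(n_genes, gene_ids = gene_ids,
                        de_genes = reg$sox, dispersion = dispersion,
                        log2fc_mean = log2fc_mean, log2fc_sd = log2fc_sd,
                        seed = derive_seed(seed, "sox17"))
  de_bcat <- simulate_de(n_genes, gene_ids = gene_ids,
                         de_genes = reg$bcat, dispersion = dispersion,
                         log2fc_mean = log2fc_mean, log2fc_sd = log2fc_sd,
                         seed = derive_seed(seed, "bcat"))
  expr <- simulate_expression(n_genes, gene_ids = gene_ids,
                              noise_cv = noise_cv, seed = seed)
  sizes <- chrom_sizes(planted$genome)
  coverage <- simulate_coverage(planted$peaks, sizes)
  windows <- summit_window(planted$peaks, width = 150L,
                           chrom_sizes = sizes)
  window_seqs <- extract_sequences(planted$genome, windows)
  manifest <- list(
    seed = seed,
    params = list(n_genes = n_genes, n_peaks = n_peaks,
                  n_regulated = n_regulated,
                  gene_spacing = gene_spacing, dispersion = dispersion,
                  noise_cv = noise_cv),
    peaks = planted$manifest$peaks,
    bound_genes = bound_genes,
    regulated_sox17 = reg$sox,
    regulated_bcat = reg$bcat,
    de_truth_sox17 = as.list(de_sox$truth),
    de_truth_bcat = as.list(de_bcat$truth),
    expression_truth = as.list(expr$truth))
  list(genome = planted$genome, genes = genes, peaks = planted$peaks,
       windows = windows, window_seqs = window_seqs,
       coverage = coverage, de_sox17 = de_sox, de_bcat = de_bcat,
       expression = expr, manifest = manifest)
}

#' Bundled example PWMs
#'
#' Synthetic 12 bp Sox17-style (HMG-box AACAAT core) and Tcf/Lef-style
#' (CTTTGAT core) probability models used by the simulators, examples and
#' tests.  They are stand-ins shaped like the respective family
#' consensus, not database motifs; their consensi were chosen so that no
#' alignment of one against the other (either strand) reaches the 0.70
#' relative-score threshold, keeping planted class labels unambiguous.
#'
#' @return list with elements `sox` and `tcf` ("pwm" objects).
#' @export
example_pwms <- function() {
  strong <- function(base) {
    p <- rep(0.04, 4); p[match(base, DNA_BASES)] <- 0.88; p
  }
  as_mat <- function(s)
    do.call(rbind, lapply(strsplit(s, NULL)[[1]], strong))
  list(sox = pwm(as_mat("CTAACAATGGCA"), "sox17_syn", tf_class = "sox"),
       tcf = pwm(as_mat("GCCTTTGATCTT"), "tcf7_syn", tf_class = "tcf"))
}
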