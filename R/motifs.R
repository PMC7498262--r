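#' Construct a position weight matrix
#'
#' @param probs L x 4 numeric matrix of base probabilities, columns in
#'   A, C, G, T order; each row must sum to 1 within 0.01 before the
#'   pseudocount is applied.
#' @param name motif identifier.
#' @param tf_class one of "sox", "tcf", "other" — the TF family the motif
#'   is scored as during co-occurrence classification.
#' @param source "homer", "cisbp" or "custom".
#' @param pseudocount small positive value added to every cell before
#'   per-row renormalization (default 1e-3), so log-odds are finite.
#' @return object of class "pwm".
#' @export
pwm <- function(probs, name, tf_class = c("other", "sox", "tcf"),
                source = "custom", pseudocount = 1e-3) {
  tf_class <- match.arg(tf_class)
  probs <- as.matrix(probs)
  if (ncol(probs) != 4) stop("PWM must have 4 columns", call. = FALSE)
  if (nrow(probs) < 4) stop("PWM must have length >= 4", call. = FALSE)
  if (any(probs < 0)) stop("negative PWM entries", call. = FALSE)
  bad <- which(abs(rowSums(probs) - 1) > 0.01)
  if (length(bad))
    stop(sprintf("PWM row %d sums to %.3f, not 1", bad[1],
                 rowSums(probs)[bad[1]]), call. = FALSE)
  probs <- probs + pseudocount
  probs <- probs / rowSums(probs)
  colnames(probs) <- DNA_BASES
  structure(list(name = name, tf_class = tf_class, probs = probs,
                 source = source, pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s' (%s, %s): length %d, consensus %s\n", x$name,
              x$tf_class, x$source, nrow(x$probs), consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM
#'
#' @param x a "pwm" object.
#' @return character string of the per-position most probable bases.
#' @export
consensus <- function(x) {
  paste(DNA_BASES[apply(x$probs, 1, which.max)], collapse = "")
}

#' Read motif models
#'
#' Two text dialects: HOMER `.motif` (one or more motifs per file; header
#' `>consensus name score` followed by one row of 4 probabilities per
#' position) and CIS-BP PWM text (header `Pos A C G T`, one motif per
#' file).
#'
#' @param path file path.
#' @param format "homer" or "cisbp".
#' @param tf_class TF family assigned to every motif in the file.
#' @param pseudocount passed to [pwm()].
#' @return list of "pwm" objects.
#' @export
read_motifs <- function(path, format = c("homer", "cisbp"),
                        tf_class = "other", pseudocount = 1e-3) {
  format <- match.arg(format)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  parse_rows <- function(rows, where) {
    if (!length(rows)) stop("empty motif matrix in ", where, call. = FALSE)
    m <- lapply(rows, function(r) {
      v <- suppressWarnings(as.numeric(strsplit(r, "[ \t]+")[[1]]))
      if (length(v) != 4 || any(is.na(v)))
        stop("motif row with wrong column count in ", where, call. = FALSE)
      v
    })
    do.call(rbind, m)
  }
  if (format == "homer") {
    hdr <- grep("^>", lines)
    if (!length(hdr)) stop("no '>' header in HOMER motif file", call. = FALSE)
    ends <- c(hdr[-1] - 1L, length(lines))
    Map(function(h, e) {
      parts <- strsplit(sub("^>", "", lines[h]), "[ \t]+")[[1]]
      name <- if (length(parts) >= 2) parts[2] else parts[1]
      pwm(parse_rows(lines[(h + 1):e], name), name = name,
          tf_class = tf_class, source = "homer", pseudocount = pseudocount)
    }, hdr, ends)
  } else {
    if (!grepl("^Pos[ \t]+A[ \t]+C[ \t]+G[ \t]+T$", lines[1]))
      stop("CIS-BP file must start with header 'Pos A C G T'",
           call. = FALSE)
    rows <- lines[-1]
    m <- lapply(rows, function(r) {
      v <- suppressWarnings(as.numeric(strsplit(r, "[ \t]+")[[1]]))
      if (length(v) != 5 || any(is.na(v)))
        stop("CIS-BP row with wrong column count", call. = FALSE)
      v[-1]
    })
    name <- sub("\\.[^.]*$", "", basename(path))
    list(pwm(do.call(rbind, m), name = name, tf_class = tf_class,
             source = "cisbp", pseudocount = pseudocount))
  }
}

# Log-odds score of every window of length L on the coded strand;
# windows containing non-ACGT bases score NA.
.scan_scores <- function(code, smat) {
  L <- nrow(smat); n <- length(code)
  if (n < L) return(numeric(0))
  sc <- numeric(n - L + 1)
  for (j in seq_len(L)) {
    cj <- code[j:(j + n - L)]
    sc <- sc + smat[cbind(j, cj)]   # NA code -> NA score
  }
  sc
}

# Precomputed scanning state for one PWM against a fixed background.
.pwm_scanner <- function(pwm, background = c(0.25, 0.25, 0.25, 0.25)) {
  smat <- log2(sweep(pwm$probs, 2, background, "/"))
  lo <- sum(apply(smat, 1, min))
  hi <- sum(apply(smat, 1, max))
  list(name = pwm$name, tf_class = pwm$tf_class, smat = smat,
       L = nrow(smat), lo = lo, span = hi - lo)
}

# Hits of one precompiled scanner on an encoded sequence (and its
# reverse-complement encoding); returns NULL or a list of columns.
.scan_hits <- function(code, rc_code, sc, rel_threshold) {
  n <- length(code)
  if (n < sc$L) return(NULL)
  rel_of <- function(s) {
    if (sc$span > 0) (s - sc$lo) / sc$span else rep(1, length(s))
  }
  fs <- .scan_scores(code, sc$smat)
  rs <- .scan_scores(rc_code, sc$smat)
  fw <- rel_of(fs); rv <- rel_of(rs)
  kf <- which(!is.na(fw) & fw >= rel_threshold - 1e-12)
  kr <- which(!is.na(rv) & rv >= rel_threshold - 1e-12)
  if (!length(kf) && !length(kr)) return(NULL)
  off <- c(kf - 1L, n - sc$L - (kr - 1L))
  strand <- rep(c("+", "-"), c(length(kf), length(kr)))
  rel <- pmin(c(fw[kf], rv[kr]), 1)
  lod <- c(fs[kf], rs[kr])
  o <- order(off, strand)
  list(offset = as.integer(off[o]), strand = strand[o],
       log_odds = lod[o], relative_score = rel[o])
}

#' Scan a sequence with a PWM at a relative-score threshold
#'
#' Both strands are scanned at every offset.  A window's log-odds score is
#' sum over positions of log2(p_base / background_base); its relative
#' score rescales that between the minimum and maximum attainable scores
#' of the PWM, so the threshold (default 0.70) is scale-free.  Windows
#' containing N are excluded.
#'
#' @param seq character string over A, C, G, T, N.
#' @param pwm a "pwm" object.
#' @param rel_threshold minimum relative score in (0, 1\] (default 0.70).
#' @param background base composition used for the log-odds (A, C, G, T;
#'   default uniform).
#' @return tibble of hits: motif_name, tf_class, offset (0-based start of
#'   the site within `seq`, on the + strand coordinate system), strand,
#'   log_odds, relative_score, width.  Sorted by offset, "+" before "-" at
#'   equal offset.  A sequence shorter than the motif yields zero rows.
#' @export
scan_sequence <- function(seq, pwm, rel_threshold = 0.70,
                          background = c(0.25, 0.25, 0.25, 0.25)) {
  stopifnot(inherits(pwm, "pwm"))
  if (rel_threshold <= 0 || rel_threshold > 1)
    stop("rel_threshold must be in (0, 1]", call. = FALSE)
  if (abs(sum(background) - 1) > 1e-6 || any(background <= 0))
    stop("background must be positive and sum to 1", call. = FALSE)
  sc <- .pwm_scanner(pwm, background)
  code <- encode_dna(seq)
  h <- .scan_hits(code, rev(5L - code), sc, rel_threshold)
  if (is.null(h))
    return(tibble::tibble(motif_name = character(),
                          tf_class = character(), offset = integer(),
                          strand = character(), log_odds = numeric(),
                          relative_score = numeric(), width = integer()))
  tibble::tibble(motif_name = pwm$name, tf_class = pwm$tf_class,
                 offset = h$offset, strand = h$strand,
                 log_odds = h$log_odds,
                 relative_score = h$relative_score, width = sc$L)
}

#' Scan a set of windows with several PWMs
#'
#' @param seqs named character vector of window sequences (names are peak
#'   ids).
#' @param pwms list of "pwm" objects (mixed TF classes allowed).
#' @param rel_threshold,background passed to [scan_sequence()].
#' @return tibble of hits with a peak_id column.
#' @export
scan_windows <- function(seqs, pwms, rel_threshold = 0.70,
                         background = c(0.25, 0.25, 0.25, 0.25)) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  ids <- names(seqs) %||% as.character(seq_along(seqs))
  scanners <- lapply(pwms, .pwm_scanner, background = background)
  acc <- vector("list", length(seqs) * length(pwms))
  k <- 0
  for (i in seq_along(seqs)) {
    code <- encode_dna(seqs[[i]])
    rc_code <- rev(5L - code)
    for (s in scanners) {
      h <- .scan_hits(code, rc_code, s, rel_threshold)
      if (!is.null(h)) {
        k <- k + 1
        h$peak_id <- ids[i]; h$motif_name <- s$name
        h$tf_class <- s$tf_class; h$width <- s$L
        acc[[k]] <- h
      }
    }
  }
  if (k == 0)
    return(tibble::tibble(peak_id = character(), motif_name = character(),
                          tf_class = character(), offset = integer(),
                          strand = character(), log_odds = numeric(),
                          relative_score = numeric(), width = integer()))
  acc <- acc[seq_len(k)]
  pull <- function(f) unlist(lapply(acc, `[[`, f), use.names = FALSE)
  nh <- vapply(acc, function(h) length(h$offset), integer(1))
  tibble::tibble(
    peak_id = rep(vapply(acc, `[[`, character(1), "peak_id"), nh),
    motif_name = rep(vapply(acc, `[[`, character(1), "motif_name"), nh),
    tf_class = rep(vapply(acc, `[[`, character(1), "tf_class"), nh),
    offset = pull("offset"), strand = pull("strand"),
    log_odds = pull("log_odds"),
    relative_score = pull("relative_score"),
    width = rep(vapply(acc, `[[`, integer(1), "width"), nh))
}

.count_distinct_sites <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0) return(0L)
  nrow(unique(hits[, c("offset", "strand")]))
}

#' Classify one peak window by motif co-occurrence
#'
#' Site counts are distinct (offset, strand) positions per TF class: hits
#' from multiple PWMs of one class starting at the same position count
#' once.
#'
#' @param sox_hits,tcf_hits hit tibbles for one window (as returned by
#'   [scan_sequence()]), possibly empty.
#' @param peak_id identifier attached to the result.
#' @return one-row tibble: peak_id, label (sox_and_tcf / sox_only /
#'   tcf_only / neither), n_sox_sites, n_tcf_sites.
#' @export
classify_peak <- function(sox_hits, tcf_hits, peak_id = NA_character_) {
  ns <- .count_distinct_sites(sox_hits)
  nt <- .count_distinct_sites(tcf_hits)
  label <- if (ns > 0 && nt > 0) "sox_and_tcf"
    else if (ns > 0) "sox_only"
    else if (nt > 0) "tcf_only"
    else "neither"
  tibble::tibble(peak_id = peak_id, label = label,
                 n_sox_sites = ns, n_tcf_sites = nt)
}

#' Classify every peak window from a pooled hit table
#'
#' @param hits tibble from [scan_windows()] (needs peak_id and tf_class).
#' @param peak_ids character vector of all window ids; windows without
#'   hits are classified "neither".
#' @return tibble with one row per peak_id.
#' @export
classify_windows <- function(hits, peak_ids) {
  count_class <- function(class) {
    h <- hits[hits$tf_class == class, c("peak_id", "offset", "strand")]
    u <- h[!duplicated(h), ]
    as.integer(table(factor(u$peak_id, levels = peak_ids)))
  }
  ns <- count_class("sox")
  nt <- count_class("tcf")
  label <- ifelse(ns > 0 & nt > 0, "sox_and_tcf",
           ifelse(ns > 0, "sox_only",
           ifelse(nt > 0, "tcf_only", "neither")))
  tibble::tibble(peak_id = peak_ids, label = label,
                 n_sox_sites = ns, n_tcf_sites = nt)
}

#' Dinucleotide-preserving sequence shuffles
#'
#' Random permutations of a sequence that keep every adjacent-pair count
#' identical (hence mononucleotide counts and GC content), built by the
#' Euler-path construction: the dinucleotide multigraph is walked along a
#' random Eulerian path with the same start and end vertices, so the
#' first and last bases are preserved.  Runs of N split the sequence into
#' segments that are shuffled independently.
#'
#' @param seq character string over A, C, G, T, N.
#' @param n number of shuffles (default 10, the usual background depth).
#' @param seed master integer seed.
#' @param id optional identifier; the RNG stream is keyed on (id, seed) so
#'   results are independent of processing order.
#' @return list with `original_id`, `shuffles` (character vector of length
#'   `n`), `seed`.
#' @export
dinucleotide_shuffle <- function(seq, n = 10, seed = 1, id = NULL) {
  if (nchar(seq) < 2) stop("sequence length must be >= 2", call. = FALSE)
  chars <- strsplit(toupper(seq), NULL)[[1]]
  if (!all(chars %in% c(DNA_BASES, "N")))
    stop("sequence must be over A, C, G, T, N", call. = FALSE)
  is_n <- chars == "N"
  r <- rle(is_n)
  seg_end <- cumsum(r$lengths)
  seg_start <- seg_end - r$lengths + 1L
  with_seed(derive_seed(seed, id), {
    shuffles <- vapply(seq_len(n), function(i) {
      out <- chars
      for (s in which(!r$values)) {
        idx <- seg_start[s]:seg_end[s]
        if (length(idx) >= 3)
          out[idx] <- .euler_shuffle(chars[idx])
      }
      paste(out, collapse = "")
    }, character(1))
    list(original_id = id, shuffles = shuffles, seed = seed)
  })
}

# One random dinucleotide-preserving shuffle of a pure-ACGT character
# vector (Altschul-Erickson Euler-path construction).
.euler_shuffle <- function(chars) {
  m <- length(chars)
  src <- chars[-m]; dst <- chars[-1]
  verts <- unique(chars)
  term <- chars[m]
  edges <- split(dst, factor(src, levels = verts))
  out_verts <- verts[lengths(edges) > 0]
  # choose a random "last edge" per non-terminal vertex until they form a
  # tree rooted at the terminal vertex
  nonterm <- setdiff(out_verts, term)
  last <- NULL
  if (length(nonterm)) {
    repeat {
      last <- vapply(nonterm, function(v) {
        e <- edges[[v]]
        e[sample.int(length(e), 1)]
      }, character(1))
      names(last) <- nonterm
      # accept when following designated last edges from every vertex
      # reaches the terminal vertex (tree condition)
      reaches <- function(v) {
        steps <- 0
        while (steps <= length(nonterm)) {
          if (v == term) return(TRUE)
          if (!(v %in% nonterm)) return(FALSE)
          v <- last[[v]]
          steps <- steps + 1
        }
        FALSE
      }
      ok <- all(vapply(nonterm, reaches, logical(1)))
      if (ok) break
    }
  }
  # permute remaining edges, append the designated last edge
  ordered <- lapply(out_verts, function(v) {
    e <- edges[[v]]
    if (v %in% nonterm) {
      li <- match(last[[v]], e)
      rest <- e[-li]
      c(if (length(rest)) rest[sample.int(length(rest))], e[li])
    } else {
      e[sample.int(length(e))]
    }
  })
  names(ordered) <- out_verts
  ptr <- stats::setNames(rep(1L, length(out_verts)), out_verts)
  res <- character(m)
  res[1] <- chars[1]
  v <- chars[1]
  for (i in 2:m) {
    nxt <- ordered[[v]][ptr[[v]]]
    ptr[[v]] <- ptr[[v]] + 1L
    res[i] <- nxt
    v <- nxt
  }
  res
}

#' Count dinucleotides in a sequence
#'
#' @param seq character string.
#' @return named integer vector over the 16 ACGT dinucleotides (pairs
#'   involving N are ignored).
#' @export
dinucleotide_counts <- function(seq) {
  chars <- strsplit(toupper(seq), NULL)[[1]]
  pairs <- paste0(chars[-length(chars)], chars[-1])
  all16 <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))
  tab <- table(factor(pairs[pairs %in% all16], levels = all16))
  stats::setNames(as.integer(tab), all16)
}

#' Build a shuffled background for a set of windows
#'
#' Generates `n_shuffles` dinucleotide-preserving shuffles of every window
#' and classifies each shuffle identically to the real windows.  Each
#' shuffle is one background observation (10x the real n by default).
#'
#' @param seqs named character vector of window sequences.
#' @param pwms list of "pwm" objects used for scanning.
#' @param n_shuffles shuffles per window (default 10).
#' @param seed master seed.
#' @param rel_threshold,background passed to [scan_windows()].
#' @return list with `classes` (classification tibble over all shuffles)
#'   and `seqs` (the named shuffle sequences).
#' @export
shuffle_background <- function(seqs, pwms, n_shuffles = 10, seed = 1,
                               rel_threshold = 0.70,
                               background = c(0.25, 0.25, 0.25, 0.25)) {
  ids <- names(seqs) %||% as.character(seq_along(seqs))
  bg <- unlist(lapply(seq_along(seqs), function(i) {
    sh <- dinucleotide_shuffle(seqs[[i]], n = n_shuffles, seed = seed,
                               id = ids[i])
    stats::setNames(sh$shuffles,
                    paste0(ids[i], "_shuf", seq_len(n_shuffles)))
  }))
  hits <- scan_windows(bg, pwms, rel_threshold, background)
  list(classes = classify_windows(hits, names(bg)), seqs = bg)
}

#' Motif-class enrichment of real peaks over a shuffled background
#'
#' One-sided (greater) Fisher's exact test on the 2x2 table of windows
#' with/without the label in the real set versus the background set.
#'
#' @param real,background classification tibbles (see
#'   [classify_windows()]).
#' @param label class label tested, e.g. "sox_and_tcf".
#' @return list: label, a, b, c, d, odds_ratio, p_value.
#' @export
motif_class_enrichment <- function(real, background, label) {
  if (nrow(real) == 0) stop("empty real set", call. = FALSE)
  a <- sum(real$label == label); b <- nrow(real) - a
  c <- sum(background$label == label); d <- nrow(background) - c
  ft <- fisher_exact(a, b, c, d, alternative = "greater")
  list(label = label, a = a, b = b, c = c, d = d,
       odds_ratio = ft$odds_ratio, p_value = ft$p_value)
}

#' Minimum Sox-Tcf site spacing within a window
#'
#' Distance between site centers (offset + width/2), minimized over all
#' cross-class pairs.
#'
#' @param sox_hits,tcf_hits hit tibbles for one window.
#' @param cluster_bp clustering cutoff in bp (default 50).
#' @return list: `min_center_distance` (NA when either class is absent)
#'   and `clustered_within` (distance <= cutoff; FALSE when undefined).
#' @export
motif_spacing <- function(sox_hits, tcf_hits, cluster_bp = 50) {
  if (is.null(sox_hits) || is.null(tcf_hits) ||
      nrow(sox_hits) == 0 || nrow(tcf_hits) == 0)
    return(list(min_center_distance = NA_real_, clustered_within = FALSE))
  cs <- sox_hits$offset + sox_hits$width / 2
  ct <- tcf_hits$offset + tcf_hits$width / 2
  d <- min(abs(outer(cs, ct, "-")))
  list(min_center_distance = d, clustered_within = d <= cluster_bp)
}

#' Summary of Sox site counts per window
#'
#' Histogram of n_sox_sites and the fraction of windows with strictly
#' more than `threshold` sites; when a background classification is
#' supplied, its companion fraction and a one-sided Fisher p-value are
#' included.
#'
#' @param classes classification tibble.
#' @param threshold site-count cutoff (default 5, i.e. ">5 sites").
#' @param background optional background classification tibble.
#' @return list: histogram (table), fraction, and with background:
#'   background_fraction, p_value.
#' @export
motif_count_summary <- function(classes, threshold = 5, background = NULL) {
  if (nrow(classes) == 0)
    return(list(histogram = table(integer(0)), fraction = NA_real_))
  hist <- table(classes$n_sox_sites)
  frac <- mean(classes$n_sox_sites > threshold)
  out <- list(histogram = hist, fraction = frac)
  if (!is.null(background) && nrow(background) > 0) {
    a <- sum(classes$n_sox_sites > threshold)
    c <- sum(background$n_sox_sites > threshold)
    ft <- fisher_exact(a, nrow(classes) - a, c, nrow(background) - c,
                       alternative = "greater")
    out$background_fraction <- mean(background$n_sox_sites > threshold)
    out$p_value <- ft$p_value
  }
  out
}
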