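#' Construct a table of genomic intervals
#'
#' Intervals are 0-based, half-open \[start, end) — the BED convention —
#' throughout the package.
#'
#' @param chrom chromosome names.
#' @param start,end integer positions, end > start >= 0.
#' @param strand "+", "-" or "." (recycled).
#' @return tibble with columns chrom, start, end, strand.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(chrom) | !nzchar(chrom)))
    stop("chrom must be non-empty", call. = FALSE)
  if (any(start < 0)) stop("start must be >= 0", call. = FALSE)
  if (any(end <= start)) stop("end must be > start", call. = FALSE)
  if (!all(strand %in% c("+", "-", ".")))
    stop("strand must be one of +, -, .", call. = FALSE)
  tibble::tibble(chrom = as.character(chrom), start = start, end = end,
                 strand = rep_len(as.character(strand), length(chrom)))
}

as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = ifelse(x$strand == ".", "*", x$strand))
}

#' Read ChIP-seq peaks
#'
#' Supports three tab-separated dialects of MACS2-style output:
#' \describe{
#'   \item{narrowPeak}{10 columns; the summit is start + column-10 offset;
#'     an offset of -1 places the summit at the interval midpoint (floor).}
#'   \item{bed6}{6 columns; the summit defaults to the interval midpoint.}
#'   \item{summit-bed}{BED of 1 bp summit positions; the interval is the
#'     single summit base.}
#' }
#' Coordinates are kept 0-based half-open.  Malformed lines raise an error
#' naming the offending line number.
#'
#' @param path file path.
#' @param format one of "narrowPeak", "bed6", "summit-bed".
#' @return tibble of peaks: chrom, start, end, peak_id, score, strand,
#'   summit.
#' @export
read_peaks <- function(path, format = c("narrowPeak", "bed6", "summit-bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  ncol_needed <- switch(format, narrowPeak = 10L, bed6 = 6L, `summit-bed` = 5L)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < ncol_needed)
  if (length(bad))
    stop(sprintf("malformed %s line %d: expected >= %d columns, found %d",
                 format, bad[1], ncol_needed, lengths(fields)[bad[1]]),
         call. = FALSE)
  get_col <- function(i) vapply(fields, `[[`, character(1), i)
  chrom <- get_col(1)
  start <- suppressWarnings(as.integer(get_col(2)))
  end <- suppressWarnings(as.integer(get_col(3)))
  name <- get_col(4)
  score <- suppressWarnings(as.numeric(get_col(5)))
  bad <- which(is.na(start) | is.na(end) | is.na(score) | end <= start |
                 start < 0)
  if (length(bad))
    stop(sprintf("malformed %s line %d: bad coordinates or score",
                 format, bad[1]), call. = FALSE)
  strand <- if (format == "summit-bed") rep(".", length(lines)) else {
    s <- get_col(6)
    if (!all(s %in% c("+", "-", ".")))
      stop(sprintf("malformed %s line %d: bad strand", format,
                   which(!s %in% c("+", "-", "."))[1]), call. = FALSE)
    s
  }
  summit <- switch(format,
    narrowPeak = {
      off <- suppressWarnings(as.integer(get_col(10)))
      bad <- which(is.na(off) | off < -1L)
      if (length(bad))
        stop(sprintf("malformed narrowPeak line %d: bad summit offset",
                     bad[1]), call. = FALSE)
      ifelse(off == -1L, start + (end - start) %/% 2L, start + off)
    },
    bed6 = start + (end - start) %/% 2L,
    `summit-bed` = start)
  bad <- which(summit < start | summit >= end)
  if (length(bad))
    stop(sprintf("line %d: summit %d outside interval [%d, %d)",
                 bad[1], summit[bad[1]], start[bad[1]], end[bad[1]]),
         call. = FALSE)
  tibble::tibble(chrom = chrom, start = start, end = end, peak_id = name,
                 score = score, strand = strand,
                 summit = as.integer(summit))
}

#' Write intervals or peaks as BED6
#'
#' @param x tibble with chrom, start, end and optionally peak_id/score/
#'   strand columns.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  name <- x[["peak_id"]] %||% x[["gene_id"]] %||% x[["name"]] %||%
    rep(".", nrow(x))
  score <- x[["score"]] %||% rep(0, nrow(x))
  strand <- x[["strand"]] %||% rep(".", nrow(x))
  out <- paste(x$chrom, x$start, x$end, name,
               vapply(score, function(s)
                 format(s, trim = TRUE, scientific = FALSE),
                 character(1)),
               strand, sep = "\t")
  writeLines(out, path)
  invisible(path)
}

#' Fixed-width windows centered on peak summits
#'
#' The unit of motif analysis: a `width` bp window \[summit - width/2,
#' summit + width/2), optionally clipped to chromosome bounds.
#'
#' @param peaks peak tibble (needs chrom, summit; see [read_peaks()]).
#' @param width window width in bp (even, default 150).
#' @param chrom_sizes optional named vector of chromosome lengths; when
#'   supplied, windows are clipped at 0 and the chromosome end.
#' @return tibble of intervals with a peak_id column.
#' @export
summit_window <- function(peaks, width = 150L, chrom_sizes = NULL) {
  if (width <= 0 || width %% 2 != 0)
    stop("width must be even and > 0", call. = FALSE)
  half <- width %/% 2L
  start <- pmax(peaks$summit - half, 0L)
  end <- peaks$summit + half
  if (!is.null(chrom_sizes)) {
    missing <- setdiff(unique(peaks$chrom), names(chrom_sizes))
    if (length(missing))
      stop("no chromosome length for: ", paste(missing, collapse = ", "),
           call. = FALSE)
    end <- pmin(end, unname(chrom_sizes[peaks$chrom]))
  }
  tibble::tibble(chrom = peaks$chrom, start = as.integer(start),
                 end = as.integer(end),
                 strand = rep(".", nrow(peaks)),
                 peak_id = peaks$peak_id)
}

#' All pairwise overlaps between two interval sets
#'
#' Standard 1 bp-overlap interval intersection (half-open coordinates:
#' abutting intervals do not overlap).  Backed by
#' `GenomicRanges::findOverlaps`.
#'
#' @param a,b interval tibbles (chrom, start, end).
#' @param min_overlap minimum shared bases (default 1).
#' @return tibble (a_index, b_index, overlap_bp) sorted by a_index then
#'   b_index.
#' @export
intersect_intervals <- function(a, b, min_overlap = 1L) {
  ga <- as_granges(a); gb <- as_granges(b)
  hits <- GenomicRanges::findOverlaps(ga, gb, minoverlap = min_overlap,
                                      ignore.strand = TRUE)
  ai <- S4Vectors::queryHits(hits); bi <- S4Vectors::subjectHits(hits)
  ov <- pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi])
  ord <- order(ai, bi)
  tibble::tibble(a_index = ai[ord], b_index = bi[ord],
                 overlap_bp = as.integer(ov[ord]))
}

#' Read gene models
#'
#' Two on-disk forms: a TSV with columns gene_id, chrom, tss, strand,
#' span_start, span_end, exon_starts, exon_ends (comma-separated block
#' lists), or BED12 (thick/blocks; the TSS is derived from strand).
#'
#' @param path file path.
#' @param format "tsv" or "bed12".
#' @return tibble: gene_id, chrom, tss, strand, span_start, span_end and a
#'   list-column `exons` of two-column (start, end) matrices.
#' @export
read_gene_models <- function(path, format = c("tsv", "bed12")) {
  format <- match.arg(format)
  if (format == "tsv") {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    needed <- c("gene_id", "chrom", "tss", "strand", "span_start",
                "span_end", "exon_starts", "exon_ends")
    if (!all(needed %in% names(d)))
      stop("gene TSV must have columns: ", paste(needed, collapse = ", "),
           call. = FALSE)
    exons <- Map(function(s, e) {
      cbind(start = as.integer(strsplit(s, ",")[[1]]),
            end = as.integer(strsplit(e, ",")[[1]]))
    }, d$exon_starts, d$exon_ends)
    g <- tibble::tibble(gene_id = d$gene_id, chrom = d$chrom,
                        tss = as.integer(d$tss), strand = d$strand,
                        span_start = as.integer(d$span_start),
                        span_end = as.integer(d$span_end),
                        exons = unname(exons))
  } else {
    fields <- strsplit(readLines(path), "\t", fixed = TRUE)
    if (any(lengths(fields) < 12))
      stop("BED12 requires 12 columns", call. = FALSE)
    g <- do.call(rbind, lapply(fields, function(f) {
      start <- as.integer(f[2]); end <- as.integer(f[3])
      sizes <- as.integer(strsplit(f[11], ",")[[1]])
      offs <- as.integer(strsplit(f[12], ",")[[1]])
      tibble::tibble(
        gene_id = f[4], chrom = f[1],
        tss = if (f[6] == "+") start else end - 1L,
        strand = f[6], span_start = start, span_end = end,
        exons = list(cbind(start = start + offs,
                           end = start + offs + sizes)))
    }))
  }
  if (!all(g$strand %in% c("+", "-")))
    stop("gene strand must be + or -", call. = FALSE)
  g
}

#' Annotate peaks with their nearest TSS and genomic feature
#'
#' Each peak is associated with the gene whose TSS is closest to the peak
#' summit on the same chromosome (ties broken by lexicographically smaller
#' gene_id).  The signed distance is expressed in the gene's orientation
#' (negative = upstream of the TSS).  The feature label is assigned at the
#' summit position with precedence promoter > exon > intron > intergenic:
#' promoter when |distance| <= `promoter_margin`, exon/intron when the
#' summit falls inside any gene span.
#'
#' @param peaks peak tibble.
#' @param genes gene-model tibble (see [read_gene_models()]).
#' @param promoter_margin promoter half-width around the TSS in bp
#'   (default 1000).
#' @return tibble: peak_id, gene_id, distance_to_tss, feature.  Peaks on
#'   chromosomes with no gene get gene_id NA, feature "intergenic" and NA
#'   distance.
#' @export
annotate_peaks <- function(peaks, genes, promoter_margin = 1000L) {
  if (nrow(genes) == 0) stop("genes must be non-empty", call. = FALSE)
  res <- lapply(seq_len(nrow(peaks)), function(i) {
    s <- peaks$summit[i]
    gi <- which(genes$chrom == peaks$chrom[i])
    if (!length(gi))
      return(tibble::tibble(peak_id = peaks$peak_id[i],
                            gene_id = NA_character_,
                            distance_to_tss = NA_integer_,
                            feature = "intergenic"))
    dist_abs <- abs(s - genes$tss[gi])
    best <- gi[dist_abs == min(dist_abs)]
    best <- best[order(genes$gene_id[best])][1]
    d <- if (genes$strand[best] == "+") s - genes$tss[best]
         else genes$tss[best] - s
    containing <- gi[genes$span_start[gi] <= s & s < genes$span_end[gi]]
    feature <- if (abs(d) <= promoter_margin) "promoter"
      else if (length(containing)) {
        in_exon <- any(vapply(containing, function(j) {
          ex <- genes$exons[[j]]
          any(ex[, 1] <= s & s < ex[, 2])
        }, logical(1)))
        if (in_exon) "exon" else "intron"
      } else "intergenic"
    tibble::tibble(peak_id = peaks$peak_id[i],
                   gene_id = genes$gene_id[best],
                   distance_to_tss = as.integer(d), feature = feature)
  })
  do.call(rbind, res)
}

#' Extract window sequences from a genome
#'
#' Minus-strand intervals are reverse-complemented; output is uppercase.
#'
#' @param genome a `Biostrings::DNAStringSet` or path to a FASTA file.
#' @param intervals interval tibble (chrom, start, end, strand).
#' @return character vector of sequences, named by `peak_id` when present.
#' @export
extract_sequences <- function(genome, intervals) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  lens <- stats::setNames(Biostrings::width(genome),
                          sub("\\s.*$", "", names(genome)))
  out <- character(nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    chrom <- intervals$chrom[i]
    if (!chrom %in% names(lens))
      stop(sprintf("interval %d: chromosome '%s' not in genome", i, chrom),
           call. = FALSE)
    if (intervals$start[i] < 0 || intervals$end[i] > lens[[chrom]])
      stop(sprintf("interval %d: [%d, %d) out of bounds for %s (length %d)",
                   i, intervals$start[i], intervals$end[i], chrom,
                   lens[[chrom]]), call. = FALSE)
    s <- Biostrings::subseq(genome[[match(chrom, names(lens))]],
                            start = intervals$start[i] + 1L,
                            end = intervals$end[i])
    if (identical(intervals$strand[i], "-"))
      s <- Biostrings::reverseComplement(s)
    out[i] <- toupper(as.character(s))
  }
  if (!is.null(intervals[["peak_id"]])) names(out) <- intervals$peak_id
  out
}

#' Chromosome lengths of a genome
#'
#' @param genome a `Biostrings::DNAStringSet` or FASTA path.
#' @return named integer vector.
#' @export
chrom_sizes <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  stats::setNames(Biostrings::width(genome), sub("\\s.*$", "", names(genome)))
}
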