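#' Read a bedGraph coverage track
#'
#' 4-column bedGraph, 0-based half-open; `track` header lines are
#' skipped.
#'
#' @param path file path.
#' @return tibble: chrom, start, end, value.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|#)", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 4)
  if (length(bad))
    stop(sprintf("malformed bedGraph line %d", bad[1]), call. = FALSE)
  tibble::tibble(
    chrom = vapply(fields, `[[`, character(1), 1),
    start = as.integer(vapply(fields, `[[`, character(1), 2)),
    end = as.integer(vapply(fields, `[[`, character(1), 3)),
    value = as.numeric(vapply(fields, `[[`, character(1), 4)))
}

#' Write a coverage track as bedGraph
#'
#' @param track tibble: chrom, start, end, value.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  writeLines(paste(track$chrom, track$start, track$end,
                   format(track$value, trim = TRUE, scientific = FALSE),
                   sep = "\t"), path)
  invisible(path)
}

# Per-chromosome run-length coverage vectors from a bedGraph tibble.
.track_rles <- function(track, chrom_sizes = NULL) {
  if (any(track$value < 0)) stop("coverage must be >= 0", call. = FALSE)
  chroms <- unique(track$chrom)
  lens <- if (is.null(chrom_sizes)) {
    stats::setNames(vapply(chroms, function(cn)
      max(track$end[track$chrom == cn]), numeric(1)), chroms)
  } else chrom_sizes
  rles <- lapply(chroms, function(cn) {
    t <- track[track$chrom == cn, ]
    IRanges::coverage(IRanges::IRanges(start = t$start + 1L, end = t$end),
                      weight = t$value, width = lens[[cn]])
  })
  names(rles) <- chroms
  list(rles = rles, lens = lens)
}

#' Summit-centered coverage matrix
#'
#' For every peak, mean per-base coverage in `bin_size` bp bins across
#' \[summit - flank, summit + flank) — the computational content of a
#' peak-density heatmap.  Windows truncated at chromosome ends contribute
#' means over covered bases only; peaks on chromosomes absent from the
#' track get zero rows (counted in `n_missing_chrom`).
#'
#' @param track bedGraph tibble (see [read_bedgraph()]) or a path.
#' @param peaks peak tibble (chrom, summit, peak_id).
#' @param flank half-window in bp (default 2000).
#' @param bin_size bin width in bp (default 50); must divide 2*flank.
#' @param chrom_sizes optional named chromosome lengths; defaults to the
#'   per-chromosome track extent.
#' @param order "signal" (rows by descending total signal, the heatmap
#'   convention) or "input".
#' @return object of class "density_matrix": list with `values` (peaks x
#'   bins), `peak_ids`, `bin_edges` (relative positions), `flank`,
#'   `bin_size`, `n_missing_chrom`.
#' @export
density_matrix <- function(track, peaks, flank = 2000L, bin_size = 50L,
                           chrom_sizes = NULL,
                           order = c("signal", "input")) {
  order <- match.arg(order)
  if (is.character(track)) track <- read_bedgraph(track)
  if ((2L * flank) %% bin_size != 0)
    stop("bin_size must divide 2*flank", call. = FALSE)
  cov <- .track_rles(track, chrom_sizes)
  nbins <- as.integer(2L * flank / bin_size)
  vals <- matrix(0, nrow = nrow(peaks), ncol = nbins)
  n_missing <- 0L
  for (i in seq_len(nrow(peaks))) {
    cn <- peaks$chrom[i]
    if (!cn %in% names(cov$rles)) {
      n_missing <- n_missing + 1L
      next
    }
    rle <- cov$rles[[cn]]
    len <- cov$lens[[cn]]
    w0 <- peaks$summit[i] - flank        # 0-based window start
    v <- rep(NA_real_, 2L * flank)
    lo <- max(w0, 0L)
    hi <- min(w0 + 2L * flank, len)
    if (hi > lo)
      v[(lo - w0 + 1L):(hi - w0)] <-
        as.numeric(S4Vectors::window(rle, start = lo + 1L, end = hi))
    bm <- colMeans(matrix(v, nrow = bin_size), na.rm = TRUE)
    bm[is.nan(bm)] <- 0
    vals[i, ] <- bm
  }
  ids <- peaks$peak_id
  if (order == "signal") {
    o <- order(rowSums(vals), decreasing = TRUE)
    vals <- vals[o, , drop = FALSE]
    ids <- ids[o]
  }
  structure(list(values = vals, peak_ids = ids,
                 bin_edges = seq(-flank, flank, by = bin_size),
                 flank = flank, bin_size = bin_size,
                 n_missing_chrom = n_missing),
            class = "density_matrix")
}

#' Average density profile across peaks
#'
#' @param matrix a "density_matrix" object.
#' @return numeric vector of per-bin column means, named by bin midpoint.
#' @export
average_profile <- function(matrix) {
  stopifnot(inherits(matrix, "density_matrix"))
  if (nrow(matrix$values) == 0) stop("empty matrix", call. = FALSE)
  mids <- matrix$bin_edges[-length(matrix$bin_edges)] + matrix$bin_size / 2
  stats::setNames(colMeans(matrix$values), mids)
}

#' Write a density matrix as TSV
#'
#' Header row gives the bin midpoints relative to the summit.
#'
#' @param matrix a "density_matrix" object.
#' @param path output path.
#' @export
write_density_matrix <- function(matrix, path) {
  mids <- matrix$bin_edges[-length(matrix$bin_edges)] + matrix$bin_size / 2
  d <- as.data.frame(matrix$values)
  names(d) <- mids
  d <- cbind(peak_id = matrix$peak_ids, d)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
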