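default_stage_order <- function(stages) {
  u <- unique(stages)
  num <- suppressWarnings(as.numeric(gsub("[^0-9.]", "", u)))
  if (any(is.na(num))) sort(u) else u[order(num)]
}

#' Filter differential-expression records into regulated genes
#'
#' A gene is kept when any stage shows |log2FC| > log2(`fc_threshold`)
#' (strict) and FDR < `fdr_threshold` (strict).  Direction and stage class
#' are taken from the earliest significant stage: a negative log2FC
#' (knockdown vs control) is "down_in_MO", meaning the depleted factor
#' normally activates the gene.
#'
#' @param records tibble with gene_id, stage, log2_fold_change, fdr (one
#'   row per gene x stage).
#' @param fc_threshold fold-change cutoff on the linear scale (default 2).
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @param early_stages stages labelled "early" (default NF9, NF10).
#' @param stage_order explicit stage ordering; by default stages are
#'   ordered by their numeric component (NF9 < NF10 < NF10.5 < ...).
#' @return tibble: gene_id, direction (down_in_MO / up_in_MO),
#'   stage_class (early / late), first_stage, log2_fold_change, fdr.
#' @export
filter_differential <- function(records, fc_threshold = 2,
                                fdr_threshold = 0.05,
                                early_stages = c("NF9", "NF10"),
                                stage_order = NULL) {
  need <- c("gene_id", "stage", "log2_fold_change", "fdr")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(records$fdr < 0 | records$fdr > 1, na.rm = TRUE))
    stop("fdr must lie in [0, 1]", call. = FALSE)
  key <- paste(records$gene_id, records$stage, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- records[key %in% key[duplicated(key)], ]
    chk <- unique(dup)
    if (anyDuplicated(paste(chk$gene_id, chk$stage, sep = "\r")))
      stop("conflicting duplicate (gene, stage) rows, e.g. ",
           chk$gene_id[1], " at ", chk$stage[1], call. = FALSE)
    records <- records[!duplicated(key), ]
  }
  stage_order <- stage_order %||% default_stage_order(records$stage)
  lfc_cut <- log2(fc_threshold)
  sig <- abs(records$log2_fold_change) > lfc_cut &
    records$fdr < fdr_threshold
  sig[is.na(sig)] <- FALSE
  hits <- records[sig, ]
  if (nrow(hits) == 0)
    return(tibble::tibble(gene_id = character(), direction = character(),
                          stage_class = character(), first_stage = character(),
                          log2_fold_change = numeric(), fdr = numeric()))
  hits$stage_rank <- match(hits$stage, stage_order)
  hits <- hits[order(hits$gene_id, hits$stage_rank), ]
  first <- hits[!duplicated(hits$gene_id), ]
  tibble::tibble(
    gene_id = first$gene_id,
    direction = ifelse(first$log2_fold_change < 0, "down_in_MO",
                       "up_in_MO"),
    stage_class = ifelse(first$stage %in% early_stages, "early", "late"),
    first_stage = as.character(first$stage),
    log2_fold_change = first$log2_fold_change,
    fdr = first$fdr)
}

#' Tissues where a gene's expression is enriched
#'
#' A tissue is enriched when the gene's normalized expression there
#' strictly exceeds `ratio` times its mean across all tissues.  An
#' all-zero profile yields an empty set; the rule is invariant to
#' rescaling the profile.
#'
#' @param profile named nonnegative numeric vector (one gene, >= 2
#'   tissues), or a genes x tissues matrix.
#' @param ratio enrichment ratio over the cross-tissue mean (default 1.5).
#' @return for a vector, a character vector of enriched tissue names; for
#'   a matrix, a tibble (gene_id, enriched_tissues list-column,
#'   n_enriched).
#' @export
spatial_enrichment <- function(profile, ratio = 1.5) {
  if (is.matrix(profile) || is.data.frame(profile)) {
    m <- as.matrix(profile)
    sets <- lapply(seq_len(nrow(m)), function(i)
      spatial_enrichment(m[i, ], ratio))
    return(tibble::tibble(
      gene_id = rownames(m) %||% as.character(seq_len(nrow(m))),
      enriched_tissues = sets,
      n_enriched = lengths(sets)))
  }
  if (length(profile) < 2)
    stop("need >= 2 tissues", call. = FALSE)
  if (any(profile < 0)) stop("negative expression value", call. = FALSE)
  labs <- names(profile) %||% paste0("tissue", seq_along(profile))
  labs[profile > ratio * mean(profile)]
}

#' Compare a gene subset's expression-pattern distribution to the genome
#'
#' Chi-square mode compares subset label counts to expected counts under
#' the genome-wide label proportions.  KS mode compares two samples of a
#' per-gene ordinal statistic (labels are mapped to their index in the
#' genome-wide label ordering when given as characters).
#'
#' @param subset_patterns labels (or ordinal values, for ks) of the gene
#'   subset.
#' @param genome_patterns labels/values of the genome background.
#' @param method "chi_square" or "ks".
#' @return list with `statistic` (chi-square X^2 or KS D), `p_value`, and
#'   `df` for chi-square.
#' @export
pattern_distribution_test <- function(subset_patterns, genome_patterns,
                                      method = c("chi_square", "ks")) {
  method <- match.arg(method)
  if (method == "chi_square") {
    labels <- sort(unique(c(as.character(subset_patterns),
                            as.character(genome_patterns))))
    obs <- table(factor(subset_patterns, levels = labels))
    gen <- table(factor(genome_patterns, levels = labels))
    res <- chi_square_gof(as.integer(obs),
                          as.integer(gen) / sum(gen))
    list(statistic = res$statistic, df = res$df, p_value = res$p_value)
  } else {
    to_ord <- function(x, levels) {
      if (is.numeric(x)) x else match(as.character(x), levels)
    }
    levels <- if (is.numeric(genome_patterns)) NULL
              else sort(unique(as.character(genome_patterns)))
    x <- to_ord(subset_patterns, levels)
    y <- to_ord(genome_patterns, levels)
    if (any(is.na(x)) || any(is.na(y)))
      stop("subset labels absent from genome labeling", call. = FALSE)
    res <- ks_two_sample(x, y)
    list(statistic = res$D, p_value = res$p_value)
  }
}

#' Hypergeometric test of gene-set overlap
#'
#' Upper-tail probability that two sets drawn from the universe share at
#' least the observed number of members.
#'
#' @param universe character vector of all genes.
#' @param set_a,set_b gene sets (must be subsets of the universe).
#' @return list: N, K, n, k, overlap (the shared genes), p_value.
#' @export
overlap_test <- function(universe, set_a, set_b) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  set_a <- unique(set_a); set_b <- unique(set_b)
  out_a <- setdiff(set_a, universe); out_b <- setdiff(set_b, universe)
  if (length(out_a) || length(out_b))
    stop("sets not subsets of universe: ",
         paste(utils::head(c(out_a, out_b), 5), collapse = ", "),
         call. = FALSE)
  k <- length(intersect(set_a, set_b))
  list(N = length(universe), K = length(set_a), n = length(set_b), k = k,
       overlap = intersect(set_a, set_b),
       p_value = hypergeom_upper_tail(length(universe), length(set_a),
                                      length(set_b), k))
}

#' Regulatory category from two knockdown directions
#'
#' "Down in a factor's morpholino" means that factor normally activates
#' the gene, so (down, down) is activated by both factors, etc.  The four
#' categories partition the 2x2 domain.
#'
#' @param direction_sox17mo,direction_bcatmo "down"/"up" (the
#'   "_in_MO"-suffixed forms are accepted); vectorized.
#' @return character vector over \{activated_by_both,
#'   bcat_activated_sox17_repressed, sox17_activated_bcat_repressed,
#'   repressed_by_both\}.
#' @export
regulatory_category <- function(direction_sox17mo, direction_bcatmo) {
  norm <- function(x) {
    x <- sub("_in_MO$", "", x)
    if (!all(x %in% c("down", "up")))
      stop("directions must be 'down' or 'up'", call. = FALSE)
    x
  }
  s <- norm(direction_sox17mo); b <- norm(direction_bcatmo)
  ifelse(s == "down" & b == "down", "activated_by_both",
  ifelse(s == "up" & b == "down", "bcat_activated_sox17_repressed",
  ifelse(s == "down" & b == "up", "sox17_activated_bcat_repressed",
         "repressed_by_both")))
}

#' Categorize genes regulated in both knockdowns
#'
#' @param regulated_sox17,regulated_bcat regulated-gene tibbles from
#'   [filter_differential()] for the two factors.
#' @return tibble: gene_id, direction_sox17mo, direction_bcatmo, category
#'   — one row per gene present in both sets.
#' @export
regulatory_categories <- function(regulated_sox17, regulated_bcat) {
  shared <- intersect(regulated_sox17$gene_id, regulated_bcat$gene_id)
  ds <- regulated_sox17$direction[match(shared, regulated_sox17$gene_id)]
  db <- regulated_bcat$direction[match(shared, regulated_bcat$gene_id)]
  tibble::tibble(gene_id = shared, direction_sox17mo = ds,
                 direction_bcatmo = db,
                 category = regulatory_category(ds, db))
}

#' Direct targets: genes both bound and regulated
#'
#' Intersects the genes carrying at least one annotated peak with the
#' regulated gene set, collects the peaks annotated to those genes, and
#' tests the intersection by the hypergeometric upper tail over the
#' supplied universe.
#'
#' @param bound_annotations annotation tibble from [annotate_peaks()].
#' @param regulated regulated-gene tibble (or character vector of gene
#'   ids).
#' @param universe character vector of all genes considered.
#' @return list: genes, peaks, test (an [overlap_test()] result).
#' @export
direct_targets <- function(bound_annotations, regulated, universe) {
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  bound <- unique(bound_annotations$gene_id)
  bound <- bound[!is.na(bound)]
  reg <- if (is.character(regulated)) unique(regulated)
         else unique(regulated$gene_id)
  test <- overlap_test(universe, bound, reg)
  genes <- test$overlap
  peaks <- unique(
    bound_annotations$peak_id[bound_annotations$gene_id %in% genes])
  list(genes = genes, peaks = peaks, test = test)
}

#' Summarize a dual-luciferase reporter experiment
#'
#' Firefly activity is normalized per replicate by the matched Renilla
#' control; each condition is reported as mean +/- sample SD of the
#' ratio, with a two-sided Student t-test (pooled variance) against the
#' reference condition.  Zero-variance comparisons are flagged as
#' degenerate (see [t_two_sample()]).
#'
#' @param firefly numeric vector of firefly measurements.
#' @param renilla matched Renilla measurements (> 0).
#' @param condition condition label per measurement.
#' @param reference_condition the baseline condition label.
#' @return tibble: condition, n, mean_ratio, sd_ratio, t, p_vs_reference,
#'   degenerate (NA test fields for the reference itself).
#' @export
reporter_summary <- function(firefly, renilla, condition,
                             reference_condition) {
  if (length(firefly) != length(renilla) ||
      length(firefly) != length(condition))
    stop("firefly, renilla, condition must have equal length",
         call. = FALSE)
  if (any(renilla <= 0)) stop("renilla values must be > 0", call. = FALSE)
  if (!reference_condition %in% condition)
    stop("reference condition not present", call. = FALSE)
  ratio <- firefly / renilla
  conds <- unique(as.character(condition))
  if (any(table(condition) < 2))
    stop("need >= 2 replicates per condition", call. = FALSE)
  ref <- ratio[condition == reference_condition]
  do.call(rbind, lapply(conds, function(cn) {
    r <- ratio[condition == cn]
    if (cn == reference_condition) {
      tt <- list(t = NA_real_, p_value = NA_real_, degenerate = FALSE)
    } else {
      tt <- t_two_sample(r, ref, equal_variance = TRUE)
    }
    tibble::tibble(condition = cn, n = length(r), mean_ratio = mean(r),
                   sd_ratio = stats::sd(r), t = tt$t,
                   p_vs_reference = tt$p_value,
                   degenerate = tt$degenerate)
  }))
}
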