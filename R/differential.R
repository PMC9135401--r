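#' Expressing fraction of a gene over a spot set
#'
#' Fraction of the given spots with raw count > 0 — a detection statistic,
#' deliberately computed on raw counts, not normalized values.
#'
#' @param dataset a [SpotDataset].
#' @param gene single gene id.
#' @param spot_set barcodes, or logical/integer index over spots; must select
#'   at least one spot.
#' @return fraction in \[0, 1\].
#' @export
expressing_fraction <- function(dataset, gene, spot_set) {
  i <- match(gene, gene_ids(dataset))
  if (is.na(i)) stop("unknown gene: ", gene)
  if (is.character(spot_set)) spot_set <- match(spot_set, spot_ids(dataset))
  v <- dataset$counts[i, spot_set]
  if (!length(v)) stop("spot_set selects no spots")
  mean(v > 0)
}

#' Specificity ratio of expressing fractions
#'
#' `pct_in / pct_out`, the third signature-selection criterion. The ratio is
#' undefined when no reference spot expresses the gene; a finite cap keeps
#' sorting total: genes with `pct_out == 0` and `pct_in > 0` map to `cap`
#' (default 1e6), and genes expressed nowhere map to 0.
#'
#' @param pct_in,pct_out expressing fractions in \[0, 1\]; vectorized.
#' @param cap value returned when `pct_out == 0 < pct_in`.
#' @return non-negative numeric vector.
#' @export
specificity_ratio <- function(pct_in, pct_out, cap = 1e6) {
  stopifnot(all(pct_in >= 0 & pct_in <= 1), all(pct_out >= 0 & pct_out <= 1))
  out <- pct_in / pct_out
  out[pct_out == 0] <- ifelse(pct_in[pct_out == 0] > 0, cap, 0)
  out
}

#' Region-versus-rest differential expression
#'
#' Wilcoxon rank-sum marker statistics for a region contrast on normalized
#' expression, with the expressing-fraction specificity ratio. Genes with
#' `max(pct_in, pct_out) < min_pct` or `|lfc| < lfc_threshold` are excluded
#' before testing; the Bonferroni denominator is the number of genes actually
#' tested. The log fold change follows the marker-test convention
#' `ln(mean(expm1(norm_target)) + 1) - ln(mean(expm1(norm_reference)) + 1)`
#' (natural log).
#'
#' @param norm normalized matrix from [normalize_log()].
#' @param dataset the [SpotDataset] the matrix was computed from (provides
#'   raw counts for expressing fractions, and region labels).
#' @param target_region region label(s) defining the target spot set.
#' @param reference_regions region label(s) for the reference set; `NULL`
#'   means every other region except `"unassigned"`. Must be disjoint from
#'   the target.
#' @param min_pct minimum expressing fraction (in either group) to test.
#' @param lfc_threshold minimum absolute natural-log fold change to test.
#' @param specificity_cap cap passed to [specificity_ratio()].
#' @param block_size genes per dense block when ranking (memory control; the
#'   full matrix is never densified).
#' @return a `DifferentialTable`: data frame with columns `gene`, `lfc`, `p`,
#'   `p_adj`, `pct_in`, `pct_out`, `specificity` (tested genes only), plus a
#'   `provenance` attribute recording group sizes and warnings.
#' @export
region_de <- function(norm, dataset, target_region, reference_regions = NULL,
                      min_pct = 0.1, lfc_threshold = 0.25,
                      specificity_cap = 1e6, block_size = 500L) {
  stopifnot(inherits(dataset, "SpotDataset"),
            min_pct >= 0, min_pct < 1, lfc_threshold >= 0)
  regions <- dataset$region
  if (is.null(reference_regions))
    reference_regions <- setdiff(unique(regions),
                                 c(target_region, "unassigned"))
  if (length(intersect(target_region, reference_regions)))
    stop("target and reference regions must be disjoint")
  tgt <- which(regions %in% target_region)
  ref <- which(regions %in% reference_regions)
  if (!length(tgt)) stop("no spots in target region(s)")
  if (!length(ref)) stop("no spots in reference region(s)")
  warnings <- character()
  if (length(tgt) < 3 || length(ref) < 3) {
    warnings <- sprintf("small group(s): %d target vs %d reference spots",
                        length(tgt), length(ref))
    warning(warnings)
  }

  counts <- dataset$counts
  pct_in <- Matrix::rowSums(counts[, tgt, drop = FALSE] > 0) / length(tgt)
  pct_out <- Matrix::rowSums(counts[, ref, drop = FALSE] > 0) / length(ref)
  expn <- norm
  if (length(expn@x)) expn@x <- expm1(expn@x)
  mean_in <- Matrix::rowSums(expn[, tgt, drop = FALSE]) / length(tgt)
  mean_out <- Matrix::rowSums(expn[, ref, drop = FALSE]) / length(ref)
  lfc <- log(mean_in + 1) - log(mean_out + 1)

  tested <- which(pmax(pct_in, pct_out) >= min_pct & abs(lfc) >= lfc_threshold)
  p <- rep(NA_real_, length(tested))
  cols <- c(tgt, ref)
  n1 <- length(tgt)
  for (start in if (length(tested)) seq(1, length(tested), by = block_size)
       else integer(0)) {
    sel <- tested[start:min(start + block_size - 1L, length(tested))]
    block <- as.matrix(norm[sel, cols, drop = FALSE])
    p[start - 1L + seq_along(sel)] <- apply(block, 1, function(v) {
      rank_sum_test(v[seq_len(n1)], v[-seq_len(n1)])
    })
  }
  genes <- gene_ids(dataset)[tested]
  out <- data.frame(gene = genes,
                    lfc = lfc[tested],
                    p = p,
                    p_adj = pmin(1, p * length(tested)),
                    pct_in = pct_in[tested],
                    pct_out = pct_out[tested],
                    specificity = specificity_ratio(pct_in[tested],
                                                    pct_out[tested],
                                                    specificity_cap),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "provenance") <- list(
    target_region = target_region, reference_regions = reference_regions,
    n_target = length(tgt), n_reference = length(ref),
    min_pct = min_pct, lfc_threshold = lfc_threshold,
    n_tested = length(tested), specificity_cap = specificity_cap,
    warnings = warnings)
  class(out) <- c("DifferentialTable", "data.frame")
  out
}

#' Sizes and pairwise overlaps of significant DEG sets
#'
#' Filters each table to significantly enriched genes
#' (`p_adj < alpha & lfc > 0`) and reports per-set sizes and pairwise
#' intersection sizes.
#'
#' @param tables named list of `DifferentialTable`s (>= 2).
#' @param alpha adjusted-p significance threshold.
#' @return list with elements `sizes` (named integer vector) and `pairs`
#'   (data frame `set_a`, `set_b`, `intersection`).
#' @export
deg_set_overlap <- function(tables, alpha = 0.05) {
  stopifnot(is.list(tables), length(tables) >= 2)
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    names(tables) <- paste0("set", seq_along(tables))
  sets <- lapply(tables, function(t) t$gene[t$p_adj < alpha & t$lfc > 0])
  sizes <- vapply(sets, length, 0L)
  cmb <- utils::combn(names(sets), 2)
  pairs <- data.frame(set_a = cmb[1, ], set_b = cmb[2, ],
                      intersection = apply(cmb, 2, function(ab)
                        length(intersect(sets[[ab[1]]], sets[[ab[2]]]))),
                      stringsAsFactors = FALSE)
  list(sizes = sizes, pairs = pairs)
}
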