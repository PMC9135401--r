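#' Top-K membership flags under the three selection criteria
#'
#' Restricts the table to positively enriched genes (`lfc > 0`) and flags,
#' for each gene, membership in the top `k` list under each criterion:
#' ascending adjusted p-value, descending log fold change, and descending
#' specificity. All ties are broken lexicographically by gene id, so the
#' flags are deterministic.
#'
#' @param table a `DifferentialTable` from [region_de()].
#' @param k top-list size (the downstream default is 200).
#' @return data frame `gene`, `in_top_padj`, `in_top_lfc`, `in_top_spec`
#'   plus the gene's statistics; one row per positively enriched gene.
#' @export
criterion_membership <- function(table, k) {
  stopifnot(k >= 1)
  tab <- table[table$lfc > 0, , drop = FALSE]
  n <- nrow(tab)
  if (k > n) {
    warning("k (", k, ") exceeds the number of enriched genes (", n,
            "); all flags set")
  }
  top_flags <- function(ord) {
    f <- logical(n)
    f[ord[seq_len(min(k, n))]] <- TRUE
    f
  }
  g <- tab$gene
  out <- data.frame(gene = g,
                    in_top_padj = top_flags(order(tab$p_adj, g)),
                    in_top_lfc = top_flags(order(-tab$lfc, g)),
                    in_top_spec = top_flags(order(-tab$specificity, g)),
                    lfc = tab$lfc, p_adj = tab$p_adj,
                    specificity = tab$specificity,
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Select an ordered gene signature by tiered criterion membership
#'
#' Implements the three-criterion signature algorithm: genes highlighted in
#' all three top-`k_top` lists (tier 3) are chosen first; genes highlighted
#' in exactly two follow (tier 2), weighted by pair identity
#' `spec+lfc > spec+padj > lfc+padj`. Within every tier genes are ordered by
#' descending specificity (ties lexicographic by gene id) and the list is
#' truncated to `size`. Excluded genes are removed before membership is
#' computed, so the next candidates are promoted into the top lists.
#'
#' @param table a `DifferentialTable` for the target-versus-rest contrast.
#' @param k_top per-criterion highlight-list size (default 200).
#' @param size requested signature length (default 100).
#' @param exclude gene ids never to include (e.g. a proliferative-cluster
#'   exclusion list).
#' @return a `GeneSignature`: data frame `rank`, `gene`, `tier`, `pair`,
#'   `in_top_padj`, `in_top_lfc`, `in_top_spec`, `specificity`, with
#'   attributes `shortfall` (requested minus delivered length) and `source`.
#' @export
select_signature <- function(table, k_top = 200L, size = 100L,
                             exclude = character()) {
  if (size < 1) stop("size must be >= 1")
  stopifnot(k_top >= 1)
  tab <- table[!(table$gene %in% exclude), , drop = FALSE]
  mem <- suppressWarnings(criterion_membership(tab, k_top))
  n_crit <- mem$in_top_padj + mem$in_top_lfc + mem$in_top_spec

  tier3 <- mem[n_crit == 3, , drop = FALSE]
  tier3 <- tier3[order(-tier3$specificity, tier3$gene), , drop = FALSE]
  if (nrow(tier3)) { tier3$tier <- 3L; tier3$pair <- "" }

  tier2 <- mem[n_crit == 2, , drop = FALSE]
  if (nrow(tier2)) {
    pair <- ifelse(tier2$in_top_spec & tier2$in_top_lfc, "spec+lfc",
            ifelse(tier2$in_top_spec & tier2$in_top_padj, "spec+padj",
                   "lfc+padj"))
    pw <- match(pair, c("spec+lfc", "spec+padj", "lfc+padj"))
    ord <- order(pw, -tier2$specificity, tier2$gene)
    tier2 <- tier2[ord, , drop = FALSE]
    tier2$tier <- 2L
    tier2$pair <- pair[ord]
  }

  pool <- rbind(if (nrow(tier3)) tier3, if (nrow(tier2)) tier2)
  shortfall <- 0L
  if (is.null(pool) || nrow(pool) < size) {
    shortfall <- size - if (is.null(pool)) 0L else nrow(pool)
    warning("candidate pool (", size - shortfall,
            ") smaller than requested size ", size)
  }
  if (is.null(pool))
    pool <- cbind(mem[0, , drop = FALSE], tier = integer(0),
                  pair = character(0))
  out <- utils::head(pool, size)
  out <- data.frame(rank = seq_len(nrow(out)), gene = out$gene,
                    tier = out$tier, pair = out$pair,
                    in_top_padj = out$in_top_padj,
                    in_top_lfc = out$in_top_lfc,
                    in_top_spec = out$in_top_spec,
                    specificity = out$specificity,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "shortfall") <- shortfall
  attr(out, "source") <- sprintf("select_signature(k_top=%d, size=%d, %d excluded)",
                                 k_top, size, length(exclude))
  class(out) <- c("GeneSignature", "data.frame")
  out
}

#' Reductive iterations: nested prefixes of a signature
#'
#' Evaluating nested prefixes of the ordered signature locates the smallest
#' gene set that still labels the target region.
#'
#' @param signature a `GeneSignature` (or character vector of ordered genes).
#' @param sizes strictly decreasing positive subset sizes, none exceeding the
#'   signature length.
#' @return named list of gene-id vectors, one per size; subsets are nested.
#' @export
reduce_signature <- function(signature, sizes = c(100L, 50L, 25L, 10L, 5L, 1L)) {
  genes <- if (is.character(signature)) signature else signature$gene
  sizes <- as.integer(sizes)
  if (any(sizes < 1)) stop("sizes must be positive")
  if (length(sizes) > 1 && any(diff(sizes) >= 0))
    stop("sizes must be strictly decreasing")
  if (max(sizes) > length(genes))
    stop("size ", max(sizes), " exceeds signature length ", length(genes))
  stats::setNames(lapply(sizes, function(s) genes[seq_len(s)]),
                  paste0("n", sizes))
}
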