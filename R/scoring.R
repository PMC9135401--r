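# Run code under a temporary RNG state so scoring is seeded without
# disturbing the caller's stream.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Equal-frequency expression bins over all genes: genes are ordered by
# dataset-wide mean normalized expression (ties broken lexicographically by
# gene id) and cut into n_bins contiguous groups of near-equal size.
.expression_bins <- function(norm, n_bins) {
  avg <- Matrix::rowMeans(norm)
  g <- rownames(norm)
  ord <- order(avg, g)
  pos <- integer(length(g))
  pos[ord] <- seq_along(g)
  bin <- ((pos - 1L) * n_bins) %/% length(g) + 1L
  stats::setNames(bin, g)
}

# Core scorer, assumes the RNG is already positioned. Controls for each
# signature gene are drawn from its expression bin EXCLUDING all signature
# genes, so that shifting the signature genes leaves the control mean
# untouched (exact shift equivariance).
.module_score_core <- function(norm, gene_set, n_bins, n_ctrl,
                               control_draws = NULL, exclude = NULL) {
  universe <- rownames(norm)
  gene_set <- as.character(gene_set)
  missing <- setdiff(gene_set, universe)
  gene_set <- intersect(gene_set, universe)
  if (!length(gene_set))
    stop("gene set has empty intersection with the dataset; missing: ",
         paste(utils::head(missing, 10), collapse = ", "))
  if (length(gene_set) == length(universe))
    stop("gene set equals the full gene universe; no control genes available")
  if (is.null(exclude)) exclude <- gene_set
  replaced <- logical(length(gene_set))
  if (is.null(control_draws)) {
    bins <- .expression_bins(norm, n_bins)
    draws <- vector("list", length(gene_set))
    names(draws) <- gene_set
    for (i in seq_along(gene_set)) {
      b <- bins[[gene_set[i]]]
      candidates <- setdiff(names(bins)[bins == b], exclude)
      if (!length(candidates))
        stop("no control candidates in bin ", b, " for gene ", gene_set[i])
      replace <- length(candidates) < n_ctrl
      draws[[i]] <- sample(candidates, n_ctrl, replace = replace)
      replaced[i] <- replace
    }
  } else {
    if (!all(unlist(control_draws) %in% universe))
      stop("control_draws reference unknown genes")
    draws <- control_draws
  }
  ctrl_pool <- unlist(draws, use.names = FALSE)
  sig_idx <- match(gene_set, universe)
  ctrl_idx <- match(ctrl_pool, universe)
  sig_mean <- Matrix::colSums(norm[sig_idx, , drop = FALSE]) / length(sig_idx)
  # pooled control mean keeps draw multiplicity
  ctrl_mean <- Matrix::colSums(norm[ctrl_idx, , drop = FALSE]) / length(ctrl_idx)
  list(score = sig_mean - ctrl_mean, gene_set = gene_set, missing = missing,
       draws = draws, replaced = replaced)
}

#' Module score of a gene set with expression-binned random controls
#'
#' Per spot, the mean normalized expression of the signature genes minus the
#' mean over a pooled draw of expression-matched control genes: genes are
#' ranked by dataset-wide mean normalized expression and cut into `n_bins`
#' equal-frequency bins; for each signature gene, `n_ctrl` controls are drawn
#' from its bin (without replacement unless the bin is too small, which is
#' recorded), excluding the signature genes themselves. Scores near zero mean
#' no program activity; positive scores mean the program is expressed above
#' expression-matched background.
#'
#' @param norm normalized matrix from [normalize_log()].
#' @param gene_set character vector of gene ids (non-empty after
#'   intersection with the dataset).
#' @param n_bins number of expression bins (>= 2).
#' @param n_ctrl control genes drawn per signature gene (>= 1).
#' @param seed integer seed making the control draw reproducible.
#' @param control_draws optionally, the `control_draws` metadata of a
#'   previous `ModuleScores` object; re-scores with exactly those control
#'   genes instead of drawing fresh ones (used, e.g., to verify shift
#'   equivariance or to score a perturbed matrix against fixed controls).
#' @return a `ModuleScores` object: list with `score` (named per-spot numeric
#'   vector) and metadata `gene_set`, `missing_genes`, `n_bins`, `n_ctrl`,
#'   `seed`, `control_draws`, `with_replacement`.
#' @export
module_score <- function(norm, gene_set, n_bins = 24L, n_ctrl = 100L,
                         seed = 1L, control_draws = NULL) {
  stopifnot(n_bins >= 2, n_ctrl >= 1)
  core <- .with_seed(seed, .module_score_core(norm, gene_set, n_bins, n_ctrl,
                                              control_draws))
  structure(list(score = core$score, gene_set = core$gene_set,
                 missing_genes = core$missing, n_bins = n_bins,
                 n_ctrl = n_ctrl, seed = seed,
                 control_draws = core$draws,
                 with_replacement = core$replaced),
            class = "ModuleScores")
}

#' @export
print.ModuleScores <- function(x, ...) {
  cat(sprintf("ModuleScores: %d genes, %d spots, n_bins=%d, n_ctrl=%d, seed=%d\n",
              length(x$gene_set), length(x$score), x$n_bins, x$n_ctrl,
              x$seed))
  cat(sprintf("score range [%.3f, %.3f], mean %.3f\n",
              min(x$score), max(x$score), mean(x$score)))
  invisible(x)
}

#' Cell-cycle scoring with S/G2M/G1 phase assignment
#'
#' S-phase and G2M-phase module scores ([module_score()]), then a phase call
#' per spot: `G1` when neither score is positive, otherwise the phase of the
#' larger score (a tie between equal positive scores is assigned `S`).
#'
#' @param norm normalized matrix from [normalize_log()].
#' @param s_genes,g2m_genes phase gene lists.
#' @inheritParams module_score
#' @return a `CellCycleResult` data frame: `barcode`, `s_score`,
#'   `g2m_score`, `phase`.
#' @export
cell_cycle_score <- function(norm, s_genes, g2m_genes, n_bins = 24L,
                             n_ctrl = 100L, seed = 1L) {
  stopifnot(n_bins >= 2, n_ctrl >= 1)
  both <- union(s_genes, g2m_genes)  # neither phase list may serve as controls
  cores <- .with_seed(seed, list(
    s = .module_score_core(norm, s_genes, n_bins, n_ctrl, exclude = both),
    g2m = .module_score_core(norm, g2m_genes, n_bins, n_ctrl,
                             exclude = both)))
  s <- cores$s$score
  g2m <- cores$g2m$score
  phase <- ifelse(pmax(s, g2m) <= 0, "G1", ifelse(s >= g2m, "S", "G2M"))
  out <- data.frame(barcode = colnames(norm), s_score = unname(s),
                    g2m_score = unname(g2m), phase = unname(phase),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("CellCycleResult", "data.frame")
  out
}

#' Region contrast of per-spot scores
#'
#' Mean score difference (a minus b) and two-sided Wilcoxon rank-sum p-value
#' of spot-level scores between two region groups.
#'
#' @param scores a `ModuleScores` object or a numeric vector named by
#'   barcode (one score per spot).
#' @param dataset the [SpotDataset] carrying the region labels.
#' @param region_a,region_b region label(s) of the two groups.
#' @return list with `mean_diff`, `p`, `n_a`, `n_b`.
#' @export
score_contrast <- function(scores, dataset, region_a, region_b) {
  v <- if (inherits(scores, "ModuleScores")) scores$score else scores
  a <- v[region_spots(dataset, region_a)]
  b <- v[region_spots(dataset, region_b)]
  if (!length(a) || !length(b)) stop("both regions must contain spots")
  if (length(a) < 3 || length(b) < 3)
    warning("fewer than 3 spots in a contrast group")
  list(mean_diff = mean(a) - mean(b), p = rank_sum_test(a, b),
       n_a = length(a), n_b = length(b))
}

#' Per-region cell-cycle phase fractions
#'
#' @param cc_result a `CellCycleResult` from [cell_cycle_score()].
#' @param dataset the [SpotDataset] carrying the region labels.
#' @return data frame `region`, `S`, `G2M`, `G1`, `n`; fractions sum to 1
#'   per region. Regions without scored spots are excluded with a warning.
#' @export
phase_distribution <- function(cc_result, dataset) {
  reg <- dataset$region[cc_result$barcode]
  all_regions <- sort(unique(dataset$region))
  present <- sort(unique(reg))
  empty <- setdiff(all_regions, present)
  if (length(empty))
    warning("region(s) without scored spots excluded: ",
            paste(empty, collapse = ", "))
  out <- do.call(rbind, lapply(present, function(r) {
    ph <- cc_result$phase[reg == r]
    data.frame(region = r,
               S = mean(ph == "S"), G2M = mean(ph == "G2M"),
               G1 = mean(ph == "G1"), n = length(ph),
               stringsAsFactors = FALSE)
  }))
  row.names(out) <- NULL
  out
}
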