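#' Depth-normalize and log-transform counts
#'
#' Standard library-size normalization: for spot j with total count
#' \eqn{T_j > 0}, the normalized value of gene g is
#' \eqn{\ln(1 + c_{gj} \cdot s / T_j)} with scale factor \eqn{s} (default
#' 10,000). A spot with zero total count maps to an all-zero column. Zeros
#' stay zero, so the result remains sparse.
#'
#' @param dataset a [SpotDataset].
#' @param scale_factor positive scale factor \eqn{s}.
#' @return a `NormalizedMatrix`: a sparse genes x spots `dgCMatrix` with
#'   attributes `scale_factor` and `log_base = "natural"`.
#' @export
normalize_log <- function(dataset, scale_factor = 1e4) {
  stopifnot(inherits(dataset, "SpotDataset"), scale_factor > 0)
  m <- dataset$counts
  totals <- Matrix::colSums(m)
  fac <- ifelse(totals > 0, scale_factor / totals, 0)
  # scale each column in place on the sparse slots, then log1p
  if (length(m@x))
    m@x <- log1p(m@x * rep.int(fac, diff(m@p)))
  attr(m, "scale_factor") <- scale_factor
  attr(m, "log_base") <- "natural"
  m
}

#' Drop spots below a minimum total count
#'
#' Optional QC step; the pipeline applies no filtering by default.
#'
#' @param dataset a [SpotDataset].
#' @param min_counts keep spots with total count >= this value.
#' @return filtered [SpotDataset].
#' @export
filter_spots <- function(dataset, min_counts = 0) {
  keep <- Matrix::colSums(dataset$counts) >= min_counts
  if (!any(keep)) stop("filter removes every spot")
  subset_spots(dataset, which(keep))
}
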