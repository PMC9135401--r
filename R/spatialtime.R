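#' Euclidean distance from points to a closed segment
#'
#' Geometry primitive of the SpatialTime statistic: the perpendicular foot is
#' clamped to the segment, so endpoints dominate beyond it. A degenerate
#' segment (`a == b`) falls back to point distance.
#'
#' @param p numeric matrix of points (n x 2) or a length-2 vector.
#' @param a,b segment endpoints, length-2 numeric.
#' @return non-negative numeric vector of distances, one per point.
#' @export
point_segment_distance <- function(p, a, b) {
  p <- matrix(as.numeric(p), ncol = 2)
  ab <- b - a
  len2 <- sum(ab^2)
  dx <- p[, 1] - a[1]
  dy <- p[, 2] - a[2]
  if (len2 == 0) return(sqrt(dx^2 + dy^2))
  t <- pmin(1, pmax(0, (dx * ab[1] + dy * ab[2]) / len2))
  sqrt((dx - t * ab[1])^2 + (dy - t * ab[2])^2)
}

#' SpatialTime: scaled distance of spots to the bone-stump reference line
#'
#' For every included spot of the polyline's sample, the minimum Euclidean
#' distance to the reference polyline is computed (minimum over segments) and
#' min-max scaled within the sample to \[0, 1\]: 0 is the spot closest to the
#' bone stump (most proximal), 1 the furthest (most distal). Distances are
#' unsigned. Scaling is strictly per sample; pooled scaling is deliberately
#' not offered.
#'
#' @param dataset a [SpotDataset].
#' @param polyline a [ReferencePolyline] whose `sample_id` selects the spots.
#' @param include_regions region labels of spots entering the statistic
#'   (e.g. `c("blastema", "boundary")`).
#' @return a `SpatialTimeResult` data frame: `barcode`, `sample_id`,
#'   `region`, `raw_dist`, `st`; attribute `degenerate` flags the all-equal-
#'   distance case (all `st` set to 0).
#' @export
spatial_time <- function(dataset, polyline, include_regions) {
  stopifnot(inherits(dataset, "SpotDataset"),
            inherits(polyline, "ReferencePolyline"),
            length(include_regions) >= 1)
  keep <- dataset$sample_id == polyline$sample_id &
    dataset$region %in% include_regions
  if (sum(keep) < 2)
    stop("need at least 2 included spots in sample '", polyline$sample_id,
         "' to scale SpatialTime")
  pts <- dataset$coords[keep, , drop = FALSE]
  v <- polyline$vertices
  d <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(v) - 1L))
    d <- pmin(d, point_segment_distance(pts, v[i, ], v[i + 1L, ]))
  rng <- range(d)
  degenerate <- rng[2] == rng[1]
  st <- if (degenerate) rep(0, length(d)) else (d - rng[1]) / (rng[2] - rng[1])
  out <- data.frame(barcode = rownames(pts),
                    sample_id = unname(dataset$sample_id[keep]),
                    region = unname(dataset$region[keep]),
                    raw_dist = d, st = st,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "degenerate") <- degenerate
  class(out) <- c("SpatialTimeResult", "data.frame")
  out
}

#' Concatenate per-sample SpatialTime results
#'
#' Row-wise union of already-scaled per-sample results; no re-scaling, so
#' each sample keeps min 0 and max 1. Concatenation pools samples to
#' increase statistical power across an "average" blastema.
#'
#' @param ... `SpatialTimeResult` objects (or a single list of them).
#' @return pooled `SpatialTimeResult`.
#' @export
concatenate_samples <- function(...) {
  results <- list(...)
  if (length(results) == 1 && is.list(results[[1]]) &&
      !inherits(results[[1]], "data.frame"))
    results <- results[[1]]
  if (!length(results)) stop("no results to concatenate")
  out <- do.call(rbind, lapply(results, as.data.frame))
  key <- paste(out$sample_id, out$barcode)
  if (anyDuplicated(key))
    stop("duplicate (sample_id, barcode) pair: ",
         key[anyDuplicated(key)][1])
  row.names(out) <- NULL
  class(out) <- c("SpatialTimeResult", "data.frame")
  out
}

#' Binned proximal-distal profile of a per-spot value
#'
#' Cuts SpatialTime into `n_bins` equal-width bins on \[0, 1\] (right-open
#' except the last) and summarises an aligned per-spot value (typically a
#' module score) per bin.
#'
#' @param st_result a `SpatialTimeResult`.
#' @param values numeric vector aligned to `st_result` rows, or named by
#'   barcode (e.g. `ModuleScores$score`).
#' @param n_bins number of bins (>= 2).
#' @return data frame `bin`, `lower`, `upper`, `mean`, `sd`, `n`; empty bins
#'   carry `n = 0` and `NA` mean/sd.
#' @export
binned_profile <- function(st_result, values, n_bins = 5L) {
  stopifnot(n_bins >= 2)
  if (inherits(values, "ModuleScores")) values <- values$score
  if (!is.null(names(values))) values <- values[st_result$barcode]
  if (length(values) != nrow(st_result))
    stop("values must align with the SpatialTime result")
  bin <- pmin(floor(st_result$st * n_bins) + 1L, n_bins)
  out <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    v <- values[bin == b]
    data.frame(bin = b, lower = (b - 1) / n_bins, upper = b / n_bins,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               n = length(v))
  }))
  row.names(out) <- NULL
  out
}
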