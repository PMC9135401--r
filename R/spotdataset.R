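# planar coordinate intake: accepts a matrix/data frame with x,y columns
# (or any two columns, taken positionally)
.xy_matrix <- function(m) {
  m <- as.data.frame(m)
  if (!all(c("x", "y") %in% names(m))) {
    if (ncol(m) < 2) stop("coordinates need two columns (x, y)")
    names(m)[1:2] <- c("x", "y")
  }
  m <- as.matrix(m[, c("x", "y")])
  storage.mode(m) <- "double"
  m
}

#' Spot-level spatial expression dataset
#'
#' A `SpotDataset` bundles the universal substrate of the pipeline: a sparse
#' genes-by-spots count matrix, planar spot coordinates, per-spot sample ids
#' and per-spot region labels. Regions are free strings (e.g. `"blastema"`,
#' `"boundary"`, `"digit"`, `"bone"`, `"fibroblast"`); the label
#' `"unassigned"` is reserved for spots without an annotation.
#'
#' @param counts genes x spots matrix of non-negative integer counts; coerced
#'   to a sparse `dgCMatrix`. Must carry unique rownames (gene ids) and unique
#'   colnames (spot barcodes).
#' @param coords numeric matrix or data frame with one row per spot and
#'   columns `x`, `y`, in a consistent planar unit (full-resolution pixels or
#'   micrometres). Spots of one sample must share one coordinate frame.
#' @param sample_id character vector, one entry per spot.
#' @param region character vector of region labels, one entry per spot.
#' @param meta optional data frame of additional per-spot columns (e.g.
#'   `array_row`, `array_col`), kept as metadata only.
#' @return An object of class `SpotDataset`.
#' @export
SpotDataset <- function(counts, coords, sample_id, region = NULL, meta = NULL) {
  if (!inherits(counts, "sparseMatrix"))
    counts <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  counts <- methods::as(counts, "CsparseMatrix")
  counts@x <- as.double(counts@x)
  gene_ids <- rownames(counts)
  spot_ids <- colnames(counts)
  if (is.null(gene_ids) && nrow(counts) == 0) gene_ids <- character(0)
  if (is.null(spot_ids) && ncol(counts) == 0) spot_ids <- character(0)
  if (is.null(gene_ids) || is.null(spot_ids))
    stop("counts must have gene rownames and spot colnames")
  dimnames(counts) <- list(gene_ids, spot_ids)
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (anyDuplicated(spot_ids)) stop("duplicate spot barcodes")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  coords <- .xy_matrix(coords)
  n <- ncol(counts)
  if (nrow(coords) != n) stop("coords must have one row per spot")
  if (!all(is.finite(coords))) stop("coords must be finite")
  rownames(coords) <- spot_ids
  sample_id <- rep_len(as.character(sample_id), n)
  if (is.null(region)) region <- "unassigned"
  region <- rep_len(as.character(region), n)
  if (anyNA(sample_id) || anyNA(region))
    stop("sample_id and region must not contain NA")
  structure(list(counts = counts, coords = coords,
                 sample_id = stats::setNames(sample_id, spot_ids),
                 region = stats::setNames(region, spot_ids),
                 meta = meta),
            class = "SpotDataset")
}

#' @export
print.SpotDataset <- function(x, ...) {
  cat(sprintf("SpotDataset: %d genes x %d spots, %d sample(s)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$sample_id))))
  tab <- table(x$region)
  cat("regions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.SpotDataset <- function(x) dim(x$counts)

#' Gene and spot identifiers of a dataset
#' @param dataset a `SpotDataset`
#' @return character vector of ids.
#' @export
gene_ids <- function(dataset) rownames(dataset$counts)

#' @rdname gene_ids
#' @export
spot_ids <- function(dataset) colnames(dataset$counts)

#' Subset a dataset to a set of spots
#'
#' @param dataset a `SpotDataset`
#' @param spots logical, integer or character (barcode) index.
#' @return a `SpotDataset` restricted to the selected spots.
#' @export
subset_spots <- function(dataset, spots) {
  if (is.character(spots)) spots <- match(spots, spot_ids(dataset))
  SpotDataset(dataset$counts[, spots, drop = FALSE],
              dataset$coords[spots, , drop = FALSE],
              dataset$sample_id[spots], dataset$region[spots],
              meta = if (is.null(dataset$meta)) NULL
                     else dataset$meta[spots, , drop = FALSE])
}

#' Spot barcodes belonging to a set of regions
#' @param dataset a `SpotDataset`
#' @param regions character vector of region labels.
#' @param sample optional sample id(s) to restrict to.
#' @return character vector of barcodes.
#' @export
region_spots <- function(dataset, regions, sample = NULL) {
  keep <- dataset$region %in% regions
  if (!is.null(sample)) keep <- keep & dataset$sample_id %in% sample
  spot_ids(dataset)[keep]
}

#' Per-spot quality-control metrics
#'
#' `n_count` is the total UMI count of a spot (column sum); `n_feature` the
#' number of genes detected (raw count > 0) in that spot.
#'
#' @param dataset a `SpotDataset`
#' @return data frame with columns `barcode`, `sample_id`, `region`,
#'   `n_count`, `n_feature`.
#' @export
qc_metrics <- function(dataset) {
  stopifnot(inherits(dataset, "SpotDataset"))
  data.frame(barcode = spot_ids(dataset),
             sample_id = unname(dataset$sample_id),
             region = unname(dataset$region),
             n_count = unname(Matrix::colSums(dataset$counts)),
             n_feature = unname(Matrix::colSums(dataset$counts > 0)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Reference polyline along the residual bone stump
#'
#' An ordered chain of at least two planar vertices in the same coordinate
#' frame as the spots of one sample. Stands in for the manually drawn
#' reference line used by the SpatialTime statistic.
#'
#' @param sample_id sample the line belongs to.
#' @param vertices numeric matrix/data frame with columns `x`, `y` and at
#'   least two rows; consecutive vertices must be distinct.
#' @return an object of class `ReferencePolyline`.
#' @export
ReferencePolyline <- function(sample_id, vertices) {
  vertices <- .xy_matrix(vertices)
  if (nrow(vertices) < 2) stop("polyline needs at least 2 vertices")
  if (!all(is.finite(vertices))) stop("polyline vertices must be finite")
  d <- diff(vertices)
  len <- sqrt(rowSums(d^2))
  if (any(len == 0)) stop("consecutive polyline vertices must be distinct")
  structure(list(sample_id = as.character(sample_id), vertices = vertices),
            class = "ReferencePolyline")
}

#' @export
print.ReferencePolyline <- function(x, ...) {
  cat(sprintf("ReferencePolyline '%s': %d vertices\n",
              x$sample_id, nrow(x$vertices)))
  invisible(x)
}
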