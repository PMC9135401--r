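#' Read a spot dataset from MatrixMarket + Visium-style sidecar files
#'
#' Counts are read from a MatrixMarket coordinate file with `features.tsv`
#' and `barcodes.tsv` sidecars (one id per line) in the same directory.
#' Positions use the 6-column Visium dialect with header
#' `barcode,in_tissue,array_row,array_col,pxl_row_in_fullres,pxl_col_in_fullres`;
#' only `in_tissue == 1` spots are kept, and the full-resolution pixel columns
#' become the geometric coordinates (`x` = pxl_col, `y` = pxl_row). The
#' regions CSV has header `barcode,sample_id,region`; barcodes missing from it
#' get region `"unassigned"`.
#'
#' @param counts_path path to the `.mtx` file (sidecars resolved next to it).
#' @param positions_path path to the positions CSV.
#' @param regions_path path to the regions CSV.
#' @return a validated [SpotDataset].
#' @export
read_dataset <- function(counts_path, positions_path, regions_path) {
  dir <- dirname(counts_path)
  header <- readLines(counts_path, n = 1)
  if (!grepl("^%%MatrixMarket[ \t]+matrix[ \t]+coordinate", header))
    stop("malformed MatrixMarket header in ", counts_path)
  counts <- methods::as(Matrix::readMM(counts_path), "CsparseMatrix")
  genes <- readLines(file.path(dir, "features.tsv"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  # tolerate multi-column features.tsv (id first)
  genes <- vapply(strsplit(genes, "\t", fixed = TRUE), `[[`, "", 1L)
  barcodes <- vapply(strsplit(barcodes, "\t", fixed = TRUE), `[[`, "", 1L)
  if (length(genes) != nrow(counts) || length(barcodes) != ncol(counts))
    stop("features/barcodes sidecar lengths do not match the matrix")
  if (anyDuplicated(barcodes))
    stop("duplicate barcodes in ", file.path(dir, "barcodes.tsv"))
  dimnames(counts) <- list(genes, barcodes)

  pos <- utils::read.csv(positions_path, stringsAsFactors = FALSE)
  need <- c("barcode", "in_tissue", "array_row", "array_col",
            "pxl_row_in_fullres", "pxl_col_in_fullres")
  if (!all(need %in% names(pos)))
    stop("positions file must carry columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(pos$barcode)) stop("duplicate barcodes in positions file")
  pos <- pos[pos$in_tissue == 1, , drop = FALSE]

  reg <- utils::read.csv(regions_path, stringsAsFactors = FALSE)
  if (!all(c("barcode", "sample_id", "region") %in% names(reg)))
    stop("regions file must have header barcode,sample_id,region")
  if (anyDuplicated(reg$barcode)) stop("duplicate barcodes in regions file")
  missing_bc <- setdiff(reg$barcode, barcodes)
  if (length(missing_bc))
    stop("barcode(s) in regions file absent from counts: ",
         paste(utils::head(missing_bc, 5), collapse = ", "))

  keep <- intersect(barcodes, pos$barcode)
  if (!length(keep)) stop("no barcode shared between counts and positions")
  pos <- pos[match(keep, pos$barcode), , drop = FALSE]
  idx <- match(keep, reg$barcode)
  default_sample <- if (length(unique(reg$sample_id)) == 1)
    reg$sample_id[1] else "unknown"
  sample_id <- ifelse(is.na(idx), default_sample, reg$sample_id[idx])
  region <- ifelse(is.na(idx), "unassigned", reg$region[idx])

  SpotDataset(counts[, keep, drop = FALSE],
              coords = data.frame(x = pos$pxl_col_in_fullres,
                                  y = pos$pxl_row_in_fullres),
              sample_id = sample_id, region = region,
              meta = data.frame(array_row = pos$array_row,
                                array_col = pos$array_col,
                                row.names = keep))
}

#' Write a spot dataset as MatrixMarket + sidecars + positions + regions
#'
#' Emits `matrix.mtx`, `features.tsv`, `barcodes.tsv`, `positions.csv` and
#' `regions.csv` into `out_dir` such that [read_dataset()] inverts the write
#' exactly (counts, coordinates and labels round-trip bit-identically).
#'
#' @param dataset a [SpotDataset] with at least one spot.
#' @param out_dir output directory, created if needed.
#' @return invisibly, the named vector of file paths written.
#' @export
write_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "SpotDataset"))
  if (ncol(dataset$counts) == 0) stop("refusing to write an empty dataset")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  paths <- c(mtx = file.path(out_dir, "matrix.mtx"),
             features = file.path(out_dir, "features.tsv"),
             barcodes = file.path(out_dir, "barcodes.tsv"),
             positions = file.path(out_dir, "positions.csv"),
             regions = file.path(out_dir, "regions.csv"))
  Matrix::writeMM(dataset$counts, paths[["mtx"]])
  writeLines(gene_ids(dataset), paths[["features"]])
  writeLines(spot_ids(dataset), paths[["barcodes"]])
  meta <- dataset$meta
  pos <- data.frame(
    barcode = spot_ids(dataset),
    in_tissue = 1L,
    array_row = if (!is.null(meta) && "array_row" %in% names(meta))
      meta$array_row else 0L,
    array_col = if (!is.null(meta) && "array_col" %in% names(meta))
      meta$array_col else 0L,
    pxl_row_in_fullres = dataset$coords[, "y"],
    pxl_col_in_fullres = dataset$coords[, "x"])
  utils::write.csv(pos, paths[["positions"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(barcode = spot_ids(dataset),
                              sample_id = unname(dataset$sample_id),
                              region = unname(dataset$region)),
                   paths[["regions"]], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Read reference polylines from CSV
#'
#' The CSV carries header `sample_id,order,x,y`; one polyline per sample,
#' vertices sorted by `order`.
#'
#' @param path CSV path.
#' @return named list of [ReferencePolyline] objects, one per sample.
#' @export
read_polylines <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "order", "x", "y") %in% names(df)))
    stop("polyline file must have header sample_id,order,x,y")
  out <- lapply(split(df, df$sample_id), function(d) {
    d <- d[order(d$order), , drop = FALSE]
    ReferencePolyline(d$sample_id[1], d[, c("x", "y")])
  })
  out[order(names(out))]
}

#' @rdname read_polylines
#' @param polylines list of [ReferencePolyline] objects.
#' @export
write_polylines <- function(polylines, path) {
  if (inherits(polylines, "ReferencePolyline")) polylines <- list(polylines)
  df <- do.call(rbind, lapply(polylines, function(p)
    data.frame(sample_id = p$sample_id, order = seq_len(nrow(p$vertices)),
               x = p$vertices[, "x"], y = p$vertices[, "y"])))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene-list file
#'
#' One gene symbol per line; blank lines and `#` comments ignored.
#'
#' @param path file path.
#' @return character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  x[nzchar(x)]
}
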