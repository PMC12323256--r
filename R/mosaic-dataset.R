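#' Construct a mosaic multimodal single-cell dataset
#'
#' A `MosaicDataset` holds one cell-by-feature count matrix per modality
#' (e.g. `"rna"`, `"atac"`, `"adt"`), with rows aligned across modalities by
#' cell barcode, together with a cell-by-modality availability mask, a
#' per-cell batch label, and an optional, possibly partial, cell-type label
#' vector. "Mosaic" means different batches may carry different subsets of
#' modalities: a cell is only observed in the modalities its batch assayed,
#' and the mask records which.
#'
#' @param counts Named list of cell x feature matrices (base or
#'   \link[Matrix]{Matrix} sparse), one per modality, all with `n_cells`
#'   rows in the same cell order. Entries must be finite and non-negative.
#' @param batch Per-cell batch label (factor or character), length `n_cells`.
#' @param mask Logical cell x modality matrix; `mask[i, m]` says modality `m`
#'   was measured for cell `i`. Defaults to all-available. Column order must
#'   match `names(counts)`.
#' @param labels Optional per-cell cell-type labels; `NA` marks an unlabeled
#'   cell (the semi-supervised case). Defaults to all-`NA`.
#' @param barcodes Cell identifiers; defaults to rownames of the first
#'   counts matrix, else `cell1..cellN`.
#' @param feature_names Optional named list of feature identifier vectors;
#'   defaults to colnames of each counts matrix.
#'
#' @return An object of class `MosaicDataset`: a list with elements
#'   `counts`, `mask`, `batch`, `labels`, `barcodes`, `feature_names`,
#'   `modalities`, `n_cells`.
#' @export
mosaic_dataset <- function(counts, batch, mask = NULL, labels = NULL,
                           barcodes = NULL, feature_names = NULL) {
  if (!is.list(counts) || is.null(names(counts)) || any(names(counts) == ""))
    stop("`counts` must be a named list of matrices, one per modality")
  modalities <- names(counts)
  counts <- lapply(counts, function(x) {
    if (inherits(x, "Matrix")) x else as.matrix(x)
  })
  n_cells <- nrow(counts[[1]])

  if (is.null(barcodes)) barcodes <- rownames(counts[[1]])
  if (is.null(barcodes)) barcodes <- paste0("cell", seq_len(n_cells))
  if (anyDuplicated(barcodes))
    stop("duplicate barcodes: ", paste(unique(barcodes[duplicated(barcodes)]), collapse = ", "))

  if (is.null(mask)) {
    mask <- matrix(TRUE, n_cells, length(modalities),
                   dimnames = list(barcodes, modalities))
  } else {
    mask <- as.matrix(mask)
    storage.mode(mask) <- "logical"
    if (is.null(colnames(mask))) colnames(mask) <- modalities
    mask <- mask[, modalities, drop = FALSE]
    rownames(mask) <- barcodes
  }

  if (is.null(labels)) labels <- factor(rep(NA_character_, n_cells))
  if (!is.factor(labels)) labels <- factor(labels)
  batch <- if (is.factor(batch)) droplevels(batch) else factor(batch)

  if (is.null(feature_names))
    feature_names <- lapply(counts, function(x) {
      colnames(x) %||% paste0("f", seq_len(ncol(x)))
    })

  ds <- structure(
    list(counts = counts, mask = mask, batch = batch, labels = labels,
         barcodes = as.character(barcodes), feature_names = feature_names,
         modalities = modalities, n_cells = n_cells),
    class = "MosaicDataset"
  )
  validate_mosaic(ds)
  ds
}

#' Validate a MosaicDataset against its invariants
#'
#' Checks that every cell has at least one available modality, that all
#' counts matrices have `n_cells` rows of finite non-negative entries, that
#' batch/labels/mask lengths agree, and that feature name vectors match the
#' matrix dimensions. Errors name the offending cell barcode where relevant.
#'
#' @param ds A [mosaic_dataset()].
#' @return `ds`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_mosaic <- function(ds) {
  stopifnot(inherits(ds, "MosaicDataset"))
  n <- ds$n_cells
  if (length(ds$barcodes) != n) stop("barcodes length != n_cells")
  if (length(ds$batch) != n) stop("batch length != n_cells")
  if (length(ds$labels) != n) stop("labels length != n_cells")
  if (!identical(dim(ds$mask), c(n, length(ds$modalities))))
    stop("mask must be n_cells x n_modalities")
  orphan <- rowSums(ds$mask) < 1
  if (any(orphan))
    stop("cell(s) with zero available modalities: ",
         paste(utils::head(ds$barcodes[orphan], 5), collapse = ", "))
  for (m in ds$modalities) {
    x <- ds$counts[[m]]
    if (nrow(x) != n) stop("counts[['", m, "']] row count != n_cells")
    vals <- if (inherits(x, "sparseMatrix")) x@x else as.numeric(x)
    if (length(vals) && (any(!is.finite(vals)) || any(vals < 0)))
      stop("counts[['", m, "']] has non-finite or negative entries")
    if (length(ds$feature_names[[m]]) != ncol(x))
      stop("feature_names[['", m, "']] length != feature count")
  }
  invisible(ds)
}

#' @exportS3Method base::print
print.MosaicDataset <- function(x, ...) {
  cat("MosaicDataset:", x$n_cells, "cells,",
      length(x$modalities), "modalities\n")
  for (m in x$modalities)
    cat(sprintf("  %-6s %6d features, %5d cells available\n",
                m, ncol(x$counts[[m]]), sum(x$mask[, m])))
  cat("  batches:", paste(levels(x$batch), collapse = ", "), "\n")
  nl <- sum(!is.na(x$labels))
  cat("  labels: ", nl, "/", x$n_cells, " cells labeled\n", sep = "")
  invisible(x)
}

# ---- I/O ---------------------------------------------------------------

read_barcode_tsv <- function(path, what) {
  v <- readLines(path)
  v <- v[nzchar(v)]
  if (anyDuplicated(v))
    stop("duplicate barcode in ", what, ": ",
         paste(unique(v[duplicated(v)]), collapse = ", "))
  v
}

# Read one modality from either an MTX directory (matrix.mtx + barcodes.tsv +
# features.tsv, features x cells per the 10x convention) or a dense CSV
# (header = feature names, first column = barcodes). Returns cells x features.
read_modality <- function(path, modality) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    if (!file.exists(mtx)) stop("no matrix.mtx under ", path)
    m <- Matrix::readMM(mtx)
    bc <- read_barcode_tsv(file.path(path, "barcodes.tsv"), modality)
    ft <- readLines(file.path(path, "features.tsv"))
    ft <- ft[nzchar(ft)]
    if (nrow(m) != length(ft) || ncol(m) != length(bc))
      stop("MTX dimensions do not match sidecars under ", path)
    x <- Matrix::t(m)
    dimnames(x) <- list(bc, ft)
    methods::as(x, "CsparseMatrix")
  } else if (grepl("\\.csv$", path)) {
    df <- utils::read.csv(path, check.names = FALSE)
    bc <- as.character(df[[1]])
    if (anyDuplicated(bc))
      stop("duplicate barcode in ", modality, ": ",
           paste(unique(bc[duplicated(bc)]), collapse = ", "))
    x <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(x)) stop("non-numeric entries in ", path)
    rownames(x) <- bc
    x
  } else {
    stop("unsupported modality path (need MTX directory or .csv): ", path)
  }
}

#' Load a mosaic dataset from per-modality files
#'
#' Each modality is read from an MTX directory (`matrix.mtx` in MatrixMarket
#' coordinate format with 1-based indices, features x cells, plus
#' `barcodes.tsv` and `features.tsv` sidecars) or a dense CSV (header row of
#' feature names, first column of barcodes). Cell alignment is by barcode
#' string; the cell order of the result is the union of barcodes in
#' first-seen order, and a cell absent from a modality file gets
#' `mask = FALSE` for that modality.
#'
#' @param paths Named list/vector of per-modality file locations.
#' @param batch_path Two-column headerless TSV `barcode<TAB>batch` covering
#'   every cell.
#' @param labels_path Optional two-column headerless TSV
#'   `barcode<TAB>label`; barcodes it omits stay unlabeled (`NA`).
#' @return A validated [mosaic_dataset()].
#' @export
load_mosaic <- function(paths, batch_path, labels_path = NULL) {
  mats <- mapply(read_modality, paths, names(paths), SIMPLIFY = FALSE)
  barcodes <- character(0)
  for (x in mats) barcodes <- union(barcodes, rownames(x))
  n <- length(barcodes)

  mask <- sapply(mats, function(x) barcodes %in% rownames(x))
  mask <- matrix(mask, nrow = n, dimnames = list(barcodes, names(mats)))

  counts <- lapply(mats, function(x) {
    full <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                 dims = c(n, ncol(x)),
                                 dimnames = list(barcodes, colnames(x)))
    full[rownames(x), ] <- methods::as(methods::as(x, "CsparseMatrix"), "generalMatrix")
    full
  })

  bt <- utils::read.delim(batch_path, header = FALSE,
                          colClasses = "character")
  batch_map <- stats::setNames(bt[[2]], bt[[1]])
  if (!all(barcodes %in% names(batch_map)))
    stop("batch file missing barcodes: ",
         paste(utils::head(setdiff(barcodes, names(batch_map)), 5), collapse = ", "))
  batch <- factor(unname(batch_map[barcodes]))

  labels <- NULL
  if (!is.null(labels_path) && file.exists(labels_path) &&
      file.size(labels_path) > 0) {
    lt <- utils::read.delim(labels_path, header = FALSE,
                            colClasses = "character")
    lmap <- stats::setNames(lt[[2]], lt[[1]])
    labels <- factor(unname(lmap[barcodes]))
  }

  mosaic_dataset(counts, batch = batch, mask = mask, labels = labels,
                 barcodes = barcodes)
}

#' Write a mosaic dataset to disk
#'
#' Writes one MTX directory per modality (only the cells available in that
#' modality, features x cells), `batch.tsv`, `labels.tsv` (labeled cells
#' only), and a JSON `manifest.json` naming all files, so the dataset
#' round-trips exactly through [load_mosaic()].
#'
#' @param ds A [mosaic_dataset()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_mosaic <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (m in ds$modalities) {
    mdir <- file.path(dir, m)
    dir.create(mdir, showWarnings = FALSE)
    keep <- ds$mask[, m]
    x <- Matrix::Matrix(ds$counts[[m]][keep, , drop = FALSE], sparse = TRUE)
    x <- methods::as(methods::as(x, "CsparseMatrix"), "generalMatrix")
    Matrix::writeMM(Matrix::t(x), file.path(mdir, "matrix.mtx"))
    writeLines(ds$barcodes[keep], file.path(mdir, "barcodes.tsv"))
    writeLines(ds$feature_names[[m]], file.path(mdir, "features.tsv"))
    paths[[m]] <- mdir
  }
  utils::write.table(data.frame(ds$barcodes, as.character(ds$batch)),
                     file.path(dir, "batch.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  lab <- !is.na(ds$labels)
  utils::write.table(
    data.frame(ds$barcodes[lab], as.character(ds$labels[lab])),
    file.path(dir, "labels.tsv"), sep = "\t",
    row.names = FALSE, col.names = FALSE, quote = FALSE)
  manifest <- list(modalities = as.list(unlist(paths)),
                   batch = file.path(dir, "batch.tsv"),
                   labels = file.path(dir, "labels.tsv"))
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE)
  invisible(mpath)
}

#' Load a mosaic dataset from a manifest written by [write_mosaic()]
#' @param manifest_path Path to `manifest.json`.
#' @return A [mosaic_dataset()].
#' @export
load_mosaic_manifest <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path)
  labels_path <- man$labels
  load_mosaic(lapply(man$modalities, identity), man$batch, labels_path)
}
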