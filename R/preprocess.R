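#' Normalize a mosaic dataset into per-modality views
#'
#' Produces the real-valued views the encoders and the neighbor graphs are
#' built on. Defaults follow single-cell practice: per-cell library-size
#' normalization to `target_sum` followed by `log1p` for RNA and ADT, and
#' TF-IDF (term frequency scaled by inverse document frequency, then
#' `log1p`) for ATAC, whose near-binary sparsity makes library-size scaling
#' uninformative. A centered log-ratio (`"clr"`) transform is available for
#' ADT. Rows of cells for which a modality is unavailable are set to `NA`,
#' never silently zero, so downstream code must consult the mask.
#'
#' @param ds A [mosaic_dataset()].
#' @param methods Named character vector mapping modality to one of
#'   `"lognorm"`, `"tfidf"`, `"clr"`. Unnamed modalities default to
#'   `"lognorm"`, except those named `"atac"`, which default to `"tfidf"`.
#' @param target_sum Library-size target for `"lognorm"` (default `1e4`).
#' @return A `PreprocessedDataset`: list with `views` (named list of dense
#'   cell x feature matrices, masked-out rows `NA`), and `provenance`
#'   (the normalization applied per modality).
#' @export
preprocess <- function(ds, methods = NULL, target_sum = 1e4) {
  validate_mosaic(ds)
  resolved <- vapply(ds$modalities, function(m) {
    if (!is.null(methods) && m %in% names(methods)) return(methods[[m]])
    if (m == "atac") "tfidf" else "lognorm"
  }, FUN.VALUE = character(1))
  views <- list()
  for (m in ds$modalities) {
    avail <- ds$mask[, m]
    x <- as.matrix(ds$counts[[m]][avail, , drop = FALSE])
    zero_rows <- rowSums(x) == 0
    if (any(zero_rows))
      warning(sum(zero_rows), " all-zero cell(s) in available modality '", m,
              "' left as zeros", call. = FALSE)
    v <- switch(resolved[[m]],
      lognorm = normalize_lognorm(x, target_sum),
      tfidf   = normalize_tfidf(x),
      clr     = normalize_clr(x),
      stop("unknown normalization '", resolved[[m]], "'")
    )
    full <- matrix(NA_real_, ds$n_cells, ncol(v),
                   dimnames = list(ds$barcodes, ds$feature_names[[m]]))
    full[avail, ] <- v
    views[[m]] <- full
  }
  structure(
    list(views = views,
         provenance = list(methods = as.list(resolved),
                           target_sum = target_sum)),
    class = "PreprocessedDataset"
  )
}

# x: available cells only, dense. Per-cell scale to target_sum, then log1p.
normalize_lognorm <- function(x, target_sum) {
  rs <- rowSums(x)
  scale <- ifelse(rs > 0, target_sum / rs, 0)
  log1p(x * scale)
}

# TF = count / cell total; IDF = n_cells / feature document frequency;
# view = log1p(TF * IDF * 1e4). Features observed in no cell get 0.
normalize_tfidf <- function(x) {
  rs <- rowSums(x)
  tf <- x / ifelse(rs > 0, rs, 1)
  df <- colSums(x > 0)
  idf <- ifelse(df > 0, nrow(x) / df, 0)
  log1p(sweep(tf, 2, idf, `*`) * 1e4)
}

# Centered log-ratio across features within each cell, on log1p counts.
normalize_clr <- function(x) {
  y <- log1p(x)
  y - rowMeans(y)
}

#' @exportS3Method base::print
print.PreprocessedDataset <- function(x, ...) {
  cat("PreprocessedDataset:\n")
  for (m in names(x$views))
    cat(sprintf("  %-6s %d x %d (%s)\n", m, nrow(x$views[[m]]),
                ncol(x$views[[m]]), x$provenance$methods[[m]]))
  invisible(x)
}
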