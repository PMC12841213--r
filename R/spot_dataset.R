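#' Spot-level spatial transcriptomics dataset
#'
#' The central container of the package: a gene x spot count matrix together
#' with per-spot metadata (2D coordinates, skin layer, sample, disease group
#' and per-sample PASI severity score).
#'
#' @param counts gene x spot matrix of non-negative integer counts (dense or
#'   sparse \code{Matrix}); rownames are gene symbols, colnames spot barcodes.
#' @param spots data.frame with one row per spot and columns \code{barcode},
#'   \code{x}, \code{y}, \code{layer} (\code{"epidermis"} or \code{"dermis"}),
#'   \code{sample}, \code{group} (\code{"HC"}, \code{"NL"} or \code{"L"}) and
#'   \code{pasi} (numeric, \code{NA} where not available, e.g. healthy
#'   controls).
#'
#' @return An object of class \code{spot_dataset}: a list with elements
#'   \code{counts} (a \code{dgCMatrix}), \code{spots} and \code{genes}.
#' @export
spot_dataset <- function(counts, spots) {
  if (!inherits(counts, "Matrix")) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  spots <- as.data.frame(spots, stringsAsFactors = FALSE)
  required <- c("barcode", "x", "y", "layer", "sample", "group", "pasi")
  missing_cols <- setdiff(required, names(spots))
  if (length(missing_cols) > 0L) {
    stop("spots table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (ncol(counts) != nrow(spots)) {
    stop("dimension mismatch: counts has ", ncol(counts), " spots but spots table has ",
         nrow(spots), " rows")
  }
  if (is.null(rownames(counts))) stop("counts must have gene symbols as rownames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene symbols in counts")
  spots$barcode <- as.character(spots$barcode)
  if (anyDuplicated(spots$barcode)) {
    dup <- spots$barcode[duplicated(spots$barcode)][1L]
    stop("duplicate barcodes rejected (first: ", dup, ")")
  }
  bad_layer <- which(!spots$layer %in% c("epidermis", "dermis"))
  if (length(bad_layer) > 0L) {
    stop("unknown layer token '", spots$layer[bad_layer[1L]], "' in spots row ",
         bad_layer[1L], " (allowed: epidermis, dermis)")
  }
  bad_group <- which(!spots$group %in% c("HC", "NL", "L"))
  if (length(bad_group) > 0L) {
    stop("unknown group token '", spots$group[bad_group[1L]], "' in spots row ",
         bad_group[1L], " (allowed: HC, NL, L)")
  }
  spots$x <- as.numeric(spots$x)
  spots$y <- as.numeric(spots$y)
  spots$pasi <- suppressWarnings(as.numeric(spots$pasi))
  if (any(counts@x < 0)) stop("negative counts are not allowed")
  colnames(counts) <- spots$barcode
  structure(
    list(counts = counts, spots = spots, genes = rownames(counts)),
    class = "spot_dataset"
  )
}

#' @export
print.spot_dataset <- function(x, ...) {
  cat("spot_dataset:", length(x$genes), "genes x", nrow(x$spots), "spots\n")
  cat("  samples:", paste(unique(x$spots$sample), collapse = ", "), "\n")
  tl <- table(x$spots$layer)
  cat("  layers: ", paste(names(tl), tl, sep = "=", collapse = ", "), "\n", sep = "")
  tg <- table(x$spots$group)
  cat("  groups: ", paste(names(tg), tg, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.spot_dataset <- function(x) c(length(x$genes), nrow(x$spots))

#' Subset a spot dataset by spot index
#'
#' @param dataset a \code{spot_dataset}.
#' @param idx integer, logical or barcode index over spots.
#' @return the subsetted \code{spot_dataset}.
#' @export
subset_spots <- function(dataset, idx) {
  stopifnot(inherits(dataset, "spot_dataset"))
  if (is.character(idx)) idx <- match(idx, dataset$spots$barcode)
  counts <- dataset$counts[, idx, drop = FALSE]
  spots <- dataset$spots[idx, , drop = FALSE]
  rownames(spots) <- NULL
  spot_dataset(counts, spots)
}
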