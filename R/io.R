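#' Run configuration
#'
#' Collects the tunable parameters of the pipeline with validated defaults.
#' QC cutoffs are deliberately exposed rather than fixed: sensible values vary
#' with platform and tissue, and the frequency denominators downstream depend
#' on them.
#'
#' @param seed non-negative integer seed used for every stochastic step.
#' @param min_genes_per_spot QC: minimum number of detected genes per spot.
#' @param max_mito_fraction QC: maximum mitochondrial transcript proportion.
#' @param mito_prefix gene-symbol prefix identifying mitochondrial genes.
#' @param knn_k neighbours for the spatial weight graph (6 matches the
#'   hexagonal Visium lattice).
#' @param t_gate_quantile per-sample quantile of the deconvolved T fraction
#'   used as the adaptive niche gate.
#' @param t_gate_floor lower bound on the adaptive gate.
#' @param signature_mode \code{"plain_mean"} or \code{"control_corrected"}
#'   module scoring.
#' @param clr_margin \code{"per_cell"} or \code{"per_feature"} CLR margin for
#'   ADT normalisation.
#' @param min_common_genes minimum reference/dataset gene intersection for
#'   deconvolution.
#' @param output_dir directory where pipeline reports are written.
#' @return a validated list of class \code{iltc_config}.
#' @export
iltc_config <- function(seed = 1L,
                        min_genes_per_spot = 100L,
                        max_mito_fraction = 0.2,
                        mito_prefix = "MT-",
                        knn_k = 6L,
                        t_gate_quantile = 0.8,
                        t_gate_floor = 0.05,
                        signature_mode = c("plain_mean", "control_corrected"),
                        clr_margin = c("per_cell", "per_feature"),
                        min_common_genes = 50L,
                        output_dir = ".") {
  signature_mode <- match.arg(signature_mode)
  clr_margin <- match.arg(clr_margin)
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0L) stop("seed must be a non-negative integer")
  if (max_mito_fraction < 0 || max_mito_fraction > 1) {
    stop("max_mito_fraction must be in [0, 1]")
  }
  if (t_gate_quantile <= 0 || t_gate_quantile >= 1) {
    stop("t_gate_quantile must be in (0, 1)")
  }
  if (t_gate_floor < 0 || t_gate_floor > 1) stop("t_gate_floor must be in [0, 1]")
  if (knn_k < 1L) stop("knn_k must be >= 1")
  structure(
    list(seed = seed,
         min_genes_per_spot = as.integer(min_genes_per_spot),
         max_mito_fraction = max_mito_fraction,
         mito_prefix = mito_prefix,
         knn_k = as.integer(knn_k),
         t_gate_quantile = t_gate_quantile,
         t_gate_floor = t_gate_floor,
         signature_mode = signature_mode,
         clr_margin = clr_margin,
         min_common_genes = as.integer(min_common_genes),
         output_dir = output_dir),
    class = "iltc_config"
  )
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   \code{\link{iltc_config}}.
#' @return an \code{iltc_config}.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(iltc_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(iltc_config, vals)
}

#' Read a spot dataset from MatrixMarket + TSV sidecars
#'
#' Counts are stored as a MatrixMarket \code{coordinate integer general}
#' matrix with genes as rows (matching common Visium exports); spot metadata
#' and gene symbols travel in TSV sidecars. Missing PASI is encoded as an
#' empty string (0 is a valid PASI score).
#'
#' @param counts_path MatrixMarket \code{.mtx} file, genes x spots, integer.
#' @param spots_path TSV with columns barcode, x, y, layer, sample, group,
#'   pasi.
#' @param genes_path TSV with one gene symbol per row, no header.
#' @return a \code{\link{spot_dataset}}.
#' @export
read_spot_dataset <- function(counts_path, spots_path, genes_path) {
  header <- readLines(counts_path, n = 1L)
  if (!grepl("^%%MatrixMarket\\s+matrix\\s+coordinate\\s+integer\\s+general\\s*$",
             header)) {
    stop("format error: expected MatrixMarket 'coordinate integer general' header in ",
         counts_path, " (got: ", header, ")")
  }
  counts <- Matrix::readMM(counts_path)
  if (any(counts@x != round(counts@x))) {
    stop("format error: non-integer entry in counts file ", counts_path)
  }
  genes <- read.delim(genes_path, header = FALSE, stringsAsFactors = FALSE)[[1L]]
  spots <- read.delim(spots_path, header = TRUE, stringsAsFactors = FALSE,
                      colClasses = list(barcode = "character", pasi = "character"))
  if (nrow(counts) != length(genes)) {
    stop("format error: counts has ", nrow(counts), " rows but genes file lists ",
         length(genes), " genes")
  }
  if (ncol(counts) != nrow(spots)) {
    stop("format error: counts has ", ncol(counts), " columns but spots file lists ",
         nrow(spots), " spots")
  }
  spots$pasi <- suppressWarnings(as.numeric(ifelse(spots$pasi == "", NA, spots$pasi)))
  rownames(counts) <- genes
  colnames(counts) <- spots$barcode
  spot_dataset(counts, spots)
}

#' Write a spot dataset to MatrixMarket + TSV sidecars
#'
#' Inverse of \code{\link{read_spot_dataset}}; the round trip reproduces
#' counts and metadata exactly.
#'
#' @param dataset a \code{spot_dataset}.
#' @param counts_path,spots_path,genes_path output file paths.
#' @return invisibly, the three paths.
#' @export
write_spot_dataset <- function(dataset, counts_path, spots_path, genes_path) {
  stopifnot(inherits(dataset, "spot_dataset"))
  m <- as(dataset$counts, "TsparseMatrix")
  ord <- order(m@j, m@i)
  con <- file(counts_path, "w")
  writeLines("%%MatrixMarket matrix coordinate integer general", con)
  writeLines(sprintf("%d %d %d", nrow(m), ncol(m), length(m@x)), con)
  writeLines(sprintf("%d %d %d", m@i[ord] + 1L, m@j[ord] + 1L,
                     as.integer(m@x[ord])), con)
  close(con)
  spots <- dataset$spots
  spots$pasi <- ifelse(is.na(spots$pasi), "", format(spots$pasi, trim = TRUE))
  write.table(spots, spots_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene = dataset$genes), genes_path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(counts = counts_path, spots = spots_path, genes = genes_path))
}

#' Read gene signatures from a GMT file
#'
#' Standard GMT: tab-separated lines of set name, description, then one or
#' more genes. Genes are de-duplicated within a set with order preserved.
#'
#' @param path GMT file path.
#' @return a named list of character vectors (class \code{signature_set}).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path)
    return(structure(list(), class = "signature_set"))
  }
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("format error: GMT line ", i, " has fewer than 3 fields")
    }
    name <- fields[[1L]]
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (name %in% names(sets)) stop("duplicate set name in GMT: ", name)
    sets[[name]] <- genes
  }
  structure(sets, class = "signature_set")
}

#' Write gene signatures to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of set descriptions.
#' @return invisibly, \code{path}.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a cell-type reference profile
#'
#' TSV with gene symbols in the first column and one column of mean
#' expression per cell type.
#'
#' @param path TSV file path.
#' @return numeric gene x cell-type matrix.
#' @export
read_reference <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  validate_reference(m)
  m
}

#' @rdname read_reference
#' @param ref gene x cell-type matrix.
#' @export
write_reference <- function(ref, path) {
  df <- data.frame(gene = rownames(ref), ref, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_reference <- function(ref) {
  if (is.null(rownames(ref)) || is.null(colnames(ref))) {
    stop("reference must carry gene rownames and cell-type colnames")
  }
  if (anyDuplicated(rownames(ref))) stop("duplicate gene symbols in reference")
  if (any(ref < 0)) stop("reference expression must be non-negative")
  zero_col <- colSums(ref) == 0
  if (any(zero_col)) {
    stop("all-zero cell-type column(s) in reference: ",
         paste(colnames(ref)[zero_col], collapse = ", "))
  }
  invisible(ref)
}

#' Spot-level quality control filter
#'
#' Retains spots with at least \code{min_genes_per_spot} detected genes and a
#' mitochondrial transcript fraction at most \code{max_mito_fraction}.
#' Retention is logged per sample so downstream frequency denominators are
#' auditable; a sample losing all its spots is dropped with a warning.
#'
#' @param dataset a \code{spot_dataset}.
#' @param config an \code{\link{iltc_config}} (QC fields used).
#' @param verbose log per-sample retention via \code{message()}.
#' @return the filtered \code{spot_dataset}.
#' @export
qc_filter <- function(dataset, config = iltc_config(), verbose = TRUE) {
  stopifnot(inherits(dataset, "spot_dataset"))
  counts <- dataset$counts
  detected <- Matrix::colSums(counts > 0)
  totals <- Matrix::colSums(counts)
  mito <- startsWith(dataset$genes, config$mito_prefix)
  mito_frac <- rep(0, ncol(counts))
  nz <- totals > 0
  if (any(mito)) {
    mito_frac[nz] <- Matrix::colSums(counts[mito, nz, drop = FALSE]) / totals[nz]
  }
  keep <- detected >= config$min_genes_per_spot & mito_frac <= config$max_mito_fraction
  if (verbose) {
    for (s in unique(dataset$spots$sample)) {
      in_s <- dataset$spots$sample == s
      message("qc_filter: sample ", s, ": ", sum(keep & in_s), "/", sum(in_s),
              " spots retained")
    }
  }
  lost <- setdiff(unique(dataset$spots$sample), unique(dataset$spots$sample[keep]))
  if (length(lost) > 0L) {
    warning("qc_filter removed all spots of sample(s): ",
            paste(lost, collapse = ", "), "; dropped from downstream tables")
  }
  subset_spots(dataset, which(keep))
}

#' Default iLTC gene signatures
#'
#' Loads the signature sets shipped with the package (gdT, MAIT, iNKT, pan-T,
#' fibroblast, keratinocyte, tissue-residency). The gdT and MAIT sets are
#' built from canonical lineage markers (TRDC/TRGC1/TRGC2/KLRD1/B2M and
#' KLRB1/DPP4/CXCR6/IL7R respectively); all sets are editable fixtures, not
#' a curated resource.
#'
#' @return a \code{signature_set}.
#' @export
default_signatures <- function() {
  read_gmt(system.file("extdata", "iltc_signatures.gmt", package = "iltcmap",
                       mustWork = TRUE))
}
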