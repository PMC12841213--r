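#' Run the full spatial niche-mapping pipeline
#'
#' Chains QC, log-normalisation, NNLS deconvolution, signature scoring,
#' adaptive niche calling, layer-stratified frequency summaries, severity
#' statistics (rank correlations + imbalance index + per-layer Moran's I of
#' the niche indicator fields), differential expression between gdT and MAIT
#' niche spots, and gene-set enrichment of the significant genes. Writes six
#' CSV reports into \code{config$output_dir}; given the same inputs and seed
#' the outputs are byte-identical across runs.
#'
#' @param dataset a \code{spot_dataset} (or set \code{counts_path} etc.).
#' @param ref gene x cell-type reference matrix.
#' @param signatures a \code{signature_set}; defaults to the shipped sets.
#' @param config an \code{\link{iltc_config}}.
#' @param counts_path,spots_path,genes_path alternative file-based input.
#' @param cite optional list with elements \code{adt} (cell x marker
#'   counts), \code{cells} (donor/group metadata) and optionally
#'   \code{rna_scores} and \code{spec} (a \code{gate_spec}); when absent
#'   \code{cite_summary.csv} is written with a header only.
#' @param verbose log progress.
#' @return invisibly, a list with all intermediate tables.
#' @export
run_pipeline <- function(dataset = NULL, ref, signatures = default_signatures(),
                         config = iltc_config(),
                         counts_path = NULL, spots_path = NULL,
                         genes_path = NULL, cite = NULL, verbose = TRUE) {
  if (is.null(dataset)) {
    dataset <- read_spot_dataset(counts_path, spots_path, genes_path)
  }
  say <- function(...) if (verbose) message("run_pipeline: ", ...)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out_path <- function(f) file.path(config$output_dir, f)
  set.seed(config$seed)

  say("QC filter")
  dataset <- qc_filter(dataset, config, verbose = verbose)
  say("log-normalisation")
  log_expr <- log_normalize(dataset$counts)
  say("deconvolution (", ncol(ref), " cell types)")
  fractions <- deconvolve_spots(dataset, ref,
                                min_common_genes = config$min_common_genes)

  say("signature scoring")
  subset_sets <- c(gdT = "gdT", MAIT = "MAIT", iNKT = "iNKT")
  scores <- sapply(subset_sets[subset_sets %in% names(signatures)],
                   function(nm) score_signature(log_expr, signatures[[nm]],
                                                mode = config$signature_mode,
                                                seed = config$seed))
  say("niche calling")
  calls <- call_niches(fractions, scores, dataset, config)
  summary_tab <- niche_frequencies(calls, dataset)
  write.csv(calls, out_path("niche_calls.csv"), row.names = FALSE)
  write.csv(summary_tab, out_path("sample_summary.csv"), row.names = FALSE)

  say("severity statistics")
  severity <- severity_stats(summary_tab, calls, dataset, config)
  write.csv(severity, out_path("severity_stats.csv"), row.names = FALSE)

  say("differential expression gdT vs MAIT niches")
  de_idx <- calls$label %in% c("gdT", "MAIT")
  de_tab <- data.frame(gene = character(), log_fc = numeric(), p = numeric(),
                       p_adj = numeric(), pct_a = numeric(), pct_b = numeric())
  enr_tab <- data.frame(set = character(), overlap = integer(),
                        set_size = integer(), query_size = integer(),
                        universe_size = integer(), gene_ratio = numeric(),
                        p = numeric(), p_adj = numeric())
  if (sum(calls$label[de_idx] == "gdT") >= 3L &&
      sum(calls$label[de_idx] == "MAIT") >= 3L) {
    de_tab <- wilcoxon_de(log_expr[, de_idx, drop = FALSE],
                          factor(calls$label[de_idx], levels = c("gdT", "MAIT")))
    hits <- filter_de(de_tab)
    if (nrow(hits) > 0L) {
      enr_tab <- hypergeom_enrich(hits$gene, unclass(signatures), de_tab$gene)
    }
  } else {
    say("too few gdT/MAIT niche spots for DE; tables empty")
  }
  write.csv(de_tab, out_path("de_table.csv"), row.names = FALSE)
  write.csv(enr_tab, out_path("enrichment.csv"), row.names = FALSE)

  cite_tab <- data.frame(donor = character(), n_root = integer(),
                         low_n = logical())
  if (!is.null(cite)) {
    say("CITE-seq stage")
    cite_tab <- run_cite(cite, config)
  }
  write.csv(cite_tab, out_path("cite_summary.csv"), row.names = FALSE)

  say("done; reports in ", config$output_dir)
  invisible(list(dataset = dataset, fractions = fractions, calls = calls,
                 sample_summary = summary_tab, severity = severity,
                 de = de_tab, enrichment = enr_tab, cite = cite_tab))
}

# severity stats: rank correlations of niche features with PASI + imbalance
# index + per-sample Moran's I of niche indicators (lesional samples)
severity_stats <- function(summary_tab, calls, dataset, config) {
  rows <- list()
  les <- summary_tab[summary_tab$group == "L" & !is.na(summary_tab$pasi), ]
  if (nrow(les) == 0L) {
    warning("no lesional samples with PASI; severity table empty")
    return(data.frame(feature = character(), layer = character(),
                      rho = numeric(), p = numeric(), n = integer()))
  }
  for (ly in c("dermis", "epidermis")) {
    for (sub in c("gdT", "MAIT", "iNKT")) {
      d <- les[les$layer == ly, ]
      if (nrow(d) < 3L) next
      ct <- severity_correlation(d[[paste0("pct_", sub)]], d$pasi)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = paste0("pct_", sub), layer = ly, rho = ct$rho, p = ct$p,
        n = ct$n, stringsAsFactors = FALSE)
    }
  }
  imb <- tryCatch(imbalance_index(summary_tab), error = function(e) NULL)
  if (!is.null(imb)) {
    ct <- severity_correlation(imb$index, imb$pasi)
    rows[[length(rows) + 1L]] <- data.frame(
      feature = "imbalance_index", layer = "both", rho = ct$rho, p = ct$p,
      n = ct$n, stringsAsFactors = FALSE)
    # Moran's I of niche indicator fields vs PASI, per layer
    for (ly in c("dermis", "epidermis")) {
      sub <- if (ly == "dermis") "gdT" else "MAIT"
      mi <- moran_by_sample(calls, dataset, layer = ly, subset = sub,
                            k = config$knn_k)
      mi <- merge(mi, unique(les[, c("sample", "pasi")]), by = "sample")
      mi <- mi[!is.na(mi$I), ]
      if (nrow(mi) >= 4L) {
        ct <- severity_correlation(mi$I, mi$pasi)
        rows[[length(rows) + 1L]] <- data.frame(
          feature = paste0("moran_", sub), layer = ly, rho = ct$rho, p = ct$p,
          n = ct$n, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Moran's I of a niche indicator per sample and layer
#'
#' Binary indicator (spot labelled with the subset or not) on the spots of
#' one layer of each lesional sample, with the default kNN weights.
#'
#' @param calls a \code{niche_call_table}.
#' @param dataset the matching \code{spot_dataset}.
#' @param layer \code{"dermis"} or \code{"epidermis"}.
#' @param subset niche label whose indicator field is tested.
#' @param k neighbours for the weight graph.
#' @param groups sample groups to include (default lesional).
#' @return data.frame: sample, I, n, flag.
#' @export
moran_by_sample <- function(calls, dataset, layer, subset, k = 6L,
                            groups = "L") {
  spots <- dataset$spots
  rows <- list()
  for (s in unique(spots$sample[spots$group %in% groups])) {
    idx <- which(spots$sample == s & spots$layer == layer)
    if (length(idx) < k + 1L) next
    w <- build_spatial_weights(spots[idx, c("x", "y")], k = k)
    v <- as.numeric(calls$label[idx] == subset)
    mi <- morans_i(v, w)
    rows[[length(rows) + 1L]] <- data.frame(
      sample = s, I = mi$I, n = mi$n, flag = mi$flag, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(sample = character(), I = numeric(), n = integer(),
                      flag = character()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# CITE stage used by run_pipeline and the CLI
run_cite <- function(cite, config = iltc_config()) {
  spec <- if (!is.null(cite$spec)) cite$spec else default_gate_spec()
  clr <- clr_transform(cite$adt, margin = config$clr_margin)
  gates <- gate_positive(clr, spec)
  freq <- subset_frequencies(gates, cite$cells$donor)
  grp <- unique(cite$cells[, c("donor", "group")])
  freq <- merge(freq, grp, by = "donor", sort = TRUE)
  if (!is.null(cite$rna_scores)) {
    for (sub in intersect(c("gdT", "MAIT", "iNKT"), colnames(cite$rna_scores))) {
      col <- paste0("pct_", sub)
      if (!col %in% names(freq)) next
      cd45 <- gates[, "CD45"]
      mean_scores <- tapply(cite$rna_scores[cd45, sub],
                            cite$cells$donor[cd45], mean)
      conc <- rna_protein_concordance(as.numeric(mean_scores[freq$donor]),
                                      freq[[col]])
      freq[[paste0("concordance_rho_", sub)]] <- conc$rho
      freq[[paste0("concordance_p_", sub)]] <- conc$p
    }
  }
  freq
}
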