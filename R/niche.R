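#' Log-normalise counts
#'
#' \code{log1p(count * scale / spot_total)} per spot (column). Spots with
#' zero total counts get an all-zero column and are flagged in the
#' \code{"zero_spots"} attribute.
#'
#' @param counts gene x spot count matrix (dense or sparse).
#' @param scale library-size scale factor (default 10 000).
#' @return matrix of the same shape (sparse in, sparse out).
#' @export
log_normalize <- function(counts, scale = 1e4) {
  if (scale <= 0) stop("scale must be > 0")
  if (any(counts < 0)) stop("negative counts are not allowed")
  totals <- if (inherits(counts, "Matrix")) Matrix::colSums(counts) else colSums(counts)
  denom <- ifelse(totals == 0, 1, totals)
  if (inherits(counts, "Matrix")) {
    out <- counts %*% Matrix::Diagonal(x = scale / denom)
    out@x <- log1p(out@x)
    dimnames(out) <- dimnames(counts)
  } else {
    out <- log1p(sweep(counts, 2L, scale / denom, "*"))
  }
  attr(out, "zero_spots") <- which(totals == 0)
  out
}

#' Score a gene signature per spot
#'
#' \code{plain_mean}: mean log-normalised expression over the signature genes
#' present in the data. \code{control_corrected}: additionally subtracts the
#' mean of a size-matched control set -- for each signature gene, 50 control
#' genes are sampled (seeded) from its expression bin, with all genes binned
#' into 25 bins of average expression.
#'
#' @param log_expr gene x spot matrix of log-normalised expression.
#' @param gene_set character vector of gene symbols.
#' @param mode \code{"plain_mean"} or \code{"control_corrected"}.
#' @param seed seed for the control-gene draw.
#' @param n_bins,n_ctrl binning and control-pool parameters.
#' @return numeric vector, one score per spot.
#' @export
score_signature <- function(log_expr, gene_set,
                            mode = c("plain_mean", "control_corrected"),
                            seed = 1L, n_bins = 25L, n_ctrl = 50L) {
  mode <- match.arg(mode)
  present <- intersect(gene_set, rownames(log_expr))
  if (length(present) == 0L) {
    stop("no signature gene present in the data for set: ",
         paste(utils::head(gene_set, 3L), collapse = ","), "...")
  }
  sig_score <- colMeans(as.matrix(log_expr[present, , drop = FALSE]))
  if (mode == "plain_mean") return(sig_score)

  gene_means <- if (inherits(log_expr, "Matrix")) {
    Matrix::rowMeans(log_expr)
  } else {
    rowMeans(log_expr)
  }
  # rank-based bins of average expression (equal occupancy)
  bins <- cut(rank(gene_means, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  names(bins) <- rownames(log_expr)
  set.seed(seed)
  ctrl <- unlist(lapply(present, function(g) {
    pool <- names(bins)[bins == bins[[g]]]
    pool <- setdiff(pool, g)
    if (length(pool) == 0L) return(character(0))
    pool[sample.int(length(pool), min(n_ctrl, length(pool)))]
  }), use.names = FALSE)
  if (length(ctrl) == 0L) return(sig_score)
  ctrl_score <- colMeans(as.matrix(log_expr[ctrl, , drop = FALSE]))
  sig_score - ctrl_score
}

#' Adaptive per-sample threshold
#'
#' Quantile-with-floor rule on a per-sample vector of values (here the
#' deconvolved T fraction): the threshold is the per-sample linear
#' interpolation quantile, bounded below by \code{floor}. Samples with fewer
#' than 10 spots fall back to the floor with a warning.
#'
#' @param values numeric vector for one sample.
#' @param quantile_p quantile in (0, 1); default 0.80.
#' @param floor lower bound; default 0.05.
#' @return scalar threshold.
#' @export
adaptive_threshold <- function(values, quantile_p = 0.8, floor = 0.05) {
  if (quantile_p <= 0 || quantile_p >= 1) stop("quantile_p must be in (0,1)")
  if (length(values) < 10L) {
    warning("fewer than 10 spots in sample; threshold set to floor")
    return(floor)
  }
  max(unname(quantile(values, quantile_p, type = 7)), floor)
}

#' Call iLTC niches per spot
#'
#' A spot is eligible when its total deconvolved T fraction passes its
#' sample's adaptive threshold (inclusive \code{>=}). Among eligible spots
#' the niche label is the subset with the largest within-sample z-scored
#' signature score, provided that z-score is positive; otherwise
#' \code{"none"}. Ties break by the larger deconvolved fraction of the
#' corresponding subset, then by the fixed order gdT > MAIT > iNKT.
#'
#' @param fractions a \code{fraction_table} from
#'   \code{\link{deconvolve_spots}}.
#' @param subset_scores spot x subset matrix of signature scores, columns
#'   named among \code{c("gdT","MAIT","iNKT")}; subsets without a signature
#'   are skipped with a warning.
#' @param dataset the \code{spot_dataset} (sample/layer/group metadata).
#' @param config an \code{\link{iltc_config}} (gate quantile and floor).
#' @return a \code{niche_call_table} data.frame: barcode, sample, layer,
#'   group, \code{T_fraction}, per-subset scores and z-scores, the sample
#'   threshold and the \code{label}.
#' @export
call_niches <- function(fractions, subset_scores, dataset,
                        config = iltc_config()) {
  stopifnot(inherits(fractions, "fraction_table"),
            inherits(dataset, "spot_dataset"))
  subsets <- c("gdT", "MAIT", "iNKT")
  have <- intersect(subsets, colnames(subset_scores))
  missing <- setdiff(subsets, have)
  if (length(missing) > 0L) {
    warning("no signature score for subset(s): ", paste(missing, collapse = ", "),
            "; skipped")
  }
  if (length(have) == 0L) stop("no scored subset available")
  spots <- dataset$spots
  n <- nrow(spots)
  stopifnot(nrow(subset_scores) == n, nrow(fractions$proportions) == n)

  t_cols <- grep("^T_", fractions$cell_types, value = TRUE)
  if (length(t_cols) == 0L) stop("no T-lineage column (prefix 'T_') in the reference")
  t_fraction <- rowSums(fractions$proportions[, t_cols, drop = FALSE])

  subset_to_type <- c(gdT = "T_gdT", MAIT = "T_MAIT", iNKT = "T_iNKT")

  z <- matrix(NA_real_, n, length(have), dimnames = list(NULL, have))
  thr <- numeric(n)
  for (s in unique(spots$sample)) {
    idx <- which(spots$sample == s)
    thr[idx] <- adaptive_threshold(t_fraction[idx], config$t_gate_quantile,
                                   config$t_gate_floor)
    for (sub in have) {
      v <- subset_scores[idx, sub]
      sdv <- sd(v)
      z[idx, sub] <- if (is.na(sdv) || sdv == 0) 0 else (v - mean(v)) / sdv
    }
  }

  pass <- t_fraction >= thr
  label <- rep("none", n)
  for (i in which(pass)) {
    zi <- z[i, ]
    if (max(zi) <= 0) next
    best <- have[zi == max(zi)]
    if (length(best) > 1L) {
      ty <- subset_to_type[best]
      fr <- ifelse(ty %in% fractions$cell_types,
                   fractions$proportions[i, ty], 0)
      best <- best[fr == max(fr)]
      if (length(best) > 1L) best <- intersect(c("gdT", "MAIT", "iNKT"), best)[1L]
    }
    label[i] <- best
  }

  out <- data.frame(barcode = spots$barcode, sample = spots$sample,
                    layer = spots$layer, group = spots$group,
                    T_fraction = t_fraction, threshold = thr,
                    stringsAsFactors = FALSE)
  for (sub in have) {
    out[[paste0("score_", sub)]] <- subset_scores[, sub]
    out[[paste0("z_", sub)]] <- z[, sub]
  }
  out$label <- label
  class(out) <- c("niche_call_table", "data.frame")
  out
}

#' Per-sample, per-layer niche frequencies
#'
#' Percentages of gdT-, MAIT- and iNKT-labelled spots over all spots of each
#' sample x layer cell, with the sample's group and PASI carried along.
#' Cells with fewer than 20 spots are flagged \code{low_n}; layers with no
#' spots simply produce no row.
#'
#' @param calls a \code{niche_call_table}.
#' @param dataset the matching \code{spot_dataset}.
#' @return a \code{sample_summary} data.frame: sample, group, layer, pasi,
#'   n_spots, pct_gdT, pct_MAIT, pct_iNKT, low_n.
#' @export
niche_frequencies <- function(calls, dataset) {
  stopifnot(inherits(dataset, "spot_dataset"))
  spots <- dataset$spots
  key <- interaction(spots$sample, spots$layer, drop = TRUE)
  rows <- lapply(levels(key), function(kk) {
    idx <- which(key == kk)
    lab <- calls$label[idx]
    n <- length(idx)
    data.frame(sample = spots$sample[idx[1L]],
               group = spots$group[idx[1L]],
               layer = spots$layer[idx[1L]],
               pasi = spots$pasi[idx[1L]],
               n_spots = n,
               pct_gdT = 100 * sum(lab == "gdT") / n,
               pct_MAIT = 100 * sum(lab == "MAIT") / n,
               pct_iNKT = 100 * sum(lab == "iNKT") / n,
               low_n = n < 20L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sample, out$layer), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sample_summary", "data.frame")
  out
}

#' Lesional to non-lesional niche frequency ratios
#'
#' For donors with paired lesional (L) and non-lesional (NL) samples, the
#' ratio of niche percentages per subset per layer. A zero NL percentage is
#' replaced by the pseudo-frequency \code{100 / (n_spots + 1)} and flagged.
#' Unpaired donors are excluded with a message.
#'
#' @param summary_l,summary_nl \code{sample_summary} rows for the lesional
#'   and non-lesional samples; pairing is by the \code{donor} column if
#'   present, else by \code{sample}.
#' @return data.frame: donor, layer, subset, pct_L, pct_NL, ratio,
#'   pseudo_nl flag.
#' @export
lesion_ratio <- function(summary_l, summary_nl) {
  donor_col <- if ("donor" %in% names(summary_l)) "donor" else "sample"
  subsets <- c("gdT", "MAIT", "iNKT")
  rows <- list()
  for (i in seq_len(nrow(summary_l))) {
    d <- summary_l[[donor_col]][i]
    ly <- summary_l$layer[i]
    j <- which(summary_nl[[donor_col]] == d & summary_nl$layer == ly)
    if (length(j) == 0L) {
      message("lesion_ratio: no non-lesional pair for donor ", d, " / ", ly,
              "; excluded")
      next
    }
    j <- j[1L]
    for (sub in subsets) {
      col <- paste0("pct_", sub)
      p_l <- summary_l[[col]][i]
      p_nl <- summary_nl[[col]][j]
      pseudo <- FALSE
      if (p_nl == 0) {
        p_nl <- 100 / (summary_nl$n_spots[j] + 1)
        pseudo <- TRUE
      }
      rows[[length(rows) + 1L]] <- data.frame(
        donor = d, layer = ly, subset = sub, pct_L = p_l, pct_NL = p_nl,
        ratio = p_l / p_nl, pseudo_nl = pseudo, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(donor = character(), layer = character(),
                      subset = character(), pct_L = numeric(),
                      pct_NL = numeric(), ratio = numeric(),
                      pseudo_nl = logical()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
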