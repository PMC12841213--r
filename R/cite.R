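#' Centred log-ratio transform of ADT counts
#'
#' \code{per_cell} (classical compositional definition):
#' \eqn{clr(x)_i = \ln(x_i + 1) - \mathrm{mean}_j \ln(x_j + 1)} over the
#' markers of that cell. \code{per_feature} applies the same formula across
#' the cells of one marker. The +1 pseudo-count accommodates the ubiquitous
#' zeros of ADT data.
#'
#' @param adt cell x marker matrix of non-negative counts.
#' @param margin \code{"per_cell"} (default) or \code{"per_feature"}.
#' @return matrix of the same shape.
#' @export
clr_transform <- function(adt, margin = c("per_cell", "per_feature")) {
  margin <- match.arg(margin)
  adt <- as.matrix(adt)
  if (any(adt < 0)) stop("ADT counts must be non-negative")
  lg <- log1p(adt)
  if (margin == "per_cell") {
    if (ncol(adt) == 1L) warning("single-marker panel: per-cell CLR is all zeros")
    lg - rowMeans(lg)
  } else {
    lg - rep(colMeans(lg), each = nrow(lg))
  }
}

#' Gate specification
#'
#' One row per gate: \code{gate} (name), \code{marker}, \code{method}
#' (\code{"fixed"} CLR cutoff or cohort \code{"quantile"}), \code{value}
#' (the cutoff or the quantile), \code{parent} (name of the parent gate or
#' \code{NA} for a root gate). Thresholds are computed once on the full
#' cohort and applied to every donor.
#'
#' @param gate,marker,method,value,parent vectors of equal length.
#' @return a \code{gate_spec} data.frame.
#' @export
gate_spec <- function(gate, marker, method, value, parent = NA_character_) {
  stopifnot(all(method %in% c("fixed", "quantile")))
  out <- data.frame(gate = gate, marker = marker, method = method,
                    value = value, parent = parent, stringsAsFactors = FALSE)
  class(out) <- c("gate_spec", "data.frame")
  out
}

#' Default iLTC gating strategy
#'
#' CD45 root gate, then one identity gate per subset (two-marker AND for
#' MAIT via a chained parent). The fixed CLR cutoffs sit between the
#' negative and positive marker modes produced by the synthetic ADT
#' generator at its default effect size; they are an editable placeholder,
#' not a calibrated clinical strategy.
#'
#' @return a \code{gate_spec}.
#' @export
default_gate_spec <- function() {
  gate_spec(
    gate   = c("CD45",  "gdT",    "MAIT_a", "MAIT",     "iNKT"),
    marker = c("CD45",  "TCRgd",  "CD161",  "TCRVa7.2", "CD1DTET"),
    method = c("fixed", "fixed",  "fixed",  "fixed",    "fixed"),
    value  = c(0,       0.75,     0.6,      0.6,        0.75),
    parent = c(NA,      "CD45",   "CD45",   "MAIT_a",   "CD45")
  )
}

#' Apply a gating hierarchy to CLR-normalised ADT values
#'
#' A cell is positive for a gate iff its CLR value on the gate's marker
#' exceeds the threshold (strict \code{>}) and it is positive for the
#' parent gate. Quantile thresholds are computed across all cells of the
#' cohort, once, so gating is consistent across donors.
#'
#' @param clr_matrix cell x marker CLR matrix.
#' @param spec a \code{gate_spec}.
#' @return logical cell x gate matrix with per-gate thresholds in the
#'   \code{"thresholds"} attribute.
#' @export
gate_positive <- function(clr_matrix, spec) {
  unknown <- setdiff(spec$marker, colnames(clr_matrix))
  if (length(unknown) > 0L) {
    stop("unknown marker(s) in gate spec: ", paste(unknown, collapse = ", "))
  }
  n <- nrow(clr_matrix)
  res <- matrix(NA, n, nrow(spec), dimnames = list(rownames(clr_matrix),
                                                   spec$gate))
  thresholds <- setNames(numeric(nrow(spec)), spec$gate)
  remaining <- seq_len(nrow(spec))
  while (length(remaining) > 0L) {
    ready <- remaining[vapply(remaining, function(i) {
      is.na(spec$parent[i]) || !anyNA(res[, spec$parent[i]])
    }, logical(1L))]
    if (length(ready) == 0L) stop("cyclic or unresolvable gate parents")
    for (i in ready) {
      v <- clr_matrix[, spec$marker[i]]
      thr <- if (spec$method[i] == "fixed") spec$value[i] else {
        unname(quantile(v, spec$value[i], type = 7))
      }
      pos <- v > thr
      if (!is.na(spec$parent[i])) pos <- pos & res[, spec$parent[i]]
      res[, spec$gate[i]] <- pos
      thresholds[spec$gate[i]] <- thr
    }
    remaining <- setdiff(remaining, ready)
  }
  attr(res, "thresholds") <- thresholds
  res
}

#' Per-donor subset frequencies and marker positivity
#'
#' Subset frequency is the percentage of subset-positive cells among
#' CD45-positive cells of the donor; phenotype-marker positivity is
#' computed within each subset. Donors with fewer than 50 CD45+ cells are
#' flagged; subsets with zero cells report \code{NA} marker positivity
#' with a flag.
#'
#' @param gates logical cell x gate matrix from \code{\link{gate_positive}}.
#' @param donors character/factor of donor ids per cell.
#' @param subset_gates names of the subset gates (default
#'   \code{c("gdT","MAIT","iNKT")}).
#' @param root name of the root gate (default \code{"CD45"}).
#' @param phenotype optional list: subset -> logical cell vector(s) or
#'   cell x marker logical matrix of phenotype positivity to summarise
#'   within subsets.
#' @return data.frame: donor, n_root, one \code{pct_*} column per subset,
#'   low_n flag.
#' @export
subset_frequencies <- function(gates, donors,
                               subset_gates = c("gdT", "MAIT", "iNKT"),
                               root = "CD45", phenotype = NULL) {
  subset_gates <- intersect(subset_gates, colnames(gates))
  donors <- as.character(donors)
  rows <- lapply(unique(donors), function(d) {
    idx <- donors == d
    n_root <- sum(gates[idx, root])
    row <- data.frame(donor = d, n_root = n_root, low_n = n_root < 50L,
                      stringsAsFactors = FALSE)
    for (sg in subset_gates) {
      row[[paste0("pct_", sg)]] <-
        if (n_root > 0) 100 * sum(gates[idx, sg]) / n_root else NA_real_
    }
    if (!is.null(phenotype)) {
      for (sg in subset_gates) {
        in_sub <- idx & gates[, sg]
        ph <- as.matrix(phenotype)
        for (pm in colnames(ph)) {
          row[[paste0("pct_", pm, "_in_", sg)]] <-
            if (sum(in_sub) > 0) 100 * sum(ph[in_sub, pm]) / sum(in_sub)
            else NA_real_
        }
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' RNA-protein concordance per subset
#'
#' Spearman correlation (same estimator as
#' \code{\link{severity_correlation}}) between per-donor mean RNA gene-set
#' scores and ADT-defined subset frequencies.
#'
#' @param gene_set_scores per-donor numeric vector (mean RNA signature score
#'   among CD45+ cells), named by donor or aligned with
#'   \code{adt_frequencies}.
#' @param adt_frequencies per-donor subset frequency vector.
#' @return list as from \code{\link{severity_correlation}}.
#' @export
rna_protein_concordance <- function(gene_set_scores, adt_frequencies) {
  severity_correlation(gene_set_scores, adt_frequencies)
}
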