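#' Wilcoxon rank-sum differential expression
#'
#' Per-gene two-sided Wilcoxon rank-sum test between two spot groups on
#' log-normalised expression, with Benjamini-Hochberg adjustment over all
#' tested genes. The fold change is the difference of group means of
#' log-normalised expression (the usual single-cell convention). Exact
#' enumeration is used when the combined group size is below 20; otherwise
#' the normal approximation with continuity and tie correction.
#'
#' @param log_expr gene x spot matrix of log-normalised expression.
#' @param groups factor/character of length \code{ncol(log_expr)} with
#'   exactly two levels; the first level (alphabetical, or factor order) is
#'   group a.
#' @return data.frame: gene, log_fc (mean_a - mean_b), p, p_adj, pct_a,
#'   pct_b. Genes expressed in neither group are skipped and recorded in the
#'   \code{"skipped"} attribute.
#' @export
wilcoxon_de <- function(log_expr, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  if (any(table(groups) < 3L)) stop("each group needs >= 3 spots")
  a <- which(groups == levels(groups)[1L])
  b <- which(groups == levels(groups)[2L])
  x <- as.matrix(log_expr)
  expressed <- rowSums(x[, c(a, b), drop = FALSE] > 0) > 0
  skipped <- rownames(x)[!expressed]
  x <- x[expressed, , drop = FALSE]
  exact <- (length(a) + length(b)) < 20L
  res <- apply(x, 1L, function(v) {
    p <- suppressWarnings(
      wilcox.test(v[a], v[b], exact = exact, correct = TRUE)$p.value)
    c(log_fc = mean(v[a]) - mean(v[b]), p = p,
      pct_a = mean(v[a] > 0), pct_b = mean(v[b] > 0))
  })
  out <- data.frame(gene = rownames(x), t(res), row.names = NULL,
                    stringsAsFactors = FALSE)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out <- out[, c("gene", "log_fc", "p", "p_adj", "pct_a", "pct_b")]
  attr(out, "skipped") <- skipped
  out
}

#' Filter differential expression records
#'
#' Keeps genes with \code{|log_fc| >= lfc_min} (inclusive: "at least") and
#' \code{p_adj < alpha} (strict: "below"), and marks direction.
#'
#' @param records output of \code{\link{wilcoxon_de}}.
#' @param lfc_min fold-change cutoff (default 0.25).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return the filtered data.frame with a \code{direction} column
#'   (\code{"up"}/\code{"down"} relative to group a).
#' @export
filter_de <- function(records, lfc_min = 0.25, alpha = 0.05) {
  keep <- abs(records$log_fc) >= lfc_min & records$p_adj < alpha
  out <- records[keep, , drop = FALSE]
  out$direction <- ifelse(out$log_fc >= 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Hypergeometric gene-set over-representation
#'
#' Upper-tail hypergeometric p for the observed overlap between a query gene
#' list and each signature set, within a stated gene universe; BH adjustment
#' across sets. Sets are intersected with the universe first; GeneRatio is
#' overlap / query size.
#'
#' @param query_genes character vector (must be a subset of the universe).
#' @param signature_sets named list of character vectors (e.g. from
#'   \code{\link{read_gmt}}).
#' @param universe character vector of all considered genes (commonly all
#'   genes tested for differential expression).
#' @return data.frame: set, overlap, set_size, query_size, universe_size,
#'   gene_ratio, p, p_adj; ordered by decreasing gene_ratio then increasing
#'   p_adj.
#' @export
hypergeom_enrich <- function(query_genes, signature_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  query <- unique(query_genes)
  if (!all(query %in% universe)) {
    stop("query genes outside the universe: ",
         paste(utils::head(setdiff(query, universe), 3L), collapse = ", "))
  }
  n_u <- length(universe)
  n_q <- length(query)
  rows <- lapply(names(signature_sets), function(nm) {
    set <- intersect(unique(signature_sets[[nm]]), universe)
    k <- length(intersect(set, query))
    kk <- length(set)
    p <- phyper(k - 1, kk, n_u - kk, n_q, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = kk, query_size = n_q,
               universe_size = n_u,
               gene_ratio = if (n_q > 0) k / n_q else 0,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out <- out[order(-out$gene_ratio, out$p_adj), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-sample x layer x niche module-score means
#'
#' Aggregates spot-level module scores to means within each (sample, layer,
#' niche label) cell; cells with fewer than 5 spots are flagged.
#'
#' @param scores named list (or spot x module matrix) of per-spot module
#'   scores.
#' @param calls a \code{niche_call_table}.
#' @param dataset the matching \code{spot_dataset}.
#' @return data.frame: sample, layer, niche, module, mean_score, n_spots,
#'   low_n.
#' @export
module_score_summary <- function(scores, calls, dataset) {
  if (is.list(scores) && !is.data.frame(scores)) {
    scores <- do.call(cbind, scores)
  }
  scores <- as.matrix(scores)
  spots <- dataset$spots
  stopifnot(nrow(scores) == nrow(spots))
  key <- interaction(spots$sample, spots$layer, calls$label, drop = TRUE)
  rows <- list()
  for (kk in levels(key)) {
    idx <- which(key == kk)
    for (mod in colnames(scores)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample = spots$sample[idx[1L]], layer = spots$layer[idx[1L]],
        niche = calls$label[idx[1L]], module = mod,
        mean_score = mean(scores[idx, mod]), n_spots = length(idx),
        low_n = length(idx) < 5L, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Distribution-gated group comparison
#'
#' Each group's distribution is first checked with the Shapiro-Wilk test.
#' Two groups: Student's t when both pass (p >= 0.05), otherwise Wilcoxon
#' rank-sum. More than two: one-way ANOVA with Tukey's post hoc when all
#' pass, otherwise Kruskal-Wallis with pairwise Wilcoxon (BH within the
#' post hoc family). Any group with n < 3 forces the non-parametric branch.
#'
#' @param values numeric vector.
#' @param group_labels grouping of the same length, >= 2 levels.
#' @param alpha_normality Shapiro-Wilk gate level (default 0.05).
#' @return list: \code{test} (\code{"t"}, \code{"wilcoxon"},
#'   \code{"anova_tukey"} or \code{"kruskal_wilcoxon"}), \code{statistic},
#'   \code{p}, \code{normality_p} per group, \code{posthoc} (pairwise table
#'   or NULL), \code{forced_nonparametric}.
#' @export
compare_groups <- function(values, group_labels, alpha_normality = 0.05) {
  g <- as.factor(group_labels)
  if (nlevels(g) < 2L) stop("need >= 2 groups")
  sizes <- table(g)
  forced <- any(sizes < 3L)
  norm_p <- vapply(levels(g), function(lv) {
    v <- values[g == lv]
    if (length(v) < 3L || length(v) > 5000L || sd(v) == 0) return(NA_real_)
    shapiro.test(v)$p.value
  }, numeric(1L))
  all_normal <- !forced && all(!is.na(norm_p)) && all(norm_p >= alpha_normality)
  two <- nlevels(g) == 2L
  if (two) {
    a <- values[g == levels(g)[1L]]; b <- values[g == levels(g)[2L]]
    if (all_normal) {
      ht <- t.test(a, b)
      res <- list(test = "t", statistic = unname(ht$statistic), p = ht$p.value,
                  posthoc = NULL)
    } else {
      ht <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
      p <- if (length(a) == length(b) &&
               isTRUE(all.equal(sort(a), sort(b)))) 1 else ht$p.value
      res <- list(test = "wilcoxon", statistic = unname(ht$statistic), p = p,
                  posthoc = NULL)
    }
  } else {
    if (all_normal) {
      fit <- aov(values ~ g)
      p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
      stat <- summary(fit)[[1L]][["F value"]][1L]
      res <- list(test = "anova_tukey", statistic = stat, p = p,
                  posthoc = TukeyHSD(fit)$g)
    } else {
      ht <- kruskal.test(values, g)
      ph <- suppressWarnings(
        pairwise.wilcox.test(values, g, p.adjust.method = "BH", exact = FALSE))
      res <- list(test = "kruskal_wilcoxon", statistic = unname(ht$statistic),
                  p = ht$p.value, posthoc = ph$p.value)
    }
  }
  res$normality_p <- norm_p
  res$forced_nonparametric <- forced
  res
}
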