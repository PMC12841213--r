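#' Binary k-nearest-neighbour spatial weights
#'
#' Euclidean kNN graph on 2D spot coordinates, symmetrised by union
#' (\eqn{w_{ij} = 1} if either spot is among the other's k nearest), no
#' self-edges. k = 6 matches the hexagonal Visium packing. Distance ties are
#' broken by spot index order, so duplicated coordinates are handled
#' deterministically.
#'
#' @param coords numeric matrix or data.frame with columns x, y.
#' @param k number of neighbours (default 6).
#' @return a \code{spatial_weights} list: sparse symmetric \code{w}
#'   (\code{n x n}), total weight \code{W}, \code{k} and \code{n}.
#' @export
build_spatial_weights <- function(coords, k = 6L) {
  coords <- as.matrix(coords[, c("x", "y")])
  n <- nrow(coords)
  if (n < k + 1L) {
    stop("need at least k+1 = ", k + 1L, " spots for a ", k,
         "-nearest-neighbour graph; reduce k")
  }
  d <- as.matrix(dist(coords))
  diag(d) <- Inf
  ii <- integer(0); jj <- integer(0)
  for (i in seq_len(n)) {
    nb <- order(d[i, ], seq_len(n))[seq_len(k)]   # index order breaks ties
    ii <- c(ii, rep.int(i, k)); jj <- c(jj, nb)
  }
  w <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = 1,
                            dims = c(n, n), use.last.ij = FALSE)
  w@x[w@x > 0] <- 1     # union symmetrisation: any edge counts once
  structure(list(w = w, W = sum(w), k = k, n = n), class = "spatial_weights")
}

#' Moran's I spatial autocorrelation
#'
#' \deqn{I = (N/W) \sum_{ij} w_{ij}(x_i-\bar x)(x_j-\bar x) /
#'       \sum_i (x_i-\bar x)^2}
#' Null expectation is \eqn{-1/(N-1)}. A constant field yields \code{NaN}
#' with flag \code{"constant_field"} rather than an error.
#'
#' @param values numeric vector aligned to the weights' spots.
#' @param weights a \code{spatial_weights}.
#' @return a \code{moran_result} list: \code{I}, \code{expectation},
#'   \code{n}, \code{flag}; \code{p} and \code{n_perm} are \code{NA} (see
#'   \code{\link{morans_permutation}}).
#' @export
morans_i <- function(values, weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  n <- weights$n
  if (length(values) != n) stop("values must align with the weights' spots")
  e_i <- -1 / (n - 1)
  z <- values - mean(values)
  denom <- sum(z^2)
  if (denom == 0) {
    return(structure(list(I = NaN, expectation = e_i, n = n, p = NA_real_,
                          n_perm = NA_integer_, flag = "constant_field"),
                     class = "moran_result"))
  }
  cross <- sum(z * as.numeric(weights$w %*% z))
  structure(list(I = (n / weights$W) * cross / denom, expectation = e_i,
                 n = n, p = NA_real_, n_perm = NA_integer_, flag = "ok"),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat("Moran's I =", signif(x$I, 4), " E[I] =", signif(x$expectation, 4),
      " n =", x$n)
  if (!is.na(x$p)) cat("  p =", signif(x$p, 4), " (", x$n_perm, "permutations )")
  if (x$flag != "ok") cat("  [", x$flag, "]")
  cat("\n")
  invisible(x)
}

#' Permutation test for Moran's I
#'
#' Two-sided p-value from seeded label permutations with the +1/+1
#' correction: \eqn{p = (1 + \#\{|I_{perm} - E[I]| \ge |I_{obs} - E[I]|\})
#' / (n_{perm} + 1)}, guaranteeing \eqn{p \in (0, 1]}.
#'
#' @param values numeric vector aligned to the weights' spots.
#' @param weights a \code{spatial_weights}.
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed.
#' @return a \code{moran_result} with \code{p} and \code{n_perm} filled in.
#' @export
morans_permutation <- function(values, weights, n_perm = 999L, seed = 1L) {
  if (n_perm < 99L) stop("n_perm must be >= 99")
  obs <- morans_i(values, weights)
  if (obs$flag == "constant_field") {
    obs$p <- 1
    obs$n_perm <- as.integer(n_perm)
    return(obs)
  }
  n <- weights$n
  z <- values - mean(values)
  denom <- sum(z^2)
  scale <- n / weights$W
  set.seed(seed)
  Z <- vapply(seq_len(n_perm), function(i) z[sample.int(n)], numeric(n))
  # I for all permutations at once: diag(Z' W Z) via colSums((W Z) * Z)
  i_perm <- scale * Matrix::colSums((weights$w %*% Z) * Z) / denom
  dev_obs <- abs(obs$I - obs$expectation)
  dev_perm <- abs(i_perm - obs$expectation)
  obs$p <- (1 + sum(dev_perm >= dev_obs - 1e-12)) / (n_perm + 1)
  obs$n_perm <- as.integer(n_perm)
  obs$perm_I <- as.numeric(i_perm)
  obs
}

#' gdT-MAIT imbalance index
#'
#' Per lesional sample: the z-scored epidermal MAIT spot percentage minus
#' the z-scored dermal gdT spot percentage. z-scoring (mean 0, sd 1 with the
#' n-1 denominator) is over the lesional samples only, since the index is
#' read against PASI, which exists only for lesional samples.
#'
#' @param summaries a \code{sample_summary} (both layers present for the
#'   lesional samples).
#' @return data.frame: sample, pasi, z_epid_MAIT, z_derm_gdT, index.
#' @export
imbalance_index <- function(summaries) {
  les <- summaries[summaries$group == "L", , drop = FALSE]
  derm <- les[les$layer == "dermis", c("sample", "pasi", "pct_gdT")]
  epid <- les[les$layer == "epidermis", c("sample", "pct_MAIT")]
  m <- merge(derm, epid, by = "sample")
  if (nrow(m) < 3L) {
    stop("imbalance index needs >= 3 lesional samples with both layers; got ",
         nrow(m))
  }
  if (sd(m$pct_gdT) == 0 || sd(m$pct_MAIT) == 0) {
    stop("imbalance index undefined: zero variance in a component")
  }
  z_gd <- (m$pct_gdT - mean(m$pct_gdT)) / sd(m$pct_gdT)
  z_ma <- (m$pct_MAIT - mean(m$pct_MAIT)) / sd(m$pct_MAIT)
  data.frame(sample = m$sample, pasi = m$pasi,
             z_epid_MAIT = z_ma, z_derm_gdT = z_gd,
             index = z_ma - z_gd, stringsAsFactors = FALSE)
}

#' Spearman rank correlation with severity
#'
#' Spearman's rho with average ranks for ties; p from the large-sample t
#' approximation \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2} degrees
#' of freedom. Pairs with missing values are dropped (count reported).
#'
#' @param x numeric feature vector (e.g. a niche percentage per sample).
#' @param pasi paired severity scores.
#' @return list: \code{rho}, \code{p} (NA when n < 4 or rho undefined),
#'   \code{n}, \code{n_dropped}, \code{flag}.
#' @export
severity_correlation <- function(x, pasi) {
  if (length(x) != length(pasi)) stop("x and pasi must be paired")
  ok <- !(is.na(x) | is.na(pasi))
  n_dropped <- sum(!ok)
  x <- x[ok]; pasi <- pasi[ok]
  n <- length(x)
  if (n < 2L || sd(x) == 0 || sd(pasi) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, n_dropped = n_dropped,
                flag = "undefined"))
  }
  rho <- cor(rank(x), rank(pasi))
  if (n < 4L) {
    return(list(rho = rho, p = NA_real_, n = n, n_dropped = n_dropped,
                flag = "n_too_small"))
  }
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n, n_dropped = n_dropped, flag = "ok")
}
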