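#' Non-negative least squares by Lawson-Hanson active set
#'
#' Solves \eqn{\min_x \|A x - y\|_2} subject to \eqn{x \ge 0} with the
#' classical active-set algorithm. Deterministic; exact (to the stated
#' tolerance) for the small column counts of cell-type deconvolution.
#'
#' Degenerate designs are handled explicitly: all-zero columns get a zero
#' coefficient and columns that are exactly proportional to an earlier column
#' (equal after scaling to unit L2 norm) are collapsed before the fit, with
#' the fitted component split equally among the duplicates afterwards. Both
#' situations flag the fit \code{"degenerate"}.
#'
#' @param design gene x cell-type matrix, non-negative, >= 1 column.
#' @param y expression vector, non-negative, length \code{nrow(design)}.
#' @param tol convergence tolerance on the dual/primal checks.
#' @return list with \code{coefficients} (named, length \code{ncol(design)}),
#'   \code{residual_norm} and \code{flag} (\code{"ok"} or \code{"degenerate"}).
#' @export
nnls_fit <- function(design, y, tol = 1e-10) {
  design <- as.matrix(design)
  y <- as.numeric(y)
  if (ncol(design) < 1L) stop("design must have at least one column")
  if (length(y) != nrow(design)) stop("length(y) must equal nrow(design)")
  if (anyNA(design) || anyNA(y)) stop("NaN/NA in NNLS inputs")
  if (any(design < 0) || any(y < 0)) stop("NNLS inputs must be non-negative")

  p_all <- ncol(design)
  cn <- colnames(design)
  flag <- "ok"

  # drop all-zero columns (coefficient pinned at 0)
  norms <- sqrt(colSums(design^2))
  nonzero <- norms > 0
  if (!all(nonzero)) flag <- "degenerate"

  # collapse exact duplicates (proportional columns) among the non-zero ones
  keep_idx <- which(nonzero)
  rep_of <- integer(0)    # representative (index into keep list) per column
  reps <- integer(0)      # representative original column indices
  if (length(keep_idx) > 0L) {
    unit <- design[, keep_idx, drop = FALSE] /
      rep(norms[keep_idx], each = nrow(design))
    key <- apply(unit, 2L, paste, collapse = "\r")
    first <- !duplicated(key)
    reps <- keep_idx[first]
    rep_of <- match(key, key[first])
    if (!all(first)) flag <- "degenerate"
  }

  x <- setNames(numeric(p_all), cn)
  if (length(reps) == 0L) {
    return(list(coefficients = x, residual_norm = sqrt(sum(y^2)), flag = flag))
  }

  A <- design[, reps, drop = FALSE]
  z <- lawson_hanson(A, y, tol)

  # split each fitted component equally among its duplicate group, on the
  # common unit direction, then rescale to each member's own column norm
  for (g in seq_along(reps)) {
    members <- keep_idx[rep_of == g]
    alpha_unit <- z[g] * norms[reps[g]]          # coefficient on unit direction
    x[members] <- alpha_unit / (length(members) * norms[members])
  }
  resid <- y - design %*% x
  list(coefficients = x, residual_norm = sqrt(sum(resid^2)), flag = flag)
}

# Lawson-Hanson active-set NNLS on a design with no zero/duplicate columns.
lawson_hanson <- function(A, y, tol = 1e-10) {
  p <- ncol(A)
  x <- numeric(p)
  passive <- rep(FALSE, p)
  w <- crossprod(A, y - A %*% x)[, 1L]
  iter_max <- 30L * p + 30L
  iter <- 0L
  while (any(!passive) && any(w[!passive] > tol) && iter < iter_max) {
    iter <- iter + 1L
    cand <- which(!passive)
    j <- cand[which.max(w[cand])]
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      z <- numeric(p)
      z[P] <- qr.coef(qr(A[, P, drop = FALSE]), y)
      z[P][is.na(z[P])] <- 0
      if (all(z[P] > tol)) {
        x <- z
        break
      }
      neg <- P[z[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[P][x[P] <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- crossprod(A, y - A %*% x)[, 1L]
  }
  x
}

#' Deconvolve spots against a cell-type reference
#'
#' Per-spot non-negative least squares of depth-normalised expression
#' (counts per 10k, linear scale -- the mixture model is linear in
#' expression, so no log transform is applied) against the reference columns
#' scaled to unit gene-sum. Proportions are the coefficients divided by
#' their sum.
#'
#' UMI count noise is strongly heteroskedastic (negative binomial, variance
#' \eqn{\mu + \phi\mu^2}), so the default fit is iteratively reweighted:
#' a first pass with weights from per-gene mean expression yields fitted
#' spot means, a global overdispersion \eqn{\phi} is moment-estimated from
#' the Pearson residuals, and a second pass weights each gene by the inverse
#' fitted noise standard deviation. \code{weighting = "none"} gives the
#' plain unweighted fit, which is noticeably less accurate on overdispersed
#' counts because high-expression genes (the noisiest in absolute terms)
#' dominate the objective.
#'
#' @param dataset a \code{spot_dataset}.
#' @param ref gene x cell-type reference matrix.
#' @param normalisation \code{"cp10k"} (default) or \code{"none"} (fit raw
#'   counts; proportions are scale-free either way).
#' @param weighting \code{"nb"} (default, IRLS as above) or \code{"none"}.
#' @param min_common_genes minimum size of the reference/dataset gene
#'   intersection.
#' @return a \code{fraction_table}: list with matrices \code{coefficients}
#'   and \code{proportions} (spots x cell types), vector
#'   \code{residual_norm} (unweighted, on the fitted scale), character
#'   \code{flag} per spot (\code{ok}/\code{zero_spot}/\code{degenerate}),
#'   \code{cell_types} and the estimated \code{phi}.
#' @export
deconvolve_spots <- function(dataset, ref, normalisation = c("cp10k", "none"),
                             weighting = c("nb", "none"),
                             min_common_genes = 50L) {
  stopifnot(inherits(dataset, "spot_dataset"))
  normalisation <- match.arg(normalisation)
  weighting <- match.arg(weighting)
  validate_reference(ref)
  common <- intersect(dataset$genes, rownames(ref))
  if (length(common) < min_common_genes) {
    stop("reference/dataset gene intersection has ", length(common),
         " genes; at least ", min_common_genes, " required")
  }
  design <- ref[common, , drop = FALSE]
  design <- sweep(design, 2L, colSums(design), "/")   # unit gene-sum profiles
  counts <- dataset$counts[common, , drop = FALSE]
  totals <- Matrix::colSums(dataset$counts)           # depth over ALL genes
  n_spots <- ncol(counts)
  k <- ncol(design)
  coefs <- matrix(0, n_spots, k, dimnames = list(dataset$spots$barcode,
                                                 colnames(design)))
  props <- coefs
  resid <- numeric(n_spots)
  flag <- rep("ok", n_spots)
  dense <- as.matrix(counts)
  ys <- dense
  if (normalisation == "cp10k") {
    nz <- totals > 0
    ys[, nz] <- sweep(dense[, nz, drop = FALSE], 2L, 1e4 / totals[nz], "*")
  }

  fit_all <- function(w_of_spot) {
    for (i in seq_len(n_spots)) {
      if (totals[i] == 0) {
        flag[i] <<- "zero_spot"
        next
      }
      w <- w_of_spot(i)
      fit <- nnls_fit(design * w, ys[, i] * w)
      coefs[i, ] <<- fit$coefficients
      if (fit$flag != "ok") flag[i] <<- fit$flag
    }
  }

  if (weighting == "none") {
    fit_all(function(i) 1)
  } else {
    mbar <- rowMeans(ys[, totals > 0, drop = FALSE])
    w0 <- 1 / sqrt(mbar + 0.5 * mbar^2 + 0.1)
    fit_all(function(i) w0)
    # fitted spot means on the count scale -> moment estimate of phi
    mix <- sweep(coefs, 1L, pmax(rowSums(coefs), 1e-12), "/")
    mu_counts <- (design %*% t(mix)) * rep(totals, each = nrow(design))
    mu_counts <- as.matrix(mu_counts)
    informative <- mu_counts > 5
    phi <- 0
    if (any(informative)) {
      r2 <- (dense - mu_counts)^2
      phi <- max(0, median(((r2 - mu_counts) / mu_counts^2)[informative]))
    }
    scale_i <- if (normalisation == "cp10k") 1e4 / totals else rep(1, n_spots)
    fit_all(function(i) {
      mu_i <- pmax(mu_counts[, i], 0.1)
      scale_i[i] / sqrt(mu_i + phi * mu_i^2)
    })
  }

  for (i in seq_len(n_spots)) {
    s <- sum(coefs[i, ])
    if (s > 0) props[i, ] <- coefs[i, ] / s
    resid[i] <- sqrt(sum((ys[, i] - design %*% coefs[i, ])^2))
  }
  structure(
    list(coefficients = coefs, proportions = props, residual_norm = resid,
         flag = flag, cell_types = colnames(design),
         phi = if (weighting == "nb") phi else NA_real_),
    class = "fraction_table"
  )
}

#' @export
print.fraction_table <- function(x, ...) {
  cat("fraction_table:", nrow(x$proportions), "spots x",
      length(x$cell_types), "cell types\n")
  cat("  flags: ", paste(names(table(x$flag)), table(x$flag), sep = "=",
                         collapse = ", "), "\n", sep = "")
  cat("  mean proportions:\n")
  print(round(colMeans(x$proportions), 4))
  invisible(x)
}

#' @export
as.data.frame.fraction_table <- function(x, ...) {
  data.frame(barcode = rownames(x$proportions), x$proportions,
             residual = x$residual_norm, flag = x$flag,
             row.names = NULL, check.names = FALSE)
}
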