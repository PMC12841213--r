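# shared fixtures and oracles, built in code

# tiny handmade dataset: 4 genes x 6 spots over two samples
toy_dataset <- function() {
  counts <- matrix(c(5, 0, 1, 2,
                     0, 3, 2, 1,
                     4, 4, 0, 0,
                     1, 1, 1, 1,
                     0, 0, 6, 3,
                     2, 5, 1, 0), nrow = 4,
                   dimnames = list(c("TRDC", "KLRB1", "MT-CO1", "G1"), NULL))
  spots <- data.frame(
    barcode = paste0("bc", 1:6),
    x = c(0, 1, 2, 0, 1, 2), y = c(0, 0, 0, 1, 1, 1),
    layer = c("epidermis", "epidermis", "dermis", "dermis", "dermis", "dermis"),
    sample = rep(c("A", "B"), each = 3),
    group = rep(c("L", "NL"), each = 3),
    pasi = c(12, 12, 12, NA, NA, NA),
    stringsAsFactors = FALSE)
  spot_dataset(counts, spots)
}

# brute-force NNLS oracle: enumerate every active set, solve the
# unconstrained LS on it, keep the best feasible objective. Exact for the
# small column counts it is used with; independent of the package solver.
nnls_oracle_objective <- function(A, y) {
  p <- ncol(A)
  best <- sum(y^2)                       # empty support: x = 0
  for (m in seq_len(2^p - 1)) {
    S <- which(bitwAnd(m, 2^(seq_len(p) - 1)) > 0)
    As <- A[, S, drop = FALSE]
    z <- tryCatch(qr.coef(qr(As), y), error = function(e) NULL)
    if (is.null(z) || anyNA(z)) next
    if (all(z >= -1e-12)) {
      obj <- sum((y - As %*% z)^2)
      if (obj < best) best <- obj
    }
  }
  best
}

# macro-F1 over the classes present in the ground truth
macro_f1 <- function(truth, call) {
  classes <- unique(truth)
  mean(vapply(classes, function(cl) {
    tp <- sum(truth == cl & call == cl)
    fp <- sum(truth != cl & call == cl)
    fn <- sum(truth == cl & call != cl)
    if (tp == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1L)))
}

# square-lattice coordinates for spatial fixtures
grid_coords <- function(n_side) {
  data.frame(x = rep(seq_len(n_side), n_side),
             y = rep(seq_len(n_side), each = n_side))
}
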