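test_that("log-normalisation behaves on edge cases and is depth-invariant", {
  counts <- rbind(G1 = c(0, 10, 4), G2 = c(0, 10, 6))
  ln <- log_normalize(counts, scale = 20)
  expect_equal(ln[, 1], c(G1 = 0, G2 = 0))             # zero-total spot
  expect_equal(attr(ln, "zero_spots"), 1L)
  expect_equal(unname(ln["G1", 2]), log1p(10))         # total equals scale
  # doubling all counts of a spot changes nothing
  ln2 <- log_normalize(cbind(counts[, 2], 2 * counts[, 2]), scale = 20)
  expect_equal(ln2[, 1], ln2[, 2])
  expect_error(log_normalize(rbind(c(-1, 1))), "negative")
})

test_that("signature scores reduce to means and respect the single-gene case", {
  m <- matrix(2.5, nrow = 3, ncol = 4,
              dimnames = list(c("A", "B", "C"), NULL))
  expect_equal(unname(score_signature(m, c("A", "B"))), rep(2.5, 4))
  m2 <- m; m2["B", ] <- c(1, 2, 3, 4)
  expect_equal(unname(score_signature(m2, "B")), c(1, 2, 3, 4))
  expect_error(score_signature(m, c("ZZZ")), "no signature gene")
  # constant data: control-corrected score is exactly 0
  mc <- matrix(1.7, nrow = 60, ncol = 5,
               dimnames = list(paste0("g", 1:60), NULL))
  s <- score_signature(mc, c("g1", "g2"), mode = "control_corrected", seed = 1)
  expect_equal(unname(s), rep(0, 5))
})

test_that("adaptive threshold applies the interpolation quantile with a floor", {
  expect_equal(adaptive_threshold(0:9, quantile_p = 0.8, floor = 0), 7.2)
  expect_equal(adaptive_threshold(seq(0, 0.04, length.out = 20),
                                  quantile_p = 0.8, floor = 0.05), 0.05)
  expect_warning(thr <- adaptive_threshold(1:5, floor = 0.05), "fewer than 10")
  expect_equal(thr, 0.05)
  # identical values above the floor: threshold equals the value, and the
  # inclusive >= gate rule lets every spot pass
  vals <- rep(0.3, 12)
  thr2 <- adaptive_threshold(vals, quantile_p = 0.8, floor = 0.05)
  expect_equal(thr2, 0.3)
  expect_true(all(vals >= thr2))
})

make_call_fixture <- function(t_fracs, scores, sample = "S") {
  n <- length(t_fracs)
  props <- cbind(T_gdT = t_fracs / 3, T_MAIT = t_fracs / 3,
                 T_iNKT = t_fracs / 3, fibroblast = 1 - t_fracs)
  fr <- structure(list(
    coefficients = props, proportions = props,
    residual_norm = rep(0, n), flag = rep("ok", n),
    cell_types = colnames(props), phi = 0), class = "fraction_table")
  spots <- data.frame(barcode = paste0("b", seq_len(n)), x = seq_len(n), y = 1,
                      layer = "dermis", sample = sample, group = "L", pasi = 5,
                      stringsAsFactors = FALSE)
  counts <- matrix(1, 2, n, dimnames = list(c("gA", "gB"), NULL))
  list(fr = fr, ds = spot_dataset(counts, spots))
}

test_that("the T gate takes precedence over any signature score", {
  fx <- make_call_fixture(c(rep(0.9, 11), 0.01),
                          NULL)
  scores <- cbind(gdT = c(rnorm(11), -1), MAIT = c(rnorm(11), 100),
                  iNKT = rnorm(12))
  calls <- call_niches(fx$fr, scores, fx$ds,
                       iltc_config(t_gate_quantile = 0.5, t_gate_floor = 0.05))
  expect_identical(calls$label[12], "none")   # huge MAIT score, below gate
})

test_that("non-positive z-scores yield no call and ties break by fraction then order", {
  fx <- make_call_fixture(rep(0.9, 12), NULL)
  # identical scores per subset -> all z = 0 -> none
  scores0 <- cbind(gdT = rep(1, 12), MAIT = rep(2, 12), iNKT = rep(3, 12))
  calls0 <- call_niches(fx$fr, scores0, fx$ds,
                        iltc_config(t_gate_quantile = 0.5, t_gate_floor = 0))
  expect_true(all(calls0$label == "none"))
  # a spot winning on gdT and MAIT equally resolves by the fixed order when
  # fractions tie as well
  s <- matrix(0, 12, 3, dimnames = list(NULL, c("gdT", "MAIT", "iNKT")))
  noise <- rnorm(11) * 0.1
  s[, "gdT"] <- c(5, noise)       # identical gdT and MAIT columns: exact
  s[, "MAIT"] <- c(5, noise)      # z-score tie at spot 1
  s[, "iNKT"] <- c(0, rnorm(11) * 0.1)
  calls <- call_niches(fx$fr, s, fx$ds,
                       iltc_config(t_gate_quantile = 0.5, t_gate_floor = 0))
  expect_identical(calls$label[1], "gdT")
})

test_that("a missing subset signature is skipped with a warning", {
  fx <- make_call_fixture(rep(0.9, 12), NULL)
  s <- cbind(gdT = rnorm(12), MAIT = rnorm(12))
  expect_warning(calls <- call_niches(fx$fr, s, fx$ds,
                                      iltc_config(t_gate_quantile = 0.5,
                                                  t_gate_floor = 0)),
                 "iNKT")
  expect_false(any(calls$label == "iNKT"))
})

test_that("raising the T-gate quantile never increases any niche frequency", {
  ref <- make_reference(seed = 1)
  sec <- simulate_section(ref, n_spots = 200, seed = 13)
  fr <- deconvolve_spots(sec$dataset, ref)
  log_expr <- log_normalize(sec$dataset$counts)
  sigs <- default_signatures()
  scores <- sapply(c(gdT = "gdT", MAIT = "MAIT", iNKT = "iNKT"),
                   function(nm) score_signature(log_expr, sigs[[nm]]))
  prev <- NULL
  for (q in c(0.5, 0.7, 0.9)) {
    calls <- call_niches(fr, scores, sec$dataset,
                         iltc_config(t_gate_quantile = q))
    freq <- niche_frequencies(calls, sec$dataset)
    tot <- colSums(freq[, c("pct_gdT", "pct_MAIT", "pct_iNKT")] * freq$n_spots)
    if (!is.null(prev)) expect_true(all(tot <= prev + 1e-9))
    prev <- tot
  }
})

test_that("niche frequencies are exact percentages and exchangeable", {
  labels <- rep("none", 100)
  labels[1:7] <- "gdT"
  spots <- data.frame(barcode = paste0("b", 1:100), x = 1:100, y = 1,
                      layer = "dermis", sample = "S", group = "L", pasi = 3,
                      stringsAsFactors = FALSE)
  ds <- spot_dataset(matrix(1, 2, 100,
                            dimnames = list(c("gA", "gB"), NULL)), spots)
  calls <- data.frame(label = labels)
  freq <- niche_frequencies(calls, ds)
  expect_equal(freq$pct_gdT, 7)
  expect_identical(freq$n_spots, 100L)
  # permuting labels among the layer's spots changes nothing
  calls2 <- data.frame(label = sample(labels))
  expect_equal(niche_frequencies(calls2, ds)$pct_gdT, 7)
  # label counts partition the spots
  expect_equal(freq$n_spots,
               sum(labels == "gdT") + sum(labels == "none"))
})

test_that("lesion ratios handle pairing, zeros and pseudo-frequencies", {
  l <- data.frame(sample = "D1", layer = "dermis", n_spots = 100,
                  pct_gdT = 10, pct_MAIT = 10, pct_iNKT = 0)
  nl <- data.frame(sample = "D1", layer = "dermis", n_spots = 99,
                   pct_gdT = 2, pct_MAIT = 10, pct_iNKT = 0)
  rat <- lesion_ratio(l, nl)
  expect_equal(rat$ratio[rat$subset == "gdT"], 5)
  expect_equal(rat$ratio[rat$subset == "MAIT"], 1)
  # pct_NL = 0 with 99 spots -> pseudo-frequency 100/(99+1) = 1, flagged
  ink <- rat[rat$subset == "iNKT", ]
  expect_equal(ink$pct_NL, 1)
  expect_true(ink$pseudo_nl)
  # unpaired donor excluded with a message
  l2 <- rbind(l, data.frame(sample = "D2", layer = "dermis", n_spots = 50,
                            pct_gdT = 5, pct_MAIT = 5, pct_iNKT = 5))
  expect_message(rat2 <- lesion_ratio(l2, nl), "D2")
  expect_false("D2" %in% rat2$donor)
})
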