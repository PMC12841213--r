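test_that("reference construction plants exclusive markers deterministically", {
  ref <- make_reference(n_genes = 300, markers_per_type = 20, marker_fold = 8,
                        seed = 1)
  expect_identical(dim(ref), c(300L, 6L))
  # the first 120 rows are the marker blocks (20 per type, in type order):
  # the owner column sits at marker_fold x the common level of the others
  owner <- apply(ref[1:120, ], 1L, which.max)
  expect_equal(unname(owner), rep(1:6, each = 20L))
  for (i in c(1, 25, 50, 119)) {
    r <- ref[i, ]
    expect_equal(max(r), 8 * min(r))
    expect_equal(length(unique(round(r[-which.max(r)], 12))), 1L)
  }
  # canonical symbols are present and owned by the right lineage
  expect_true(ref["TRDC", "T_gdT"] > max(ref["TRDC", -3]))
  expect_true(ref["KLRB1", "T_MAIT"] > max(ref["KLRB1", -4]))
  # determinism
  expect_identical(ref, make_reference(seed = 1))
  expect_false(identical(ref, make_reference(seed = 2)))
  # infeasible allocation
  expect_error(make_reference(n_genes = 50, markers_per_type = 20), "infeasible")
  # fold = 1: no type distinguishable on marker rows (degenerate control)
  flat <- make_reference(marker_fold = 1, seed = 1)
  expect_true(all(apply(flat[1:120, ], 1L, function(r) max(r) == min(r))))
})

test_that("simulated sections honour geometry, ground truth and determinism", {
  ref <- make_reference(seed = 1)
  sec <- simulate_section(ref, n_spots = 100, epidermal_fraction = 0.3,
                          seed = 5)
  expect_identical(sum(sec$dataset$spots$layer == "epidermis"), 30L)
  # true fractions sum to 1 per spot
  fr <- as.matrix(sec$truth[, colnames(ref)])
  expect_true(all(abs(rowSums(fr) - 1) < 1e-9))
  # labelled niche spots carry the strictly largest matching T-subset fraction
  sub_cols <- c(gdT = "T_gdT", MAIT = "T_MAIT", iNKT = "T_iNKT")
  for (i in which(sec$truth$niche != "none")) {
    own <- fr[i, sub_cols[[sec$truth$niche[i]]]]
    others <- fr[i, setdiff(unname(sub_cols), sub_cols[[sec$truth$niche[i]]])]
    expect_true(all(own > others))
  }
  # empty niche spec -> all background
  sec0 <- simulate_section(ref, n_spots = 60,
                           niche_spec = list(epidermis = c(gdT = 0),
                                             dermis = c(gdT = 0)), seed = 5)
  expect_true(all(sec0$truth$niche == "none"))
  # over-full niche spec rejected
  expect_error(simulate_section(ref, n_spots = 60,
                                niche_spec = list(epidermis = c(gdT = 0.7,
                                                                MAIT = 0.5))),
               "more than 1")
  # determinism
  s1 <- simulate_section(ref, n_spots = 80, seed = 9)
  s2 <- simulate_section(ref, n_spots = 80, seed = 9)
  expect_equal(as.matrix(s1$dataset$counts), as.matrix(s2$dataset$counts))
})

test_that("Poisson-mode counts match the planted spot mean (Monte Carlo)", {
  ref <- make_reference(seed = 1)
  # 200 replicate draws of the same spot; compare gene-wise mean to planted mu
  reps <- lapply(1:200, function(r) {
    simulate_section(ref, n_spots = 1, dispersion = 0,
                     niche_spec = list(epidermis = c(gdT = 0),
                                       dermis = c(gdT = 0)),
                     epidermal_fraction = 0, seed = 4000 + r)
  })
  counts <- sapply(reps, function(s) as.numeric(s$dataset$counts))
  mus <- sapply(reps, function(s) as.numeric(s$expected_mu))
  # gene-wise standardised deviation of summed counts from summed planted
  # means; Poisson variance equals the mean
  z <- rowSums(counts - mus) / sqrt(rowSums(mus))
  expect_gt(mean(abs(z) <= 3), 0.97)
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)) + 0.2)
})

test_that("cohort generator plants exact monotone severity links at zero jitter", {
  link0 <- severity_link(jitter_sd = 0)
  coh <- simulate_cohort(n_hc = 0, n_nl = 0, n_lesional = 12, link = link0,
                         counts = FALSE, seed = 3)
  les <- coh$truth[coh$truth$group == "L", ]
  derm <- les[les$layer == "dermis", ]
  epid <- les[les$layer == "epidermis", ]
  expect_equal(cor(rank(derm$pasi), rank(derm$prop_gdT)), -1)
  expect_equal(cor(rank(epid$pasi), rank(epid$prop_MAIT)), 1)
  # same seed -> identical cohort
  coh2 <- simulate_cohort(n_hc = 0, n_nl = 0, n_lesional = 12, link = link0,
                          counts = FALSE, seed = 3)
  expect_identical(coh$truth, coh2$truth)
})

test_that("CITE-seq generator validates frequencies and plants subset sizes", {
  expect_error(simulate_citeseq(subset_freqs = c(gdT = 0.5, MAIT = 0.2,
                                                 iNKT = 0.1, other = 0.1)),
               "sum to 1")
  none <- simulate_citeseq(n_cells = 500,
                           subset_freqs = c(gdT = 0, MAIT = 0, iNKT = 0,
                                            other = 1), seed = 2)
  expect_identical(sum(none$cells$subset != "other"), 0L)
  sim <- simulate_citeseq(n_cells = 5000, seed = 2)
  n_mait <- sum(sim$cells$subset == "MAIT")
  # multinomial 3 SE band around 200
  expect_lt(abs(n_mait - 200), 3 * sqrt(5000 * 0.04 * 0.96) + 1)
  expect_identical(sim$adt, simulate_citeseq(n_cells = 5000, seed = 2)$adt)
})
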