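#' Synthetic cell-type reference profile
#'
#' Builds a gene x cell-type mean-expression matrix with a shared log-normal
#' baseline and, per cell type, a block of exclusive marker genes elevated
#' \code{marker_fold}-fold over baseline in that type only. The leading
#' markers of each type carry canonical symbols (TRDC/TRGC1/... for gdT,
#' KLRB1/DPP4/... for MAIT, etc.) so the shipped signature sets apply to
#' synthetic data out of the box.
#'
#' @param n_genes total genes (>= types x markers_per_type).
#' @param markers_per_type exclusive markers per cell type.
#' @param marker_fold marker elevation over baseline (> 1; 1 makes the types
#'   indistinguishable and is only useful as a degenerate control).
#' @param seed RNG seed.
#' @param cell_types cell-type names; the defaults cover the skin
#'   deconvolution design (fibroblast, keratinocyte and four T lineages).
#' @return gene x cell-type matrix.
#' @export
make_reference <- function(n_genes = 300L, markers_per_type = 20L,
                           marker_fold = 8, seed = 1L,
                           cell_types = c("fibroblast", "keratinocyte",
                                          "T_gdT", "T_MAIT", "T_iNKT",
                                          "T_conv")) {
  k <- length(cell_types)
  if (n_genes < k * markers_per_type) {
    stop("infeasible marker allocation: need at least ", k * markers_per_type,
         " genes for ", k, " types x ", markers_per_type, " markers")
  }
  if (marker_fold < 1) stop("marker_fold must be >= 1")
  canonical <- list(
    fibroblast = c("COL1A1", "COL1A2", "PDGFRA", "LUM", "DCN"),
    keratinocyte = c("KRT14", "KRT5", "KRT10", "KRT1", "FLG"),
    T_gdT = c("TRDC", "TRGC1", "TRGC2", "KLRD1", "B2M"),
    T_MAIT = c("KLRB1", "DPP4", "CXCR6", "IL7R"),
    T_iNKT = c("ZBTB16", "CD1D", "GZMK", "IL2RB"),
    T_conv = c("CD3D", "CD3E", "CD2", "CD7")
  )
  genes <- character(n_genes)
  idx <- 0L
  marker_rows <- vector("list", k)
  names(marker_rows) <- cell_types
  for (t in cell_types) {
    can <- canonical[[t]]
    if (is.null(can)) can <- character(0)
    can <- can[seq_len(min(length(can), markers_per_type))]
    extra <- markers_per_type - length(can)
    nm <- c(can, if (extra > 0) sprintf("MK_%s_%02d", t, seq_len(extra)))
    marker_rows[[t]] <- idx + seq_len(markers_per_type)
    genes[marker_rows[[t]]] <- nm
    idx <- idx + markers_per_type
  }
  if (idx < n_genes) genes[(idx + 1L):n_genes] <- sprintf("G%04d", seq_len(n_genes - idx))
  set.seed(seed)
  baseline <- rlnorm(n_genes, meanlog = 0, sdlog = 1)
  # mild per-type variation around the shared baseline: real cell types
  # differ genome-wide, not only at their exclusive markers
  m <- matrix(baseline * rlnorm(n_genes * k, meanlog = 0, sdlog = 0.3),
              n_genes, k, dimnames = list(genes, cell_types))
  for (t in cell_types) {
    rows <- marker_rows[[t]]
    m[rows, ] <- baseline[rows]               # markers: exact baseline ...
    m[rows, t] <- baseline[rows] * marker_fold  # ... except fold-up in own type
  }
  m
}

# hexagonal lattice with unit spacing and offset rows (Visium-like)
hex_lattice <- function(n_spots) {
  ncolk <- ceiling(sqrt(n_spots))
  nrowk <- ceiling(n_spots / ncolk)
  rows <- rep(seq_len(nrowk), each = ncolk)[seq_len(n_spots)]
  cols <- rep(seq_len(ncolk), times = nrowk)[seq_len(n_spots)]
  data.frame(x = cols + ifelse(rows %% 2 == 0, 0.5, 0),
             y = rows * sqrt(3) / 2,
             row = rows)
}

#' Simulate one Visium-like tissue section
#'
#' Spots live on a hexagonal lattice split into an epidermal band (top
#' fraction of rows by spot count) and a dermal remainder. Each spot gets a
#' true cell-type fraction vector: background spots are dominated by
#' keratinocytes (epidermis) or fibroblasts (dermis) with a total T fraction
#' of \code{background_t}; planted niche spots carry
#' \code{niche_t_fraction} of their subset. Counts are negative binomial
#' with mean \code{depth} x (mixture of unit-sum reference profiles) and
#' overdispersion \code{dispersion} (0 = Poisson limit).
#'
#' @param ref reference from \code{\link{make_reference}}.
#' @param n_spots number of spots.
#' @param niche_spec named list per layer (\code{epidermis}, \code{dermis})
#'   of planted spot proportions for \code{gdT}, \code{MAIT}, \code{iNKT};
#'   per-layer proportions must sum to <= 1.
#' @param epidermal_fraction fraction of spots in the epidermal band.
#' @param depth expected total counts per spot.
#' @param dispersion negative binomial overdispersion \eqn{\phi} in the
#'   standard UMI parameterisation, variance \eqn{\mu + \phi\mu^2}
#'   (\code{rnbinom} size \eqn{= 1/\phi}); \code{dispersion = 0} draws
#'   Poisson counts.
#' @param niche_t_fraction planted subset fraction in niche spots (0.25).
#' @param background_t total T fraction in background spots (0.05).
#' @param sample_id,group,pasi metadata stamped on every spot.
#' @param seed RNG seed.
#' @return list: \code{dataset} (a \code{spot_dataset}) and \code{truth}
#'   (data.frame of per-spot true fractions and niche label).
#' @export
simulate_section <- function(ref, n_spots = 400L,
                             niche_spec = list(
                               epidermis = c(gdT = 0.05, MAIT = 0.10, iNKT = 0.01),
                               dermis = c(gdT = 0.10, MAIT = 0.03, iNKT = 0.01)),
                             epidermal_fraction = 0.3,
                             depth = 5000, dispersion = 0.5,
                             niche_t_fraction = 0.25, background_t = 0.05,
                             sample_id = "S1", group = "L", pasi = NA_real_,
                             seed = 1L) {
  validate_reference(ref)
  for (ly in names(niche_spec)) {
    if (sum(niche_spec[[ly]]) > 1 + 1e-12) {
      stop("niche proportions for layer ", ly, " sum to more than 1")
    }
  }
  set.seed(seed)
  lat <- hex_lattice(n_spots)
  ord <- order(-lat$y, lat$x)      # top rows first
  n_epi <- round(epidermal_fraction * n_spots)
  layer <- rep("dermis", n_spots)
  layer[ord[seq_len(n_epi)]] <- "epidermis"

  types <- colnames(ref)
  subset_type <- c(gdT = "T_gdT", MAIT = "T_MAIT", iNKT = "T_iNKT")
  niche <- rep("none", n_spots)
  for (ly in c("epidermis", "dermis")) {
    idx <- which(layer == ly)
    spec <- niche_spec[[ly]]
    if (is.null(spec) || length(idx) == 0L) next
    n_each <- round(unlist(spec) * length(idx))
    pool <- sample(idx)
    off <- 0L
    for (sub in names(n_each)) {
      if (n_each[[sub]] == 0L) next
      niche[pool[off + seq_len(n_each[[sub]])]] <- sub
      off <- off + n_each[[sub]]
    }
  }

  fractions <- matrix(0, n_spots, length(types), dimnames = list(NULL, types))
  for (i in seq_len(n_spots)) {
    struct_type <- if (layer[i] == "epidermis") "keratinocyte" else "fibroblast"
    other_type <- setdiff(c("keratinocyte", "fibroblast"), struct_type)
    f <- setNames(numeric(length(types)), types)
    t_total <- if (niche[i] == "none") background_t else background_t + niche_t_fraction
    if (niche[i] != "none") f[subset_type[[niche[i]]]] <- niche_t_fraction
    # split the background T mass: mostly conventional T
    bg_subsets <- setdiff(c("T_gdT", "T_MAIT", "T_iNKT"), subset_type[niche[i]])
    f["T_conv"] <- background_t * 0.7
    f[bg_subsets] <- background_t * 0.3 / 3
    rest <- 1 - sum(f)
    mix <- abs(rnorm(1, 0.8, 0.05)); mix <- min(max(mix, 0.5), 0.95)
    f[struct_type] <- rest * mix
    f[other_type] <- rest * (1 - mix)
    fractions[i, ] <- f / sum(f)
  }

  profiles <- sweep(ref, 2L, colSums(ref), "/")    # unit gene-sum per type
  mu <- depth * (profiles %*% t(fractions))        # gene x spot
  if (dispersion < 0) stop("dispersion must be >= 0")
  counts <- if (dispersion == 0) {
    matrix(rpois(length(mu), as.vector(mu)), nrow(mu), ncol(mu))
  } else {
    matrix(rnbinom(length(mu), size = 1 / dispersion, mu = as.vector(mu)),
           nrow(mu), ncol(mu))
  }
  rownames(counts) <- rownames(ref)
  barcodes <- sprintf("%s_spot%04d", sample_id, seq_len(n_spots))
  colnames(counts) <- barcodes
  spots <- data.frame(barcode = barcodes, x = lat$x, y = lat$y, layer = layer,
                      sample = sample_id, group = group, pasi = pasi,
                      stringsAsFactors = FALSE)
  truth <- data.frame(barcode = barcodes, layer = layer, niche = niche,
                      fractions, stringsAsFactors = FALSE, check.names = FALSE)
  list(dataset = spot_dataset(counts, spots), truth = truth,
       expected_mu = mu)
}

#' Planted severity links
#'
#' Linear links between PASI and per-sample planted niche-spot proportions:
#' dermal gdT decreasing, epidermal MAIT increasing over the PASI range.
#'
#' @param pasi_range PASI range for lesional samples (default 2-30).
#' @param derm_gdT_range planted dermal gdT spot proportion at (low, high)
#'   PASI.
#' @param epid_MAIT_range planted epidermal MAIT spot proportion at
#'   (low, high) PASI.
#' @param jitter_sd Gaussian jitter on the proportion scale.
#' @param background baseline niche proportion used for HC/NL samples and
#'   for the subsets without a link.
#' @return a \code{severity_link} list.
#' @export
severity_link <- function(pasi_range = c(2, 30),
                          derm_gdT_range = c(0.15, 0.03),
                          epid_MAIT_range = c(0.03, 0.20),
                          jitter_sd = 0.02,
                          background = 0.02) {
  structure(list(pasi_range = pasi_range, derm_gdT_range = derm_gdT_range,
                 epid_MAIT_range = epid_MAIT_range, jitter_sd = jitter_sd,
                 background = background),
            class = "severity_link")
}

#' Simulate a cohort with planted severity links
#'
#' Lesional samples draw PASI uniformly over the configured range; their
#' planted dermal gdT and epidermal MAIT spot proportions follow the linear
#' links plus Gaussian jitter (clipped at 0 with a warning if negative).
#' HC and NL samples get background proportions. With \code{counts = TRUE}
#' each sample becomes a full simulated section; with \code{counts = FALSE}
#' only the planted ground truth is returned, which is what
#' calibration-style parameter-recovery studies consume.
#'
#' @param n_hc,n_nl,n_lesional samples per group.
#' @param link a \code{\link{severity_link}}.
#' @param ref reference profile (required when \code{counts = TRUE}).
#' @param spots_per_sample section size when generating counts.
#' @param depth,dispersion passed to \code{\link{simulate_section}}.
#' @param counts generate count-level sections or ground truth only.
#' @param seed top-level seed; per-section child seeds are derived by fixed
#'   offsets.
#' @return list: \code{truth} (per sample x layer planted proportions +
#'   PASI), and when \code{counts = TRUE} a combined \code{dataset} plus
#'   per-spot \code{spot_truth}.
#' @export
simulate_cohort <- function(n_hc = 4L, n_nl = 6L, n_lesional = 12L,
                            link = severity_link(), ref = NULL,
                            spots_per_sample = 300L, depth = 5000,
                            dispersion = 0.5, counts = TRUE, seed = 1L) {
  set.seed(seed)
  groups <- c(rep("HC", n_hc), rep("NL", n_nl), rep("L", n_lesional))
  samples <- sprintf("%s%02d", groups, unlist(lapply(table(groups)[unique(groups)],
                                                     seq_len)))
  samples <- make.unique(samples, sep = "_")
  pasi <- rep(NA_real_, length(groups))
  pasi[groups == "L"] <- runif(n_lesional, link$pasi_range[1], link$pasi_range[2])

  lin <- function(p, rng) {
    t <- (p - link$pasi_range[1]) / diff(link$pasi_range)
    rng[1] + t * (rng[2] - rng[1])
  }
  truth <- list()
  clipped <- FALSE
  for (i in seq_along(samples)) {
    for (ly in c("epidermis", "dermis")) {
      prop <- c(gdT = link$background, MAIT = link$background, iNKT = link$background)
      if (groups[i] == "L") {
        if (ly == "dermis") prop["gdT"] <- lin(pasi[i], link$derm_gdT_range)
        if (ly == "epidermis") prop["MAIT"] <- lin(pasi[i], link$epid_MAIT_range)
      }
      prop <- prop + rnorm(3, 0, link$jitter_sd)
      if (any(prop < 0)) clipped <- TRUE
      prop <- pmax(prop, 0)
      truth[[length(truth) + 1L]] <- data.frame(
        sample = samples[i], group = groups[i], layer = ly, pasi = pasi[i],
        prop_gdT = prop[["gdT"]], prop_MAIT = prop[["MAIT"]],
        prop_iNKT = prop[["iNKT"]], stringsAsFactors = FALSE)
    }
  }
  if (clipped) warning("negative planted proportions clipped at 0")
  truth <- do.call(rbind, truth)

  if (!counts) return(list(truth = truth))
  if (is.null(ref)) ref <- make_reference(seed = seed)
  sections <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    tr <- truth[truth$sample == samples[i], ]
    spec <- lapply(c(epidermis = "epidermis", dermis = "dermis"), function(ly) {
      r <- tr[tr$layer == ly, ]
      c(gdT = r$prop_gdT, MAIT = r$prop_MAIT, iNKT = r$prop_iNKT)
    })
    child_seed <- (seed + 104729L * i) %% 2147483647L
    sections[[i]] <- simulate_section(
      ref, n_spots = spots_per_sample, niche_spec = spec,
      depth = depth, dispersion = dispersion,
      sample_id = samples[i], group = groups[i], pasi = pasi[i],
      seed = child_seed)
  }
  counts_all <- do.call(cbind, lapply(sections, function(s) s$dataset$counts))
  spots_all <- do.call(rbind, lapply(sections, function(s) s$dataset$spots))
  spot_truth <- do.call(rbind, lapply(sections, function(s) s$truth))
  rownames(spots_all) <- rownames(spot_truth) <- NULL
  list(truth = truth, dataset = spot_dataset(counts_all, spots_all),
       spot_truth = spot_truth, ref = ref)
}

#' Simulate a CITE-seq-like cohort
#'
#' Cells are assigned to subsets by multinomial draw from
#' \code{subset_freqs} and to donors uniformly. ADT counts are negative
#' binomial (size 2) around a baseline mean, with each subset's positive
#' markers elevated \code{effect}-fold; CD45 is high for every cell (PBMC
#' convention). Each cell also carries one RNA gene-set score per subset:
#' a noisy indicator of membership whose signal scales with
#' \code{rna_effect}.
#'
#' @param n_cells total cells.
#' @param subset_freqs named frequencies over gdT, MAIT, iNKT, other
#'   (must sum to 1 within 1e-6).
#' @param marker_panel named list: subset -> positive marker(s).
#' @param effect ADT fold elevation on positive markers (1 = chance-level
#'   gating, a degenerate control).
#' @param n_donors donors, split evenly over groups HC/PsO/PsA.
#' @param base_mu baseline ADT mean.
#' @param adt_size negative binomial size for ADT counts. Identity markers
#'   in real CITE-seq panels are strongly bimodal (antibody signal is much
#'   tighter than RNA UMI noise), which is what makes protein gating
#'   meaningful; the default emulates that regime.
#' @param rna_effect RNA score elevation (in SD units) for member cells.
#' @param seed RNG seed.
#' @return list: \code{adt} (cell x marker counts), \code{clr}-ready
#'   metadata \code{cells} (donor, group, true subset), \code{rna_scores}
#'   (cell x subset matrix).
#' @export
simulate_citeseq <- function(n_cells = 5000L,
                             subset_freqs = c(gdT = 0.03, MAIT = 0.04,
                                              iNKT = 0.01, other = 0.92),
                             marker_panel = list(gdT = "TCRgd",
                                                 MAIT = c("CD161", "TCRVa7.2"),
                                                 iNKT = "CD1DTET"),
                             effect = 8, n_donors = 12L, base_mu = 20,
                             adt_size = 8, rna_effect = 3, seed = 1L) {
  if (abs(sum(subset_freqs) - 1) > 1e-6) stop("subset_freqs must sum to 1")
  set.seed(seed)
  subsets <- names(subset_freqs)
  lab <- sample(subsets, n_cells, replace = TRUE, prob = subset_freqs)
  donors <- sprintf("D%02d", sample.int(n_donors, n_cells, replace = TRUE))
  groups <- c("HC", "PsO", "PsA")[((seq_len(n_donors) - 1L) %% 3L) + 1L]
  names(groups) <- sprintf("D%02d", seq_len(n_donors))
  markers <- unique(c("CD45", unlist(marker_panel),
                      "CD27", "OX40", "2B4", "KLRG1", "CCR4", "CXCR6"))
  mu <- matrix(base_mu, n_cells, length(markers),
               dimnames = list(NULL, markers))
  mu[, "CD45"] <- base_mu * 10
  for (sub in setdiff(subsets, "other")) {
    pos <- marker_panel[[sub]]
    if (is.null(pos)) next
    mu[lab == sub, pos] <- base_mu * effect
  }
  adt <- matrix(rnbinom(length(mu), size = adt_size, mu = as.vector(mu)),
                n_cells, length(markers), dimnames = dimnames(mu))
  rownames(adt) <- sprintf("cell%05d", seq_len(n_cells))
  rna <- vapply(setdiff(subsets, "other"), function(sub) {
    rnorm(n_cells) + rna_effect * (lab == sub)
  }, numeric(n_cells))
  list(adt = adt,
       cells = data.frame(cell = rownames(adt), donor = donors,
                          group = unname(groups[donors]), subset = lab,
                          stringsAsFactors = FALSE),
       rna_scores = rna)
}

#' Simulate per-donor RNA-protein concordance pairs
#'
#' Draws per-donor (RNA score, subset frequency) pairs from a bivariate
#' normal with the planted correlation; frequencies are mapped to a
#' positive percentage scale. Used to calibrate
#' \code{\link{rna_protein_concordance}} recovery.
#'
#' @param n_donors number of donors.
#' @param rho planted correlation.
#' @param seed RNG seed.
#' @return data.frame: donor, rna_score, frequency.
#' @export
simulate_donor_concordance <- function(n_donors = 12L, rho = 0.9, seed = 1L) {
  set.seed(seed)
  z1 <- rnorm(n_donors)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n_donors)
  data.frame(donor = sprintf("D%02d", seq_len(n_donors)),
             rna_score = z1,
             frequency = 4 + 1.5 * z2,   # percent scale around 4%
             stringsAsFactors = FALSE)
}
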