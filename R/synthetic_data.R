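# Synthetic-data generators with planted ground truth. These emulate the
# statistical structure the analysis assumes -- negative-binomial UMI counts
# per cell type, reporter-status-conditioned transgene emission, doublets as
# exact sums of two singlet profiles, planted low-complexity cells,
# AFOG-like trichrome wound images and Mef2/PCNA nuclei tables -- so every
# pipeline stage can be exercised against known truth.

#' Transgene emission rates conditioned on reporter status
#'
#' Builds the per-feature Poisson rates used when emitting transgene UMIs.
#' Each transgene sequence content is owned by one reporter channel
#' (mCherry contents by the mChr status, all seven Citrine contents by the
#' Cit status); a cell's true status for that channel selects the positive
#' or negative rate. The endogenous driver genes (kdrl, runx1) are emitted
#' the same way, overriding their background expression.
#'
#' @param positive_rate,negative_rate Poisson rate per transgene feature for
#'   reporter-positive / -negative cells.
#' @param driver_positive_rate,driver_negative_rate rates for the kdrl and
#'   runx1 driver genes.
#' @param map a \code{\link{reporter_feature_map}} providing feature names.
#' @return A list with named rate vectors \code{positive}, \code{negative}
#'   (over the ten transgene features) and \code{driver_positive},
#'   \code{driver_negative} (over the two driver genes).
#' @export
transgene_emission <- function(positive_rate = 4, negative_rate = 0,
                               driver_positive_rate = 3,
                               driver_negative_rate = 0,
                               map = reporter_feature_map()) {
  tg <- transgene_feature_names(map)
  drv <- c(map$kdrl_gene, map$runx1_gene)
  stop_if_not(positive_rate >= 0 && negative_rate >= 0 &&
                driver_positive_rate >= 0 && driver_negative_rate >= 0,
              "emission rates must be >= 0")
  list(positive = setNames(rep(positive_rate, length(tg)), tg),
       negative = setNames(rep(negative_rate, length(tg)), tg),
       driver_positive = setNames(rep(driver_positive_rate, 2), drv),
       driver_negative = setNames(rep(driver_negative_rate, 2), drv),
       map = map)
}

#' Describe one simulated cell type
#'
#' @param name cell-type name.
#' @param n_cells default number of cells per sample (overridable per sample
#'   in \code{\link{sim_count_config}}).
#' @param mean per-gene negative-binomial mean vector (length = n_genes of
#'   the config). All entries must be >= 0.
#' @param dispersion NB dispersion phi (variance = mu + phi * mu^2).
#' @param reporters logical vector with entries \code{mChr}, \code{Cit},
#'   \code{kdrl}, \code{runx1}: the type's true reporter status.
#' @return A list describing the type.
#' @export
sim_cell_type <- function(name, n_cells, mean, dispersion = 0.3,
                          reporters = c(mChr = FALSE, Cit = FALSE,
                                        kdrl = FALSE, runx1 = FALSE)) {
  stop_if_not(is_count_scalar(n_cells), "n_cells must be a count")
  stop_if_not(all(mean >= 0), "NB means must be >= 0")
  stop_if_not(dispersion >= 0, "dispersion must be >= 0")
  reporters <- reporters[c("mChr", "Cit", "kdrl", "runx1")]
  stop_if_not(!anyNA(reporters), "reporters must name mChr, Cit, kdrl, runx1")
  list(name = name, n_cells = n_cells, mean = as.numeric(mean),
       dispersion = dispersion, reporters = as.logical(reporters))
}

#' Configuration for the synthetic count-matrix generator
#'
#' @param n_genes number of gene features (>= 100 unless
#'   \code{singlet_min_features} is lowered); the kdrl and runx1 driver
#'   genes and the mitochondrial genes are drawn from this pool, and the ten
#'   transgene features are appended on top.
#' @param cell_types list of \code{\link{sim_cell_type}} descriptions.
#' @param emission a \code{\link{transgene_emission}} rate set.
#' @param doublet_fraction,lowq_fraction fractions in [0,1) of the emitted
#'   barcodes that are planted doublets / low-complexity cells.
#' @param mito_gene_fraction fraction of genes labelled mitochondrial; their
#'   names get the \code{mito_prefix}.
#' @param mito_prefix mitochondrial gene-name prefix (default \code{"mt-"}).
#' @param samples either a character vector of sample names (all samples use
#'   each type's default \code{n_cells}) or a named list mapping sample name
#'   to a named numeric vector of per-type cell counts (types omitted from
#'   an override keep their default; set 0 to drop a population).
#' @param emission_mode \code{"poisson"} (default) or
#'   \code{"deterministic"}: deterministic emission gives every
#'   reporter-positive cell exactly \code{max(1, round(rate))} UMIs per
#'   owned feature and every negative cell exactly \code{round(negative
#'   rate)}, making gate calls coincide with planted truth.
#' @param singlet_min_features planted lower bound on expressed features for
#'   ordinary singlets (default 100); low-complexity cells are planted
#'   strictly below it by construction.
#' @param seed integer RNG seed.
#' @return A validated \code{sim_count_config} list.
#' @export
sim_count_config <- function(n_genes, cell_types, emission = transgene_emission(),
                             doublet_fraction = 0.05, lowq_fraction = 0.025,
                             mito_gene_fraction = 0.05, mito_prefix = "mt-",
                             samples = "sample1",
                             emission_mode = c("poisson", "deterministic"),
                             singlet_min_features = 100, seed = 1) {
  emission_mode <- match.arg(emission_mode)
  stop_if_not(is_count_scalar(n_genes) && n_genes >= 3,
              "n_genes must be a count >= 3")
  stop_if_not(n_genes >= singlet_min_features,
              "n_genes must be >= singlet_min_features")
  stop_if_not(is_fraction(doublet_fraction), "doublet_fraction not in [0,1)")
  stop_if_not(is_fraction(lowq_fraction), "lowq_fraction not in [0,1)")
  stop_if_not(is_fraction(mito_gene_fraction),
              "mito_gene_fraction not in [0,1)")
  stop_if_not(length(cell_types) >= 1, "need at least one cell type")
  for (ct in cell_types) {
    stop_if_not(length(ct$mean) == n_genes,
                "mean vector of type '%s' has length %d, expected %d",
                ct$name, length(ct$mean), n_genes)
  }
  type_names <- vapply(cell_types, `[[`, character(1), "name")
  stop_if_not(!anyDuplicated(type_names), "duplicate cell type names")
  names(cell_types) <- type_names
  if (is.character(samples)) {
    samples <- setNames(vector("list", length(samples)), samples)
  }
  stop_if_not(length(samples) >= 1 && !is.null(names(samples)) &&
                !anyDuplicated(names(samples)), "samples must be uniquely named")
  for (s in names(samples)) {
    ov <- samples[[s]]
    if (!is.null(ov)) {
      stop_if_not(all(names(ov) %in% type_names),
                  "sample '%s' overrides unknown cell type", s)
      stop_if_not(all(ov >= 0 & ov == floor(ov)),
                  "cell counts must be non-negative integers")
    }
  }
  structure(list(n_genes = n_genes, cell_types = cell_types,
                 emission = emission, doublet_fraction = doublet_fraction,
                 lowq_fraction = lowq_fraction,
                 mito_gene_fraction = mito_gene_fraction,
                 mito_prefix = mito_prefix, samples = samples,
                 emission_mode = emission_mode,
                 singlet_min_features = singlet_min_features,
                 seed = as.integer(seed)),
            class = "sim_count_config")
}

# Per-type cell counts for one sample, after overrides.
sample_composition <- function(config, sample) {
  stop_if_not(sample %in% names(config$samples),
              "unknown sample name '%s'", sample)
  n <- vapply(config$cell_types, `[[`, numeric(1), "n_cells")
  ov <- config$samples[[sample]]
  if (!is.null(ov)) n[names(ov)] <- ov
  n
}

# Feature table of a config: genes first (drivers, then mito, then the
# rest), transgene features last.
sim_feature_table <- function(config) {
  map <- config$emission$map
  n_mito <- round(config$mito_gene_fraction * config$n_genes)
  n_plain <- config$n_genes - 2L - n_mito
  stop_if_not(n_plain >= 0, "too many mito genes for n_genes")
  gene_names <- c(map$kdrl_gene, map$runx1_gene,
                  if (n_mito > 0) paste0(config$mito_prefix,
                                         sprintf("gene%03d", seq_len(n_mito))),
                  sprintf("gene%05d", seq_len(n_plain)))
  cls <- c("gene", "gene", rep("mito", n_mito), rep("gene", n_plain))
  tg <- transgene_feature_names(map)
  data.frame(name = c(gene_names, tg),
             class = c(cls, rep("transgene", length(tg))),
             stringsAsFactors = FALSE)
}

# Draw an n_cells x n_genes NB count matrix for one cell type.
draw_nb_counts <- function(n_cells, mu, dispersion) {
  n_genes <- length(mu)
  if (dispersion <= 0) {
    m <- matrix(rpois(n_cells * n_genes, rep(mu, each = n_cells)),
                nrow = n_cells)
  } else {
    m <- matrix(rnbinom(n_cells * n_genes, mu = rep(mu, each = n_cells),
                        size = 1 / dispersion), nrow = n_cells)
  }
  m
}

# Emit transgene + driver counts for a block of cells sharing one reporter
# status, writing into `mat` (dense, cells x features of the full table).
emit_reporters <- function(mat, rows, reporters, config) {
  em <- config$emission
  map <- em$map
  owner <- c(setNames(rep("mChr", length(map$mcherry_features)),
                      map$mcherry_features),
             setNames(rep("Cit", 7), c(map$citrine_positive_features,
                                       map$citrine_other_features)))
  feats <- c(names(owner), map$kdrl_gene, map$runx1_gene)
  stat <- c(unname(reporters[owner]), reporters[["kdrl"]],
            reporters[["runx1"]])
  rate_pos <- c(em$positive[names(owner)],
                em$driver_positive[c(map$kdrl_gene, map$runx1_gene)])
  rate_neg <- c(em$negative[names(owner)],
                em$driver_negative[c(map$kdrl_gene, map$runx1_gene)])
  rate <- ifelse(stat, rate_pos, rate_neg)
  n <- length(rows)
  for (j in seq_along(feats)) {
    if (config$emission_mode == "deterministic") {
      val <- if (stat[j]) max(1, round(rate[j])) else round(rate_neg[j])
      mat[rows, feats[j]] <- val
    } else {
      mat[rows, feats[j]] <- rpois(n, rate[j])
    }
  }
  mat
}

#' Simulate one sample's count matrix with ground truth
#'
#' Generates ordinary singlets per cell type from the configured negative
#' binomials, plants low-complexity cells (strictly fewer expressed features
#' than \code{singlet_min_features}, by construction) and doublets (exact
#' element-wise sums of two sampled singlet profiles, both parents
#' recorded), emits transgene and driver-gene UMIs conditioned on each
#' cell's true reporter status, and shuffles barcode order. Ordinary
#' singlets are guaranteed at least \code{singlet_min_features} expressed
#' features (deficient draws are topped up with single UMIs in unexpressed
#' genes). Deterministic under a fixed config seed.
#'
#' The planted fractions are of the emitted barcode total: with singlet
#' counts summing to S, the generator emits round(f * S / (1 - f_d - f_l))
#' doublets and low-quality cells respectively.
#'
#' @param config a \code{\link{sim_count_config}}.
#' @param sample one of the config's sample names.
#' @return A list with \code{matrix} (a \code{\link{count_matrix}}) and
#'   \code{truth}, a data.frame with one row per emitted barcode: planted
#'   \code{cell_type}, true reporter status (\code{mChr}, \code{Cit},
#'   \code{kdrl}, \code{runx1}), \code{is_doublet}, \code{is_lowq},
#'   \code{sample}, and for doublets the two \code{parent_types} and
#'   \code{parent_barcodes} (pipe-separated).
#' @export
simulate_sample <- function(config, sample) {
  stopifnot(inherits(config, "sim_count_config"))
  comp <- sample_composition(config, sample)
  comp <- comp[comp > 0]
  stop_if_not(sum(comp) > 0, "zero cells requested for sample '%s'", sample)
  si <- match(sample, names(config$samples))
  with_seed(child_seed(config$seed, si), {
    n_sing <- sum(comp)
    denom <- 1 - config$doublet_fraction - config$lowq_fraction
    total <- n_sing / denom
    n_doub <- round(config$doublet_fraction * total)
    n_lowq <- round(config$lowq_fraction * total)
    feat <- sim_feature_table(config)
    n_feat <- nrow(feat)
    gene_cols <- seq_len(config$n_genes)

    n_all_sing <- n_sing + n_lowq
    mat <- matrix(0, nrow = n_all_sing + n_doub, ncol = n_feat,
                  dimnames = list(NULL, feat$name))
    type_of <- character(n_all_sing + n_doub)
    is_lowq <- logical(n_all_sing + n_doub)
    is_doub <- logical(n_all_sing + n_doub)
    rep_truth <- matrix(FALSE, n_all_sing + n_doub, 4,
                        dimnames = list(NULL, c("mChr", "Cit", "kdrl",
                                                "runx1")))
    # ordinary singlets
    row0 <- 0L
    for (tn in names(comp)) {
      ct <- config$cell_types[[tn]]
      rows <- row0 + seq_len(comp[[tn]])
      gm <- draw_nb_counts(comp[[tn]], ct$mean, ct$dispersion)
      # enforce the planted complexity floor
      deficit <- config$singlet_min_features - rowSums(gm > 0)
      for (i in which(deficit > 0)) {
        zero <- which(gm[i, ] == 0)
        gm[i, sample(zero, deficit[i])] <- 1
      }
      mat[rows, gene_cols] <- gm
      type_of[rows] <- tn
      rep_truth[rows, ] <- matrix(ct$reporters, comp[[tn]], 4, byrow = TRUE)
      row0 <- row0 + comp[[tn]]
    }
    # planted low-complexity cells: small multinomial libraries
    if (n_lowq > 0) {
      lq_types <- sample(names(comp), n_lowq, replace = TRUE,
                         prob = comp / sum(comp))
      for (i in seq_len(n_lowq)) {
        ct <- config$cell_types[[lq_types[i]]]
        lib <- sample(30:min(80, config$singlet_min_features - 20), 1)
        pr <- ct$mean
        if (sum(pr) == 0) pr <- rep(1, length(pr))
        draw <- tabulate(sample.int(config$n_genes, lib, replace = TRUE,
                                    prob = pr), nbins = config$n_genes)
        mat[row0 + i, gene_cols] <- draw
        type_of[row0 + i] <- lq_types[i]
        rep_truth[row0 + i, ] <- ct$reporters
      }
      is_lowq[row0 + seq_len(n_lowq)] <- TRUE
      row0 <- row0 + n_lowq
    }
    # reporter emission on every singlet (before doublet summation, so a
    # doublet is the exact sum of its recorded parents)
    for (tn in names(comp)) {
      ct <- config$cell_types[[tn]]
      rows <- which(type_of == tn & !is_doub)
      names(ct$reporters) <- c("mChr", "Cit", "kdrl", "runx1")
      mat <- emit_reporters(mat, rows, ct$reporters, config)
    }
    barcodes <- sprintf("%s_cell%05d", sample, seq_len(n_all_sing + n_doub))
    parent_types <- rep(NA_character_, n_all_sing + n_doub)
    parent_barcodes <- rep(NA_character_, n_all_sing + n_doub)
    # doublets: exact sums of two distinct ordinary-singlet profiles
    if (n_doub > 0) {
      ord <- which(!is_lowq & seq_len(n_all_sing + n_doub) <= n_all_sing)
      for (i in seq_len(n_doub)) {
        pr <- sample(ord, 2)
        r <- n_all_sing + i
        mat[r, ] <- mat[pr[1], ] + mat[pr[2], ]
        is_doub[r] <- TRUE
        type_of[r] <- "doublet"
        rep_truth[r, ] <- rep_truth[pr[1], ] | rep_truth[pr[2], ]
        parent_types[r] <- paste(sort(type_of[pr]), collapse = "|")
        parent_barcodes[r] <- paste(barcodes[pr], collapse = "|")
      }
    }
    ord <- sample(nrow(mat))
    truth <- data.frame(barcode = barcodes, sample = sample,
                        cell_type = type_of, is_doublet = is_doub,
                        is_lowq = is_lowq, mChr = rep_truth[, "mChr"],
                        Cit = rep_truth[, "Cit"], kdrl = rep_truth[, "kdrl"],
                        runx1 = rep_truth[, "runx1"],
                        parent_types = parent_types,
                        parent_barcodes = parent_barcodes,
                        stringsAsFactors = FALSE)[ord, ]
    rownames(truth) <- NULL
    cm <- count_matrix(mat[ord, , drop = FALSE], barcodes[ord], feat, sample)
    list(matrix = cm, truth = truth)
  })
}

#' Simulate every sample of a config and combine them
#'
#' @param config a \code{\link{sim_count_config}}.
#' @return A list with \code{matrix} (all samples row-bound) and
#'   \code{truth} (row-bound ground truth).
#' @export
simulate_dataset <- function(config) {
  out <- lapply(names(config$samples), function(s) simulate_sample(config, s))
  list(matrix = cm_bind(lapply(out, `[[`, "matrix")),
       truth = do.call(rbind, lapply(out, `[[`, "truth")))
}

#' Combine count matrices over a shared feature space
#'
#' @param matrices list of \code{count_matrix} objects with identical
#'   feature tables.
#' @return A single row-bound \code{count_matrix}.
#' @export
cm_bind <- function(matrices) {
  stop_if_not(length(matrices) >= 1, "nothing to bind")
  f1 <- matrices[[1]]$features
  for (m in matrices[-1]) {
    stop_if_not(identical(m$features$name, f1$name),
                "feature tables differ; cannot bind")
  }
  count_matrix(do.call(rbind, lapply(matrices, `[[`, "counts")),
               unlist(lapply(matrices, `[[`, "barcodes")), f1,
               unlist(lapply(matrices, `[[`, "samples")))
}

#' Study-like default configuration
#'
#' A three-sample design mirroring a cryoinjury time-course with a mutant
#' arm: an uninjured wild-type sample, an injured (3 days post cryoinjury)
#' wild-type sample, and an injured mutant sample. Endocardial cells carry
#' the kdrl-driven mCherry reporter; thrombocytes and myofibroblasts carry
#' the runx1-driven Citrine reporter; an injury-specific endocardial
#' population (both reporters) appears only in injured samples; the mutant
#' sample is depleted of thrombocytes and myofibroblasts. Per-sample totals
#' default to the post-QC scale of a typical 10x run (roughly 4,700-6,100
#' cells); \code{cells_scale} shrinks every population proportionally for
#' quick demonstrations.
#'
#' @param n_genes number of gene features.
#' @param cells_scale multiplier applied to every population size.
#' @param seed integer seed (drives both profile construction and counts).
#' @param ... passed on to \code{\link{sim_count_config}} (e.g.
#'   \code{emission_mode}, \code{doublet_fraction}).
#' @return A \code{\link{sim_count_config}}.
#' @export
sim_study_config <- function(n_genes = 1200, cells_scale = 1, seed = 1, ...) {
  types <- c("cardiomyocyte", "endocardium", "endocardium_injury",
             "epicardium", "immune", "thrombocyte", "myofibroblast")
  profiles <- sim_mean_profiles(n_genes, types,
                                seed = child_seed(seed, 999))
  rep_of <- list(
    cardiomyocyte = c(mChr = FALSE, Cit = FALSE, kdrl = FALSE, runx1 = FALSE),
    endocardium = c(mChr = TRUE, Cit = FALSE, kdrl = TRUE, runx1 = FALSE),
    endocardium_injury = c(mChr = TRUE, Cit = TRUE, kdrl = TRUE, runx1 = TRUE),
    epicardium = c(mChr = FALSE, Cit = FALSE, kdrl = FALSE, runx1 = FALSE),
    immune = c(mChr = FALSE, Cit = FALSE, kdrl = FALSE, runx1 = FALSE),
    thrombocyte = c(mChr = FALSE, Cit = TRUE, kdrl = FALSE, runx1 = TRUE),
    myofibroblast = c(mChr = FALSE, Cit = TRUE, kdrl = FALSE, runx1 = TRUE))
  base_n <- c(cardiomyocyte = 300, endocardium = 2200,
              endocardium_injury = 0, epicardium = 700, immune = 700,
              thrombocyte = 800, myofibroblast = 0)
  cell_types <- lapply(types, function(tn) {
    sim_cell_type(tn, round(base_n[[tn]] * cells_scale), profiles[[tn]],
                  dispersion = 0.3, reporters = rep_of[[tn]])
  })
  sc <- function(x) round(x * cells_scale)
  samples <- list(
    wt_uninjured = NULL,
    wt_3dpci = c(cardiomyocyte = sc(250), endocardium = sc(1500),
                 endocardium_injury = sc(900), epicardium = sc(600),
                 immune = sc(800), thrombocyte = sc(450),
                 myofibroblast = sc(200)),
    runx1_3dpci = c(cardiomyocyte = sc(300), endocardium = sc(2600),
                    endocardium_injury = sc(1600), epicardium = sc(700),
                    immune = sc(800), thrombocyte = sc(50),
                    myofibroblast = sc(50)))
  sim_count_config(n_genes = n_genes, cell_types = cell_types,
                   samples = samples, seed = seed, ...)
}

#' Per-type NB mean profiles with marker blocks
#'
#' Shared log-normal baseline plus a per-type block of boosted marker
#' genes, scaled to a target library size.
#'
#' @param n_genes number of genes.
#' @param type_names character vector of type names.
#' @param n_markers marker genes per type.
#' @param marker_boost multiplicative boost of marker means.
#' @param library_size target expected UMIs per cell.
#' @param seed RNG seed.
#' @return Named list of mean vectors.
#' @export
sim_mean_profiles <- function(n_genes, type_names, n_markers = 40,
                              marker_boost = 8, library_size = 2500,
                              seed = 1) {
  stop_if_not(2 + length(type_names) * n_markers <= n_genes,
              "not enough genes for the requested marker blocks")
  with_seed(seed, {
    base <- exp(rnorm(n_genes, mean = 0, sd = 1.2))
    # keep driver-gene background (first two slots) low: gating overrides it
    base[1:2] <- 0
    out <- list()
    start <- 3L
    for (tn in type_names) {
      mu <- base
      idx <- start:(start + n_markers - 1L)
      mu[idx] <- mu[idx] * marker_boost
      out[[tn]] <- mu * library_size / sum(mu)
      start <- start + n_markers
    }
    out
  })
}

# ---------------------------------------------------------------------------
# AFOG-like wound images

# Synthetic AFOG palette, [0,1] RGB rows: fibrin bright red, collagen blue,
# other/muscle a darker orange. Channel margins are >= 0.15 from the default
# 0.6 thresholds so moderate Gaussian noise does not flip classes.
afog_palette <- function() {
  rbind(fibrin   = c(0.92, 0.10, 0.12),
        collagen = c(0.10, 0.15, 0.88),
        other    = c(0.45, 0.30, 0.10))
}

#' Simulate an AFOG-stained wound image with known colour fractions
#'
#' Produces an RGB image with an elliptical wound mask whose pixels are
#' assigned to fibrin (bright red), collagen (blue) and other (orange)
#' classes in exactly the requested area fractions (up to one pixel of
#' rounding, remainder assigned by largest fractional part), then adds
#' optional i.i.d. Gaussian channel noise clipped to [0,1]. Pixels outside
#' the mask are a neutral light background.
#'
#' @param fractions named numeric: \code{fibrin}, \code{collagen},
#'   \code{other}; non-negative, summing to 1 (tolerance 1e-6).
#' @param width,height image size in pixels.
#' @param noise_sd Gaussian channel noise standard deviation.
#' @param seed RNG seed.
#' @return A list: \code{image} (height x width x 3 array in [0,1]),
#'   \code{mask} (logical matrix), \code{fractions} (the planted truth),
#'   \code{class_map} (integer matrix: 0 outside mask, 1 fibrin, 2 collagen,
#'   3 other).
#' @export
simulate_afog_image <- function(fractions = c(fibrin = 0.5, collagen = 0.3,
                                              other = 0.2),
                                width = 200, height = 160, noise_sd = 0,
                                seed = 1) {
  fractions <- fractions[c("fibrin", "collagen", "other")]
  stop_if_not(!anyNA(fractions) && all(fractions >= 0),
              "fractions must name fibrin, collagen, other and be >= 0")
  stop_if_not(abs(sum(fractions) - 1) < 1e-6, "fractions must sum to 1")
  with_seed(seed, {
    yy <- matrix(seq_len(height), height, width)
    xx <- matrix(seq_len(width), height, width, byrow = TRUE)
    mask <- ((xx - width / 2) / (width * 0.33))^2 +
      ((yy - height / 2) / (height * 0.33))^2 <= 1
    area <- sum(mask)
    n <- floor(fractions * area)
    rem <- area - sum(n)
    if (rem > 0) {
      frac_part <- fractions * area - n
      ord <- order(frac_part, decreasing = TRUE)
      n[ord[seq_len(rem)]] <- n[ord[seq_len(rem)]] + 1
    }
    classes <- rep.int(1:3, n)
    idx <- which(mask)
    classes <- classes[order(runif(length(classes)))]
    class_map <- matrix(0L, height, width)
    class_map[idx] <- classes
    pal <- afog_palette()
    img <- array(0, c(height, width, 3))
    for (ch in 1:3) {
      plane <- matrix(0.93, height, width)   # background
      plane[idx] <- pal[classes, ch]
      img[, , ch] <- plane
    }
    if (noise_sd > 0) {
      img <- img + array(rnorm(length(img), 0, noise_sd), dim(img))
      img[img < 0] <- 0
      img[img > 1] <- 1
    }
    list(image = img, mask = mask, fractions = fractions,
         class_map = class_map)
  })
}

# ---------------------------------------------------------------------------
# Nuclei tables

#' Simulate a Mef2/PCNA nuclei table with a planted proliferation fraction
#'
#' Emits one row per nucleus over \code{n_sections} sections of one fish.
#' Each section carries \code{mef2_per_section} Mef2-positive (myocardial)
#' nuclei plus \code{other_per_section} Mef2-negative nuclei. Every Mef2+
#' nucleus is PCNA-positive independently with probability
#' \code{pcna_fraction} (the planted truth); Mef2- nuclei are PCNA+ at a
#' nuisance rate. Zones (border/remote) are assigned independently of PCNA
#' status, so the planted fraction holds in both zones.
#'
#' @param n_sections number of sections (>= 1).
#' @param mef2_per_section Mef2+ nuclei per section.
#' @param pcna_fraction probability in [0,1] that a Mef2+ nucleus is PCNA+.
#' @param seed RNG seed.
#' @param fish_id fish identifier written to every row.
#' @param other_per_section Mef2- nuclei per section.
#' @param border_fraction probability a nucleus lies in the border zone.
#' @param other_pcna_rate PCNA rate among Mef2- nuclei.
#' @return A list: \code{nuclei} (data.frame with \code{fish}, \code{section},
#'   \code{zone}, \code{mef2}, \code{pcna}) and \code{truth} (list with the
#'   planted \code{pcna_fraction}).
#' @export
simulate_nuclei_table <- function(n_sections, mef2_per_section = 100,
                                  pcna_fraction = 0.3, seed = 1,
                                  fish_id = "fish1", other_per_section = 30,
                                  border_fraction = 0.5,
                                  other_pcna_rate = 0.1) {
  stop_if_not(is_count_scalar(n_sections) && n_sections >= 1,
              "n_sections must be >= 1")
  stop_if_not(is_count_scalar(mef2_per_section) &&
                is_count_scalar(other_per_section),
              "per-section counts must be non-negative integers")
  stop_if_not(pcna_fraction >= 0 && pcna_fraction <= 1,
              "pcna_fraction must be in [0,1]")
  with_seed(seed, {
    rows <- lapply(seq_len(n_sections), function(s) {
      n <- mef2_per_section + other_per_section
      mef2 <- rep(c(TRUE, FALSE), c(mef2_per_section, other_per_section))
      pcna <- logical(n)
      pcna[mef2] <- runif(mef2_per_section) < pcna_fraction
      pcna[!mef2] <- runif(other_per_section) < other_pcna_rate
      zone <- ifelse(runif(n) < border_fraction, "border", "remote")
      data.frame(fish = fish_id, section = sprintf("section%02d", s),
                 zone = zone, mef2 = mef2, pcna = pcna,
                 stringsAsFactors = FALSE)
    })
    list(nuclei = do.call(rbind, rows),
         truth = list(pcna_fraction = pcna_fraction))
  })
}

# ---------------------------------------------------------------------------
# GO universes

#' Simulate a GO annotation universe with exact term sizes
#'
#' @param n_genes number of genes in the universe.
#' @param term_sizes integer vector of requested term sizes; each term is
#'   assigned exactly that many distinct genes (sampled with replacement
#'   across terms, without replacement within a term).
#' @param seed RNG seed.
#' @param gene_names optional gene names (default \code{gene00001...}).
#' @return A list: \code{annotations} (data.frame \code{term}, \code{gene},
#'   \code{term_name}) and \code{universe} (character vector of all genes).
#' @export
simulate_go_universe <- function(n_genes, term_sizes, seed = 1,
                                 gene_names = NULL) {
  stop_if_not(all(term_sizes >= 0 & term_sizes == floor(term_sizes)),
              "term sizes must be non-negative integers")
  stop_if_not(all(term_sizes <= n_genes),
              "a term size exceeds the universe size")
  if (is.null(gene_names)) gene_names <- sprintf("gene%05d", seq_len(n_genes))
  stop_if_not(length(gene_names) == n_genes, "gene_names length mismatch")
  with_seed(seed, {
    ann <- lapply(seq_along(term_sizes), function(i) {
      k <- term_sizes[i]
      if (k == 0) return(NULL)
      data.frame(term = sprintf("GO:%07d", i),
                 gene = sample(gene_names, k),
                 term_name = sprintf("synthetic process %d", i),
                 stringsAsFactors = FALSE)
    })
    ann <- do.call(rbind, ann)
    if (is.null(ann)) {
      ann <- data.frame(term = character(0), gene = character(0),
                        term_name = character(0), stringsAsFactors = FALSE)
    }
    list(annotations = ann, universe = gene_names)
  })
}
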