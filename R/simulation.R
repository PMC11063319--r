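## Synthetic paired methylation/expression data with planted ground truth.
##
## The generator emulates the structure the analysis is designed to detect:
## 450K-like bimodal beta values, group-shifted promoter DMPs (plus a
## body-annotated decoy set that the promoter criterion must reject),
## log-scale expression with planted DEGs, CpG-gene driver pairs with a
## calibrated negative Spearman correlation, latent-factor co-expression
## modules, and a trait tied to one module.

#' Simulation configuration
#'
#' Defaults describe the study conditions the pipeline is validated under:
#' two arms (AR/HC) of `n_per_group` patients, each sampled in the pollen and
#' the non-pollen season on both assays.
#'
#' @param n_probes_meth number of methylation probes.
#' @param n_genes number of expression genes.
#' @param n_per_group patients per AR/HC arm (each contributes one sample per
#'   season per assay).
#' @param n_planted_dmps promoter DMPs with group beta shift `delta_beta`; an
#'   equally sized decoy set carries the same shift but gene-body annotation.
#' @param delta_beta planted group difference in beta units (AR - HC).
#' @param n_planted_degs genes with planted log2 fold change `log2fc`.
#' @param log2fc planted expression effect, log2 units (AR - HC).
#' @param n_driver_pairs CpG-gene pairs whose gene tracks its CpG's beta
#'   through a monotone decreasing link.
#' @param driver_cor target population Spearman correlation of each driver
#'   pair (in (-1, 0]); noise is solved numerically to achieve it.
#' @param n_modules number of latent-factor co-expression modules.
#' @param module_size genes per module.
#' @param trait_module_cor target correlation between the trait (symptom
#'   score) and the first module's latent factor.
#' @param missing_rate completely-at-random missingness fraction applied to
#'   the beta matrix.
#' @param seed master seed; expanded into per-component streams via
#'   [stream_seed()].
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_probes_meth = 3000, n_genes = 2000, n_per_group = 8,
                       n_planted_dmps = 30, delta_beta = 0.3,
                       n_planted_degs = 30, log2fc = 1.5,
                       n_driver_pairs = 15, driver_cor = -0.8,
                       n_modules = 3, module_size = 120,
                       trait_module_cor = 0.8, missing_rate = 0.02,
                       seed = 1) {
  cfg <- list(n_probes_meth = n_probes_meth, n_genes = n_genes,
              n_per_group = n_per_group, n_planted_dmps = n_planted_dmps,
              delta_beta = delta_beta, n_planted_degs = n_planted_degs,
              log2fc = log2fc, n_driver_pairs = n_driver_pairs,
              driver_cor = driver_cor, n_modules = n_modules,
              module_size = module_size, trait_module_cor = trait_module_cor,
              missing_rate = missing_rate, seed = seed)
  counts <- c("n_probes_meth", "n_genes", "n_per_group", "n_planted_dmps",
              "n_planted_degs", "n_driver_pairs", "n_modules", "module_size")
  for (f in counts) assert_that(is_count(cfg[[f]]), "field '%s' must be a nonnegative integer", f)
  assert_that(is_number(driver_cor) && driver_cor > -1 && driver_cor <= 0,
              "field 'driver_cor' must lie in (-1, 0]")
  assert_that(is_number(missing_rate) && missing_rate >= 0 && missing_rate < 1,
              "field 'missing_rate' must lie in [0, 1)")
  assert_that(n_driver_pairs <= min(n_planted_dmps, n_planted_degs),
              "field 'n_driver_pairs' must not exceed min(n_planted_dmps, n_planted_degs)")
  assert_that(n_probes_meth >= 2 * n_planted_dmps,
              "field 'n_probes_meth' too small for planted + decoy DMPs")
  assert_that(n_genes >= n_planted_degs + n_modules * module_size,
              "field 'n_genes' too small for planted DEGs plus modules")
  assert_that(is_number(delta_beta) && delta_beta >= 0 && delta_beta < 1,
              "field 'delta_beta' must lie in [0, 1)")
  assert_that(is_number(log2fc) && log2fc >= 0, "field 'log2fc' must be >= 0")
  assert_that(is_number(trait_module_cor) && abs(trait_module_cor) <= 1,
              "field 'trait_module_cor' must lie in [-1, 1]")
  structure(cfg, class = "sim_config")
}

## --- driver-pair noise calibration ------------------------------------------
## The driver latent is X ~ 0.5*N(-h, sx^2) + 0.5*N(+h, sx^2) (the group
## mixture); beta = pnorm(X) and expression y = mu - b*X + sigma*E. Since
## beta is strictly monotone in X, Spearman(beta, y) = Spearman(X, y).
## sigma is solved by bisection on a large fixed quasi-random sample
## (common random numbers, so the objective is smooth and deterministic).
.calib_env <- new.env(parent = emptyenv())

solve_driver_noise <- function(h, sx, b, target_rho, n_mc = 2e5) {
  key <- paste(signif(c(h, sx, b, target_rho), 10), collapse = "_")
  if (!is.null(.calib_env[[key]])) return(.calib_env[[key]])
  assert_that(target_rho < 0, "driver noise calibration requires negative target")
  ## fixed quadrature-style draws: plug-in normal scores, shuffled
  ## deterministically so the two streams are independent
  q <- stats::qnorm((seq_len(n_mc) - 0.5) / n_mc)
  g <- rep(c(-1, 1), length.out = n_mc)
  set.seed(stream_seed(997, "driver_calibration"))
  w <- sample(q)
  e <- sample(q)
  x <- h * g + sx * w
  rho_at <- function(sigma) {
    y <- -b * x + sigma * e
    stats::cor(rank(x), rank(y))
  }
  ## rho_at(0) = -1 (perfect monotone), rho_at(Inf) -> 0; bisect on sigma
  lo <- 0; hi <- max(1, 4 * b * (h + sx))
  while (rho_at(hi) < target_rho) hi <- hi * 2
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (rho_at(mid) < target_rho) lo <- mid else hi <- mid
  }
  sigma <- (lo + hi) / 2
  .calib_env[[key]] <- sigma
  sigma
}

#' Generate a paired methylation/expression dataset with planted truth
#'
#' @param config a [sim_config()] object.
#' @return list with components `meth` (class `meth_set`: `beta`,
#'   `annotation`, `sample_sheet`), `expr` (class `expr_set`: `expr` raw
#'   intensities, `detection_p`, `probe_to_gene`, `sample_sheet`), `truth`
#'   (class `truth_table`), and `gene_sets` (planted-module GMT-style list).
#' @details Deterministic given `config$seed`. See the methods vignette for
#'   the generative model and the rationale behind each default.
#' @export
generate_dataset <- function(config) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  cfg <- config
  npg <- cfg$n_per_group
  assert_that(npg >= 2, "field 'n_per_group' must be >= 2")

  ## ---- samples: each patient measured in both seasons on both assays
  patients <- sprintf("P%03d", seq_len(2 * npg))
  group <- rep(c("AR", "HC"), each = npg)
  seasons <- c("pollen", "non-pollen")
  sheet <- expand.grid(patient_id = patients, season = seasons,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sheet$group <- group[match(sheet$patient_id, patients)]
  set.seed(stream_seed(cfg$seed, "samples"))
  sex_by_patient <- stats::setNames(sample(c("F", "M"), 2 * npg, replace = TRUE),
                                    patients)
  sheet$sex <- sex_by_patient[sheet$patient_id]
  n_samp <- nrow(sheet)
  samp_key <- paste(sheet$patient_id, sheet$season, sep = "_")

  meth_sheet <- data.frame(sample_id = paste0("M_", samp_key), sheet,
                           stringsAsFactors = FALSE)
  expr_sheet <- data.frame(sample_id = paste0("E_", samp_key), sheet,
                           stringsAsFactors = FALSE)
  is_ar <- sheet$group == "AR"

  ## ---- gene layout
  ng <- cfg$n_genes
  gene_ids <- sprintf("GENE%05d", seq_len(ng))
  driver_genes <- gene_ids[seq_len(cfg$n_driver_pairs)]
  other_degs <- gene_ids[seq_len(cfg$n_planted_degs)][-seq_len(cfg$n_driver_pairs)]
  if (cfg$n_driver_pairs == 0) other_degs <- gene_ids[seq_len(cfg$n_planted_degs)]
  module_idx <- if (cfg$n_modules > 0)
    cfg$n_planted_degs + seq_len(cfg$n_modules * cfg$module_size) else integer(0)
  module_genes <- gene_ids[module_idx]
  module_of <- rep(seq_len(cfg$n_modules), each = cfg$module_size)

  ## ---- probe layout
  np <- cfg$n_probes_meth
  probe_ids <- sprintf("cg%08d", seq_len(np))
  dmp_probes <- probe_ids[seq_len(cfg$n_planted_dmps)]
  driver_probes <- dmp_probes[seq_len(cfg$n_driver_pairs)]
  decoy_probes <- probe_ids[cfg$n_planted_dmps + seq_len(cfg$n_planted_dmps)]
  dmp_sign <- rep_len(c(1, -1), cfg$n_planted_dmps)  # alternate hyper/hypo

  ## ---- methylation background: bimodal beta mixture
  set.seed(stream_seed(cfg$seed, "meth_background"))
  lowmeth <- stats::runif(np) < 0.5
  beta <- matrix(NA_real_, np, n_samp,
                 dimnames = list(probe_ids, meth_sheet$sample_id))
  beta[lowmeth, ] <- stats::rbeta(sum(lowmeth) * n_samp, 2, 10)
  beta[!lowmeth, ] <- stats::rbeta(sum(!lowmeth) * n_samp, 10, 2)

  ## planted (and decoy) DMPs: resample around 0.5 so the shift stays in range
  set.seed(stream_seed(cfg$seed, "planted_dmps"))
  plant_shift <- function(ids, signs) {
    base <- matrix(stats::rbeta(length(ids) * n_samp, 8, 8), length(ids), n_samp)
    shift <- outer(signs * cfg$delta_beta / 2, ifelse(is_ar, 1, -1))
    pmin(pmax(base + shift, 0.001), 0.999)
  }
  non_driver_dmps <- setdiff(dmp_probes, driver_probes)
  if (length(non_driver_dmps))
    beta[non_driver_dmps, ] <- plant_shift(non_driver_dmps,
      dmp_sign[match(non_driver_dmps, dmp_probes)])
  if (length(decoy_probes))
    beta[decoy_probes, ] <- plant_shift(decoy_probes, rep_len(c(1, -1), length(decoy_probes)))

  ## ---- driver pairs: shared latent per (patient, season). The
  ## within-group latent spread sx is kept small so the realized expression
  ## fold change stays close to the planted log2fc.
  sx <- 0.05
  h <- if (cfg$delta_beta > 0)
    sqrt(1 + sx^2) * stats::qnorm((1 + cfg$delta_beta) / 2) / 1 else 0
  b_link <- if (h > 0) cfg$log2fc / (2 * h) else if (cfg$driver_cor < 0) 1 else 0
  driver_sigma <- if (cfg$driver_cor < 0)
    solve_driver_noise(h, sx, b_link, cfg$driver_cor) else Inf

  set.seed(stream_seed(cfg$seed, "driver_latent"))
  driver_sign <- dmp_sign[seq_len(cfg$n_driver_pairs)]
  X_lat <- matrix(0, cfg$n_driver_pairs, n_samp)  # latent per pair x sample
  if (cfg$n_driver_pairs > 0) {
    W <- matrix(stats::rnorm(cfg$n_driver_pairs * n_samp), cfg$n_driver_pairs)
    X_lat <- driver_sign * h * rep(ifelse(is_ar, 1, -1), each = cfg$n_driver_pairs) +
      sx * W
    dim(X_lat) <- c(cfg$n_driver_pairs, n_samp)
    beta[driver_probes, ] <- stats::pnorm(X_lat)
  }

  ## ---- expression (log2 scale first)
  set.seed(stream_seed(cfg$seed, "expression"))
  base_mu <- stats::runif(ng, 6, 12)
  ## heterogeneous biological variability: most genes quiet, a continuum of
  ## noisier ones (keeps the MAD filter from selecting module genes only)
  gene_sd <- stats::runif(ng, 0.3, 0.8)
  y <- matrix(stats::rnorm(ng * n_samp), ng, n_samp,
              dimnames = list(gene_ids, expr_sheet$sample_id)) * gene_sd + base_mu

  ## undetected background genes: low intensity, high detection p
  bg_genes <- setdiff(gene_ids, c(driver_genes, other_degs, module_genes))
  n_undet <- floor(0.05 * length(bg_genes))
  undetected_all <- bg_genes[seq_len(n_undet)]
  n_grp_undet <- floor(0.02 * length(bg_genes))
  undetected_ar <- bg_genes[n_undet + seq_len(n_grp_undet)]
  y[undetected_all, ] <- matrix(stats::rnorm(n_undet * n_samp, sd = 0.5),
                                n_undet, n_samp) + stats::runif(n_undet, 0, 2)
  ## a smaller set hovers near the detection limit: just above background in
  ## HC, below it in AR (group-specific detection, modest fold change)
  y[undetected_ar, ] <- matrix(
    stats::rnorm(n_grp_undet * n_samp, sd = 0.5), n_grp_undet) +
    stats::runif(n_grp_undet, 2.5, 4)
  y[undetected_ar, is_ar] <- matrix(
    stats::rnorm(n_grp_undet * sum(is_ar), sd = 0.5), n_grp_undet) +
    stats::runif(n_grp_undet, 0, 2)

  ## planted non-driver DEGs: additive group shift, alternate up/down
  if (length(other_degs)) {
    deg_sign <- rep_len(c(1, -1), length(other_degs))
    y[other_degs, ] <- y[other_degs, , drop = FALSE] +
      outer(deg_sign * cfg$log2fc, as.numeric(is_ar))
  }

  ## co-expression modules: shared latent factor per module + trait
  set.seed(stream_seed(cfg$seed, "modules"))
  trait <- stats::rnorm(n_samp)
  fac <- NULL
  if (cfg$n_modules > 0) {
    fac <- matrix(stats::rnorm(cfg$n_modules * n_samp), cfg$n_modules)
    noise_sd <- sqrt(3 / 7)  # within-module pairwise correlation ~ 0.7
    y[module_genes, ] <- base_mu[module_idx] + fac[module_of, ] +
      matrix(stats::rnorm(length(module_genes) * n_samp, sd = noise_sd),
             length(module_genes), n_samp)
    f1 <- as.numeric(scale(fac[1, ]))
    rho_t <- cfg$trait_module_cor
    trait <- rho_t * f1 + sqrt(max(0, 1 - rho_t^2)) * stats::rnorm(n_samp)
  }

  ## driver genes: monotone decreasing link to their CpG latent. The first
  ## driver gene additionally loads on the first module factor (at the
  ## expense of its independent noise, leaving the target Spearman intact),
  ## emulating a key methylation-driven gene sitting inside the trait module.
  set.seed(stream_seed(cfg$seed, "driver_noise"))
  if (cfg$n_driver_pairs > 0) {
    eps <- matrix(stats::rnorm(cfg$n_driver_pairs * n_samp), cfg$n_driver_pairs)
    if (is.finite(driver_sigma)) {
      noise <- driver_sigma * eps
      if (!is.null(fac)) {
        lam <- 0.8 * driver_sigma
        noise[1L, ] <- lam * fac[1L, ] +
          sqrt(driver_sigma^2 - lam^2) * eps[1L, ]
      }
      y[driver_genes, ] <- base_mu[seq_len(cfg$n_driver_pairs)] -
        b_link * X_lat + noise
    } else {
      ## uncoupled limit (driver_cor = 0): keep only the group effect
      y[driver_genes, ] <- y[driver_genes, , drop = FALSE] +
        outer(-driver_sign * cfg$log2fc, as.numeric(is_ar))
    }
  }
  meth_sheet$symptom_score <- round(5 + 2 * trait, 2)
  expr_sheet$symptom_score <- meth_sheet$symptom_score

  ## ---- detection p-values
  set.seed(stream_seed(cfg$seed, "detection"))
  det <- matrix(stats::runif(ng * n_samp, 0, 0.04), ng, n_samp,
                dimnames = dimnames(y))
  det[undetected_all, ] <- stats::runif(n_undet * n_samp, 0.5, 1)
  det[undetected_ar, is_ar] <- stats::runif(n_grp_undet * sum(is_ar), 0.5, 1)

  ## ---- expression probes: one per gene plus low-signal duplicates
  n_dup <- floor(0.05 * ng)
  dup_genes <- gene_ids[seq_len(n_dup)]
  probe_main <- sprintf("ep%06d", seq_len(ng))
  probe_dup <- sprintf("ep%06d", ng + seq_len(n_dup))
  set.seed(stream_seed(cfg$seed, "dup_probes"))
  y_dup <- y[dup_genes, , drop = FALSE] - 1 +
    matrix(stats::rnorm(n_dup * n_samp, sd = 0.3), n_dup, n_samp)
  expr_log <- rbind(y, y_dup)
  rownames(expr_log) <- c(probe_main, probe_dup)
  det_all <- rbind(det, det[dup_genes, , drop = FALSE])
  rownames(det_all) <- rownames(expr_log)
  probe_to_gene <- stats::setNames(c(gene_ids, dup_genes), rownames(expr_log))
  expr_raw <- 2^expr_log
  colnames(expr_raw) <- expr_sheet$sample_id
  colnames(det_all) <- expr_sheet$sample_id

  ## ---- probe annotation
  set.seed(stream_seed(cfg$seed, "annotation"))
  promoter_feats <- c("TSS1500", "TSS200", "5'UTR", "1stExon")
  all_feats <- c(promoter_feats, "Body", "3'UTR", "IGR")
  feature <- sample(all_feats, np, replace = TRUE,
                    prob = c(0.12, 0.12, 0.08, 0.08, 0.35, 0.1, 0.15))
  feature[match(dmp_probes, probe_ids)] <-
    sample(promoter_feats, cfg$n_planted_dmps, replace = TRUE)
  feature[match(decoy_probes, probe_ids)] <- "Body"
  ann_gene <- sample(gene_ids, np, replace = TRUE)
  ann_gene[match(dmp_probes, probe_ids)] <-
    c(driver_genes, sample(bg_genes, length(non_driver_dmps)))
  annotation <- data.frame(
    probe = probe_ids, gene = ann_gene, feature = feature,
    island = sample(c("Island", "Shore", "Shelf", "OpenSea"), np, TRUE),
    design_type = sample(c("I", "II"), np, TRUE, prob = c(0.3, 0.7)),
    stringsAsFactors = FALSE)

  ## ---- missingness (MCAR) on beta
  set.seed(stream_seed(cfg$seed, "missing"))
  if (cfg$missing_rate > 0) {
    nmiss <- round(cfg$missing_rate * length(beta))
    beta[sample(length(beta), nmiss)] <- NA_real_
  }

  truth <- structure(list(
    dmp_ids = dmp_probes,
    decoy_dmp_ids = decoy_probes,
    deg_ids = gene_ids[seq_len(cfg$n_planted_degs)],
    driver_pairs = data.frame(probe = driver_probes, gene = driver_genes,
                              sign = driver_sign, stringsAsFactors = FALSE),
    module_membership = stats::setNames(module_of - 1L, module_genes),
    trait_values = stats::setNames(trait, expr_sheet$sample_id)),
    class = "truth_table")

  gene_sets <- list()
  if (cfg$n_modules > 0) {
    gene_sets <- split(module_genes, module_of)
    names(gene_sets) <- sprintf("planted_module_%d", seq_len(cfg$n_modules))
    set.seed(stream_seed(cfg$seed, "decoy_sets"))
    for (i in seq_len(cfg$n_modules)) {
      gene_sets[[sprintf("decoy_set_%d", i)]] <-
        sample(gene_ids, cfg$module_size)
    }
  }

  list(
    meth = structure(list(beta = beta, annotation = annotation,
                          sample_sheet = meth_sheet), class = "meth_set"),
    expr = structure(list(expr = expr_raw, detection_p = det_all,
                          probe_to_gene = probe_to_gene,
                          sample_sheet = expr_sheet), class = "expr_set"),
    truth = truth,
    gene_sets = gene_sets,
    config = cfg)
}

#' Write a generated dataset to a directory of plain-text files
#'
#' Emits TSV matrices, annotation, sample sheets, the truth table, and a GMT
#' of planted-module plus decoy gene sets; everything round-trips through
#' [read_dataset()].
#'
#' @param dataset a list as returned by [generate_dataset()].
#' @param directory output directory (created if absent).
#' @return named character vector of written file paths.
#' @export
write_dataset <- function(dataset, directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create directory '%s'", directory))
  }
  p <- function(f) file.path(directory, f)
  paths <- c(
    beta = write_matrix_tsv(dataset$meth$beta, p("beta.tsv"), "probe"),
    meth_annotation = write_table_tsv(dataset$meth$annotation, p("meth_annotation.tsv")),
    meth_samples = write_table_tsv(dataset$meth$sample_sheet, p("meth_samples.tsv")),
    expr = write_matrix_tsv(dataset$expr$expr, p("expr.tsv"), "probe"),
    detection_p = write_matrix_tsv(dataset$expr$detection_p, p("detection_p.tsv"), "probe"),
    probe_to_gene = write_table_tsv(
      data.frame(probe = names(dataset$expr$probe_to_gene),
                 gene = unname(dataset$expr$probe_to_gene)),
      p("probe_to_gene.tsv")),
    expr_samples = write_table_tsv(dataset$expr$sample_sheet, p("expr_samples.tsv")),
    truth_dmps = write_table_tsv(
      data.frame(probe = dataset$truth$dmp_ids), p("truth_dmps.tsv")),
    truth_degs = write_table_tsv(
      data.frame(gene = dataset$truth$deg_ids), p("truth_degs.tsv")),
    truth_pairs = write_table_tsv(dataset$truth$driver_pairs, p("truth_pairs.tsv")),
    truth_modules = write_table_tsv(
      data.frame(gene = names(dataset$truth$module_membership),
                 module = unname(dataset$truth$module_membership)),
      p("truth_modules.tsv")),
    truth_trait = write_table_tsv(
      data.frame(sample_id = names(dataset$truth$trait_values),
                 trait = unname(dataset$truth$trait_values)),
      p("truth_trait.tsv")),
    gene_sets = write_gmt(dataset$gene_sets, p("gene_sets.gmt")))
  paths
}

#' Read back a dataset written by [write_dataset()]
#' @param directory directory containing the TSV/GMT files.
#' @return list with `meth`, `expr`, `truth`, `gene_sets` as in
#'   [generate_dataset()].
#' @export
read_dataset <- function(directory) {
  p <- function(f) file.path(directory, f)
  p2g <- read_table_tsv(p("probe_to_gene.tsv"))
  pairs <- read_table_tsv(p("truth_pairs.tsv"))
  modules <- read_table_tsv(p("truth_modules.tsv"))
  trait <- read_table_tsv(p("truth_trait.tsv"))
  list(
    meth = structure(list(beta = read_matrix_tsv(p("beta.tsv")),
                          annotation = read_table_tsv(p("meth_annotation.tsv")),
                          sample_sheet = read_table_tsv(p("meth_samples.tsv"))),
                     class = "meth_set"),
    expr = structure(list(expr = read_matrix_tsv(p("expr.tsv")),
                          detection_p = read_matrix_tsv(p("detection_p.tsv")),
                          probe_to_gene = stats::setNames(p2g$gene, p2g$probe),
                          sample_sheet = read_table_tsv(p("expr_samples.tsv"))),
                     class = "expr_set"),
    truth = structure(list(
      dmp_ids = read_table_tsv(p("truth_dmps.tsv"))$probe,
      deg_ids = read_table_tsv(p("truth_degs.tsv"))$gene,
      driver_pairs = pairs,
      module_membership = stats::setNames(modules$module, modules$gene),
      trait_values = stats::setNames(trait$trait, trait$sample_id)),
      class = "truth_table"),
    gene_sets = read_gmt(p("gene_sets.gmt")))
}
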