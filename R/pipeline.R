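## End-to-end orchestration: methylation QC -> expression preprocessing ->
## per-season differential screens -> CpG-gene integration -> enrichment ->
## co-expression, with a manifest of the counts each stage produced.

#' Default pipeline configuration
#'
#' All thresholds default to the analysis' stated criteria: raw p < 0.05
#' gates with adaptive mean+2sd effect thresholds, Spearman Cor < -0.4 for
#' pairs, promoter restriction for DMPs, MAD top 25% / R^2 0.85 /
#' minModuleSize 100 for the network stage, Cor > 0.4 for key modules and
#' key-gene neighbors.
#'
#' @param ... overrides for any listed field.
#' @return named list of parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    max_missing_rate = 0.10,
    beta_offset = 100,
    detection_alpha = 0.05,
    detection_min_frac = 0.5,
    alpha = 0.05,
    rho_max = -0.4,
    promoter_features = c("TSS1500", "TSS200", "5'UTR", "1stExon"),
    meth_transform = "none",       # or "mvalue"
    mad_top_fraction = 0.25,
    r2_target = 0.85,
    candidate_powers = 1:20,
    min_module_size = 100,
    power = NULL,                  # override the soft-threshold pick
    cor_min = 0.4,
    effect_tau = NULL,             # fixed effect threshold; NULL = adaptive
    check_consistency = TRUE,
    n_perm = 1000,
    seasons = c("pollen", "non-pollen"),
    coexpress_season = "pollen",
    seed = 1)
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  assert_that(length(unknown) == 0, "unknown config field(s): %s",
              paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  cfg
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(sprintf("stage '%s': %s", stage, conditionMessage(e)),
                        class = c("mdg_stage_error", class(e))))
  })
}

#' Run the full methylation-driven gene analysis
#'
#' Executes methylation QC (missing-rate filter, blacklist, probe-type
#' normalization), expression preprocessing (background correction,
#' detection filter with group-mean replacement, gene collapse), per-season
#' moderated differential screens with adaptive thresholds, promoter DMP and
#' DEG calls, Spearman CpG-gene integration, season comparison, ORA (and
#' single-CpG GSEA when gene sets are supplied), and the co-expression
#' module stage on the configured season.
#'
#' @param meth `meth_set` list (`beta`, `annotation`, `sample_sheet`).
#' @param expr `expr_set` list (`expr` raw intensities, `detection_p`,
#'   `probe_to_gene`, `sample_sheet`).
#' @param blacklist character vector of probe IDs to remove (may be empty).
#' @param gene_sets optional named list of gene sets (GMT) for enrichment.
#' @param config list from [pipeline_config()].
#' @param out_dir optional directory; when given, stage TSVs and a JSON
#'   manifest are written there.
#' @return list with per-stage results and `manifest` (named counts).
#' @export
run_pipeline <- function(meth, expr, blacklist = character(0),
                         gene_sets = NULL, config = pipeline_config(),
                         out_dir = NULL) {
  manifest <- list(seed = config$seed,
                   parameters = config[setdiff(names(config), "promoter_features")])

  ## ---- methylation preprocessing
  mstage <- with_stage("meth_preprocess", {
    manifest$n_probes_input <- nrow(meth$beta)
    fm <- filter_missing(meth$beta, config$max_missing_rate)
    manifest$n_probes_after_missing <- nrow(fm$matrix)
    bl <- apply_probe_blacklist(fm$matrix, blacklist)
    manifest$n_probes_after_blacklist <- nrow(bl$matrix)
    dt <- stats::setNames(meth$annotation$design_type, meth$annotation$probe)
    norm <- normalize_probe_types(bl$matrix, dt)
    list(beta = norm, filter_report = fm)
  })
  beta <- mstage$beta
  meth_sheet <- meth$sample_sheet[meth$sample_sheet$sample_id %in% colnames(beta), ]

  ## ---- expression preprocessing (per season: detection filter by group)
  estage <- with_stage("expr_preprocess", {
    log_expr <- background_correct(expr$expr, expr$detection_p)
    log_expr
  })
  expr_sheet <- expr$sample_sheet

  seasons <- config$seasons
  per_season <- list()
  for (season in seasons) {
    per_season[[season]] <- with_stage(paste0("differential/", season), {
      ms <- meth_sheet[meth_sheet$season == season, ]
      es <- expr_sheet[expr_sheet$season == season, ]
      assert_that(nrow(ms) > 0 && nrow(es) > 0, "no samples for season '%s'", season)

      ## detection filter within season, split AR/HC
      grp <- stats::setNames(es$group, es$sample_id)
      dfi <- detection_filter_impute(
        estage[, es$sample_id, drop = FALSE],
        expr$detection_p[, es$sample_id, drop = FALSE],
        grp, alpha = config$detection_alpha,
        min_frac = config$detection_min_frac)
      genes <- collapse_to_genes(dfi$expr, expr$probe_to_gene)

      bmat <- beta[, intersect(colnames(beta), ms$sample_id), drop = FALSE]
      test_mat <- if (config$meth_transform == "mvalue")
        beta_to_mvalue(bmat) else bmat
      mres <- moderated_ttest(test_mat, stats::setNames(ms$group, ms$sample_id))
      if (config$meth_transform == "mvalue") {
        ## effects for thresholding/calls stay on the beta scale
        bres <- moderated_ttest(bmat, stats::setNames(ms$group, ms$sample_id))
        mres$effect <- bres$effect
      }
      fixed_thr <- function() structure(list(tau = config$effect_tau,
        mean_abs = NA_real_, sd_abs = NA_real_, n_features = NA_integer_),
        class = "adaptive_threshold")
      dmps <- call_dmps(mres, meth$annotation,
                        threshold = if (is.null(config$effect_tau)) NULL else fixed_thr(),
                        alpha = config$alpha,
                        promoter_features = config$promoter_features)
      eres <- moderated_ttest(genes, stats::setNames(es$group, es$sample_id))
      degs <- call_degs(eres,
                        threshold = if (is.null(config$effect_tau)) NULL else fixed_thr(),
                        alpha = config$alpha)

      matched <- match_samples(ms, es)
      cand <- meth$annotation[meth$annotation$probe %in% rownames(bmat),
                              c("probe", "gene")]
      scored <- correlate_pairs(bmat, genes, cand, matched)
      pairs <- call_driver_pairs(scored, dmps, degs, rho_max = config$rho_max,
                                 alpha = config$alpha, season = season,
                                 check_consistency = config$check_consistency)
      list(meth_results = mres, expr_results = eres, dmps = dmps, degs = degs,
           genes = genes, scored = scored, pairs = pairs, matched = matched,
           significant_probes = dfi$significant)
    })
    st <- per_season[[season]]
    tag <- gsub("-", "_", season)
    manifest[[paste0("n_dmps_", tag)]] <- sum(st$meth_results$p < config$alpha &
      abs(st$meth_results$effect) > attr(st$dmps, "threshold")$tau)
    manifest[[paste0("n_promoter_dmps_", tag)]] <- nrow(st$dmps)
    manifest[[paste0("n_degs_up_", tag)]] <- sum(st$degs$direction == "up")
    manifest[[paste0("n_degs_down_", tag)]] <- sum(st$degs$direction == "down")
    manifest[[paste0("n_scored_pairs_", tag)]] <-
      sum(st$scored$rho < config$rho_max & st$scored$p < config$alpha, na.rm = TRUE)
    manifest[[paste0("n_driver_pairs_", tag)]] <- nrow(st$pairs)
    manifest[[paste0("n_matched_samples_", tag)]] <- nrow(st$matched)
  }

  ## ---- season comparison of driver genes
  venn <- NULL
  if (length(seasons) == 2L) {
    venn <- with_stage("season_comparison", {
      compare_gene_sets(per_season[[seasons[1]]]$pairs$gene,
                        per_season[[seasons[2]]]$pairs$gene, seasons)
    })
    manifest$n_genes_shared <- length(venn$intersection)
    manifest$n_genes_unique_1 <- length(venn$unique_a)
    manifest$n_genes_unique_2 <- length(venn$unique_b)
  }

  ## ---- enrichment
  enrichment <- NULL
  gsea <- NULL
  if (!is.null(gene_sets) && length(gene_sets)) {
    enrichment <- with_stage("enrich", {
      lapply(per_season, function(st) {
        q <- unique(st$pairs$gene)
        if (length(q) == 0) return(NULL)
        ora_hypergeometric(q, gene_sets, rownames(st$genes))
      })
    })
    s1 <- per_season[[config$coexpress_season]]
    if (!is.null(s1) && nrow(s1$pairs)) {
      gsea <- with_stage("gsea", {
        top <- s1$pairs[order(s1$pairs$rho), ][1L, ]
        ranked <- rank_by_cpg(beta[top$probe, ], s1$genes, s1$matched)
        gsea_run(ranked, gene_sets, n_perm = config$n_perm,
                 seed = stream_seed(config$seed, "gsea"))
      })
      manifest$gsea_top_probe <- with_stage("gsea", {
        s1$pairs$probe[which.min(s1$pairs$rho)]
      })
    }
  }

  ## ---- co-expression network on the configured season
  coexpress <- with_stage("coexpress", {
    st <- per_season[[config$coexpress_season]]
    es <- expr_sheet[expr_sheet$season == config$coexpress_season, ]
    mat <- mad_filter(st$genes, config$mad_top_fraction)
    outl <- tryCatch(remove_outlier_samples(mat),
                     mdg_validation_error = function(e) {
                       warning(sprintf("outlier removal skipped: %s",
                                       conditionMessage(e)))
                       list(retained = colnames(mat), dropped = character(0))
                     })
    mat <- mat[, outl$retained, drop = FALSE]
    pick <- if (is.null(config$power))
      pick_soft_threshold(mat, config$candidate_powers, config$r2_target)
    else list(power = config$power, fit_table = NULL)
    adj <- abs(stats::cor(t(mat)))^pick$power
    diag(adj) <- 0
    tom <- tom_similarity(adj)
    colors <- detect_modules(tom, config$min_module_size)
    if (all(colors == "grey")) {
      list(mat = mat, power = pick$power, fit_table = pick$fit_table,
           colors = colors, eigengenes = NULL, trait_cor = NULL,
           outliers = outl$dropped)
    } else {
      me <- module_eigengenes(mat, colors)
      es2 <- es[match(colnames(mat), es$sample_id), ]
      traits <- data.frame(group = as.numeric(es2$group == "AR"),
                           sex = as.numeric(es2$sex == "F"),
                           symptom_score = es2$symptom_score)
      tc <- module_trait_correlation(me$eigengenes, traits,
                                     cor_min = config$cor_min,
                                     alpha = config$alpha)
      list(mat = mat, power = pick$power, fit_table = pick$fit_table,
           colors = colors, eigengenes = me, trait_cor = tc,
           outliers = outl$dropped)
    }
  })
  manifest$n_network_genes <- nrow(coexpress$mat)
  manifest$soft_threshold_power <- coexpress$power
  manifest$n_modules <- length(setdiff(unique(coexpress$colors), "grey"))
  manifest$n_key_modules <- if (!is.null(coexpress$trait_cor))
    length(unique(coexpress$trait_cor$module[coexpress$trait_cor$key])) else 0L

  ## key-gene neighborhood: most negatively correlated driver gene that sits
  ## in a key module
  neighbors <- NULL
  if (!is.null(coexpress$trait_cor) && any(coexpress$trait_cor$key)) {
    st <- per_season[[config$coexpress_season]]
    key_mods <- unique(coexpress$trait_cor$module[coexpress$trait_cor$key])
    cand <- st$pairs[order(st$pairs$rho), ]
    cand <- cand[coexpress$colors[cand$gene] %in% key_mods &
                   !is.na(coexpress$colors[cand$gene]), ]
    if (nrow(cand)) {
      kg <- cand$gene[1L]
      km <- coexpress$colors[kg]
      sub <- coexpress$mat[names(coexpress$colors)[coexpress$colors == km], ,
                           drop = FALSE]
      neighbors <- with_stage("key_gene_neighbors", {
        key_gene_neighbors(sub, kg, cor_min = config$cor_min,
                           alpha = config$alpha)
      })
      manifest$key_gene <- kg
      manifest$key_module <- unname(km)
      manifest$n_key_gene_neighbors <- nrow(neighbors)
    }
  }

  result <- list(manifest = manifest, seasons = per_season, venn = venn,
                 enrichment = enrichment, gsea = gsea, coexpress = coexpress,
                 neighbors = neighbors, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (season in names(result$seasons)) {
    st <- result$seasons[[season]]
    tag <- gsub("-", "_", season)
    write_table_tsv(st$meth_results, file.path(out_dir, paste0("meth_results_", tag, ".tsv")))
    write_table_tsv(st$expr_results, file.path(out_dir, paste0("expr_results_", tag, ".tsv")))
    write_table_tsv(st$dmps, file.path(out_dir, paste0("dmps_", tag, ".tsv")))
    write_table_tsv(st$degs, file.path(out_dir, paste0("degs_", tag, ".tsv")))
    write_table_tsv(st$pairs, file.path(out_dir, paste0("driver_pairs_", tag, ".tsv")))
  }
  if (!is.null(result$venn))
    write_table_tsv(result$venn$counts, file.path(out_dir, "season_venn.tsv"))
  if (!is.null(result$gsea))
    write_table_tsv(result$gsea, file.path(out_dir, "gsea.tsv"))
  if (!is.null(result$coexpress$trait_cor))
    write_table_tsv(result$coexpress$trait_cor, file.path(out_dir, "module_trait.tsv"))
  write_table_tsv(data.frame(gene = names(result$coexpress$colors),
                             module = unname(result$coexpress$colors)),
                  file.path(out_dir, "module_assignment.tsv"))
  if (!is.null(result$neighbors))
    write_table_tsv(result$neighbors, file.path(out_dir, "key_gene_neighbors.tsv"))
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Compare driver genes against external differential-expression tables
#'
#' For each driver gene, reports presence and direction in each supplied DEG
#' table and whether the directions agree (e.g. "concordant down").
#'
#' @param deg_tables named list of data.frames from [call_degs()] (columns
#'   `feature`, `direction`).
#' @param driver_genes character vector of methylation-driven gene IDs.
#' @return data.frame with one row per driver gene present in at least one
#'   table; `attr(, "unmatched")` lists driver genes found nowhere.
#' @export
external_comparison <- function(deg_tables, driver_genes) {
  assert_that(length(deg_tables) > 0 && !is.null(names(deg_tables)),
              "deg_tables must be a named list")
  driver_genes <- unique(driver_genes)
  rows <- lapply(driver_genes, function(g) {
    dirs <- vapply(deg_tables, function(tb) {
      i <- match(g, tb$feature)
      if (is.na(i)) NA_character_ else tb$direction[i]
    }, "")
    if (all(is.na(dirs))) return(NULL)
    hit <- dirs[!is.na(dirs)]
    verdict <- if (length(unique(hit)) == 1L)
      paste("concordant", unique(hit)) else "discordant"
    df <- data.frame(gene = g, t(dirs), verdict = verdict,
                     stringsAsFactors = FALSE, check.names = FALSE)
    df
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(gene = character(), verdict = character())
  attr(out, "unmatched") <- setdiff(driver_genes, out$gene)
  rownames(out) <- NULL
  out
}
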