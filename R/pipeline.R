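#' Simulate a manifest-like probe annotation
#'
#' Random gene-region and CpG-island-relation categories with proportions
#' typical of the 450K array, plus a `known_snp` flag. When a truth table
#' is supplied, probes marked SNP-like have even odds of also carrying the
#' manifest SNP flag (annotation and genotype pattern overlap only partly
#' on the real array), and a small background rate applies elsewhere.
#'
#' @param probe_ids probe identifiers.
#' @param seed integer seed.
#' @param truth optional truth table from [simulate_cohort()].
#' @param known_snp_rate background manifest SNP-flag rate.
#' @return probe annotation data.frame.
#' @export
simulate_annotation <- function(probe_ids, seed, truth = NULL,
                                known_snp_rate = 0.02) {
  withr::with_seed(seed, {
    n <- length(probe_ids)
    gene_region <- sample(GENE_REGIONS, n, replace = TRUE,
                          prob = c(0.14, 0.10, 0.12, 0.08, 0.33, 0.04, 0.19))
    island_relation <- sample(ISLAND_RELATIONS, n, replace = TRUE,
                              prob = c(0.31, 0.13, 0.10, 0.05, 0.04, 0.37))
    known_snp <- stats::runif(n) < known_snp_rate
    if (!is.null(truth)) {
      snp_like <- truth$is_snp_like[match(probe_ids, truth$probe_id)]
      known_snp[snp_like] <- stats::runif(sum(snp_like)) < 0.5
    }
    data.frame(probe_id = probe_ids,
               chrom = paste0("chr", sample(c(1:22, "X"), n, replace = TRUE)),
               pos = sample.int(2.4e8, n, replace = TRUE),
               gene_symbols = paste0("GENE", sample.int(2000, n,
                                                        replace = TRUE)),
               gene_region = gene_region,
               island_relation = island_relation,
               known_snp = known_snp,
               stringsAsFactors = FALSE)
  })
}

read_probe_list <- function(path) {
  readLines(path, warn = FALSE)
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    sc <- config$simulate
    seed <- config$seed
    cohort <- simulate_cohort(
      n_is = sc$n_is %||% 23, n_ir = sc$n_ir %||% 14,
      n_probes = sc$n_probes %||% 5000, n_dml = sc$n_dml %||% 200,
      delta = sc$delta %||% 0.15, precision = sc$precision %||% 50,
      snp_frac = sc$snp_frac %||% 0.01, seed = seed)
    refs <- simulate_references(
      cell_types = c("monocyte", "pbmc"),
      n_markers_per_type = sc$n_markers_per_type %||% 100,
      marker_delta = sc$marker_delta %||% 0.35,
      seed = seed + 1L, cohort = cohort,
      hsc_maintained = sc$hsc_maintained)
    ann <- simulate_annotation(cohort$truth$probe_id, seed = seed + 2L,
                               truth = cohort$truth)
    list(beta = cohort$beta, samples = cohort$samples, truth = refs$truth,
         annotation = ann, refs = refs, confounder_dmls = NULL)
  } else {
    inp <- config$inputs
    if (is.null(inp)) stop("config must provide either inputs or simulate")
    for (f in c("beta", "samples")) {
      if (is.null(inp[[f]])) stop("config inputs missing required '", f, "'")
    }
    paths <- Filter(is.character, inp)
    missing_files <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(missing_files) > 0)
      stop("input file(s) not found: ", paste(missing_files, collapse = ", "))
    beta <- read_beta_matrix(inp$beta)
    samples <- read_sample_table(inp$samples)
    ann <- if (!is.null(inp$annotation)) read_probe_annotation(inp$annotation)
    conf <- if (!is.null(inp$confounder_dmls)) read_probe_list(inp$confounder_dmls)
    refs <- NULL
    if (!is.null(inp$ref_a) && !is.null(inp$ref_b)) {
      refs <- list(ref_a = read_beta_matrix(inp$ref_a),
                   ref_b = read_beta_matrix(inp$ref_b))
    }
    hsc <- NULL
    if (!is.null(inp$hsc_profile)) {
      hdf <- utils::read.delim(inp$hsc_profile, stringsAsFactors = FALSE)
      hsc <- stats::setNames(hdf[[2]], hdf[[1]])
    }
    list(beta = beta, samples = samples, truth = NULL, annotation = ann,
         refs = refs, hsc_profile = hsc, confounder_dmls = conf)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes the complete workflow in order: differential methylation
#' calling (permutation moderated-t plus the absolute-delta filter), then
#' confounder-overlap subtraction, SNP-pattern and known-SNP flagging,
#' reference-based identity QC, HSC maintenance classification with PCA,
#' biomarker logistic models, genomic-context enrichment and Manhattan
#' clustering. All randomness derives from the single `seed` in the
#' config, so a rerun with the same config is bit-identical.
#'
#' @param config path to a YAML config, or an equivalent named list. Keys:
#'   `seed`, `B`, `p_threshold`, `delta_threshold`, and either `simulate:`
#'   (synthetic cohort parameters, see [simulate_cohort()]) or `inputs:`
#'   (paths: beta, samples, and optionally annotation, confounder_dmls,
#'   ref_a, ref_b, hsc_profile).
#' @param out_dir output directory; created if absent.
#' @param force overwrite an existing output directory.
#' @return invisibly, the pipeline report (named list of stage counts and
#'   parameters); outputs written as TSV/YAML under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config must set a seed")
  seed <- as.integer(config$seed)
  B <- config$B %||% 1000
  p_thr <- config$p_threshold %||% 0.05
  d_thr <- config$delta_threshold %||% 0.10

  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force)
    stop("output directory exists and is nonempty; use force = TRUE")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  inputs <- load_pipeline_inputs(config)
  beta <- inputs$beta
  samples <- inputs$samples
  report <- list(parameters = list(seed = seed, B = B, p_threshold = p_thr,
                                   delta_threshold = d_thr),
                 stages = list())
  log_stage <- function(stage, n_in, n_out) {
    report$stages[[length(report$stages) + 1]] <<-
      list(stage = stage, n_in = n_in, n_out = n_out)
    message(sprintf("[%s] in=%d out=%d", stage, n_in, n_out))
  }

  # --- differential methylation ---
  gs <- group_stats(beta, samples)
  pp <- permutation_pvalues(beta, samples, B = B, seed = seed)
  records <- merge(gs, pp, by = "probe_id", sort = FALSE)
  records <- records[match(rownames(beta), records$probe_id), ]
  pass_pd <- !is.na(records$p_perm) & records$p_perm < p_thr &
    abs(records$delta) >= d_thr
  log_stage("permutation+delta", nrow(records), sum(pass_pd))

  # --- confounder overlap ---
  records$flag_confound <- FALSE
  if (!is.null(inputs$confounder_dmls)) {
    cand <- records$probe_id[pass_pd]
    cof <- confound_overlap_filter(cand, inputs$confounder_dmls)
    records$flag_confound <- records$probe_id %in% cof$overlap
    report$confounder_overlap <- list(n_overlap = cof$n_overlap,
                                      pct_overlap = cof$pct_overlap)
    log_stage("confounder_overlap", length(cand), length(cof$retained))
  }

  # --- SNP flags (assessed on the surviving candidates) ---
  cand_idx <- which(pass_pd & !records$flag_confound)
  records$flag_snp_pattern <- FALSE
  records$flag_snp_pattern[cand_idx] <-
    unname(snp_pattern_flags(as.matrix(beta)[cand_idx, , drop = FALSE]))
  records$flag_known_snp <- FALSE
  if (!is.null(inputs$annotation)) {
    ks <- known_snp_flag(inputs$annotation)
    records$flag_known_snp <- unname(ks[records$probe_id])
    records$flag_known_snp[is.na(records$flag_known_snp)] <- FALSE
  }
  records <- call_dmls(records, p_threshold = p_thr, delta_threshold = d_thr)
  summ <- dml_summary(records)
  report$dml_summary <- summ
  log_stage("snp_flags", length(cand_idx), summ$n_dml)
  dml_probes <- records$probe_id[records$is_dml]
  write_tsv_fixed(records, file.path(out_dir, "dml.tsv"))

  # --- identity QC ---
  if (!is.null(inputs$refs)) {
    refs <- inputs$refs
    if (!is.null(refs$ref_beta)) {  # simulated reference bundle
      is_a <- refs$ref_samples$cell_type == refs$ref_samples$cell_type[1]
      ref_a <- as.matrix(refs$ref_beta)[, is_a, drop = FALSE]
      ref_b <- as.matrix(refs$ref_beta)[, !is_a, drop = FALSE]
      type_a <- refs$ref_samples$cell_type[1]
      type_b <- setdiff(unique(refs$ref_samples$cell_type), type_a)[1]
    } else {
      ref_a <- refs$ref_a; ref_b <- refs$ref_b
      type_a <- "type_a"; type_b <- "type_b"
    }
    panel <- build_panel(ref_a, ref_b, type_a = type_a, type_b = type_b,
                         delta_threshold = config$panel_delta %||% 0.30,
                         B = B, seed = seed + 3L)
    scores <- purity_scores(beta, panel, target_type = type_a)
    cmp <- compare_group_scores(scores, samples)
    purity <- data.frame(sample_id = names(scores), score = unname(scores),
                         stringsAsFactors = FALSE)
    write_tsv_fixed(purity, file.path(out_dir, "purity.tsv"))
    report$identity_qc <- list(n_panel = length(panel$panel_probes),
                               group_p = cmp$p)
    log_stage("identity_qc", ncol(beta), length(panel$panel_probes))
  }

  # --- HSC maintenance + PCA ---
  hsc_profile <- inputs$hsc_profile
  if (is.null(hsc_profile) && !is.null(inputs$refs$hsc_profile))
    hsc_profile <- inputs$refs$hsc_profile
  if (!is.null(hsc_profile) && length(dml_probes) >= 2) {
    mrec <- maintenance_records(beta, samples, hsc_profile,
                                probes = intersect(dml_probes,
                                                   names(hsc_profile)))
    msum <- maintenance_summary(mrec)
    write_tsv_fixed(mrec, file.path(out_dir, "maintenance.tsv"))
    report$maintenance <- msum[c("n_maintained_ir", "n_maintained_is",
                                 "n_maintained_both")]
    log_stage("hsc_maintenance", length(dml_probes), nrow(mrec))
    pca_mat <- as.matrix(beta)[mrec$probe_id, , drop = FALSE]
    if (!is.null(inputs$refs$hsc_beta))
      pca_mat <- cbind(pca_mat,
                       as.matrix(inputs$refs$hsc_beta)[mrec$probe_id, ,
                                                       drop = FALSE])
    pca <- pca_dmls(pca_mat)
    pca_df <- data.frame(sample_id = rownames(pca$scores),
                         pc1 = pca$scores[, 1], pc2 = pca$scores[, 2],
                         stringsAsFactors = FALSE)
    write_tsv_fixed(pca_df, file.path(out_dir, "pca.tsv"))
    report$pca_var_explained <- round(pca$var_explained[1:2], 4)
  }

  # --- prediction ---
  if (length(dml_probes) >= 2) {
    cand <- select_candidates(as.matrix(beta)[dml_probes, , drop = FALSE],
                              samples,
                              q_threshold = config$q_threshold %||% 0.01)
    log_stage("candidate_selection", length(dml_probes), length(cand))
    if (length(cand) >= 1) {
      X <- t(as.matrix(beta)[cand, , drop = FALSE])
      y <- resolve_groups(beta, samples) == "IR"
      # rank candidates by single-feature AUC; keep the top four as the
      # independent single-CpG biomarker models
      single <- lapply(cand, function(pr)
        fit_logistic(stats::setNames(data.frame(X[, pr]), pr), y))
      names(single) <- cand
      top <- names(sort(vapply(single, function(m) -m$auc, numeric(1))))
      top <- utils::head(top, 4)
      models <- single[top]
      clin_cols <- intersect(c("fasting_glucose", "frs", "bmi"),
                             names(samples))
      for (cc in clin_cols) {
        v <- samples[[cc]][match(colnames(beta), samples$sample_id)]
        cf <- stats::setNames(data.frame(v, row.names = colnames(beta)), cc)
        models[[cc]] <- fit_logistic(cf, y)
      }
      if (length(cand) >= 2) {
        sw <- stepwise_select(as.data.frame(X[, utils::head(cand, 10),
                                              drop = FALSE]), y)
        if (length(sw$feature_names) > 0) models[["stepwise"]] <- sw
      }
      ranked <- compare_models(models)
      cut_rows <- lapply(names(models), function(nm) {
        m <- models[[nm]]
        if (length(m$coefficients) == 1) {
          bc <- beta_cutoff(m)
          data.frame(model = nm, feature = m$feature_names,
                     intercept = m$intercept,
                     coefficient = unname(m$coefficients), auc = m$auc,
                     cutoff = bc$cutoff, rule = bc$rule,
                     accuracy_ir = bc$accuracy_ir,
                     accuracy_is = bc$accuracy_is,
                     separation = m$separation, stringsAsFactors = FALSE)
        }
      })
      cuts <- do.call(rbind, cut_rows)
      write_tsv_fixed(cuts, file.path(out_dir, "models.tsv"))
      write_tsv_fixed(ranked, file.path(out_dir, "model_ranking.tsv"))
      report$prediction <- list(n_candidates = length(cand),
                                best_model = ranked$model[1],
                                best_auc = ranked$auc[1])
    }
  }

  # --- enrichment ---
  if (!is.null(inputs$annotation) && length(dml_probes) >= 1) {
    enr <- rbind(cbind(family = "gene_region",
                       region_enrichment(dml_probes, inputs$annotation,
                                         "gene_region")),
                 cbind(family = "island_relation",
                       region_enrichment(dml_probes, inputs$annotation,
                                         "island_relation")))
    write_tsv_fixed(enr, file.path(out_dir, "enrichment.tsv"))
    log_stage("enrichment", length(dml_probes), nrow(enr))
  }

  # --- clustering ---
  if (length(dml_probes) >= 2) {
    cl <- manhattan_cluster(as.matrix(beta)[dml_probes, , drop = FALSE])
    utils::write.table(data.frame(leaf_order = cl$leaf_order),
                       file.path(out_dir, "cluster_order.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log_stage("clustering", length(dml_probes), ncol(beta))
  }

  yaml::write_yaml(report, file.path(out_dir, "pipeline_report.yaml"))
  yaml::write_yaml(config, file.path(out_dir, "config_used.yaml"))
  invisible(report)
}
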