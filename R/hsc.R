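#' Classify methylation maintenance relative to the HSC state
#'
#' Compares a group mean beta to the hematopoietic stem cell (HSC) mean at
#' the same probe: the locus is "maintained" when the difference is
#' strictly within 0.10 in absolute beta, "hyper" when delta >= 0.10
#' (hypermethylated in the group vs HSCs) and "hypo" when delta <= -0.10.
#' The +/-0.10 boundary is assigned to the divergent classes.
#'
#' @param group_mean,hsc_mean beta means in \[0,1\] (vectorized).
#' @param threshold divergence threshold (beta units).
#' @return factor with levels hypo, maintained, hyper.
#' @export
maintenance_classify <- function(group_mean, hsc_mean, threshold = 0.10) {
  if (any(group_mean < 0 | group_mean > 1 | hsc_mean < 0 | hsc_mean > 1,
          na.rm = TRUE))
    stop("means must lie in [0,1]")
  delta <- group_mean - hsc_mean
  eps <- 1e-9  # keep a delta of exactly 0.10 divergent despite rounding
  cls <- ifelse(delta >= threshold - eps, "hyper",
                ifelse(delta <= -threshold + eps, "hypo", "maintained"))
  factor(cls, levels = c("hypo", "maintained", "hyper"))
}

#' Per-DML maintenance records for both groups
#'
#' Computes, for each requested probe, the IS and IR group means from the
#' cohort beta matrix, their differences from the HSC mean, and the
#' three-way maintenance class per group.
#'
#' @param beta cohort beta matrix.
#' @param groups "IS"/"IR" vector or sample table.
#' @param hsc_profile named vector of HSC mean beta (or a probes x samples
#'   HSC matrix, averaged rowwise).
#' @param probes probe ids to classify (default: all shared probes).
#' @param threshold divergence threshold.
#' @return data.frame: probe_id, delta_is_hsc, delta_ir_hsc, class_is,
#'   class_ir.
#' @export
maintenance_records <- function(beta, groups, hsc_profile, probes = NULL,
                                threshold = 0.10) {
  if (is.matrix(hsc_profile))
    hsc_profile <- rowMeans(hsc_profile, na.rm = TRUE)
  if (is.null(probes))
    probes <- intersect(rownames(beta), names(hsc_profile))
  miss <- setdiff(probes, intersect(rownames(beta), names(hsc_profile)))
  if (length(miss) > 0)
    stop("probes absent from cohort or HSC profile: ",
         paste(utils::head(miss, 3), collapse = ", "))
  g <- resolve_groups(beta, groups)
  X <- as.matrix(beta)[probes, , drop = FALSE]
  m_is <- rowMeans(X[, g == "IS", drop = FALSE], na.rm = TRUE)
  m_ir <- rowMeans(X[, g == "IR", drop = FALSE], na.rm = TRUE)
  hsc <- hsc_profile[probes]
  data.frame(probe_id = probes,
             delta_is_hsc = m_is - hsc,
             delta_ir_hsc = m_ir - hsc,
             class_is = maintenance_classify(m_is, hsc, threshold),
             class_ir = maintenance_classify(m_ir, hsc, threshold),
             stringsAsFactors = FALSE)
}

#' Summarize maintenance classifications
#'
#' Counts DMLs maintained in the IR group, in the IS group, and in both,
#' plus the per-group hypo/maintained/hyper breakdown with frequencies.
#'
#' @param records data.frame from [maintenance_records()].
#' @return list(n_maintained_ir, n_maintained_is, n_maintained_both,
#'   breakdown (class x group count matrix), fractions).
#' @export
maintenance_summary <- function(records) {
  m_ir <- records$class_ir == "maintained"
  m_is <- records$class_is == "maintained"
  breakdown <- cbind(IS = table(records$class_is),
                     IR = table(records$class_ir))
  list(n_maintained_ir = sum(m_ir),
       n_maintained_is = sum(m_is),
       n_maintained_both = sum(m_ir & m_is),
       breakdown = breakdown,
       fractions = breakdown / nrow(records))
}

#' PCA of DML methylation states
#'
#' Principal component analysis of samples (IS, IR and optionally HSC)
#' described by their beta values at the DML probes. Beta values are
#' centered but not scaled (they already share a common scale). A
#' deterministic sign convention is applied: each component's
#' largest-magnitude loading is made positive.
#'
#' @param beta probes x samples matrix restricted to the DML probes.
#' @param center center probes before decomposition (default TRUE).
#' @return list(scores (samples x PCs), loadings, var_explained).
#' @export
pca_dmls <- function(beta, center = TRUE) {
  X <- as.matrix(beta)
  if (nrow(X) < 2) stop("need >= 2 probes for PCA")
  if (ncol(X) < 3) stop("need >= 3 samples for PCA")
  if (anyNA(X)) stop("missing values must be completed before PCA")
  pc <- stats::prcomp(t(X), center = center, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2, flip, "*")
  pc$x <- sweep(pc$x, 2, flip, "*")
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation,
       var_explained = ve)
}
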