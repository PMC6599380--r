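#' Build a cell-type-discriminative CpG panel from reference methylomes
#'
#' Runs the permutation moderated-t procedure between two reference sample
#' sets and keeps probes significant at `p_threshold` with an absolute mean
#' difference strictly greater than `delta_threshold` (e.g. 0.30 for a
#' monocyte-vs-PBMC panel, 0.10 for monocyte subset panels). The panel
#' stores each type's mean beta profile at the panel probes.
#'
#' @param ref_a,ref_b probes x samples matrices for the two reference
#'   groups (same probe universe; >= 3 samples each recommended).
#' @param type_a,type_b names for the two cell types.
#' @param delta_threshold minimum absolute between-type mean difference
#'   (exclusive).
#' @param p_threshold permutation p threshold.
#' @param B permutation count or "exhaustive".
#' @param seed integer seed.
#' @param profile "mean" (default) or "median" reference summary.
#' @return object of class `reference_panel`: list(panel_probes, profiles
#'   (probes x 2 matrix), builder_params).
#' @export
build_panel <- function(ref_a, ref_b, type_a = "type_a", type_b = "type_b",
                        delta_threshold = 0.30, p_threshold = 0.05,
                        B = 1000, seed, profile = c("mean", "median")) {
  profile <- match.arg(profile)
  ref_a <- as.matrix(ref_a)
  ref_b <- as.matrix(ref_b)
  if (!identical(rownames(ref_a), rownames(ref_b)))
    stop("reference matrices must share one probe universe")
  X <- cbind(ref_a, ref_b)
  colnames(X) <- make.unique(c(colnames(ref_a), colnames(ref_b)))
  g <- rep(c("IS", "IR"), c(ncol(ref_a), ncol(ref_b)))  # internal labels
  pp <- permutation_pvalues(X, g, B = B, seed = seed)
  summ <- if (profile == "mean") rowMeans else
    function(m) apply(m, 1, stats::median)
  prof_a <- summ(ref_a)
  prof_b <- summ(ref_b)
  delta <- prof_b - prof_a
  keep <- !is.na(pp$p_perm) & pp$p_perm < p_threshold &
    abs(delta) > delta_threshold
  if (!any(keep))
    stop("empty panel: no probe passed |delta| > ", delta_threshold,
         " at P < ", p_threshold, "; consider a lower delta_threshold")
  probes <- rownames(X)[keep]
  profiles <- cbind(prof_a[keep], prof_b[keep])
  dimnames(profiles) <- list(probes, c(type_a, type_b))
  structure(list(panel_probes = probes, profiles = profiles,
                 builder_params = list(delta_threshold = delta_threshold,
                                       p_threshold = p_threshold, B = B)),
            class = "reference_panel")
}

#' Score a sample's identity against a reference panel
#'
#' Spearman correlation between a sample's beta values and the target
#' cell type's mean profile at the panel probes. Rank correlation makes the
#' score invariant to monotone distortions of the sample's measurements.
#' Panel probes missing from the sample are dropped pairwise; fewer than 20
#' usable probes is an error.
#'
#' @param sample_beta named numeric vector (or one-column matrix) of the
#'   sample's beta values.
#' @param panel a `reference_panel`.
#' @param target_type column of the panel profiles to score against.
#' @param method "spearman" (default) or "pearson".
#' @return correlation coefficient.
#' @export
purity_score <- function(sample_beta, panel, target_type,
                         method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (is.matrix(sample_beta)) sample_beta <- sample_beta[, 1]
  if (!target_type %in% colnames(panel$profiles))
    stop("unknown target_type '", target_type, "'")
  prof <- panel$profiles[, target_type]
  common <- intersect(names(prof), names(sample_beta))
  x <- sample_beta[common]
  y <- prof[common]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 20)
    stop("need >= 20 panel probes present in the sample (got ", sum(ok), ")")
  if (stats::sd(y[ok]) == 0 || stats::sd(x[ok]) == 0)
    stop("constant profile or sample: correlation undefined")
  stats::cor(x[ok], y[ok], method = method)
}

#' Purity scores for every sample of a beta matrix
#'
#' @param beta beta matrix (probes x samples).
#' @inheritParams purity_score
#' @return named numeric vector of per-sample scores.
#' @export
purity_scores <- function(beta, panel, target_type,
                          method = c("spearman", "pearson")) {
  method <- match.arg(method)
  X <- as.matrix(beta)
  vapply(colnames(X), function(s)
    purity_score(stats::setNames(X[, s], rownames(X)), panel, target_type,
                 method = method),
    numeric(1))
}

#' Compare identity scores between groups
#'
#' Two-sided Mann-Whitney test of per-sample purity scores between the IS
#' and IR groups (exact for small cohorts, normal approximation with tie
#' correction otherwise).
#'
#' @param scores named per-sample scores.
#' @param groups "IS"/"IR" vector aligned to `scores`, or a sample table.
#' @return list(U, p, method) from [mann_whitney()].
#' @export
compare_group_scores <- function(scores, groups) {
  if (is.data.frame(groups)) {
    g <- groups$group[match(names(scores), groups$sample_id)]
  } else {
    g <- as.character(groups)
  }
  if (sum(g == "IS") < 3 || sum(g == "IR") < 3)
    stop("need >= 3 scores per group")
  mann_whitney(scores[g == "IS"], scores[g == "IR"])
}
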