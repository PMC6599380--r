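# Null probe means are drawn from a mixture that mimics the bimodal
# methylome: mostly near-0 and near-1 probes with a midrange minority.
r_null_mean <- function(n) {
  comp <- sample.int(3L, n, replace = TRUE, prob = c(0.45, 0.45, 0.10))
  mu <- numeric(n)
  mu[comp == 1L] <- stats::rbeta(sum(comp == 1L), 0.5, 5)
  mu[comp == 2L] <- stats::rbeta(sum(comp == 2L), 5, 0.5)
  mu[comp == 3L] <- stats::runif(sum(comp == 3L), 0.2, 0.8)
  pmin(pmax(mu, 0.01), 0.99)
}

# Beta noise with common concentration kappa: beta ~ Beta(mu*k, (1-mu)*k),
# variance mu(1-mu)/(k+1) -- shrinks towards 0/1 like array beta values.
r_beta_noise <- function(mu, kappa) {
  stats::rbeta(length(mu), mu * kappa, (1 - mu) * kappa)
}

#' Simulate a 450K-like methylation cohort with ground truth
#'
#' Generates a probes x samples beta matrix for an insulin-sensitive (IS)
#' vs insulin-resistant (IR) cohort, a sample metadata table whose HOMA-IR
#' values reproduce the group labels under the standard stratification rule,
#' and a truth table marking planted differentially methylated loci and
#' SNP-like probes.
#'
#' Null probes share one mean per probe drawn from a bimodal-plus-midrange
#' mixture; per-sample values are Beta(mu*kappa, (1-mu)*kappa), giving the
#' heteroscedastic variance structure of array beta values. Planted probes
#' shift the IR mean by `delta` with random sign. SNP-like probes draw a
#' per-sample genotype level from {0.03, 0.5, 0.97} with Hardy-Weinberg
#' frequencies (allele frequency uniform on 0.2--0.8) plus small Beta noise,
#' producing the trimodal 0/50/100% pattern the SNP filter targets.
#'
#' Defaults reproduce the study conditions: 23 IS vs 14 IR samples.
#'
#' @param n_is,n_ir samples per group.
#' @param n_probes total probes.
#' @param n_dml planted differential probes.
#' @param delta absolute planted group difference (IR - IS), beta units.
#' @param precision Beta concentration kappa (larger = less noise).
#' @param snp_frac fraction of probes given a SNP-like trimodal pattern.
#' @param seed integer seed (mandatory; same seed gives identical output).
#' @return list with `beta` (beta_matrix), `samples` (data.frame),
#'   `truth` (data.frame with per-probe `is_planted_dml`, `true_delta`,
#'   `mu_is`, `mu_ir`, `is_snp_like`, `is_celltype_marker`,
#'   `hsc_maintained_in`).
#' @export
simulate_cohort <- function(n_is = 23, n_ir = 14, n_probes = 5000,
                            n_dml = 200, delta = 0.15, precision = 50,
                            snp_frac = 0.01, seed) {
  if (missing(seed)) stop("seed is required")
  if (delta < 0 || delta >= 0.98)
    stop("delta pushes means outside (0.01, 0.99)")
  n_snp <- round(snp_frac * n_probes)
  if (n_dml + n_snp > n_probes)
    stop("n_dml + snp-like count exceeds n_probes")
  withr::with_seed(seed, {
    probe_ids <- sprintf("cg%08d", seq_len(n_probes))
    sample_ids <- c(sprintf("IS%02d", seq_len(n_is)),
                    sprintf("IR%02d", seq_len(n_ir)))
    group <- rep(c("IS", "IR"), c(n_is, n_ir))

    planted <- sample.int(n_probes, n_dml)
    snp_like <- sample(setdiff(seq_len(n_probes), planted), n_snp)

    mu_is <- r_null_mean(n_probes)
    true_delta <- numeric(n_probes)
    if (n_dml > 0) {
      sgn <- sample(c(-1, 1), n_dml, replace = TRUE)
      mu <- mu_is[planted]
      bad <- which(mu + sgn * delta <= 0.01 | mu + sgn * delta >= 0.99)
      while (length(bad) > 0) {
        mu[bad] <- r_null_mean(length(bad))
        bad <- bad[mu[bad] + sgn[bad] * delta <= 0.01 |
                     mu[bad] + sgn[bad] * delta >= 0.99]
      }
      mu_is[planted] <- mu
      true_delta[planted] <- sgn * delta
    }
    mu_ir <- mu_is + true_delta

    n <- n_is + n_ir
    vals <- matrix(NA_real_, n_probes, n)
    vals[, group == "IS"] <- r_beta_noise(rep(mu_is, n_is), precision)
    vals[, group == "IR"] <- r_beta_noise(rep(mu_ir, n_ir), precision)

    if (n_snp > 0) {
      p <- stats::runif(n_snp, 0.2, 0.8)
      geno_levels <- c(0.03, 0.5, 0.97)
      for (k in seq_len(n_snp)) {
        g <- sample(geno_levels, n, replace = TRUE,
                    prob = c(p[k]^2, 2 * p[k] * (1 - p[k]), (1 - p[k])^2))
        vals[snp_like[k], ] <- r_beta_noise(g, 400)
      }
    }

    homa <- ifelse(group == "IR", stats::runif(n, 2.0, 7.0),
                   stats::runif(n, 0.5, 1.9))
    glucose <- pmin(pmax(stats::rnorm(n, 92, 8), 70), 125)
    insulin <- homa * 405 / glucose
    samples <- data.frame(
      sample_id = sample_ids,
      group = group,
      homa_ir = homa,
      fasting_glucose = glucose,
      fasting_insulin = insulin,
      bmi = stats::rnorm(n, 26 + 2 * (group == "IR"), 3.5),
      frs = pmax(stats::rnorm(n, 6 + 3 * (group == "IR"), 3), 0),
      mcp1 = stats::rlnorm(n, log(300 + 80 * (group == "IR")), 0.4),
      hiv_status = "positive",
      stringsAsFactors = FALSE
    )
    truth <- data.frame(
      probe_id = probe_ids,
      is_planted_dml = seq_len(n_probes) %in% planted,
      true_delta = true_delta,
      mu_is = mu_is,
      mu_ir = mu_ir,
      is_snp_like = seq_len(n_probes) %in% snp_like,
      is_celltype_marker = NA_character_,
      hsc_maintained_in = "",
      stringsAsFactors = FALSE
    )
    list(beta = beta_matrix(vals, probe_ids, sample_ids),
         samples = samples, truth = truth)
  })
}

#' Simulate reference methylomes (cell types and an HSC profile)
#'
#' Builds per-cell-type reference sample matrices over a shared probe
#' universe: each type receives `n_markers_per_type` marker probes at which
#' its mean differs from every other type by at least `marker_delta`, while
#' all types agree elsewhere. Also emits a hematopoietic stem cell (HSC)
#' profile; when `cohort` is supplied, HSC values at a configurable subset
#' of the cohort's planted DMLs equal the IR group mean (maintenance), the
#' IS mean, or the midpoint (maintained in both), and diverge by >= 0.10
#' from both groups elsewhere among the planted set.
#'
#' @param cell_types character vector of type names (unique).
#' @param n_markers_per_type markers per type.
#' @param marker_delta minimum between-type mean difference at markers
#'   (>= 0.10 required).
#' @param seed integer seed.
#' @param cohort optional output of [simulate_cohort()]; fixes the probe
#'   universe and enables the HSC maintenance scenario.
#' @param n_probes probe-universe size when no cohort is given.
#' @param n_ref_samples reference samples per type.
#' @param precision Beta concentration for reference samples.
#' @param hsc_maintained optional list/vector with counts `ir`, `is`,
#'   `both`: numbers of planted DMLs whose HSC methylation is maintained in
#'   the IR group, the IS group, or both (`both` is included in each total).
#' @param n_hsc_samples HSC samples to simulate around the HSC profile.
#' @return list with `ref_beta` (probes x reference samples), `ref_samples`
#'   (sample_id, cell_type), `profiles` (true per-type mean matrix),
#'   `hsc_profile` (named vector), `hsc_beta` (probes x HSC samples) and
#'   `truth` (cohort truth, or a fresh one, with `is_celltype_marker` and
#'   `hsc_maintained_in` filled in).
#' @export
simulate_references <- function(cell_types = c("monocyte", "pbmc"),
                                n_markers_per_type = 100,
                                marker_delta = 0.35, seed,
                                cohort = NULL, n_probes = 2000,
                                n_ref_samples = 6, precision = 200,
                                hsc_maintained = NULL, n_hsc_samples = 3) {
  if (missing(seed)) stop("seed is required")
  if (anyDuplicated(cell_types)) stop("duplicate cell-type names")
  if (marker_delta < 0.10)
    stop("marker_delta must be >= 0.10")
  withr::with_seed(seed, {
    if (is.null(cohort)) {
      probe_ids <- sprintf("cg%08d", seq_len(n_probes))
      truth <- data.frame(
        probe_id = probe_ids, is_planted_dml = FALSE, true_delta = 0,
        mu_is = r_null_mean(n_probes), mu_ir = NA_real_,
        is_snp_like = FALSE, is_celltype_marker = NA_character_,
        hsc_maintained_in = "", stringsAsFactors = FALSE)
      truth$mu_ir <- truth$mu_is
      base_mu <- truth$mu_is
    } else {
      truth <- cohort$truth
      probe_ids <- truth$probe_id
      n_probes <- length(probe_ids)
      base_mu <- truth$mu_is
    }

    k <- length(cell_types)
    free <- which(!truth$is_planted_dml & !truth$is_snp_like)
    need <- k * n_markers_per_type
    if (length(free) < need) stop("not enough non-planted probes for markers")
    marker_idx <- matrix(sample(free, need), ncol = k)

    # The first type keeps the shared baseline everywhere, so a cohort
    # generated from that baseline scores as this type (the enriched cell).
    # At type 1's markers every other type is shifted away; at type j's
    # (j > 1) markers only type j is shifted, so each marker set separates
    # its type from all others by >= marker_delta.
    profiles <- matrix(rep(base_mu, k), ncol = k,
                       dimnames = list(probe_ids, cell_types))
    shift_away <- function(mu) {
      up <- mu + marker_delta <= 0.97
      pmin(pmax(ifelse(up, mu + marker_delta, mu - marker_delta),
                0.01), 0.99)
    }
    for (j in seq_len(k)) {
      idx <- marker_idx[, j]
      cols <- if (j == 1) setdiff(seq_len(k), 1) else j
      profiles[idx, cols] <- shift_away(base_mu[idx])
      truth$is_celltype_marker[idx] <- cell_types[j]
    }

    ref_ids <- as.vector(t(outer(cell_types, seq_len(n_ref_samples),
                                 function(ct, i) sprintf("%s_ref%02d", ct, i))))
    ref_type <- rep(cell_types, each = n_ref_samples)
    ref_vals <- matrix(NA_real_, n_probes, length(ref_ids))
    for (s in seq_along(ref_ids)) {
      ref_vals[, s] <- r_beta_noise(profiles[, ref_type[s]], precision)
    }

    # HSC profile: baseline everywhere, overridden at planted DMLs per the
    # maintenance configuration
    hsc <- base_mu
    if (!is.null(cohort)) {
      planted <- which(truth$is_planted_dml)
      mid <- (truth$mu_is + truth$mu_ir) / 2
      if (!is.null(hsc_maintained)) {
        hm <- as.list(hsc_maintained)
        n_ir_m <- hm$ir; n_is_m <- hm$is; n_both <- hm$both
        if (n_both > min(n_ir_m, n_is_m))
          stop("'both' count cannot exceed the per-group totals")
        n_assign <- n_ir_m + n_is_m - n_both
        if (n_assign > length(planted))
          stop("maintenance counts exceed the planted DML count")
        pick <- sample(planted, n_assign)
        both_idx <- pick[seq_len(n_both)]
        ir_only <- pick[seq_len(n_ir_m - n_both) + n_both]
        is_only <- pick[seq(length.out = n_is_m - n_both,
                            from = n_ir_m + 1)]
        rest <- setdiff(planted, pick)
        hsc[both_idx] <- mid[both_idx]
        hsc[ir_only] <- truth$mu_ir[ir_only]
        hsc[is_only] <- truth$mu_is[is_only]
        truth$hsc_maintained_in[both_idx] <- "both"
        truth$hsc_maintained_in[ir_only] <- "IR"
        truth$hsc_maintained_in[is_only] <- "IS"
      } else {
        rest <- planted
      }
      # remaining planted probes diverge from both groups by >= 0.10
      div <- ifelse(mid[rest] + 0.2 <= 0.97, mid[rest] + 0.2, mid[rest] - 0.2)
      hsc[rest] <- pmin(pmax(div, 0.01), 0.99)
    }
    names(hsc) <- probe_ids

    hsc_ids <- sprintf("HSC%02d", seq_len(n_hsc_samples))
    hsc_vals <- matrix(r_beta_noise(rep(hsc, n_hsc_samples), precision),
                       n_probes, n_hsc_samples)

    list(ref_beta = beta_matrix(ref_vals, probe_ids, ref_ids),
         ref_samples = data.frame(sample_id = ref_ids, cell_type = ref_type,
                                  stringsAsFactors = FALSE),
         profiles = profiles,
         hsc_profile = hsc,
         hsc_beta = beta_matrix(hsc_vals, probe_ids, hsc_ids),
         truth = truth)
  })
}
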