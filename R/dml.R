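# Resolve a grouping argument: either a character/factor vector aligned to
# the columns of the beta matrix, or a sample table with sample_id + group.
resolve_groups <- function(beta, groups) {
  if (is.data.frame(groups)) {
    if (!all(c("sample_id", "group") %in% names(groups)))
      stop("sample table must have sample_id and group columns")
    idx <- match(colnames(beta), groups$sample_id)
    if (anyNA(idx)) stop("samples missing from metadata: ",
                         paste(colnames(beta)[is.na(idx)], collapse = ", "))
    g <- groups$group[idx]
  } else {
    g <- as.character(groups)
    if (length(g) != ncol(beta))
      stop("group vector length must match sample count")
  }
  if (!all(g %in% c("IS", "IR")))
    stop("groups must be 'IS' or 'IR'")
  g
}

# Per-probe two-group summary for given column index sets; NA-aware.
# Returns means, pooled variance and residual df per probe.
two_group_stats <- function(X, idx1, idx2) {
  sub_stats <- function(idx) {
    Xs <- X[, idx, drop = FALSE]
    if (anyNA(Xs)) {
      M <- !is.na(Xs)
      X0 <- Xs
      X0[!M] <- 0
      n <- rowSums(M)
      s <- rowSums(X0)
      m <- ifelse(n > 0, s / n, NA_real_)
      ss <- rowSums(X0^2) - n * m^2
    } else {
      n <- rep(length(idx), nrow(Xs))
      m <- rowMeans(Xs)
      ss <- rowSums(Xs^2) - n * m^2
    }
    list(n = n, m = m, ss = pmax(ss, 0))
  }
  a <- sub_stats(idx1)
  b <- sub_stats(idx2)
  d <- a$n + b$n - 2
  s_sq <- ifelse(d > 0, (a$ss + b$ss) / d, NA_real_)
  list(n1 = a$n, n2 = b$n, mean1 = a$m, mean2 = b$m,
       delta = b$m - a$m, s_sq = s_sq, d = d)
}

#' Per-probe group means, delta and pooled variance
#'
#' Computes, for every probe, the IS and IR group means, their difference
#' delta = mean(IR) - mean(IS), the pooled two-sample variance and the
#' residual degrees of freedom (n1 + n2 - 2, adjusted probewise for missing
#' values). Probes with fewer than 2 usable values in either group are
#' marked unusable.
#'
#' @param beta beta matrix (probes x samples).
#' @param groups "IS"/"IR" vector aligned to columns, or a sample table.
#' @return data.frame with columns probe_id, n_is, n_ir, mean_is, mean_ir,
#'   delta, s_sq, d, usable.
#' @export
group_stats <- function(beta, groups) {
  g <- resolve_groups(beta, groups)
  if (sum(g == "IS") < 2 || sum(g == "IR") < 2)
    stop("need at least 2 samples per group")
  st <- two_group_stats(beta, which(g == "IS"), which(g == "IR"))
  usable <- st$n1 >= 2 & st$n2 >= 2
  if (any(!usable))
    message(sum(!usable), " probe(s) with <2 usable values in a group ",
            "marked unusable")
  data.frame(probe_id = rownames(beta), n_is = st$n1, n_ir = st$n2,
             mean_is = st$mean1, mean_ir = st$mean2, delta = st$delta,
             s_sq = st$s_sq, d = st$d, usable = usable,
             stringsAsFactors = FALSE)
}

# Newton inversion of the trigamma function, for matching the spread of
# log sample variances to a scaled inverse-chi-square prior.
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

#' Estimate empirical-Bayes variance-shrinkage hyperparameters
#'
#' Moment-matches the distribution of log sample variances against a scaled
#' inverse-chi-square prior with d0 degrees of freedom and scale s0^2: the
#' excess spread of log(s^2) beyond what chi-square sampling noise at d
#' residual df explains determines d0 (via trigamma inversion), and the
#' location determines s0^2. When probe variances are (near-)constant d0 is
#' capped at 1e6, in which limit the moderated t reduces to the ordinary
#' pooled-variance t.
#'
#' @param s_sq per-probe pooled variances (beta^2 units).
#' @param d residual degrees of freedom (scalar or per probe).
#' @param d0_cap cap for the prior degrees of freedom.
#' @return object of class `shrinkage_estimate`: list(d0, s0_sq, d).
#' @export
estimate_shrinkage <- function(s_sq, d, d0_cap = 1e6) {
  if (length(d) == 1) d <- rep(d, length(s_sq))
  ok <- is.finite(s_sq) & s_sq > 0 & d > 0
  if (all(!is.finite(s_sq) | s_sq == 0, na.rm = TRUE) && sum(ok) == 0)
    stop("all variances are zero or missing: degenerate input")
  if (sum(ok) < 50)
    stop("need >= 50 probes with finite positive variance (got ", sum(ok), ")")
  z <- log(s_sq[ok])
  dd <- d[ok]
  e <- z - digamma(dd / 2) + log(dd / 2)
  ebar <- mean(e)
  excess <- mean((e - ebar)^2 * length(e) / (length(e) - 1)) -
    mean(trigamma(dd / 2))
  if (excess > 1e-8) {
    d0 <- 2 * trigamma_inverse(excess)
    if (d0 > d0_cap) d0 <- d0_cap
    s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # (near-)constant variances: infinite-prior limit, where the moderated
    # t must reduce to the ordinary t with the common variance
    d0 <- d0_cap
    s0_sq <- mean(s_sq[ok])
  }
  structure(list(d0 = d0, s0_sq = s0_sq, d = d),
            class = "shrinkage_estimate")
}

#' Moderated t statistic
#'
#' Shrinks each probe's pooled variance towards the prior:
#' s_tilde^2 = (d0 s0^2 + d s^2) / (d0 + d), then
#' t_mod = delta / sqrt(s_tilde^2 (1/n1 + 1/n2)). With d0 at the cap this
#' equals the ordinary two-sample t statistic.
#'
#' @param stats data.frame from [group_stats()].
#' @param shrinkage a `shrinkage_estimate`.
#' @return `stats` with added columns s_tilde_sq and t_mod.
#' @export
moderated_t <- function(stats, shrinkage) {
  st <- compute_tmod(stats$delta, stats$s_sq, stats$d,
                     stats$n_is, stats$n_ir, shrinkage$d0, shrinkage$s0_sq)
  stats$s_tilde_sq <- st$s_tilde_sq
  stats$t_mod <- st$t_mod
  stats
}

compute_tmod <- function(delta, s_sq, d, n1, n2, d0, s0_sq) {
  s_tilde_sq <- (d0 * s0_sq + d * s_sq) / (d0 + d)
  se <- sqrt(s_tilde_sq * (1 / n1 + 1 / n2))
  t_mod <- ifelse(se > 0, delta / se, ifelse(delta == 0, 0, NA_real_))
  list(s_tilde_sq = s_tilde_sq, t_mod = t_mod)
}

# Observed + permuted moderated-t machinery shared by permutation_pvalues
# and build_panel. Returns |t| for the observed labelling and a P x B matrix
# of permuted |t|.
perm_tmod <- function(X, g, B, seed, reestimate = TRUE, d0_cap = 1e6) {
  idx1 <- which(g == "IS")
  idx2 <- which(g == "IR")
  n <- ncol(X)
  n2 <- length(idx2)
  # with too few probes to estimate a prior, use the unshrunken pooled t
  # (d0 = 0 makes s_tilde^2 = s^2)
  maybe_shrink <- function(st) {
    if (sum(is.finite(st$s_sq) & st$s_sq > 0) >= 50) {
      estimate_shrinkage(st$s_sq, st$d, d0_cap = d0_cap)
    } else {
      structure(list(d0 = 0, s0_sq = 1, d = st$d),
                class = "shrinkage_estimate")
    }
  }
  obs_st <- two_group_stats(X, idx1, idx2)
  obs_shr <- maybe_shrink(obs_st)
  obs_t <- compute_tmod(obs_st$delta, obs_st$s_sq, obs_st$d, obs_st$n1,
                        obs_st$n2, obs_shr$d0, obs_shr$s0_sq)$t_mod

  one_perm <- function(cols2) {
    cols1 <- setdiff(seq_len(n), cols2)
    st <- two_group_stats(X, cols1, cols2)
    if (reestimate) {
      shr <- maybe_shrink(st)
    } else {
      shr <- obs_shr
    }
    abs(compute_tmod(st$delta, st$s_sq, st$d, st$n1, st$n2,
                     shr$d0, shr$s0_sq)$t_mod)
  }

  if (identical(B, "exhaustive")) {
    if (n > 10)
      stop("exhaustive enumeration limited to <= 10 samples ",
           "(combinatorial blow-up)")
    combos <- utils::combn(n, n2)
    null_t <- apply(combos, 2, one_perm)
    n_perm <- ncol(combos)
  } else {
    B <- as.integer(B)
    if (B < 100) stop("B must be >= 100 (or 'exhaustive' for <= 10 samples)")
    null_t <- withr::with_seed(seed, {
      vapply(seq_len(B), function(b) one_perm(sample.int(n, n2)),
             numeric(nrow(X)))
    })
    n_perm <- B
  }
  if (!is.matrix(null_t)) null_t <- matrix(null_t, nrow = nrow(X))
  list(obs_t = obs_t, null_t = null_t, n_perm = n_perm,
       shrinkage = obs_shr, stats = obs_st)
}

#' Permutation p-values and permutation FDR for moderated t
#'
#' For each of B random group-label permutations (or all distinct
#' labellings when `B = "exhaustive"`, <= 10 samples) the full pipeline --
#' group statistics, shrinkage hyperparameter estimation, moderated t -- is
#' recomputed, preserving exchangeability. Two-sided empirical p-values use
#' the add-one correction: with the pooled null (default) the reference
#' distribution is all B x P permuted |t| values, giving resolution beyond
#' 1/B; per-probe mode uses each probe's own B values. The permutation FDR
#' q is, at each observed |t| threshold, the mean permuted exceedance count
#' over the observed exceedance count, monotonized and capped at 1.
#'
#' @param beta beta matrix.
#' @param groups "IS"/"IR" vector or sample table.
#' @param B permutation count (>= 100) or "exhaustive".
#' @param seed integer seed (required unless exhaustive).
#' @param pool pool the null across probes (default TRUE).
#' @param reestimate re-estimate shrinkage within each permutation
#'   (default TRUE; FALSE reuses the observed-data estimate for speed).
#' @return data.frame with probe_id, t_obs, p_perm, q_perm.
#' @export
permutation_pvalues <- function(beta, groups, B = 1000, seed,
                                pool = TRUE, reestimate = TRUE) {
  g <- resolve_groups(beta, groups)
  if (!identical(B, "exhaustive") && missing(seed))
    stop("seed is required")
  if (identical(B, "exhaustive") && missing(seed)) seed <- 0L
  pt <- perm_tmod(as.matrix(beta), g, B, seed, reestimate = reestimate)
  abs_obs <- abs(pt$obs_t)
  eps <- 1e-9
  if (pool) {
    null_all <- sort(as.vector(pt$null_t))
    L <- length(null_all)
    ge <- L - findInterval(abs_obs - eps, null_all)
    p <- (1 + ge) / (1 + L)
  } else {
    ge <- rowSums(pt$null_t >= matrix(abs_obs, nrow(pt$null_t),
                                      ncol(pt$null_t)) - eps)
    p <- (1 + ge) / (1 + pt$n_perm)
  }
  # permutation FDR: expected null exceedances per permutation over observed
  # exceedances at each threshold, monotone in |t|
  null_sorted <- sort(as.vector(pt$null_t))
  L <- length(null_sorted)
  ord <- order(abs_obs, decreasing = TRUE, na.last = TRUE)
  q <- rep(NA_real_, length(abs_obs))
  t_desc <- abs_obs[ord]
  fin <- is.finite(t_desc)
  n_null_ge <- L - findInterval(t_desc[fin] - eps, null_sorted)
  fp_hat <- n_null_ge / pt$n_perm
  r_obs <- seq_along(n_null_ge)
  q_raw <- pmin(fp_hat / r_obs, 1)
  q_mono <- rev(cummin(rev(q_raw)))
  q[ord[fin]] <- q_mono
  data.frame(probe_id = rownames(beta), t_obs = pt$obs_t, p_perm = p,
             q_perm = q, stringsAsFactors = FALSE)
}

#' Call differentially methylated loci
#'
#' A probe is a DML iff its permutation p-value is below `p_threshold`, its
#' absolute group difference is at least `delta_threshold` (inclusive
#' boundary), and no exclusion flag (SNP pattern, known SNP, confounder
#' overlap) is set.
#'
#' @param records data.frame with at least probe_id, delta, p_perm;
#'   optional logical columns flag_snp_pattern, flag_known_snp,
#'   flag_confound (missing flags are treated as all-FALSE).
#' @param p_threshold pointwise permutation p threshold (in (0,1)).
#' @param delta_threshold absolute delta threshold (in (0,1)).
#' @return `records` with added logical `is_dml`.
#' @seealso [dml_summary()] for stagewise counts and the hypo/hyper split.
#' @export
call_dmls <- function(records, p_threshold = 0.05, delta_threshold = 0.10) {
  if (p_threshold <= 0 || p_threshold >= 1 ||
      delta_threshold <= 0 || delta_threshold >= 1)
    stop("thresholds must lie in (0,1)")
  for (fl in c("flag_snp_pattern", "flag_known_snp", "flag_confound")) {
    if (!fl %in% names(records)) records[[fl]] <- FALSE
  }
  flagged <- records$flag_snp_pattern | records$flag_known_snp |
    records$flag_confound
  records$is_dml <- !is.na(records$p_perm) & !is.na(records$delta) &
    records$p_perm < p_threshold &
    abs(records$delta) >= delta_threshold & !flagged
  attr(records, "thresholds") <- c(p = p_threshold, delta = delta_threshold)
  records
}

#' Stagewise DML counts and direction-of-change summary
#'
#' Reports the number of probes passing each successive filter (permutation
#' p, then |delta|, then exclusion flags) and, among the final DML set, the
#' hypo-/hypermethylated split (delta < 0 means hypomethylated in IR
#' relative to IS) with the hypomethylated percentage rounded to one
#' decimal.
#'
#' @param records output of [call_dmls()].
#' @param p_threshold,delta_threshold thresholds (default: those recorded
#'   by [call_dmls()]).
#' @return list of counts: n_probes, n_pass_p, n_pass_p_delta, n_flagged,
#'   n_dml, n_hypo, n_hyper, pct_hypo.
#' @export
dml_summary <- function(records, p_threshold = NULL, delta_threshold = NULL) {
  thr <- attr(records, "thresholds")
  if (is.null(p_threshold)) p_threshold <- unname(thr["p"])
  if (is.null(delta_threshold)) delta_threshold <- unname(thr["delta"])
  pass_p <- !is.na(records$p_perm) & records$p_perm < p_threshold
  pass_pd <- pass_p & abs(records$delta) >= delta_threshold
  flagged <- records$flag_snp_pattern | records$flag_known_snp |
    records$flag_confound
  dml <- records$is_dml
  n_hypo <- sum(dml & records$delta < 0)
  n_hyper <- sum(dml & records$delta > 0)
  list(n_probes = nrow(records),
       n_pass_p = sum(pass_p),
       n_pass_p_delta = sum(pass_pd),
       n_flagged = sum(pass_pd & flagged),
       n_dml = sum(dml),
       n_hypo = n_hypo,
       n_hyper = n_hyper,
       pct_hypo = if (sum(dml) > 0) round(100 * n_hypo / sum(dml), 1)
                  else NA_real_)
}
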