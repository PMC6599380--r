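test_that("group_stats matches hand arithmetic on a 3+3 fixture", {
  X <- beta_matrix(matrix(c(0.70, 0.68, 0.69, 0.60, 0.58, 0.59), 1),
                   "cg01", paste0("S", 1:6))
  g <- rep(c("IS", "IR"), each = 3)
  st <- group_stats(X, g)
  x <- c(0.70, 0.68, 0.69); y <- c(0.60, 0.58, 0.59)
  expect_equal(st$mean_is, mean(x))
  expect_equal(st$mean_ir, mean(y))
  expect_equal(st$delta, mean(y) - mean(x))
  expect_equal(st$s_sq, (2 * var(x) + 2 * var(y)) / 4)
  expect_equal(st$d, 4)
  # a probe with IS mean 0.69 and IR mean 0.59 has delta -0.10
  expect_equal(round(st$delta, 2), -0.10)
})

test_that("group_stats handles missing values probewise", {
  vals <- matrix(runif(20, 0.3, 0.7), 4, 5)
  vals[1, 1] <- NA
  vals[2, 4:5] <- NA  # <2 usable IR values
  X <- beta_matrix(vals, sprintf("cg%02d", 1:4), sprintf("S%d", 1:5))
  g <- c("IS", "IS", "IS", "IR", "IR")
  expect_message(st <- group_stats(X, g), "unusable")
  expect_false(st$usable[2])
  expect_true(st$usable[1])
  expect_equal(st$mean_is[1], mean(vals[1, 2:3]))
  expect_equal(st$d[1], 2)  # one IS value lost to NA
})

test_that("shrinkage recovers a known scaled inverse-chi-square prior", {
  set.seed(101)
  d0 <- 4; s0_sq <- 0.01; d <- 35; P <- 10000
  sigma2 <- d0 * s0_sq / rchisq(P, d0)
  s_sq <- sigma2 * rchisq(P, d) / d
  sh <- estimate_shrinkage(s_sq, d)
  expect_gt(sh$d0, 3); expect_lt(sh$d0, 5)
  expect_lt(abs(sh$s0_sq - s0_sq) / s0_sq, 0.20)
  # independent cross-check against limma's hyperparameter estimator
  sq <- limma::squeezeVar(s_sq, df = d)
  expect_equal(sh$d0, sq$df.prior, tolerance = 0.05)
  expect_equal(sh$s0_sq, sq$var.prior, tolerance = 0.05)
})

test_that("constant variances hit the d0 cap and give the ordinary t", {
  s_sq <- rep(0.02, 100)
  sh <- estimate_shrinkage(s_sq, 35)
  expect_equal(sh$d0, 1e6)
  st <- data.frame(probe_id = "p", n_is = 3, n_ir = 3, mean_is = 0.5,
                   mean_ir = 0.6, delta = 0.1, s_sq = 0.02, d = 4)
  mt <- moderated_t(st, sh)
  expect_equal(mt$t_mod, 0.1 / sqrt(0.02 * (1 / 3 + 1 / 3)), tolerance = 1e-3)
  expect_error(estimate_shrinkage(c(0.1, 0.2), 4), ">= 50 probes")
  expect_error(estimate_shrinkage(rep(0, 100), 4), "degenerate|>= 50")
})

test_that("moderated t follows the shrinkage formula and its limits", {
  sh <- structure(list(d0 = 4, s0_sq = 0.01, d = 10),
                  class = "shrinkage_estimate")
  st <- data.frame(probe_id = "p", n_is = 5, n_ir = 7, mean_is = 0.4,
                   mean_ir = 0.55, delta = 0.15, s_sq = 0.03, d = 10)
  mt <- moderated_t(st, sh)
  s_tilde <- (4 * 0.01 + 10 * 0.03) / 14
  expect_equal(mt$s_tilde_sq, s_tilde)
  expect_equal(mt$t_mod, 0.15 / sqrt(s_tilde * (1 / 5 + 1 / 7)))
  st$delta <- 0
  expect_equal(moderated_t(st, sh)$t_mod, 0)
})

test_that("exhaustive permutation equals independent label enumeration", {
  set.seed(5)
  for (rep_i in 1:3) {
    X <- beta_matrix(matrix(runif(8 * 8, 0.2, 0.8), 8),
                     sprintf("cg%02d", 1:8), sprintf("S%d", 1:8))
    g <- rep(c("IS", "IR"), each = 4)
    pp <- permutation_pvalues(X, g, B = "exhaustive", pool = FALSE)
    oracle <- apply(as.matrix(X), 1, oracle_exhaustive_p, g = g)
    expect_equal(pp$p_perm, unname(oracle))
  }
})

test_that("the largest observed statistic gets the minimal exhaustive p", {
  # one clearly separated probe among noise: among the 70 label
  # assignments of a 4v4 design, only the observed assignment and its
  # group-swapped complement (same |t|) reach the observed statistic, so
  # the add-one exhaustive p is (1+2)/(1+70) -- the enumeration oracle
  # computed the same value
  set.seed(2)
  vals <- rbind(c(0.10, 0.11, 0.12, 0.11, 0.80, 0.82, 0.81, 0.83),
                matrix(runif(7 * 8, 0.4, 0.6), 7))
  X <- beta_matrix(vals, sprintf("cg%02d", 1:8), sprintf("S%d", 1:8))
  g <- rep(c("IS", "IR"), each = 4)
  pp <- permutation_pvalues(X, g, B = "exhaustive", pool = FALSE)
  expect_equal(pp$p_perm[1], 3 / 71)
  expect_equal(pp$p_perm[1], oracle_exhaustive_p(as.matrix(X)[1, ], g))
  big <- beta_matrix(matrix(runif(2 * 12, 0.2, 0.8), 2),
                     c("cg01", "cg02"), sprintf("S%02d", 1:12))
  expect_error(permutation_pvalues(big, rep(c("IS", "IR"), 6),
                                   B = "exhaustive"), "exhaustive")
})

test_that("identical groups yield p of 1 and permutation p-values are valid", {
  vals <- matrix(rep(runif(20, 0.2, 0.8), 8), 20)
  X <- beta_matrix(vals, sprintf("cg%02d", 1:20), sprintf("S%d", 1:8))
  g <- rep(c("IS", "IR"), each = 4)
  pp <- permutation_pvalues(X, g, B = "exhaustive", pool = FALSE)
  expect_true(all(pp$p_perm == 1))
  sim <- simulate_cohort(n_probes = 200, n_dml = 10, seed = 3)
  pp2 <- permutation_pvalues(sim$beta, sim$samples, B = 100, seed = 2)
  expect_true(all(pp2$p_perm > 0 & pp2$p_perm <= 1))
  expect_true(all(pp2$q_perm >= 0 & pp2$q_perm <= 1, na.rm = TRUE))
  expect_error(permutation_pvalues(sim$beta, sim$samples, B = 50, seed = 1),
               ">= 100")
})

test_that("|t_mod| is monotone in |delta| at fixed variance", {
  sh <- structure(list(d0 = 10, s0_sq = 0.01, d = 20),
                  class = "shrinkage_estimate")
  deltas <- seq(0, 0.5, by = 0.05)
  st <- data.frame(probe_id = paste0("p", seq_along(deltas)), n_is = 10,
                   n_ir = 10, mean_is = 0.3, mean_ir = 0.3 + deltas,
                   delta = deltas, s_sq = 0.02, d = 20)
  tm <- abs(moderated_t(st, sh)$t_mod)
  expect_true(all(diff(tm) >= 0))
})

test_that("call_dmls applies the inclusive boundary and flag rules", {
  rec <- data.frame(probe_id = c("a", "b", "c", "d", "e"),
                    delta = c(-0.10, 0.099, 0.25, -0.30, 0.20),
                    p_perm = c(0.01, 0.01, 0.20, 0.01, 0.04))
  rec$flag_known_snp <- c(FALSE, FALSE, FALSE, TRUE, FALSE)
  out <- call_dmls(rec)
  # |delta| = 0.10 at p < 0.05 is a DML (inclusive boundary)
  expect_true(out$is_dml[out$probe_id == "a"])
  expect_false(out$is_dml[out$probe_id == "b"])  # effect too small
  expect_false(out$is_dml[out$probe_id == "c"])  # not significant
  expect_false(out$is_dml[out$probe_id == "d"])  # flagged
  expect_true(out$is_dml[out$probe_id == "e"])
  expect_error(call_dmls(rec, p_threshold = 0), "thresholds")
})

test_that("the DML set shrinks as thresholds tighten", {
  sim <- simulate_cohort(n_probes = 800, n_dml = 60, seed = 13)
  gs <- group_stats(sim$beta, sim$samples)
  pp <- permutation_pvalues(sim$beta, sim$samples, B = 100, seed = 1)
  rec <- merge(gs, pp, by = "probe_id")
  loose <- sum(call_dmls(rec, 0.05, 0.10)$is_dml)
  tight_p <- sum(call_dmls(rec, 0.01, 0.10)$is_dml)
  tight_d <- sum(call_dmls(rec, 0.05, 0.14)$is_dml)
  expect_lte(tight_p, loose)
  expect_lte(tight_d, loose)
})

test_that("summary reports the hypomethylated fraction of the DML set", {
  rec <- data.frame(probe_id = sprintf("cg%03d", 1:123),
                    delta = c(rep(-0.15, 106), rep(0.15, 17)),
                    p_perm = 0.001)
  out <- call_dmls(rec)
  s <- dml_summary(out)
  expect_equal(s$n_dml, 123)
  expect_equal(s$n_hypo, 106)
  expect_equal(s$pct_hypo, 86.2)
})
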