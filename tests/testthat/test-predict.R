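test_that("candidate selection finds separable probes and respects q=1", {
  set.seed(51)
  n <- 20
  g <- rep(c("IS", "IR"), each = 10)
  vals <- matrix(runif(11 * n, 0.3, 0.7), 11, n)
  vals[1, g == "IR"] <- runif(10, 0.05, 0.15)  # fully separated probe
  X <- beta_matrix(vals, sprintf("cg%02d", 1:11), paste0("S", 1:n))
  sel <- select_candidates(X, g, q_threshold = 0.01)
  expect_true("cg01" %in% sel)
  # BH oracle by hand: per-probe exact rank-test p-values, adjusted
  p <- apply(vals, 1, function(r) oracle_mw_p(r[g == "IS"], r[g == "IR"]))
  expect_setequal(sel, rownames(X)[p.adjust(p, "BH") < 0.01])
  expect_setequal(select_candidates(X, g, q_threshold = 1), rownames(X))
})

test_that("an all-null probe set yields no candidates", {
  sim <- simulate_cohort(n_probes = 100, n_dml = 0, snp_frac = 0, seed = 52)
  sel <- select_candidates(sim$beta, sim$samples, q_threshold = 0.01)
  expect_length(sel, 0)
})

test_that("perfect separation is flagged and scores AUC 1", {
  x <- c(rnorm(10, 0), rnorm(10, 10))
  y <- rep(c(FALSE, TRUE), each = 10)
  m <- fit_logistic(data.frame(x = x), y)
  expect_true(m$separation)
  expect_equal(m$auc, 1.0)
  expect_error(fit_logistic(data.frame(x = rep(1, 20)), y), "constant")
})

test_that("AUC is near 0.5 when the outcome is independent of the feature", {
  set.seed(53)
  m <- fit_logistic(data.frame(x = rnorm(2000)),
                    rep(c(TRUE, FALSE), 1000))
  expect_lt(abs(m$auc - 0.5), 0.05)
})

test_that("known coefficients are recovered within 15% at n = 500", {
  set.seed(54)
  b0 <- 6.1; b1 <- -10
  x <- runif(500, 0.3, 0.9)
  y <- runif(500) < 1 / (1 + exp(-(b0 + b1 * x)))
  m <- fit_logistic(data.frame(beta = x), y)
  expect_lt(abs(m$intercept - b0) / abs(b0), 0.15)
  expect_lt(abs(unname(m$coefficients) - b1) / abs(b1), 0.15)
  # independent oracle: the AUC of the fitted scores equals pROC's
  expect_equal(m$auc,
               as.numeric(pROC::auc(pROC::roc(y, m$fitted_prob,
                                              quiet = TRUE, direction = "<"))))
})

test_that("the beta cutoff is the probability-0.5 point with a 'less' rule", {
  m <- structure(list(feature_names = "cpg", intercept = 6.1,
                      coefficients = c(cpg = -10),
                      features = data.frame(cpg = c(0.5, 0.55, 0.58, 0.7,
                                                    0.72, 0.8)),
                      outcome = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)),
                 class = "logistic_model")
  bc <- beta_cutoff(m)
  expect_equal(bc$cutoff, 0.61)
  expect_equal(bc$rule, "less")
  expect_equal(bc$accuracy_ir, 1.0)
  expect_equal(bc$accuracy_is, 1.0)
  # fitted probability at the cutoff is exactly one half
  expect_equal(1 / (1 + exp(-(6.1 - 10 * bc$cutoff))), 0.5, tolerance = 1e-12)
})

test_that("per-class accuracy uses class-size denominators", {
  # 9 of 14 IR below the cutoff and 21 of 23 IS above it
  x <- c(seq(0.40, 0.56, length.out = 9), seq(0.62, 0.70, length.out = 5),
         seq(0.62, 0.80, length.out = 21), c(0.50, 0.55))
  y <- rep(c(TRUE, FALSE), c(14, 23))
  m <- structure(list(feature_names = "cpg", intercept = 6.1,
                      coefficients = c(cpg = -10),
                      features = data.frame(cpg = x), outcome = y),
                 class = "logistic_model")
  bc <- beta_cutoff(m)
  expect_equal(bc$accuracy_ir, 9 / 14)
  expect_equal(round(100 * bc$accuracy_ir, 1), 64.3)
  expect_equal(bc$accuracy_is, 21 / 23)
  expect_error(beta_cutoff(fit_logistic(data.frame(a = rnorm(10),
                                                   b = rnorm(10)),
                                        rep(c(TRUE, FALSE), 5))),
               "single-feature")
})

test_that("AUC is invariant under monotone transforms of the feature", {
  set.seed(55)
  x <- runif(60, 0.2, 0.8)
  y <- runif(60) < 1 / (1 + exp(-(4 - 8 * x)))
  a1 <- fit_logistic(data.frame(x = x), y)$auc
  a2 <- fit_logistic(data.frame(x = exp(3 * x)), y)$auc
  expect_equal(a1, a2)
})

test_that("forward stepwise picks the informative feature and one of a collinear pair", {
  set.seed(56)
  n <- 120
  inform <- runif(n, 0.2, 0.8)
  y <- runif(n) < 1 / (1 + exp(-(5 - 10 * inform)))
  X <- data.frame(inform = inform,
                  n1 = runif(n), n2 = runif(n), n3 = runif(n),
                  n4 = runif(n), n5 = runif(n))
  sw <- stepwise_select(X, y)
  expect_equal(attr(sw, "path")$added[2], "inform")
  # exhaustive single-feature AIC comparison agrees on the first entry
  aics <- vapply(names(X), function(f)
    AIC(glm(y ~ ., data = data.frame(y = y, X[, f, drop = FALSE]),
            family = binomial())), numeric(1))
  expect_equal(names(which.min(aics)), "inform")
  # duplicated informative feature: exactly one copy enters
  X2 <- data.frame(a = inform, b = inform, noise = runif(n))
  sw2 <- stepwise_select(X2, y)
  expect_equal(sum(sw2$feature_names %in% c("a", "b")), 1)
})

test_that("exactly balanced features give an intercept-only stepwise model", {
  # features whose cross-tabulation with the outcome is perfectly balanced
  # carry zero association, so adding any of them costs AIC
  y <- rep(c(TRUE, FALSE), each = 30)
  X <- data.frame(a = rep(c(0, 1), 30),
                  b = rep(c(0, 0, 1, 1), 15))
  sw <- stepwise_select(X, y)
  expect_length(sw$feature_names, 0)
  expect_equal(sw$auc, 0.5)
  expect_equal(attr(sw, "path")$added, "(intercept)")
})

test_that("model comparison ranks by AUC with ties broken by parsimony", {
  set.seed(58)
  n <- 40
  x <- runif(n, 0.2, 0.8)
  y <- runif(n) < 1 / (1 + exp(-(5 - 10 * x)))
  X <- data.frame(x = x, noise = runif(n), row.names = paste0("S", 1:n))
  m1 <- fit_logistic(X["x"], y)
  m2 <- fit_logistic(X, y)  # same signal plus noise, more features
  m3 <- fit_logistic(X["noise"], y)
  tab <- compare_models(list(signal = m1, both = m2, noise = m3))
  expect_equal(tab$model[3], "noise")
  expect_true(tab$auc[1] >= tab$auc[2])
  # identical models tie and the comparison is by feature count
  tab2 <- compare_models(list(a = m2, b = m1))
  expect_equal(tab2$model[tab2$n_features == 1], "b")
  m4 <- fit_logistic(data.frame(x = x[1:30], row.names = paste0("S", 1:30)),
                     y[1:30])
  expect_error(compare_models(list(a = m1, b = m4)), "differing sample sets")
})

test_that("methylation beats clinical features when only methylation carries signal", {
  sim <- simulate_cohort(n_probes = 300, n_dml = 30, seed = 59)
  tr <- sim$truth
  probe <- tr$probe_id[tr$is_planted_dml][1]
  y <- sim$samples$group == "IR"
  ids <- sim$samples$sample_id
  meth <- fit_logistic(data.frame(cpg = as.matrix(sim$beta)[probe, ],
                                  row.names = ids), y)
  set.seed(60)
  clin <- fit_logistic(data.frame(chol = rnorm(37, 190, 25),
                                  row.names = ids), y)
  tab <- compare_models(list(methylation = meth, cholesterol = clin))
  expect_equal(tab$model[1], "methylation")
})
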