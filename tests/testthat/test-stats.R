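test_that("HOMA-IR follows the mass-unit formula with IR at the boundary", {
  expect_equal(homa_ir(90, 9), 2.0)
  expect_equal(homa_ir(81, 5), 1.0)
  expect_equal(as.character(stratify_homa(homa_ir(90, 9))), "IR")
  expect_equal(as.character(stratify_homa(homa_ir(81, 5))), "IS")
  expect_equal(homa_ir(5, 10, divisor = 22.5), 50 / 22.5)
  expect_error(homa_ir(90, 0), "positive")
  expect_error(homa_ir(-1, 5), "positive")
})

test_that("Mann-Whitney is exact by enumeration for combined n <= 12", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)
  expect_equal(res$method, "exact enumeration")
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # property: matches the independent enumeration oracle, with and
  # without ties, across random small fixtures
  set.seed(71)
  for (i in 1:25) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- sample(1:8, n1, replace = TRUE) / 2  # ties likely
    y <- sample(1:8, n2, replace = TRUE) / 2
    expect_equal(mann_whitney(x, y)$p, oracle_mw_p(x, y))
  }
  # without ties the exact p agrees with wilcox.test's exact p
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(6)
    expect_equal(mann_whitney(x, y)$p,
                 wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("large samples switch to a tie-corrected normal approximation", {
  set.seed(72)
  x <- rnorm(30); y <- rnorm(30, 1)
  res <- mann_whitney(x, y)
  expect_equal(res$method, "normal approximation")
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(res$p, ref$p.value, tolerance = 1e-8)
  xt <- round(rnorm(20), 0); yt <- round(rnorm(20, 0.5), 0)
  expect_equal(mann_whitney(xt, yt)$p,
               wilcox.test(xt, yt, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-8)
})

test_that("Spearman association matches the rank-Pearson contract", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(spearman_assoc(x, exp(x))$r, 1.0)
  expect_equal(spearman_assoc(x, -x^3)$r, -1.0)
  set.seed(73)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(spearman_assoc(a, b)$r, cor(rank(a), rank(b)))
  expect_error(spearman_assoc(rep(1, 5), 1:5), "constant")
})

test_that("two-cell enrichment chi-square equals the closed form", {
  res <- enrichment_chisq(66, 41, 123)
  expect_equal(res$chi2, (66 - 41)^2 / 41 + (57 - 82)^2 / 82,
               tolerance = 1e-12)
  expect_equal(res$p, pchisq(res$chi2, 1, lower.tail = FALSE))
  expect_equal(enrichment_chisq(41, 41, 123)$chi2, 0)
  expect_error(enrichment_chisq(5, 0, 10), "strictly between")
})

test_that("region enrichment reports direction and respects family totals", {
  set.seed(74)
  n_arr <- 4000
  ann <- simulate_annotation(sprintf("cg%05d", 1:n_arr), seed = 74)
  # enrich Body among the DMLs by sampling it preferentially
  body <- ann$probe_id[ann$gene_region == "Body"]
  other <- setdiff(ann$probe_id, body)
  dml <- c(sample(body, 66), sample(other, 57))
  res <- region_enrichment(dml, ann, "gene_region")
  expect_equal(sum(res$observed), 123)
  expect_equal(sum(res$expected), 123, tolerance = 1e-9)
  expect_equal(res$direction[res$category == "Body"], "enriched")
  expect_true(all(res$p_bonf >= res$p))
  expect_true(all(res$p_bonf <= 1))
  # observed == expected in every category gives chi2 = 0, p = 1
  flat <- region_enrichment(ann$probe_id, ann, "gene_region")
  expect_true(all(abs(flat$chi2) < 1e-9))
  expect_true(all(flat$p > 0.999))
  expect_error(region_enrichment("not_a_probe", ann), "cover")
})

test_that("Manhattan clustering is deterministic and separates planted groups", {
  # L1 arithmetic anchor
  X <- matrix(c(0, 0.5, 0.1, 0.6), 2,
              dimnames = list(c("p1", "p2"), c("A", "B")))
  d <- dist(t(X), method = "manhattan")
  expect_equal(as.numeric(d), 0.2)
  cl <- manhattan_cluster(X)
  expect_setequal(cl$leaf_order, c("A", "B"))
  # duplicate samples merge at height zero
  X3 <- cbind(X, C = X[, "A"])
  cl3 <- manhattan_cluster(X3)
  expect_equal(min(cl3$hclust$height), 0)
  # planted two-group structure recovered at the 2-cut
  sim <- simulate_cohort(n_probes = 100, n_dml = 100, delta = 0.15,
                         snp_frac = 0, seed = 75)
  cl2 <- manhattan_cluster(as.matrix(sim$beta))
  cut <- cutree(cl2$hclust, k = 2)
  g <- sim$samples$group[match(names(cut), sim$samples$sample_id)]
  purity <- max(mean(cut[g == "IR"] == 1), mean(cut[g == "IR"] == 2))
  expect_gte(purity, 0.9)
  # probe order cannot matter
  shuffled <- manhattan_cluster(as.matrix(sim$beta)[sample(100), ])
  expect_identical(shuffled$leaf_order, cl2$leaf_order)
  expect_error(manhattan_cluster(X[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("power iteration returns the smallest adequate group size", {
  n <- power_sample_size(0.10, 0.08)
  expect_equal(n, 12)
  # one fewer sample per group falls short of the target power
  pw <- function(n, delta = 0.10, sd = 0.08) {
    df <- 2 * (n - 1); ncp <- delta / (sd * sqrt(2 / n))
    tc <- qt(0.975, df)
    1 - pt(tc, df, ncp) + pt(-tc, df, ncp)
  }
  expect_lt(pw(n - 1), 0.80)
  expect_gte(pw(n), 0.80)
  # huge effects need only the minimum group size
  expect_equal(power_sample_size(10, 0.01), 2)
  # halving the effect roughly quadruples the requirement
  n_half <- power_sample_size(0.05, 0.08)
  expect_equal(n_half / n, 4, tolerance = 0.15)
  expect_error(power_sample_size(0.1, 0.08, power = 1), "< 1")
  expect_error(power_sample_size(0, 0.08), "positive")
})

test_that("gene-set Fisher test flags a loaded set and not a random one", {
  universe <- paste0("G", 1:200)
  hits <- paste0("G", 1:20)
  sets <- list(loaded = paste0("G", 1:15),
               random = paste0("G", 101:115))
  res <- gene_set_fisher(hits, universe, sets)
  expect_equal(res$n_hit_in_set[res$set == "loaded"], 15)
  expect_lt(res$p[res$set == "loaded"], 1e-6)
  expect_gt(res$p[res$set == "random"], 0.5)
  ft <- fisher.test(matrix(c(15, 5, 0, 180), 2), alternative = "greater")
  expect_equal(res$p[res$set == "loaded"], ft$p.value)
})
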