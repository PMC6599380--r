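#' HOMA-IR index from fasting glucose and insulin
#'
#' Homeostatic model assessment of insulin resistance under the mass-unit
#' convention: glucose (mg/dL) x insulin (uU/mL) / 405. Set
#' `divisor = 22.5` for SI units (glucose in mmol/L).
#'
#' @param glucose fasting glucose, mg/dL (> 0).
#' @param insulin fasting insulin, uU/mL (> 0).
#' @param divisor unit constant.
#' @return numeric HOMA-IR index.
#' @export
homa_ir <- function(glucose, insulin, divisor = 405) {
  if (any(glucose <= 0, na.rm = TRUE) || any(insulin <= 0, na.rm = TRUE))
    stop("glucose and insulin must be positive")
  glucose * insulin / divisor
}

#' Stratify samples by HOMA-IR
#'
#' Insulin resistant (IR) iff HOMA-IR >= `threshold` (the boundary value is
#' IR); below the threshold is insulin sensitive (IS).
#'
#' @param index HOMA-IR values.
#' @param threshold stratification boundary.
#' @return factor with levels IS, IR.
#' @export
stratify_homa <- function(index, threshold = 2.0) {
  factor(ifelse(index >= threshold, "IR", "IS"), levels = c("IS", "IR"))
}

# U statistic of x relative to y with midrank tie handling:
# number of (x_i, y_j) pairs with x_i > y_j, ties counting one half.
u_stat <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Mann-Whitney U test (exact by enumeration for small samples)
#'
#' Two-sided Mann-Whitney U test. For combined n <= `exact_max` the p-value
#' is exact: all choose(n, n1) group-label assignments are enumerated
#' (valid with ties, via midranks) and the p-value is the fraction of
#' assignments whose U deviates from n1*n2/2 at least as much as the
#' observed U. Larger samples use the normal approximation with tie
#' correction and continuity correction.
#'
#' @param x,y numeric vectors (>= 3 each recommended).
#' @param exact_max combined-size limit for exhaustive enumeration.
#' @return list(U, p, method).
#' @export
mann_whitney <- function(x, y, exact_max = 12) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  u_obs <- u_stat(x, y)
  mu <- n1 * n2 / 2
  if (n1 + n2 <= exact_max) {
    pool <- c(x, y)
    combos <- utils::combn(n1 + n2, n1)
    dev_obs <- abs(u_obs - mu)
    devs <- apply(combos, 2, function(ix)
      abs(u_stat(pool[ix], pool[-ix]) - mu))
    p <- sum(devs >= dev_obs - 1e-12) / ncol(combos)
    method <- "exact enumeration"
  } else {
    r <- rank(c(x, y))
    n <- n1 + n2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal approximation"
  }
  list(U = u_obs, p = p, method = method)
}

#' Spearman rank correlation with p-value
#'
#' Rank (midrank) Pearson correlation; p-value via the t approximation as
#' in [stats::cor.test()] with `exact = FALSE`.
#'
#' @param x,y numeric vectors (>= 3 each).
#' @return list(r, p).
#' @export
spearman_assoc <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: correlation undefined")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Two-cell goodness-of-fit chi-square for one category vs the rest
#'
#' chi2 = (obs - exp)^2/exp + ((n - obs) - (n - exp))^2/(n - exp), 1 df.
#'
#' @param observed observed count in the category.
#' @param expected expected count (background proportion x n).
#' @param n total count across the family.
#' @return list(chi2, p).
#' @export
enrichment_chisq <- function(observed, expected, n) {
  if (expected <= 0 || expected >= n)
    stop("expected count must lie strictly between 0 and n")
  chi2 <- (observed - expected)^2 / expected +
    ((n - observed) - (n - expected))^2 / (n - expected)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Genomic-context enrichment of DMLs
#'
#' For each category of the chosen annotation family (gene region or
#' CpG-island relation), tests the DML count against the expectation under
#' the array-wide category proportions using a two-cell chi-square
#' goodness-of-fit (category vs sum of all others, 1 df), Bonferroni
#' corrected by the number of categories tested. Categories with expected
#' count below 1 are skipped with a warning.
#'
#' @param dml_probes character vector of DML probe ids.
#' @param annotation probe annotation covering the full analysis universe
#'   (must include all DML probes).
#' @param family "gene_region" or "island_relation".
#' @return data.frame: category, observed, expected, chi2, p, p_bonf,
#'   direction.
#' @export
region_enrichment <- function(dml_probes, annotation,
                              family = c("gene_region", "island_relation")) {
  family <- match.arg(family)
  if (!all(dml_probes %in% annotation$probe_id))
    stop("array annotation must cover all DML probes")
  cats <- if (family == "gene_region") GENE_REGIONS else ISLAND_RELATIONS
  all_cat <- annotation[[family]]
  dml_cat <- all_cat[match(dml_probes, annotation$probe_id)]
  n_dml <- length(dml_probes)
  obs <- as.vector(table(factor(dml_cat, levels = cats)))
  prop <- as.vector(table(factor(all_cat, levels = cats))) / nrow(annotation)
  exp_ <- prop * n_dml
  keep <- exp_ >= 1
  if (any(!keep & obs + exp_ > 0))
    warning("skipping category with expected < 1: ",
            paste(cats[!keep & obs + exp_ > 0], collapse = ", "))
  res <- lapply(which(keep), function(i) {
    ec <- enrichment_chisq(obs[i], exp_[i], n_dml)
    data.frame(category = cats[i], observed = obs[i], expected = exp_[i],
               chi2 = ec$chi2, p = ec$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bonf <- pmin(1, out$p * nrow(out))
  out$direction <- ifelse(out$observed >= out$expected, "enriched",
                          "depleted")
  out
}

#' Hierarchical clustering of samples by Manhattan distance
#'
#' Pairwise L1 distances between samples over the DML probes, complete
#' linkage by default. Samples are ordered by id before distance
#' computation so that tie-breaking (and hence the dendrogram) is
#' deterministic across runs.
#'
#' @param beta probes x samples matrix at the DML probes (no missing
#'   values).
#' @param linkage hclust agglomeration method.
#' @return list(hclust, leaf_order (sample ids in dendrogram order)).
#' @export
manhattan_cluster <- function(beta, linkage = "complete") {
  X <- as.matrix(beta)
  if (ncol(X) < 2) stop("need >= 2 samples to cluster")
  if (anyNA(X)) stop("missing values must be completed before clustering")
  X <- X[, order(colnames(X)), drop = FALSE]
  d <- stats::dist(t(X), method = "manhattan")
  hc <- stats::hclust(d, method = linkage)
  list(hclust = hc, leaf_order = hc$labels[hc$order])
}

#' Smallest per-group sample size for a two-sample t test
#'
#' Iterates the noncentral-t power function of the two-sided two-sample
#' t test upward from n = 2 and returns the smallest per-group n whose
#' power reaches the target.
#'
#' @param delta true mean difference (beta units, > 0).
#' @param sd common standard deviation (> 0).
#' @param alpha significance level.
#' @param power target power (< 1).
#' @param n_max search bound.
#' @return integer n per group.
#' @export
power_sample_size <- function(delta, sd, alpha = 0.05, power = 0.80,
                              n_max = 1e6) {
  if (delta <= 0 || sd <= 0) stop("delta and sd must be positive")
  if (power >= 1) stop("power must be < 1")
  for (n in 2:n_max) {
    df <- 2 * (n - 1)
    ncp <- delta / (sd * sqrt(2 / n))
    tc <- stats::qt(1 - alpha / 2, df)
    pw <- 1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
    if (pw >= power) return(n)
  }
  stop("no n <= n_max reaches the target power")
}

#' Fisher's exact gene-set over-representation test
#'
#' Generic over-representation analysis of a hit-gene list against
#' user-supplied gene sets (GMT-style named list) over a stated gene
#' universe, one 2x2 Fisher's exact test per set.
#'
#' @param hits character vector of hit genes.
#' @param universe character vector of all eligible genes.
#' @param sets named list of character vectors.
#' @return data.frame: set, n_set, n_hit_in_set, expected, odds_ratio, p.
#' @export
gene_set_fisher <- function(hits, universe, sets) {
  hits <- intersect(unique(hits), universe)
  out <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), universe)
    a <- length(intersect(hits, s))
    b <- length(setdiff(hits, s))
    c <- length(setdiff(s, hits))
    d <- length(universe) - a - b - c
    ft <- stats::fisher.test(matrix(c(a, b, c, d), 2), alternative = "greater")
    data.frame(set = nm, n_set = length(s), n_hit_in_set = a,
               expected = length(hits) * length(s) / length(universe),
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
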