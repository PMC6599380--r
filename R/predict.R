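# In-sample AUC via the rank (Mann-Whitney) formula with midranks:
# probability that a random positive scores above a random negative.
rank_auc <- function(scores, outcome) {
  pos <- scores[outcome]
  neg <- scores[!outcome]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Select candidate CpGs by rank test with FDR control
#'
#' Per-probe two-sided Wilcoxon rank-sum (Mann-Whitney) comparison of the
#' IS and IR groups, Benjamini-Hochberg adjusted; probes with adjusted
#' p below `q_threshold` are candidates for the biomarker models.
#'
#' @param beta beta matrix restricted to the DML probes (or any probe set).
#' @param groups "IS"/"IR" vector or sample table.
#' @param q_threshold BH-adjusted p threshold.
#' @return character vector of selected probe ids.
#' @export
select_candidates <- function(beta, groups, q_threshold = 0.01) {
  g <- resolve_groups(beta, groups)
  X <- as.matrix(beta)
  if (q_threshold >= 1) return(rownames(X))  # filtering disabled
  p <- apply(X, 1, function(r) mann_whitney(r[g == "IS"], r[g == "IR"])$p)
  q <- stats::p.adjust(p, method = "BH")
  rownames(X)[!is.na(q) & q < q_threshold]
}

# Ridge-penalized logistic IRLS (intercept unpenalized); used as the
# declared fallback under perfect separation, where the MLE diverges.
ridge_logistic <- function(X, y, lambda = 1e-2, maxit = 200, tol = 1e-10) {
  Xd <- cbind(1, as.matrix(X))
  p <- ncol(Xd)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  b <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(Xd %*% b)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    b_new <- solve(crossprod(Xd, Xd * w) + pen, crossprod(Xd, w * z))
    if (max(abs(b_new - b)) < tol) {
      b <- b_new
      break
    }
    b <- b_new
  }
  drop(b)
}

#' Fit a logistic model for insulin-resistance outcome
#'
#' Maximum-likelihood logistic regression of the IR indicator on the given
#' features. Perfect separation (divergent MLE) is detected and, unless
#' `penalty = "none"` is forced, the fit falls back to a small ridge
#' penalty and the model is flagged. The AUC is computed in-sample from
#' the fitted probabilities by the rank formula.
#'
#' @param features data.frame or matrix of numeric predictors (columns
#'   named).
#' @param outcome logical IR indicator, or "IS"/"IR" vector, aligned to
#'   rows.
#' @param penalty "auto" (ridge on separation), "none", or "ridge".
#' @param ridge_lambda penalty weight for the ridge fallback.
#' @return object of class `logistic_model`: list(feature_names, intercept,
#'   coefficients, fitted_prob, auc, separation, aic, n_used, sample_ids,
#'   features, outcome).
#' @export
fit_logistic <- function(features, outcome,
                         penalty = c("auto", "none", "ridge"),
                         ridge_lambda = 1e-2) {
  penalty <- match.arg(penalty)
  X <- as.data.frame(features)
  if (is.character(outcome) || is.factor(outcome))
    outcome <- as.character(outcome) == "IR"
  y <- as.logical(outcome)
  ok <- stats::complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]
  y <- y[ok]
  if (sum(y) < 3 || sum(!y) < 3) stop("need >= 3 samples per class")
  if (any(vapply(X, function(v) stats::sd(v) == 0, logical(1))))
    stop("constant feature")
  sample_ids <- rownames(X)

  separation <- FALSE
  if (penalty == "ridge") {
    b <- ridge_logistic(X, y, lambda = ridge_lambda)
    aic <- NA_real_
  } else {
    dat <- cbind(.y = y, X)
    fit <- withCallingHandlers(
      stats::glm(.y ~ ., data = dat, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
            grepl("algorithm did not converge", conditionMessage(w)))
          separation <<- TRUE
        invokeRestart("muffleWarning")
      })
    b <- unname(stats::coef(fit))
    aic <- stats::AIC(fit)
    if (separation && penalty == "auto") {
      b <- ridge_logistic(X, y, lambda = ridge_lambda)
      aic <- NA_real_
    }
  }
  eta <- drop(cbind(1, as.matrix(X)) %*% b)
  prob <- 1 / (1 + exp(-eta))
  structure(list(feature_names = colnames(X), intercept = b[1],
                 coefficients = stats::setNames(b[-1], colnames(X)),
                 fitted_prob = prob, auc = rank_auc(prob, y),
                 separation = separation, aic = aic,
                 n_used = length(y), sample_ids = sample_ids,
                 features = X, outcome = y),
            class = "logistic_model")
}

#' Forward stepwise logistic model selection by AIC
#'
#' Greedy forward selection: starting from the intercept-only model, the
#' feature whose addition most improves the AIC enters at each step; the
#' path stops when no addition improves the AIC. With a limited cohort and
#' collinear features this typically terminates at a single-feature model.
#'
#' @param features data.frame of candidate predictors.
#' @param outcome IR indicator.
#' @param criterion only "AIC" is implemented.
#' @param direction only "forward" is implemented.
#' @return a `logistic_model` (intercept-only when nothing improves AIC,
#'   with empty `feature_names`), with attribute `path` listing the entry
#'   order and AICs.
#' @export
stepwise_select <- function(features, outcome, criterion = "AIC",
                            direction = "forward") {
  stopifnot(criterion == "AIC", direction == "forward")
  X <- as.data.frame(features)
  if (ncol(X) < 2) stop("need >= 2 candidate features")
  if (is.character(outcome) || is.factor(outcome))
    outcome <- as.character(outcome) == "IR"
  y <- as.logical(outcome)
  null_fit <- stats::glm(y ~ 1, family = stats::binomial())
  current_aic <- stats::AIC(null_fit)
  selected <- character(0)
  path <- data.frame(step = 0L, added = "(intercept)", aic = current_aic,
                     stringsAsFactors = FALSE)
  remaining <- colnames(X)
  repeat {
    aics <- vapply(remaining, function(f) {
      dat <- cbind(.y = y, X[, c(selected, f), drop = FALSE])
      suppressWarnings(stats::AIC(
        stats::glm(.y ~ ., data = dat, family = stats::binomial())))
    }, numeric(1))
    if (length(aics) == 0 || min(aics) >= current_aic) break
    best <- remaining[which.min(aics)]
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    current_aic <- min(aics)
    path <- rbind(path, data.frame(step = length(selected), added = best,
                                   aic = current_aic))
  }
  if (length(selected) == 0) {
    prob <- rep(mean(y), length(y))
    model <- structure(list(feature_names = character(0),
                            intercept = stats::qlogis(mean(y)),
                            coefficients = numeric(0), fitted_prob = prob,
                            auc = 0.5, separation = FALSE,
                            aic = current_aic, n_used = length(y),
                            sample_ids = rownames(X), features = X[, 0],
                            outcome = y),
                       class = "logistic_model")
  } else {
    model <- fit_logistic(X[, selected, drop = FALSE], y)
  }
  attr(model, "path") <- path
  model
}

#' Beta-value cutoff and per-class accuracy of a single-CpG model
#'
#' For a single-feature logistic model the fitted probability crosses 0.5
#' at beta = -b0/b1. With a negative coefficient (methylation lower in IR)
#' the decision rule is "beta < cutoff predicts IR"; with a positive
#' coefficient the rule direction reverses. Per-class accuracies divide
#' correct calls by the class size (IR accuracy = correctly called IR /
#' n_IR); their unweighted mean is reported as the macro average.
#'
#' @param model a single-feature `logistic_model` with nonzero slope.
#' @return list(cutoff, rule ("less"/"greater"), accuracy_ir, accuracy_is,
#'   macro_accuracy).
#' @export
beta_cutoff <- function(model) {
  if (length(model$coefficients) != 1)
    stop("beta_cutoff is defined only for single-feature models")
  b1 <- unname(model$coefficients)
  if (b1 == 0) stop("zero coefficient: no cutoff")
  cutoff <- -model$intercept / b1
  x <- model$features[[1]]
  y <- model$outcome
  pred_ir <- if (b1 < 0) x < cutoff else x > cutoff
  acc_ir <- sum(pred_ir & y) / sum(y)
  acc_is <- sum(!pred_ir & !y) / sum(!y)
  list(cutoff = cutoff, rule = if (b1 < 0) "less" else "greater",
       accuracy_ir = acc_ir, accuracy_is = acc_is,
       macro_accuracy = (acc_ir + acc_is) / 2)
}

#' Rank fitted models by AUC
#'
#' Models must have been fitted on the same samples; ties in AUC are broken
#' in favor of fewer features.
#'
#' @param models named list of `logistic_model` objects.
#' @return data.frame: model, auc, n_features, n, separation, ranked.
#' @export
compare_models <- function(models) {
  if (length(models) < 2) stop("need >= 2 models to compare")
  ids <- lapply(models, function(m) sort(m$sample_ids))
  if (!all(vapply(ids, identical, logical(1), y = ids[[1]])))
    stop("models were fitted on differing sample sets")
  df <- data.frame(
    model = names(models),
    auc = vapply(models, function(m) m$auc, numeric(1)),
    n_features = vapply(models, function(m) length(m$feature_names),
                        integer(1)),
    n = vapply(models, function(m) m$n_used, integer(1)),
    separation = vapply(models, function(m) m$separation, logical(1)),
    stringsAsFactors = FALSE)
  df <- df[order(-df$auc, df$n_features, df$model), ]
  rownames(df) <- NULL
  df
}
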