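#' Flag a probe whose beta values look like a SNP genotype pattern
#'
#' A probe whose per-sample beta values cluster at 0%, 50% and/or 100%
#' methylation cannot be distinguished from a SNP segregating in the cohort.
#' Each sample is assigned to the nearest of the modes {0, 0.5, 1} if it
#' lies within `tol`; the probe is flagged when at least `min_assigned` of
#' the samples are assigned and at least `min_modes` distinct modes are
#' occupied (requiring >= 2 modes avoids flagging constitutively
#' hemimethylated loci). Rows with fewer than 6 non-missing samples return
#' FALSE with a note.
#'
#' @param beta_row numeric vector of per-sample beta values.
#' @param tol assignment tolerance around each mode (beta units).
#' @param min_assigned minimum fraction of samples assigned to a mode.
#' @param min_modes minimum distinct occupied modes.
#' @return logical scalar.
#' @export
snp_pattern_flag <- function(beta_row, tol = 0.12, min_assigned = 0.80,
                             min_modes = 2) {
  x <- beta_row[!is.na(beta_row)]
  if (length(x) < 6) {
    message("snp_pattern_flag: fewer than 6 samples; returning FALSE")
    return(FALSE)
  }
  modes <- c(0, 0.5, 1)
  dist <- abs(outer(x, modes, "-"))
  nearest <- max.col(-dist, ties.method = "first")
  assigned <- dist[cbind(seq_along(x), nearest)] <= tol
  frac <- mean(assigned)
  n_modes <- length(unique(nearest[assigned]))
  frac >= min_assigned && n_modes >= min_modes
}

#' Vectorized SNP-pattern flags over a beta matrix
#'
#' @param beta beta matrix (probes x samples).
#' @inheritParams snp_pattern_flag
#' @return named logical vector, one flag per probe.
#' @export
snp_pattern_flags <- function(beta, tol = 0.12, min_assigned = 0.80,
                              min_modes = 2) {
  out <- apply(as.matrix(beta), 1, function(r) {
    suppressMessages(snp_pattern_flag(r, tol = tol,
                                      min_assigned = min_assigned,
                                      min_modes = min_modes))
  })
  stats::setNames(as.logical(out), rownames(beta))
}

#' Flag probes annotated as harboring a known SNP
#'
#' @param annotation probe annotation data.frame with a logical `known_snp`
#'   column.
#' @return named logical vector per probe.
#' @export
known_snp_flag <- function(annotation) {
  if (!"known_snp" %in% names(annotation))
    stop("annotation is missing the known_snp column")
  stats::setNames(as.logical(annotation$known_snp), annotation$probe_id)
}

#' Remove probes that overlap a confounder DML list
#'
#' Subtracts a confounder comparison's DMLs (e.g. an HIV-status contrast)
#' from the primary DML set, reporting the overlap and its percentage of
#' the primary set (nearest whole percent).
#'
#' @param primary_dmls character vector of primary DML probe ids.
#' @param confounder_dmls character vector of confounder DML probe ids.
#' @return list(retained, overlap, n_primary, n_overlap, pct_overlap).
#' @export
confound_overlap_filter <- function(primary_dmls, confounder_dmls) {
  if (length(primary_dmls) == 0 || length(confounder_dmls) == 0)
    stop("both probe sets must be nonempty")
  overlap <- intersect(primary_dmls, confounder_dmls)
  retained <- setdiff(primary_dmls, confounder_dmls)
  list(retained = retained, overlap = overlap,
       n_primary = length(unique(primary_dmls)),
       n_overlap = length(overlap),
       pct_overlap = round(100 * length(overlap) /
                             length(unique(primary_dmls))))
}
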