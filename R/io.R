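#' Closed vocabulary for gene-region annotation categories
#'
#' Gene-context categories used by the 450K manifest-style annotation:
#' promoter-proximal bins (TSS1500, TSS200), 5'UTR, first exon, gene body,
#' 3'UTR, and intergenic.
#' @export
GENE_REGIONS <- c("TSS1500", "TSS200", "5UTR", "1stExon", "Body", "3UTR",
                  "Intergenic")

#' Closed vocabulary for CpG-island relation categories
#'
#' Position of a probe relative to a CpG island: inside an island, within
#' ~2 kb (shore) or 2--4 kb (shelf) on the upstream (north) or downstream
#' (south) side, or in the open sea.
#' @export
ISLAND_RELATIONS <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf",
                      "OpenSea")

#' Construct and validate a beta-value matrix
#'
#' A beta matrix is a numeric probes x samples matrix of methylation
#' fractions in \[0, 1\] (0 = unmethylated, 1 = fully methylated) with unique
#' probe ids as rownames and unique sample ids as colnames. `NA` encodes a
#' missing measurement.
#'
#' @param values numeric matrix, probes in rows, samples in columns.
#' @param probe_ids,sample_ids optional ids; default to dimnames of `values`.
#' @return the validated matrix with class `beta_matrix`.
#' @export
beta_matrix <- function(values, probe_ids = rownames(values),
                        sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(probe_ids) || is.null(sample_ids))
    stop("beta_matrix requires probe and sample ids")
  if (length(probe_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("id lengths inconsistent with matrix dimensions")
  rownames(values) <- as.character(probe_ids)
  colnames(values) <- as.character(sample_ids)
  validate_beta_matrix(values)
  class(values) <- c("beta_matrix", class(values))
  values
}

#' Validate a beta matrix
#'
#' Checks id uniqueness and that every non-missing value lies in \[0, 1\].
#' The error message names the offending probe and sample.
#'
#' @param x numeric matrix with probe rownames and sample colnames.
#' @return `x`, invisibly.
#' @export
validate_beta_matrix <- function(x) {
  if (anyDuplicated(rownames(x)))
    stop("duplicate probe ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  bad <- which(!is.na(x) & (x < 0 | x > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "beta value %.6g outside [0,1] at probe '%s', sample '%s'",
      x[bad[1, 1], bad[1, 2]], rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]]))
  }
  invisible(x)
}

#' Read a beta-value matrix from TSV
#'
#' Expects a header row of sample ids, a first column of probe ids, and
#' numeric cells ("." decimal); empty cells become missing values.
#'
#' @param path TSV file path.
#' @return a `beta_matrix`.
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2) stop("beta matrix file needs probe ids plus >=1 sample")
  probe_ids <- df[[1]]
  vals <- df[, -1, drop = FALSE]
  m <- matrix(NA_real_, nrow(vals), ncol(vals),
              dimnames = list(probe_ids, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    v <- vals[[j]]
    v[v == ""] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v))
    if (length(bad) > 0)
      stop(sprintf("non-numeric cell '%s' at probe '%s', sample '%s'",
                   v[bad[1]], probe_ids[bad[1]], colnames(vals)[j]))
    m[, j] <- num
  }
  beta_matrix(m)
}

#' Write a beta-value matrix to TSV
#'
#' Fixed-precision output (6 decimals by default) so that write-read-write
#' is byte-stable; missing values are written as empty cells.
#'
#' @param x beta matrix.
#' @param path output path.
#' @param digits decimal places to write.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(x, path, digits = 6) {
  fmt <- paste0("%.", digits, "f")
  chr <- matrix(sprintf(fmt, x), nrow(x), ncol(x))
  chr[is.na(x)] <- ""
  df <- data.frame(probe_id = rownames(x), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("probe_id", colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a sample metadata table
#'
#' Required columns: `sample_id` (unique). Optional typed columns: `group`
#' (IS/IR or NA), `homa_ir` (>= 0), `fasting_glucose`, `fasting_insulin`,
#' `hiv_status` (positive/seronegative); any further numeric columns are
#' treated as covariates. When both `group` and `homa_ir` are present the
#' labels must agree with the HOMA-IR stratification rule (IR iff
#' homa_ir >= `homa_threshold`).
#'
#' @param df data.frame.
#' @param homa_threshold HOMA-IR boundary defining insulin resistance.
#' @return `df`, invisibly.
#' @export
validate_sample_table <- function(df, homa_threshold = 2.0) {
  if (!"sample_id" %in% names(df)) stop("sample table needs a sample_id column")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if ("group" %in% names(df)) {
    ok <- is.na(df$group) | df$group %in% c("IS", "IR")
    if (!all(ok))
      stop("unknown group label(s): ",
           paste(unique(df$group[!ok]), collapse = ", "),
           "; allowed: IS, IR")
  }
  if ("homa_ir" %in% names(df)) {
    if (any(!is.na(df$homa_ir) & df$homa_ir < 0))
      stop("homa_ir must be >= 0 (sample ",
           df$sample_id[which(!is.na(df$homa_ir) & df$homa_ir < 0)[1]], ")")
    if ("group" %in% names(df)) {
      has <- !is.na(df$group) & !is.na(df$homa_ir)
      expect <- ifelse(df$homa_ir[has] >= homa_threshold, "IR", "IS")
      if (any(expect != df$group[has]))
        stop("group label inconsistent with HOMA-IR threshold rule (sample ",
             df$sample_id[has][which(expect != df$group[has])[1]], ")")
    }
  }
  if ("hiv_status" %in% names(df)) {
    ok <- is.na(df$hiv_status) | df$hiv_status %in% c("positive", "seronegative")
    if (!all(ok))
      stop("unknown hiv_status: ",
           paste(unique(df$hiv_status[!ok]), collapse = ", "),
           "; allowed: positive, seronegative")
  }
  invisible(df)
}

#' Read a sample metadata table from TSV
#'
#' @param path TSV file path.
#' @param homa_threshold HOMA-IR boundary used for the consistency check.
#' @return validated data.frame.
#' @export
read_sample_table <- function(path, homa_threshold = 2.0) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  validate_sample_table(df, homa_threshold = homa_threshold)
  df
}

#' Write a sample metadata table to TSV
#' @param df sample table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a probe annotation table
#'
#' Required columns: `probe_id` (unique), `chrom`, `pos` (hg19, 1-based,
#' >= 1), `gene_region` and `island_relation` drawn from the closed
#' vocabularies [GENE_REGIONS] and [ISLAND_RELATIONS], and logical
#' `known_snp`. `gene_symbols` is free text (";"-separated).
#'
#' @param df data.frame.
#' @return `df`, invisibly.
#' @export
validate_probe_annotation <- function(df) {
  need <- c("probe_id", "chrom", "pos", "gene_region", "island_relation",
            "known_snp")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("probe annotation missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$probe_id))
    stop("duplicate probe ids in annotation")
  if (any(!is.na(df$pos) & df$pos < 1)) stop("pos must be >= 1 (1-based hg19)")
  bad <- setdiff(unique(df$gene_region), c(GENE_REGIONS, NA))
  if (length(bad) > 0)
    stop("unknown gene_region '", bad[1], "'; allowed: ",
         paste(GENE_REGIONS, collapse = ", "))
  bad <- setdiff(unique(df$island_relation), c(ISLAND_RELATIONS, NA))
  if (length(bad) > 0)
    stop("unknown island_relation '", bad[1], "'; allowed: ",
         paste(ISLAND_RELATIONS, collapse = ", "))
  if (!is.logical(df$known_snp)) {
    v <- tolower(as.character(df$known_snp))
    if (!all(v %in% c("true", "false", "na")))
      stop("known_snp must be logical (TRUE/FALSE)")
  }
  invisible(df)
}

#' Read a probe annotation table from TSV
#' @param path TSV file path.
#' @return validated data.frame with logical `known_snp`.
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  validate_probe_annotation(df)
  df$known_snp <- as.logical(toupper(as.character(df$known_snp)))
  df
}

#' Write a probe annotation table to TSV
#' @param df annotation table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probe_annotation <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# fixed-precision numeric TSV writer shared by pipeline outputs; guarantees
# byte-identical reruns
write_tsv_fixed <- function(df, path, digits = 6) {
  out <- df
  fmt <- paste0("%.", digits, "f")
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf(fmt, out[[j]])
      v[is.na(out[[j]])] <- ""
      out[[j]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
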