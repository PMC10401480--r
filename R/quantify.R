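## Validation helpers shared across the package -------------------------------

assert_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix (features x samples)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry feature IDs (rownames) and sample IDs (colnames)")
  if (anyDuplicated(rownames(counts)))
    stop("duplicated feature IDs in count matrix")
  if (anyDuplicated(colnames(counts)))
    stop("duplicated sample IDs in count matrix")
  if (any(counts < 0)) stop("negative values in count matrix")
  invisible(counts)
}

assert_design <- function(design, counts = NULL) {
  if (is.null(names(design)) || !is.character(design))
    stop("design must be a named character vector: sample_id -> group")
  if (anyDuplicated(names(design))) stop("duplicated sample IDs in design")
  if (!is.null(counts)) {
    missing <- setdiff(colnames(counts), names(design))
    if (length(missing))
      stop("samples without a group assignment: ",
           paste(utils::head(missing, 5), collapse = ", "))
  }
  invisible(design)
}

match_lengths <- function(counts, lengths) {
  if (is.null(names(lengths))) stop("lengths must be named by feature_id")
  miss <- setdiff(rownames(counts), names(lengths))
  if (length(miss))
    stop("no length available for feature(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  len <- lengths[rownames(counts)]
  if (any(!is.finite(len)) || any(len <= 0))
    stop("feature lengths must be positive and finite")
  len
}

#' Compute transcripts-per-million (TPM) abundances
#'
#' Converts a raw read-count matrix into TPM using the standard
#' rate normalization: per sample, each feature's count is divided by its
#' length in bp, and the resulting rates are rescaled to sum to one
#' million.  TPM is a within-sample relative measure, so per-sample
#' sequencing depth and scaling factors cancel.
#'
#' @param counts integer matrix, features x samples, with feature IDs as
#'   rownames and sample IDs as colnames.
#' @param lengths named numeric vector of feature lengths in base pairs;
#'   every feature in `counts` must be present.
#' @return numeric matrix with the same dimnames as `counts` and
#'   attribute `unit = "TPM"`; each column with any nonzero count sums to
#'   1e6.  An all-zero sample yields an all-zero column with a warning.
#' @export
compute_tpm <- function(counts, lengths) {
  assert_count_matrix(counts)
  len <- match_lengths(counts, lengths)
  rate <- counts / len
  denom <- colSums(rate)
  zero <- denom == 0
  if (any(zero)) {
    warning("all-zero sample column(s): ",
            paste(colnames(counts)[zero], collapse = ", "),
            "; TPM set to zero for these samples")
    denom[zero] <- 1
  }
  tpm <- sweep(rate, 2, denom, "/") * 1e6
  attr(tpm, "unit") <- "TPM"
  tpm
}

#' Compute FPKM abundances
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' `FPKM_ij = count_ij * 1e9 / (length_i * N_j)` with `N_j` the total
#' count of sample `j`.
#'
#' @inheritParams compute_tpm
#' @return numeric matrix with attribute `unit = "FPKM"`.
#' @export
compute_fpkm <- function(counts, lengths) {
  assert_count_matrix(counts)
  len <- match_lengths(counts, lengths)
  N <- colSums(counts)
  zero <- N == 0
  if (any(zero)) {
    warning("all-zero sample column(s): ",
            paste(colnames(counts)[zero], collapse = ", "),
            "; FPKM set to zero for these samples")
    N[zero] <- 1
  }
  fpkm <- sweep(counts / len, 2, N, "/") * 1e9
  attr(fpkm, "unit") <- "FPKM"
  fpkm
}

#' Per-feature summary of abundance within one sample group
#'
#' Summarizes an abundance (or count) matrix over the samples belonging
#' to one group of a cohort design.  The default statistic is the median
#' (for even group sizes, the mean of the two central order statistics);
#' this is the aggregate the cascade's presence filters consume.
#'
#' @param abund numeric matrix, features x samples.
#' @param design named character vector, sample_id -> group label.
#' @param group group label to summarize.
#' @param statistic `"median"` (default) or `"mean"`.
#' @return named numeric vector, one value per feature.
#' @export
group_summary <- function(abund, design, group,
                          statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  assert_design(design, abund)
  if (!group %in% design)
    stop("unknown group label: ", group)
  samples <- intersect(colnames(abund), names(design)[design == group])
  if (!length(samples))
    stop("group '", group, "' has no samples in the matrix")
  sub <- abund[, samples, drop = FALSE]
  if (statistic == "mean") return(rowMeans(sub))
  apply(sub, 1, stats::median)
}
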