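## Summary reporting: the stage-count funnel and the per-group mean
## expression matrix used for heat-map style displays.

#' Stage-count funnel of a filter trace
#'
#' One row per cascade stage with feature counts in and out, the
#' stage's parameters and the most frequent drop reasons.
#'
#' @param trace a `filter_trace`.
#' @param top_n how many reasons to list per stage (default 3).
#' @return data.frame with columns `stage`, `params`, `n_in`, `n_out`,
#'   `top_reasons`.
#' @export
funnel_report <- function(trace, top_n = 3) {
  stopifnot(inherits(trace, "filter_trace"))
  rows <- lapply(trace$stages, function(st) {
    reasons <- if (nrow(st$drops)) {
      tab <- sort(table(st$drops$reason), decreasing = TRUE)
      tab <- utils::head(tab, top_n)
      paste(sprintf("%s:%d", names(tab), as.integer(tab)),
            collapse = ",")
    } else ""
    params <- if (length(st$params))
      paste(sprintf("%s=%s", names(st$params),
                    vapply(st$params, format, character(1))),
            collapse = ",") else ""
    data.frame(stage = st$name, params = params,
               n_in = st$n_in, n_out = st$n_out,
               top_reasons = reasons, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export per-group mean expression for selected features
#'
#' Mean abundance per cohort group (columns ordered benign, pca, crpc,
#' nepc, then any further groups), optionally followed by per-tissue
#' median columns — the matrix behind the usual candidate heat map.
#'
#' @param abund abundance matrix, features x samples.
#' @param design named character vector, sample_id -> group.
#' @param features feature IDs to export (all must be present).
#' @param tissue_medians optional features x tissues matrix appended
#'   on the right.
#' @return numeric matrix, features x groups (+ tissues).
#' @export
export_group_means <- function(abund, design, features,
                               tissue_medians = NULL) {
  unknown <- setdiff(features, rownames(abund))
  if (length(unknown))
    stop("unknown feature(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  canonical <- c("benign", "pca", "crpc", "nepc")
  groups <- unique(design[colnames(abund)])
  groups <- c(intersect(canonical, groups), setdiff(sort(groups), canonical))
  out <- matrix(0, length(features), length(groups),
                dimnames = list(features, groups))
  for (g in groups)
    out[, g] <- group_summary(abund[features, , drop = FALSE],
                              design, g, "mean")
  if (!is.null(tissue_medians))
    out <- cbind(out, tissue_medians[features, , drop = FALSE])
  out
}

#' Cross-tabulate a cascade outcome against a simulation truth table
#'
#' For a simulated cohort, classifies every feature by where the
#' cascade actually dropped it (or `nominated`) and compares with the
#' expected outcome in the truth table.
#'
#' @param trace a `filter_trace` from a cascade run.
#' @param truth truth table data.frame with `feature_id`,
#'   `expected_outcome` (and optionally `expected_reason`).
#' @return data.frame with per-feature `observed_outcome`,
#'   `observed_reason` and logical `matches_expected`.
#' @export
truth_comparison <- function(trace, truth) {
  observed <- stats::setNames(rep("nominated", length(trace$universe)),
                              trace$universe)
  reason <- stats::setNames(rep(NA_character_, length(trace$universe)),
                            trace$universe)
  for (st in trace$stages) {
    if (nrow(st$drops)) {
      observed[st$drops$feature_id] <- paste0("dropped_", st$name)
      reason[st$drops$feature_id] <- st$drops$reason
    }
  }
  out <- truth
  out$observed_outcome <- unname(observed[truth$feature_id])
  out$observed_reason <- unname(reason[truth$feature_id])
  match_out <- out$observed_outcome == out$expected_outcome
  if ("expected_reason" %in% names(out)) {
    has_reason <- !is.na(out$expected_reason)
    match_out[has_reason] <- match_out[has_reason] &
      !is.na(out$observed_reason[has_reason]) &
      out$observed_reason[has_reason] == out$expected_reason[has_reason]
  }
  out$matches_expected <- match_out
  out
}

#' Report expression features absent from every annotation source
#'
#' Surface annotation files are matched verbatim (no alias
#' resolution); this helper surfaces how much of the expression space
#' the supplied catalog covers.
#'
#' @param catalog a `surface_catalog`.
#' @param ids feature identifiers present in the expression data.
#' @return character vector of unannotated IDs, invisibly; a message
#'   reports the count.
#' @export
report_unannotated <- function(catalog, ids) {
  missing <- ids[!in_catalog(catalog, ids)]
  message(length(missing), " of ", length(ids),
          " expression features are absent from all annotation sources")
  invisible(missing)
}
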