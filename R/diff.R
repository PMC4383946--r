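# Two-group comparison of tRF abundance (descriptive fold changes).
#
# With two replicates per group, as in the B-cell case study this mirrors,
# formal inference is not meaningful; the module deliberately reports
# pseudocount-stabilized fold changes and class-level aggregates only.

#' Compare tRF abundance between two library groups
#'
#' Per tRF: mean RPM in each group, log2 fold change
#' \code{log2((mean_B + p) / (mean_A + p))} with pseudocount \code{p}, and a
#' detection flag. Under the default \code{detect = "group-mean"} a tRF is
#' detected iff its mean RPM exceeds \code{min_rpm} in at least one group;
#' only detected tRFs are returned, ordered by |log2FC| descending.
#'
#' @param mat RPM matrix from [build_matrix()].
#' @param group_a,group_b column (library) IDs of the two groups; must be
#'   non-empty and disjoint.
#' @param min_rpm detection threshold in RPM, default 20.
#' @param pseudocount fold-change stabilizer in RPM, default 1.
#' @param trf_types optional named vector trf_id -> type, carried into the
#'   output for class summaries.
#' @param detect detection rule: \code{"group-mean"} (default),
#'   \code{"per-library-any"} (above threshold in at least one library), or
#'   \code{"per-library-all"} (above threshold in every library of at least
#'   one group).
#' @return data.frame: trf_id, trf_type (if supplied), mean_rpm_A,
#'   mean_rpm_B, log2_fold_change, detected (all TRUE in the returned rows).
#' @export
compare_groups <- function(mat, group_a, group_b, min_rpm = 20,
                           pseudocount = 1, trf_types = NULL,
                           detect = c("group-mean", "per-library-any",
                                      "per-library-all")) {
  detect <- match.arg(detect)
  stopifnot(length(group_a) > 0, length(group_b) > 0)
  if (length(intersect(group_a, group_b)) > 0) {
    stop("groups must be disjoint")
  }
  missing <- setdiff(c(group_a, group_b), colnames(mat))
  if (length(missing) > 0) stop("unknown library ID: ",
                                paste(missing, collapse = ", "))
  a <- mat[, group_a, drop = FALSE]
  b <- mat[, group_b, drop = FALSE]
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  detected <- switch(detect,
    "group-mean" = pmax(mean_a, mean_b) > min_rpm,
    "per-library-any" = apply(cbind(a, b) > min_rpm, 1, any),
    "per-library-all" = apply(a > min_rpm, 1, all) |
                        apply(b > min_rpm, 1, all))
  out <- data.frame(
    trf_id = rownames(mat),
    mean_rpm_A = mean_a,
    mean_rpm_B = mean_b,
    log2_fold_change = log2((mean_b + pseudocount) / (mean_a + pseudocount)),
    detected = detected,
    stringsAsFactors = FALSE
  )
  if (!is.null(trf_types)) {
    out$trf_type <- unname(trf_types[out$trf_id])
    out <- out[, c("trf_id", "trf_type", "mean_rpm_A", "mean_rpm_B",
                   "log2_fold_change", "detected")]
  }
  out <- out[out$detected, , drop = FALSE]
  out <- out[order(-abs(out$log2_fold_change), out$trf_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Class-level summary of a group comparison
#'
#' Aggregates per tRF type: number of detected tRFs, median log2 fold
#' change, and up / down / flat counts at \code{|log2FC| >= lfc_threshold}.
#' Types with no detected tRF are reported with count 0 and NA median.
#'
#' @param comparisons output of [compare_groups()] with a \code{trf_type}
#'   column.
#' @param lfc_threshold up/down call threshold, default 1 (two-fold).
#' @return data.frame: trf_type, n, median_log2_fc, up, down, flat.
#' @export
class_summary <- function(comparisons, lfc_threshold = 1) {
  stopifnot(nrow(comparisons) >= 1, "trf_type" %in% names(comparisons))
  rows <- lapply(TRF_TYPES, function(type) {
    lfc <- comparisons$log2_fold_change[comparisons$trf_type %in% type]
    data.frame(trf_type = type,
               n = length(lfc),
               median_log2_fc = if (length(lfc)) stats::median(lfc) else NA_real_,
               up = sum(lfc >= lfc_threshold),
               down = sum(lfc <= -lfc_threshold),
               flat = sum(abs(lfc) < lfc_threshold),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
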