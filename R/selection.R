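#' Select top and bottom hybrids from predictions
#'
#' Deterministic ranking on the predicted value, ties broken by
#' (`parent1`, `parent2`) lexicographic order, so the selection is invariant
#' to the input row order.
#'
#' @param predictions data.frame with `parent1`, `parent2`, `predicted`
#'   (e.g. from [predict_all_hybrids()]).
#' @param k_top,k_bottom number of hybrids selected at each extreme
#'   (default 100 each).
#' @return list with `top` and `bottom` data.frames (disjoint by
#'   construction).
#' @export
select_extremes <- function(predictions, k_top = 100, k_bottom = 100) {
  predictions <- as.data.frame(predictions)
  n <- nrow(predictions)
  if (k_top + k_bottom > n)
    stopf("k_top + k_bottom (%d) exceeds the %d predictions",
          k_top + k_bottom, n)
  ord <- order(-predictions$predicted, predictions$parent1,
               predictions$parent2)
  sorted <- predictions[ord, , drop = FALSE]
  top <- sorted[seq_len(k_top), , drop = FALSE]
  bottom <- sorted[seq(n - k_bottom + 1, n), , drop = FALSE]
  rownames(top) <- rownames(bottom) <- NULL
  list(top = top, bottom = bottom)
}

#' Top-selection gain against the bottom set, the overall mean and a check
#'
#' Field-validation logic: among the validated observations, computes
#' `gain_vs_bottom = (mean_top - mean_bottom) / mean_bottom x 100`,
#' `gain_vs_mean = (mean_top - overall_mean) / overall_mean x 100` (and the
#' analogous loss of the bottom set), plus the number of validated hybrids
#' exceeding the check value and exceeding it by more than 5%. The overall
#' mean is the mean of *all* validated hybrids. Gains use validated entries
#' only; sides with no validated entry raise an error.
#'
#' @param observed named numeric vector: observed value per validated
#'   hybrid ID.
#' @param top,bottom character vectors of selected hybrid IDs (or
#'   data.frames with a `hybrid` column).
#' @param check value of the check variety (optional).
#' @param method label recorded in the report.
#' @return object of class `selection_report`: list with validated counts,
#'   means, `gain_vs_bottom`, `gain_vs_mean`, `loss_vs_mean`,
#'   `n_exceed_check`, `n_exceed_check_5pct`, and the validated subsets.
#' @export
selection_gain <- function(observed, top, bottom, check = NULL,
                           method = "model") {
  if (is.data.frame(top)) top <- top$hybrid
  if (is.data.frame(bottom)) bottom <- bottom$hybrid
  if (length(intersect(top, bottom)))
    stopf("top and bottom lists must be disjoint")
  val_top <- observed[intersect(top, names(observed))]
  val_bottom <- observed[intersect(bottom, names(observed))]
  if (!length(val_top)) stopf("no validated entries on the top side")
  if (!length(val_bottom)) stopf("no validated entries on the bottom side")
  overall <- mean(observed)
  mt <- mean(val_top)
  mb <- mean(val_bottom)
  n_exc <- n_exc5 <- NA_integer_
  if (!is.null(check)) {
    n_exc <- sum(observed > check)
    n_exc5 <- sum(observed > check * 1.05)
  }
  structure(list(method = method,
                 n_validated = length(observed),
                 n_validated_top = length(val_top),
                 n_validated_bottom = length(val_bottom),
                 mean_top = mt, mean_bottom = mb, overall_mean = overall,
                 gain_vs_bottom = (mt - mb) / mb * 100,
                 gain_vs_mean = (mt - overall) / overall * 100,
                 loss_vs_mean = (mb - overall) / overall * 100,
                 check = check, n_exceed_check = n_exc,
                 n_exceed_check_5pct = n_exc5,
                 validated_top = val_top, validated_bottom = val_bottom),
            class = "selection_report")
}

#' @export
#' @method print selection_report
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> %s: top %d / bottom %d validated\n",
              x$method, x$n_validated_top, x$n_validated_bottom))
  cat(sprintf("  top mean %.1f vs bottom mean %.1f: gain %.1f%%\n",
              x$mean_top, x$mean_bottom, x$gain_vs_bottom))
  cat(sprintf("  vs overall mean %.3f: top %+.1f%%, bottom %+.1f%%\n",
              x$overall_mean, x$gain_vs_mean, x$loss_vs_mean))
  if (!is.null(x$check))
    cat(sprintf("  %d exceed the check (%.1f), %d by > 5%%\n",
                x$n_exceed_check, x$check, x$n_exceed_check_5pct))
  invisible(x)
}

#' Venn-region counts across per-method selections
#'
#' @param selections named list (one element per method) of hybrid ID
#'   vectors.
#' @return list with `n_union`, `n_intersection`, `pairwise` (matrix of
#'   pairwise intersection sizes), and `regions` (data.frame: membership
#'   pattern, count).
#' @export
overlap_counts <- function(selections) {
  if (length(selections) < 2) stopf("need selections from at least 2 methods")
  sets <- lapply(selections, unique)
  all_ids <- unique(unlist(sets))
  memb <- vapply(sets, function(s) all_ids %in% s, logical(length(all_ids)))
  if (is.null(dim(memb))) memb <- matrix(memb, nrow = 1)
  pattern <- apply(memb, 1, function(z) paste(ifelse(z, "1", "0"),
                                              collapse = ""))
  regions <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
  names(regions) <- c("pattern", "count")
  k <- length(sets)
  pw <- matrix(NA_integer_, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) for (j in seq_len(k))
    pw[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  list(n_union = length(all_ids),
       n_intersection = sum(rowSums(memb) == k),
       pairwise = pw, regions = regions, methods = names(sets))
}
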