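#' Absolute median correlation of an item with the other surviving items
#'
#' @param R Correlation matrix with item labels.
#' @param item Item label.
#' @param surviving Character vector of surviving item labels (must contain
#'   `item` and at least one other item).
#' @return Median of `|r(item, k)|` over the other surviving items.
#' @export
absolute_median_correlation <- function(R, item, surviving = colnames(R)) {
  if (!item %in% surviving) stopf("item not in surviving set")
  others <- setdiff(surviving, item)
  if (!length(others)) stopf("surviving set must contain at least 2 items")
  median(abs(R[item, others]))
}

#' Stepwise redundancy reduction of near-duplicate items
#'
#' Walks a descending threshold schedule (default 0.90, 0.85, ..., 0.50). At
#' each threshold `t`, while any surviving pair correlates beyond `|t|`, the
#' most strongly correlated such pair is examined and the item with the
#' *higher* absolute median correlation with the other surviving items is
#' removed (the one capturing less unique variance); medians are recomputed on
#' the surviving set after every removal. Exact ties are broken by the
#' optional `priority` rank (lower rank kept) and then by item label, with the
#' tie recorded.
#'
#' @param R Labeled correlation matrix or a `polychoric` object.
#' @param start_threshold,stop_threshold,step Threshold schedule (descending
#'   from `start_threshold` to `stop_threshold` by `step`).
#' @param priority Optional named numeric rank per item; on an exact median
#'   tie the lower-ranked item is kept (a stand-in for the judgment call of
#'   preferring trait-like over state-like wording).
#' @return Object of class `reduction_trace`: list with `removals` (tibble:
#'   threshold, removed_item, kept_item, pair_correlation, tie_broken),
#'   `surviving_items`, `threshold_schedule`.
#' @export
reduce_items <- function(R, start_threshold = 0.9, stop_threshold = 0.5,
                         step = 0.05, priority = NULL) {
  if (inherits(R, "polychoric")) R <- R$rho
  if (is.null(colnames(R))) stopf("R must have item labels")
  if (step <= 0) stopf("step must be positive")
  if (stop_threshold > start_threshold) {
    stopf("stop_threshold must not exceed start_threshold")
  }
  schedule <- seq(start_threshold, stop_threshold, by = -step)
  surviving <- colnames(R)

  thr_v <- numeric(0); rem_v <- keep_v <- character(0)
  cor_v <- numeric(0); tie_v <- logical(0)

  for (t in schedule) {
    repeat {
      if (length(surviving) < 2) break
      sub <- abs(R[surviving, surviving])
      diag(sub) <- 0
      m <- max(sub)
      if (m <= t) break
      # strongest offending pair; deterministic lexicographic tie-break
      hits <- which(sub == m, arr.ind = TRUE)
      hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
      pair_labels <- cbind(surviving[hits[, 1]], surviving[hits[, 2]])
      ord <- order(pair_labels[, 1], pair_labels[, 2])
      a <- pair_labels[ord[1], 1]; b <- pair_labels[ord[1], 2]

      med_a <- absolute_median_correlation(R, a, surviving)
      med_b <- absolute_median_correlation(R, b, surviving)
      tie <- FALSE
      if (med_a < med_b) {
        keep <- a; remove <- b
      } else if (med_b < med_a) {
        keep <- b; remove <- a
      } else {
        tie <- TRUE
        if (!is.null(priority) && !is.na(priority[a]) && !is.na(priority[b]) &&
            priority[a] != priority[b]) {
          keep <- if (priority[a] < priority[b]) a else b
        } else {
          keep <- min(a, b)
        }
        remove <- setdiff(c(a, b), keep)
      }
      thr_v <- c(thr_v, t); rem_v <- c(rem_v, remove); keep_v <- c(keep_v, keep)
      cor_v <- c(cor_v, R[a, b]); tie_v <- c(tie_v, tie)
      surviving <- setdiff(surviving, remove)
    }
  }

  structure(
    list(removals = tibble(threshold = thr_v, removed_item = rem_v,
                           kept_item = keep_v, pair_correlation = cor_v,
                           tie_broken = tie_v),
         surviving_items = surviving,
         threshold_schedule = schedule),
    class = "reduction_trace"
  )
}

#' @export
print.reduction_trace <- function(x, ...) {
  cat(sprintf("<reduction_trace> %d removed, %d surviving (thresholds %g to %g)\n",
              nrow(x$removals), length(x$surviving_items),
              max(x$threshold_schedule), min(x$threshold_schedule)))
  invisible(x)
}

#' @rdname reduce_items
#' @param x A `reduction_trace`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.reduction_trace <- function(x, ...) x$removals
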