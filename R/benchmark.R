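# Truth-set matching and performance metrics.
#
# A call matches a truth record when both lie on the same contig, have the
# same SV type, both breakpoints agree within ref_dist and the size ratio
# min(len)/max(len) reaches the similarity floor. Assignment is one-to-one
# and greedy by ascending breakpoint distance (|pos diff| + |end diff|),
# ties resolved by smaller truth position then smaller call position --
# fully deterministic. Sequence comparison is not performed. A truth
# record with no assigned call counts as FN, which includes truth SVs no
# caller reported at all.

#' Matching parameters
#'
#' @param ref_dist Maximum breakpoint distance in bp (each breakpoint).
#' @param size_similarity_min Minimum `min(len)/max(len)` ratio.
#' @param restrict_regions Optional region table (see [read_bed_regions()])
#'   applied to both call and truth sets before matching.
#' @param autosomes_only Restrict both sets to contigs 1..22.
#' @return Object of class `match_params`.
#' @export
match_params <- function(ref_dist = 500L, size_similarity_min = 0.7,
                         restrict_regions = NULL, autosomes_only = TRUE) {
  if (ref_dist < 0) stopf("ref_dist must be >= 0")
  if (size_similarity_min < 0 || size_similarity_min > 1)
    stopf("size_similarity_min must lie in [0, 1]")
  structure(list(ref_dist = as.integer(ref_dist),
                 size_similarity_min = size_similarity_min,
                 restrict_regions = restrict_regions,
                 autosomes_only = isTRUE(autosomes_only)),
            class = "match_params")
}

restrict_set <- function(x, params) {
  x <- data.table::as.data.table(x)
  if (params$autosomes_only) x <- x[chrom %in% AUTOSOMES]
  if (!is.null(params$restrict_regions)) {
    reg <- data.table::as.data.table(params$restrict_regions)
    keep <- logical(nrow(x))
    for (k in seq_len(nrow(reg)))
      keep <- keep | (x$chrom == reg$chrom[k] &
                        x$pos >= reg$start[k] & x$pos <= reg$end[k])
    x <- x[keep]
  }
  x
}

#' Match a call set against a truth set
#'
#' @param calls data.table with `id`, `chrom`, `pos`, `end`, `svtype`,
#'   `svlen` (e.g. consensus calls or one caller's filtered calls).
#' @param truth data.table with the same columns; `id` must be unique.
#' @param params A [match_params()].
#' @return Object of class `match_result`: `tp`, `fp`, `fn`, `pairs`
#'   (data.table of `call_id`, `truth_id`, `dist`), `n_calls`, `n_truth`
#'   (evaluated set sizes after region restriction).
#' @export
match_to_truth <- function(calls, truth, params = match_params()) {
  stopifnot(inherits(params, "match_params"))
  calls <- restrict_set(calls, params)
  truth <- restrict_set(truth, params)
  if (anyDuplicated(truth$id)) stopf("duplicated truth IDs")

  pairs <- data.table::data.table(call_id = character(0),
                                  truth_id = character(0), dist = integer(0))
  if (nrow(calls) && nrow(truth)) {
    cand <- merge(
      calls[, .(call_id = id, chrom, svtype, cpos = pos, cend = end, clen = svlen)],
      truth[, .(truth_id = id, chrom, svtype, tpos = pos, tend = end, tlen = svlen)],
      by = c("chrom", "svtype"), allow.cartesian = TRUE)
    if (nrow(cand)) {
      cand <- cand[abs(cpos - tpos) <= params$ref_dist &
                     abs(cend - tend) <= params$ref_dist &
                     pmin(clen, tlen) / pmax(clen, tlen) >=
                       params$size_similarity_min]
    }
    if (nrow(cand)) {
      cand[, dist := abs(cpos - tpos) + abs(cend - tend)]
      data.table::setorder(cand, dist, tpos, cpos, truth_id, call_id)
      used_call <- new.env(hash = TRUE); used_truth <- new.env(hash = TRUE)
      ci <- character(0); ti <- character(0); dd <- integer(0)
      for (i in seq_len(nrow(cand))) {
        cid <- cand$call_id[i]; tid <- cand$truth_id[i]
        if (!is.null(used_call[[cid]]) || !is.null(used_truth[[tid]])) next
        used_call[[cid]] <- TRUE; used_truth[[tid]] <- TRUE
        ci <- c(ci, cid); ti <- c(ti, tid); dd <- c(dd, cand$dist[i])
      }
      pairs <- data.table::data.table(call_id = ci, truth_id = ti, dist = dd)
    }
  }
  tp <- nrow(pairs)
  structure(list(tp = tp, fp = nrow(calls) - tp, fn = nrow(truth) - tp,
                 pairs = pairs, n_calls = nrow(calls), n_truth = nrow(truth)),
            class = "match_result")
}

#' Precision, recall and F1 from match counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2 TP / (2 TP + FP + FN)`; empty denominators yield 0 by
#' convention. Values are kept at full precision; round at report time
#' with [round_half_up()] (printed tables use 2 decimals, half-up).
#'
#' @param result A `match_result`, or any list with `tp`, `fp`, `fn`.
#' @return Object of class `benchmark_metrics`: `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`.
#' @export
compute_metrics <- function(result) {
  tp <- result$tp; fp <- result$fp; fn <- result$fn
  if (any(c(tp, fp, fn) < 0)) stopf("counts must be non-negative")
  safe_div <- function(a, b) if (b > 0) a / b else 0
  structure(list(
    tp = tp, fp = fp, fn = fn,
    precision = safe_div(tp, tp + fp),
    recall = safe_div(tp, tp + fn),
    f1 = safe_div(2 * tp, 2 * tp + fp + fn)),
    class = "benchmark_metrics")
}

#' @export
print.benchmark_metrics <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d | precision %.2f recall %.2f F1 %.2f\n",
              x$tp, x$fp, x$fn, round_half_up(x$precision),
              round_half_up(x$recall), round_half_up(x$f1)))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-statistic formulation: the probability that a uniformly drawn
#' positive outranks a uniformly drawn negative, with ties counting one
#' half (equivalent to the Mann-Whitney U statistic).
#'
#' @param probabilities Numeric scores.
#' @param labels Logical (or 0/1) class labels; both classes must occur.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(probabilities, labels) {
  labels <- as.logical(labels)
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0L || nneg == 0L)
    stopf("AUC undefined: both classes must be present")
  r <- rank(probabilities, ties.method = "average")
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Calls and TP proportion per prediction-probability decile
#'
#' Bins `[0,0.1), [0.1,0.2), ..., [0.9,1.0]` (top bin closed so that a
#' probability of exactly 1 lands in the highest decile). Bin sizes sum to
#' the number of calls and fractions to 1.
#'
#' @param probabilities Numeric vector in `[0, 1]`.
#' @param labels Optional logical TP labels; adds a `tp_prop` column.
#' @return data.table with `bin`, `lower`, `upper`, `n`, `fraction` and
#'   (when labeled) `tp_prop` (NA for empty bins).
#' @export
decile_report <- function(probabilities, labels = NULL) {
  if (anyNA(probabilities))
    stopf("probabilities must not contain missing values")
  if (length(probabilities) &&
      (any(probabilities < 0) || any(probabilities > 1)))
    stopf("probabilities must lie in [0, 1]")
  lower <- seq(0, 0.9, by = 0.1)
  bin <- pmin(findInterval(probabilities, lower), 10L)
  n <- tabulate(bin, nbins = 10L)
  out <- data.table::data.table(
    bin = sprintf("[%.1f,%.1f%s", lower, lower + 0.1,
                  c(rep(")", 9), "]")),
    lower = lower, upper = lower + 0.1, n = n,
    fraction = if (sum(n)) n / sum(n) else rep(0, 10))
  if (!is.null(labels)) {
    labels <- as.logical(labels)
    tp_prop <- vapply(1:10, function(b) {
      w <- bin == b
      if (!any(w)) NA_real_ else mean(labels[w])
    }, numeric(1))
    out[, tp_prop := tp_prop]
  }
  out[]
}
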