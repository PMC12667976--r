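# Balanced precision-recall benchmarking of a variant effect map (or any
# predictor column) against a clinical reference set.
#
# "Balanced" precision re-weights the confusion matrix to a 50/50 class
# prior, so performance does not depend on the (arbitrary) class balance
# of the curated reference set: with recall r_P = tp/(tp+fn) and false
# positive rate r_N = fp/(fp+tn), balanced precision = r_P/(r_P + r_N).

#' Balanced precision from a confusion matrix
#'
#' @param tp,fn,fp,tn Confusion-matrix counts at one threshold.
#' @return List with \code{recall} (= \code{tp/(tp+fn)}) and
#'   \code{balanced_precision} (= \code{r_P/(r_P + r_N)}), the precision
#'   expected under a balanced (50/50) reference set.
#' @examples
#' balanced_precision(tp = 9, fn = 1, fp = 1, tn = 9)
#' @export
balanced_precision <- function(tp, fn, fp, tn) {
  if (tp + fn <= 0) stop("no positive reference variants", call. = FALSE)
  if (fp + tn <= 0) stop("no negative reference variants", call. = FALSE)
  r_p <- tp / (tp + fn)
  r_n <- fp / (fp + tn)
  bp <- if (r_p + r_n == 0) NA_real_ else r_p / (r_p + r_n)
  list(recall = r_p, balanced_precision = bp)
}

#' Balanced precision-recall curve
#'
#' Sweeps every observed score value as a classification threshold
#' (identical scores are grouped at one threshold; no interpolation or
#' monotonization) and computes recall, nominal precision and balanced
#' precision at each. Orientation declares which direction is "damaging":
#' for a functional map lower scores are damaging; for most computational
#' predictors higher scores are.
#'
#' @param scores Numeric predictor values.
#' @param positive Logical: variant is a positive (P/LP) reference.
#' @param orientation \code{"lower_is_damaging"} (default, map
#'   convention) or \code{"higher_is_damaging"}.
#' @return Object of class \code{"prc_curve"}: data.frame with
#'   \code{threshold}, \code{tp}, \code{fn}, \code{fp}, \code{tn},
#'   \code{recall}, \code{precision}, \code{balanced_precision}, plus the
#'   orientation.
#' @export
prc_curve <- function(scores, positive,
                      orientation = c("lower_is_damaging",
                                      "higher_is_damaging")) {
  orientation <- match.arg(orientation)
  stopifnot(length(scores) == length(positive))
  keep <- is.finite(scores) & !is.na(positive)
  scores <- scores[keep]; positive <- positive[keep]
  if (!any(positive) || all(positive))
    stop("need at least one positive and one negative reference variant",
         call. = FALSE)
  s <- if (orientation == "lower_is_damaging") scores else -scores
  thr <- sort(unique(s))
  rows <- lapply(thr, function(t) {
    damaging <- s <= t
    tp <- sum(damaging & positive)
    fp <- sum(damaging & !positive)
    fn <- sum(!damaging & positive)
    tn <- sum(!damaging & !positive)
    b <- balanced_precision(tp, fn, fp, tn)
    data.frame(threshold = t, tp = tp, fn = fn, fp = fp, tn = tn,
               recall = b$recall,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               balanced_precision = b$balanced_precision)
  })
  curve <- do.call(rbind, rows)
  if (orientation == "higher_is_damaging")
    curve$threshold <- -curve$threshold
  structure(list(curve = curve, orientation = orientation),
            class = "prc_curve")
}

#' Recall at 90% balanced precision (R90BP)
#'
#' The maximum recall over thresholds whose balanced precision reaches
#' \code{min_precision}; 0 when no threshold qualifies. No interpolation.
#'
#' @param x A \code{"prc_curve"}.
#' @param min_precision Balanced-precision bar (default 0.90).
#' @return Recall in [0, 1].
#' @export
r90bp <- function(x, min_precision = 0.90) {
  stopifnot(inherits(x, "prc_curve"))
  ok <- !is.na(x$curve$balanced_precision) &
    x$curve$balanced_precision >= min_precision
  if (!any(ok)) 0 else max(x$curve$recall[ok])
}

#' @export
print.prc_curve <- function(x, ...) {
  cat("Balanced precision-recall curve (", x$orientation, ")\n",
      "  thresholds: ", nrow(x$curve), "\n",
      "  R90BP: ", round(r90bp(x), 3), "\n", sep = "")
  invisible(x)
}

#' @export
plot.prc_curve <- function(x, ...) {
  graphics::plot(x$curve$recall, x$curve$balanced_precision, type = "b",
                 xlim = c(0, 1), ylim = c(0, 1), xlab = "recall",
                 ylab = "balanced precision", ...)
  graphics::abline(h = 0.9, lty = 3)
  invisible(x)
}

#' Benchmark several predictor columns against one reference set
#'
#' Restricts to the intersection of variants scored by every requested
#' predictor (exclusions are reported), builds one balanced
#' precision-recall curve per predictor, and tabulates R90BP.
#'
#' @param data Data.frame with one row per reference variant: a logical
#'   \code{positive} column plus one numeric column per predictor.
#' @param columns Named character vector mapping predictor column names to
#'   orientations, e.g. \code{c(score = "lower_is_damaging",
#'   revel = "higher_is_damaging")}.
#' @return Data.frame with \code{predictor}, \code{n}, \code{r90bp};
#'   attribute \code{"curves"} holds the \code{"prc_curve"} objects.
#' @export
benchmark_predictors <- function(data, columns) {
  stopifnot("positive" %in% names(data))
  missing_cols <- setdiff(names(columns), names(data))
  if (length(missing_cols))
    stop("predictor column(s) not in data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  complete <- stats::complete.cases(data[names(columns)])
  if (any(!complete))
    message("benchmark_predictors: dropping ", sum(!complete),
            " variant(s) not scored by every predictor")
  data <- data[complete, , drop = FALSE]
  curves <- lapply(names(columns), function(col)
    prc_curve(data[[col]], data$positive, orientation = columns[[col]]))
  names(curves) <- names(columns)
  out <- data.frame(predictor = names(columns),
                    n = nrow(data),
                    r90bp = vapply(curves, r90bp, numeric(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "curves") <- curves
  out
}
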