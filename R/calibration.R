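# Clinical calibration: functional scores -> log likelihood ratios of
# pathogenicity (LLRp) and ACMG/AMP functional-evidence strengths.
#
# Two kernel density estimates are fitted over the map scores of
# pathogenic (P/LP) and benign (B/LB) reference variants; the LLRp of a
# score is the log10 ratio of the two densities at that score. Scores
# outside the observed range of reference scores get "undetermined"
# evidence. The kernel is Epanechnikov with a Scott rule-of-thumb
# bandwidth; the two-class density-ratio calibration is authored here
# because it is the package's core statistic.

#' Epanechnikov kernel density estimate at given points
#'
#' \code{f(s) = 1/(N h) * sum_i 0.75 (1 - u_i^2) [|u_i| <= 1]},
#' \code{u_i = (s - x_i)/h}.
#'
#' @param points Numeric sample the density is estimated from.
#' @param bandwidth Kernel half-width \code{h > 0}.
#' @param at Numeric vector of evaluation points.
#' @return Density values at \code{at}.
#' @examples
#' epanechnikov_density(0, 1, at = 0)    # 0.75
#' epanechnikov_density(0, 1, at = 1.5)  # 0
#' @export
epanechnikov_density <- function(points, bandwidth, at) {
  if (!is.numeric(bandwidth) || bandwidth <= 0)
    stop("bandwidth must be > 0", call. = FALSE)
  if (!length(points)) stop("need at least one point", call. = FALSE)
  vapply(at, function(s) {
    u <- (s - points) / bandwidth
    mean(0.75 * (1 - u^2) * (abs(u) <= 1)) / bandwidth
  }, numeric(1))
}

#' Scott rule-of-thumb bandwidth for the Epanechnikov kernel
#'
#' \code{h = c * sigma * N^(-1/5)} with the robust spread
#' \code{sigma = min(SD, IQR/1.349)} and \code{c = 2.34}, the canonical
#' Epanechnikov scaling of the Gaussian reference rule.
#'
#' @param points Numeric sample (length >= 2, nonzero spread).
#' @param constant Scale constant \code{c} (default 2.34).
#' @return Bandwidth \code{h}.
#' @export
scott_bandwidth <- function(points, constant = 2.34) {
  if (length(points) < 2)
    stop("need at least two points for a bandwidth", call. = FALSE)
  sigma <- min(stats::sd(points),
               stats::IQR(points) / 1.349)
  if (!is.finite(sigma) || sigma <= 0)
    stop("points have zero spread; supply a minimum-bandwidth override",
         call. = FALSE)
  constant * sigma * length(points)^(-1 / 5)
}

#' Calibrate functional scores against clinical reference variants
#'
#' Fits the two-class kernel density model over the scores of positive
#' (P/LP) and negative (B/LB) reference variants. The valid score range is
#' the union range \code{[min, max]} over both reference sets; scores
#' outside it are later assigned undetermined evidence.
#'
#' @param scores Numeric map scores of the reference variants, or a
#'   \code{"mave_map"} from which reference-variant scores are looked up
#'   by \code{hgvs_pro} (then \code{reference} must carry
#'   \code{hgvs_pro}). When calibrating from a map, only variants seen in
#'   both biological replicates are used.
#' @param positive Logical vector: reference label is pathogenic (P/LP).
#'   Ignored when \code{reference} is given.
#' @param reference Optional reference-set data.frame with columns
#'   \code{hgvs_pro} and \code{positive} (see
#'   \code{\link{read_reference_set}}).
#' @param bandwidth_constant Scott-rule constant (default 2.34).
#' @param density_floor Positive floor applied to both densities before
#'   the ratio so the LLRp stays finite inside the valid range
#'   (default 1e-12).
#' @return Object of class \code{"llr_calibration"}: reference scores per
#'   class, bandwidths, \code{valid_range}, and the settings.
#' @seealso \code{\link{predict.llr_calibration}},
#'   \code{\link{evidence_strength}}
#' @export
llr_calibrate <- function(scores, positive = NULL, reference = NULL,
                          bandwidth_constant = 2.34,
                          density_floor = 1e-12) {
  if (inherits(scores, "mave_map")) {
    if (is.null(reference))
      stop("calibrating from a map requires a reference set", call. = FALSE)
    tab <- scores$scores
    tab <- tab[tab$in_both_replicates, , drop = FALSE]
    idx <- match(reference$hgvs_pro, tab$hgvs_pro)
    found <- !is.na(idx)
    if (!all(found))
      message("llr_calibrate: ", sum(!found),
              " reference variant(s) without a both-replicate map score ",
              "dropped")
    scores <- tab$score[idx[found]]
    positive <- reference$positive[found]
  }
  stopifnot(length(scores) == length(positive))
  pos <- scores[positive]
  neg <- scores[!positive]
  if (length(pos) < 2 || length(neg) < 2)
    stop("need at least two reference variants in each class",
         call. = FALSE)
  structure(list(
    positive_scores = pos,
    negative_scores = neg,
    bandwidth_pos = scott_bandwidth(pos, bandwidth_constant),
    bandwidth_neg = scott_bandwidth(neg, bandwidth_constant),
    valid_range = range(c(pos, neg)),
    density_floor = density_floor,
    bandwidth_constant = bandwidth_constant),
    class = "llr_calibration")
}

#' Log likelihood ratio of pathogenicity at given scores
#'
#' \code{LLRp(s) = log10(fP(s) / fB(s))} with both densities floored at
#' the model's \code{density_floor}. Scores outside the valid range (the
#' observed range of reference scores) give \code{NA} — undetermined.
#'
#' @param model An \code{"llr_calibration"}.
#' @param score Numeric scores.
#' @return Numeric LLRp values (\code{NA} = undetermined).
#' @export
llrp <- function(model, score) {
  stopifnot(inherits(model, "llr_calibration"))
  fp <- pmax(epanechnikov_density(model$positive_scores,
                                  model$bandwidth_pos, score),
             model$density_floor)
  fb <- pmax(epanechnikov_density(model$negative_scores,
                                  model$bandwidth_neg, score),
             model$density_floor)
  out <- log10(fp / fb)
  out[score < model$valid_range[1] | score > model$valid_range[2]] <- NA
  out
}

# Evidence ladder on |log10 LR|: supporting / moderate / strong cut
# points from the point-based ACMG/AMP calibration lineage; the
# very-strong level (2 * 1.272) is collapsed into strong (capped).
.EVIDENCE_THRESHOLDS <- c(supporting = 0.318, moderate = 0.636,
                          strong = 1.272)

#' Convert LLRp values to ACMG/AMP functional-evidence strengths
#'
#' Thresholds on the log10 likelihood ratio: |LLRp| >= 1.272 is strong,
#' >= 0.636 moderate, >= 0.318 supporting (pathogenic direction for
#' positive values, benign for negative); below 0.318 the evidence is
#' indeterminate, and evidence beyond the very-strong level still reports
#' strong (capped). \code{NA} LLRp values give \code{"undetermined"}.
#'
#' Positions in \code{benign_mask} (an assay blind spot, e.g. a domain
#' whose loss of function the reporter cannot detect) never receive
#' benign-direction labels: a benign-direction LLRp there collapses to
#' indeterminate.
#'
#' @param llrp Numeric log10 likelihood ratios (\code{NA} = undetermined).
#' @param position Optional residue positions (needed when
#'   \code{benign_mask} is used).
#' @param benign_mask Integer positions masked from benign-direction
#'   evidence (default none; see \code{\link{phd1_positions}}).
#' @param thresholds Named ladder of |LLRp| cut points.
#' @return Character vector over \code{pathogenic_strong},
#'   \code{pathogenic_moderate}, \code{pathogenic_supporting},
#'   \code{indeterminate}, \code{benign_supporting},
#'   \code{benign_moderate}, \code{benign_strong}, \code{undetermined}.
#' @export
evidence_strength <- function(llrp, position = NULL,
                              benign_mask = integer(0),
                              thresholds = .EVIDENCE_THRESHOLDS) {
  lev <- function(a) {
    ifelse(a >= thresholds["strong"], "strong",
           ifelse(a >= thresholds["moderate"], "moderate",
                  ifelse(a >= thresholds["supporting"], "supporting",
                         "indeterminate")))
  }
  out <- rep("undetermined", length(llrp))
  ok <- !is.na(llrp)
  strength <- lev(abs(llrp[ok]))
  dir <- ifelse(llrp[ok] > 0, "pathogenic", "benign")
  lab <- ifelse(strength == "indeterminate", "indeterminate",
                paste(dir, strength, sep = "_"))
  if (length(benign_mask)) {
    if (is.null(position))
      stop("benign_mask requires positions", call. = FALSE)
    masked <- position[ok] %in% benign_mask & llrp[ok] < 0
    lab[masked] <- "indeterminate"
  }
  out[ok] <- lab
  out
}

#' Residue positions of the AIRE PHD1 domain
#'
#' The PHD1 histone-reader domain (residues 296 to 343) is the canonical
#' benign-mask example: a reporter integrated in open chromatin cannot
#' detect loss of PHD1 function, so benign-direction evidence is withheld
#' there.
#'
#' @return Integer vector 296:343.
#' @export
phd1_positions <- function() 296:343

#' Caution flag for scores whose confidence interval straddles the midpoint
#'
#' Flags variants whose two-sided confidence interval
#' \code{[score - z se, score + z se]} contains the midpoint between the
#' nonsense and synonymous medians (0.5 on the rescaled score scale), i.e.
#' scores that cannot be confidently placed on either side of
#' half-function. The interval is closed.
#'
#' @param score Numeric scores.
#' @param se Standard errors (>= 0).
#' @param midpoint Score midpoint (default 0.5).
#' @param z Normal quantile of the interval (default 1.96, 95% two-sided).
#' @return Logical flags.
#' @export
caution_flag <- function(score, se, midpoint = 0.5, z = 1.96) {
  if (any(se < 0, na.rm = TRUE)) stop("se must be >= 0", call. = FALSE)
  score - z * se <= midpoint & midpoint <= score + z * se
}

#' Predict LLRp, evidence and caution for new scores
#'
#' @param object An \code{"llr_calibration"}.
#' @param newdata Numeric scores, or a data.frame/\code{"mave_map"} with
#'   \code{score}, \code{se} and (optionally) \code{position} columns.
#' @param benign_mask Positions masked from benign-direction evidence.
#' @param ... Unused.
#' @return Data.frame with \code{score}, \code{llrp}, \code{evidence} and
#'   (when errors are available) \code{caution}.
#' @export
predict.llr_calibration <- function(object, newdata, benign_mask = integer(0),
                                    ...) {
  if (inherits(newdata, "mave_map")) newdata <- newdata$scores
  if (is.numeric(newdata)) newdata <- data.frame(score = newdata)
  out <- data.frame(score = newdata$score)
  if ("hgvs_pro" %in% names(newdata)) out$hgvs_pro <- newdata$hgvs_pro
  out$llrp <- llrp(object, newdata$score)
  out$evidence <- evidence_strength(out$llrp,
                                    position = newdata$position,
                                    benign_mask = benign_mask)
  if ("se" %in% names(newdata))
    out$caution <- caution_flag(newdata$score, newdata$se)
  out
}

#' @export
print.llr_calibration <- function(x, ...) {
  cat("LLRp calibration (Epanechnikov kernel, Scott bandwidths)\n")
  cat(sprintf("  positive refs: %d (h = %.4f)\n",
              length(x$positive_scores), x$bandwidth_pos))
  cat(sprintf("  negative refs: %d (h = %.4f)\n",
              length(x$negative_scores), x$bandwidth_neg))
  cat(sprintf("  valid score range: [%.3f, %.3f]\n",
              x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' Reference densities and the LLRp curve
#' @param x An \code{"llr_calibration"}.
#' @param n Grid size.
#' @param ... Unused.
#' @export
plot.llr_calibration <- function(x, n = 400, ...) {
  s <- seq(x$valid_range[1], x$valid_range[2], length.out = n)
  fp <- epanechnikov_density(x$positive_scores, x$bandwidth_pos, s)
  fb <- epanechnikov_density(x$negative_scores, x$bandwidth_neg, s)
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(old))
  graphics::matplot(s, cbind(fp, fb), type = "l", lty = 1,
                    col = c("firebrick", "steelblue"),
                    xlab = "functional score", ylab = "density")
  graphics::legend("top", legend = c("pathogenic refs", "benign refs"),
                   col = c("firebrick", "steelblue"), lty = 1, bty = "n")
  graphics::plot(s, llrp(x, s), type = "l", xlab = "functional score",
                 ylab = "LLRp (log10)")
  graphics::abline(h = c(-1, 1) %o% .EVIDENCE_THRESHOLDS, lty = 3,
                   col = "grey")
  invisible(x)
}
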