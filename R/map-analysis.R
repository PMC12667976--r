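# Descriptive and inferential analyses of a finished score table:
# positional consensus, group comparisons against structural or chemical
# annotations, amino-acid category transition trends, and one-tailed
# empirical gain-of-function testing against the synonymous distribution.

#' Per-position median missense score (consensus track)
#'
#' @param scores Score data.frame with \code{position}, \code{score} and
#'   \code{vclass} columns (e.g. \code{mave_map$scores}), or a
#'   \code{"mave_map"}.
#' @return Data.frame with \code{position} and \code{median_score}, one
#'   row per position holding at least one missense score.
#' @export
positional_medians <- function(scores) {
  if (inherits(scores, "mave_map")) scores <- scores$scores
  mis <- scores[scores$vclass == "missense", , drop = FALSE]
  med <- tapply(mis$score, mis$position, stats::median)
  data.frame(position = as.integer(names(med)),
             median_score = as.numeric(med))
}

#' Compare score distributions between two groups
#'
#' Two-sided Wilcoxon rank-sum test between group \code{a} and group
#' \code{b} scores (e.g. buried vs surface positions, interface vs
#' non-interface, substitutions introducing a hydrophobic residue vs not).
#'
#' @param scores_a,scores_b Numeric scores of the two groups.
#' @param names Length-2 labels for reporting.
#' @return List with \code{median_a}, \code{median_b}, \code{delta}
#'   (= \code{median_a - median_b}), \code{p}, \code{n_a}, \code{n_b}.
#' @export
group_comparison <- function(scores_a, scores_b,
                             names = c("a", "b")) {
  if (!length(scores_a) || !length(scores_b))
    stop("both groups must be non-empty", call. = FALSE)
  wt <- stats::wilcox.test(scores_a, scores_b, exact = FALSE)
  out <- list(median_a = stats::median(scores_a),
              median_b = stats::median(scores_b),
              delta = stats::median(scores_a) - stats::median(scores_b),
              p = wt$p.value, n_a = length(scores_a),
              n_b = length(scores_b))
  names(out)[1:2] <- paste0("median_", names)
  out
}

# Chemical categories of the 20 amino acids (three-letter codes).
# Membership is a documented convention: hydrophobic covers the aliphatic
# and aromatic side chains; His counts as positively charged; Cys, Gly
# and Pro are grouped with the polar/special class.
.AA_CATEGORY <- c(
  Ala = "hydrophobic", Val = "hydrophobic", Ile = "hydrophobic",
  Leu = "hydrophobic", Met = "hydrophobic", Phe = "hydrophobic",
  Trp = "hydrophobic", Tyr = "hydrophobic",
  Lys = "positive", Arg = "positive", His = "positive",
  Asp = "negative", Glu = "negative",
  Ser = "polar", Thr = "polar", Asn = "polar", Gln = "polar",
  Cys = "polar", Gly = "polar", Pro = "polar")

#' Amino-acid chemical category
#' @param aa Three-letter amino-acid codes.
#' @return Character: \code{hydrophobic}, \code{polar}, \code{positive}
#'   or \code{negative} (\code{NA} for \code{Ter}).
#' @export
aa_category <- function(aa) unname(.AA_CATEGORY[aa])

#' Median score matrix over from/to amino-acid categories
#'
#' Median missense score per (reference category, substituted category)
#' cell, with cell counts. Within-category cells sit on the diagonal.
#'
#' @param scores Score data.frame (or \code{"mave_map"}) with
#'   \code{ref_aa}, \code{alt_aa}, \code{vclass}, \code{score}.
#' @param categories Category lookup (named by three-letter code).
#' @return List with \code{medians} and \code{counts}, both 4x4 matrices
#'   (rows = from, cols = to); empty cells are \code{NA} / 0.
#' @export
category_transition_matrix <- function(scores,
                                       categories = .AA_CATEGORY) {
  if (inherits(scores, "mave_map")) scores <- scores$scores
  mis <- scores[scores$vclass == "missense", , drop = FALSE]
  lev <- c("hydrophobic", "polar", "positive", "negative")
  from <- factor(unname(categories[mis$ref_aa]), levels = lev)
  to <- factor(unname(categories[mis$alt_aa]), levels = lev)
  med <- tapply(mis$score, list(from, to), stats::median)
  cnt <- table(from, to)
  list(medians = med, counts = unclass(cnt))
}

#' One-tailed empirical gain-of-function test
#'
#' For each tested variant, the empirical p-value of its score against the
#' synonymous reference distribution with the add-one form
#' \code{p = (1 + #synonymous >= score) / (N_syn + 1)}; ties count toward
#' the exceedance set (conservative) and the add-one form avoids zero
#' p-values. Benjamini-Hochberg adjustment is applied over all tested
#' variants.
#'
#' @param scores Numeric scores of the variants to test.
#' @param synonymous_scores Synonymous reference scores (>= 20 required).
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @return Data.frame with \code{score}, \code{p}, \code{p_adj},
#'   \code{significant}.
#' @export
gain_of_function_test <- function(scores, synonymous_scores,
                                  alpha = 0.05) {
  n_syn <- length(synonymous_scores)
  if (n_syn < 20)
    stop("need at least 20 synonymous scores (got ", n_syn, ")",
         call. = FALSE)
  p <- vapply(scores, function(s)
    (1 + sum(synonymous_scores >= s)) / (n_syn + 1), numeric(1))
  p_adj <- stats::p.adjust(p, method = "BH")
  data.frame(score = scores, p = p, p_adj = p_adj,
             significant = p_adj < alpha)
}
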