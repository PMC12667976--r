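# Functional score calculation: count table -> rescaled per-amino-acid
# scores with standard errors.
#
# Pipeline (per biological replicate): counts-per-million conversion,
# abundance filtering on the non-select pool, wild-type error subtraction,
# enrichment log-ratio, affine rescaling anchored on the nonsense and
# synonymous medians (0 and 1), codon-to-amino-acid aggregation with
# delta-method standard errors, abundance-trend error regularization; then
# replicates are averaged and errors propagated.

#' Counts per million
#'
#' @param count Non-negative read counts.
#' @param depth Positive total reads for the tile/condition.
#' @return \code{1e6 * count / depth}.
#' @export
cpm <- function(count, depth) {
  if (any(depth <= 0)) stop("depth must be > 0", call. = FALSE)
  1e6 * count / depth
}

#' Marginal variant frequencies by condition and replicate
#'
#' Converts a long count table into one row per codon change and replicate
#' with a counts-per-million column for each condition; codon changes
#' absent from a condition get 0. Raw select/non-select counts are kept
#' for the delta-method standard error of singleton measurements.
#'
#' @param counts Count data.frame (see \code{\link{read_count_table}}).
#'   Multiple tiles of the same condition/replicate are summed (counts and
#'   depths) before conversion.
#' @return Data.frame with columns \code{replicate}, \code{codon_index},
#'   \code{ref_codon}, \code{alt_codon}, \code{cpm_select},
#'   \code{cpm_nonselect}, \code{cpm_wt_select}, \code{cpm_wt_nonselect},
#'   \code{n_select}, \code{n_nonselect}.
#' @export
marginal_frequencies <- function(counts) {
  counts <- validate_count_table(counts)
  key <- paste(counts$replicate, counts$codon_index, counts$alt_codon,
               sep = "\r")
  conds <- c("select", "nonselect", "wt_select", "wt_nonselect")
  base <- unique(counts[c("replicate", "codon_index", "ref_codon",
                          "alt_codon")])
  base <- base[order(base$replicate, base$codon_index, base$alt_codon), ]
  rownames(base) <- NULL
  bkey <- paste(base$replicate, base$codon_index, base$alt_codon,
                sep = "\r")
  for (cond in conds) {
    sel <- counts$condition == cond
    cnt <- rowsum(counts$count[sel], group = key[sel])
    dep <- rowsum(counts$depth[sel], group = key[sel])
    v <- numeric(nrow(base))
    n <- numeric(nrow(base))
    idx <- match(rownames(cnt), bkey)
    v[idx] <- 1e6 * cnt[, 1] / dep[, 1]
    n[idx] <- cnt[, 1]
    base[[paste0("cpm_", cond)]] <- v
    if (cond %in% c("select", "nonselect"))
      base[[paste0("n_", cond)]] <- n
  }
  base
}

#' Filter codon changes on non-select abundance
#'
#' A codon change is retained in a replicate iff its non-select frequency
#' reaches \code{threshold} counts per million in that replicate
#' (boundary inclusive). Filtering is per replicate: a change may survive
#' in one replicate only, in which case its final score comes from that
#' replicate alone.
#'
#' @param freqs Output of \code{\link{marginal_frequencies}}.
#' @param threshold Minimum non-select cpm (default 10).
#' @return The retained rows of \code{freqs}.
#' @export
filter_by_nonselect <- function(freqs, threshold = 10) {
  out <- freqs[freqs$cpm_nonselect >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Error-corrected enrichment ratio
#'
#' Subtracts the wild-type control (base-call error) frequencies from both
#' pools and forms the select / non-select frequency ratio; numerator and
#' denominator are floored at \code{floor_cpm} so the ratio stays finite
#' and positive when error subtraction drives a frequency to zero or
#' below.
#'
#' @param freqs Filtered frequency rows (see
#'   \code{\link{filter_by_nonselect}}).
#' @param floor_cpm Positive floor applied after subtraction
#'   (default 0.1 cpm).
#' @param log_base Base of the enrichment logarithm (default natural).
#'   Rescaling makes final scores invariant to this choice.
#' @return \code{freqs} with added columns \code{phi}, \code{logphi} and
#'   \code{floored} (logical: either side hit the floor).
#' @export
enrichment_ratio <- function(freqs, floor_cpm = 0.1, log_base = exp(1)) {
  if (!is.numeric(floor_cpm) || floor_cpm <= 0)
    stop("floor_cpm must be > 0", call. = FALSE)
  num <- freqs$cpm_select - freqs$cpm_wt_select
  den <- freqs$cpm_nonselect - freqs$cpm_wt_nonselect
  floored <- num < floor_cpm | den < floor_cpm
  num <- pmax(num, floor_cpm)
  den <- pmax(den, floor_cpm)
  freqs$phi <- num / den
  freqs$logphi <- log(freqs$phi, base = log_base)
  freqs$floored <- floored
  attr(freqs, "log_base") <- log_base
  freqs
}

# variant class of each codon change from the genetic code
.codon_vclass <- function(ref_codon, alt_codon) {
  ref_aa <- unname(.GENETIC_CODE[ref_codon])
  alt_aa <- unname(.GENETIC_CODE[alt_codon])
  ifelse(alt_aa == "Ter", "nonsense",
         ifelse(alt_aa == ref_aa, "synonymous", "missense"))
}

#' Rescale enrichment log-ratios to functional scores within a replicate
#'
#' Affine rescaling anchored on internal controls: the median nonsense
#' log-ratio maps to 0 and the median synonymous log-ratio maps to 1, so a
#' score of 0 means "null-like" and 1 means "wild-type-like". Applied
#' separately per replicate.
#'
#' @param enr Output of \code{\link{enrichment_ratio}} for one replicate.
#' @return \code{enr} with added columns \code{vclass} and \code{score};
#'   attribute \code{"anchors"} holds the nonsense/synonymous medians and
#'   the rescale denominator.
#' @export
rescale_replicate <- function(enr) {
  enr$vclass <- .codon_vclass(enr$ref_codon, enr$alt_codon)
  med_non <- stats::median(enr$logphi[enr$vclass == "nonsense"])
  med_syn <- stats::median(enr$logphi[enr$vclass == "synonymous"])
  if (!is.finite(med_non))
    stop("no nonsense changes scored in this replicate; cannot calibrate",
         call. = FALSE)
  if (!is.finite(med_syn))
    stop("no synonymous changes scored in this replicate; cannot calibrate",
         call. = FALSE)
  if (med_syn == med_non)
    stop("degenerate calibration: nonsense and synonymous medians are equal",
         call. = FALSE)
  enr$score <- (enr$logphi - med_non) / (med_syn - med_non)
  lb <- attr(enr, "log_base")
  attr(enr, "anchors") <- c(median_nonsense = med_non,
                            median_synonymous = med_syn,
                            rescale_denom = med_syn - med_non,
                            log_base = if (is.null(lb)) exp(1) else lb)
  enr
}

#' Aggregate codon-level scores to amino-acid changes within a replicate
#'
#' All codon changes translating to the same amino-acid substitution are
#' averaged. The standard error is the sample SD over codon-level scores
#' divided by \code{sqrt(n)} when \code{n >= 2}; a substitution measured by
#' a single codon change gets a count-based (Poisson delta-method) error,
#' \code{sqrt(1/n_select + 1/n_nonselect)} on the log-ratio scale divided
#' by the rescale denominator, with zero counts clamped to 1 read.
#'
#' @param scored Output of \code{\link{rescale_replicate}}.
#' @return Data.frame with one row per amino-acid change: \code{replicate},
#'   \code{position}, \code{ref_aa}, \code{alt_aa}, \code{vclass},
#'   \code{hgvs_pro}, \code{score}, \code{se}, \code{n_codon_measurements},
#'   \code{cpm_nonselect} (mean over contributing codon changes),
#'   \code{snv_accessible}.
#' @export
aggregate_codon_to_aa <- function(scored) {
  anchors <- attr(scored, "anchors")
  lb <- if ("log_base" %in% names(anchors)) unname(anchors["log_base"])
        else exp(1)
  # rescale denominator converted to natural-log units so the Poisson
  # delta-method error does not depend on the enrichment log base
  denom <- abs(unname(anchors["rescale_denom"])) * log(lb)
  scored$ref_aa <- unname(.GENETIC_CODE[scored$ref_codon])
  scored$alt_aa <- unname(.GENETIC_CODE[scored$alt_codon])
  key <- paste(scored$replicate, scored$codon_index, scored$alt_aa,
               sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(replicate = scored$replicate[first],
                    position = scored$codon_index[first],
                    ref_aa = scored$ref_aa[first],
                    alt_aa = scored$alt_aa[first],
                    vclass = scored$vclass[first],
                    stringsAsFactors = FALSE)
  okey <- key[first]
  grp <- match(key, okey)
  out$score <- as.numeric(tapply(scored$score, grp, mean))
  out$n_codon_measurements <- as.integer(tapply(scored$score, grp, length))
  sd_codon <- as.numeric(tapply(scored$score, grp, stats::sd))
  out$se <- sd_codon / sqrt(out$n_codon_measurements)
  # singleton substitutions: delta-method SE from read counts
  single <- which(out$n_codon_measurements == 1L)
  if (length(single)) {
    idx <- match(okey[single], key)
    n_sel <- pmax(scored$n_select[idx], 1)
    n_non <- pmax(scored$n_nonselect[idx], 1)
    out$se[single] <- sqrt(1 / n_sel + 1 / n_non) / denom
  }
  out$cpm_nonselect <- as.numeric(tapply(scored$cpm_nonselect, grp, mean))
  # SNV accessibility: reachable by one nucleotide change of any
  # contributing reference codon
  snv <- logical(nrow(scored))
  ref_alt <- unique(scored[c("ref_codon", "alt_aa")])
  ref_alt$reach <- mapply(function(rc, aa)
    aa %in% snv_neighbor_substitutions(rc),
    ref_alt$ref_codon, ref_alt$alt_aa)
  m <- match(paste(scored$ref_codon, scored$alt_aa),
             paste(ref_alt$ref_codon, ref_alt$alt_aa))
  snv <- ref_alt$reach[m]
  out$snv_accessible <- as.logical(tapply(snv, grp, any))
  out$hgvs_pro <- ifelse(out$vclass == "synonymous",
                         paste0("p.", out$ref_aa, out$position, "="),
                         paste0("p.", out$ref_aa, out$position, out$alt_aa))
  rownames(out) <- NULL
  attr(out, "anchors") <- anchors
  out
}

#' Regularize standard errors against the abundance trend
#'
#' Experimental error tracks variant abundance in the non-select pool:
#' rarer variants have noisier scores. A log-log linear trend
#' \code{log(se) ~ log(cpm_nonselect)} is fitted across variants by least
#' squares, and each observed error is shrunk toward its fitted value with
#' weight \code{w = prior_mass / (prior_mass + n_obs - 1)} (so a variant
#' measured once takes the trend value, and weight on the observed error
#' grows with its number of codon-level measurements):
#' \code{se' = sqrt(w * se_fit^2 + (1 - w) * se_obs^2)}.
#'
#' @param aa Output of \code{\link{aggregate_codon_to_aa}} (one replicate).
#' @param prior_mass Pseudo-measurements behind the fitted trend
#'   (default 4).
#' @return \code{aa} with \code{se} replaced by the shrunken value and the
#'   raw value kept as \code{se_raw}.
#' @export
regularize_se <- function(aa, prior_mass = 4) {
  aa$se_raw <- aa$se
  usable <- is.finite(aa$se) & aa$se > 0 & aa$cpm_nonselect > 0
  if (sum(usable) < 10) {
    warning("fewer than 10 variants with usable errors; ",
            "skipping regularization")
    return(aa)
  }
  fit <- stats::lm(log(se) ~ log(cpm_nonselect), data = aa[usable, ])
  se_fit <- exp(stats::predict(fit, newdata = aa))
  w <- prior_mass / (prior_mass + aa$n_codon_measurements - 1)
  se_obs <- ifelse(is.finite(aa$se), aa$se, se_fit)
  aa$se <- sqrt(w * se_fit^2 + (1 - w) * se_obs^2)
  aa
}

#' Combine biological replicates
#'
#' Replicate scores are averaged (unweighted) and standard errors
#' propagated by the delta method for a mean of independent estimates:
#' \code{se = sqrt(sum(se_i^2)) / k}. Substitutions seen in a single
#' replicate keep that replicate's score and error and are flagged
#' \code{in_both_replicates = FALSE}.
#'
#' @param aa_reps Row-bound per-replicate tables from
#'   \code{\link{regularize_se}} (or \code{\link{aggregate_codon_to_aa}}).
#' @param n_replicates Total replicates in the experiment (for the
#'   \code{in_both_replicates} flag); defaults to the number of distinct
#'   replicate ids present.
#' @return One row per amino-acid substitution: \code{hgvs_pro},
#'   \code{position}, \code{ref_aa}, \code{alt_aa}, \code{vclass},
#'   \code{score}, \code{se}, \code{in_both_replicates},
#'   \code{snv_accessible}, \code{n_codon_measurements} (summed),
#'   \code{n_replicates_seen}, \code{cpm_nonselect} (mean).
#' @export
combine_replicates <- function(aa_reps,
                               n_replicates = length(unique(aa_reps$replicate))) {
  key <- paste(aa_reps$position, aa_reps$alt_aa, sep = "\r")
  first <- !duplicated(key)
  out <- aa_reps[first, c("hgvs_pro", "position", "ref_aa", "alt_aa",
                          "vclass")]
  grp <- match(key, key[first])
  out$score <- as.numeric(tapply(aa_reps$score, grp, mean))
  k <- as.integer(tapply(aa_reps$score, grp, length))
  out$se <- sqrt(as.numeric(tapply(aa_reps$se^2, grp, sum))) / k
  out$in_both_replicates <- k == n_replicates
  out$snv_accessible <-
    as.logical(tapply(aa_reps$snv_accessible, grp, any))
  out$n_codon_measurements <-
    as.integer(tapply(aa_reps$n_codon_measurements, grp, sum))
  out$n_replicates_seen <- k
  out$cpm_nonselect <- as.numeric(tapply(aa_reps$cpm_nonselect, grp, mean))
  out <- out[order(out$position, out$alt_aa), ]
  rownames(out) <- NULL
  out
}

#' Fit a variant effect map from a count table
#'
#' The central fitting function: runs the full scoring pipeline
#' (frequencies, non-select filtering, wild-type error subtraction,
#' enrichment log-ratio, nonsense/synonymous rescaling, codon-to-residue
#' aggregation, error regularization, replicate averaging) and returns a
#' \code{"mave_map"} object.
#'
#' @param counts Count data.frame (layout of
#'   \code{\link{read_count_table}}) or a \code{"sim_experiment"}.
#' @param filter_cpm Minimum non-select counts per million (default 10).
#' @param floor_cpm Post-subtraction frequency floor (default 0.1).
#' @param log_base Enrichment logarithm base (default natural; final
#'   scores do not depend on it).
#' @param prior_mass Regularization prior mass (default 4);
#'   \code{NULL} disables error regularization.
#' @return An object of class \code{"mave_map"}: \code{scores} (final
#'   per-substitution table), \code{replicate_scores}, \code{codon_scores}
#'   (rescaled codon-level table), \code{anchors} (per-replicate
#'   nonsense/synonymous medians), \code{log} (filtering/flooring tallies)
#'   and \code{settings}.
#' @seealso \code{\link{coef.mave_map}}, \code{\link{plot.mave_map}}
#' @examples
#' \donttest{
#' expt <- simulate_experiment(sim_config(seed = 1, n_clones = 20000,
#'                                        depth = 1e5, protein_length = 60))
#' fit <- score_variants(expt)
#' summary(fit)
#' }
#' @export
score_variants <- function(counts, filter_cpm = 10, floor_cpm = 0.1,
                           log_base = exp(1), prior_mass = 4) {
  if (inherits(counts, "sim_experiment")) counts <- counts$counts
  freqs <- marginal_frequencies(counts)
  n_all <- nrow(freqs)
  kept <- filter_by_nonselect(freqs, threshold = filter_cpm)
  reps <- sort(unique(kept$replicate))
  codon_scores <- list()
  aa_tables <- list()
  anchors <- list()
  for (r in reps) {
    enr <- enrichment_ratio(kept[kept$replicate == r, , drop = FALSE],
                            floor_cpm = floor_cpm, log_base = log_base)
    scr <- rescale_replicate(enr)
    aa <- aggregate_codon_to_aa(scr)
    if (!is.null(prior_mass)) aa <- regularize_se(aa, prior_mass)
    codon_scores[[as.character(r)]] <- scr
    aa_tables[[as.character(r)]] <- aa
    anchors[[as.character(r)]] <- attr(scr, "anchors")
  }
  aa_reps <- do.call(rbind, aa_tables)
  rownames(aa_reps) <- NULL
  scores <- combine_replicates(aa_reps, n_replicates = length(reps))
  codon_all <- do.call(rbind, codon_scores)
  rownames(codon_all) <- NULL
  structure(list(
    scores = scores,
    replicate_scores = aa_reps,
    codon_scores = codon_all,
    anchors = anchors,
    log = list(n_codon_changes = n_all,
               n_filtered_out = n_all - nrow(kept),
               n_floored = sum(codon_all$floored),
               n_single_replicate = sum(!scores$in_both_replicates)),
    settings = list(filter_cpm = filter_cpm, floor_cpm = floor_cpm,
                    log_base = log_base, prior_mass = prior_mass,
                    replicates = reps)),
    class = "mave_map")
}

#' @export
print.mave_map <- function(x, ...) {
  cat("Variant effect map (", nrow(x$scores), " substitutions, ",
      length(x$settings$replicates), " replicate(s))\n", sep = "")
  cat("  in both replicates: ", sum(x$scores$in_both_replicates), "\n",
      sep = "")
  cat("  filtered codon changes (< ", x$settings$filter_cpm,
      " cpm non-select): ", x$log$n_filtered_out, "\n", sep = "")
  invisible(x)
}

#' @export
summary.mave_map <- function(object, ...) {
  s <- object$scores
  by_class <- split(s$score, s$vclass)
  cat("Variant effect map summary\n")
  cat(sprintf("  %d substitutions (%d missense, %d nonsense, %d synonymous)\n",
              nrow(s), sum(s$vclass == "missense"),
              sum(s$vclass == "nonsense"), sum(s$vclass == "synonymous")))
  for (cl in names(by_class))
    cat(sprintf("  median %s score: %.3f\n", cl,
                stats::median(by_class[[cl]])))
  cat(sprintf("  median standard error: %.4f\n", stats::median(s$se)))
  invisible(object)
}

#' Extract final scores from a fitted map
#' @param object A \code{"mave_map"}.
#' @param ... Unused.
#' @return Named numeric vector of scores (names are HGVS strings).
#' @export
coef.mave_map <- function(object, ...) {
  stats::setNames(object$scores$score, object$scores$hgvs_pro)
}

#' Score distributions by variant class
#' @param x A \code{"mave_map"}.
#' @param ... Passed to \code{\link[graphics]{boxplot}}.
#' @export
plot.mave_map <- function(x, ...) {
  graphics::boxplot(score ~ vclass, data = x$scores,
                    xlab = "variant class", ylab = "functional score", ...)
  graphics::abline(h = c(0, 1), lty = 3)
  invisible(x)
}
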