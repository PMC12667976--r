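# Genotype-phenotype analyses: combined-allele map (CAM) scores for
# diploid genotypes, symptom-count correlation, diagnostic-dyad
# comparison, and carrier-based case/control association.

#' Score one allele against a variant effect map
#'
#' Wild-type alleles score 1, truncating alleles (nonsense, frameshift,
#' splice site) are modeled as null and score 0, and a missense allele
#' takes its map score. An allele carrying several missense variants
#' scores as the minimum over them (the most damaging hit dominates).
#'
#' @param allele \code{"WT"}, \code{"truncating"}, or a character vector
#'   of protein-variant HGVS strings.
#' @param score_table Data.frame with \code{hgvs_pro} and \code{score}
#'   columns (e.g. \code{mave_map$scores}).
#' @return Numeric allele score.
#' @export
allele_score <- function(allele, score_table) {
  if (length(allele) == 1L && allele %in% c("WT", "wt")) return(1)
  if (length(allele) == 1L && allele %in% c("truncating", "null"))
    return(0)
  idx <- match(allele, score_table$hgvs_pro)
  if (anyNA(idx))
    stop("no map score for variant(s): ",
         paste(allele[is.na(idx)], collapse = ", "), call. = FALSE)
  min(score_table$score[idx])
}

#' Combined-allele map (CAM) score of a diploid genotype
#'
#' The sum of the two allele scores: WT/WT gives 2, a homozygous null 0.
#' With all map scores in [0, 1] the CAM lies in [0, 2]; gain-of-function
#' scores above 1 can push it higher.
#'
#' @param allele1,allele2 Alleles as in \code{\link{allele_score}}.
#' @param score_table Score lookup table.
#' @return List with \code{cam} and the per-allele \code{components}.
#' @export
cam_score <- function(allele1, allele2, score_table) {
  s1 <- allele_score(allele1, score_table)
  s2 <- allele_score(allele2, score_table)
  list(cam = s1 + s2, components = c(s1, s2))
}

#' CAM scores for a whole cohort
#'
#' @param cohort Cohort data.frame (see \code{\link{read_cohort_table}}):
#'   list-columns \code{allele1}, \code{allele2} of alleles.
#' @param score_table Score lookup table (or a \code{"mave_map"}).
#' @return \code{cohort} with an added numeric \code{cam} column.
#' @export
cohort_cam <- function(cohort, score_table) {
  if (inherits(score_table, "mave_map")) score_table <- score_table$scores
  cohort$cam <- mapply(function(a1, a2)
    cam_score(a1, a2, score_table)$cam,
    cohort$allele1, cohort$allele2)
  cohort
}

# positions touched by a patient's missense alleles
.cohort_positions <- function(cohort) {
  lapply(seq_len(nrow(cohort)), function(i) {
    alleles <- c(cohort$allele1[[i]], cohort$allele2[[i]])
    hgvs <- setdiff(alleles, c("WT", "wt", "truncating", "null"))
    if (!length(hgvs)) return(integer(0))
    pv <- parse_protein_variant(hgvs)
    if (inherits(pv, "protein_variant")) pv <- list(pv)
    vapply(pv, `[[`, integer(1), "position")
  })
}

#' Drop patients carrying a variant in given positions
#'
#' Used to exclude patients with any variant in an assay blind spot (e.g.
#' the PHD1 domain) before genotype-phenotype testing.
#'
#' @param cohort Cohort data.frame.
#' @param positions Integer positions to exclude on.
#' @return The filtered cohort.
#' @export
exclude_positions <- function(cohort, positions) {
  pos <- .cohort_positions(cohort)
  keep <- !vapply(pos, function(p) any(p %in% positions), logical(1))
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correlate CAM scores with symptom counts
#'
#' @param cam Numeric CAM scores.
#' @param n_symptoms Integer symptom counts.
#' @param method \code{"pearson"} (default, the conventional "R") or
#'   \code{"spearman"}.
#' @return List with \code{r}, \code{p} (two-sided) and \code{n}.
#' @export
symptom_correlation <- function(cam, n_symptoms,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(cam) & is.finite(n_symptoms)
  cam <- cam[ok]; n_symptoms <- n_symptoms[ok]
  if (length(cam) < 3) stop("need at least 3 patients", call. = FALSE)
  if (stats::sd(cam) == 0 || stats::sd(n_symptoms) == 0)
    stop("zero variance in CAM or symptom counts", call. = FALSE)
  ct <- stats::cor.test(cam, n_symptoms, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(cam))
}

#' Diagnostic-dyad status from symptom labels
#'
#' The APS-1 diagnostic rule: at least two of hypoparathyroidism, adrenal
#' insufficiency, and chronic mucocutaneous candidiasis.
#'
#' @param symptoms Character vector of symptom labels for one patient, or
#'   a list of such vectors.
#' @param dyad_symptoms The three diagnostic labels.
#' @return Logical flag(s).
#' @export
dyad_status <- function(symptoms,
                        dyad_symptoms = c("hypoparathyroidism",
                                          "adrenal_insufficiency",
                                          "candidiasis")) {
  if (is.list(symptoms))
    return(vapply(symptoms, dyad_status, logical(1),
                  dyad_symptoms = dyad_symptoms))
  sum(dyad_symptoms %in% symptoms) >= 2
}

#' Compare CAM scores between dyad and non-dyad patients
#'
#' Two-sided Wilcoxon rank-sum test of CAM between patients with and
#' without the diagnostic dyad.
#'
#' @param cam Numeric CAM scores.
#' @param dyad Logical dyad status per patient.
#' @return List with \code{median_dyad}, \code{median_nondyad}, \code{p},
#'   and the group sizes \code{n_dyad}, \code{n_nondyad}.
#' @export
dyad_comparison <- function(cam, dyad) {
  stopifnot(length(cam) == length(dyad))
  if (!any(dyad) || all(dyad))
    stop("both dyad and non-dyad groups must be non-empty", call. = FALSE)
  wt <- stats::wilcox.test(cam[dyad], cam[!dyad], exact = FALSE)
  list(median_dyad = stats::median(cam[dyad]),
       median_nondyad = stats::median(cam[!dyad]),
       p = wt$p.value, n_dyad = sum(dyad), n_nondyad = sum(!dyad))
}

#' Carrier-based case/control association
#'
#' Odds ratio for a diagnosis given carrier status of (at least one)
#' qualifying variant, with the Haldane-Anscombe +0.5 correction applied
#' to all cells when any cell is zero, a Wald 95% confidence interval on
#' the log odds ratio, a Fisher exact p-value, and (when several symptoms
#' are tested together via \code{\link{carrier_association_table}})
#' Benjamini-Hochberg adjustment.
#'
#' @param carrier Logical carrier flags per participant.
#' @param diagnosis Logical diagnosis flags per participant.
#' @return List with \code{odds_ratio}, \code{ci95} (length 2), \code{p},
#'   \code{corrected} (logical: +0.5 applied) and the 2x2 \code{table}
#'   (a, b, c, d) = (carrier cases, carrier controls, non-carrier cases,
#'   non-carrier controls).
#' @export
carrier_association <- function(carrier, diagnosis) {
  stopifnot(length(carrier) == length(diagnosis))
  a <- sum(carrier & diagnosis)
  b <- sum(carrier & !diagnosis)
  c <- sum(!carrier & diagnosis)
  d <- sum(!carrier & !diagnosis)
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    stop("empty margin in the 2x2 carrier/diagnosis table", call. = FALSE)
  corrected <- any(c(a, b, c, d) == 0)
  h <- if (corrected) 0.5 else 0
  or <- ((a + h) / (b + h)) / ((c + h) / (d + h))
  se_log <- sqrt(1 / (a + h) + 1 / (b + h) + 1 / (c + h) + 1 / (d + h))
  ci <- exp(log(or) + c(-1, 1) * 1.96 * se_log)
  p <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
  list(odds_ratio = or, ci95 = ci, p = p, corrected = corrected,
       table = c(a = a, b = b, c = c, d = d))
}

#' Carrier associations across a symptom list with BH adjustment
#'
#' @param carrier Logical carrier flags per participant.
#' @param diagnoses Data.frame (or named list) of logical diagnosis flags,
#'   one column per symptom.
#' @return Data.frame with one row per symptom: \code{symptom},
#'   \code{odds_ratio}, \code{ci_lo}, \code{ci_hi}, \code{p},
#'   \code{p_adj} (Benjamini-Hochberg across the symptom family).
#' @export
carrier_association_table <- function(carrier, diagnoses) {
  diagnoses <- as.data.frame(diagnoses)
  res <- lapply(names(diagnoses), function(sym) {
    ca <- carrier_association(carrier, diagnoses[[sym]])
    data.frame(symptom = sym, odds_ratio = ca$odds_ratio,
               ci_lo = ca$ci95[1], ci_hi = ca$ci95[2], p = ca$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Carrier flags under non-exclusive definitions of "damaging"
#'
#' Builds per-participant carrier flags for each of five definitions of a
#' damaging variant: classical predicted loss of function (cLoF) only;
#' cLoF or map-damaging; cLoF or AlphaMissense-damaging; cLoF or
#' REVEL-damaging; and any of the above. Only rare variants (minor allele
#' frequency below \code{maf_max}) qualify under any definition.
#' Map-damaging defaults to pathogenic-direction evidence at supporting
#' strength or stronger; REVEL-damaging is score > 0.5 and
#' AlphaMissense-damaging a "pathogenic" annotation.
#'
#' @param variants Data.frame, one row per (participant, variant):
#'   \code{participant}, \code{maf}, logical \code{clof}, and per
#'   requested definition: \code{evidence} (map evidence label),
#'   \code{revel} (numeric), \code{alphamissense} (annotation string).
#' @param definitions Subset of \code{c("clof", "map", "alphamissense",
#'   "revel", "any")}.
#' @param maf_max Rarity bound (default 1e-4).
#' @param map_damaging_levels Map evidence labels counted as damaging.
#' @return Data.frame: \code{participant} plus one logical column per
#'   definition.
#' @export
damaging_carrier_sets <- function(variants,
                                  definitions = c("clof", "map",
                                                  "alphamissense", "revel",
                                                  "any"),
                                  maf_max = 1e-4,
                                  map_damaging_levels =
                                    c("pathogenic_supporting",
                                      "pathogenic_moderate",
                                      "pathogenic_strong")) {
  definitions <- match.arg(definitions, several.ok = TRUE)
  .require_columns(variants, c("participant", "maf", "clof"),
                   "variant table")
  need <- c(map = "evidence", alphamissense = "alphamissense",
            revel = "revel")
  for (def in intersect(names(need), c(definitions,
                                       if ("any" %in% definitions)
                                         names(need))))
    if (!need[[def]] %in% names(variants))
      stop("definition '", def, "' requires column '", need[[def]], "'",
           call. = FALSE)
  rare <- variants$maf < maf_max
  qual <- list(clof = variants$clof)
  if ("evidence" %in% names(variants))
    qual$map <- variants$clof |
      variants$evidence %in% map_damaging_levels
  if ("alphamissense" %in% names(variants))
    qual$alphamissense <- variants$clof |
      tolower(variants$alphamissense) == "pathogenic"
  if ("revel" %in% names(variants))
    qual$revel <- variants$clof |
      (!is.na(variants$revel) & variants$revel > 0.5)
  if ("any" %in% definitions)
    qual$any <- Reduce(`|`, qual)
  participants <- unique(variants$participant)
  out <- data.frame(participant = participants, stringsAsFactors = FALSE)
  for (def in definitions) {
    flag <- rare & qual[[def]]
    hit <- tapply(flag, variants$participant, any)
    out[[def]] <- as.logical(hit[match(participants, names(hit))])
  }
  out
}
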