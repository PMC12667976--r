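# Ground-truthed sort-seq simulator.
#
# Emulates one regional mutagenesis experiment: a clone library built with
# NNN degenerate oligos (Poisson(lambda) codon substitutions per clone), a
# FACS selection keeping the top fraction of reporter-expressing cells, and
# tile sequencing of select, non-select and unmutagenized wild-type control
# pools to a fixed read depth, with per-nucleotide base-call error. Every
# variant carries a known true activity, so downstream score estimates can
# be checked against truth.

#' Simulation configuration
#'
#' Defaults describe one desk-scale mutagenic region: 182 codons, a mean of
#' 0.6 amino-acid substitutions per clone, two biological replicates,
#' sequencing to 1e6 reads per tile and condition, a top-10% fluorescence
#' gate, and a per-nucleotide base-call error of 1e-4 measured on the
#' wild-type template.
#'
#' True activities live on the map scale: synonymous changes have activity
#' exactly 1, nonsense changes 0 (except an optional tolerant C-terminal
#' window), and missense activities are drawn from a two-component mixture
#' (a deleterious component near 0, a tolerant component near 1) with a
#' small gain-of-function tail above 1.
#'
#' @param seed Integer seed; all randomness in a simulation flows from it.
#' @param protein_length Codons in the mutagenic region.
#' @param lambda Mean codon substitutions per clone (Poisson).
#' @param depth Reads per tile per condition.
#' @param error_rate Per-nucleotide base-call error probability.
#' @param gate_fraction Fraction of top fluorescence cells sorted into the
#'   select pool.
#' @param n_replicates Biological replicates.
#' @param n_clones Clones in the library pool.
#' @param cell_noise_sd Standard deviation of per-cell log-fluorescence
#'   around the clone mean (activity units).
#' @param p_deleterious Mixture weight of the deleterious missense
#'   component.
#' @param deleterious_shape Beta shape parameters (length 2) of the
#'   deleterious activity component.
#' @param tolerant_sd SD of the tolerant (near-1) missense component.
#' @param p_gof Fraction of missense variants in the gain-of-function tail.
#' @param gof_range Activity range (length 2) of the gain-of-function tail.
#' @param tolerant_cterm Number of C-terminal residues where nonsense is
#'   tolerated (activity 1); 0 disables the window.
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 1L,
                       protein_length = 182L,
                       lambda = 0.6,
                       depth = 1e6,
                       error_rate = 1e-4,
                       gate_fraction = 0.10,
                       n_replicates = 2L,
                       n_clones = 200000L,
                       cell_noise_sd = 0.4,
                       p_deleterious = 0.4,
                       deleterious_shape = c(2, 8),
                       tolerant_sd = 0.07,
                       p_gof = 0.02,
                       gof_range = c(1.1, 1.5),
                       tolerant_cterm = 0L) {
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  if (gate_fraction <= 0 || gate_fraction >= 1)
    stop("gate_fraction must lie in (0, 1)", call. = FALSE)
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  if (error_rate < 0 || error_rate > 1)
    stop("error_rate must lie in [0, 1]", call. = FALSE)
  structure(list(seed = as.integer(seed),
                 protein_length = as.integer(protein_length),
                 lambda = lambda, depth = depth, error_rate = error_rate,
                 gate_fraction = gate_fraction,
                 n_replicates = as.integer(n_replicates),
                 n_clones = as.integer(n_clones),
                 cell_noise_sd = cell_noise_sd,
                 p_deleterious = p_deleterious,
                 deleterious_shape = deleterious_shape,
                 tolerant_sd = tolerant_sd,
                 p_gof = p_gof, gof_range = gof_range,
                 tolerant_cterm = as.integer(tolerant_cterm)),
            class = "sim_config")
}

# Random sense codon sequence for the wild-type region.
.sim_wt_codons <- function(L) {
  sense <- names(.GENETIC_CODE)[.GENETIC_CODE != "Ter"]
  sample(sense, L, replace = TRUE)
}

#' Simulate per-variant ground-truth activities
#'
#' Draws a wild-type codon sequence for the region and a true activity for
#' every possible codon-level substitution (63 NNN alternatives per codon),
#' where the activity attaches to the amino-acid outcome: all codon changes
#' yielding the same amino-acid substitution share one activity.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A list of class \code{"sim_truth"}: \code{wt_codons} (character
#'   vector), \code{wt_aa} (translations), and \code{activity}, a
#'   data.frame with one row per (position, alt_aa) pair: columns
#'   \code{position}, \code{ref_aa}, \code{alt_aa}, \code{vclass},
#'   \code{activity}.
#' @export
simulate_ground_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$protein_length
  wt_codons <- .sim_wt_codons(L)
  wt_aa <- unname(.GENETIC_CODE[wt_codons])
  aa_out <- .AA3  # 20 aa + Ter
  grid <- expand.grid(position = seq_len(L), alt_aa = aa_out,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$ref_aa <- wt_aa[grid$position]
  grid$vclass <- ifelse(grid$alt_aa == "Ter", "nonsense",
                        ifelse(grid$alt_aa == grid$ref_aa, "synonymous",
                               "missense"))
  a <- numeric(nrow(grid))
  a[grid$vclass == "synonymous"] <- 1
  non <- grid$vclass == "nonsense"
  a[non] <- ifelse(grid$position[non] > L - config$tolerant_cterm, 1, 0)
  mis <- which(grid$vclass == "missense")
  u <- stats::runif(length(mis))
  a_mis <- numeric(length(mis))
  del <- u < config$p_deleterious
  gof <- u >= 1 - config$p_gof
  tol <- !del & !gof
  a_mis[del] <- stats::rbeta(sum(del), config$deleterious_shape[1],
                             config$deleterious_shape[2])
  a_mis[tol] <- pmax(0, stats::rnorm(sum(tol), 1, config$tolerant_sd))
  a_mis[gof] <- stats::runif(sum(gof), config$gof_range[1],
                             config$gof_range[2])
  a[mis] <- a_mis
  grid$activity <- a
  grid <- grid[c("position", "ref_aa", "alt_aa", "vclass", "activity")]
  structure(list(wt_codons = wt_codons, wt_aa = wt_aa, activity = grid),
            class = "sim_truth")
}

# Activity lookup for codon-level events given the truth table.
.truth_activity <- function(truth, position, alt_aa) {
  key <- paste(truth$activity$position, truth$activity$alt_aa)
  idx <- match(paste(position, alt_aa), key)
  truth$activity$activity[idx]
}

#' Simulate a mutagenized clone library
#'
#' Each clone carries \code{Poisson(lambda)} codon substitutions at
#' uniformly chosen positions, each replaced by one of the 63 NNN
#' alternative codons uniformly at random. Reports the marginal frequency
#' of every codon substitution present and the fraction of the possible
#' substitution space represented above 10 counts per million
#' (clone-marginal), the standard library quality-control metric.
#'
#' @param config A \code{\link{sim_config}}.
#' @param truth A \code{"sim_truth"} from
#'   \code{\link{simulate_ground_truth}} (supplies the wild-type codons).
#' @return A list of class \code{"sim_pool"}: \code{events} (data.frame
#'   \code{clone}, \code{codon_index}, \code{ref_codon}, \code{alt_codon},
#'   \code{alt_aa}, \code{activity}), \code{n_clones},
#'   \code{clone_activity} (length \code{n_clones}; minimum activity over a
#'   clone's substitutions, 1 for wild-type clones), \code{coverage_10cpm},
#'   and \code{mean_subs_per_clone}.
#' @export
simulate_library <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  set.seed(config$seed + 1L)
  L <- config$protein_length
  n <- config$n_clones
  nsub <- stats::rpois(n, config$lambda)
  total <- sum(nsub)
  clone <- rep.int(seq_len(n), nsub)
  pos <- sample.int(L, total, replace = TRUE)
  ref_codon <- truth$wt_codons[pos]
  # uniform over the 63 alternatives: draw from 64 and redraw collisions
  all64 <- names(.GENETIC_CODE)
  alt_codon <- sample(all64, total, replace = TRUE)
  while (any(hit <- alt_codon == ref_codon))
    alt_codon[hit] <- sample(all64, sum(hit), replace = TRUE)
  alt_aa <- unname(.GENETIC_CODE[alt_codon])
  activity <- .truth_activity(truth, pos, alt_aa)
  events <- data.frame(clone = clone, codon_index = pos,
                       ref_codon = ref_codon, alt_codon = alt_codon,
                       alt_aa = alt_aa, activity = activity,
                       stringsAsFactors = FALSE)
  clone_activity <- rep.int(1, n)
  if (nrow(events)) {
    mins <- tapply(events$activity, events$clone, min)
    clone_activity[as.integer(names(mins))] <- as.numeric(mins)
  }
  # QC: marginal clone frequency of each codon substitution, in cpm
  if (nrow(events)) {
    sub_key <- paste(events$codon_index, events$alt_codon)
    sub_n <- table(sub_key)
    cpm <- as.numeric(sub_n) * 1e6 / n
    n_covered <- sum(cpm > 10)
  } else n_covered <- 0L
  coverage <- n_covered / (63 * L)
  structure(list(events = events, n_clones = n,
                 clone_activity = clone_activity,
                 coverage_10cpm = coverage,
                 mean_subs_per_clone = total / n),
            class = "sim_pool")
}

# Pool-level fluorescence gate: the (1 - gate_fraction) quantile of the
# mixture of per-cell Normal(clone activity, sd) fluorescence.
.solve_gate <- function(clone_activity, sd, gate_fraction) {
  mu <- clone_activity
  f <- function(g) mean(stats::pnorm(g, mean = mu, sd = sd,
                                     lower.tail = FALSE)) - gate_fraction
  lo <- min(mu) - 10 * sd
  hi <- max(mu) + 10 * sd
  stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
}

# Number of differing nucleotides between two codons.
.codon_nt_diffs <- function(a, b) {
  da <- matrix(unlist(strsplit(a, "")), ncol = 3, byrow = TRUE)
  db <- matrix(unlist(strsplit(b, "")), ncol = 3, byrow = TRUE)
  rowSums(da != db)
}

# Per-read probability of miscalling the WT codon as a specific alternative:
# (error_rate / 3) per specific nucleotide substitution, independent across
# the differing positions of the codon change.
.error_prob <- function(ref_codon, alt_codon, error_rate) {
  (error_rate / 3) ^ .codon_nt_diffs(ref_codon, alt_codon)
}

#' Simulate sequencing counts for select / non-select / WT-control pools
#'
#' Selection: per-cell log-fluorescence is Normal(clone activity,
#' \code{cell_noise_sd}); the gate is the pool-level
#' \code{1 - gate_fraction} quantile of that mixture; a clone's chance of
#' passing is its Normal upper-tail mass above the gate. Select reads are a
#' multinomial draw over clones with weights proportional to frequency
#' times pass probability; non-select reads are multinomial on raw clone
#' frequency. Base-call error adds Poisson counts (mean \code{depth} times
#' the per-read miscall probability of the codon change) to both variant
#' channels, and the \code{wt_select}/\code{wt_nonselect} control channels
#' contain such error counts only. Replicates are independent draws from
#' the same clone pool.
#'
#' @param pool A \code{"sim_pool"} from \code{\link{simulate_library}}.
#' @param truth The matching \code{"sim_truth"}.
#' @param config The \code{\link{sim_config}} used throughout.
#' @return A count table data.frame in the layout of
#'   \code{\link{read_count_table}} (region 1, tile 1), containing every
#'   codon change with a nonzero count in at least one channel.
#' @export
simulate_sort_counts <- function(pool, truth, config) {
  stopifnot(inherits(pool, "sim_pool"), inherits(truth, "sim_truth"),
            inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  depth <- config$depth
  events <- pool$events
  gate <- .solve_gate(pool$clone_activity, config$cell_noise_sd,
                      config$gate_fraction)
  p_pass <- stats::pnorm(gate, mean = pool$clone_activity,
                         sd = config$cell_noise_sd, lower.tail = FALSE)

  # universe of codon changes: library substitutions + single-nt
  # sequencing-error neighbours of the wild type
  lib_changes <- unique(events[c("codon_index", "ref_codon", "alt_codon")])
  err_changes <- do.call(rbind, lapply(seq_len(config$protein_length),
    function(i) {
      ref <- truth$wt_codons[i]
      nts <- strsplit(ref, "")[[1]]
      alts <- character(0)
      for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"), nts[p])) {
        alt <- nts; alt[p] <- b
        alts <- c(alts, paste(alt, collapse = ""))
      }
      data.frame(codon_index = i, ref_codon = ref, alt_codon = alts,
                 stringsAsFactors = FALSE)
    }))
  changes <- unique(rbind(lib_changes, err_changes))
  changes <- changes[order(changes$codon_index, changes$alt_codon), ]
  rownames(changes) <- NULL
  ckey <- paste(changes$codon_index, changes$alt_codon)
  p_err <- .error_prob(changes$ref_codon, changes$alt_codon,
                       config$error_rate)
  ekey <- paste(events$codon_index, events$alt_codon)
  eidx <- match(ekey, ckey)

  rows <- list()
  for (rep_id in seq_len(config$n_replicates)) {
    sel_reads <- as.integer(stats::rmultinom(1, depth,
                                             prob = pmax(p_pass, 0)))
    non_reads <- as.integer(stats::rmultinom(1, depth,
                                             prob = rep(1, pool$n_clones)))
    agg <- function(clone_reads) {
      per_event <- clone_reads[events$clone]
      counts <- numeric(nrow(changes))
      if (length(per_event)) {
        s <- rowsum(per_event, group = eidx)
        counts[as.integer(rownames(s))] <- s[, 1]
      }
      counts
    }
    err_counts <- function() stats::rpois(nrow(changes), depth * p_err)
    tab <- function(cond, counts)
      data.frame(region = 1L, replicate = rep_id, condition = cond,
                 tile = 1L, codon_index = changes$codon_index,
                 ref_codon = changes$ref_codon,
                 alt_codon = changes$alt_codon,
                 count = pmin(counts, depth), depth = depth,
                 stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- tab("select", agg(sel_reads) + err_counts())
    rows[[length(rows) + 1L]] <- tab("nonselect", agg(non_reads) + err_counts())
    rows[[length(rows) + 1L]] <- tab("wt_select", err_counts())
    rows[[length(rows) + 1L]] <- tab("wt_nonselect", err_counts())
  }
  out <- do.call(rbind, rows)
  out <- out[out$count > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run a full synthetic sort-seq experiment
#'
#' Convenience wrapper: ground truth, clone library, and counts for all
#' conditions and replicates, all driven by \code{config$seed}.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A list of class \code{"sim_experiment"} with \code{truth},
#'   \code{pool}, \code{counts} and the \code{config}.
#' @export
simulate_experiment <- function(config = sim_config()) {
  truth <- simulate_ground_truth(config)
  pool <- simulate_library(config, truth)
  counts <- simulate_sort_counts(pool, truth, config)
  structure(list(truth = truth, pool = pool, counts = counts,
                 config = config),
            class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat("Synthetic sort-seq experiment\n",
      "  region length: ", x$config$protein_length, " codons\n",
      "  clones: ", x$pool$n_clones,
      " (mean substitutions/clone ",
      round(x$pool$mean_subs_per_clone, 3), ")\n",
      "  coverage above 10 cpm: ",
      round(100 * x$pool$coverage_10cpm, 1), "%\n",
      "  count rows: ", nrow(x$counts), "\n", sep = "")
  invisible(x)
}

#' Simulate a clinical reference-variant set from ground truth
#'
#' Positives (P/LP analogues) are sampled from the low-activity missense
#' stratum, negatives (B/LB) from the near-wild-type stratum; labels are
#' flipped independently with probability \code{label_noise}. Default
#' sizes mirror a 30-positive / 16-negative clinical reference set.
#'
#' @param truth A \code{"sim_truth"}.
#' @param n_pos,n_neg Positive and negative set sizes.
#' @param label_noise Probability of flipping each label.
#' @param seed Integer seed.
#' @param pos_max Maximum true activity of the positive stratum.
#' @param neg_tol Half-width of the negative stratum around activity 1.
#' @return Data.frame with \code{hgvs_pro}, \code{label}, \code{stars},
#'   \code{positive}, \code{position}, \code{alt_aa}, \code{activity}.
#' @export
simulate_reference_set <- function(truth, n_pos = 30L, n_neg = 16L,
                                   label_noise = 0, seed = 1L,
                                   pos_max = 0.3, neg_tol = 0.1) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(seed)
  mis <- truth$activity[truth$activity$vclass == "missense", ]
  pos_pool <- which(mis$activity <= pos_max)
  neg_pool <- which(abs(mis$activity - 1) <= neg_tol)
  if (length(pos_pool) < n_pos || length(neg_pool) < n_neg)
    stop("not enough variants in the requested truth strata", call. = FALSE)
  pick <- rbind(
    cbind(mis[sample(pos_pool, n_pos), ], positive = TRUE),
    cbind(mis[sample(neg_pool, n_neg), ], positive = FALSE))
  flip <- stats::runif(nrow(pick)) < label_noise
  pick$positive <- xor(pick$positive, flip)
  pick$label <- ifelse(pick$positive, "P", "B")
  pick$stars <- 1L
  pick$hgvs_pro <- paste0("p.", pick$ref_aa, pick$position, pick$alt_aa)
  rownames(pick) <- NULL
  pick[c("hgvs_pro", "label", "stars", "positive", "position", "alt_aa",
         "activity")]
}

#' Simulate a diploid patient cohort with symptom counts
#'
#' Genotypes are drawn from three classes (homozygous missense, missense in
#' trans with a truncating allele, heterozygous missense with a wild-type
#' allele); the missense variants come from the deleterious-leaning part of
#' the truth table. Each patient's true combined-allele score is the sum
#' of the two allele activities (wild type = 1, truncating = 0). Symptom
#' counts are Poisson with log-mean \code{beta0 + beta1 * CAM}; each of the
#' three diagnostic-dyad symptoms (hypoparathyroidism, adrenal
#' insufficiency, candidiasis) is present independently with probability
#' \code{plogis(dyad_beta0 + dyad_beta1 * CAM)}, so both severity measures
#' decrease in CAM when the slopes are negative.
#'
#' @param truth A \code{"sim_truth"}.
#' @param n_patients Number of patients (>= 2).
#' @param beta0,beta1 Intercept and CAM slope of the log symptom-count
#'   model (\code{beta1 <= 0} gives the clinically expected direction).
#' @param dyad_beta0,dyad_beta1 Logistic coefficients for each diagnostic
#'   symptom's presence.
#' @param seed Integer seed.
#' @return Cohort data.frame with list-columns as in
#'   \code{\link{read_cohort_table}}, plus \code{cam_true} and
#'   \code{n_symptoms}.
#' @export
simulate_cohort <- function(truth, n_patients = 98L, beta0 = 1.6,
                            beta1 = -0.5, dyad_beta0 = 1.5,
                            dyad_beta1 = -1.5, seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  if (n_patients < 2) stop("n_patients must be >= 2", call. = FALSE)
  set.seed(seed)
  mis <- truth$activity[truth$activity$vclass == "missense", ]
  # clinical alleles skew damaging: sample missense weighted to low activity
  w <- 1 - 0.8 * pmin(mis$activity, 1)
  hgvs <- paste0("p.", mis$ref_aa, mis$position, mis$alt_aa)
  gclass <- sample(c("hom", "trans_truncating", "het_wt"), n_patients,
                   replace = TRUE, prob = c(0.21, 0.46, 0.33))
  idx1 <- sample(nrow(mis), n_patients, replace = TRUE, prob = w)
  a1 <- hgvs[idx1]; s1 <- mis$activity[idx1]
  a2 <- character(n_patients); s2 <- numeric(n_patients)
  a2[gclass == "hom"] <- a1[gclass == "hom"]
  s2[gclass == "hom"] <- s1[gclass == "hom"]
  a2[gclass == "trans_truncating"] <- "truncating"
  s2[gclass == "trans_truncating"] <- 0
  a2[gclass == "het_wt"] <- "WT"
  s2[gclass == "het_wt"] <- 1
  cam <- s1 + s2
  n_sym <- stats::rpois(n_patients, exp(beta0 + beta1 * cam))
  p_dyad_sym <- stats::plogis(dyad_beta0 + dyad_beta1 * cam)
  dyad_syms <- c("hypoparathyroidism", "adrenal_insufficiency",
                 "candidiasis")
  other_syms <- paste0("symptom_", sprintf("%02d", 1:40))
  symptoms <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    present <- dyad_syms[stats::runif(3) < p_dyad_sym[i]]
    n_other <- max(0L, n_sym[i] - length(present))
    symptoms[[i]] <- c(present,
                       sample(other_syms, min(n_other, length(other_syms))))
  }
  out <- data.frame(patient_id = sprintf("PT%03d", seq_len(n_patients)),
                    stringsAsFactors = FALSE)
  out$allele1 <- as.list(a1)
  out$allele2 <- as.list(a2)
  out$symptoms <- symptoms
  out$cam_true <- cam
  out$n_symptoms <- lengths(symptoms)
  out
}
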