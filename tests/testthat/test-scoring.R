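# Scoring pipeline: each stage against hand-computed values, then
# pipeline-level invariants.

# minimal one-replicate count table with chosen cpm values
counts_from_cpm <- function(cpm_by_cond, codon_index = 1,
                            ref_codon = "GCT", alt_codon = "GAT",
                            replicate = 1, depth = 1e6) {
  rows <- lapply(names(cpm_by_cond), function(cond) {
    v <- cpm_by_cond[[cond]]
    data.frame(region = 1L, replicate = replicate, condition = cond,
               tile = 1L, codon_index = codon_index,
               ref_codon = ref_codon, alt_codon = alt_codon,
               count = v * depth / 1e6, depth = depth,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

test_that("counts-per-million conversion is definitional", {
  expect_equal(cpm(10, 1e6), 10)
  expect_equal(cpm(0, 5e5), 0)
  expect_equal(cpm(37, 2.5e6), 14.8)
  expect_error(cpm(1, 0), "depth")
})

test_that("marginal frequencies sum tiles and fill absent conditions with 0", {
  df <- rbind(
    counts_from_cpm(list(select = 100, nonselect = 50)),
    within(counts_from_cpm(list(select = 20)), tile <- 2L))
  freqs <- marginal_frequencies(df)
  expect_equal(nrow(freqs), 1)
  # two tiles: (100 + 20 reads) / 2e6 reads
  expect_equal(freqs$cpm_select, 60)
  expect_equal(freqs$cpm_nonselect, 50)
  expect_equal(freqs$cpm_wt_select, 0)
  expect_equal(freqs$n_select, 120)
})

test_that("the non-select abundance filter is per replicate and inclusive", {
  df <- rbind(
    counts_from_cpm(list(nonselect = 9.99), replicate = 1),
    counts_from_cpm(list(nonselect = 10.0), replicate = 2))
  freqs <- marginal_frequencies(df)
  kept <- filter_by_nonselect(freqs, threshold = 10)
  expect_equal(kept$replicate, 2)
  # boundary inclusive; strictly-below excluded
  expect_equal(nrow(filter_by_nonselect(freqs, threshold = 9.99)), 2)
})

test_that("enrichment ratios subtract WT error and floor at delta", {
  f <- marginal_frequencies(counts_from_cpm(list(
    select = 100, wt_select = 20, nonselect = 50, wt_nonselect = 10)))
  enr <- enrichment_ratio(f)
  expect_equal(enr$phi, 2.0)  # 80 / 40
  expect_false(enr$floored)

  f2 <- marginal_frequencies(counts_from_cpm(list(
    select = 20, wt_select = 20, nonselect = 50, wt_nonselect = 10)))
  enr2 <- enrichment_ratio(f2, floor_cpm = 0.1)
  expect_equal(enr2$phi, 0.1 / 40)  # floored numerator
  expect_true(enr2$floored)

  f3 <- marginal_frequencies(counts_from_cpm(list(
    select = 100, nonselect = 50)))
  expect_equal(enrichment_ratio(f3)$phi, 2.0)  # no WT error: plain ratio

  expect_error(enrichment_ratio(f, floor_cpm = 0), "floor_cpm")
})

# one-replicate table with two nonsense, two synonymous and one missense
# codon change engineered to hit chosen logphi values
calib_table <- function(logphis = c(-2, -1, 0.5, 1.5, -0.25),
                        replicate = 1) {
  # nonselect 100 cpm throughout; select = 100 * exp(logphi)
  specs <- list(
    list(ref = "TGC", alt = "TGA", lp = logphis[1]),  # Cys -> Ter
    list(ref = "TAC", alt = "TAA", lp = logphis[2]),  # Tyr -> Ter
    list(ref = "GCT", alt = "GCC", lp = logphis[3]),  # Ala -> Ala
    list(ref = "CGT", alt = "CGC", lp = logphis[4]),  # Arg -> Arg
    list(ref = "GCT", alt = "GAT", lp = logphis[5]))  # Ala -> Asp
  do.call(rbind, lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    counts_from_cpm(list(select = 100 * exp(s$lp), nonselect = 100),
                    codon_index = i, ref_codon = s$ref,
                    alt_codon = s$alt, replicate = replicate)
  }))
}

test_that("rescaling anchors nonsense at 0 and synonymous at 1", {
  enr <- enrichment_ratio(filter_by_nonselect(
    marginal_frequencies(calib_table())))
  scr <- rescale_replicate(enr)
  # nonsense medians {-2,-1} -> -1.5; synonymous {0.5,1.5} -> 1.0
  anchors <- attr(scr, "anchors")
  expect_equal(unname(anchors["median_nonsense"]), -1.5)
  expect_equal(unname(anchors["median_synonymous"]), 1.0)
  # x = -0.25 -> (-0.25 + 1.5)/2.5 = 0.5
  expect_equal(scr$score[scr$vclass == "missense"], 0.5)
  expect_equal(median(scr$score[scr$vclass == "nonsense"]), 0)
  expect_equal(median(scr$score[scr$vclass == "synonymous"]), 1)
})

test_that("degenerate or missing calibration classes raise errors", {
  tab <- calib_table()
  no_syn <- tab[!(tab$alt_codon %in% c("GCC", "CGC")), ]
  enr <- enrichment_ratio(filter_by_nonselect(
    marginal_frequencies(no_syn)))
  expect_error(rescale_replicate(enr), "synonymous")
  no_non <- tab[!(tab$alt_codon %in% c("TGA", "TAA")), ]
  enr2 <- enrichment_ratio(filter_by_nonselect(
    marginal_frequencies(no_non)))
  expect_error(rescale_replicate(enr2), "nonsense")
  flat <- calib_table(logphis = c(1, 1, 1, 1, 0))
  enr3 <- enrichment_ratio(filter_by_nonselect(
    marginal_frequencies(flat)))
  expect_error(rescale_replicate(enr3), "degenerate")
})

test_that("codon-to-residue aggregation averages and propagates error", {
  # two Ala1 -> Asp codon changes with rescaled scores 0.4 and 0.6:
  # pick logphi = -1.5 + 2.5 * score
  tab <- rbind(calib_table(logphis = c(-2, -1, 0.5, 1.5, -0.5)),
               counts_from_cpm(list(select = 100 * exp(0), nonselect = 100),
                               codon_index = 5, ref_codon = "GCT",
                               alt_codon = "GAC"))
  scr <- rescale_replicate(enrichment_ratio(filter_by_nonselect(
    marginal_frequencies(tab))))
  aa <- aggregate_codon_to_aa(scr)
  asp <- aa[aa$alt_aa == "Asp", ]
  expect_equal(asp$score, 0.5)
  expect_equal(asp$n_codon_measurements, 2L)
  expect_equal(asp$se, sd(c(0.4, 0.6)) / sqrt(2))
  expect_equal(asp$hgvs_pro, "p.Ala5Asp")
  # GAT and GAC are both single-nucleotide neighbours of GCT
  expect_true(asp$snv_accessible)
  # synonymous changes aggregate like any other class
  expect_equal(sum(aa$vclass == "synonymous"), 2)
})

test_that("singleton substitutions get the Poisson delta-method error", {
  scr <- rescale_replicate(enrichment_ratio(filter_by_nonselect(
    marginal_frequencies(calib_table()))))
  # missense row: 400 select reads (100*exp(-0.25) cpm at 1e6 depth
  # rounds to 77880... use recorded counts), nonsense/synonymous too;
  # verify against the formula with the actual counts
  aa <- aggregate_codon_to_aa(scr)
  mis <- aa[aa$vclass == "missense", ]
  row <- scr[scr$vclass == "missense", ]
  expected <- sqrt(1 / row$n_select + 1 / row$n_nonselect) / 2.5
  expect_equal(mis$se, expected)
})

test_that("the hand-checked delta-method arithmetic holds", {
  # 400 select and 400 non-select reads, rescale denominator 2.5
  expect_equal(sqrt(1 / 400 + 1 / 400) / 2.5, 0.0283, tolerance = 1e-3)
})

test_that("error regularization shrinks toward the abundance trend", {
  set.seed(8)
  n <- 60
  aa <- data.frame(cpm_nonselect = exp(runif(n, 2, 6)))
  aa$se <- exp(-1 - 0.5 * log(aa$cpm_nonselect))  # exactly on a trend
  aa$n_codon_measurements <- sample(2:5, n, TRUE)
  out <- regularize_se(aa)
  expect_equal(out$se, out$se_raw, tolerance = 1e-8)  # fixed point

  aa2 <- aa
  aa2$n_codon_measurements <- 1L
  aa2$se[1] <- aa2$se[1] * 10  # off-trend singleton
  out2 <- regularize_se(aa2)
  fit <- lm(log(se) ~ log(cpm_nonselect), data = aa2)
  se_fit1 <- exp(predict(fit, newdata = aa2[1, ]))
  expect_equal(out2$se[1], unname(se_fit1))  # w = 1: full shrinkage

  expect_warning(regularize_se(aa[1:5, ]), "fewer than 10")
})

test_that("replicate combination averages scores and pools errors", {
  aa_reps <- data.frame(
    replicate = c(1, 2, 1),
    position = c(7, 7, 9), ref_aa = "Ala", alt_aa = c("Val", "Val", "Asp"),
    vclass = "missense",
    hgvs_pro = c("p.Ala7Val", "p.Ala7Val", "p.Ala9Asp"),
    score = c(0.4, 0.6, 0.8), se = c(0.1, 0.1, 0.2),
    n_codon_measurements = 1L, snv_accessible = TRUE,
    cpm_nonselect = 50, stringsAsFactors = FALSE)
  out <- combine_replicates(aa_reps, n_replicates = 2)
  both <- out[out$hgvs_pro == "p.Ala7Val", ]
  expect_equal(both$score, 0.5)
  expect_equal(both$se, sqrt(0.01 + 0.01) / 2)  # ~0.0707
  expect_true(both$in_both_replicates)
  single <- out[out$hgvs_pro == "p.Ala9Asp", ]
  expect_equal(single$score, 0.8)
  expect_equal(single$se, 0.2)
  expect_false(single$in_both_replicates)
  # identical replicates: combined SE = se / sqrt(2)
  sym <- combine_replicates(within(aa_reps[1:2, ], {score <- 0.5}),
                            n_replicates = 2)
  expect_equal(sym$se, 0.1 / sqrt(2))
  # permutation invariance in replicate order
  flip <- combine_replicates(aa_reps[c(2, 1, 3), ], n_replicates = 2)
  expect_equal(flip[order(flip$hgvs_pro), ],
               out[order(out$hgvs_pro), ], ignore_attr = TRUE)
})

test_that("final scores do not depend on the enrichment log base", {
  expt <- small_experiment()
  fit_ln <- score_variants(expt, log_base = exp(1))
  fit_10 <- score_variants(expt, log_base = 10)
  expect_equal(fit_10$scores$score, fit_ln$scores$score,
               tolerance = 1e-10)
  expect_equal(fit_10$scores$se, fit_ln$scores$se, tolerance = 1e-10)
})

test_that("per-replicate anchor medians are exact on simulated data", {
  fit <- score_variants(small_experiment())
  for (r in unique(fit$codon_scores$replicate)) {
    cs <- fit$codon_scores[fit$codon_scores$replicate == r, ]
    expect_equal(median(cs$score[cs$vclass == "nonsense"]), 0)
    expect_equal(median(cs$score[cs$vclass == "synonymous"]), 1)
  }
})

test_that("no substitution failing the filter in every replicate is scored", {
  expt <- small_experiment()
  fit <- score_variants(expt, filter_cpm = 10)
  freqs <- marginal_frequencies(expt$counts)
  passed <- filter_by_nonselect(freqs, 10)
  passed$alt_aa <- vapply(passed$alt_codon, translate_codon, character(1))
  ok <- unique(paste(passed$codon_index, passed$alt_aa))
  expect_true(all(paste(fit$scores$position, fit$scores$alt_aa) %in% ok))
})
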