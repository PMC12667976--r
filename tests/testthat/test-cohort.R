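# Combined-allele map scores and genotype-phenotype statistics.

score_tab <- data.frame(
  hgvs_pro = c("p.Trp78Arg", "p.Arg92Trp", "p.Ala301Val"),
  score = c(0.22, 0.3, 0.9), stringsAsFactors = FALSE)

test_that("allele scores follow the WT/truncating/missense conventions", {
  expect_equal(allele_score("WT", score_tab), 1.0)
  expect_equal(allele_score("truncating", score_tab), 0.0)
  expect_equal(allele_score("p.Trp78Arg", score_tab), 0.22)
  # multi-variant allele: most damaging variant dominates
  expect_equal(allele_score(c("p.Trp78Arg", "p.Ala301Val"), score_tab),
               0.22)
  expect_error(allele_score("p.Gly999Asp", score_tab), "p.Gly999Asp")
})

test_that("CAM scores add the two allele scores and are order-symmetric", {
  expect_equal(cam_score("WT", "WT", score_tab)$cam, 2.0)
  expect_equal(cam_score("p.Trp78Arg", "truncating", score_tab)$cam, 0.22)
  expect_equal(cam_score("p.Arg92Trp", "p.Arg92Trp", score_tab)$cam, 0.6)
  expect_equal(cam_score("p.Trp78Arg", "WT", score_tab)$cam,
               cam_score("WT", "p.Trp78Arg", score_tab)$cam)
})

test_that("CAM lies in [0, 2] whenever map scores lie in [0, 1]", {
  set.seed(31)
  tab <- data.frame(hgvs_pro = paste0("p.Ala", 1:50, "Val"),
                    score = runif(50), stringsAsFactors = FALSE)
  alleles <- c("WT", "truncating", tab$hgvs_pro)
  for (i in 1:100) {
    a1 <- sample(alleles, 1); a2 <- sample(alleles, 1)
    cam <- cam_score(a1, a2, tab)$cam
    expect_gte(cam, 0); expect_lte(cam, 2)
  }
})

test_that("cohort CAM and position-based exclusion work end to end", {
  cohort <- data.frame(patient_id = c("A", "B", "C"),
                       stringsAsFactors = FALSE)
  cohort$allele1 <- list("p.Trp78Arg", "p.Ala301Val", "p.Arg92Trp")
  cohort$allele2 <- list("truncating", "WT", "p.Arg92Trp")
  cohort$symptoms <- list(character(0), character(0), character(0))
  cc <- cohort_cam(cohort, score_tab)
  expect_equal(cc$cam, c(0.22, 1.9, 0.6))
  # drop the patient with a variant inside the masked domain (301)
  kept <- exclude_positions(cc, phd1_positions())
  expect_equal(kept$patient_id, c("A", "C"))
})

test_that("symptom correlation recovers the programmed negative slope", {
  truth <- simulate_ground_truth(small_config(seed = 9))
  cohort <- simulate_cohort(truth, n_patients = 500, beta1 = -0.5,
                            seed = 11)
  res <- symptom_correlation(cohort$cam_true, cohort$n_symptoms)
  expect_lt(res$r, 0)
  expect_lt(res$p, 0.01)
  expect_equal(res$n, 500)
  expect_error(symptom_correlation(c(1, 2, 3), c(2, 2, 2)), "variance")
})

test_that("permuted symptom counts behave like the null", {
  truth <- simulate_ground_truth(small_config(seed = 9))
  cohort <- simulate_cohort(truth, n_patients = 120, beta1 = -0.5,
                            seed = 12)
  set.seed(13)
  rejections <- 0
  n_perm <- 200
  for (i in seq_len(n_perm)) {
    p <- symptom_correlation(cohort$cam_true,
                             sample(cohort$n_symptoms))$p
    rejections <- rejections + (p < 0.05)
  }
  rate <- rejections / n_perm
  mc_se <- sqrt(0.05 * 0.95 / n_perm)
  expect_lt(abs(rate - 0.05), 3 * mc_se + 1e-9)
})

test_that("dyad status requires two of the three diagnostic symptoms", {
  expect_true(dyad_status(c("hypoparathyroidism", "candidiasis")))
  expect_false(dyad_status("candidiasis"))
  expect_true(dyad_status(c("adrenal_insufficiency", "hypoparathyroidism",
                            "vitiligo")))
  expect_false(dyad_status(character(0)))
  expect_equal(dyad_status(list(c("hypoparathyroidism", "candidiasis"),
                                "vitiligo")),
               c(TRUE, FALSE))
})

test_that("dyad patients have lower CAM scores in the synthetic cohort", {
  truth <- simulate_ground_truth(small_config(seed = 9))
  cohort <- simulate_cohort(truth, n_patients = 200, seed = 14)
  dyad <- dyad_status(cohort$symptoms)
  res <- dyad_comparison(cohort$cam_true, dyad)
  expect_lt(res$median_dyad, res$median_nondyad)
  expect_lt(res$p, 0.05)
  expect_error(dyad_comparison(1:5, rep(TRUE, 5)), "non-empty")
})

test_that("carrier odds ratios match hand arithmetic with CI and correction", {
  carrier <- rep(c(TRUE, FALSE), c(10, 1000))
  diagnosis <- c(rep(c(TRUE, FALSE), c(2, 8)),
                 rep(c(TRUE, FALSE), c(20, 980)))
  res <- carrier_association(carrier, diagnosis)
  expect_equal(res$odds_ratio, (2 / 8) / (20 / 980))  # 12.25
  expect_false(res$corrected)
  expect_true(res$ci95[1] < res$odds_ratio &
                res$odds_ratio < res$ci95[2])
  # zero cell: Haldane-Anscombe correction keeps the OR finite
  diagnosis0 <- c(rep(FALSE, 10), rep(c(TRUE, FALSE), c(20, 980)))
  res0 <- carrier_association(carrier, diagnosis0)
  expect_true(res0$corrected)
  expect_true(is.finite(res0$odds_ratio))
  expect_error(carrier_association(rep(TRUE, 4), rep(c(TRUE, FALSE), 2)),
               "margin")
})

test_that("symptom families get Benjamini-Hochberg adjustment", {
  set.seed(32)
  n <- 2000
  carrier <- runif(n) < 0.05
  diagnoses <- data.frame(
    linked = runif(n) < ifelse(carrier, 0.4, 0.05),
    unlinked1 = runif(n) < 0.1, unlinked2 = runif(n) < 0.1)
  tab <- carrier_association_table(carrier, diagnoses)
  expect_equal(tab$symptom, c("linked", "unlinked1", "unlinked2"))
  expect_equal(tab$p_adj, p.adjust(tab$p, "BH"))
  expect_lt(tab$p_adj[1], 0.05)
})

test_that("damaging-variant definitions apply rarity and source logic", {
  variants <- data.frame(
    participant = c("u1", "u2", "u3", "u4", "u5"),
    maf = c(1e-5, 1e-2, 1e-5, 1e-5, 1e-6),
    clof = c(FALSE, TRUE, FALSE, TRUE, FALSE),
    evidence = c("indeterminate", "indeterminate", "pathogenic_supporting",
                 "indeterminate", "indeterminate"),
    revel = c(0.51, 0.9, 0.1, 0.2, 0.4),
    alphamissense = c("benign", "benign", "benign", "benign",
                      "pathogenic"),
    stringsAsFactors = FALSE)
  flags <- damaging_carrier_sets(variants)
  # u1: REVEL 0.51 and rare -> revel & any only
  expect_false(flags$clof[flags$participant == "u1"])
  expect_true(flags$revel[flags$participant == "u1"])
  expect_true(flags$any[flags$participant == "u1"])
  # u2: cLoF but common (MAF 0.01) -> excluded everywhere
  expect_false(any(unlist(flags[flags$participant == "u2", -1])))
  # u3: map evidence only -> map & any, not clof/revel/alphamissense
  u3 <- flags[flags$participant == "u3", ]
  expect_equal(unlist(u3[-1], use.names = FALSE),
               c(FALSE, TRUE, FALSE, FALSE, TRUE))
  # u4: rare cLoF -> every definition includes cLoF
  expect_true(all(unlist(flags[flags$participant == "u4", -1])))
  expect_error(damaging_carrier_sets(variants[c("participant", "maf",
                                                "clof")],
                                     definitions = "revel"),
               "revel")
})
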