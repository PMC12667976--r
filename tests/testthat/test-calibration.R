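# Kernel density LLR calibration and evidence assignment.

test_that("the Epanechnikov kernel evaluates to hand-computed values", {
  expect_equal(epanechnikov_density(0, 1, at = 0), 0.75)
  expect_equal(epanechnikov_density(0, 1, at = 1.5), 0)
  expect_equal(epanechnikov_density(c(0, 1), 1, at = 0.5), 0.5625)
  expect_error(epanechnikov_density(0, 0, at = 0), "bandwidth")
  expect_error(epanechnikov_density(numeric(0), 1, at = 0), "point")
})

test_that("each fitted density integrates to one", {
  set.seed(12)
  for (pts in list(rnorm(30, 0.1, 0.15), rnorm(16, 1.0, 0.15),
                   runif(50))) {
    h <- scott_bandwidth(pts)
    grid <- seq(min(pts) - h, max(pts) + h, length.out = 4000)
    f <- epanechnikov_density(pts, h, grid)
    integral <- sum((f[-1] + f[-length(f)]) / 2 * diff(grid))
    expect_equal(integral, 1, tolerance = 1e-3)
  }
})

test_that("kernel estimate cross-checks against stats::density", {
  set.seed(13)
  pts <- rnorm(40)
  h <- 0.5
  # stats::density parameterizes the Epanechnikov kernel by its SD:
  # bw * sqrt(5) equals our half-width h
  d <- density(pts, bw = h / sqrt(5), kernel = "epanechnikov", n = 512)
  ours <- epanechnikov_density(pts, h, d$x)
  # stats::density bins onto a grid before smoothing, so agreement is
  # approximate
  expect_equal(ours, d$y, tolerance = 0.02)
})

test_that("Scott bandwidths use the robust spread and N^(-1/5) scaling", {
  set.seed(14)
  pts <- rnorm(30, 0, 0.3)
  sigma <- min(sd(pts), IQR(pts) / 1.349)
  expect_equal(scott_bandwidth(pts), 2.34 * sigma * 30^(-0.2))
  # doubling N at fixed spread multiplies h by 2^(-1/5)
  pts2 <- rep(pts, 2)
  sigma2 <- min(sd(pts2), IQR(pts2) / 1.349)
  expect_equal(scott_bandwidth(pts2) / (2.34 * sigma2 * 60^(-0.2)), 1)
  expect_equal(scott_bandwidth(pts2) * 30^(-0.2) * sigma,
               scott_bandwidth(pts) * 60^(-0.2) * sigma2,
               tolerance = 1e-12)
  expect_error(scott_bandwidth(rep(1, 10)), "spread")
  expect_error(scott_bandwidth(1), "two points")
})

ref_model <- function(seed = 1) {
  set.seed(seed)
  pos <- rnorm(30, 0.1, 0.15)
  neg <- rnorm(16, 1.0, 0.15)
  llr_calibrate(c(pos, neg), positive = rep(c(TRUE, FALSE), c(30, 16)))
}

test_that("LLRp is positive near pathogenic mass, negative near benign", {
  m <- ref_model()
  expect_gt(llrp(m, 0.1), 0)
  expect_lt(llrp(m, 1.0), 0)
  expect_equal(m$valid_range,
               range(c(m$positive_scores, m$negative_scores)))
})

test_that("scores outside the reference range are undetermined", {
  m <- ref_model()
  lo <- m$valid_range[1] - 0.01
  hi <- m$valid_range[2] + 0.01
  expect_true(is.na(llrp(m, lo)))
  expect_true(is.na(llrp(m, hi)))
  expect_equal(evidence_strength(llrp(m, c(lo, hi))),
               c("undetermined", "undetermined"))
  # boundary scores are determined
  expect_false(anyNA(llrp(m, m$valid_range)))
})

test_that("swapping reference classes negates LLRp everywhere in range", {
  m <- ref_model()
  swapped <- llr_calibrate(c(m$positive_scores, m$negative_scores),
                           positive = rep(c(FALSE, TRUE),
                                          c(length(m$positive_scores),
                                            length(m$negative_scores))))
  s <- seq(m$valid_range[1], m$valid_range[2], length.out = 101)
  expect_equal(llrp(swapped, s), -llrp(m, s))
})

test_that("evidence strengths follow the threshold ladder with a strong cap", {
  l <- c(0.1, 0.318, 0.5, 0.636, 1.0, 1.272, 1.30, 3.0,
         -0.318, -0.7, -1.3, -5, NA)
  expect_equal(
    evidence_strength(l),
    c("indeterminate", "pathogenic_supporting", "pathogenic_supporting",
      "pathogenic_moderate", "pathogenic_moderate", "pathogenic_strong",
      "pathogenic_strong", "pathogenic_strong",
      "benign_supporting", "benign_moderate", "benign_strong",
      "benign_strong", "undetermined"))
})

test_that("evidence is monotone in LLRp for in-range scores", {
  l <- seq(-3, 3, by = 0.01)
  lev <- c(benign_strong = -3, benign_moderate = -2,
           benign_supporting = -1, indeterminate = 0,
           pathogenic_supporting = 1, pathogenic_moderate = 2,
           pathogenic_strong = 3)
  ranks <- lev[evidence_strength(l)]
  expect_true(all(diff(ranks) >= 0))
})

test_that("the benign mask withholds benign evidence inside the masked domain", {
  l <- c(-2.0, -0.5, 2.0, -2.0)
  pos <- c(300, 320, 310, 50)
  got <- evidence_strength(l, position = pos,
                           benign_mask = phd1_positions())
  expect_equal(got, c("indeterminate", "indeterminate",
                      "pathogenic_strong", "benign_strong"))
  expect_error(evidence_strength(-1, benign_mask = 296:343), "position")
})

test_that("caution flags mark confidence intervals straddling 0.5", {
  expect_true(caution_flag(0.45, 0.10))   # CI [0.254, 0.646]
  expect_false(caution_flag(0.90, 0.05))  # CI [0.802, 0.998]
  expect_true(caution_flag(0.5, 0))       # closed interval boundary
  expect_error(caution_flag(0.5, -1), "se")
})

test_that("predict() assembles llrp, evidence and caution from a score table", {
  m <- ref_model()
  newdata <- data.frame(score = c(0.1, 1.0, 5), se = c(0.05, 0.3, 0.01),
                        position = c(10, 20, 30))
  out <- predict(m, newdata)
  expect_equal(names(out), c("score", "llrp", "evidence", "caution"))
  expect_gt(out$llrp[1], 0)
  expect_equal(out$evidence[3], "undetermined")
  expect_true(out$caution[2])   # 1.0 +/- 1.96*0.3 straddles 0.5
  expect_false(out$caution[1])
})

test_that("calibrating from a fitted map keeps both-replicate variants only", {
  fit <- score_variants(small_experiment())
  tab <- fit$scores
  pos_v <- head(tab$hgvs_pro[tab$vclass == "missense" & tab$score < 0.3 &
                               tab$in_both_replicates], 10)
  neg_v <- head(tab$hgvs_pro[tab$vclass == "missense" &
                               abs(tab$score - 1) < 0.1 &
                               tab$in_both_replicates], 10)
  ref <- data.frame(hgvs_pro = c(pos_v, neg_v, "p.Ala9999Val"),
                    positive = rep(c(TRUE, FALSE, TRUE), c(10, 10, 1)),
                    stringsAsFactors = FALSE)
  expect_message(m <- llr_calibrate(fit, reference = ref), "dropped")
  expect_length(m$positive_scores, 10)
  expect_gt(llrp(m, 0.1), 0)
})
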