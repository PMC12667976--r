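# Shared fixtures, memoized so the default-scale simulation and fit are
# computed once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# Default study-condition experiment: 182-codon region, lambda 0.6,
# depth 1e6, two replicates, seed 1.
default_experiment <- function() {
  if (is.null(.fixture_cache$expt))
    .fixture_cache$expt <- simulate_experiment(sim_config(seed = 1))
  .fixture_cache$expt
}

default_fit <- function() {
  if (is.null(.fixture_cache$fit))
    .fixture_cache$fit <- score_variants(default_experiment())
  .fixture_cache$fit
}

# Small fast experiment for tests that rerun the pipeline repeatedly.
small_config <- function(seed = 7, depth = 2e5, ...) {
  sim_config(seed = seed, protein_length = 60L, n_clones = 50000L,
             depth = depth, ...)
}

small_experiment <- function() {
  if (is.null(.fixture_cache$small))
    .fixture_cache$small <- simulate_experiment(small_config())
  .fixture_cache$small
}

# Random sense-codon CDS for SNV enumeration tests.
random_cds <- function(n_codons, seed) {
  set.seed(seed)
  sense <- setdiff(names(mavemap:::.GENETIC_CODE),
                   c("TAA", "TAG", "TGA"))
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# Brute-force SNV enumeration oracle: mutate every nucleotide of the CDS
# to each of the 3 alternatives, translate, and collect non-synonymous
# outcomes.
snv_oracle <- function(cds) {
  nts <- strsplit(cds, "")[[1]]
  out <- character(0)
  for (i in seq_along(nts)) {
    for (b in setdiff(c("A", "C", "G", "T"), nts[i])) {
      mut <- nts
      mut[i] <- b
      codon_i <- (i - 1) %/% 3 + 1
      ref_codon <- paste(nts[(3 * codon_i - 2):(3 * codon_i)],
                         collapse = "")
      alt_codon <- paste(mut[(3 * codon_i - 2):(3 * codon_i)],
                         collapse = "")
      ref_aa <- translate_codon(ref_codon)
      alt_aa <- translate_codon(alt_codon)
      if (alt_aa != ref_aa)
        out <- c(out, paste(codon_i, alt_aa))
    }
  }
  sort(unique(out))
}

# Directly-constructed count table for validating standard errors against
# a count-resampling bootstrap. Counts are Poisson around per-variant
# means, so resampling counts reproduces exactly the noise the pipeline's
# SEs describe (a full sort-seq simulation adds clone-composition noise
# that count resampling cannot see). Activities are bimodal (floored
# deleterious vs near-wild-type), codons of one variant share an
# abundance up to mild jitter as under NNN mutagenesis, and anchor
# classes are included for rescaling.
make_se_fixture <- function(seed, n_var = 500, depth = 1e6) {
  set.seed(seed)
  leu_codons <- c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG")
  rows <- list()
  add <- function(pos, ref, alt, mu_non, r) {
    for (rep_id in 1:2) {
      n_non <- rpois(1, mu_non)
      n_sel <- rpois(1, mu_non * r)
      rows[[length(rows) + 1L]] <<- data.frame(
        region = 1L, replicate = rep_id,
        condition = c("select", "nonselect"), tile = 1L,
        codon_index = pos, ref_codon = ref, alt_codon = alt,
        count = c(n_sel, n_non), depth = depth,
        stringsAsFactors = FALSE)
    }
  }
  for (i in 1:40)
    add(1000 + i, "GCT", "GCC", depth * runif(1, 5e-5, 2e-4), 1.2)
  for (i in 1:40)
    add(2000 + i, "GCT", "TAA", depth * runif(1, 5e-5, 2e-4), 1e-5)
  for (i in seq_len(n_var)) {
    k <- sample(2:4, 1)
    mu <- depth * exp(runif(1, log(3e-5), log(3e-4))) *
      exp(rnorm(k, 0, 0.1))
    r <- if (runif(1) < 0.4) 1e-5 else exp(rnorm(1, log(1.2), 0.1))
    for (j in seq_len(k)) add(i, "GCT", leu_codons[j], mu[j], r)
  }
  counts <- do.call(rbind, rows)
  counts[counts$count > 0, ]
}
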