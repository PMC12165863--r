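# Off-target editing probability, mismatch taxonomy, codon consequences.

make_pileup <- function(pos, ref, ref_n, alt, alt_n) {
  df <- data.frame(pos = pos, A = 0L, C = 0L, G = 0L, T = 0L,
                   depth = ref_n + alt_n)
  for (i in seq_along(pos)) {
    df[i, ref[i]] <- ref_n[i]
    df[i, alt[i]] <- df[i, alt[i]] + alt_n[i]
  }
  df
}

test_that("locus probability matches exhaustive Bernoulli enumeration", {
  expect_equal(locus_probability(numeric()), 0)
  expect_equal(locus_probability(c(0, 0, 0)), 0)
  expect_equal(locus_probability(0.3), 0.3)
  expect_equal(locus_probability(c(0.1, 0.2)), 0.28)
  set.seed(42)
  for (k in c(1, 3, 7, 10)) {
    p <- runif(k, 0, 0.5)
    expect_equal(locus_probability(p), enumerate_at_least_one(p),
                 tolerance = 1e-12)
  }
})

test_that("adding an edited position never decreases the locus probability", {
  set.seed(7)
  p <- runif(6, 0, 0.3)
  base <- locus_probability(p)
  expect_gte(locus_probability(c(p, 0.01)), base)
  expect_equal(locus_probability(c(p, 0)), base)
})

test_that("coverage filter removes loci at 30 or fewer reads", {
  treated <- make_pileup(1:3, rep("C", 3), rep(25L, 3), rep("T", 3),
                         rep(5L, 3))       # depth 30 everywhere
  untreated <- make_pileup(1:3, rep("C", 3), rep(30L, 3), rep("T", 3),
                           rep(0L, 3))
  pf <- position_frequencies(treated, untreated)
  expect_equal(pf$status, "filtered-low-coverage")

  treated31 <- make_pileup(1:3, rep("C", 3), rep(26L, 3), rep("T", 3),
                           rep(5L, 3))     # depth 31: retained
  untreated31 <- make_pileup(1:3, rep("C", 3), rep(31L, 3), rep("T", 3),
                             rep(0L, 3))
  expect_equal(position_frequencies(treated31, untreated31)$status, "ok")
})

test_that("background positions above 2.5% in the untreated sample are excluded", {
  treated <- make_pileup(1:2, c("C", "C"), c(95L, 95L), c("T", "T"),
                         c(5L, 5L))
  untreated <- make_pileup(1:2, c("C", "C"), c(97L, 100L), c("T", "T"),
                           c(3L, 0L))     # pos 1: 3% background
  pf <- position_frequencies(treated, untreated)
  expect_equal(pf$evaluable_positions, 1L)
  expect_equal(unname(pf$frequencies), 0.05)
  expect_named(pf$frequencies, "2")

  all_bg <- make_pileup(1:2, c("C", "C"), c(90L, 90L), c("T", "T"),
                        c(10L, 10L))     # 10% in untreated everywhere
  expect_equal(position_frequencies(treated, all_bg)$status,
               "background-excluded-all")
})

test_that("minus-strand loci complement the conversion", {
  # C->T edit on the minus strand appears as G->A on the reference strand
  treated <- make_pileup(1, "G", 90L, "A", 10L)
  untreated <- make_pileup(1, "G", 100L, "A", 0L)
  pf <- position_frequencies(treated, untreated, ref_base = "C",
                             alt_base = "T", strand = "-")
  expect_equal(unname(pf$frequencies), 0.1)
  expect_equal(position_frequencies(treated, untreated, ref_base = "C",
                                    alt_base = "T", strand = "+")$status,
               "background-excluded-all")
})

test_that("mismatched position sets are rejected", {
  a <- make_pileup(1:2, c("C", "C"), c(50L, 50L), c("T", "T"), c(0L, 0L))
  b <- make_pileup(2:3, c("C", "C"), c(50L, 50L), c("T", "T"), c(0L, 0L))
  expect_error(position_frequencies(a, b), "different positions")
})

test_that("locus classification applies detection and substantial thresholds", {
  expect_equal(classify_locus(0.006, 0), "detected")
  expect_equal(classify_locus(0.05, 0), "substantial")
  expect_equal(classify_locus(0.004, 0), "below-detection")
  expect_equal(classify_locus(0.05, 0.048), "below-detection")  # over background
})

test_that("locus probability is recovered from high-coverage pileups", {
  truth <- data.frame(locus = "L", pos = 1:2, ref = "C", alt = "T",
                      freq = c(0.1, 0.2), background = FALSE)
  piles <- simulate_pileups(truth, coverage = 10000L, seed = 13)
  le <- locus_editing(piles$treated$L, piles$untreated$L, locus = "L")
  # truth: 1 - 0.9 * 0.8 = 0.28; binomial SE at n = 10000
  se <- sqrt(0.28 * 0.72 / 10000) * 2   # rough combined-position scale
  expect_equal(le$probability, 0.28, tolerance = 3 * max(se, 0.005))
  expect_equal(le$status, "substantial")

  null_truth <- data.frame(locus = "L", pos = 1:3, ref = "C", alt = "T",
                           freq = 0, background = FALSE)
  null_piles <- simulate_pileups(null_truth, coverage = 10000L, seed = 14)
  le0 <- locus_editing(null_piles$treated$L, null_piles$untreated$L,
                       locus = "L")
  expect_equal(le0$probability, 0, tolerance = 0.005)
  expect_equal(le0$status, "below-detection")
})

test_that("flagged background polymorphisms are excluded by the filter chain", {
  truth <- data.frame(locus = "L", pos = 1:3, ref = "C", alt = "T",
                      freq = c(0.1, 0, 0), background = c(FALSE, TRUE, FALSE))
  piles <- simulate_pileups(truth, coverage = 5000L, background_freq = 0.05,
                            seed = 15)
  le <- locus_editing(piles$treated$L, piles$untreated$L, locus = "L")
  expect_equal(le$evaluable_positions, 2L)   # the 5% SNP position is out
  expect_false("2" %in% names(le$frequencies))
})

test_that("mismatch taxonomy matches brute force on random 20-mer pairs", {
  expect_equal(classify_mismatches(strrep("A", 20), strrep("A", 20))$total, 0)
  one <- classify_mismatches(paste0("AA", "G", strrep("A", 17)),
                             strrep("A", 20))
  expect_equal(one$A, 1); expect_equal(one$total, 1)
  two <- classify_mismatches(strrep("A", 20),
                             paste0(strrep("A", 6), "C", strrep("A", 7), "C",
                                    strrep("A", 5)))
  expect_equal(two$B, 1); expect_equal(two$C, 1); expect_equal(two$total, 2)

  set.seed(99)
  bases <- c("A", "C", "G", "T")
  for (i in 1:1000) {
    s <- sample(bases, 20, replace = TRUE)
    t <- sample(bases, 20, replace = TRUE)
    got <- classify_mismatches(paste0(s, collapse = ""),
                               paste0(t, collapse = ""))
    # brute-force per-position comparison
    a <- 0L; b <- 0L; c_ <- 0L
    for (pos in 1:20) {
      if (s[pos] != t[pos]) {
        if (pos <= 5) a <- a + 1L
        else if (pos <= 10) b <- b + 1L
        else c_ <- c_ + 1L
      }
    }
    stopifnot(got$A == a, got$B == b, got$C == c_,
              got$total == a + b + c_)
  }
  succeed()
})

test_that("mismatch classifier rejects non-20-mers", {
  expect_error(classify_mismatches("ACGT", strrep("A", 20)), "20 nt")
})

test_that("codon consequences match the genetic code exhaustively", {
  expect_equal(coding_effect("CAG", "CAA"), "synonymous")  # Gln
  expect_equal(coding_effect("CTG", "TTG"), "synonymous")  # Leu
  expect_equal(coding_effect("CAG", "TAG"), "nonsense")
  expect_equal(coding_effect("CAG", "TAA"), "nonsense")
  expect_equal(coding_effect("GAA", "GGA"), "missense")    # Glu -> Gly
  expect_equal(coding_effect("AAA", "AAA"), "none")
  expect_error(coding_effect("AXA", "AAA"), "ACGT")

  for (ref in all_codons) {
    for (alt in all_codons) {
      stopifnot(coding_effect(ref, alt) == oracle_coding_effect(ref, alt))
    }
  }
  succeed()
})
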