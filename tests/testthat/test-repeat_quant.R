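# Repeat-tract quantification: anchoring, triplet classification, per-read
# calls and sample summaries.

spec_cag <- cag_cbe_spec()
spec_gaa <- gaa_abe_spec()

test_that("triplet classification covers the documented cases", {
  expect_equal(classify_triplet("CAA", spec_cag), "intended")
  expect_equal(classify_triplet("CAG", spec_cag), "pure")
  expect_equal(classify_triplet("TAG", spec_cag), "byproduct")
  expect_equal(classify_triplet("TAA", spec_cag), "byproduct")
  expect_equal(classify_triplet("GGA", spec_gaa), "intended")
  expect_equal(classify_triplet("GAG", spec_gaa), "intended")
  expect_equal(classify_triplet("NAA", spec_cag), "other")
  expect_error(classify_triplet("CA", spec_cag), "length 3")
})

test_that("every 3-mer classification is consistent with the IUPAC pattern", {
  bases <- c("A", "C", "G", "T")
  trips <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  for (spec in list(spec_cag, spec_gaa)) {
    pat <- strsplit(spec$edited_pattern, "")[[1]]
    iupac <- list(Y = c("C", "T"), R = c("A", "G"), A = "A", C = "C",
                  G = "G", T = "T")
    in_pattern <- vapply(trips, function(t) {
      b <- strsplit(t, "")[[1]]
      all(vapply(1:3, function(i) b[i] %in% iupac[[pat[i]]], logical(1)))
    }, logical(1))
    cls <- classify_triplet(trips, spec)
    # intended and pure triplets all match the pattern
    expect_true(all(in_pattern[cls %in% c("intended", "pure")]))
    # everything matching the pattern is pure, intended or a listed byproduct
    expect_true(all(cls[in_pattern] %in% c("pure", "intended", "byproduct")))
    expect_true(all(cls[!in_pattern] == "other"))
  }
})

test_that("tract anchoring distinguishes both/left/right/unanchored", {
  lf <- "AAGCTTAAGCTT"; rf <- "GGATCCGGATCC"
  sp <- repeat_spec("CAG", "YAR", c("TAG", "TAA"),
                    left_flank = lf, right_flank = rf, anchor_length = 6L)
  both <- locate_tract(paste0("AAGCTT", "CAGCAGCAA", "GGATCC"), sp)
  expect_equal(both$status, "both")
  expect_equal(both$tract, "CAGCAGCAA")

  left <- locate_tract(paste0("AAGCTT", strrep("CAG", 40)), sp)
  expect_equal(left$status, "left-only")
  expect_equal(left$tract, strrep("CAG", 40))

  right <- locate_tract(paste0(strrep("CAG", 10), "GGATCC"), sp)
  expect_equal(right$status, "right-only")
  expect_equal(right$frame, "right")

  none <- locate_tract("TTTTTTTTTTTTTTTTTTTT", sp)
  expect_equal(none$status, "unanchored")
})

test_that("reads with more than 20% N are unanchored", {
  r <- paste0(spec_cag$left_flank, "CAGCAGCAG", spec_cag$right_flank)
  n_count <- ceiling(0.25 * nchar(r))
  noisy <- paste0(strrep("N", n_count),
                  substr(r, n_count + 1, nchar(r)))
  expect_equal(locate_tract(noisy, spec_cag)$status, "unanchored")
})

test_that("per-read calls decompose tracts in frame and flag indels", {
  read <- function(tract) paste0(spec_cag$left_flank, tract,
                                 spec_cag$right_flank)
  rc <- call_read(read("CAGCAACAG"), spec_cag)
  expect_equal(rc$triplets, 3L)
  expect_equal(rc$interruptions, 1L)
  expect_false(rc$indel)

  rc2 <- call_read(read("CAGCA"), spec_cag)
  expect_equal(rc2$triplets, 1L)
  expect_true(rc2$indel)           # 5 mod 3 != 0 while both-anchored

  g <- function(tract) paste0(spec_gaa$left_flank, tract,
                              spec_gaa$right_flank)
  rc3 <- call_read(g("GAAGAGGGAGAA"), spec_gaa)
  expect_equal(rc3$interruptions, 2L)  # GAG + GGA by brute-force walk
  expect_equal(rc3$pure, 2L)

  # counters partition the triplet count
  expect_equal(rc3$pure + rc3$interruptions + rc3$byproducts + rc3$other,
               rc3$triplets)
})

test_that("right-only anchoring of an in-frame tract matches left-only", {
  tract <- "CAGCAATAGCAGCAGCAA"   # length 18, multiple of 3
  left_read <- paste0(spec_cag$left_flank, tract)
  right_read <- paste0(tract, spec_cag$right_flank)
  a <- call_read(left_read, spec_cag)
  b <- call_read(right_read, spec_cag)
  expect_equal(a$triplet_types, b$triplet_types)
  expect_equal(a$interruptions, b$interruptions)
})

test_that("summaries count edited fractions and purity as specified", {
  tracts <- c(rep("CAGCAACAGCAGCAG", 4),   # edited (1 CAA)
              rep(strrep("CAG", 5), 6))    # pure
  reads <- paste0(spec_cag$left_flank, tracts, spec_cag$right_flank)
  s <- summarize_editing(call_reads(reads, spec_cag), spec_cag)
  expect_equal(s$aligned_reads, 10L)
  expect_equal(s$edited_fraction, 0.4)
  expect_equal(s$f, 4 / 50)
  expect_equal(s$n_i, 1)
  expect_true(is.infinite(s$purity_ratio))   # all-intended: Inf:1 sentinel

  pure_only <- paste0(spec_cag$left_flank, strrep("CAG", 6),
                      spec_cag$right_flank)
  s0 <- summarize_editing(call_reads(rep(pure_only, 3), spec_cag), spec_cag)
  expect_equal(s0$edited_fraction, 0)
  expect_equal(s0$f, 0)
})

test_that("reads below the triplet floor are excluded from denominators", {
  long <- paste0(spec_cag$left_flank, strrep("CAG", 10),
                 spec_cag$right_flank)
  short <- paste0(spec_cag$left_flank, "CAACAA", spec_cag$right_flank)
  s <- summarize_editing(call_reads(c(long, short), spec_cag), spec_cag,
                         min_triplets = 5L)
  expect_equal(s$aligned_reads, 1L)
  expect_error(summarize_editing(call_reads(short, spec_cag), spec_cag),
               "no aligned reads")
})

test_that("summary invariants hold on simulated samples", {
  al <- simulate_alleles(300, allele_model(modal_length = 20, p_edit = 0.08,
                                           byproduct_prob = 0.05),
                         spec_cag, seed = 11)
  rd <- simulate_reads(al, spec_cag, read_length = 150, seed = 12)
  s <- summarize_editing(call_reads(rd, spec_cag), spec_cag)
  expect_gte(s$n_i, 1)
  expect_lte(s$f, s$f_i)      # per-triplet rate cannot exceed edited-tract rate
  expect_gte(s$f_i, 0); expect_lte(s$f_i, 1)
})

test_that("adding an edited read never decreases the edited fraction", {
  base_tracts <- c("CAGCAACAGCAGCAG", strrep("CAG", 5), strrep("CAG", 5))
  reads <- paste0(spec_cag$left_flank, base_tracts, spec_cag$right_flank)
  s0 <- summarize_editing(call_reads(reads, spec_cag), spec_cag)
  edited <- paste0(spec_cag$left_flank, "CAACAACAACAACAA",
                   spec_cag$right_flank)
  pure <- paste0(spec_cag$left_flank, strrep("CAG", 5), spec_cag$right_flank)
  s_edit <- summarize_editing(call_reads(c(reads, edited), spec_cag), spec_cag)
  s_pure <- summarize_editing(call_reads(c(reads, pure), spec_cag), spec_cag)
  expect_gte(s_edit$edited_fraction, s0$edited_fraction)
  expect_lte(s_pure$edited_fraction, s0$edited_fraction)
})

test_that("editing summary JSON round-trips", {
  al <- simulate_alleles(100, allele_model(p_edit = 0.1), spec_cag, seed = 3)
  rd <- simulate_reads(al, spec_cag, seed = 4)
  s <- summarize_editing(call_reads(rd, spec_cag), spec_cag)
  path <- withr::local_tempfile(fileext = ".json")
  write_editing_summary(s, path)
  back <- read_editing_summary(path)
  expect_equal(back$f, s$f)
  expect_equal(back$n_i, s$n_i)
  expect_equal(back$edited_fraction, s$edited_fraction)
  expect_equal(as.integer(back$interruption_histogram),
               as.integer(s$interruption_histogram))
})
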