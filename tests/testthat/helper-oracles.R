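# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops, if/else chains and a hand-written
# codon table.

# Brute-force recount of triplet classes over tract sequences (no regex, no
# package classifier): returns totals comparable to summarize_editing().
brute_force_recount <- function(tracts, pure, intended, byproducts) {
  totals <- list(triplets = 0L, pure = 0L, intended = 0L,
                 byproduct = 0L, other = 0L, edited_reads = 0L,
                 per_read_intended = integer(length(tracts)))
  for (i in seq_along(tracts)) {
    tract <- tracts[i]
    k <- nchar(tract) %/% 3L
    n_int <- 0L
    for (j in seq_len(k)) {
      trip <- substr(tract, 3L * j - 2L, 3L * j)
      totals$triplets <- totals$triplets + 1L
      if (trip == pure) {
        totals$pure <- totals$pure + 1L
      } else if (trip %in% byproducts) {
        totals$byproduct <- totals$byproduct + 1L
      } else if (trip %in% intended) {
        totals$intended <- totals$intended + 1L
        n_int <- n_int + 1L
      } else {
        totals$other <- totals$other + 1L
      }
    }
    totals$per_read_intended[i] <- n_int
    if (n_int >= 1L) totals$edited_reads <- totals$edited_reads + 1L
  }
  totals
}

# Hand-written standard genetic code (DNA codons), independent of any
# package constant.
codon_table <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

all_codons <- names(codon_table)

# Consequence of a codon change according to the hand-written table.
oracle_coding_effect <- function(ref, alt) {
  if (ref == alt) return("none")
  if (codon_table[[ref]] == codon_table[[alt]]) return("synonymous")
  if (codon_table[[alt]] == "*") return("nonsense")
  "missense"
}

# Exhaustive-outcome probability of at least one edit for independent
# Bernoulli positions (enumerates all 2^k outcomes; k <= ~15).
enumerate_at_least_one <- function(p) {
  k <- length(p)
  total <- 0
  for (mask in 0:(2^k - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(k)]
    prob <- prod(ifelse(bits == 1L, p, 1 - p))
    if (any(bits == 1L)) total <- total + prob
  }
  total
}

# Random tract built from an explicit triplet alphabet.
random_tract <- function(n_triplets, triplets, probs) {
  paste0(sample(triplets, n_triplets, replace = TRUE, prob = probs),
         collapse = "")
}
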