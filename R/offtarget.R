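# Off-target editing quantification from treated/untreated pileup counts,
# PAM-anchored mismatch classification of spacer/target pairs, and
# codon-level consequence calls.

#' Per-position edit frequencies at one locus
#'
#' Applies the locus-level filters and returns the per-position edit
#' frequencies that feed [locus_probability()]:
#'
#' 1. Editable positions are those whose untreated consensus (majority) base
#'    equals `ref_base` (the pileup schema carries no reference sequence, so
#'    the untreated sample defines it). On a minus-strand locus pass
#'    `strand = "-"` and the ref/alt bases are complemented.
#' 2. If any editable position has treated depth `<= min_coverage` the locus
#'    is filtered (`status = "filtered-low-coverage"`).
#' 3. Positions whose untreated alt-allele frequency exceeds
#'    `background_cutoff` are excluded as pre-existing polymorphisms; if all
#'    are excluded the status is `"background-excluded-all"`.
#' 4. Remaining positions get `frequency = alt count / depth` in the treated
#'    sample.
#'
#' @param treated,untreated data.frames for the same locus with columns
#'   `pos`, `A`, `C`, `G`, `T`, `depth` over identical position sets (e.g.
#'   one element of [read_pileup()]).
#' @param ref_base,alt_base the strategy's conversion on the spacer strand
#'   (C -> T for CBE, A -> G for ABE).
#' @param min_coverage depth filter; loci with any editable position at or
#'   below it are removed (default 30).
#' @param background_cutoff untreated allele-frequency cutoff (default
#'   0.025).
#' @param strand `"+"` or `"-"`; on `"-"` the conversion is complemented to
#'   reference-strand coordinates.
#' @return A list with `status` (`"ok"`, `"filtered-low-coverage"` or
#'   `"background-excluded-all"`), `frequencies` (named by position),
#'   `untreated_frequencies` (same positions) and `evaluable_positions`.
#' @export
position_frequencies <- function(treated, untreated, ref_base = "C",
                                 alt_base = "T", min_coverage = 30L,
                                 background_cutoff = 0.025,
                                 strand = c("+", "-")) {
  strand <- match.arg(strand)
  need <- c("pos", "A", "C", "G", "T", "depth")
  stopifnot(all(need %in% names(treated)), all(need %in% names(untreated)))
  if (!setequal(treated$pos, untreated$pos)) {
    stop("treated and untreated pileups cover different positions",
         call. = FALSE)
  }
  untreated <- untreated[match(treated$pos, untreated$pos), , drop = FALSE]
  if (strand == "-") {
    ref_base <- complement_base(ref_base)
    alt_base <- complement_base(alt_base)
  }
  bases <- c("A", "C", "G", "T")
  consensus <- bases[max.col(as.matrix(untreated[bases]), ties.method = "first")]
  editable <- consensus == toupper(ref_base)
  if (!any(editable)) {
    return(list(status = "background-excluded-all",
                frequencies = numeric(), untreated_frequencies = numeric(),
                evaluable_positions = 0L))
  }
  t_ed <- treated[editable, , drop = FALSE]
  u_ed <- untreated[editable, , drop = FALSE]
  if (any(t_ed$depth <= min_coverage)) {
    return(list(status = "filtered-low-coverage",
                frequencies = numeric(), untreated_frequencies = numeric(),
                evaluable_positions = 0L))
  }
  u_freq <- u_ed[[toupper(alt_base)]] / u_ed$depth
  keep <- u_freq <= background_cutoff
  if (!any(keep)) {
    return(list(status = "background-excluded-all",
                frequencies = numeric(), untreated_frequencies = numeric(),
                evaluable_positions = 0L))
  }
  t_keep <- t_ed[keep, , drop = FALSE]
  freqs <- stats::setNames(t_keep[[toupper(alt_base)]] / t_keep$depth,
                           t_keep$pos)
  u_keep <- stats::setNames(u_freq[keep], t_keep$pos)
  list(status = "ok", frequencies = freqs, untreated_frequencies = u_keep,
       evaluable_positions = sum(keep))
}

#' Probability of at least one edit at a locus
#'
#' Combines per-position edit frequencies under position independence:
#' `1 - prod(1 - p_i)`. Independence is a documented modeling assumption.
#'
#' @param frequencies numeric vector of per-position frequencies in \[0, 1\]
#'   (an empty vector gives probability 0).
#' @return Probability in \[0, 1\].
#' @export
locus_probability <- function(frequencies) {
  if (length(frequencies) == 0L) return(0)
  if (any(frequencies < 0 | frequencies > 1)) {
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  }
  1 - prod(1 - frequencies)
}

#' Classify a locus by editing level over background
#'
#' A locus is `detected` when the treated-minus-untreated editing
#' probability exceeds the detection threshold (default 0.5%), and
#' `substantial` when it reaches the substantial threshold (default 5%);
#' substantial implies detected.
#'
#' @param treated_prob,untreated_prob locus editing probabilities
#'   ([locus_probability()]) for treated and untreated samples.
#' @param detection_threshold default 0.005.
#' @param substantial_threshold default 0.05.
#' @return `"substantial"`, `"detected"` or `"below-detection"`.
#' @export
classify_locus <- function(treated_prob, untreated_prob = 0,
                           detection_threshold = 0.005,
                           substantial_threshold = 0.05) {
  check_prob(treated_prob, "treated_prob")
  check_prob(untreated_prob, "untreated_prob")
  excess <- treated_prob - untreated_prob
  if (excess >= substantial_threshold) return("substantial")
  if (excess > detection_threshold) return("detected")
  "below-detection"
}

#' Full per-locus off-target editing call
#'
#' Runs [position_frequencies()], computes treated and untreated locus
#' probabilities with the same independence rule, and classifies the locus.
#'
#' @inheritParams position_frequencies
#' @param locus locus identifier carried into the result.
#' @param detection_threshold,substantial_threshold forwarded to
#'   [classify_locus()].
#' @return An object of class `locus_editing`: list with `locus`, `status`,
#'   `evaluable_positions`, `frequencies`, `probability` (treated),
#'   `untreated_probability`.
#' @export
locus_editing <- function(treated, untreated, ref_base = "C", alt_base = "T",
                          min_coverage = 30L, background_cutoff = 0.025,
                          strand = "+", locus = NA_character_,
                          detection_threshold = 0.005,
                          substantial_threshold = 0.05) {
  pf <- position_frequencies(treated, untreated, ref_base, alt_base,
                             min_coverage, background_cutoff, strand)
  if (pf$status != "ok") {
    res <- list(locus = locus, status = pf$status,
                evaluable_positions = 0L, frequencies = numeric(),
                probability = 0, untreated_probability = 0)
  } else {
    p_t <- locus_probability(pf$frequencies)
    p_u <- locus_probability(pf$untreated_frequencies)
    res <- list(locus = locus,
                status = classify_locus(p_t, p_u, detection_threshold,
                                        substantial_threshold),
                evaluable_positions = pf$evaluable_positions,
                frequencies = pf$frequencies,
                probability = p_t, untreated_probability = p_u)
  }
  class(res) <- "locus_editing"
  res
}

#' @export
print.locus_editing <- function(x, ...) {
  cat(sprintf("locus_editing <%s>: %s (P = %.4f over %d positions)\n",
              x$locus, x$status, x$probability, x$evaluable_positions))
  invisible(x)
}

#' Classify spacer/target mismatches by PAM-relative position
#'
#' Compares a 20-nt spacer with a 20-nt genomic target (position 1
#' PAM-proximal) and bins mismatches into category A (positions 1-5,
#' PAM-proximal), B (positions 6-10) and C (positions 11-20, PAM-distal).
#'
#' @param spacer,target character 20-mers, PAM-proximal end first.
#' @return A list with `total`, `A`, `B`, `C` and `positions` (the
#'   mismatching positions).
#' @export
classify_mismatches <- function(spacer, target) {
  spacer <- toupper(spacer); target <- toupper(target)
  if (nchar(spacer) != 20L || nchar(target) != 20L) {
    stop("spacer and target must both be 20 nt", call. = FALSE)
  }
  s <- strsplit(spacer, "")[[1L]]
  t <- strsplit(target, "")[[1L]]
  mm <- which(s != t)
  list(total = length(mm),
       A = sum(mm >= 1L & mm <= 5L),
       B = sum(mm >= 6L & mm <= 10L),
       C = sum(mm >= 11L & mm <= 20L),
       positions = mm)
}

#' Codon-level consequence of an edit
#'
#' Translates both codons with the standard genetic code. Identical codons
#' give `"none"`; equal amino acids give `"synonymous"`; a stop gained gives
#' `"nonsense"`; anything else (including stop lost) is `"missense"`.
#'
#' @param ref_codon,edited_codon character 3-mers over ACGT.
#' @return One of `"none"`, `"synonymous"`, `"missense"`, `"nonsense"`.
#' @examples
#' coding_effect("CAG", "CAA")  # synonymous (Gln)
#' coding_effect("CAG", "TAG")  # nonsense
#' @export
coding_effect <- function(ref_codon, edited_codon) {
  ref_codon <- toupper(ref_codon); edited_codon <- toupper(edited_codon)
  if (!grepl("^[ACGT]{3}$", ref_codon) || !grepl("^[ACGT]{3}$", edited_codon)) {
    stop("codons must be 3-mers over ACGT", call. = FALSE)
  }
  if (ref_codon == edited_codon) return("none")
  gc <- Biostrings::GENETIC_CODE
  aa_ref <- unname(gc[[ref_codon]])
  aa_edit <- unname(gc[[edited_codon]])
  if (aa_ref == aa_edit) return("synonymous")
  if (aa_edit == "*") return("nonsense")
  "missense"
}
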