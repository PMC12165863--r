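# Synthetic-data generator. Emulates the statistical structure the pipeline
# assumes — alleles with configurable repeat-length distributions and
# per-triplet interruption probabilities (i.i.d. or clustered), byproduct
# edits, uniform sequencing substitution errors, fragment-analysis traces
# with expansion/contraction mass around a modal allele, and binomial
# treated/untreated pileups with background polymorphism — so every stage is
# verifiable against ground truth without external data. Every operation
# takes an explicit seed and runs on a private RNG stream.

#' Allele simulation model
#'
#' @param modal_length modal repeat length in repeat units.
#' @param length_sd standard deviation of the (rounded, >= 1) normal length
#'   distribution; 0 gives fixed-length alleles.
#' @param transduced_fraction probability a cell's allele is editable
#'   (emulates viral transduction efficiency).
#' @param p_edit per-triplet edit probability in transduced alleles.
#' @param byproduct_prob probability an edited triplet becomes a byproduct
#'   instead of an intended interruption (0 when the spec has no byproduct
#'   set).
#' @param clustered if `TRUE`, edited alleles receive exactly
#'   `cluster_interruptions` interruptions at uniformly chosen triplets
#'   (fixed-count clustering) instead of i.i.d. per-triplet edits.
#' @param cluster_interruptions interruption count per edited allele under
#'   clustering.
#' @return An object of class `allele_model`.
#' @export
allele_model <- function(modal_length = 20L, length_sd = 0,
                         transduced_fraction = 1, p_edit = 0.05,
                         byproduct_prob = 0, clustered = FALSE,
                         cluster_interruptions = 3L) {
  check_prob(transduced_fraction, "transduced_fraction")
  check_prob(p_edit, "p_edit")
  check_prob(byproduct_prob, "byproduct_prob")
  stopifnot(modal_length >= 1, length_sd >= 0, cluster_interruptions >= 1)
  structure(list(modal_length = as.integer(modal_length),
                 length_sd = length_sd,
                 transduced_fraction = transduced_fraction,
                 p_edit = p_edit, byproduct_prob = byproduct_prob,
                 clustered = clustered,
                 cluster_interruptions = as.integer(cluster_interruptions)),
            class = "allele_model")
}

#' Simulate repeat alleles with ground truth
#'
#' @param n number of alleles (>= 1).
#' @param model an [allele_model()].
#' @param spec a [repeat_spec()] supplying the pure triplet, intended set
#'   and byproduct set.
#' @param seed integer seed (private RNG stream; deterministic).
#' @return A list with `sequences` (character vector of tract sequences) and
#'   `truth`: a data.frame with `allele`, `length` (triplets), `transduced`,
#'   `interruptions` (intended), `byproducts`, `edited` (logical,
#'   >= 1 intended interruption).
#' @export
simulate_alleles <- function(n, model, spec, seed = 1L) {
  stopifnot(inherits(model, "allele_model"), inherits(spec, "repeat_spec"),
            n >= 1)
  with_seed(seed, {
    lens <- if (model$length_sd > 0) {
      pmax(1L, as.integer(round(stats::rnorm(n, model$modal_length,
                                             model$length_sd))))
    } else {
      rep(model$modal_length, n)
    }
    transduced <- stats::runif(n) < model$transduced_fraction
    seqs <- character(n)
    n_int <- integer(n)
    n_byp <- integer(n)
    for (i in seq_len(n)) {
      trips <- rep(spec$pure, lens[i])
      if (transduced[i]) {
        if (model$clustered) {
          k <- min(model$cluster_interruptions, lens[i])
          is_edited_allele <- stats::runif(1) <
            min(1, model$p_edit * lens[i] / model$cluster_interruptions)
          # clustered regime: allele-level editing probability chosen so the
          # expected per-triplet rate matches p_edit
          edit_idx <- if (is_edited_allele) sample.int(lens[i], k) else integer()
        } else {
          edit_idx <- which(stats::runif(lens[i]) < model$p_edit)
        }
        for (j in edit_idx) {
          if (length(spec$byproducts) &&
              stats::runif(1) < model$byproduct_prob) {
            trips[j] <- sample(spec$byproducts, 1L)
            n_byp[i] <- n_byp[i] + 1L
          } else {
            trips[j] <- sample(spec$intended, 1L)
            n_int[i] <- n_int[i] + 1L
          }
        }
      }
      seqs[i] <- paste0(trips, collapse = "")
    }
    list(sequences = seqs,
         truth = data.frame(allele = seq_len(n), length = lens,
                            transduced = transduced,
                            interruptions = n_int, byproducts = n_byp,
                            edited = n_int >= 1L))
  })
}

#' Simulate amplicon reads from alleles
#'
#' Each allele yields one read: left flank + tract, plus the right flank
#' when the read length permits, truncated to `read_length`. Uniform
#' substitution errors are applied at `error_rate` per base (each error
#' replaces the base with one of the three alternatives uniformly).
#'
#' @param alleles result of [simulate_alleles()] (or a character vector of
#'   tract sequences).
#' @param spec a [repeat_spec()] supplying the flanks.
#' @param read_length read length in nt; must be at least the anchor length.
#' @param error_rate per-base substitution probability.
#' @param seed integer seed.
#' @return A data.frame with columns `id`, `seq`, `qual` (constant Phred-40
#'   qualities), suitable for [write_fastq()]; the allele truth table (if
#'   given) is attached as attribute `truth`.
#' @export
simulate_reads <- function(alleles, spec, read_length = 150L,
                           error_rate = 0, seed = 1L) {
  stopifnot(inherits(spec, "repeat_spec"))
  seqs <- if (is.list(alleles)) alleles$sequences else alleles
  if (read_length < spec$anchor_length) {
    stop("read_length must be at least the anchor length", call. = FALSE)
  }
  check_prob(error_rate, "error_rate")
  with_seed(seed, {
    full <- paste0(spec$left_flank, seqs, spec$right_flank)
    reads <- substr(full, 1L, read_length)
    if (error_rate > 0) {
      bases <- c("A", "C", "G", "T")
      reads <- vapply(reads, function(r) {
        b <- strsplit(r, "")[[1L]]
        hit <- which(stats::runif(length(b)) < error_rate)
        for (j in hit) {
          b[j] <- sample(setdiff(bases, b[j]), 1L)
        }
        paste0(b, collapse = "")
      }, character(1L), USE.NAMES = FALSE)
    }
    out <- data.frame(id = sprintf("sim_%06d", seq_along(reads)),
                      seq = reads,
                      qual = strrep("I", nchar(reads)),
                      stringsAsFactors = FALSE)
    if (is.list(alleles) && !is.null(alleles$truth)) {
      attr(out, "truth") <- alleles$truth
    }
    out
  })
}

#' Fragment-trace simulation model
#'
#' @param reference_modal modal allele size in repeat units.
#' @param expansion_fraction,contraction_fraction mass fractions placed at
#'   the shifted peaks (their sum must be <= 1; the remainder stays at the
#'   modal size).
#' @param expansion_shift,contraction_shift mean shifts in repeat units
#'   (positive numbers; the contraction peak sits at
#'   `reference_modal - contraction_shift`).
#' @param noise multiplicative peak-height noise level (lognormal sd on the
#'   log scale; 0 for none).
#' @param intensity total trace intensity distributed over the peaks.
#' @return An object of class `trace_model`.
#' @export
trace_model <- function(reference_modal = 100L, expansion_fraction = 0,
                        expansion_shift = 6L, contraction_fraction = 0,
                        contraction_shift = 6L, noise = 0,
                        intensity = 10000L) {
  check_prob(expansion_fraction, "expansion_fraction")
  check_prob(contraction_fraction, "contraction_fraction")
  if (expansion_fraction + contraction_fraction > 1) {
    stop("mass fractions must sum to <= 1", call. = FALSE)
  }
  stopifnot(expansion_shift >= 0, contraction_shift >= 0, noise >= 0,
            intensity > 0)
  structure(list(reference_modal = reference_modal,
                 expansion_fraction = expansion_fraction,
                 expansion_shift = expansion_shift,
                 contraction_fraction = contraction_fraction,
                 contraction_shift = contraction_shift,
                 noise = noise, intensity = intensity),
            class = "trace_model")
}

#' Simulate a fragment-analysis peak trace
#'
#' Places multinomial-sampled intensity at the modal size and at the
#' expansion/contraction shifts, optionally perturbed by lognormal height
#' noise. Deterministic given the seed.
#'
#' @param model a [trace_model()].
#' @param seed integer seed.
#' @param label trace label.
#' @return A [peak_trace()].
#' @export
simulate_trace <- function(model, seed = 1L, label = "simulated") {
  stopifnot(inherits(model, "trace_model"))
  with_seed(seed, {
    sizes <- model$reference_modal +
      c(0, model$expansion_shift, -model$contraction_shift)
    probs <- c(1 - model$expansion_fraction - model$contraction_fraction,
               model$expansion_fraction, model$contraction_fraction)
    keep <- probs > 0
    sizes <- sizes[keep]; probs <- probs[keep]
    # collapse coincident sizes (e.g. zero shifts)
    probs <- tapply(probs, sizes, sum)
    sizes <- as.numeric(names(probs))
    heights <- if (length(sizes) == 1L) {
      model$intensity
    } else {
      as.numeric(stats::rmultinom(1L, model$intensity, as.numeric(probs)))
    }
    if (model$noise > 0) {
      heights <- heights * stats::rlnorm(length(heights), 0, model$noise)
    }
    nz <- heights > 0
    peak_trace(sizes[nz], heights[nz], label = label)
  })
}

#' Simulate treated/untreated pileups with ground truth
#'
#' Binomial alt-allele counts at fixed coverage. Positions flagged as
#' background polymorphisms carry `background_freq` alt alleles in *both*
#' samples (so the off-target filter should exclude them); other positions
#' carry the true editing frequency in the treated sample only.
#'
#' @param truth data.frame with columns `locus`, `pos`, `ref`, `alt`,
#'   `freq` (true per-position editing frequency) and `background` (logical
#'   polymorphism flag).
#' @param coverage read depth at every position.
#' @param background_freq alt-allele frequency at flagged positions.
#' @param seed integer seed.
#' @return A list with `treated` and `untreated`, each a named list of
#'   per-locus pileup data.frames in the [read_pileup()] schema.
#' @export
simulate_pileups <- function(truth, coverage = 1000L, background_freq = 0.05,
                             seed = 1L) {
  need <- c("locus", "pos", "ref", "alt", "freq", "background")
  stopifnot(all(need %in% names(truth)))
  check_prob(background_freq, "background_freq")
  with_seed(seed, {
    make_counts <- function(p_alt, ref, alt) {
      alt_n <- stats::rbinom(1L, coverage, p_alt)
      counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
      counts[alt] <- alt_n
      counts[ref] <- counts[ref] + coverage - alt_n
      counts
    }
    build <- function(treated) {
      rows <- lapply(seq_len(nrow(truth)), function(i) {
        r <- truth[i, ]
        p_alt <- if (r$background) background_freq
                 else if (treated) r$freq else 0
        cnt <- make_counts(p_alt, toupper(r$ref), toupper(r$alt))
        data.frame(locus = r$locus, pos = r$pos,
                   A = cnt[["A"]], C = cnt[["C"]], G = cnt[["G"]],
                   T = cnt[["T"]], depth = as.integer(coverage))
      })
      df <- do.call(rbind, rows)
      split(df, factor(df$locus, levels = unique(df$locus)))
    }
    list(treated = build(TRUE), untreated = build(FALSE))
  })
}
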