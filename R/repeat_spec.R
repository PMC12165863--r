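#' Define a repeat locus and its edited-allele pattern
#'
#' A `repeat_spec` describes a trinucleotide repeat locus for quantification:
#' the pure repeat unit, an IUPAC degenerate pattern capturing every triplet
#' the base-editing strategy can produce, the subset of pattern matches that
#' count as intended interruptions, an explicit byproduct set (e.g.
#' opposite-strand deamination products), and the flanking sequences used to
#' anchor reads.
#'
#' The intended set is derived automatically: all concrete matches of
#' `edited_pattern` minus the pure triplet minus the byproducts. For the
#' shipped cytosine-base-editing CAG strategy the pattern is `YAR`
#' (Y = C/T, A, R = A/G), so the intended set is `{CAA}` and the byproducts
#' `{TAG, TAA}` are the nonsense products of opposite-strand editing. For the
#' adenine-base-editing GAA strategy the pattern is `GRR`, giving intended
#' interruptions `{GAG, GGA, GGG}` and no byproducts.
#'
#' @param pure pure repeat triplet, e.g. `"CAG"`.
#' @param edited_pattern IUPAC 3-mer matched by all editing outcomes, e.g.
#'   `"YAR"`.
#' @param byproducts character vector of byproduct triplets (may be empty).
#' @param left_flank,right_flank flanking sequences bordering the repeat
#'   tract in the amplicon; only the `anchor_length` bases adjacent to the
#'   tract are used for anchoring.
#' @param anchor_length number of flank bases (>= 6) used as exact-match
#'   anchors; default 12.
#' @param name label for reports.
#' @return An object of class `repeat_spec`: a list with elements `name`,
#'   `pure`, `edited_pattern`, `intended`, `byproducts`, `left_flank`,
#'   `right_flank`, `anchor_length`.
#' @examples
#' spec <- cag_cbe_spec()
#' spec$intended    # "CAA"
#' spec$byproducts  # "TAG" "TAA"
#' @seealso [classify_triplet()], [call_reads()]
#' @export
repeat_spec <- function(pure, edited_pattern, byproducts = character(),
                        left_flank, right_flank, anchor_length = 12L,
                        name = pure) {
  pure <- toupper(pure)
  byproducts <- toupper(byproducts)
  left_flank <- toupper(left_flank)
  right_flank <- toupper(right_flank)
  stopifnot(nchar(pure) == 3L, grepl("^[ACGT]{3}$", pure))
  matches <- expand_iupac(edited_pattern)
  if (!pure %in% matches) {
    stop("pure triplet ", pure, " does not match the edited pattern ",
         edited_pattern, call. = FALSE)
  }
  intended <- setdiff(matches, c(pure, byproducts))
  if (length(intersect(intended, byproducts)) ||
      pure %in% byproducts || pure %in% intended) {
    stop("pure, intended and byproduct sets must be pairwise disjoint",
         call. = FALSE)
  }
  anchor_length <- as.integer(anchor_length)
  if (anchor_length < 6L) {
    stop("anchor_length must be >= 6", call. = FALSE)
  }
  if (nchar(left_flank) < anchor_length || nchar(right_flank) < anchor_length) {
    stop("flanks must be at least anchor_length long", call. = FALSE)
  }
  structure(
    list(name = name, pure = pure, edited_pattern = toupper(edited_pattern),
         intended = intended, byproducts = byproducts,
         left_flank = left_flank, right_flank = right_flank,
         anchor_length = anchor_length),
    class = "repeat_spec"
  )
}

#' @export
print.repeat_spec <- function(x, ...) {
  cat("repeat_spec <", x$name, ">\n", sep = "")
  cat("  pure:      ", x$pure, "\n", sep = "")
  cat("  pattern:   ", x$edited_pattern, "\n", sep = "")
  cat("  intended:  ", paste(x$intended, collapse = ", "), "\n", sep = "")
  cat("  byproduct: ",
      if (length(x$byproducts)) paste(x$byproducts, collapse = ", ") else "(none)",
      "\n", sep = "")
  cat("  anchors:   ", x$anchor_length, " nt\n", sep = "")
  invisible(x)
}

#' Shipped CAG cytosine-base-editing spec
#'
#' CAG repeat tract edited on the opposite (CTG) strand by a cytosine base
#' editor. Intended outcome is the synonymous CAA interruption; opposite-strand
#' deamination yields TAG/TAA nonsense byproducts. The default flanks are
#' synthetic non-repeat sequences for simulation; supply the true amplicon
#' flanks for real data.
#'
#' @param left_flank,right_flank optional amplicon flanks.
#' @param anchor_length anchor size in nt.
#' @return A [repeat_spec()].
#' @export
cag_cbe_spec <- function(left_flank = "TTGCACCGACTGTGGAAGCTT",
                         right_flank = "GGATCCTTCGTACTGACCTAG",
                         anchor_length = 12L) {
  repeat_spec("CAG", "YAR", byproducts = c("TAG", "TAA"),
              left_flank = left_flank, right_flank = right_flank,
              anchor_length = anchor_length, name = "CAG-CBE")
}

#' Shipped GAA adenine-base-editing spec
#'
#' GAA repeat tract edited by an adenine base editor; the GRR pattern captures
#' every A-to-G outcome combination (GAG, GGA, GGG interruptions). No
#' byproduct set: nonsense products are not generated by this strategy.
#' Default flanks are synthetic non-repeat sequences for simulation.
#'
#' @inheritParams cag_cbe_spec
#' @return A [repeat_spec()].
#' @export
gaa_abe_spec <- function(left_flank = "CTTGCACCGACTGTCCATGCA",
                         right_flank = "TTCGATCCATCGTACTCCTAG",
                         anchor_length = 12L) {
  repeat_spec("GAA", "GRR", byproducts = character(),
              left_flank = left_flank, right_flank = right_flank,
              anchor_length = anchor_length, name = "GAA-ABE")
}

#' Classify one triplet against a repeat spec
#'
#' @param triplet character 3-mer (alphabet ACGTN).
#' @param spec a [repeat_spec()].
#' @return One of `"pure"`, `"intended"`, `"byproduct"`, `"other"`. Any N
#'   makes a triplet `"other"`.
#' @examples
#' classify_triplet("CAA", cag_cbe_spec())  # intended
#' classify_triplet("TAG", cag_cbe_spec())  # byproduct
#' @export
classify_triplet <- function(triplet, spec) {
  stopifnot(inherits(spec, "repeat_spec"))
  triplet <- toupper(triplet)
  if (any(nchar(triplet) != 3L)) {
    stop("triplets must have length 3", call. = FALSE)
  }
  if (!all(grepl("^[ACGTN]{3}$", triplet))) {
    stop("triplets must be over the alphabet ACGTN", call. = FALSE)
  }
  out <- rep("other", length(triplet))
  out[triplet == spec$pure] <- "pure"
  out[triplet %in% spec$byproducts] <- "byproduct"
  out[triplet %in% spec$intended] <- "intended"
  out[grepl("N", triplet, fixed = TRUE)] <- "other"
  out
}
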