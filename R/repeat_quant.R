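# Repeat-tract quantification engine: anchor reads at the repeat flanks,
# decompose the tract into in-frame triplets, classify each triplet against
# the spec's IUPAC edited-allele pattern, and summarize per-sample editing.

#' Locate the repeat tract within a read
#'
#' Anchors a read using exact matches of the `anchor_length`-base suffix of
#' the left flank and prefix of the right flank. Anchor status is one of
#' `both`, `left-only`, `right-only` or `unanchored`; unanchored is a status,
#' not an error. When both anchors are found the tract is the sequence
#' strictly between them; with only the left anchor the tract is the suffix
#' after it (frame counted from the left); with only the right anchor the
#' tract is the prefix before it and triplets are counted from the right
#' edge. Reads with more than 20% N are treated as unanchored.
#'
#' @param read character scalar of read bases.
#' @param spec a [repeat_spec()].
#' @return A list with `status`, `tract` (NA when unanchored) and `frame`
#'   (`"left"` or `"right"`).
#' @export
locate_tract <- function(read, spec) {
  stopifnot(inherits(spec, "repeat_spec"))
  read <- toupper(read)
  if (nchar(read) < spec$anchor_length) {
    stop("read shorter than anchor length", call. = FALSE)
  }
  n_frac <- lengths(regmatches(read, gregexpr("N", read)))[1L] / nchar(read)
  if (n_frac > 0.2) {
    return(list(status = "unanchored", tract = NA_character_, frame = NA_character_))
  }
  la <- substr(spec$left_flank,
               nchar(spec$left_flank) - spec$anchor_length + 1L,
               nchar(spec$left_flank))
  ra <- substr(spec$right_flank, 1L, spec$anchor_length)
  # first occurrence of the left anchor from the read start
  lpos <- regexpr(la, read, fixed = TRUE)
  # last occurrence of the right anchor (first from the read end)
  rall <- gregexpr(ra, read, fixed = TRUE)[[1L]]
  rpos <- if (rall[1L] == -1L) -1L else rall[length(rall)]
  tract_start <- if (lpos > 0L) lpos + spec$anchor_length else NA_integer_
  if (lpos > 0L && rpos > 0L && rpos >= tract_start) {
    tract <- substr(read, tract_start, rpos - 1L)
    return(list(status = "both", tract = tract, frame = "left"))
  }
  if (lpos > 0L) {
    return(list(status = "left-only",
                tract = substr(read, tract_start, nchar(read)),
                frame = "left"))
  }
  if (rpos > 0L) {
    return(list(status = "right-only",
                tract = substr(read, 1L, rpos - 1L),
                frame = "right"))
  }
  list(status = "unanchored", tract = NA_character_, frame = NA_character_)
}

# Split a tract into in-frame triplets. Frame "left": from the start,
# dropping the trailing partial triplet; frame "right": aligned to the right
# edge, dropping the leading partial triplet.
tract_triplets <- function(tract, frame = c("left", "right")) {
  frame <- match.arg(frame)
  len <- nchar(tract)
  k <- len %/% 3L
  if (k == 0L) return(character())
  offset <- if (frame == "left") 0L else len %% 3L
  starts <- offset + 3L * seq_len(k) - 2L
  substring(tract, starts, starts + 2L)
}

#' Classify one read against a repeat spec
#'
#' Locates the tract ([locate_tract()]), decomposes it into in-frame triplets
#' and counts pure, intended-interruption, byproduct and other triplets. An
#' indel signal is flagged when a both-anchored tract length is not a
#' multiple of 3 (whole-unit slippage or sequencing indel).
#'
#' @param read character scalar of read bases.
#' @param spec a [repeat_spec()].
#' @param id read identifier carried into the result.
#' @return A list (one ReadCall) with fields `id`, `status`, `triplets`
#'   (count), `pure`, `interruptions` (intended), `byproducts`, `other`,
#'   `indel` and `triplet_types` (character vector of the triplets seen).
#' @export
call_read <- function(read, spec, id = NA_character_) {
  loc <- locate_tract(read, spec)
  if (loc$status == "unanchored") {
    return(list(id = id, status = loc$status, triplets = 0L, pure = 0L,
                interruptions = 0L, byproducts = 0L, other = 0L,
                indel = FALSE, triplet_types = character()))
  }
  trips <- tract_triplets(loc$tract, loc$frame)
  cls <- if (length(trips)) classify_triplet(trips, spec) else character()
  list(id = id, status = loc$status, triplets = length(trips),
       pure = sum(cls == "pure"),
       interruptions = sum(cls == "intended"),
       byproducts = sum(cls == "byproduct"),
       other = sum(cls == "other"),
       indel = loc$status == "both" && nchar(loc$tract) %% 3L != 0L,
       triplet_types = trips)
}

#' Classify a set of reads
#'
#' Vectorized driver over [call_read()].
#'
#' @param reads data.frame with columns `id` and `seq` (e.g. from
#'   [read_fastq()]), or a character vector of sequences.
#' @param spec a [repeat_spec()].
#' @return A data.frame of per-read calls (`id`, `status`, `triplets`,
#'   `pure`, `interruptions`, `byproducts`, `other`, `indel`) with an
#'   attribute `type_counts`: a named integer vector tallying every triplet
#'   observed in anchored reads.
#' @export
call_reads <- function(reads, spec) {
  if (is.character(reads)) {
    reads <- data.frame(id = paste0("read_", seq_along(reads)), seq = reads,
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "seq") %in% names(reads)))
  calls <- Map(call_read, reads$seq, id = reads$id,
               MoreArgs = list(spec = spec), USE.NAMES = FALSE)
  df <- data.frame(
    id = vapply(calls, `[[`, "", "id"),
    status = vapply(calls, `[[`, "", "status"),
    triplets = vapply(calls, `[[`, 0L, "triplets"),
    pure = vapply(calls, `[[`, 0L, "pure"),
    interruptions = vapply(calls, `[[`, 0L, "interruptions"),
    byproducts = vapply(calls, `[[`, 0L, "byproducts"),
    other = vapply(calls, `[[`, 0L, "other"),
    indel = vapply(calls, `[[`, FALSE, "indel"),
    stringsAsFactors = FALSE
  )
  types <- unlist(lapply(calls, `[[`, "triplet_types"), use.names = FALSE)
  tc <- if (length(types)) table(types) else table(character())
  attr(df, "type_counts") <- stats::setNames(as.integer(tc), names(tc))
  df
}

#' Summarize sample-level editing
#'
#' Aggregates per-read calls into the sample statistics used throughout the
#' downstream model:
#' * `edited_fraction` — fraction of aligned reads with at least one intended
#'   interruption (byproduct-only reads are reported separately, not counted
#'   as edited);
#' * `f` — fraction of all sequenced triplets that are intended
#'   interruptions;
#' * `n_i` — mean interruptions per edited read;
#' * `f_i` — mean interrupted fraction of the tract among edited reads;
#' * `purity_ratio` — total intended : total byproduct triplets, reported as
#'   a ratio to 1 (`Inf` when no byproducts were seen).
#'
#' Anchored reads covering fewer than `min_triplets` triplets are excluded
#' from all denominators: very short tract coverage makes a per-read
#' "edited" label uninformative.
#'
#' @param calls data.frame from [call_reads()].
#' @param spec the [repeat_spec()] used for the calls.
#' @param min_triplets minimum triplets per read (default 5).
#' @return An object of class `editing_summary`: a list with `aligned_reads`,
#'   `edited_reads`, `edited_fraction`, `byproduct_read_fraction`, `f`,
#'   `n_i`, `median_n_i`, `f_i`, `purity_ratio`,
#'   `interruption_histogram` (table over edited reads), and
#'   `triplet_type_counts`.
#' @export
summarize_editing <- function(calls, spec, min_triplets = 5L) {
  stopifnot(is.data.frame(calls))
  keep <- calls$status != "unanchored" & calls$triplets >= min_triplets
  k <- calls[keep, , drop = FALSE]
  if (nrow(k) == 0L) {
    stop("no aligned reads after filtering (min_triplets = ", min_triplets,
         ")", call. = FALSE)
  }
  edited <- k$interruptions >= 1L
  total_triplets <- sum(k$triplets)
  total_intended <- sum(k$interruptions)
  total_byprod <- sum(k$byproducts)
  hist <- table(factor(k$interruptions[edited]))
  res <- list(
    aligned_reads = nrow(k),
    edited_reads = sum(edited),
    edited_fraction = mean(edited),
    byproduct_read_fraction = mean(k$byproducts >= 1L & !edited),
    f = total_intended / total_triplets,
    n_i = if (any(edited)) mean(k$interruptions[edited]) else NA_real_,
    median_n_i = if (any(edited)) stats::median(k$interruptions[edited]) else NA_real_,
    f_i = if (any(edited)) {
      mean(k$interruptions[edited] / k$triplets[edited])
    } else NA_real_,
    purity_ratio = if (total_byprod > 0L) total_intended / total_byprod else Inf,
    interruption_histogram = hist,
    triplet_type_counts = attr(calls, "type_counts"),
    min_triplets = as.integer(min_triplets),
    spec_name = spec$name
  )
  class(res) <- "editing_summary"
  res
}

#' @export
print.editing_summary <- function(x, ...) {
  cat("editing_summary <", x$spec_name, ">\n", sep = "")
  cat(sprintf("  aligned reads:      %d\n", x$aligned_reads))
  cat(sprintf("  edited reads:       %d (%.1f%%)\n", x$edited_reads,
              100 * x$edited_fraction))
  cat(sprintf("  f  (triplet level): %.4f\n", x$f))
  if (!is.na(x$n_i)) {
    cat(sprintf("  n_i (per edited):   %.2f (median %g)\n", x$n_i, x$median_n_i))
    cat(sprintf("  f_i (tract frac):   %.4f\n", x$f_i))
  }
  cat(sprintf("  purity:             %s:1\n",
              if (is.infinite(x$purity_ratio)) "Inf"
              else format(round(x$purity_ratio, 1))))
  invisible(x)
}

#' Serialize an editing summary to JSON
#'
#' @param summary an [summarize_editing()] result.
#' @param path destination JSON file.
#' @return `path`, invisibly.
#' @export
write_editing_summary <- function(summary, path) {
  stopifnot(inherits(summary, "editing_summary"))
  x <- unclass(summary)
  x$interruption_histogram <- as.list(stats::setNames(
    as.integer(summary$interruption_histogram),
    names(summary$interruption_histogram)))
  x$triplet_type_counts <- as.list(summary$triplet_type_counts)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read back an editing summary written by [write_editing_summary()]
#'
#' @param path JSON file.
#' @return An `editing_summary` object.
#' @export
read_editing_summary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  nm <- names(x$interruption_histogram)
  cnt <- unlist(x$interruption_histogram)
  x$interruption_histogram <- table(factor(rep(nm, cnt), levels = nm))
  x$triplet_type_counts <- unlist(x$triplet_type_counts)
  class(x) <- "editing_summary"
  x
}
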