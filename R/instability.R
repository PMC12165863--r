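# Somatic repeat-instability metrics from fragment-analysis peak data.
#
# Each sample is a trace of (size, height) peaks; sizes are in repeat units
# after calibration (see read_peak_table). Instability is quantified as the
# peak-height-weighted mean signed change in repeat units relative to the
# modal allele of a stable reference tissue (tail), after discarding peaks
# below a relative height threshold and contractions beyond a cap.

#' Construct a peak trace
#'
#' @param size numeric vector of peak sizes in repeat units (strictly
#'   increasing after sorting; duplicates are rejected — sum them upstream,
#'   as [read_peak_table()] does).
#' @param height nonnegative peak heights (arbitrary intensity units).
#' @param label sample/tissue label.
#' @return An object of class `peak_trace`.
#' @export
peak_trace <- function(size, height, label = NA_character_) {
  if (length(size) == 0L) stop("a trace needs at least one peak", call. = FALSE)
  if (length(size) != length(height)) {
    stop("size and height lengths differ", call. = FALSE)
  }
  if (any(height < 0)) stop("peak heights must be >= 0", call. = FALSE)
  ord <- order(size)
  size <- size[ord]; height <- height[ord]
  if (anyDuplicated(size)) stop("duplicate peak sizes", call. = FALSE)
  structure(list(size = size, height = height, label = label),
            class = "peak_trace")
}

#' @export
print.peak_trace <- function(x, ...) {
  cat("peak_trace", if (!is.na(x$label)) paste0("<", x$label, ">"), "with",
      length(x$size), "peaks\n")
  print(data.frame(size = x$size, height = x$height))
  invisible(x)
}

#' Modal allele of a trace
#'
#' The peak with maximal height; ties are broken toward the smaller size
#' (deterministic; ties are a degenerate input).
#'
#' @param trace a [peak_trace()].
#' @return A list with `size` and `height`.
#' @export
modal_allele <- function(trace) {
  stopifnot(inherits(trace, "peak_trace"))
  i <- which(trace$height == max(trace$height))[1L]  # sizes sorted ascending
  list(size = trace$size[i], height = trace$height[i])
}

#' Modal-peak-height quality control
#'
#' Traces whose modal peak height falls below `min_modal_height` are
#' rejected from instability analysis (default 1000, matching capillary
#' fragment analysis practice). Gel-densitometry traces disable QC with
#' `min_modal_height = NULL`.
#'
#' @param trace a [peak_trace()].
#' @param min_modal_height threshold, or `NULL` to disable.
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
qc_trace <- function(trace, min_modal_height = 1000) {
  if (is.null(min_modal_height)) return(TRUE)
  modal_allele(trace)$height >= min_modal_height
}

#' Instability, expansion and contraction indices
#'
#' For each peak, the signed change is `delta = size - reference_modal`.
#' Peaks below `threshold` times the tallest peak of the analyzed trace are
#' discarded, as are contractions beyond `-cap` repeat units. The retained
#' peaks are then restricted by `mode` (`"both"`: all; `"expansion"`:
#' `delta >= 0`; `"contraction"`: `delta <= 0` — the `delta = 0` peak is
#' included in both one-sided modes and contributes zero either way), and
#' the index is the height-weighted mean of `delta`:
#' `sum(delta * h) / sum(h)`.
#'
#' @param trace a [peak_trace()] of the analyzed tissue.
#' @param reference_modal modal allele size (repeat units) of the stable
#'   reference tissue of the same individual.
#' @param threshold relative peak-height threshold in \[0, 1\] (default 0.05;
#'   use 0.10 for gel densitometry).
#' @param mode `"both"`, `"expansion"` or `"contraction"`.
#' @param cap largest contraction retained, in repeat units (default 40);
#'   `Inf` disables the cap.
#' @return An object of class `instability_result`: list with
#'   `reference_modal`, `mode`, `threshold`, `cap`, `retained_peaks` and
#'   `index` (`NA` when no peaks are retained).
#' @examples
#' tr <- peak_trace(size = c(100, 102), height = c(100, 50))
#' instability_index(tr, reference_modal = 100)$index  # 2*50/150
#' @export
instability_index <- function(trace, reference_modal, threshold = 0.05,
                              mode = c("both", "expansion", "contraction"),
                              cap = 40) {
  stopifnot(inherits(trace, "peak_trace"))
  mode <- match.arg(mode)
  check_prob(threshold, "threshold")
  if (!is.numeric(reference_modal) || length(reference_modal) != 1L) {
    stop("reference_modal must be a single size", call. = FALSE)
  }
  delta <- trace$size - reference_modal
  keep <- trace$height >= threshold * max(trace$height)
  keep <- keep & delta >= -cap
  keep <- keep & switch(mode,
                        both = TRUE,
                        expansion = delta >= 0,
                        contraction = delta <= 0)
  h <- trace$height[keep]
  d <- delta[keep]
  idx <- if (length(h) && sum(h) > 0) sum(d * h) / sum(h) else NA_real_
  structure(
    list(reference_modal = reference_modal, mode = mode,
         threshold = threshold, cap = cap,
         retained_peaks = sum(keep), index = idx,
         label = trace$label),
    class = "instability_result"
  )
}

#' @export
print.instability_result <- function(x, ...) {
  cat(sprintf("instability_result [%s]: index = %s (%d peaks, ref modal %g)\n",
              x$mode,
              if (is.na(x$index)) "NA" else sprintf("%.3f", x$index),
              x$retained_peaks, x$reference_modal))
  invisible(x)
}

#' Allele frequencies relative to the predominant allele
#'
#' Normalizes peak heights to the modal peak, whose frequency is set to 1.
#'
#' @param trace a [peak_trace()].
#' @return A data.frame with columns `size` and `frequency`.
#' @export
normalize_allele_frequencies <- function(trace) {
  stopifnot(inherits(trace, "peak_trace"))
  m <- modal_allele(trace)
  if (m$height <= 0) stop("modal height is zero; cannot normalize", call. = FALSE)
  data.frame(size = trace$size, frequency = trace$height / m$height)
}

#' Instability report over samples and modes
#'
#' Convenience driver producing one row per (trace, mode), the shape written
#' by the `instability` pipeline stage.
#'
#' @param traces list of [peak_trace()] objects.
#' @param reference_modal reference modal size shared by all traces.
#' @param threshold,cap forwarded to [instability_index()].
#' @param min_modal_height QC threshold forwarded to [qc_trace()]; failing
#'   traces are reported with `qc = FALSE` and `NA` indices.
#' @return A data.frame with columns `label`, `mode`, `qc`, `retained_peaks`,
#'   `index`.
#' @export
instability_report <- function(traces, reference_modal, threshold = 0.05,
                               cap = 40, min_modal_height = 1000) {
  rows <- lapply(traces, function(tr) {
    ok <- qc_trace(tr, min_modal_height)
    do.call(rbind, lapply(c("both", "expansion", "contraction"), function(m) {
      r <- instability_index(tr, reference_modal, threshold, m, cap)
      data.frame(label = tr$label, mode = m, qc = ok,
                 retained_peaks = if (ok) r$retained_peaks else NA_integer_,
                 index = if (ok) r$index else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
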