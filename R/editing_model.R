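# Extrapolation from windowed observed editing to full-length alleles.
#
# Amplicon sequencing observes only a window of W repeat units of a long
# tract (e.g. 70 of >= 300 GAA units), so the observed edited-read fraction
# underestimates the fraction of full alleles carrying at least one
# interruption. The model converts the observed interrupted-triplet fraction
# f and the mean interruptions per interrupted allele n_i into a per-triplet
# edit probability p = f / n_i, and extrapolates to an allele of N units as
# 1 - (1 - p)^N. The expected interruption count in an edited allele of N
# units is f_i * N, where f_i is the mean interrupted fraction of the
# observed tract among edited reads.

#' Per-triplet edit probability
#'
#' `p = f / n_i`: the interrupted-triplet fraction over all sequenced
#' triplets, normalized by the mean number of interruptions per interrupted
#' allele. Under an independent-edits model this is the probability that any
#' single triplet is edited.
#'
#' @param f interrupted-triplet fraction in \[0, 1\].
#' @param n_i mean interruptions per interrupted allele; must be >= 1 (an
#'   interrupted allele has at least one interruption).
#' @return `p` in \[0, 1\].
#' @export
per_triplet_rate <- function(f, n_i) {
  check_prob(f, "f")
  if (!is.numeric(n_i) || length(n_i) != 1L || is.na(n_i) || n_i < 1) {
    stop("n_i must be >= 1: an interrupted allele carries at least one interruption",
         call. = FALSE)
  }
  p <- f / n_i
  if (p > 1) stop("f / n_i exceeds 1", call. = FALSE)
  p
}

#' Estimated editing of a full-length allele
#'
#' Probability that an allele of `N` repeat units carries at least one
#' interruption, assuming independent per-triplet edits at rate `p`:
#' `1 - (1 - p)^N`.
#'
#' @param p per-triplet edit probability ([per_triplet_rate()]).
#' @param N allele repeat length in repeat units (integer >= 1); vectorized.
#' @return Estimated editing probability, nondecreasing in both `p` and `N`.
#' @examples
#' estimate_editing(0.01, 100)  # 1 - 0.99^100
#' @export
estimate_editing <- function(p, N) {
  check_prob(p, "p")
  if (any(N < 1) || any(N != round(N))) {
    stop("N must be a positive integer repeat length", call. = FALSE)
  }
  1 - (1 - p)^N
}

#' Expected interruptions in a full-length edited allele
#'
#' `f_i * N`: the mean interrupted tract fraction among edited reads scaled
#' to an allele of `N` repeat units.
#'
#' @param f_i mean interrupted fraction of the tract in \[0, 1\].
#' @param N allele repeat length (>= 1); vectorized.
#' @return Expected interruption count (>= 0).
#' @export
estimate_interruptions <- function(f_i, N) {
  check_prob(f_i, "f_i")
  if (any(N < 1)) stop("N must be >= 1", call. = FALSE)
  f_i * N
}

#' Full editing estimate for a sample
#'
#' Combines an [summarize_editing()] result with a target allele length,
#' reporting observed and estimated editing side by side (the two are never
#' silently substituted for one another).
#'
#' @param summary an `editing_summary`.
#' @param N target allele repeat length, typically the genotyped modal
#'   repeat length of the sample.
#' @return A list of class `editing_estimate` with `f`, `n_i`, `f_i`, `N`,
#'   `p`, `observed_editing` (the edited-read fraction in the window),
#'   `estimated_editing` and `estimated_interruptions`.
#' @export
editing_estimate <- function(summary, N) {
  stopifnot(inherits(summary, "editing_summary"))
  if (is.na(summary$n_i)) {
    stop("no edited reads in summary; estimate undefined", call. = FALSE)
  }
  p <- per_triplet_rate(summary$f, summary$n_i)
  res <- list(f = summary$f, n_i = summary$n_i, f_i = summary$f_i,
              N = as.integer(N), p = p,
              observed_editing = summary$edited_fraction,
              estimated_editing = estimate_editing(p, N),
              estimated_interruptions = estimate_interruptions(summary$f_i, N))
  class(res) <- "editing_estimate"
  res
}

#' @export
print.editing_estimate <- function(x, ...) {
  cat("editing_estimate (N =", x$N, "repeat units)\n")
  cat(sprintf("  p (per triplet):          %.5f\n", x$p))
  cat(sprintf("  observed editing:         %.3f\n", x$observed_editing))
  cat(sprintf("  estimated editing:        %.3f\n", x$estimated_editing))
  cat(sprintf("  estimated interruptions:  %.2f\n", x$estimated_interruptions))
  invisible(x)
}

#' Bootstrap confidence interval for the editing estimate
#'
#' Nonparametric bootstrap over reads: resamples the per-read calls with
#' replacement, recomputes the summary and the full-allele estimate, and
#' returns percentile intervals.
#'
#' @param calls per-read calls from [call_reads()].
#' @param spec the [repeat_spec()] used.
#' @param N target allele repeat length.
#' @param n_boot bootstrap resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @param min_triplets forwarded to [summarize_editing()].
#' @param seed integer seed for the private RNG stream.
#' @return A data.frame with one row per statistic (`estimated_editing`,
#'   `estimated_interruptions`) and columns `estimate`, `lower`, `upper`.
#' @export
bootstrap_estimate <- function(calls, spec, N, n_boot = 1000L, level = 0.95,
                               min_triplets = 5L, seed = 1L) {
  point <- editing_estimate(summarize_editing(calls, spec, min_triplets), N)
  draws <- with_seed(seed, {
    replicate(n_boot, {
      idx <- sample.int(nrow(calls), replace = TRUE)
      b <- calls[idx, , drop = FALSE]
      attr(b, "type_counts") <- attr(calls, "type_counts")
      s <- tryCatch(summarize_editing(b, spec, min_triplets),
                    error = function(e) NULL)
      if (is.null(s) || is.na(s$n_i)) {
        c(NA_real_, NA_real_)
      } else {
        e <- editing_estimate(s, N)
        c(e$estimated_editing, e$estimated_interruptions)
      }
    })
  })
  a <- (1 - level) / 2
  qs <- apply(draws, 1L, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE)
  data.frame(
    statistic = c("estimated_editing", "estimated_interruptions"),
    estimate = c(point$estimated_editing, point$estimated_interruptions),
    lower = qs[1L, ], upper = qs[2L, ],
    row.names = NULL
  )
}
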