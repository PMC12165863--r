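# Internal helpers shared across modules.

#' Evaluate code with a private RNG stream
#'
#' Runs `expr` after seeding the RNG with `seed`, restoring the caller's
#' global `.Random.seed` afterwards so simulations never leak state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Expand an IUPAC degenerate nucleotide string
#'
#' @param pattern character scalar over the IUPAC alphabet (e.g. `"YAR"`).
#' @return Character vector of all concrete ACGT strings matched by `pattern`.
#' @keywords internal
expand_iupac <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  code <- Biostrings::IUPAC_CODE_MAP
  letters <- strsplit(toupper(pattern), "")[[1]]
  if (!all(letters %in% names(code))) {
    stop("invalid IUPAC letter(s) in pattern: ", pattern, call. = FALSE)
  }
  per_pos <- lapply(letters, function(l) strsplit(code[[l]], "")[[1]])
  combos <- expand.grid(rev(per_pos), stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest; reverse for lexicographic feel
  sort(apply(combos[, rev(seq_along(per_pos)), drop = FALSE], 1L, paste0,
             collapse = ""))
}

# Reverse complement for plain character vectors (ACGTN).
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(strsplit(toupper(x), ""), function(b) {
    paste0(rev(unname(comp[b])), collapse = "")
  }, character(1L))
}

complement_base <- function(b) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  unname(comp[toupper(b)])
}

# Assert a scalar probability.
check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("%s must be a single value in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
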