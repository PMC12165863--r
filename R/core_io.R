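# Readers and writers for the external formats the pipeline consumes:
# 4-line FASTQ (plain or gzip), GeneMapper-style peak tables (TSV),
# per-position pileup count tables (TSV), and key=value run configs.
# All tabular writers emit a commented header carrying tool version and,
# where relevant, the seed and a config hash, so every report is auditable.

#' Read a FASTQ file
#'
#' Reads 4-line FASTQ records (plain or gzip; compression is detected
#' transparently). Bases are uppercased. Each record is validated: a quality
#' string whose length differs from the base string is rejected with the
#' 1-based record index.
#'
#' @param path file path.
#' @return A data.frame with columns `id`, `seq`, `qual`, one row per record
#'   (zero rows for an empty file).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    return(data.frame(id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: line count ", length(lines),
         " is not a multiple of 4", call. = FALSE)
  }
  n <- length(lines) %/% 4L
  idx <- seq_len(n)
  hdr <- lines[4L * idx - 3L]
  seq <- toupper(lines[4L * idx - 2L])
  plus <- lines[4L * idx - 1L]
  qual <- lines[4L * idx]
  bad_hdr <- which(!startsWith(hdr, "@"))
  if (length(bad_hdr)) {
    stop("malformed FASTQ record ", bad_hdr[1L], ": header must start with '@'",
         call. = FALSE)
  }
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus)) {
    stop("malformed FASTQ record ", bad_plus[1L],
         ": separator must start with '+'", call. = FALSE)
  }
  bad_len <- which(nchar(seq) != nchar(qual))
  if (length(bad_len)) {
    stop("malformed FASTQ record ", bad_len[1L],
         ": quality length does not match sequence length", call. = FALSE)
  }
  data.frame(id = sub("^@", "", hdr), seq = seq, qual = qual,
             stringsAsFactors = FALSE)
}

#' Write a FASTQ file
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`
#'   (as returned by [read_fastq()] or [simulate_reads()]).
#' @param path destination; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    stop("sequence and quality lengths differ", call. = FALSE)
  }
  lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", reads$qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a fragment-analysis peak table
#'
#' Expects a TSV with columns `size` and `height` (GeneMapper-style export).
#' Rows are sorted by size and duplicate sizes are summed. An optional linear
#' calibration converts fragment size in nucleotides to repeat units via
#' `(size - flank_bp) / unit_length`; amplicons differ in flank length between
#' assays, so no universal constant is applied.
#'
#' @param path TSV path; lines starting with `#` are ignored.
#' @param flank_bp total flanking bases in the amplicon; `NULL` (default)
#'   leaves sizes unconverted.
#' @param unit_length repeat unit length in nt (default 3).
#' @param label sample/tissue label attached to the trace.
#' @return A [peak_trace()].
#' @export
read_peak_table <- function(path, flank_bp = NULL, unit_length = 3,
                            label = basename(path)) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("size", "height") %in% names(df))) {
    stop("peak table needs columns 'size' and 'height'", call. = FALSE)
  }
  if (any(df$height < 0)) {
    stop("negative peak height in ", path, call. = FALSE)
  }
  size <- df$size
  if (!is.null(flank_bp)) {
    size <- (size - flank_bp) / unit_length
  }
  agg <- tapply(df$height, size, sum)
  peak_trace(size = as.numeric(names(agg)), height = as.numeric(agg),
             label = label)
}

#' Write a peak trace as a TSV peak table
#'
#' @param trace a [peak_trace()].
#' @param path destination TSV.
#' @param header_comments optional character vector written as `#` lines.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(trace, path, header_comments = NULL) {
  stopifnot(inherits(trace, "peak_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(report_header(), header_comments), con)
  utils::write.table(data.frame(size = trace$size, height = trace$height),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-position pileup count table
#'
#' Expects a TSV with columns `locus`, `pos`, `A`, `C`, `G`, `T`, `depth`;
#' `depth` must equal `A + C + G + T` at every row. Rows are grouped by locus
#' (order of first appearance) with the original per-locus position order
#' kept; duplicate positions within a locus are rejected.
#'
#' @param path TSV path; `#` lines ignored.
#' @return A named list of data.frames, one per locus.
#' @export
read_pileup <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("locus", "pos", "A", "C", "G", "T", "depth")
  if (!all(need %in% names(df))) {
    stop("pileup table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(df$A + df$C + df$G + df$T != df$depth)
  if (length(bad)) {
    stop("pileup depth mismatch at locus ", df$locus[bad[1L]],
         " position ", df$pos[bad[1L]], call. = FALSE)
  }
  groups <- split(df[need], factor(df$locus, levels = unique(df$locus)))
  for (nm in names(groups)) {
    if (anyDuplicated(groups[[nm]]$pos)) {
      stop("duplicate position within locus ", nm, call. = FALSE)
    }
    rownames(groups[[nm]]) <- NULL
  }
  groups
}

#' Write pileup groups back to a TSV
#'
#' Inverse of [read_pileup()].
#'
#' @param pileup named list of per-locus data.frames, or a single data.frame
#'   with a `locus` column.
#' @param path destination TSV.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(pileup, path) {
  if (is.data.frame(pileup)) pileup <- list(pileup)
  df <- do.call(rbind, lapply(pileup, function(g) {
    g[c("locus", "pos", "A", "C", "G", "T", "depth")]
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(report_header(), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

report_header <- function(seed = NULL, config_hash = NULL) {
  v <- as.character(utils::packageVersion("repeatedit"))
  h <- paste0("# repeatedit v", v)
  if (!is.null(seed)) h <- c(h, paste0("# seed=", seed))
  if (!is.null(config_hash)) h <- c(h, paste0("# config=", config_hash))
  h
}

#' Write a TSV report with an audit header
#'
#' All tabular pipeline outputs go through this writer, which prepends `#`
#' comment lines carrying the tool version and, when given, the seed and the
#' MD5 hash of the run config, so identical inputs and seed yield
#' byte-identical reports.
#'
#' @param df data.frame to write.
#' @param path destination TSV.
#' @param seed optional integer recorded in the header.
#' @param config optional [run_config()] whose hash is recorded.
#' @return `path`, invisibly.
#' @export
write_report <- function(df, path, seed = NULL, config = NULL) {
  hash <- if (!is.null(config)) config_hash(config) else NULL
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(report_header(seed, hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
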