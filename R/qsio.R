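#' Read quality-score lines from a plain or FASTQ file
#'
#' Reads a text file of quality-score lines, either one line per record
#' (`mode = "plain"`) or as the fourth line of each 4-line FASTQ record
#' (`mode = "fastq"`).  Lines are returned as a character vector in file
#' order; position `i` of the result is the line with global 0-based
#' ordinal `i - 1`.
#'
#' Input must be LF-terminated.  CR bytes are rejected unless
#' `strip_cr = TRUE`, which drops a single CR immediately before each LF
#' (CRLF normalisation).  With `validate = TRUE` (default) every byte must
#' lie in the quality-score range \[33, 104\]; the first violation is
#' reported with its line number and byte value.  Empty lines are legal in
#' plain mode and illegal in FASTQ mode.
#'
#' @param path path to an existing file.
#' @param mode `"plain"` (one quality line per text line) or `"fastq"`.
#' @param validate check that all bytes are in \[33, 104\].
#' @param strip_cr normalise CRLF line endings instead of rejecting them.
#' @return character vector of quality lines.
#' @examples
#' f <- tempfile()
#' writeLines(c("IIII", "JJJJ"), f)
#' read_quality_lines(f)
#' @seealso [write_quality_lines()], [generate_synthetic()]
#' @export
read_quality_lines <- function(path, mode = c("plain", "fastq"),
                               validate = TRUE, strip_cr = FALSE) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("no such file: ", path)
  sz <- file.size(path)
  data <- readBin(path, what = "raw", n = sz)
  sp <- tryCatch(cpp_split_lines(data, strip_cr),
                 error = function(e) stop_format(conditionMessage(e)))
  lines <- sp$lines
  if (mode == "fastq") {
    nl <- length(lines)
    if (nl %% 4L != 0L)
      stop_format(sprintf("malformed FASTQ: %d lines is not a multiple of 4", nl))
    n <- nl %/% 4L
    if (n > 0L) {
      hdr <- lines[seq(1L, by = 4L, length.out = n)]
      sep <- lines[seq(3L, by = 4L, length.out = n)]
      bad <- which(substr(hdr, 1L, 1L) != "@")
      if (length(bad))
        stop_format(sprintf("malformed FASTQ record %d: header does not start with '@'", bad[1L]))
      bad <- which(substr(sep, 1L, 1L) != "+")
      if (length(bad))
        stop_format(sprintf("malformed FASTQ record %d: separator does not start with '+'", bad[1L]))
      lines <- lines[seq(4L, by = 4L, length.out = n)]
      empty <- which(!nzchar(lines))
      if (length(empty))
        stop_format(sprintf("malformed FASTQ record %d: empty quality line", empty[1L]))
    } else {
      lines <- character(0)
    }
  }
  if (validate)
    tryCatch(cpp_validate_lines(lines),
             error = function(e) stop_format(conditionMessage(e)))
  lines
}

#' Write quality-score lines to a plain text file
#'
#' Writes lines LF-joined with a trailing LF, so that
#' `read_quality_lines(write_quality_lines(x))` is the identity.  An empty
#' vector produces an empty file.
#'
#' @param lines character vector of quality lines.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_quality_lines <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Default synthetic mixture sources
#'
#' Two discrete sources over the quality alphabet 33..104 emulating what the
#' partition stage assumes about real data: a dominant (weight 0.8)
#' high-quality component sharply peaked near value 70, and a minor (weight
#' 0.2) broad low-quality component centred near 50.  Both are discretised
#' normals renormalised over the alphabet, giving the strongly uneven
#' marginal distribution typical of sequencer output.
#'
#' @return list of sources, each a list with elements `weight` and `probs`
#'   (length-72 probability vector over values 33:104).
#' @export
default_sources <- function() {
  vals <- 33:104
  hi <- dnorm(vals, mean = 70, sd = 2.5)
  lo <- dnorm(vals, mean = 50, sd = 8)
  list(
    list(weight = 0.8, probs = hi / sum(hi)),
    list(weight = 0.2, probs = lo / sum(lo))
  )
}

#' Specification for a synthetic quality-score fixture
#'
#' Describes a synthetic file of quality lines: each line picks a source
#' from the mixture, then draws its bytes i.i.d. from that source's
#' distribution over 33..104.
#'
#' @param n_lines number of lines.
#' @param lengths a single integer for fixed line length, or a length-2
#'   vector `c(min, max)` for uniformly variable lengths.
#' @param sources mixture sources as in [default_sources()]; weights must
#'   sum to 1 and every distribution's support is 33:104.
#' @param seed integer seed; generation is deterministic given the seed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_lines, lengths = 100L, sources = default_sources(),
                           seed = 1L) {
  if (!is.numeric(n_lines) || length(n_lines) != 1L || n_lines < 0)
    stop("n_lines must be a single non-negative number")
  if (!is.numeric(lengths) || !length(lengths) %in% c(1L, 2L) || any(lengths < 0))
    stop("lengths must be one fixed length or c(min, max)")
  if (length(lengths) == 2L && lengths[1L] > lengths[2L])
    stop("variable lengths need min <= max")
  if (!is.list(sources) || !length(sources))
    stop("sources must be a non-empty list")
  w <- vapply(sources, function(s) s$weight, numeric(1))
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
    stop("mixture weights must be non-negative and sum to 1")
  for (s in sources) {
    if (length(s$probs) != 72L || any(s$probs < 0) || abs(sum(s$probs) - 1) > 1e-9)
      stop("each source needs a length-72 probability vector over values 33:104")
  }
  structure(list(n_lines = as.integer(n_lines), lengths = as.integer(lengths),
                 sources = sources, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic quality-score fixture
#'
#' Draws `spec$n_lines` lines: a mixture component per line, then i.i.d.
#' byte values from that component.  Byte-identical output for identical
#' specs; the caller's RNG state is left untouched.
#'
#' @param spec a [synthetic_spec()].
#' @param path optional output file; when given, lines are written as with
#'   [write_quality_lines()].
#' @return the generated lines, invisibly when `path` is given.
#' @export
generate_synthetic <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  n <- spec$n_lines
  if (n == 0L) {
    lines <- character(0)
  } else {
    nsrc <- length(spec$sources)
    w <- vapply(spec$sources, function(s) s$weight, numeric(1))
    src <- sample.int(nsrc, n, replace = TRUE, prob = w)
    lens <- if (length(spec$lengths) == 1L) rep.int(spec$lengths, n)
            else sample(seq.int(spec$lengths[1L], spec$lengths[2L]), n, replace = TRUE)
    vals <- integer(sum(lens))
    by_val <- rep.int(src, lens)
    for (s in seq_len(nsrc)) {
      m <- by_val == s
      if (any(m))
        vals[m] <- sample(33:104, sum(m), replace = TRUE, prob = spec$sources[[s]]$probs)
    }
    lines <- cpp_bytes_to_lines(vals, lens)
  }
  if (!is.null(path)) {
    write_quality_lines(lines, path)
    return(invisible(lines))
  }
  lines
}
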