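#' Modal quality value of a sample
#'
#' Returns the byte value with the highest occurrence count over all bytes
#' of the sampled lines; ties break to the smallest value.  The modal value
#' anchors the adaptive pack table, because it has the best chance of
#' forming packable groups with its neighbours.
#'
#' @param sample character vector of quality lines with at least one byte.
#' @return the modal byte value as an integer in \[33, 104\] (for valid
#'   quality data).
#' @export
compute_mode <- function(sample) {
  counts <- cpp_byte_counts(sample)
  if (sum(counts) == 0)
    stop("cannot compute a modal quality value: sample contains no bytes")
  as.integer(which.max(counts) - 1L)
}

#' Build the adaptive pack table for a modal value C
#'
#' Constructs the bijective code-to-group mapping used by [pack_lines()].
#' Codes are assigned in four contiguous ranges, enumerating value tuples
#' in lexicographic order with windows clipped to \[33, 104\]:
#' \describe{
#'   \item{singles}{every value 33..104, codes 1..72 (`value - 32`);}
#'   \item{triples}{all `(a, b, c)` with each value in `[C-1, C+1]`,
#'     codes from 73;}
#'   \item{pairs}{all `(a, b)` with both values in `[C-5, C+6]`, codes
#'     continuing after the triples;}
#'   \item{runs}{runs of `C` of length 4..15, the final 12 codes.}
#' }
#' For an interior `C` this uses all 255 codes (72 + 27 + 144 + 12); code 0
#' is reserved as the line terminator.  The table is a pure function of
#' `C`, so an encoder and a decoder that share only `C` (via the container
#' header) reconstruct identical tables.
#'
#' @param C modal quality value in \[33, 104\].
#' @return an object of class `pack_table` with elements `C`, `decode`
#'   (list: code -> integer vector of values), `encode` (named integer:
#'   comma-joined values -> code) and `n_codes`.
#' @export
build_pack_table <- function(C) {
  C <- as.integer(C)
  if (is.na(C) || C < 33L || C > 104L)
    stop("modal value C must lie in [33, 104]")
  decode <- vector("list", 0L)
  # singles
  for (v in 33:104) decode[[v - 32L]] <- v
  # triples over [C-1, C+1] clipped
  w3 <- max(33L, C - 1L):min(104L, C + 1L)
  for (a in w3) for (b in w3) for (d in w3)
    decode[[length(decode) + 1L]] <- c(a, b, d)
  # pairs over [C-5, C+6] clipped
  w2 <- max(33L, C - 5L):min(104L, C + 6L)
  for (a in w2) for (b in w2)
    decode[[length(decode) + 1L]] <- c(a, b)
  # runs of C, lengths 4..15
  for (len in 4:15)
    decode[[length(decode) + 1L]] <- rep.int(C, len)
  stopifnot(length(decode) <= 255L)
  keys <- vapply(decode, paste, character(1), collapse = ",")
  encode <- stats::setNames(seq_along(decode), keys)
  structure(list(C = C, decode = decode, encode = encode,
                 n_codes = length(decode)),
            class = "pack_table")
}

#' Pack quality lines into code bytes
#'
#' Greedy left-to-right longest-match encoding: at each position a run of
#' the modal value `C` (length 4..15) is tried first, then a triple, a
#' pair, and finally a single value.  Each matched group emits one code
#' byte in 1..255; every line ends with the terminator byte 0.  The
#' transform is exactly invertible by [unpack_lines()].
#'
#' @param lines character vector of quality lines (bytes in \[33, 104\]).
#' @param table a [build_pack_table()] or the modal value `C` itself.
#' @return raw vector of code bytes.
#' @export
pack_lines <- function(lines, table) {
  C <- if (inherits(table, "pack_table")) table$C else as.integer(table)
  cpp_pack_lines(lines, C)
}

#' Unpack code bytes back into quality lines
#'
#' Pure table-lookup inverse of [pack_lines()]: each nonzero code expands
#' to its value group, each 0 ends a line.  `unpack_lines(pack_lines(x))`
#' is the identity for any valid input; an unknown code byte raises a
#' corruption error with its offset.
#'
#' @param packed raw vector of code bytes.
#' @inheritParams pack_lines
#' @return character vector of quality lines, one per terminator.
#' @export
unpack_lines <- function(packed, table) {
  C <- if (inherits(table, "pack_table")) table$C else as.integer(table)
  tryCatch(cpp_unpack_lines(packed, C),
           error = function(e) stop_corrupt(conditionMessage(e)))
}
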