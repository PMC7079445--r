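#' Dual-buffer block builder with the embedded light-weight index
#'
#' Two size-thresholded buffers turn the partitioned line streams into
#' blocks.  Buffer A receives the bytes of every stream-0 line plus one
#' placeholder newline for every stream-1 line, so each A block covers a
#' contiguous range of global line ordinals.  Buffer B receives the bytes
#' of stream-1 lines only.  A buffer whose size exceeds the threshold is
#' flushed into a block; to keep random access stable, buffer A is flushed
#' by force when buffer B has been flushed three times in a row, which
#' bounds the number of B blocks any A block overlaps at 3.
#'
#' Buffer sizes are measured in raw line bytes plus one byte per newline
#' (packing happens later, at flush time).  The state only tracks ordinals
#' and sizes; block payloads are assembled by the container writer.
#'
#' @param threshold flush threshold in bytes (default 8 MiB), shared by
#'   both buffers.
#' @return an environment of class `buffer_state`.
#' @seealso [bs_append()], [bs_finalize()], [plan_range()], [merge_lines()]
#' @export
buffer_state <- function(threshold = 8 * 1024^2) {
  if (!is.numeric(threshold) || threshold < 1) stop("threshold must be >= 1 byte")
  e <- new.env(parent = emptyenv())
  e$threshold <- threshold
  e$size_A <- 0
  e$size_B <- 0
  e$first_A <- 0L          # ordinal of A's first pending line
  e$next_index <- 0L       # expected next record ordinal
  e$s1_before_A <- 0L      # stream-1 lines before first_A
  e$s1_seen <- 0L          # stream-1 lines seen so far
  e$firstB_ord <- NA_integer_
  e$lastB_ord <- NA_integer_
  e$nB <- 0L               # stream-1 lines pending in B
  e$s1_start_B <- 0L       # stream-1 sequence number of B's first pending line
  e$consecutive_B_flushes <- 0L
  e$blocks <- list()
  class(e) <- "buffer_state"
  e
}

make_block_meta <- function(state, stream) {
  if (stream == 0L) {
    list(stream = 0L,
         start_line = state$first_A,
         end_line = state$next_index - 1L,
         n_lines = state$next_index - state$first_A,
         s1_before = state$s1_before_A)
  } else {
    list(stream = 1L,
         start_line = state$firstB_ord,
         end_line = state$lastB_ord,
         n_lines = state$nB,
         s1_before = NA_integer_,
         s1_start = state$s1_start_B)  # not stored on disk; compression aid
  }
}

flush_A <- function(state) {
  meta <- make_block_meta(state, 0L)
  state$blocks[[length(state$blocks) + 1L]] <- meta
  state$first_A <- state$next_index
  state$size_A <- 0
  state$s1_before_A <- state$s1_seen
  state$consecutive_B_flushes <- 0L
  meta
}

flush_B <- function(state) {
  meta <- make_block_meta(state, 1L)
  state$blocks[[length(state$blocks) + 1L]] <- meta
  state$firstB_ord <- NA_integer_
  state$lastB_ord <- NA_integer_
  state$nB <- 0L
  state$size_B <- 0
  state$s1_start_B <- state$s1_seen
  meta
}

#' Append one labelled record to the buffers
#'
#' A stream-0 line adds its bytes plus a newline to buffer A; a stream-1
#' line adds one placeholder newline to buffer A and its bytes plus a
#' newline to buffer B.  Any buffer pushed over the threshold is flushed.
#' A third consecutive B flush (without an intervening A flush) forces an
#' A flush immediately.
#'
#' @param state a [buffer_state()].
#' @param line the quality line (character scalar).
#' @param index its global 0-based ordinal; records must arrive in order.
#' @param label stream label 0 or 1.
#' @param len byte length of the line (computed if missing).
#' @return list of block metadata entries flushed by this append (possibly
#'   empty), invisibly.
#' @export
bs_append <- function(state, line, index, label,
                      len = nchar(line, type = "bytes")) {
  if (index != state$next_index)
    stop("internal error: out-of-order record ", index,
         " (expected ", state$next_index, ")")
  if (label == 0L) {
    state$size_A <- state$size_A + len + 1
  } else {
    state$size_A <- state$size_A + 1
    state$size_B <- state$size_B + len + 1
    if (state$nB == 0L) {
      state$firstB_ord <- index
      state$s1_start_B <- state$s1_seen
    }
    state$lastB_ord <- index
    state$nB <- state$nB + 1L
    state$s1_seen <- state$s1_seen + 1L
  }
  state$next_index <- index + 1L
  flushed <- list()
  if (state$size_B > state$threshold) {
    flushed[[length(flushed) + 1L]] <- flush_B(state)
    state$consecutive_B_flushes <- state$consecutive_B_flushes + 1L
    if (state$consecutive_B_flushes >= 3L)
      flushed[[length(flushed) + 1L]] <- flush_A(state)
  }
  if (state$size_A > state$threshold && state$next_index > state$first_A)
    flushed[[length(flushed) + 1L]] <- flush_A(state)
  invisible(flushed)
}

#' Flush all pending buffers at end of input
#'
#' Both non-empty buffers are flushed regardless of the threshold, B
#' before A, so the block directory order is deterministic.
#'
#' @param state a [buffer_state()].
#' @return list of flushed block metadata entries, invisibly.
#' @export
bs_finalize <- function(state) {
  flushed <- list()
  if (state$nB > 0L)
    flushed[[length(flushed) + 1L]] <- flush_B(state)
  if (state$next_index > state$first_A)
    flushed[[length(flushed) + 1L]] <- flush_A(state)
  invisible(flushed)
}

blocks_to_dir <- function(blocks) {
  n <- length(blocks)
  data.frame(
    stream = vapply(blocks, `[[`, integer(1), "stream"),
    start_line = vapply(blocks, `[[`, integer(1), "start_line"),
    end_line = vapply(blocks, `[[`, integer(1), "end_line"),
    n_lines = vapply(blocks, `[[`, integer(1), "n_lines"),
    s1_before = vapply(blocks, `[[`, integer(1), "s1_before"),
    offset = numeric(n),
    comp_len = numeric(n),
    packed_len = numeric(n)
  )
}

#' Plan the blocks needed for a line-range query
#'
#' Selects every A block whose line span overlaps `[a, b]` and every B
#' block whose span of stream-1 ordinals overlaps `[a, b]`.  When the
#' range lies inside a single A block's span the plan holds at most 4
#' blocks (one A, three B); when it straddles one boundary between two
#' consecutive A blocks, at most 8 (two A, six B).
#'
#' @param directory block directory data frame (as stored in a container).
#' @param a,b requested global line range, 0-based inclusive.
#' @param total_lines total number of lines in the container.
#' @return an object of class `range_plan`: list with `a`, `b` and
#'   `blocks` (the selected directory rows, with a `row` column giving
#'   their position in the directory).
#' @export
plan_range <- function(directory, a, b, total_lines) {
  if (a < 0 || b < a || b >= total_lines)
    stop("range [", a, ", ", b, "] is out of bounds (0..", total_lines - 1, ")")
  sel <- directory$start_line <= b & directory$end_line >= a
  blocks <- directory[sel, , drop = FALSE]
  blocks$row <- which(sel)
  structure(list(a = a, b = b, blocks = blocks), class = "range_plan")
}

#' Merge decoded blocks into the requested line range
#'
#' Walks the decoded A lines in global order over `[a, b]` and fills every
#' placeholder position from the decoded B blocks, aligned by the
#' cumulative stream-1 counts (`s1_before` of the A blocks plus the
#' per-block placeholder tallies).  Placeholders are the empty entries of
#' A blocks; this is unambiguous because the classifier can only route an
#' empty line to stream 0 when `alpha == 0`, in which case stream 1 is
#' empty and no placeholders exist.
#'
#' @param plan a [plan_range()] result.
#' @param decoded list of decoded line vectors, named by directory row
#'   number, covering every block in the plan.
#' @param directory the full block directory of the container.
#' @return character vector: lines `a..b` exactly as in the original file.
#' @export
merge_lines <- function(plan, decoded, directory) {
  a <- plan$a
  b <- plan$b
  blocks <- plan$blocks
  arows <- blocks[blocks$stream == 0L, , drop = FALSE]
  arows <- arows[order(arows$start_line), , drop = FALSE]
  if (!nrow(arows) || arows$start_line[1L] > a ||
      arows$end_line[nrow(arows)] < b)
    stop_corrupt("plan does not cover the requested range with A blocks")

  # stream-1 sequence offsets of every B block, from directory order
  bsel <- directory$stream == 1L
  has_B <- any(bsel)
  b_rows_all <- which(bsel)
  s1_starts <- cumsum(c(0, directory$n_lines[bsel]))[seq_len(sum(bsel))]

  out <- character(b - a + 1L)
  for (i in seq_len(nrow(arows))) {
    key <- as.character(arows$row[i])
    lines_i <- decoded[[key]]
    if (is.null(lines_i) || length(lines_i) != arows$n_lines[i])
      stop_corrupt(paste0("decoded A block ", key, " has wrong line count"))
    start_i <- arows$start_line[i]
    mask <- has_B & !nzchar(lines_i)
    s1seq <- arows$s1_before[i] + cumsum(mask) - 1L  # 0-based, at placeholders
    lo <- max(a, start_i)
    hi <- min(b, arows$end_line[i])
    idx <- (lo - start_i + 1L):(hi - start_i + 1L)
    seg <- lines_i[idx]
    ph <- which(mask[idx])
    if (length(ph)) {
      s <- s1seq[idx][ph]
      j <- findInterval(s, s1_starts)  # B block index in stream-1 order
      for (u in seq_along(ph)) {
        brow <- b_rows_all[j[u]]
        bl <- decoded[[as.character(brow)]]
        if (is.null(bl))
          stop_corrupt(paste0("missing decoded B block for placeholder at line ",
                              lo + ph[u] - 1L))
        off <- s[u] - s1_starts[j[u]] + 1L
        if (off < 1L || off > length(bl))
          stop_corrupt("stream-1 alignment outside decoded B block")
        seg[ph[u]] <- bl[off]
      }
    }
    out[(lo - a + 1L):(hi - a + 1L)] <- seg
  }
  out
}
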