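# Single-file container layout (all integers little-endian):
#
#   header (48 bytes, fixed width)
#     0-3   magic "QSAR"        16    C (modal value)
#     4     format version      17    coder table_bits
#     5     backend id          18    coder adapt_shift
#     6-7   k            (u16)  19    coder clamp_bits
#     8-11  alpha *10^4  (u32)  20-23 coder mixer lambda *10^6 (u32)
#     12-15 M sample lines(u32) 24-31 buffer threshold T (u64)
#                               32-39 total_lines (u64)
#                               40-47 original byte size (u64)
#   block payloads, in flush order
#   directory: varint n_blocks, then per block
#     u8 stream; varint start_line, end_line, n_lines;
#     varint s1_before (A blocks only); varint offset, comp_len, packed_len
#   footer (12 bytes): u64 directory offset + magic echo
#
# The directory is the whole light-weight index: no sidecar file exists,
# and a reader can seek to the footer, jump to the directory, and plan any
# line-range query without touching the payloads.

QS_MAGIC <- as.raw(c(0x51, 0x53, 0x41, 0x52))  # "QSAR"
QS_VERSION <- 1L
QS_HEADER_SIZE <- 48L
QS_FOOTER_SIZE <- 12L

CODER_CONSTANTS <- list(table_bits = 16L, adapt_shift = 5L,
                        clamp_bits = 12L, lambda_ppm = 2000L)

make_header <- function(backend_id, k, alpha, sample_lines, C, threshold,
                        total_lines, orig_bytes) {
  c(QS_MAGIC,
    w_uint(QS_VERSION, 1L),
    w_uint(backend_id, 1L),
    w_uint(k, 2L),
    w_uint(round(alpha * 10000), 4L),
    w_uint(sample_lines, 4L),
    w_uint(C, 1L),
    w_uint(CODER_CONSTANTS$table_bits, 1L),
    w_uint(CODER_CONSTANTS$adapt_shift, 1L),
    w_uint(CODER_CONSTANTS$clamp_bits, 1L),
    w_uint(CODER_CONSTANTS$lambda_ppm, 4L),
    w_uint(threshold, 8L),
    w_uint(total_lines, 8L),
    w_uint(orig_bytes, 8L))
}

parse_header <- function(data) {
  if (length(data) < QS_HEADER_SIZE)
    stop_corrupt("container too small to hold a header")
  if (!identical(data[1:4], QS_MAGIC))
    stop_corrupt("bad magic: not a qsarc container")
  version <- r_uint(data, 4, 1L)
  if (version != QS_VERSION)
    stop_corrupt(paste0("unsupported container version ", version))
  list(version = version,
       backend_id = r_uint(data, 5, 1L),
       k = r_uint(data, 6, 2L),
       alpha = r_uint(data, 8, 4L) / 10000,
       sample_lines = r_uint(data, 12, 4L),
       C = r_uint(data, 16, 1L),
       table_bits = r_uint(data, 17, 1L),
       adapt_shift = r_uint(data, 18, 1L),
       clamp_bits = r_uint(data, 19, 1L),
       lambda_ppm = r_uint(data, 20, 4L),
       threshold = r_uint(data, 24, 8L),
       total_lines = r_uint(data, 32, 8L),
       orig_bytes = r_uint(data, 40, 8L))
}

encode_directory <- function(dir) {
  parts <- list(varint_encode(nrow(dir)))
  for (i in seq_len(nrow(dir))) {
    entry <- c(w_uint(dir$stream[i], 1L),
               varint_encode(dir$start_line[i]),
               varint_encode(dir$end_line[i]),
               varint_encode(dir$n_lines[i]))
    if (dir$stream[i] == 0L)
      entry <- c(entry, varint_encode(dir$s1_before[i]))
    entry <- c(entry,
               varint_encode(dir$offset[i]),
               varint_encode(dir$comp_len[i]),
               varint_encode(dir$packed_len[i]))
    parts[[length(parts) + 1L]] <- entry
  }
  do.call(c, parts)
}

decode_directory <- function(data, pos) {
  v <- varint_decode(data, pos)
  n <- v$value
  pos <- v$pos
  dir <- data.frame(stream = integer(n), start_line = integer(n),
                    end_line = integer(n), n_lines = integer(n),
                    s1_before = integer(n), offset = numeric(n),
                    comp_len = numeric(n), packed_len = numeric(n))
  rd <- function() {
    v <<- varint_decode(data, pos)
    pos <<- v$pos
    v$value
  }
  for (i in seq_len(n)) {
    if (pos > length(data)) stop_corrupt("truncated directory")
    dir$stream[i] <- as.integer(data[pos])
    pos <- pos + 1L
    dir$start_line[i] <- rd()
    dir$end_line[i] <- rd()
    dir$n_lines[i] <- rd()
    dir$s1_before[i] <- if (dir$stream[i] == 0L) rd() else NA_integer_
    dir$offset[i] <- rd()
    dir$comp_len[i] <- rd()
    dir$packed_len[i] <- rd()
  }
  dir
}

# compression core over an in-memory line vector
compress_lines <- function(lines, output, k = 4L, alpha = 0.1,
                           sample_lines = 100000L, block_size = 8 * 1024^2,
                           backend = "cm1") {
  params <- partition_params(k = k, sample_lines = sample_lines, alpha = alpha)
  be <- get_backend(backend)
  n <- length(lines)
  lens <- if (n) nchar(lines, type = "bytes") else integer(0)
  orig_bytes <- sum(lens) + n  # LF-terminated original

  if (n > 0L) {
    sample <- lines[seq_len(min(params$sample_lines, n))]
    model <- build_kmer_weights(sample, params)
    # a sample of only empty lines has no bytes; any valid C works because
    # packing an empty line is the bare terminator
    C <- tryCatch(compute_mode(sample), error = function(e) 33L)
    labels <- classify_line(lines, model, params)
    if (any(labels == 1L) && any(labels == 0L & lens == 0L))
      stop("empty stream-0 lines cannot coexist with stream-1 lines ",
           "(placeholder ambiguity); this cannot happen with classify_line labels")
    state <- buffer_state(block_size)
    for (i in seq_len(n))
      bs_append(state, lines[i], i - 1L, labels[i], len = lens[i])
    bs_finalize(state)
    blocks <- state$blocks
  } else {
    C <- 33L
    labels <- integer(0)
    blocks <- list()
  }

  dir <- blocks_to_dir(blocks)
  s1_ords <- which(labels == 1L) - 1L
  payloads <- vector("list", length(blocks))
  offset <- QS_HEADER_SIZE
  for (i in seq_along(blocks)) {
    meta <- blocks[[i]]
    if (meta$stream == 0L) {
      span <- (meta$start_line:meta$end_line) + 1L
      content <- lines[span]
      content[labels[span] == 1L] <- ""
    } else {
      content <- lines[s1_ords[meta$s1_start + seq_len(meta$n_lines)] + 1L]
    }
    packed <- cpp_pack_lines(content, C)
    payload <- be$encode(packed)
    payloads[[i]] <- payload
    dir$packed_len[i] <- length(packed)
    dir$comp_len[i] <- length(payload)
    dir$offset[i] <- offset
    offset <- offset + length(payload)
  }

  check_structure_bound(dir)

  header <- make_header(be$id, params$k, params$alpha, params$sample_lines,
                        C, block_size, n, orig_bytes)
  dir_raw <- encode_directory(dir)
  footer <- c(w_uint(offset, 8L), QS_MAGIC)
  ok <- FALSE
  tryCatch({
    con <- file(output, open = "wb")
    writeBin(do.call(c, c(list(header), payloads, list(dir_raw, footer))), con)
    close(con)
    ok <- TRUE
  }, finally = if (!ok && file.exists(output)) unlink(output))

  structure(list(lines = n, blocks = nrow(dir),
                 a_blocks = sum(dir$stream == 0L),
                 b_blocks = sum(dir$stream == 1L),
                 bytes_in = orig_bytes, bytes_out = file.size(output),
                 C = C, backend = backend, output = output),
            class = "qsarc_summary")
}

# every A block must overlap at most 3 B blocks (forced-flush consequence);
# cheap, asserted on every compression run
check_structure_bound <- function(dir) {
  arows <- dir[dir$stream == 0L, , drop = FALSE]
  brows <- dir[dir$stream == 1L, , drop = FALSE]
  for (i in seq_len(nrow(arows))) {
    nov <- sum(brows$start_line <= arows$end_line[i] &
               brows$end_line >= arows$start_line[i])
    if (nov > 3L)
      stop("internal error: A block overlaps ", nov, " B blocks (bound is 3)")
  }
  invisible(TRUE)
}

#' Compress a quality-score file into a qsarc container
#'
#' Runs the full pipeline: sample the file head, estimate k-mer weights and
#' the modal value, classify every line into stream 0/1, buffer the streams
#' into blocks, pack each block, entropy-code it with the chosen backend,
#' and write a single self-indexed container.  Output bytes are a
#' deterministic function of the input and the configuration.
#'
#' @param input path to the input file.
#' @param output path of the container to write (partial output is removed
#'   on failure).
#' @param mode `"plain"` or `"fastq"`, see [read_quality_lines()].
#' @param k,alpha,sample_lines partition parameters, see
#'   [partition_params()].
#' @param block_size buffer flush threshold in bytes (default 8 MiB).
#' @param backend block compression backend, `"cm1"` or `"store"`.
#' @param validate,strip_cr input handling, see [read_quality_lines()].
#' @return a summary object (lines, blocks, byte counts), invisibly.
#' @examples
#' f <- tempfile(); out <- tempfile(fileext = ".qsarc")
#' generate_synthetic(synthetic_spec(200, seed = 7), f)
#' compress_file(f, out, backend = "store")
#' back <- tempfile()
#' decompress_file(out, back)
#' identical(readBin(f, raw(), file.size(f)), readBin(back, raw(), file.size(back)))
#' @export
compress_file <- function(input, output, mode = c("plain", "fastq"),
                          k = 4L, alpha = 0.1, sample_lines = 100000L,
                          block_size = 8 * 1024^2, backend = "cm1",
                          validate = TRUE, strip_cr = FALSE) {
  mode <- match.arg(mode)
  lines <- read_quality_lines(input, mode, validate = validate,
                              strip_cr = strip_cr)
  invisible(compress_lines(lines, output, k = k, alpha = alpha,
                           sample_lines = sample_lines,
                           block_size = block_size, backend = backend))
}

#' Open a qsarc container
#'
#' Reads and checks the header, footer and block directory.  The returned
#' handle is used by [range_decompress()] and friends; payloads are decoded
#' lazily per block.
#'
#' @param path container path.
#' @return an object of class `qsarc_container`.
#' @export
container_open <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sz <- file.size(path)
  if (sz < QS_HEADER_SIZE + QS_FOOTER_SIZE)
    stop_corrupt("container too small (truncated?)")
  data <- readBin(path, what = "raw", n = sz)
  header <- parse_header(data)
  if (!identical(data[(sz - 3):sz], QS_MAGIC))
    stop_corrupt("bad footer magic (truncated container?)")
  dir_offset <- r_uint(data, sz - QS_FOOTER_SIZE, 8L)
  if (dir_offset < QS_HEADER_SIZE || dir_offset > sz - QS_FOOTER_SIZE)
    stop_corrupt("directory offset out of bounds")
  dir <- decode_directory(data, dir_offset + 1L)
  if (nrow(dir)) {
    if (any(dir$offset + dir$comp_len > sz - QS_FOOTER_SIZE))
      stop_corrupt("block payload extends past the directory")
    aspan <- dir[dir$stream == 0L, , drop = FALSE]
    if (sum(aspan$n_lines) != header$total_lines)
      stop_corrupt("A blocks do not cover the stated line count")
  } else if (header$total_lines != 0) {
    stop_corrupt("container claims lines but has no blocks")
  }
  structure(list(path = path, header = header, dir = dir, data = data,
                 backend = backend_by_id(header$backend_id)),
            class = "qsarc_container")
}

decode_block <- function(cont, row, cache = NULL) {
  key <- as.character(row)
  if (!is.null(cache)) {
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  meta <- cont$dir[row, ]
  payload <- cont$data[meta$offset + seq_len(meta$comp_len)]
  packed <- cont$backend$decode(payload, meta$packed_len)
  lines <- tryCatch(cpp_unpack_lines(packed, cont$header$C),
                    error = function(e) stop_corrupt(conditionMessage(e)))
  if (length(lines) != meta$n_lines)
    stop_corrupt(sprintf("block %d decoded to %d lines, directory says %d",
                         row, length(lines), meta$n_lines))
  if (!is.null(cache)) cache[[key]] <- lines
  lines
}

# restore lines a..b (0-based inclusive); cache is an optional environment
range_lines <- function(cont, a, b, cache = NULL) {
  plan <- plan_range(cont$dir, a, b, cont$header$total_lines)
  decoded <- list()
  for (row in plan$blocks$row)
    decoded[[as.character(row)]] <- decode_block(cont, row, cache)
  merge_lines(plan, decoded, cont$dir)
}

#' Decompress a whole container back to a quality-score file
#'
#' The output is byte-identical to the originally compressed input.
#'
#' @param container container path or an open [container_open()] handle.
#' @param output path of the plain quality file to write.
#' @return `output`, invisibly.
#' @export
decompress_file <- function(container, output) {
  cont <- if (inherits(container, "qsarc_container")) container
          else container_open(container)
  n <- cont$header$total_lines
  lines <- if (n == 0) character(0)
           else range_lines(cont, 0L, n - 1L, cache = new.env(parent = emptyenv()))
  write_quality_lines(lines, output)
  invisible(output)
}

#' Randomly access a line range of a container
#'
#' Restores lines `a..b` (1-based inclusive, as on the command line) by
#' decoding only the blocks selected by [plan_range()] — at most one A and
#' three B blocks when the range sits inside one A block span, at most two
#' A and six B when it straddles one A block boundary.
#'
#' @inheritParams decompress_file
#' @param a,b 1-based inclusive line range.
#' @param output optional file to write the lines to.
#' @return the lines, invisibly when `output` is given.
#' @export
range_decompress <- function(container, a, b, output = NULL) {
  cont <- if (inherits(container, "qsarc_container")) container
          else container_open(container)
  total <- cont$header$total_lines
  if (!is.numeric(a) || !is.numeric(b) || a < 1 || b < a || b > total)
    stop("line range [", a, ", ", b, "] is out of bounds; container has ",
         total, " lines (1-based inclusive)")
  lines <- range_lines(cont, a - 1, b - 1)
  if (!is.null(output)) {
    write_quality_lines(lines, output)
    return(invisible(lines))
  }
  lines
}

#' Summarise a container
#'
#' Reports the stored parameters, per-block spans and sizes, and the index
#' overhead: every byte that is neither fixed header nor compressed payload
#' (i.e. the embedded directory plus footer), also as a percentage of the
#' original uncompressed size.  There is no sidecar index file, so this is
#' the entire random-access cost on disk.
#'
#' @inheritParams decompress_file
#' @return an object of class `qsarc_info` (a list; see details), printed
#'   in a human-readable form.
#' @export
container_info <- function(container) {
  cont <- if (inherits(container, "qsarc_container")) container
          else container_open(container)
  h <- cont$header
  file_size <- length(cont$data)
  payload_bytes <- sum(cont$dir$comp_len)
  overhead <- file_size - payload_bytes - QS_HEADER_SIZE
  structure(list(
    path = cont$path,
    version = h$version,
    backend = cont$backend$name,
    k = h$k, alpha = h$alpha, sample_lines = h$sample_lines,
    C = h$C, threshold = h$threshold,
    total_lines = h$total_lines,
    orig_bytes = h$orig_bytes,
    file_size = file_size,
    payload_bytes = payload_bytes,
    header_bytes = QS_HEADER_SIZE,
    index_overhead_bytes = overhead,
    index_overhead_pct = if (h$orig_bytes > 0) 100 * overhead / h$orig_bytes else 0,
    compression_ratio = if (file_size > 0) h$orig_bytes / file_size else NA_real_,
    n_blocks = nrow(cont$dir),
    blocks = cont$dir
  ), class = "qsarc_info")
}

#' @export
print.qsarc_summary <- function(x, ...) {
  cat(sprintf("qsarc: %d lines -> %d blocks (%d A, %d B), %s -> %s bytes (backend %s, C = %d)\n",
              x$lines, x$blocks, x$a_blocks, x$b_blocks,
              format(x$bytes_in, big.mark = ","),
              format(x$bytes_out, big.mark = ","), x$backend, x$C))
  invisible(x)
}

#' @export
print.qsarc_info <- function(x, ...) {
  cat("qsarc container:", x$path, "\n")
  cat(sprintf("  version %d, backend %s, k = %d, alpha = %g, M = %d, C = %d, T = %s\n",
              x$version, x$backend, x$k, x$alpha, x$sample_lines, x$C,
              format(x$threshold, big.mark = ",")))
  cat(sprintf("  %s lines, %s original bytes -> %s compressed (ratio %.4f)\n",
              format(x$total_lines, big.mark = ","),
              format(x$orig_bytes, big.mark = ","),
              format(x$file_size, big.mark = ","),
              x$compression_ratio))
  cat(sprintf("  %d blocks; index overhead %d bytes (%.4f%% of original), no sidecar file\n",
              x$n_blocks, x$index_overhead_bytes, x$index_overhead_pct))
  invisible(x)
}
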