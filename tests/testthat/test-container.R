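test_that("empty input yields a valid empty container", {
  f <- tempfile(); out <- tempfile(); back <- tempfile()
  write_quality_lines(character(0), f)
  compress_file(f, out)
  cont <- container_open(out)
  expect_identical(cont$header$total_lines, 0)
  expect_identical(nrow(cont$dir), 0L)
  decompress_file(out, back)
  expect_identical(file.size(back), 0)
  unlink(c(f, out, back))
})

test_that("compression is deterministic to the byte", {
  lines <- generate_synthetic(synthetic_spec(200, lengths = c(2, 40), seed = 7))
  o1 <- tmp_container(lines, block_size = 2048)
  o2 <- tmp_container(lines, block_size = 2048)
  expect_identical(file_bytes(o1), file_bytes(o2))
  unlink(c(o1, o2))
})

test_that("round trips are lossless across shapes and backends", {
  set.seed(61)
  # variable long-read-like lengths
  long <- random_lines(80, min_len = 1, max_len = 500)
  expect_roundtrip(long, backend = "cm1", block_size = 4096)
  # all 72 alphabet values, plus empty lines
  allvals <- c("", intToUtf8(33:104), "", strrep(intToUtf8(c(104, 33)), 50))
  expect_roundtrip(allvals, backend = "store")
  # file of only empty lines (no sample bytes at all)
  expect_roundtrip(rep("", 25), backend = "cm1")
  # single line
  expect_roundtrip("IIII", backend = "cm1")
  # alpha = 0 sends everything to stream 0, including empty lines
  expect_roundtrip(c("", "JJJJ", ""), alpha = 0, backend = "store")
})

test_that("store and cm1 containers decompress identically", {
  lines <- generate_synthetic(synthetic_spec(400, lengths = c(10, 120), seed = 13))
  f1 <- tempfile(); f2 <- tempfile()
  o1 <- tmp_container(lines, backend = "store", block_size = 8192)
  o2 <- tmp_container(lines, backend = "cm1", block_size = 8192)
  decompress_file(o1, f1)
  decompress_file(o2, f2)
  expect_identical(file_bytes(f1), file_bytes(f2))
  expect_lt(file.size(o2), file.size(o1))  # cm1 actually compresses
  unlink(c(f1, f2, o1, o2))
})

test_that("range access equals the naive scan, exhaustively on 120 lines", {
  lines <- generate_synthetic(synthetic_spec(120, lengths = c(3, 60), seed = 42,
                                             sources = binned_sources()))
  out <- tmp_container(lines, block_size = 512, backend = "store")
  cont <- container_open(out)
  expect_gt(sum(cont$dir$stream == 0L), 2L)
  expect_gt(sum(cont$dir$stream == 1L), 0L)  # both streams populated
  cache <- new.env(parent = emptyenv())
  bad <- character(0)
  for (a in 1:120) for (b in a:120) {
    got <- qsarc:::range_lines(cont, a - 1L, b - 1L, cache)
    if (!identical(got, lines[a:b])) bad <- c(bad, sprintf("[%d,%d]", a, b))
  }
  expect_identical(bad, character(0))
  expect_error(range_decompress(out, 0, 5), "out of bounds")
  expect_error(range_decompress(out, 5, 121), "out of bounds")
  expect_identical(range_decompress(out, 1, 1), lines[1])
  expect_identical(range_decompress(out, 120, 120), lines[120])
  unlink(out)
})

test_that("block-touch counts respect the printed bounds", {
  lines <- generate_synthetic(synthetic_spec(150, lengths = c(5, 80), seed = 3,
                                             sources = binned_sources()))
  out <- tmp_container(lines, block_size = 1024, backend = "store")
  cont <- container_open(out)
  dir <- cont$dir
  worst1 <- 0L
  worst2 <- 0L
  for (a in 0:149) for (b in a:149) {
    plan <- plan_range(dir, a, b, 150)
    na <- sum(plan$blocks$stream == 0L)
    nb <- nrow(plan$blocks)
    if (na == 1L) worst1 <- max(worst1, nb)
    if (na == 2L) worst2 <- max(worst2, nb)
  }
  expect_lte(worst1, 4L)
  expect_lte(worst2, 8L)
  unlink(out)
})

test_that("full decompression equals concatenated per-A-span merges", {
  lines <- generate_synthetic(synthetic_spec(90, lengths = c(2, 50), seed = 17,
                                             sources = binned_sources()))
  out <- tmp_container(lines, block_size = 700, backend = "store")
  cont <- container_open(out)
  aspans <- cont$dir[cont$dir$stream == 0L, ]
  cache <- new.env(parent = emptyenv())
  pieces <- lapply(seq_len(nrow(aspans)), function(i)
    qsarc:::range_lines(cont, aspans$start_line[i], aspans$end_line[i], cache))
  expect_identical(unlist(pieces), lines)
  unlink(out)
})

test_that("corruption is detected, never silently wrong at block scale", {
  lines <- generate_synthetic(synthetic_spec(60, lengths = 40, seed = 9))
  out <- tmp_container(lines, block_size = 512, backend = "cm1")
  data <- file_bytes(out)

  flip <- function(bytes, i) { bytes[i] <- xor(bytes[i], as.raw(1)); bytes }
  bad <- tempfile()

  writeBin(flip(data, 2), bad)  # magic
  expect_error(container_open(bad), class = "qsarc_corruption_error")

  writeBin(data[1:(length(data) - 4)], bad)  # truncated footer
  expect_error(container_open(bad), class = "qsarc_corruption_error")

  # flip one payload bit: either an error or a detectable mismatch
  cont <- container_open(out)
  mid <- floor(cont$dir$offset[1]) + 5L
  writeBin(flip(data, mid), bad)
  res <- tryCatch(read_quality_lines({
    tmp <- tempfile(); decompress_file(bad, tmp); tmp
  }, validate = FALSE), error = function(e) e)
  expect_true(inherits(res, "error") || !identical(res, lines))
  unlink(c(out, bad))
})

test_that("info reports the directory+footer as the only index overhead", {
  lines <- generate_synthetic(synthetic_spec(500, lengths = 80, seed = 19))
  out <- tmp_container(lines, block_size = 4096, backend = "store")
  info <- container_info(out)
  dir_raw <- qsarc:::encode_directory(container_open(out)$dir)
  expect_equal(info$index_overhead_bytes,
               length(dir_raw) + qsarc:::QS_FOOTER_SIZE)
  expect_equal(info$file_size,
               info$payload_bytes + info$header_bytes +
                 info$index_overhead_bytes)
  # store backend: payloads are exactly the packed blocks
  expect_equal(info$payload_bytes, sum(info$blocks$packed_len))
  expect_equal(info$total_lines, 500)
  unlink(out)
})

test_that("blocks can be encoded in any order (parallel contract)", {
  lines <- generate_synthetic(synthetic_spec(300, lengths = 60, seed = 23))
  out <- tmp_container(lines, block_size = 2048, backend = "cm1")
  cont <- container_open(out)
  # re-encode every payload independently, in reverse order, and compare
  for (r in rev(seq_len(nrow(cont$dir)))) {
    meta <- cont$dir[r, ]
    payload <- cont$data[meta$offset + seq_len(meta$comp_len)]
    packed <- cm_decode(payload, meta$packed_len)
    expect_identical(cm_encode(packed), payload)
  }
  unlink(out)
})

test_that("fastq input compresses to the same container as its quality lines", {
  qual <- generate_synthetic(synthetic_spec(40, lengths = 30, seed = 29))
  fq <- tempfile(); pl <- tempfile(); o1 <- tempfile(); o2 <- tempfile()
  writeLines(rbind("@r", strrep("A", 30), "+", matrix(qual, nrow = 1)), fq)
  write_quality_lines(qual, pl)
  compress_file(fq, o1, mode = "fastq", backend = "store")
  compress_file(pl, o2, backend = "store")
  expect_identical(file_bytes(o1), file_bytes(o2))
  unlink(c(fq, pl, o1, o2))
})
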