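# drive a buffer_state over labelled lines and return the flushed blocks
run_buffers <- function(lines, labels, threshold) {
  st <- buffer_state(threshold)
  for (i in seq_along(lines))
    bs_append(st, lines[i], i - 1L, labels[i])
  bs_finalize(st)
  st$blocks
}

test_that("size-triggered A flush follows the byte arithmetic", {
  st <- buffer_state(8)
  expect_length(bs_append(st, "AAAA", 0L, 0L), 0)          # 5 bytes, no flush
  ev <- bs_append(st, "BBBB", 1L, 0L)                      # 10 > 8 -> flush
  expect_length(ev, 1)
  expect_identical(ev[[1]]$stream, 0L)
  expect_identical(ev[[1]]$start_line, 0L)
  expect_identical(ev[[1]]$end_line, 1L)
  expect_identical(ev[[1]]$s1_before, 0L)
})

test_that("stream-1 lines grow buffer A by exactly one placeholder byte", {
  st <- buffer_state(1000)
  bs_append(st, "QQQQ", 0L, 1L)
  expect_identical(st$size_A, 1)
  expect_identical(st$size_B, 5)
})

test_that("the third consecutive B flush forces an A flush", {
  # every line is stream 1, 4 bytes: B flushes after every 2nd line (9 > 8)
  lines <- rep(strrep("Q", 4), 12)
  blocks <- run_buffers(lines, rep(1L, 12), 8)
  streams <- vapply(blocks, `[[`, integer(1), "stream")
  # B,B,B then forced A, repeating; finalize closes the open A
  expect_identical(streams[1:4], c(1L, 1L, 1L, 0L))
  expect_identical(blocks[[4]]$start_line, 0L)
  expect_identical(blocks[[4]]$end_line, 5L)  # flushed at the 6th line
  expect_identical(blocks[[4]]$s1_before, 0L)
  # next A block starts where the forced one ended and counts the 6 lines
  a2 <- blocks[streams == 0L][[2]]
  expect_identical(a2$start_line, 6L)
  expect_identical(a2$s1_before, 6L)
})

test_that("finalize flushes B before A and covers everything", {
  blocks <- run_buffers(c("AAAA", "QQQQ"), c(0L, 1L), 10000)
  streams <- vapply(blocks, `[[`, integer(1), "stream")
  expect_identical(streams, c(1L, 0L))
  expect_identical(blocks[[1]]$start_line, 1L)  # B holds the ordinal-1 line
  expect_identical(blocks[[1]]$end_line, 1L)
  expect_identical(blocks[[2]]$start_line, 0L)
  expect_identical(blocks[[2]]$end_line, 1L)

  expect_length(run_buffers(character(0), integer(0), 100), 0)

  one <- run_buffers("AAAA", 0L, 1e6)
  expect_length(one, 1)
  expect_identical(one[[1]]$stream, 0L)
})

test_that("A blocks partition the ordinals; B metadata counts stream-1 lines", {
  set.seed(33)
  for (trial in 1:6) {
    n <- sample(30:120, 1)
    lines <- random_lines(n, min_len = 0, max_len = 20)
    labels <- sample(0:1, n, replace = TRUE)
    if (any(labels == 0L & nchar(lines) == 0L)) # avoid placeholder ambiguity
      lines[labels == 0L & nchar(lines) == 0L] <- "K"
    blocks <- run_buffers(lines, labels, sample(c(16, 64, 256), 1))
    streams <- vapply(blocks, `[[`, integer(1), "stream")
    ab <- blocks[streams == 0L]
    starts <- vapply(ab, `[[`, integer(1), "start_line")
    ends <- vapply(ab, `[[`, integer(1), "end_line")
    expect_identical(starts[1], 0L)
    expect_identical(ends[length(ends)], n - 1L)
    if (length(ab) > 1)
      expect_identical(starts[-1], ends[-length(ends)] + 1L)
    expect_identical(sum(ends - starts + 1L), n)
    # s1_before equals the counting oracle
    for (blk in ab)
      expect_identical(blk$s1_before,
                       sum(labels[seq_len(blk$start_line)] == 1L))
    # B blocks carry the ordinals of their first/last stream-1 lines
    s1_ords <- which(labels == 1L) - 1L
    taken <- 0L
    for (blk in blocks[streams == 1L]) {
      span <- s1_ords[taken + seq_len(blk$n_lines)]
      expect_identical(blk$start_line, span[1])
      expect_identical(blk$end_line, span[length(span)])
      taken <- taken + blk$n_lines
    }
    expect_identical(taken, sum(labels == 1L))
    # structure bound: no A block overlaps more than 3 B blocks
    for (blk in ab) {
      nov <- sum(vapply(blocks[streams == 1L], function(bb)
        bb$start_line <= blk$end_line && bb$end_line >= blk$start_line,
        logical(1)))
      expect_lte(nov, 3L)
    }
  }
})

test_that("s1_before and B spans on a hand-checked 12-line fixture", {
  # ordinals 3, 5, 6, 9 are stream 1 (10-byte lines); stream 0 lines are
  # 4 bytes; threshold 30
  labels <- rep(0L, 12)
  labels[c(3, 5, 6, 9) + 1] <- 1L
  lines <- ifelse(labels == 1L, strrep("Q", 10), "PPPP")
  st <- buffer_state(30)
  flushed <- list()
  for (i in 1:12)
    flushed <- c(flushed, bs_append(st, lines[i], i - 1L, labels[i]))
  # B reaches 33 > 30 bytes at ordinal 6: B block holding {3,5,6} spans 3..6
  b1 <- flushed[[1]]
  expect_identical(b1$stream, 1L)
  expect_identical(b1$start_line, 3L)
  expect_identical(b1$end_line, 6L)
  expect_identical(b1$n_lines, 3L)
  # A reaches 33 > 30 bytes at ordinal 8: first A block 0..8, s1_before 0
  a1 <- flushed[[2]]
  expect_identical(a1$stream, 0L)
  expect_identical(a1$start_line, 0L)
  expect_identical(a1$end_line, 8L)
  expect_identical(a1$s1_before, 0L)
  # finalize: B block {9}, then A block 9..11 with 3 stream-1 lines before it
  rest <- bs_finalize(st)
  expect_identical(vapply(rest, `[[`, integer(1), "stream"), c(1L, 0L))
  a2 <- rest[[2]]
  expect_identical(a2$start_line, 9L)
  expect_identical(a2$s1_before, 3L)
  expect_identical(a2$s1_before, sum(labels[seq_len(a2$start_line)] == 1L))
})

test_that("plan_range + merge_lines equal the naive scan, exhaustively", {
  set.seed(55)
  n <- 30
  lines <- random_lines(n, min_len = 1, max_len = 12)
  p <- partition_params(sample_lines = n, alpha = 0.1)
  m <- build_kmer_weights(lines, p)
  labels <- classify_line(lines, m, p)
  st <- buffer_state(48)
  for (i in seq_len(n)) bs_append(st, lines[i], i - 1L, labels[i])
  bs_finalize(st)
  dir <- qsarc:::blocks_to_dir(st$blocks)

  # decoded content straight from the truth (blockstore-level test)
  s1_ords <- which(labels == 1L) - 1L
  decoded <- list()
  taken <- 0L
  for (r in seq_len(nrow(dir))) {
    if (dir$stream[r] == 0L) {
      span <- (dir$start_line[r]:dir$end_line[r]) + 1L
      content <- lines[span]
      content[labels[span] == 1L] <- ""
    } else {
      content <- lines[s1_ords[taken + seq_len(dir$n_lines[r])] + 1L]
      taken <- taken + dir$n_lines[r]
    }
    decoded[[as.character(r)]] <- content
  }

  n_a_blocks <- sum(dir$stream == 0L)
  expect_gt(n_a_blocks, 2L)  # the fixture must actually be multi-block
  for (a in 0:(n - 1)) for (b in a:(n - 1)) {
    plan <- plan_range(dir, a, b, n)
    got <- merge_lines(plan, decoded, dir)
    expect_identical(got, lines[(a:b) + 1L],
                     info = sprintf("range [%d,%d]", a, b))
    # block-touch bounds from the directory structure
    pa <- plan$blocks[plan$blocks$stream == 0L, ]
    if (nrow(pa) == 1L) expect_lte(nrow(plan$blocks), 4L)
    if (nrow(pa) == 2L) expect_lte(nrow(plan$blocks), 8L)
  }
  expect_error(plan_range(dir, -1, 0, n), "out of bounds")
  expect_error(plan_range(dir, 0, n, n), "out of bounds")
})
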