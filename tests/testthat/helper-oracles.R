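# Independent brute-force oracles and fixture builders used across tests.

# Brute-force reimplementation of the two-way partition: nested loops and
# substr(), no shared code with the package's k-mer machinery.
oracle_partition <- function(lines, k, M, alpha) {
  sample <- lines[seq_len(min(M, length(lines)))]
  cnt <- new.env(parent = emptyenv())
  total <- 0
  for (ln in sample) {
    L <- nchar(ln)
    if (L >= k) for (i in 1:(L - k + 1)) {
      km <- substr(ln, i, i + k - 1)
      prev <- if (is.null(cnt[[km]])) 0 else cnt[[km]]
      cnt[[km]] <- prev + 1
      total <- total + 1
    }
  }
  lw <- function(ln) {
    L <- nchar(ln)
    nk <- L - k + 1
    if (nk <= 0 || total == 0) return(0)
    s <- 0
    for (i in 1:nk) {
      km <- substr(ln, i, i + k - 1)
      if (!is.null(cnt[[km]])) s <- s + cnt[[km]] / total
    }
    s / nk
  }
  wmax <- 0
  for (ln in sample) wmax <- max(wmax, lw(ln))
  vapply(lines, function(ln) {
    wn <- if (wmax > 0) lw(ln) / wmax else 0
    if (wn >= alpha) 0L else 1L
  }, integer(1), USE.NAMES = FALSE)
}

# Greedy packer driven purely by the R-built table's encode map; independent
# of the C++ group-geometry arithmetic.
oracle_pack <- function(line, table) {
  C <- table$C
  v <- if (nchar(line)) utf8ToInt(line) else integer(0)
  n <- length(v)
  enc <- table$encode
  out <- integer(0)
  i <- 1L
  while (i <= n) {
    if (v[i] == C) {
      r <- 1L
      while (r < 15L && i + r <= n && v[i + r] == C) r <- r + 1L
      if (r >= 4L) {
        out <- c(out, enc[[paste(rep(C, r), collapse = ",")]])
        i <- i + r
        next
      }
    }
    if (i + 2L <= n) {
      cd <- enc[paste(v[i:(i + 2L)], collapse = ",")]
      if (!is.na(cd) && length(table$decode[[cd]]) == 3L) {
        out <- c(out, unname(cd))
        i <- i + 3L
        next
      }
    }
    if (i + 1L <= n) {
      cd <- enc[paste(v[i:(i + 1L)], collapse = ",")]
      if (!is.na(cd) && length(table$decode[[cd]]) == 2L) {
        out <- c(out, unname(cd))
        i <- i + 2L
        next
      }
    }
    out <- c(out, enc[[as.character(v[i])]])
    i <- i + 1L
  }
  c(out, 0L)
}

# A mixture world that separates into two clusters at desk-scale sample
# sizes: a binned major source (four discrete quality values, as modern
# Illumina instruments emit) whose k-mers repeat heavily even in a
# 200-line sample, and a 20% uniform minor source whose k-mers are
# near-singletons and weigh ~0.  Used wherever a test needs both streams
# populated.
binned_sources <- function() {
  pb <- rep(0, 72)
  pb[c(37, 59, 70, 72) - 32] <- c(0.05, 0.15, 0.6, 0.2)
  list(list(weight = 0.8, probs = pb),
       list(weight = 0.2, probs = rep(1 / 72, 72)))
}

# Random valid quality lines, uniform over the alphabet by default.
random_lines <- function(n, min_len = 0, max_len = 100, values = 33:104,
                         prob = NULL) {
  lens <- sample(min_len:max_len, n, replace = TRUE)
  vals <- sample(values, sum(lens), replace = TRUE, prob = prob)
  qsarc:::cpp_bytes_to_lines(as.integer(vals), as.integer(lens))
}

file_bytes <- function(path) readBin(path, raw(), file.size(path))

# Compress lines to a temp container and return its path.
tmp_container <- function(lines, ...) {
  out <- tempfile(fileext = ".qsarc")
  qsarc:::compress_lines(lines, out, ...)
  out
}

expect_roundtrip <- function(lines, ...) {
  f <- tempfile()
  back <- tempfile()
  write_quality_lines(lines, f)
  # degenerate fixtures (e.g. all lines shorter than k) warn on purpose
  out <- suppressWarnings(tmp_container(lines, ...))
  decompress_file(out, back)
  expect_identical(file_bytes(back), file_bytes(f))
  unlink(c(f, back, out))
}
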