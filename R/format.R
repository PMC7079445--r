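# Little-endian fixed-width integer packing and base-128 varints.
# All values are handled as doubles (exact below 2^53), since R has no
# native 64-bit integer type.

w_uint <- function(x, nbytes) {
  if (x < 0 || x != floor(x)) stop("cannot encode ", x, " as unsigned")
  out <- raw(nbytes)
  for (i in seq_len(nbytes)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  if (x != 0) stop("value too large for ", nbytes, "-byte field")
  out
}

r_uint <- function(data, offset, nbytes) {
  # offset is 0-based
  v <- 0
  for (i in rev(seq_len(nbytes)))
    v <- v * 256 + as.integer(data[offset + i])
  v
}

varint_encode <- function(x) {
  if (x < 0 || x != floor(x)) stop("varint must be a non-negative integer")
  out <- raw(0)
  repeat {
    b <- x %% 128
    x <- x %/% 128
    if (x > 0) out <- c(out, as.raw(b + 128))
    else return(c(out, as.raw(b)))
  }
}

varint_decode <- function(data, pos) {
  # pos is 1-based; returns list(value, pos) with pos after the varint
  v <- 0
  mult <- 1
  repeat {
    if (pos > length(data)) stop_corrupt("truncated varint in directory")
    b <- as.integer(data[pos])
    pos <- pos + 1L
    v <- v + (b %% 128) * mult
    if (b < 128) return(list(value = v, pos = pos))
    mult <- mult * 128
  }
}
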