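#' @name cmcodec
#' @title Block compression backends
#'
#' @description
#' Byte-stream compression behind the container.  Two backends are built
#' in: `"cm1"`, a context-mixing binary arithmetic coder (three adaptive
#' bit-probability models over order-0/1/2 byte contexts, logistic mixing,
#' carryless 32-bit range coding), and `"store"`, the identity (useful for
#' testing and for fast structural sweeps).  Each block is encoded with a
#' fresh predictor state, so blocks are independently compressible — the
#' contract that allows arbitrary (e.g. parallel) block processing order.
#' The raw length travels in the block metadata, not in the stream.
#'
#' The cm1 model constants are fixed in this version: probability tables
#' of 2^16 entries per order, adaptation rate 1/32, mixer learning rate
#' 0.002, mixed probability clamped to `[2^-12, 1 - 2^-12]`.  They are
#' recorded in the container header for forward compatibility.
NULL

.qsarc_backends <- new.env(parent = emptyenv())

#' Register a compression backend
#'
#' Backends are keyed by name and carry a small integer id stored in the
#' container header.  `decode(encode(x), length(x))` must be the identity
#' for every raw vector `x`.
#'
#' @param name backend name.
#' @param id integer id in 0..255, unique across registered backends.
#' @param encode function(raw) -> raw.
#' @param decode function(raw, raw_len) -> raw.
#' @return `name`, invisibly.
#' @export
register_backend <- function(name, id, encode, decode) {
  stopifnot(is.character(name), length(name) == 1L,
            is.function(encode), is.function(decode))
  id <- as.integer(id)
  if (is.na(id) || id < 0L || id > 255L) stop("backend id must be in 0..255")
  for (other in ls(.qsarc_backends)) {
    if (other != name && .qsarc_backends[[other]]$id == id)
      stop("backend id ", id, " already used by '", other, "'")
  }
  assign(name, list(name = name, id = id, encode = encode, decode = decode),
         envir = .qsarc_backends)
  invisible(name)
}

#' List registered backend names
#' @return character vector of backend names.
#' @export
list_backends <- function() sort(ls(.qsarc_backends))

get_backend <- function(name) {
  if (!exists(name, envir = .qsarc_backends, inherits = FALSE))
    stop("unknown backend '", name, "'; registered: ",
         paste(list_backends(), collapse = ", "))
  get(name, envir = .qsarc_backends, inherits = FALSE)
}

backend_by_id <- function(id) {
  for (name in ls(.qsarc_backends)) {
    b <- .qsarc_backends[[name]]
    if (b$id == id) return(b)
  }
  stop_corrupt(paste0("container names unknown backend id ", id))
}

#' Compress a raw byte vector
#'
#' @param data raw vector (may be empty).
#' @param backend backend name, see [list_backends()].
#' @return compressed raw vector.
#' @export
cm_encode <- function(data, backend = "cm1") {
  stopifnot(is.raw(data))
  get_backend(backend)$encode(data)
}

#' Decompress a raw byte vector
#'
#' Exact inverse of [cm_encode()] given the correct `raw_len`.  Decoding
#' with a wrong `raw_len` yields that many bytes of unspecified content
#' (garbage in, garbage out) but does not crash; a truncated cm1 stream
#' raises a corruption error.
#'
#' @param data compressed raw vector.
#' @param raw_len length of the original data in bytes.
#' @inheritParams cm_encode
#' @return raw vector of `raw_len` bytes.
#' @export
cm_decode <- function(data, raw_len, backend = "cm1") {
  stopifnot(is.raw(data))
  get_backend(backend)$decode(data, raw_len)
}

register_builtin_backends <- function() {
  register_backend("store", 0L,
    encode = function(data) data,
    decode = function(data, raw_len) {
      if (length(data) != raw_len)
        stop_corrupt(sprintf("store payload has %d bytes, expected %.0f",
                             length(data), raw_len))
      data
    })
  register_backend("cm1", 1L,
    encode = function(data) cpp_cm_encode(data),
    decode = function(data, raw_len) {
      tryCatch(cpp_cm_decode(data, raw_len),
               error = function(e) stop_corrupt(conditionMessage(e)))
    })
}

.onLoad <- function(libname, pkgname) {
  register_builtin_backends()
}
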