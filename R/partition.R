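#' Parameters of the two-way k-mer frequency partition
#'
#' @param k k-mer length; overlapping substrings of length `k` represent a
#'   line.  Default 4.
#' @param sample_lines number of head lines `M` used to estimate k-mer
#'   weights and the modal value.  Default 100000; files with fewer lines
#'   are sampled whole.
#' @param alpha classification threshold on the normalized line weight, in
#'   \[0, 1\].  Default 0.1.
#' @return an object of class `partition_params`.
#' @export
partition_params <- function(k = 4L, sample_lines = 100000L, alpha = 0.1) {
  k <- as.integer(k)
  sample_lines <- as.integer(sample_lines)
  if (is.na(k) || k < 1L) stop("k must be >= 1")
  if (is.na(sample_lines) || sample_lines < 1L) stop("sample_lines must be >= 1")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]")
  structure(list(k = k, sample_lines = sample_lines, alpha = alpha),
            class = "partition_params")
}

#' Build the k-mer weight model from the sampled file head
#'
#' Counts every overlapping k-mer of the sampled lines (a line of length L
#' contributes `max(0, L - k + 1)` k-mers).  Each k-mer's weight is its
#' count divided by the total k-mer count, so the weights sum to 1.  The
#' maximum raw line weight over the sample, `w_max`, is kept as the
#' normaliser for classification.  The model is frozen after the sample:
#' no adaptation happens on later lines, preserving the single-pass
#' property of the compressor.
#'
#' @param sample character vector: the first `min(M, n)` lines of the file.
#' @param params a [partition_params()].
#' @return an object of class `kmer_weight_model` with elements `k`,
#'   `weight` (named numeric, names are k-mers), `total_kmer_count` and
#'   `w_max`.  If every sampled line is shorter than `k` the weight map is
#'   empty and `w_max` is 0 (with a warning).
#' @export
build_kmer_weights <- function(sample, params = partition_params()) {
  stopifnot(inherits(params, "partition_params"))
  if (!length(sample)) stop("sample must be non-empty")
  st <- cpp_kmer_model(sample, params$k)
  if (st$total == 0)
    warning("all sampled lines are shorter than k = ", params$k,
            "; empty weight model (w_max = 0)")
  structure(list(k = params$k,
                 weight = stats::setNames(st$weights, st$kmers),
                 total_kmer_count = st$total,
                 w_max = st$w_max),
            class = "kmer_weight_model")
}

#' Raw k-mer frequency weight of quality lines
#'
#' The raw weight of a line is the sum of the weights of its overlapping
#' k-mers divided by the number of k-mers in it.  K-mers not observed in
#' the sample contribute 0; lines shorter than `k` have weight 0.
#'
#' @param lines character vector of quality lines.
#' @param model a [build_kmer_weights()] model.
#' @return numeric vector of raw weights, one per line.
#' @export
line_weight <- function(lines, model) {
  stopifnot(inherits(model, "kmer_weight_model"))
  cpp_line_weights(lines, names(model$weight), unname(model$weight), model$k)
}

#' Classify quality lines into stream 0 or stream 1
#'
#' The normalized weight of a line is its raw [line_weight()] divided by
#' the model's `w_max` (taken as 0 when `w_max` is 0).  A line goes to
#' stream 0 (the order-keeping buffer A) iff its normalized weight is
#' `>= alpha`, otherwise to stream 1.  Post-sample lines may have
#' normalized weight above 1; they are not clamped, which cannot change
#' the label.  Exactly two streams exist and every line gets exactly one
#' label.
#'
#' @inheritParams line_weight
#' @param params a [partition_params()] supplying `alpha`.
#' @return integer vector of labels, 0 or 1.
#' @export
classify_line <- function(lines, model, params = partition_params()) {
  stopifnot(inherits(params, "partition_params"))
  lw <- line_weight(lines, model)
  wn <- if (model$w_max > 0) lw / model$w_max else rep.int(0, length(lw))
  ifelse(wn >= params$alpha, 0L, 1L)
}
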