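---
title: "qsarc: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{qsarc: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsarc)
```

# The problem

Quality scores are the per-base confidence values of FASTQ records, encoded
as printable ASCII in the range 33–104. They dominate the compressed size
of sequencing archives (roughly 70% of a losslessly compressed FASTQ file)
and, unlike the reads themselves, are consulted mostly by *look-ups*: a
caller wants the quality lines of a specific read range, not the whole
file. `qsarc` therefore optimises for lossless compression with fast
**line-range random access** from a single self-indexed file, and for
robustness: fixed or variable line lengths, any coding standard inside
33–104, empty files and empty lines all round-trip byte-identically.

Three distributional assumptions — deliberately weak, so they hold across
sequencing machines and pipelines — underpin every stage:

1. all byte values lie in 33–104;
2. the marginal distribution over values is strongly uneven;
3. lines come from a mixture of a few source distributions (machine noise
   and library effects produce distinct line "types" within one file).

# Pipeline

## Stage 1: two-way partition by k-mer frequency weight

Lines of different mixture components compress better when modeled
separately, but clustering must not cost a second pass. `qsarc` samples the
first $M$ lines (default $10^5$), counts all overlapping k-mers (default
$k = 4$), and assigns each k-mer the weight
$w(\text{kmer}) = \text{count}/\text{total}$. A line's raw weight is the
mean weight of its k-mers; the maximum raw weight over the sample,
$w_{\max}$, normalises all later weights. A line is routed to **stream 0**
iff $w/w_{\max} \ge \alpha$ (default $\alpha = 0.1$), else to **stream 1**.
Exactly two clusters keep the time/space balance; the model is frozen after
the sample so the compressor stays single-pass and deterministic.

Decisions the underlying description leaves open, fixed here:

* the comparison is `>=` (so $\alpha = 0$ routes everything to stream 0,
  and $\alpha = 1$ keeps only lines at least as heavy as the heaviest
  sampled line);
* unseen k-mers weigh 0; lines shorter than $k$ weigh 0 and go to
  stream 1 — they carry no k-mer evidence, and stream 1 stores raw content
  without placeholders;
* normalised weights above 1 (possible after the sample) are not clamped;
  the label is unaffected.

A consequence worth noting: with $\alpha > 0$ an *empty* line always lands
in stream 1, and with $\alpha = 0$ stream 1 is empty altogether. This is
what makes the placeholder convention of stage 2 unambiguous.

## Stage 2: dual buffers, blocks, and the embedded index

Two byte-size-thresholded buffers (default threshold $T$ = 8 MiB, shared)
turn the streams into blocks. Buffer A receives stream-0 line bytes plus a
*placeholder newline* for every stream-1 line, so an A block covers a
contiguous range of global line ordinals. Buffer B receives stream-1 line
bytes only. A buffer exceeding $T$ is flushed; after three consecutive B
flushes, A is flushed by force. The forced flush is the load-balance
guarantee for random access: no A block can overlap more than 3 B blocks,
so restoring a range inside one A span touches at most 4 blocks, and a
range straddling one A-block boundary at most 8. (Ranges spanning three or
more A blocks scale linearly, as they must.)

Each A block's directory entry records its line span and the number of
stream-1 lines before it; each B block's entry records the ordinals of its
first and last stream-1 line. The directory also stores each block's line
count: the B-block count is in principle derivable by decoding neighbouring
A blocks, but doing so during a range query would defeat the point of the
index, and the count costs one to three bytes per block. Buffers measure
*raw* bytes and packing happens at flush time, so index entries live in raw
line coordinates and the pack table can stay global.

## Stage 3: adaptive packing anchored on the modal value

Before entropy coding, groups of quality values are bijectively replaced
by single code bytes to shrink the content the model must process. The
table is a pure function of the modal value $C$ (the most frequent byte of
the sampled head, ties to the smallest value), stored in the header:

| group   | window                  | codes                 |
|---------|-------------------------|-----------------------|
| singles | every value 33..104     | 1..72                 |
| triples | $[C-1, C+1]^3$          | 73..99 (27)           |
| pairs   | $[C-5, C+6]^2$          | 100..243 (144)        |
| runs of $C$ | lengths 4..15       | 244..255 (12)         |

(windows clipped to 33–104; counts shown for an interior $C$; code 0 is
the line terminator). Encoding is greedy longest-match with priority
run > triple > pair > single; decoding is a pure table lookup, so any
encoder ambiguity would be harmless to losslessness. Because the marginal
distribution is strongly uneven, most content falls in the `[C-1, C+1]`
triple window and packs three bytes per code. The window widths are this
package's own concrete instantiation of the published constraints (anchor
$C$, one-to-one, codes 1–255, priority increasing toward 255); they use
the entire code space for an interior $C$ and give runs, the cheapest
groups, the highest priority.

## Stage 4: context-mixing entropy coding

Each packed block is compressed independently by `cm1`: three adaptive
bit-probability tables (order-0/1/2 byte contexts hashed into $2^{16}$
16-bit fixed-point entries each, initialised to $\tfrac12$), combined in
the logistic domain, $p = \sigma\!\big(\sum_i w_i\,
\mathrm{st}(p_i)\big)$ with $\mathrm{st}(p) = \ln\frac{p}{1-p}$, clamped
to $[2^{-12}, 1 - 2^{-12}]$, driving a carryless 32-bit binary arithmetic
coder with byte-wise renormalisation (4-byte flush). After each bit, every
model adapts by $p_i \mathrel{+}= (\text{bit} - p_i)/32$ and the mixer by
$w_i \mathrel{+}= \lambda\,(\text{bit} - p)\,\mathrm{st}(p_i)$,
$\lambda = 0.002$. Encoder and decoder run the identical model over the
identical bit history — that symmetry *is* the correctness argument, and
it is asserted by instrumented round trips in the tests.

This is intentionally a small, exactly invertible stand-in for a
heavyweight context-mixing library: the constants above are this
package's own, are recorded in the container header, and make no claim of
matching any external compressor's ratios. Fresh predictor state per block
is what makes blocks independently decodable (the contract that permits —
without mandating — parallel block processing). A `store` backend (the
identity) is registered alongside for testing and structural sweeps, and
the backend registry accepts external adapters.

## Container format

One output file, no sidecar: a 48-byte little-endian header (magic,
version, backend id, $k$, $\alpha$ as parts-per-10⁴ to avoid float drift,
$M$, $C$, coder constants, $T$, total lines, original bytes), the block
payloads in flush order, a varint-encoded directory, and a 12-byte footer
(directory offset + magic echo) so a reader can find the directory with
two seeks. Line ranges are 0-based internally; the R API and CLI are
1-based inclusive. Partial output is removed on failure.

# The synthetic world

`generate_synthetic()` emulates exactly the three priors: bytes confined
to 33–104, a strongly uneven marginal, and per-line mixture structure. The
default world is a two-source mixture — weight 0.8 sharply peaked at 70
(discretised normal, sd 2.5) and weight 0.2 broad around 50 (sd 8) — with
fixed length 100, resembling short-read data; variable-length specs
emulate long-read files. Structural tests that must populate both streams
at small sample sizes use a variant world whose major source is *binned*
to four discrete values (as quality-binned Illumina instruments emit) with
a 20% uniform minor source; diffuse continuous mixtures only separate at
$\alpha = 0.1$ once the sampled k-mer counts concentrate, i.e. at larger
$M$. What it does **not** emulate: positional quality
decay along the read, autocorrelation within lines, and instrument-binned
alphabets. A green round-trip or random-access test therefore establishes
correctness of the machinery on data satisfying the priors, not
competitive compression ratios on real archives; no ratio claims are made
or tested beyond "cm1 beats store on mixture data".

# Numerical and degenerate-input choices

* Ties in the modal value break to the smallest byte; deterministic.
* A sample containing no bytes at all (a file of empty lines) cannot
  define $C$; compression falls back to $C = 33$, sound because empty
  lines pack to a bare terminator without consulting the table.
* All sampled lines shorter than $k$ give an empty weight model,
  $w_{\max} = 0$, a warning, and (for $\alpha > 0$) stream 1 for
  everything.
* Probabilities in the coder never saturate: table updates floor at
  $31/2^{16}$ and the mixed probability is clamped at $2^{-12}$.
* `decode` with a wrong `raw_len` is documented garbage-in/garbage-out of
  the requested length; corruption *is* detected at block granularity via
  the stored packed length and line counts, and header/footer magic and
  version are checked on open.
* Flush order at end of input is B before A — arbitrary, but fixed so
  containers are byte-deterministic; likewise blocks could be encoded in
  any order and written canonically with identical output.

# Known limitations

* The coder is a compact three-model mixer, not a full context-mixing
  chain; ratios on real data will trail specialised tools.
* SAM/BAM quality extraction, gzip-transparent input, and lossy binning
  are out of scope.
* The compressor runs single-threaded; parallelism is enabled by the
  independent-block contract but not implemented.
* Quality values above ASCII 104 (historic Solexa-64 up to 105+, PacBio
  tag extensions) are rejected by design; `--no-validate` exists for
  robustness experiments only.

# A worked example

```{r example}
f <- tempfile(); arc <- tempfile(fileext = ".qsarc")
lines <- generate_synthetic(synthetic_spec(2000, lengths = 100, seed = 7), f)
compress_file(f, arc, backend = "cm1")
container_info(arc)
range_decompress(arc, 1001, 1003)
```
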