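# qsarc

Lossless compression of FASTQ quality scores with line-range random access
from a single self-indexed file.

## Why

Quality scores — the per-base ASCII confidence values on line 4 of every
FASTQ record, here constrained to ASCII 33–104 — are the bulk of a
losslessly compressed FASTQ archive, and they are consulted mostly through
*look-ups*: "give me the quality lines of reads 40,000–80,000", not "give
me the whole file". General compressors force a full decompress for that;
fine-grained indexed compressors pay for it with large sidecar index files
and slow compression. `qsarc` targets the middle ground: a robust lossless
compressor for quality lines of any length whose random-access index is a
few bytes per block, embedded in the one output file.

## How it works

Four stages, all derived from weak distributional priors (alphabet 33–104,
strongly uneven value distribution, per-line mixture structure):

1. **Partition.** The first *M* lines (default 10⁵) are sampled; every
   overlapping k-mer (default *k* = 4) gets weight count/total. A line's
   weight is the mean weight of its k-mers, normalised by the sample
   maximum *w*max. Lines with *w*/*w*max ≥ α (default 0.1) form stream 0,
   the rest stream 1 — one pass, two clusters, frozen model.
2. **Blocking + light-weight index.** Stream 0 bytes fill buffer A (with a
   placeholder newline for every stream-1 line, preserving global order);
   stream 1 bytes fill buffer B. Buffers flush into independently
   compressed blocks past a size threshold (default 8 MiB); after three
   consecutive B flushes, A is force-flushed, so restoring a range inside
   one A block touches ≤ 4 blocks (1 A + 3 B) and a range straddling one
   A boundary ≤ 8 (2 A + 6 B). Per-block line spans live in a varint
   directory at the end of the container — no external index file.
3. **Adaptive packing.** Anchored on the modal quality value *C*, groups
   of values (runs of *C* of length 4–15, triples in [*C*−1, *C*+1], pairs
   in [*C*−5, *C*+6], singles) are bijectively replaced by single code
   bytes 1–255 (0 terminates a line). Encoder and decoder rebuild the
   identical table from the *C* stored in the header.
4. **Context mixing.** Each packed block goes through `cm1`: order-0/1/2
   adaptive bit models mixed logistically
   (p = σ(Σᵢ wᵢ·ln(pᵢ/(1−pᵢ))), adaptation rate 1/32, mixer rate 0.002)
   feeding a carryless 32-bit binary arithmetic coder. A `store` backend
   (identity) is available for structural work.

## Worked example

```r
library(qsarc)
f <- tempfile(); arc <- tempfile(fileext = ".qsarc")
generate_synthetic(synthetic_spec(2000, lengths = 100, seed = 7), f)
compress_file(f, arc, backend = "cm1")
#> qsarc: 2000 lines -> 2 blocks (1 A, 1 B), 202,000 -> 97,182 bytes (backend cm1, C = 70)
container_info(arc)
#> qsarc container: /tmp/.../file.qsarc
#>   version 1, backend cm1, k = 4, alpha = 0.1, M = 100000, C = 70, T = 8,388,608
#>   2,000 lines, 202,000 original bytes -> 97,182 compressed (ratio 2.0786)
#>   2 blocks; index overhead 42 bytes (0.0208% of original), no sidecar file
range_decompress(arc, 1001, 1002)
#> [1] "HDAHGCDGBFCHEFGHEHGDLCJGHEDH?ECGGIDEKDFIGFFHEDBIGHGEIBEFEEEHGFFJFCGEHEDHCFFEFBFADFEJHCKGBFDKHGFJBEDD"
#> [2] "91.95;30&58487*,07,8:71//-=::,5<6:@:99&3:)%)*362845)<1-:23.9)#,,-+@3',50<22587-+@93D/-A/?67..('/050-"
```

The summary line says: 2,000 synthetic quality lines became one stream-0
and one stream-1 block, shrinking 202,000 bytes to 97,182 (ratio ≈ 2.08)
with the modal value *C* = 70 anchoring the pack table. The info report
shows the entire random-access index costs 42 bytes inside the container.
The two lines printed by `range_decompress` are reads 1001–1002 exactly as
in the input — the first from the dominant high-quality source, the second
from the broad low-quality source of the default mixture.

Command line (same operations):

```sh
./exec/qsarc synth -o q.txt -n 2000 --seed 7
./exec/qsarc compress -i q.txt -o q.qsarc --backend cm1
./exec/qsarc range -i q.qsarc -a 1001 -b 1002
./exec/qsarc info -i q.qsarc
```

## Scope

Quality lines only (plain text or extracted from uncompressed FASTQ).
No SAM/BAM input, no gzip transparency, no lossy binning, no
multithreading (blocks are independently decodable, so parallelism is
possible but not implemented). See `vignettes/qsarc-methods.Rmd` for the
model details, parameter rationale and limitations.
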