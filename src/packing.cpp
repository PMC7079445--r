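#include <Rcpp.h>
using namespace Rcpp;

// Group geometry of the adaptive pack table.  Everything is a pure function
// of the modal quality value C, so encoder and decoder only need to share C.
//
// Code space (72 quality values, 255 available codes, 0 = line terminator):
//   singles  : values 33..104            -> codes 1..72            (value - 32)
//   triples  : (a,b,c), all in [C-1,C+1] -> codes from 73, lex order
//   pairs    : (a,b),   both in [C-5,C+6]-> codes after triples, lex order
//   runs of C: lengths 4..15             -> 12 codes after pairs
// Windows are clipped to [33,104]; for an interior C the total is exactly
// 72 + 27 + 144 + 12 = 255.
struct PackGeom {
  int C;
  int lo3, hi3, n3;
  int lo2, hi2, n2;
  int base3, base2, run_base, max_code;
};

static PackGeom geom_from_C(int C) {
  if (C < 33 || C > 104)
    stop("modal value C must lie in [33, 104], got %d", C);
  PackGeom g;
  g.C = C;
  g.lo3 = std::max(33, C - 1);
  g.hi3 = std::min(104, C + 1);
  g.lo2 = std::max(33, C - 5);
  g.hi2 = std::min(104, C + 6);
  g.n3 = g.hi3 - g.lo3 + 1;
  g.n2 = g.hi2 - g.lo2 + 1;
  g.base3 = 73;
  g.base2 = g.base3 + g.n3 * g.n3 * g.n3;
  g.run_base = g.base2 + g.n2 * g.n2;
  g.max_code = g.run_base + 11;  // run lengths 4..15
  return g;
}

// [[Rcpp::export]]
RawVector cpp_pack_lines(CharacterVector lines, int C) {
  PackGeom g = geom_from_C(C);
  std::vector<unsigned char> out;
  // rough reserve: one code per 2 bytes plus terminators
  R_xlen_t nl = lines.size();
  size_t guess = (size_t)nl;
  for (R_xlen_t li = 0; li < nl; ++li) guess += LENGTH(STRING_ELT(lines, li)) / 2 + 1;
  out.reserve(guess);

  for (R_xlen_t li = 0; li < nl; ++li) {
    SEXP s = STRING_ELT(lines, li);
    if (s == NA_STRING) stop("line %lld is NA", (long long)(li + 1));
    const unsigned char* p = (const unsigned char*)CHAR(s);
    int n = LENGTH(s);
    for (int j = 0; j < n; ++j)
      if (p[j] < 33 || p[j] > 104)
        stop("invalid quality byte %d at line %lld (must be in [33, 104])",
             (int)p[j], (long long)(li + 1));
    int i = 0;
    while (i < n) {
      int b = p[i];
      if (b == g.C) {  // greedy: run of C first (length 4..15)
        int r = 1;
        while (r < 15 && i + r < n && p[i + r] == g.C) ++r;
        if (r >= 4) {
          out.push_back((unsigned char)(g.run_base + (r - 4)));
          i += r;
          continue;
        }
      }
      if (i + 3 <= n &&
          p[i] >= g.lo3 && p[i] <= g.hi3 &&
          p[i + 1] >= g.lo3 && p[i + 1] <= g.hi3 &&
          p[i + 2] >= g.lo3 && p[i + 2] <= g.hi3) {
        int code = g.base3 +
          ((p[i] - g.lo3) * g.n3 + (p[i + 1] - g.lo3)) * g.n3 + (p[i + 2] - g.lo3);
        out.push_back((unsigned char)code);
        i += 3;
        continue;
      }
      if (i + 2 <= n &&
          p[i] >= g.lo2 && p[i] <= g.hi2 &&
          p[i + 1] >= g.lo2 && p[i + 1] <= g.hi2) {
        int code = g.base2 + (p[i] - g.lo2) * g.n2 + (p[i + 1] - g.lo2);
        out.push_back((unsigned char)code);
        i += 2;
        continue;
      }
      out.push_back((unsigned char)(b - 32));
      ++i;
    }
    out.push_back(0);  // line terminator
  }
  return RawVector(out.begin(), out.end());
}

// [[Rcpp::export]]
CharacterVector cpp_unpack_lines(RawVector packed, int C) {
  PackGeom g = geom_from_C(C);
  R_xlen_t n = packed.size();
  if (n > 0 && packed[n - 1] != 0)
    stop("corrupt packed stream: missing line terminator at end of stream");
  R_xlen_t nlines = 0;
  for (R_xlen_t i = 0; i < n; ++i)
    if (packed[i] == 0) ++nlines;
  CharacterVector out(nlines);
  std::string cur;
  R_xlen_t k = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    int c = packed[i];
    if (c == 0) {
      SET_STRING_ELT(out, k++, Rf_mkCharLen(cur.data(), (int)cur.size()));
      cur.clear();
    } else if (c <= 72) {
      cur.push_back((char)(c + 32));
    } else if (c < g.base2) {
      int idx = c - g.base3;
      int a = idx / (g.n3 * g.n3);
      int b = (idx / g.n3) % g.n3;
      int d = idx % g.n3;
      cur.push_back((char)(g.lo3 + a));
      cur.push_back((char)(g.lo3 + b));
      cur.push_back((char)(g.lo3 + d));
    } else if (c < g.run_base) {
      int idx = c - g.base2;
      cur.push_back((char)(g.lo2 + idx / g.n2));
      cur.push_back((char)(g.lo2 + idx % g.n2));
    } else if (c <= g.max_code) {
      cur.append((size_t)(c - g.run_base + 4), (char)g.C);
    } else {
      stop("corrupt packed stream: unknown code %d at offset %lld",
           c, (long long)i);
    }
  }
  return out;
}
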