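#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Split a raw byte buffer into LF-terminated lines, byte-exactly.
// CR bytes are rejected unless strip_cr is set, in which case a single CR
// immediately before the LF is dropped (CRLF normalisation); a CR anywhere
// else is always an error, because the container stores exact bytes and the
// line boundaries must be unambiguous.
// [[Rcpp::export]]
List cpp_split_lines(RawVector data, bool strip_cr) {
  R_xlen_t n = data.size();
  const unsigned char* p = n ? (const unsigned char*)RAW(data) : NULL;
  std::vector<std::pair<R_xlen_t, R_xlen_t> > spans;  // (start, len)
  R_xlen_t start = 0;
  bool final_newline = true;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (p[i] == '\n') {
      R_xlen_t len = i - start;
      if (len > 0 && p[i - 1] == '\r') {
        if (strip_cr) --len;
        else stop("carriage return at line %lld; input must be LF-terminated (use strip_cr to normalise CRLF)",
                  (long long)(spans.size() + 1));
      }
      for (R_xlen_t j = start; j < start + len; ++j)
        if (p[j] == '\r')
          stop("stray carriage return inside line %lld", (long long)(spans.size() + 1));
      spans.push_back(std::make_pair(start, len));
      start = i + 1;
    }
  }
  if (start < n) {  // trailing bytes with no final LF
    final_newline = false;
    R_xlen_t len = n - start;
    for (R_xlen_t j = start; j < n; ++j)
      if (p[j] == '\r') {
        if (strip_cr && j == n - 1) { --len; break; }
        stop("stray carriage return inside line %lld", (long long)(spans.size() + 1));
      }
    spans.push_back(std::make_pair(start, len));
  }
  CharacterVector lines((R_xlen_t)spans.size());
  for (size_t i = 0; i < spans.size(); ++i)
    SET_STRING_ELT(lines, (R_xlen_t)i,
                   Rf_mkCharLen((const char*)(p + spans[i].first), (int)spans[i].second));
  return List::create(_["lines"] = lines, _["final_newline"] = final_newline);
}

// Validate that every byte of every line lies in [33, 104]; error names the
// first offending line (1-based) and byte value.
// [[Rcpp::export]]
void cpp_validate_lines(CharacterVector lines) {
  R_xlen_t nl = lines.size();
  for (R_xlen_t li = 0; li < nl; ++li) {
    SEXP s = STRING_ELT(lines, li);
    const unsigned char* p = (const unsigned char*)CHAR(s);
    int n = LENGTH(s);
    for (int i = 0; i < n; ++i)
      if (p[i] < 33 || p[i] > 104)
        stop("quality byte %d at line %lld is outside [33, 104]",
             (int)p[i], (long long)(li + 1));
  }
}

// Assemble lines from a flat vector of byte values and per-line lengths.
// [[Rcpp::export]]
CharacterVector cpp_bytes_to_lines(IntegerVector vals, IntegerVector lens) {
  R_xlen_t nl = lens.size();
  CharacterVector out(nl);
  R_xlen_t pos = 0, total = vals.size();
  std::string buf;
  for (R_xlen_t li = 0; li < nl; ++li) {
    int len = lens[li];
    if (len < 0 || pos + len > total) stop("lengths do not match value vector");
    buf.assign((size_t)len, '\0');
    for (int j = 0; j < len; ++j) {
      int v = vals[pos + j];
      if (v < 1 || v > 255) stop("byte value %d out of range", v);
      buf[j] = (char)v;
    }
    pos += len;
    SET_STRING_ELT(out, li, Rf_mkCharLen(buf.data(), len));
  }
  if (pos != total) stop("lengths do not match value vector");
  return out;
}
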