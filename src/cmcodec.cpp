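#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// A small context-mixing bit predictor feeding a carryless binary arithmetic
// coder.  Three adaptive bit-probability tables (order 0, 1, 2 byte contexts,
// each 2^16 entries of 16-bit fixed point) are combined in the logistic
// domain by an online-trained mixer.  Encoder and decoder run the identical
// model over the identical bit history, which is the whole correctness
// argument: the probability sequences are bit-for-bit the same on both
// sides.  Constants: adaptation rate 1/32, mixer learning rate 0.002,
// mixed probability clamped to [2^-12, 1 - 2^-12].

static const int TBITS = 16;
static const uint32_t TMASK = (1u << TBITS) - 1;

class CMPredictor {
  std::vector<uint16_t> t0, t1, t2;
  double w[3];
  uint32_t c1, c2;   // previous two bytes
  uint32_t h1, h2;   // hashed order-1 / order-2 byte contexts
  int node;          // bit-tree index within the current byte (1..255)
  uint32_t idx[3];
  double st[3];
  double pm;         // last mixed probability in (0,1)
public:
  CMPredictor()
    : t0(1u << TBITS, 32768), t1(1u << TBITS, 32768), t2(1u << TBITS, 32768),
      c1(0), c2(0), h1(0), h2(0), node(1) {
    w[0] = w[1] = w[2] = 0.0;
  }

  // probability that the next bit is 1, as 16-bit fixed point in [16, 65520]
  int predict() {
    idx[0] = (uint32_t)node & TMASK;
    idx[1] = (h1 + (uint32_t)node) & TMASK;
    idx[2] = (h2 + (uint32_t)node) & TMASK;
    const uint16_t* tabs[3] = { t0.data(), t1.data(), t2.data() };
    double S = 0.0;
    for (int m = 0; m < 3; ++m) {
      double pi = tabs[m][idx[m]] / 65536.0;
      st[m] = std::log(pi / (1.0 - pi));
      S += w[m] * st[m];
    }
    double p = 1.0 / (1.0 + std::exp(-S));
    const double eps = 1.0 / 4096.0;
    if (p < eps) p = eps;
    else if (p > 1.0 - eps) p = 1.0 - eps;
    pm = p;
    int pr = (int)std::lround(p * 65536.0);
    if (pr < 16) pr = 16;
    else if (pr > 65520) pr = 65520;
    return pr;
  }

  double mixed() const { return pm; }

  void update(int bit) {
    uint16_t* tabs[3] = { t0.data(), t1.data(), t2.data() };
    for (int m = 0; m < 3; ++m) {
      int q = tabs[m][idx[m]];
      if (bit) q += (65536 - q) >> 5;  // p += (1 - p)/32
      else     q -= q >> 5;            // p -= p/32
      tabs[m][idx[m]] = (uint16_t)q;
      w[m] += 0.002 * ((double)bit - pm) * st[m];
    }
    node = (node << 1) | bit;
    if (node >= 256) {
      c2 = c1;
      c1 = (uint32_t)(node & 255);
      node = 1;
      h1 = (c1 + 1u) * 2654435761u;
      h2 = (c1 + (c2 << 8) + 0x9E3779B9u) * 2654435761u;
    }
  }
};

// 32-bit carryless binary arithmetic coder with byte-wise renormalisation
// (the lpaq family design).  raw_len is carried externally (block metadata),
// so the stream itself need not be self-delimiting.
class ArEncoder {
  uint32_t x1, x2;
public:
  std::vector<unsigned char> out;
  ArEncoder() : x1(0), x2(0xFFFFFFFFu) {}
  void encode(int bit, int pr16) {
    uint32_t xmid = x1 + (uint32_t)((((uint64_t)(x2 - x1)) >> 16) * (uint64_t)pr16);
    if (bit) x2 = xmid; else x1 = xmid + 1;
    while (((x1 ^ x2) & 0xFF000000u) == 0) {
      out.push_back((unsigned char)(x2 >> 24));
      x1 <<= 8;
      x2 = (x2 << 8) | 255u;
    }
  }
  void flush() {
    for (int i = 0; i < 4; ++i) {
      out.push_back((unsigned char)(x1 >> 24));
      x1 <<= 8;
    }
  }
};

class ArDecoder {
  uint32_t x1, x2, x;
  const unsigned char* in;
  size_t pos, len;
  unsigned char get() { return pos < len ? in[pos++] : 0; }
public:
  ArDecoder(const unsigned char* data, size_t n)
    : x1(0), x2(0xFFFFFFFFu), x(0), in(data), pos(0), len(n) {
    for (int i = 0; i < 4; ++i) x = (x << 8) | get();
  }
  int decode(int pr16) {
    uint32_t xmid = x1 + (uint32_t)((((uint64_t)(x2 - x1)) >> 16) * (uint64_t)pr16);
    int bit = (x <= xmid) ? 1 : 0;
    if (bit) x2 = xmid; else x1 = xmid + 1;
    while (((x1 ^ x2) & 0xFF000000u) == 0) {
      x1 <<= 8;
      x2 = (x2 << 8) | 255u;
      x = (x << 8) | get();
    }
    return bit;
  }
};

// [[Rcpp::export]]
RawVector cpp_cm_encode(RawVector data) {
  CMPredictor pred;
  ArEncoder enc;
  R_xlen_t n = data.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    int byte = data[i];
    for (int b = 7; b >= 0; --b) {
      int bit = (byte >> b) & 1;
      int pr = pred.predict();
      enc.encode(bit, pr);
      pred.update(bit);
    }
  }
  enc.flush();
  return RawVector(enc.out.begin(), enc.out.end());
}

// [[Rcpp::export]]
RawVector cpp_cm_decode(RawVector comp, double raw_len) {
  if (raw_len < 0 || raw_len != std::floor(raw_len))
    stop("raw_len must be a non-negative integer");
  R_xlen_t n = (R_xlen_t)raw_len;
  if (n > 0 && comp.size() < 4)
    stop("corrupt compressed stream: truncated (need at least 4 bytes)");
  CMPredictor pred;
  ArDecoder dec(comp.size() ? (const unsigned char*)RAW(comp) : (const unsigned char*)"",
                (size_t)comp.size());
  RawVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int byte = 0;
    for (int b = 7; b >= 0; --b) {
      int pr = pred.predict();
      int bit = dec.decode(pr);
      pred.update(bit);
      byte = (byte << 1) | bit;
    }
    out[i] = (unsigned char)byte;
  }
  return out;
}

// Mixed probability emitted before each bit of `data`; test instrumentation
// for the encoder/decoder symmetry and learning-behaviour checks.
// [[Rcpp::export]]
NumericVector cpp_cm_trace(RawVector data) {
  CMPredictor pred;
  R_xlen_t n = data.size();
  NumericVector out(n * 8);
  R_xlen_t k = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    int byte = data[i];
    for (int b = 7; b >= 0; --b) {
      int bit = (byte >> b) & 1;
      pred.predict();
      out[k++] = pred.mixed();
      pred.update(bit);
    }
  }
  return out;
}

// One step of the per-model adaptation rule on a probability in (0,1),
// using the same 16-bit fixed-point arithmetic as the tables.
// [[Rcpp::export]]
double cpp_cm_adapt(double p, int bit) {
  if (p <= 0 || p >= 1) stop("p must be in (0,1)");
  int q = (int)std::lround(p * 65536.0);
  if (q < 1) q = 1;
  if (q > 65535) q = 65535;
  if (bit) q += (65536 - q) >> 5;
  else     q -= q >> 5;
  return q / 65536.0;
}

// Arithmetic coder with the predictor forced to a static probability;
// used to check the code length against the binary entropy closed form.
// [[Rcpp::export]]
RawVector cpp_arith_encode_static(RawVector bits, double p) {
  if (p <= 0 || p >= 1) stop("p must be in (0,1)");
  int pr = (int)std::lround(p * 65536.0);
  if (pr < 16) pr = 16;
  if (pr > 65520) pr = 65520;
  ArEncoder enc;
  R_xlen_t n = bits.size();
  for (R_xlen_t i = 0; i < n; ++i)
    enc.encode(bits[i] ? 1 : 0, pr);
  enc.flush();
  return RawVector(enc.out.begin(), enc.out.end());
}

// [[Rcpp::export]]
RawVector cpp_arith_decode_static(RawVector comp, double nbits, double p) {
  if (p <= 0 || p >= 1) stop("p must be in (0,1)");
  int pr = (int)std::lround(p * 65536.0);
  if (pr < 16) pr = 16;
  if (pr > 65520) pr = 65520;
  R_xlen_t n = (R_xlen_t)nbits;
  ArDecoder dec(comp.size() ? (const unsigned char*)RAW(comp) : (const unsigned char*)"",
                (size_t)comp.size());
  RawVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (unsigned char)dec.decode(pr);
  return out;
}
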