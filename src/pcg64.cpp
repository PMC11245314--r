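// PCG64 (XSL-RR 128/64): 128-bit state and increment, 64-bit output,
// period 2^128 per stream; distinct odd increments give independent streams.
#include <Rcpp.h>
#include <cstdint>
#include <cstdio>
#include <cstdlib>
#include <cinttypes>

using namespace Rcpp;

typedef unsigned __int128 pcg128_t;

static const pcg128_t PCG_MULT =
    (((pcg128_t)0x2360ed051fc65da4ULL) << 64) | 0x4385df649fccf645ULL;

struct pcg64_state {
  pcg128_t state;
  pcg128_t inc;
};

static inline uint64_t pcg64_next(pcg64_state *g) {
  g->state = g->state * PCG_MULT + g->inc;
  uint64_t xored = (uint64_t)(g->state >> 64) ^ (uint64_t)g->state;
  unsigned int rot = (unsigned int)(g->state >> 122);
  return (xored >> rot) | (xored << ((-rot) & 63u));
}

// [[Rcpp::export(name = ".pcg64_new")]]
SEXP pcg64_new(double seed, double stream) {
  pcg64_state *g = new pcg64_state;
  pcg128_t initstate = (pcg128_t)(uint64_t)seed;
  pcg128_t initseq = (pcg128_t)(uint64_t)stream;
  g->state = 0u;
  g->inc = (initseq << 1) | 1u;
  pcg64_next(g);
  g->state += initstate;
  pcg64_next(g);
  XPtr<pcg64_state> p(g, true);
  return p;
}

// [[Rcpp::export(name = ".pcg64_runif")]]
NumericVector pcg64_runif(SEXP ptr, int n) {
  XPtr<pcg64_state> p(ptr);
  NumericVector out(n);
  // 53-bit mantissa, offset by half an ulp: values lie strictly in (0, 1)
  const double scale = 1.0 / 9007199254740992.0; // 2^-53
  for (int i = 0; i < n; ++i) {
    out[i] = ((double)(pcg64_next(p) >> 11) + 0.5) * scale;
  }
  return out;
}

static void u64_hex(uint64_t v, char *buf) { snprintf(buf, 17, "%016" PRIx64, v); }

// [[Rcpp::export(name = ".pcg64_get_state")]]
CharacterVector pcg64_get_state(SEXP ptr) {
  XPtr<pcg64_state> p(ptr);
  char buf[17];
  CharacterVector out(4);
  u64_hex((uint64_t)(p->state >> 64), buf); out[0] = buf;
  u64_hex((uint64_t)p->state, buf);         out[1] = buf;
  u64_hex((uint64_t)(p->inc >> 64), buf);   out[2] = buf;
  u64_hex((uint64_t)p->inc, buf);           out[3] = buf;
  return out;
}

static uint64_t parse_hex64(const char *s) {
  uint64_t v = 0;
  for (; *s; ++s) {
    char c = *s;
    int d;
    if (c >= '0' && c <= '9') d = c - '0';
    else if (c >= 'a' && c <= 'f') d = c - 'a' + 10;
    else if (c >= 'A' && c <= 'F') d = c - 'A' + 10;
    else stop("invalid hex digit in RNG state");
    v = (v << 4) | (uint64_t)d;
  }
  return v;
}

// [[Rcpp::export(name = ".pcg64_set_state")]]
void pcg64_set_state(SEXP ptr, CharacterVector st) {
  if (st.size() != 4) stop("state must have 4 components");
  XPtr<pcg64_state> p(ptr);
  uint64_t w[4];
  for (int i = 0; i < 4; ++i) {
    w[i] = parse_hex64(CHAR(STRING_ELT(st, i)));
  }
  p->state = (((pcg128_t)w[0]) << 64) | w[1];
  p->inc = (((pcg128_t)w[2]) << 64) | w[3];
}
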