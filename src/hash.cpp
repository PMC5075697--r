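#include <Rcpp.h>
#include <cstdint>
#include <cstdio>
#include <cstdlib>
using namespace Rcpp;

// 64-bit FNV-1a, used for the incremental prefix hashing in prefix
// dereplication.  States are passed to/from R as 16-char lowercase hex
// strings because R has no native 64-bit integer type.

static const uint64_t FNV64_BASIS = 14695981039346656037ULL;
static const uint64_t FNV64_PRIME = 1099511628211ULL;

static std::string hex64(uint64_t x) {
  char buf[17];
  std::snprintf(buf, sizeof(buf), "%016llx", (unsigned long long) x);
  return std::string(buf);
}

static uint64_t unhex64(const std::string& s) {
  uint64_t x = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    const char c = s[i];
    int d;
    if (c >= '0' && c <= '9') d = c - '0';
    else if (c >= 'a' && c <= 'f') d = c - 'a' + 10;
    else if (c >= 'A' && c <= 'F') d = c - 'A' + 10;
    else Rcpp::stop("invalid hex state '%s'", s.c_str());
    x = (x << 4) | (uint64_t)d;
  }
  return x;
}

// [[Rcpp::export(name = ".fnv1a64_basis_hex")]]
std::string fnv1a64_basis_hex() {
  return hex64(FNV64_BASIS);
}

// Hash of every prefix of `bytes` (lengths 1..n), each state computed from
// the previous one by folding in a single byte: O(n) total.
// [[Rcpp::export(name = ".fnv1a64_prefixes_hex")]]
CharacterVector fnv1a64_prefixes_hex(const std::string& bytes) {
  const size_t n = bytes.size();
  CharacterVector out(n);
  uint64_t h = FNV64_BASIS;
  for (size_t i = 0; i < n; ++i) {
    h = (h ^ (uint64_t)(unsigned char) bytes[i]) * FNV64_PRIME;
    out[i] = hex64(h);
  }
  return out;
}

// [[Rcpp::export(name = ".fnv1a64_extend_hex")]]
std::string fnv1a64_extend_hex(const std::string& state_hex,
                               const std::string& bytes) {
  uint64_t h = unhex64(state_hex);
  for (size_t i = 0; i < bytes.size(); ++i) {
    h = (h ^ (uint64_t)(unsigned char) bytes[i]) * FNV64_PRIME;
  }
  return hex64(h);
}
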