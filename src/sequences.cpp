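// Exact integer sequences (Motzkin and the coordination-number-3
// generalization, OEIS A036765) in arbitrary-precision arithmetic.
// Numbers are little-endian limb vectors in base 1e6; limb products fit
// comfortably in 64-bit and convolution sums are normalized after each
// addition, so no intermediate overflow is possible.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>

using Big = std::vector<int64_t>;
static const int64_t BASE = 1000000;

static Big big_from(int64_t v) {
  Big b;
  if (v == 0) b.push_back(0);
  while (v > 0) { b.push_back(v % BASE); v /= BASE; }
  return b;
}

static void big_add_inplace(Big &a, const Big &b) {
  if (b.size() > a.size()) a.resize(b.size(), 0);
  int64_t carry = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    int64_t s = a[i] + (i < b.size() ? b[i] : 0) + carry;
    a[i] = s % BASE;
    carry = s / BASE;
  }
  while (carry > 0) { a.push_back(carry % BASE); carry /= BASE; }
}

static Big big_mul(const Big &a, const Big &b) {
  Big r(a.size() + b.size(), 0);
  for (size_t i = 0; i < a.size(); ++i) {
    if (a[i] == 0) continue;
    int64_t carry = 0;
    for (size_t j = 0; j < b.size(); ++j) {
      int64_t s = r[i + j] + a[i] * b[j] + carry;
      r[i + j] = s % BASE;
      carry = s / BASE;
    }
    size_t k = i + b.size();
    while (carry > 0) {
      int64_t s = r[k] + carry;
      r[k] = s % BASE;
      carry = s / BASE;
      ++k;
    }
  }
  while (r.size() > 1 && r.back() == 0) r.pop_back();
  return r;
}

static std::string big_str(const Big &a) {
  std::string s = std::to_string(a.back());
  char buf[8];
  for (int i = (int)a.size() - 2; i >= 0; --i) {
    snprintf(buf, sizeof(buf), "%06lld", (long long)a[i]);
    s += buf;
  }
  return s;
}

// Generic driver: M1 = M2 = 1;
//   M_i = M_{i-1} + sum_{k=1}^{i-2} M_k M_{i-1-k}
//         + triple_coef * sum_{k=1}^{i-3} sum_{l=1}^{i-k-2} M_k M_l M_{i-k-l-1}
// triple_coef = 0 gives the Motzkin numbers, 1 gives A036765.
// The pair convolution A_m = sum_{k=1}^{m-1} M_k M_{m-k} is cached, so the
// triple sum is sum_{k=1}^{i-3} M_k A_{i-1-k} and the whole run costs
// O(n^2) big multiplications.
static std::vector<Big> seq_driver(int n_terms, int triple_coef) {
  std::vector<Big> M, A(n_terms + 1, big_from(0));
  M.reserve(n_terms);
  for (int i = 0; i < std::min(n_terms, 2); ++i) M.push_back(big_from(1));
  for (int i = 3; i <= n_terms; ++i) {        // 1-based index i
    int m = i - 1;                             // fill A_m
    for (int k = 1; k <= m - 1; ++k)
      big_add_inplace(A[m], big_mul(M[k - 1], M[m - k - 1]));
    Big mi = M[i - 2];                         // M_{i-1}
    big_add_inplace(mi, A[m]);
    if (triple_coef != 0)
      for (int k = 1; k <= i - 3; ++k)
        big_add_inplace(mi, big_mul(M[k - 1], A[i - 1 - k]));
    M.push_back(std::move(mi));
  }
  return M;
}

// [[Rcpp::export(name = ".seq_k3_cpp")]]
Rcpp::CharacterVector seq_k3_cpp(int n_terms, int triple_coef) {
  if (n_terms < 1) Rcpp::stop("n_terms must be >= 1");
  std::vector<Big> M = seq_driver(n_terms, triple_coef);
  Rcpp::CharacterVector out(n_terms);
  for (int i = 0; i < n_terms; ++i) out[i] = big_str(M[i]);
  return out;
}
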