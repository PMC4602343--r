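// Arbitrary-precision evaluation of the expected-cycles series for the
// random transposition walk (Eriksen-Hultman).  The alternating coefficient
// sum cancels catastrophically -- coefficients grow like C(n, n/2) while the
// result is O(n) -- so the series is evaluated in fixed-point arithmetic with
// a caller-chosen number of fractional limbs (base 1e9).  Coefficient
// numerators (products of binomials) are built exactly; the only roundings
// are the two small divisions per coefficient and one per power step, each
// correct to the last limb.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

const uint64_t B9 = 1000000000ULL;

// value = sign * (sum d[i] * B9^i) * B9^{-F}; F is fixed per call
struct FP {
  int sign = 0;                 // -1, 0, +1
  std::vector<uint32_t> d;
  void trim() {
    while (!d.empty() && d.back() == 0) d.pop_back();
    if (d.empty()) sign = 0;
  }
  bool is_zero() const { return sign == 0; }
};

int cmp_abs(const FP& a, const FP& b) {
  if (a.d.size() != b.d.size()) return a.d.size() < b.d.size() ? -1 : 1;
  for (size_t i = a.d.size(); i-- > 0;) {
    if (a.d[i] != b.d[i]) return a.d[i] < b.d[i] ? -1 : 1;
  }
  return 0;
}

std::vector<uint32_t> add_abs(const std::vector<uint32_t>& a,
                              const std::vector<uint32_t>& b) {
  const std::vector<uint32_t>* x = &a;
  const std::vector<uint32_t>* y = &b;
  if (x->size() < y->size()) std::swap(x, y);
  std::vector<uint32_t> r(x->size() + 1, 0);
  uint64_t carry = 0;
  for (size_t i = 0; i < x->size(); ++i) {
    uint64_t s = carry + (*x)[i] + (i < y->size() ? (*y)[i] : 0);
    r[i] = (uint32_t)(s % B9);
    carry = s / B9;
  }
  r[x->size()] = (uint32_t)carry;
  return r;
}

// |a| - |b| assuming |a| >= |b|
std::vector<uint32_t> sub_abs(const std::vector<uint32_t>& a,
                              const std::vector<uint32_t>& b) {
  std::vector<uint32_t> r(a.size(), 0);
  int64_t borrow = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    int64_t s = (int64_t)a[i] - borrow - (i < b.size() ? (int64_t)b[i] : 0);
    if (s < 0) { s += B9; borrow = 1; } else { borrow = 0; }
    r[i] = (uint32_t)s;
  }
  return r;
}

void fp_add_inplace(FP& a, const FP& b) {
  if (b.is_zero()) return;
  if (a.is_zero()) { a = b; return; }
  if (a.sign == b.sign) {
    a.d = add_abs(a.d, b.d);
  } else {
    int c = cmp_abs(a, b);
    if (c == 0) { a.sign = 0; a.d.clear(); return; }
    if (c > 0) {
      a.d = sub_abs(a.d, b.d);
    } else {
      a.d = sub_abs(b.d, a.d);
      a.sign = b.sign;
    }
  }
  a.trim();
}

void mul_small_inplace(FP& a, uint32_t m) {
  if (m == 0) { a.sign = 0; a.d.clear(); return; }
  if (a.is_zero()) return;
  uint64_t carry = 0;
  for (size_t i = 0; i < a.d.size(); ++i) {
    uint64_t s = (uint64_t)a.d[i] * m + carry;
    a.d[i] = (uint32_t)(s % B9);
    carry = s / B9;
  }
  while (carry > 0) {
    a.d.push_back((uint32_t)(carry % B9));
    carry /= B9;
  }
}

// truncated (floor on |.|) division by a small integer
void div_small_inplace(FP& a, uint32_t m) {
  if (a.is_zero()) return;
  uint64_t rem = 0;
  for (size_t i = a.d.size(); i-- > 0;) {
    uint64_t cur = rem * B9 + a.d[i];
    a.d[i] = (uint32_t)(cur / m);
    rem = cur % m;
  }
  a.trim();
}

FP fp_from_int(int64_t v, int F) {
  FP r;
  if (v == 0) return r;
  r.sign = v < 0 ? -1 : 1;
  uint64_t x = v < 0 ? (uint64_t)(-v) : (uint64_t)v;
  r.d.assign(F, 0);
  while (x > 0) {
    r.d.push_back((uint32_t)(x % B9));
    x /= B9;
  }
  return r;
}

// exact integer binomial as raw limbs (F = 0 semantics)
FP binom_big(int64_t n, int64_t k) {
  FP r;
  r.sign = 1;
  r.d.assign(1, 1);
  if (k < 0 || k > n) { r.sign = 0; r.d.clear(); return r; }
  for (int64_t i = 1; i <= k; ++i) {
    mul_small_inplace(r, (uint32_t)(n - k + i));
    div_small_inplace(r, (uint32_t)i);  // exact at every step
  }
  return r;
}

double fp_to_double(const FP& a, int F) {
  if (a.is_zero()) return 0.0;
  size_t h = a.d.size();
  while (h > 0 && a.d[h - 1] == 0) --h;
  if (h == 0) return 0.0;
  size_t lo = h >= 8 ? h - 8 : 0;
  long double acc = 0.0L;
  for (size_t i = h; i-- > lo;) acc = acc * (long double)B9 + a.d[i];
  long double scale = powl(1.0e9L, (long double)((int64_t)lo - (int64_t)F));
  return (double)(a.sign * acc * scale);
}

}  // namespace

// Printed-form series: n - H_n + sum_{p,q} a_pq * base_pq^k for k = 0..kmax.
// a_pq = (-1)^{n-p-q+1} (p-q+1)^2 / ((n-q+1)^2 (n-p)) C(n-p-1, q-1) C(n, p)
// base_pq = (C(p,2) + C(q-1,2) - C(n-p-q+2,2)) / C(n,2)
// [[Rcpp::export]]
NumericVector eh_formula_table_cpp(int n, int kmax, int frac_limbs) {
  if (n < 2) stop("n must be >= 2");
  if (kmax < 0) stop("kmax must be >= 0");
  const int F = frac_limbs;

  // n - H_n
  FP base_val = fp_from_int(n, F);
  for (int i = 1; i <= n; ++i) {
    FP t = fp_from_int(1, F);
    div_small_inplace(t, (uint32_t)i);
    t.sign = -1;
    fp_add_inplace(base_val, t);
  }
  std::vector<FP> res((size_t)kmax + 1, base_val);

  const int64_t C2 = (int64_t)n * (n - 1) / 2;
  auto ch2 = [](int64_t x) { return x >= 2 ? x * (x - 1) / 2 : 0; };

  for (int p = 1; p <= n - 1; ++p) {
    Rcpp::checkUserInterrupt();
    int qmax = std::min(p, n - p);
    // C(n, p) shared across q
    FP cnp = binom_big(n, p);
    for (int q = 1; q <= qmax; ++q) {
      // numerator: C(n-p-1, q-1) * C(n, p) * (p-q+1)^2, built exactly:
      // start from C(n,p) and extend by the partial products of C(n-p-1,q-1)
      FP a = cnp;
      for (int64_t i = 1; i <= q - 1; ++i) {
        mul_small_inplace(a, (uint32_t)(n - p - q + i));
        div_small_inplace(a, (uint32_t)i);  // exact: partial binomial
      }
      int64_t pq1 = (int64_t)(p - q + 1);
      mul_small_inplace(a, (uint32_t)(pq1 * pq1));
      a.sign = ((n - p - q + 1) % 2 == 0) ? 1 : -1;
      // shift to fixed point and divide by (n-q+1)^2 (n-p)
      a.d.insert(a.d.begin(), (size_t)F, 0u);
      uint32_t nq1 = (uint32_t)(n - q + 1);
      div_small_inplace(a, nq1);
      div_small_inplace(a, nq1);
      div_small_inplace(a, (uint32_t)(n - p));

      int64_t b = ch2(p) + ch2(q - 1) - ch2(n - p - q + 2);
      int bsign = b < 0 ? -1 : (b > 0 ? 1 : 0);
      uint64_t bm = b < 0 ? (uint64_t)(-b) : (uint64_t)b;

      if (bsign == 0) {
        fp_add_inplace(res[0], a);  // base^0 = 1, all later powers vanish
        continue;
      }
      FP term = a;
      for (int k = 0; k <= kmax; ++k) {
        fp_add_inplace(res[(size_t)k], term);
        if (term.is_zero()) break;
        if (k < kmax) {
          mul_small_inplace(term, (uint32_t)bm);
          div_small_inplace(term, (uint32_t)C2);
          if (bsign < 0) term.sign = -term.sign;
        }
      }
    }
  }

  NumericVector out(kmax + 1);
  for (int k = 0; k <= kmax; ++k) out[k] = fp_to_double(res[(size_t)k], F);
  return out;
}
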