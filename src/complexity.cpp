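#include <Rcpp.h>
#include <string>
#include <vector>
#include <unordered_map>
#include <cmath>

using namespace Rcpp;

// Lempel-Ziv 1976 exhaustive-history component count, computed with the
// Kaspar-Schuster scan. A component ends when the current extension cannot
// be copied from the prefix seen so far; the final (possibly incomplete)
// component counts as one.
// [[Rcpp::export]]
int lz76_count(const std::string& s) {
  const int n = (int) s.size();
  if (n == 0) stop("empty string");
  if (n == 1) return 1;
  int c = 1;      // components committed (first symbol starts component 1)
  int i = 0;      // start of prefix available for copying
  int k = 1;      // current extension length
  int kmax = 1;   // longest copy found for the current component
  int l = 1;      // start of current component
  while (true) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; } // string exhausted inside a copy: incomplete component
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {              // no prefix position reproduces the extension
        ++c;
        l += kmax;
        if (l + 1 > n) break;    // component ended exactly at the string end
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}

// Lempel-Ziv 1978 incremental-dictionary phrase count. Each phrase is the
// shortest prefix of the remainder not yet in the dictionary; a trailing
// already-seen fragment counts as one final phrase.
// [[Rcpp::export]]
int lz78_count(const std::string& s) {
  const int n = (int) s.size();
  if (n == 0) stop("empty string");
  std::unordered_map<std::string, int> dict;
  dict.reserve(n);
  int c = 0;
  std::string cur;
  for (int i = 0; i < n; ++i) {
    cur.push_back(s[i]);
    if (dict.find(cur) == dict.end()) {
      dict.emplace(cur, 1);
      ++c;
      cur.clear();
    }
  }
  if (!cur.empty()) ++c;  // trailing partial phrase
  return c;
}

// Titchener T-complexity via greedy right-to-left T-decomposition.
// The string is decomposed as p_m^{k_m} ... p_1^{k_1} a, where a is the
// final literal and each pattern p_i is the longest codeword (under the
// T-code built from the steps taken so far) ending at the current boundary.
// T-complexity = sum over steps of log2(k_i + 1), in taugs.
//
// Codeword parse (right to left): one literal, then up to k_1 copies of p_1,
// then up to k_2 copies of p_2, ... up to k_{i-1} copies of p_{i-1}.
// [[Rcpp::export]]
double tcomp_cpp(const std::string& s) {
  const int n = (int) s.size();
  if (n < 2) stop("string length must be >= 2");
  std::vector<std::string> pats;
  std::vector<int> exps;
  double tc = 0.0;
  int end = n - 1;               // s[0..end-1] remains; s[end..] decomposed
  while (end > 0) {
    // greedy parse of one codeword ending at position end-1:
    // literal, then up to exps[l] copies of each earlier pattern, level by level
    int start = end - 1;         // start index of the parsed codeword
    for (size_t l = 0; l < pats.size(); ++l) {
      const std::string& p = pats[l];
      const int plen = (int) p.size();
      int copies = 0;
      while (copies < exps[l] && start - plen >= 0 &&
             s.compare(start - plen, plen, p) == 0) {
        start -= plen;
        ++copies;
      }
    }
    std::string pat = s.substr(start, end - start);
    const int plen = (int) pat.size();
    // total consecutive copies of the new pattern ending at end-1
    int k = 1;
    while (start - plen >= 0 && s.compare(start - plen, plen, pat) == 0) {
      start -= plen;
      ++k;
    }
    pats.push_back(pat);
    exps.push_back(k);
    tc += std::log2((double) k + 1.0);
    end = start;
  }
  return tc;
}

static inline double cheb_dist(const NumericVector& x, int i, int j, int m) {
  double d = 0.0;
  for (int l = 0; l < m; ++l) {
    double a = std::fabs(x[i + l] - x[j + l]);
    if (a > d) d = a;
  }
  return d;
}

// Approximate entropy (Pincus): phi(m) - phi(m+1) with self-matches included,
// Chebyshev distance, absolute tolerance r.
// [[Rcpp::export]]
double apen_cpp(const NumericVector& x, int m, double r) {
  const int n = x.size();
  if (n <= m + 1) stop("series too short for embedding length m");
  double phi[2];
  for (int mm = m; mm <= m + 1; ++mm) {
    const int N = n - mm + 1;
    double acc = 0.0;
    for (int i = 0; i < N; ++i) {
      int cnt = 0;
      for (int j = 0; j < N; ++j) {
        if (cheb_dist(x, i, j, mm) <= r) ++cnt;
      }
      acc += std::log((double) cnt / (double) N);
    }
    phi[mm - m] = acc / (double) N;
  }
  return phi[0] - phi[1];
}

// Sample entropy (Richman & Moorman): -ln(A/B) over distinct template pairs,
// templates of length m (B) and m+1 (A), self-matches excluded.
// Returns NA if B == 0; 0 if A == 0 convention is NOT applied (caller decides).
// [[Rcpp::export]]
List sampen_counts(const NumericVector& x, int m, double r) {
  const int n = x.size();
  if (n <= m + 1) stop("series too short for embedding length m");
  const int N = n - m;  // templates of length m+1: indices 0..N-1; of length m: use same range for fair pairing
  long long A = 0, B = 0;
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      if (cheb_dist(x, i, j, m) <= r) {
        ++B;
        if (std::fabs(x[i + m] - x[j + m]) <= r) ++A;
      }
    }
  }
  return List::create(Named("A") = (double) A, Named("B") = (double) B);
}
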