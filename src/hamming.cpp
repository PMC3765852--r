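#include <Rcpp.h>
using namespace Rcpp;

// All-pairs Hamming distances between equal-length strings. Used as the
// brute-force mapping oracle; intentionally has no shortcuts beyond an early
// exit once the distance can no longer matter (capped at 255).

// [[Rcpp::export]]
IntegerMatrix hamming_matrix(CharacterVector queries, CharacterVector refs) {
  const int nq = queries.size(), nr = refs.size();
  std::vector<std::string> q(nq), r(nr);
  for (int i = 0; i < nq; ++i) q[i] = as<std::string>(queries[i]);
  for (int j = 0; j < nr; ++j) r[j] = as<std::string>(refs[j]);
  IntegerMatrix out(nq, nr);
  for (int i = 0; i < nq; ++i) {
    const std::string &qi = q[i];
    for (int j = 0; j < nr; ++j) {
      const std::string &rj = r[j];
      if (qi.size() != rj.size()) {
        out(i, j) = 255;
        continue;
      }
      int d = 0;
      for (size_t k = 0; k < qi.size() && d < 255; ++k)
        if (qi[k] != rj[k]) ++d;
      out(i, j) = d;
    }
  }
  return out;
}
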