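#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Chi-squared statistics for candidate parental pairs.
// For each pair of parental haplotype combinations (indexed into the
// per-parent gamete supports), builds the error-free expected marker
// genotype classes by adding the mixed-radix dosage keys of the two
// gametes, applies the per-marker +/-1 dosage-error transition matrix,
// pools classes with less than one expected individual together with the
// observed-but-unexpected classes, and returns the Pearson statistic and
// degrees of freedom. Only classes whose expected count can reach 1 need
// exact probabilities: a class at error distance d from every error-free
// class has probability at most eps^d, so rings of +/-1 neighbors are
// added around sufficiently probable classes until n * eps^d < 1;
// everything else is pooled by the complement sums. df = -1 encodes an
// impossible observation with zero pooled expectation (P = 0).
// [[Rcpp::export]]
NumericMatrix score_pairs_cpp(List keys1, List probs1, List keys2, List probs2,
                              IntegerMatrix idx, NumericVector obs_key,
                              NumericVector obs_count, double n, double eps,
                              int ploidy, int nmrk, NumericMatrix Tm) {
  const int b = ploidy + 1;
  std::vector<long long> pw(nmrk);
  pw[0] = 1;
  for (int m = 1; m < nmrk; m++) pw[m] = pw[m - 1] * b;
  int depth = 0;  // neighbor rings needed
  if (eps > 0) {
    double t = n * eps;
    while (t >= 1.0) { depth++; t *= eps; }
  }
  const int np = idx.nrow();
  const int nobs = obs_key.size();
  NumericMatrix out(np, 2);
  std::vector<double> tmflat(b * b);
  for (int i = 0; i < b; i++)
    for (int j = 0; j < b; j++) tmflat[i * b + j] = Tm(i, j);

  std::vector<long long> kb, cand;
  std::vector<double> pb, pc, O;
  std::vector<unsigned char> db, dc;

  for (int r = 0; r < np; r++) {
    NumericVector k1 = keys1[idx(r, 0) - 1], p1 = probs1[idx(r, 0) - 1];
    NumericVector k2 = keys2[idx(r, 1) - 1], p2 = probs2[idx(r, 1) - 1];
    std::unordered_map<long long, double> base;
    for (int i = 0; i < k1.size(); i++)
      for (int j = 0; j < k2.size(); j++)
        base[(long long)(k1[i] + k2[j])] += p1[i] * p2[j];

    kb.clear(); pb.clear();
    for (std::unordered_map<long long, double>::iterator it = base.begin();
         it != base.end(); ++it) {
      kb.push_back(it->first);
      pb.push_back(it->second);
    }
    const int B = (int)kb.size();

    // candidate classes that could reach one expected individual
    std::unordered_map<long long, int> candidx;
    cand.clear();
    for (int i = 0; i < B; i++) {
      candidx[kb[i]] = (int)cand.size();
      cand.push_back(kb[i]);
    }
    if (depth > 0) {
      // ring d neighbors of classes with pb >= 1 / (n * eps^d)
      size_t ring_lo = 0, ring_hi = cand.size();
      double thr = 1.0 / (n * eps);
      for (int d = 1; d <= depth; d++) {
        for (size_t ci = ring_lo; ci < ring_hi; ci++) {
          long long kk = cand[ci];
          // source probability bound: base classes use pb; later rings
          // are kept unconditionally (they are few)
          if (d == 1) {
            std::unordered_map<long long, double>::iterator it = base.find(kk);
            if (it == base.end() || it->second < thr) continue;
          }
          for (int m = 0; m < nmrk; m++) {
            int dig = (int)((kk / pw[m]) % b);
            if (dig < ploidy) {
              long long nb = kk + pw[m];
              if (!candidx.count(nb)) { candidx[nb] = (int)cand.size(); cand.push_back(nb); }
            }
            if (dig > 0) {
              long long nb = kk - pw[m];
              if (!candidx.count(nb)) { candidx[nb] = (int)cand.size(); cand.push_back(nb); }
            }
          }
        }
        ring_lo = ring_hi;
        ring_hi = cand.size();
        thr /= eps;
      }
    }
    const int C = (int)cand.size();

    // digit tables, computed once per pair
    db.assign((size_t)B * nmrk, 0);
    dc.assign((size_t)C * nmrk, 0);
    for (int i = 0; i < B; i++) {
      long long k = kb[i];
      for (int m = 0; m < nmrk; m++) { db[(size_t)i * nmrk + m] = (unsigned char)(k % b); k /= b; }
    }
    for (int c = 0; c < C; c++) {
      long long k = cand[c];
      for (int m = 0; m < nmrk; m++) { dc[(size_t)c * nmrk + m] = (unsigned char)(k % b); k /= b; }
    }

    pc.assign(C, 0.0);
    for (int i = 0; i < B; i++) {
      const unsigned char *di = &db[(size_t)i * nmrk];
      const double pbi = pb[i];
      for (int c = 0; c < C; c++) {
        const unsigned char *dj = &dc[(size_t)c * nmrk];
        double t = tmflat[di[0] * b + dj[0]];
        for (int m = 1; m < nmrk; m++) t *= tmflat[di[m] * b + dj[m]];
        pc[c] += pbi * t;
      }
    }

    O.assign(C, 0.0);
    for (int o = 0; o < nobs; o++) {
      std::unordered_map<long long, int>::iterator it =
        candidx.find((long long)obs_key[o]);
      if (it != candidx.end()) O[it->second] = obs_count[o];
    }
    double stat = 0.0, Ekept = 0.0, Okept = 0.0;
    int ncat = 0;
    for (int c = 0; c < C; c++) {
      double E = n * pc[c];
      if (E >= 1.0) {
        stat += (O[c] - E) * (O[c] - E) / E;
        Ekept += E; Okept += O[c]; ncat++;
      }
    }
    double Epool = n - Ekept, Opool = n - Okept;
    if (Epool > 1e-12 || Opool > 0) {
      if (Epool <= 1e-12) { out(r, 0) = R_PosInf; out(r, 1) = -1.0; continue; }
      stat += (Opool - Epool) * (Opool - Epool) / Epool;
      ncat++;
    }
    out(r, 0) = stat;
    out(r, 1) = ncat - 1 > 1 ? ncat - 1 : 1;
  }
  return out;
}
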