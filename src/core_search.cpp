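#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Nearest-entry bookkeeping: for every accession i we track the two smallest
// distances to current core members, *including* i itself when i is a member
// (d(i,i) = 0). A-NE then uses the first minimum (members contribute 0) and
// E-NE, for a member, the second minimum (its nearest other entry).

static inline void two_smallest(const double* d, int n, int i,
                                const std::vector<int>& members,
                                int skip, int add,
                                double& d1, int& i1, double& d2, int& i2) {
  d1 = R_PosInf; d2 = R_PosInf; i1 = -1; i2 = -1;
  const double* row = d + (size_t)i * n; // symmetric: column == row
  for (size_t m = 0; m < members.size(); ++m) {
    int e = members[m];
    if (e == skip) continue;
    double v = row[e];
    if (v < d1) { d2 = d1; i2 = i1; d1 = v; i1 = e; }
    else if (v < d2) { d2 = v; i2 = e; }
  }
  if (add >= 0) {
    double v = row[add];
    if (v < d1) { d2 = d1; i2 = i1; d1 = v; i1 = add; }
    else if (v < d2) { d2 = v; i2 = add; }
  }
}

// [[Rcpp::export]]
NumericVector cpp_core_objective(NumericMatrix dmat, IntegerVector core0) {
  int n = dmat.nrow();
  int k = core0.size();
  const double* d = dmat.begin();
  std::vector<int> members(core0.begin(), core0.end());
  double ane = 0.0, ene = 0.0, ee = 0.0;
  for (int i = 0; i < n; ++i) {
    double d1, d2; int i1, i2;
    two_smallest(d, n, i, members, -1, -1, d1, i1, d2, i2);
    ane += d1;
  }
  ane /= n;
  if (k >= 2) {
    for (int m = 0; m < k; ++m) {
      const double* row = d + (size_t)members[m] * n;
      double best = R_PosInf;
      for (int m2 = 0; m2 < k; ++m2) {
        if (m2 == m) continue;
        double v = row[members[m2]];
        best = std::min(best, v);
        if (m2 > m) ee += v;
      }
      ene += best;
    }
    ene /= k;
    ee /= (double)k * (k - 1) / 2.0;
  } else {
    ene = NA_REAL;
    ee = NA_REAL;
  }
  return NumericVector::create(ene, ane, ee);
}

// Random-descent single-swap local search maximizing
// a_en * E-NE - a_an * A-NE. A proposal is evaluated read-only from the
// cached nearest/second-nearest tables (full rescans only for the few
// accessions whose cached neighbours involve the leaving entry); the tables
// are rebuilt only on acceptance, which is rare. Stops after `budget`
// consecutive non-improving proposals or `max_proposals` in total. Uses R's
// RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_local_search(NumericMatrix dmat, IntegerVector init0,
                      IntegerVector forced0, double a_en, double a_an,
                      int budget, int max_proposals) {
  int n = dmat.nrow();
  int k = init0.size();
  const double* d = dmat.begin();

  std::vector<bool> forced(n, false);
  std::vector<int> members(init0.begin(), init0.end());
  for (int f : forced0) forced[f] = true;
  std::vector<bool> in_core(n, false);
  for (int m : members) in_core[m] = true;
  std::vector<int> outside;
  outside.reserve(n - k);
  for (int i = 0; i < n; ++i) if (!in_core[i]) outside.push_back(i);

  std::vector<double> d1(n), d2(n);
  std::vector<int> i1(n), i2(n);
  auto rebuild = [&]() {
    for (int i = 0; i < n; ++i)
      two_smallest(d, n, i, members, -1, -1, d1[i], i1[i], d2[i], i2[i]);
  };
  rebuild();
  auto objective_full = [&]() {
    double ane = 0.0, ene = 0.0;
    for (int i = 0; i < n; ++i) ane += d1[i];
    for (int m : members) ene += d2[m];
    ane /= n;
    ene = (k >= 2) ? ene / k : 0.0;
    return a_en * ene - a_an * ane;
  };
  double cur_obj = objective_full();

  int swappable = 0;
  for (int m : members) if (!forced[m]) ++swappable;
  if (swappable == 0 || outside.empty()) {
    return List::create(_["members"] = IntegerVector(members.begin(), members.end()),
                        _["objective"] = cur_obj);
  }

  int fails = 0, proposals = 0;
  double td1, td2; int ti1, ti2;
  while (fails < budget && proposals < max_proposals) {
    ++proposals;
    int rpos;
    do { rpos = (int)(unif_rand() * k); if (rpos >= k) rpos = k - 1; }
    while (forced[members[rpos]]);
    int apos = (int)(unif_rand() * outside.size());
    if (apos >= (int)outside.size()) apos = outside.size() - 1;
    int r = members[rpos], a = outside[apos];
    const double* da = d + (size_t)a * n;
    const double* dr = d + (size_t)r * n;

    // nearest entry of r (now outside) and nearest other entry of a
    double r_d1 = da[r], a_no = R_PosInf;
    for (int m : members) {
      if (m == r) continue;
      r_d1 = std::min(r_d1, dr[m]);
      a_no = std::min(a_no, da[m]);
    }
    double anes = r_d1; // accession r contribution; a contributes 0
    for (int i = 0; i < n; ++i) {
      if (i == r || i == a) continue;
      double v1;
      if (i1[i] == r) {
        two_smallest(d, n, i, members, r, a, td1, ti1, td2, ti2);
        v1 = td1;
      } else {
        v1 = std::min(d1[i], da[i]);
      }
      anes += v1;
    }
    double enes = a_no;
    for (int m : members) {
      if (m == r) continue;
      double no;
      if (i1[m] == r || i2[m] == r) {
        two_smallest(d, n, m, members, r, a, td1, ti1, td2, ti2);
        no = td2;
      } else {
        no = std::min(d2[m], da[m]);
      }
      enes += no;
    }
    double ane = anes / n;
    double ene = (k >= 2) ? enes / k : 0.0;
    double new_obj = a_en * ene - a_an * ane;
    if (new_obj > cur_obj + 1e-12) {
      members[rpos] = a;
      outside[apos] = r;
      in_core[r] = false;
      in_core[a] = true;
      rebuild();
      cur_obj = objective_full();
      fails = 0;
    } else {
      ++fails;
    }
  }
  return List::create(_["members"] = IntegerVector(members.begin(), members.end()),
                      _["objective"] = cur_obj);
}
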