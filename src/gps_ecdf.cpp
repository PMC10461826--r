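// Fast bivariate empirical-CDF backends and permutation loops for the GPS
// and Hoeffding tests. All joint counts are exact integers (#{j : u_j <= u_i
// and v_j <= v_i}); division by n happens at the R boundary or the last
// moment, so backends can be compared bitwise on counts.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

// Fenwick (binary indexed) tree over 1..n, prefix-sum counts.
struct Fenwick {
  std::vector<int> t;
  int n;
  explicit Fenwick(int n_) : t(n_ + 1, 0), n(n_) {}
  void reset() { std::fill(t.begin(), t.end(), 0); }
  void add(int i) {
    for (; i <= n; i += i & (-i)) t[i]++;
  }
  int sum(int i) const {  // count of inserted ranks <= i
    int s = 0;
    for (; i > 0; i -= i & (-i)) s += t[i];
    return s;
  }
};

// Dense ranks 1..m with ties sharing a rank; input need not be sorted.
std::vector<int> dense_rank(const NumericVector& x) {
  const int n = x.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  std::vector<int> r(n);
  int rank = 0;
  for (int k = 0; k < n; ++k) {
    if (k == 0 || x[ord[k]] > x[ord[k - 1]]) ++rank;
    r[ord[k]] = rank;
  }
  return r;
}

// Indices 0..n-1 sorted ascending by x, plus tie-group boundaries:
// groups[g] is the first position of group g in ord, groups.back() == n.
void order_groups(const NumericVector& x, std::vector<int>& ord,
                  std::vector<int>& groups) {
  const int n = x.size();
  ord.resize(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  groups.clear();
  groups.push_back(0);
  for (int k = 1; k < n; ++k)
    if (x[ord[k]] > x[ord[k - 1]]) groups.push_back(k);
  groups.push_back(n);
}

// Marginal "count <=" (maximal rank under ties) from a sort.
std::vector<int> le_count(const NumericVector& x) {
  std::vector<int> ord, groups;
  order_groups(x, ord, groups);
  const int n = x.size();
  std::vector<int> c(n);
  for (size_t g = 0; g + 1 < groups.size(); ++g) {
    int end = groups[g + 1];  // one past last member; count <= is end
    for (int k = groups[g]; k < end; ++k) c[ord[k]] = end;
  }
  return c;
}

// Tree backend on precomputed u-order/groups and v dense ranks (1..m).
// Tied u-groups are inserted wholesale before any member is queried so that
// u_j <= u_i holds for tied j.
void joint_tree_core(const std::vector<int>& uord,
                     const std::vector<int>& ugroups,
                     const int* vdr, int m, Fenwick& fen,
                     std::vector<int>& out) {
  fen.reset();
  for (size_t g = 0; g + 1 < ugroups.size(); ++g) {
    for (int k = ugroups[g]; k < ugroups[g + 1]; ++k)
      fen.add(vdr[uord[k]]);
    for (int k = ugroups[g]; k < ugroups[g + 1]; ++k) {
      int i = uord[k];
      out[i] = fen.sum(vdr[i]);
    }
  }
}

// Divide-and-conquer backend: counts the strict-u part
// #{j : u_j < u_i and v_j <= v_i} by recursive splitting on dense u-rank
// (so the two halves are strictly separated in u), merging v-sorted halves
// with a two-pointer sweep; the tied-u part is added per u-group.
void cdq(std::vector<int>& idx, int ulo, int uhi,
         const std::vector<int>& ur, const std::vector<int>& vr,
         std::vector<int>& cnt) {
  if (ulo >= uhi || idx.empty()) return;
  int mid = ulo + (uhi - ulo) / 2;
  std::vector<int> L, R;
  L.reserve(idx.size());
  R.reserve(idx.size());
  for (int i : idx) (ur[i] <= mid ? L : R).push_back(i);  // stable in v
  size_t lpos = 0;
  for (int r : R) {
    while (lpos < L.size() && vr[L[lpos]] <= vr[r]) ++lpos;
    cnt[r] += static_cast<int>(lpos);
  }
  idx.clear();
  idx.shrink_to_fit();
  cdq(L, ulo, mid, ur, vr, cnt);
  cdq(R, mid + 1, uhi, ur, vr, cnt);
}

std::vector<int> joint_dac_core(const NumericVector& u,
                                const NumericVector& v) {
  const int n = u.size();
  std::vector<int> ur = dense_rank(u), vr = dense_rank(v);
  int umax = *std::max_element(ur.begin(), ur.end());
  std::vector<int> byv(n);
  for (int i = 0; i < n; ++i) byv[i] = i;
  std::stable_sort(byv.begin(), byv.end(),
                   [&](int a, int b) { return vr[a] < vr[b]; });
  std::vector<int> cnt(n, 0);
  cdq(byv, 1, umax, ur, vr, cnt);
  // tied-u contribution, including self: within each u-group count v <=
  std::vector<int> uord, ugroups;
  order_groups(u, uord, ugroups);
  for (size_t g = 0; g + 1 < ugroups.size(); ++g) {
    std::vector<int> mem(uord.begin() + ugroups[g],
                         uord.begin() + ugroups[g + 1]);
    std::sort(mem.begin(), mem.end(),
              [&](int a, int b) { return vr[a] < vr[b]; });
    size_t k = 0;
    while (k < mem.size()) {
      size_t e = k;
      while (e + 1 < mem.size() && vr[mem[e + 1]] == vr[mem[k]]) ++e;
      for (size_t q = k; q <= e; ++q) cnt[mem[q]] += static_cast<int>(e) + 1;
      k = e + 1;
    }
  }
  return cnt;
}

void check_pair(const NumericVector& u, const NumericVector& v) {
  if (u.size() != v.size())
    stop("u and v must have equal length (got %d and %d)",
         (int)u.size(), (int)v.size());
  for (int i = 0; i < u.size(); ++i) {
    if (!R_finite(u[i]))
      stop("non-finite value in u at index %d", i + 1);
    if (!R_finite(v[i]))
      stop("non-finite value in v at index %d", i + 1);
  }
}

std::vector<int> joint_counts(const NumericVector& u, const NumericVector& v,
                              const std::string& backend) {
  const int n = u.size();
  if (backend == "naive") {
    std::vector<int> cnt(n, 0);
    for (int i = 0; i < n; ++i) {
      int c = 0;
      for (int j = 0; j < n; ++j)
        if (u[j] <= u[i] && v[j] <= v[i]) ++c;
      cnt[i] = c;
    }
    return cnt;
  } else if (backend == "tree") {
    std::vector<int> uord, ugroups;
    order_groups(u, uord, ugroups);
    std::vector<int> vdr = dense_rank(v);
    int m = *std::max_element(vdr.begin(), vdr.end());
    Fenwick fen(m);
    std::vector<int> cnt(n, 0);
    joint_tree_core(uord, ugroups, vdr.data(), m, fen, cnt);
    return cnt;
  } else if (backend == "dac") {
    return joint_dac_core(u, v);
  }
  stop("unknown backend '%s' (use 'naive', 'tree' or 'dac')",
       backend.c_str());
}

// Weighted sup-norm statistic from integer counts. Points with
// cu*cv == n^2 (radicand <= 0) are excluded and counted. Smallest index
// wins arg-max ties. Returns D scaled by sqrt(n / ln n).
struct GpsMax {
  double D;
  int argmax;      // 0-based, -1 if all excluded
  int n_excluded;
};

GpsMax gps_max(const std::vector<int>& cu, const std::vector<int>& cv,
               const std::vector<int>& cj, int n) {
  const double dn = static_cast<double>(n);
  const double n2 = dn * dn;
  const double w = std::sqrt(dn / std::log(dn));
  GpsMax res{-1.0, -1, 0};
  for (int i = 0; i < n; ++i) {
    double prod = static_cast<double>(cu[i]) * static_cast<double>(cv[i]);
    if (prod >= n2) {  // F_u * F_v == 1: 0/0 point, excluded
      res.n_excluded++;
      continue;
    }
    double F = prod / n2;
    double num = std::fabs(static_cast<double>(cj[i]) / dn - F);
    double t = w * num / std::sqrt(F - F * F);
    if (t > res.D) {
      res.D = t;
      res.argmax = i;
    }
  }
  return res;
}

// ---- Hoeffding machinery ------------------------------------------------
// c_i = #{j != i : u_j < u_i, v_j < v_i} with ties contributing 1/2 per
// tied coordinate (1/4 when tied on both); computed exactly in quarter
// units with two-stage Fenwick queries (strict-less and equal v ranks).
void hoeffding_c4(const std::vector<int>& uord,
                  const std::vector<int>& ugroups,
                  const int* vdr, int m, Fenwick& fen,
                  std::vector<int64_t>& c4) {
  fen.reset();
  const size_t G = ugroups.size() - 1;
  std::vector<int> mem;
  for (size_t g = 0; g < G; ++g) {
    // strict-u contributions (everything already inserted has u_j < u_i)
    for (int k = ugroups[g]; k < ugroups[g + 1]; ++k) {
      int i = uord[k];
      int less = fen.sum(vdr[i] - 1);
      int leq = fen.sum(vdr[i]);
      c4[i] += 4LL * less + 2LL * (leq - less);
    }
    // tied-u contributions within the group
    mem.assign(uord.begin() + ugroups[g], uord.begin() + ugroups[g + 1]);
    if (mem.size() > 1) {
      std::sort(mem.begin(), mem.end(),
                [&](int a, int b) { return vdr[a] < vdr[b]; });
      size_t k = 0;
      while (k < mem.size()) {
        size_t e = k;
        while (e + 1 < mem.size() && vdr[mem[e + 1]] == vdr[mem[k]]) ++e;
        int64_t nless = static_cast<int64_t>(k);
        int64_t neq = static_cast<int64_t>(e - k + 1) - 1;  // excl. self
        for (size_t q = k; q <= e; ++q)
          c4[mem[q]] += 2LL * nless + 1LL * neq;
        k = e + 1;
      }
    }
    for (int k = ugroups[g]; k < ugroups[g + 1]; ++k) fen.add(vdr[uord[k]]);
  }
}

double hoeffding_from_parts(const std::vector<double>& R,
                            const std::vector<double>& S,
                            const std::vector<int64_t>& c4, int n) {
  double D1 = 0, D2 = 0, D3 = 0;
  for (int i = 0; i < n; ++i) {
    double c = static_cast<double>(c4[i]) / 4.0;
    D1 += c * (c - 1.0);
    D2 += (R[i] - 1) * (R[i] - 2) * (S[i] - 1) * (S[i] - 2);
    D3 += (R[i] - 2) * (S[i] - 2) * c;
  }
  double dn = n;
  double denom = dn * (dn - 1) * (dn - 2) * (dn - 3) * (dn - 4);
  return 30.0 * ((dn - 2) * (dn - 3) * D1 + D2 - 2 * (dn - 2) * D3) / denom;
}

std::vector<double> midrank(const NumericVector& x) {
  std::vector<int> ord, groups;
  order_groups(x, ord, groups);
  std::vector<double> r(x.size());
  for (size_t g = 0; g + 1 < groups.size(); ++g) {
    double mr = (groups[g] + 1 + groups[g + 1]) / 2.0;  // mean of ranks
    for (int k = groups[g]; k < groups[g + 1]; ++k) r[ord[k]] = mr;
  }
  return r;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".joint_count_cpp")]]
IntegerVector joint_count_cpp(NumericVector u, NumericVector v,
                              std::string backend) {
  check_pair(u, v);
  std::vector<int> cnt = joint_counts(u, v, backend);
  return IntegerVector(cnt.begin(), cnt.end());
}

//' @noRd
// [[Rcpp::export(name = ".gps_stat_cpp")]]
List gps_stat_cpp(NumericVector u, NumericVector v, std::string backend) {
  check_pair(u, v);
  const int n = u.size();
  std::vector<int> cu = le_count(u), cv = le_count(v);
  std::vector<int> cj = joint_counts(u, v, backend);
  GpsMax m = gps_max(cu, cv, cj, n);
  if (m.argmax < 0)
    stop("degenerate input: all evaluation points have F_u * F_v = 1 (both vectors constant)");
  return List::create(
      _["D"] = m.D, _["argmax_index"] = m.argmax + 1,
      _["F_u"] = static_cast<double>(cu[m.argmax]) / n,
      _["F_v"] = static_cast<double>(cv[m.argmax]) / n,
      _["F_uv"] = static_cast<double>(cj[m.argmax]) / n,
      _["n_used"] = n - m.n_excluded, _["n_excluded"] = m.n_excluded);
}

//' @noRd
// [[Rcpp::export(name = ".gps_perm_null_cpp")]]
NumericVector gps_perm_null_cpp(NumericVector u, NumericVector v,
                                int n_perm, std::string backend) {
  check_pair(u, v);
  const int n = u.size();
  std::vector<int> uord, ugroups;
  order_groups(u, uord, ugroups);
  std::vector<int> cu = le_count(u), cvc = le_count(v);
  std::vector<int> vdr = dense_rank(v);
  int mmax = *std::max_element(vdr.begin(), vdr.end());
  Fenwick fen(mmax);
  std::vector<int> vdr_p(n), cv_p(n), cj(n);
  NumericVector out(n_perm);
  for (int r = 0; r < n_perm; ++r) {
    IntegerVector perm = Rcpp::sample(n, n, false);  // R RNG, 1-based
    for (int i = 0; i < n; ++i) {
      int s = perm[i] - 1;
      vdr_p[i] = vdr[s];
      cv_p[i] = cvc[s];
    }
    if (backend == "tree") {
      joint_tree_core(uord, ugroups, vdr_p.data(), mmax, fen, cj);
    } else {
      NumericVector vp(n);
      for (int i = 0; i < n; ++i) vp[i] = v[perm[i] - 1];
      std::vector<int> cnt = joint_counts(u, vp, backend);
      std::copy(cnt.begin(), cnt.end(), cj.begin());
    }
    GpsMax m = gps_max(cu, cv_p, cj, n);
    if (m.argmax < 0)
      stop("degenerate input: all evaluation points have F_u * F_v = 1");
    out[r] = m.D;
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".hoeffding_stat_cpp")]]
double hoeffding_stat_cpp(NumericVector u, NumericVector v) {
  check_pair(u, v);
  const int n = u.size();
  if (n < 5) stop("Hoeffding's statistic requires n >= 5");
  std::vector<int> uord, ugroups;
  order_groups(u, uord, ugroups);
  std::vector<int> vdr = dense_rank(v);
  int m = *std::max_element(vdr.begin(), vdr.end());
  Fenwick fen(m);
  std::vector<int64_t> c4(n, 0);
  hoeffding_c4(uord, ugroups, vdr.data(), m, fen, c4);
  std::vector<double> R = midrank(u), S = midrank(v);
  return hoeffding_from_parts(R, S, c4, n);
}

//' @noRd
// [[Rcpp::export(name = ".hoeffding_perm_null_cpp")]]
NumericVector hoeffding_perm_null_cpp(NumericVector u, NumericVector v,
                                      int n_perm) {
  check_pair(u, v);
  const int n = u.size();
  if (n < 5) stop("Hoeffding's statistic requires n >= 5");
  std::vector<int> uord, ugroups;
  order_groups(u, uord, ugroups);
  std::vector<int> vdr = dense_rank(v);
  int m = *std::max_element(vdr.begin(), vdr.end());
  Fenwick fen(m);
  std::vector<double> R = midrank(u), S = midrank(v);
  std::vector<int> vdr_p(n);
  std::vector<double> S_p(n);
  std::vector<int64_t> c4(n);
  NumericVector out(n_perm);
  for (int r = 0; r < n_perm; ++r) {
    IntegerVector perm = Rcpp::sample(n, n, false);
    for (int i = 0; i < n; ++i) {
      int s = perm[i] - 1;
      vdr_p[i] = vdr[s];
      S_p[i] = S[s];
    }
    std::fill(c4.begin(), c4.end(), 0);
    hoeffding_c4(uord, ugroups, vdr_p.data(), m, fen, c4);
    out[r] = hoeffding_from_parts(R, S_p, c4, n);
  }
  return out;
}
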