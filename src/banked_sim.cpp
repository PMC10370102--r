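// Banked-trajectory simulation for the RMSE objective: walks the merged
// error chain using the pre-drawn uniform bank (inverse-CDF sampling with a
// parameter-independent draw order) and reduces each timepoint through the
// cached emission-classification table. Bit-identical to the R reference
// path in simulate_core_banked() + banked_tracks().

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List banked_traj_cpp(List u, NumericVector gpar, NumericMatrix dud_thr,
                     List loss_thr, IntegerMatrix rem, IntegerVector poschan,
                     List khat, int n, int C, int Tn, IntegerVector L) {
  const double e = gpar[0], p = gpar[1], b = gpar[2], c = gpar[3];
  IntegerMatrix tracks(n, (Tn + 1) * C);

  std::vector<const double*> uptr(u.size());
  for (int i = 0; i < u.size(); ++i) uptr[i] = REAL(static_cast<SEXP>(u[i]));
  std::vector<const int*> kh(C);
  for (int ch = 0; ch < C; ++ch) kh[ch] = INTEGER(static_cast<SEXP>(khat[ch]));
  std::vector<const double*> lthr(C);
  std::vector<int> lthr_nrow(C);
  for (int ch = 0; ch < C; ++ch) {
    NumericMatrix m = loss_thr[ch];
    lthr[ch] = m.begin();
    lthr_nrow[ch] = m.nrow();
  }

  std::vector<int> k(static_cast<size_t>(n) * C);
  std::vector<char> blocked(n), detached(n);
  std::vector<int> nED(n, 0);

  int ui = 0;
  // dud realization
  for (int ch = 0; ch < C; ++ch) {
    const double* uu = uptr[ui++];
    for (int r = 0; r < n; ++r) {
      int x = 0;
      for (int j = 0; j < L[ch]; ++j) x += uu[r] > dud_thr(ch, j);
      k[static_cast<size_t>(ch) * n + r] = x;
    }
  }
  std::vector<int> invisible;
  for (int r = 0; r < n; ++r) {
    int tot = 0;
    for (int ch = 0; ch < C; ++ch) tot += k[static_cast<size_t>(ch) * n + r];
    if (tot == 0) invisible.push_back(r + 1);
  }
  // initial block
  {
    const double* uu = uptr[ui++];
    for (int r = 0; r < n; ++r) blocked[r] = uu[r] < b;
  }
  // timepoint 0 reduction
  const size_t tp = Tn + 1;
  for (int ch = 0; ch < C; ++ch) {
    for (int r = 0; r < n; ++r) {
      const int kk = k[static_cast<size_t>(ch) * n + r];
      tracks(r, ch * tp) = kh[ch][static_cast<size_t>(kk) * tp * n + r];
    }
  }

  for (int t = 1; t <= Tn; ++t) {
    const double* u_c = uptr[ui++];
    const double* u_p = uptr[ui++];
    std::vector<const double*> u_l(C);
    for (int ch = 0; ch < C; ++ch) u_l[ch] = uptr[ui++];
    const double* u_a = uptr[ui++];
    const double* u_d = uptr[ui++];

    for (int r = 0; r < n; ++r) {
      if (!detached[r] && !blocked[r] && u_c[r] < c) blocked[r] = 1;
      if (!detached[r] && u_p[r] < p) {
        detached[r] = 1;
        for (int ch = 0; ch < C; ++ch) k[static_cast<size_t>(ch) * n + r] = 0;
      }
      for (int ch = 0; ch < C; ++ch) {
        const int kv = k[static_cast<size_t>(ch) * n + r];
        if (kv > 0) {
          int x = 0;
          const double uu = u_l[ch][r];
          // row kv of the channel's threshold matrix holds pbinom(0:(kv-1))
          for (int j = 0; j < kv; ++j) {
            x += uu > lthr[ch][static_cast<size_t>(j) * lthr_nrow[ch] + kv];
          }
          k[static_cast<size_t>(ch) * n + r] = x;
        }
      }
      if (!blocked[r] && !detached[r] && nED[r] < Tn && u_a[r] < 1.0 - e) {
        const int pos = nED[r] + 1;
        const int ch = poschan[pos - 1];
        if (ch > 0) {
          const int R = rem(ch - 1, nED[r]);
          const int kv = k[static_cast<size_t>(ch - 1) * n + r];
          if (R > 0 && u_d[r] < static_cast<double>(kv) / R) {
            k[static_cast<size_t>(ch - 1) * n + r] = kv - 1;
          }
        }
        nED[r] += 1;
      }
      for (int ch = 0; ch < C; ++ch) {
        const int kk = k[static_cast<size_t>(ch) * n + r];
        tracks(r, ch * tp + t) =
          kh[ch][static_cast<size_t>(kk) * tp * n + t * static_cast<size_t>(n) + r];
      }
    }
  }

  return List::create(
    _["tracks"] = tracks,
    _["invisible"] = wrap(invisible)
  );
}
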