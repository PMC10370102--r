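// Full E-step driver: chunked forward/backward over all reads with
// preallocated buffers, returning per-read log-likelihoods and the
// column sums (over reads) of the state posteriors at every sub-step
// boundary. The tied-parameter M-step needs only those aggregates.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct SparseFac {
  const int* i;
  const int* p;
  const double* x;
  int ncol;
};

// out (n x S) = in (n x S) %*% M (CSC)
inline void apply_factor(const double* in, double* out, int n,
                         const SparseFac& f) {
  for (int j = 0; j < f.ncol; ++j) {
    double* outj = out + static_cast<size_t>(j) * n;
    int idx = f.p[j];
    const int end = f.p[j + 1];
    if (idx == end) {
      std::fill(outj, outj + n, 0.0);
      continue;
    }
    {
      const double v = f.x[idx];
      const double* inj = in + static_cast<size_t>(f.i[idx]) * n;
      for (int r = 0; r < n; ++r) outj[r] = v * inj[r];
      ++idx;
    }
    for (; idx < end; ++idx) {
      const double v = f.x[idx];
      const double* inj = in + static_cast<size_t>(f.i[idx]) * n;
      for (int r = 0; r < n; ++r) outj[r] += v * inj[r];
    }
  }
}

} // namespace

// [[Rcpp::export]]
List hmm_estep_cpp(NumericVector pi0, List fwd, List bwd, IntegerVector em_t,
                   List dens, IntegerVector kindex, int n_reads,
                   int chunk_size) {
  const int S = pi0.size();
  const int n_ops = fwd.size();
  const int n_bound = n_ops + 1;

  std::vector<SparseFac> ffac(n_ops), bfac(n_ops);
  std::vector<const double*> dptr(dens.size());
  for (int d = 0; d < dens.size(); ++d) {
    dptr[d] = REAL(static_cast<SEXP>(dens[d]));
  }
  for (int oi = 0; oi < n_ops; ++oi) {
    if (em_t[oi] >= 0) continue;
    List f = fwd[oi], b = bwd[oi];
    IntegerVector fi = f["i"], fp = f["p"];
    NumericVector fx = f["x"];
    ffac[oi] = {fi.begin(), fp.begin(), fx.begin(), static_cast<int>(f["nc"])};
    IntegerVector bi = b["i"], bp = b["p"];
    NumericVector bx = b["x"];
    bfac[oi] = {bi.begin(), bp.begin(), bx.begin(), static_cast<int>(b["nc"])};
  }

  NumericVector loglik(n_reads);
  NumericMatrix margsum(S, n_bound);
  const int nc = chunk_size;
  std::vector<double> astore(static_cast<size_t>(nc) * S * n_bound);
  std::vector<double> bbuf(static_cast<size_t>(nc) * S);
  std::vector<double> bbuf2(static_cast<size_t>(nc) * S);
  std::vector<std::vector<double>> scales(n_ops);
  for (int oi = 0; oi < n_ops; ++oi) {
    if (em_t[oi] >= 0) scales[oi].resize(nc);
  }

  for (int r0 = 0; r0 < n_reads; r0 += nc) {
    const int n = std::min(nc, n_reads - r0);
    const size_t slab = static_cast<size_t>(n) * S;

    double* A = astore.data();
    for (int s = 0; s < S; ++s) {
      std::fill(A + static_cast<size_t>(s) * n,
                A + static_cast<size_t>(s + 1) * n, pi0[s]);
    }
    for (int oi = 0; oi < n_ops; ++oi) {
      const double* in = astore.data() + slab * oi;
      double* out = astore.data() + slab * (oi + 1);
      if (em_t[oi] < 0) {
        apply_factor(in, out, n, ffac[oi]);
      } else {
        const double* D = dptr[em_t[oi]];
        double* sc = scales[oi].data();
        std::fill(sc, sc + n, 0.0);
        for (int s = 0; s < S; ++s) {
          const double* dj = D + static_cast<size_t>(kindex[s] - 1) * n_reads + r0;
          const double* inj = in + static_cast<size_t>(s) * n;
          double* outj = out + static_cast<size_t>(s) * n;
          for (int r = 0; r < n; ++r) {
            const double v = inj[r] * dj[r];
            outj[r] = v;
            sc[r] += v;
          }
        }
        for (int s = 0; s < S; ++s) {
          double* outj = out + static_cast<size_t>(s) * n;
          for (int r = 0; r < n; ++r) outj[r] /= sc[r];
        }
        for (int r = 0; r < n; ++r) loglik[r0 + r] += std::log(sc[r]);
      }
    }

    double* B = bbuf.data();
    double* Bnext = bbuf2.data();
    std::fill(B, B + slab, 1.0);
    for (int oi = n_ops; oi >= 0; --oi) {
      // accumulate marginals at boundary oi (alpha at slab oi times beta)
      const double* Aj = astore.data() + slab * oi;
      for (int s = 0; s < S; ++s) {
        const double* aj = Aj + static_cast<size_t>(s) * n;
        const double* bj = B + static_cast<size_t>(s) * n;
        double acc = 0.0;
        for (int r = 0; r < n; ++r) acc += aj[r] * bj[r];
        margsum(s, oi) += acc;
      }
      if (oi == 0) break;
      const int po = oi - 1; // op producing boundary oi
      if (em_t[po] < 0) {
        apply_factor(B, Bnext, n, bfac[po]);
        std::swap(B, Bnext);
      } else {
        const double* D = dptr[em_t[po]];
        const double* sc = scales[po].data();
        for (int s = 0; s < S; ++s) {
          const double* dj = D + static_cast<size_t>(kindex[s] - 1) * n_reads + r0;
          double* bj = B + static_cast<size_t>(s) * n;
          for (int r = 0; r < n; ++r) bj[r] *= dj[r] / sc[r];
        }
      }
    }
  }

  return List::create(_["loglik"] = loglik, _["margsum"] = margsum);
}
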