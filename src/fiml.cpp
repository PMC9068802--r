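// Full-information maximum-likelihood kernel for moderated bivariate
// Cholesky ACE twin models.
//
// Each pair contributes the Gaussian -2 log-likelihood of its observed
// subvector of (x1, y1, x2, y2), with the model-implied 4x4 covariance
// built from each twin's own tracking-status path set evaluated at the
// twin's own centered moderator value (definition variables). Means are
// precomputed in R (intercepts + covariate effects) and passed in.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

// Column order of the `paths` matrix (one row per tracking status);
// must match .path_roles on the R side.
enum PathRole {
  A_XX, C_XX, E_XX,
  A_YX, C_YX, E_YX,
  A_YY, C_YY, E_YY,
  A_YX_M, C_YX_M, E_YX_M,
  A_YY_M, C_YY_M, E_YY_M
};

// [[Rcpp::export(name = ".fiml_neg2ll_cpp")]]
NumericVector fiml_neg2ll_cpp(NumericMatrix Y,      // n x 4 data (x1,y1,x2,y2)
                              LogicalMatrix obs,    // n x 4 observed mask
                              NumericVector r,      // n relatedness
                              IntegerVector s1,     // n status twin 1 (1..3)
                              IntegerVector s2,     // n status twin 2
                              NumericVector X1,     // n moderator twin 1
                              NumericVector X2,     // n moderator twin 2
                              NumericMatrix paths,  // 3 x 15 per status
                              NumericMatrix mu) {   // n x 4 means
  const int n = Y.nrow();
  double total = 0.0;
  int n_singular = 0;

  for (int i = 0; i < n; ++i) {
    const int g1 = s1[i] - 1, g2 = s2[i] - 1;
    const double rr = r[i];
    const double x1 = X1[i], x2 = X2[i];

    // effective attainment paths per twin
    const double ayx1 = paths(g1, A_YX) + paths(g1, A_YX_M) * x1;
    const double cyx1 = paths(g1, C_YX) + paths(g1, C_YX_M) * x1;
    const double eyx1 = paths(g1, E_YX) + paths(g1, E_YX_M) * x1;
    const double ayy1 = paths(g1, A_YY) + paths(g1, A_YY_M) * x1;
    const double cyy1 = paths(g1, C_YY) + paths(g1, C_YY_M) * x1;
    const double eyy1 = paths(g1, E_YY) + paths(g1, E_YY_M) * x1;
    const double ayx2 = paths(g2, A_YX) + paths(g2, A_YX_M) * x2;
    const double cyx2 = paths(g2, C_YX) + paths(g2, C_YX_M) * x2;
    const double eyx2 = paths(g2, E_YX) + paths(g2, E_YX_M) * x2;
    const double ayy2 = paths(g2, A_YY) + paths(g2, A_YY_M) * x2;
    const double cyy2 = paths(g2, C_YY) + paths(g2, C_YY_M) * x2;
    const double eyy2 = paths(g2, E_YY) + paths(g2, E_YY_M) * x2;
    const double ax1 = paths(g1, A_XX), cx1 = paths(g1, C_XX),
                 ex1 = paths(g1, E_XX);
    const double ax2 = paths(g2, A_XX), cx2 = paths(g2, C_XX),
                 ex2 = paths(g2, E_XX);

    double S[4][4];
    S[0][0] = ax1 * ax1 + cx1 * cx1 + ex1 * ex1;
    S[2][2] = ax2 * ax2 + cx2 * cx2 + ex2 * ex2;
    S[1][1] = ayx1 * ayx1 + cyx1 * cyx1 + eyx1 * eyx1 +
              ayy1 * ayy1 + cyy1 * cyy1 + eyy1 * eyy1;
    S[3][3] = ayx2 * ayx2 + cyx2 * cyx2 + eyx2 * eyx2 +
              ayy2 * ayy2 + cyy2 * cyy2 + eyy2 * eyy2;
    S[0][1] = S[1][0] = ax1 * ayx1 + cx1 * cyx1 + ex1 * eyx1;
    S[2][3] = S[3][2] = ax2 * ayx2 + cx2 * cyx2 + ex2 * eyx2;
    S[0][2] = S[2][0] = rr * ax1 * ax2 + cx1 * cx2;
    S[0][3] = S[3][0] = rr * ax1 * ayx2 + cx1 * cyx2;
    S[1][2] = S[2][1] = rr * ayx1 * ax2 + cyx1 * cx2;
    S[1][3] = S[3][1] = rr * (ayx1 * ayx2 + ayy1 * ayy2) +
                        (cyx1 * cyx2 + cyy1 * cyy2);

    // observed subvector
    int keep[4], k = 0;
    for (int j = 0; j < 4; ++j)
      if (obs(i, j)) keep[k++] = j;
    if (k == 0) continue;

    double A[4][4], d[4];
    for (int a = 0; a < k; ++a) {
      d[a] = Y(i, keep[a]) - mu(i, keep[a]);
      for (int b = 0; b < k; ++b)
        A[a][b] = S[keep[a]][keep[b]];
    }

    // Cholesky A = L L'
    double L[4][4];
    bool ok = true;
    for (int a = 0; a < k && ok; ++a) {
      for (int b = 0; b <= a; ++b) {
        double s = A[a][b];
        for (int m = 0; m < b; ++m) s -= L[a][m] * L[b][m];
        if (a == b) {
          if (s <= 1e-12) { ok = false; break; }
          L[a][a] = std::sqrt(s);
        } else {
          L[a][b] = s / L[b][b];
        }
      }
    }
    if (!ok) {
      ++n_singular;
      total += 1e10;  // penalty keeps the objective finite and climbable
      continue;
    }

    double logdet = 0.0, quad = 0.0;
    double z[4];
    for (int a = 0; a < k; ++a) {
      double s = d[a];
      for (int m = 0; m < a; ++m) s -= L[a][m] * z[m];
      z[a] = s / L[a][a];
      logdet += std::log(L[a][a]);
      quad += z[a] * z[a];
    }
    total += k * LOG2PI + 2.0 * logdet + quad;
  }

  NumericVector out(2);
  out[0] = total;
  out[1] = n_singular;
  return out;
}
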