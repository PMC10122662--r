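// Exact convex-hull volume in low dimension (d <= ~6) by facet enumeration.
//
// Every d-subset of points is tested as a supporting hyperplane; a subset is a
// facet when all remaining points lie (weakly) on one side.  The hull volume is
// the sum over facets of pyramid volumes anchored at the interior centroid.
// Coplanar facets (more than d points on the supporting plane) are counted once
// and their (d-1)-volume obtained by projecting onto the plane and recursing.
//
// Complexity is O(C(n, d) * n): intended for community-sized point sets
// (tens of species) in a 3-5 dimensional functional space, not for large n.

#include <RcppArmadillo.h>
#include <set>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double hull_volume_rec(const mat &P, double tol, std::set<uword> *verts);

// (d-1)-volume of a set of coplanar points in R^d: project onto an
// orthonormal basis of their affine span and recurse one dimension down.
static double facet_volume(const mat &F, double tol) {
  const uword d = F.n_cols;
  rowvec c = mean(F, 0);
  mat C = F.each_row() - c;
  mat U, V;
  vec s;
  if (!svd_econ(U, s, V, C)) return 0.0;
  double smax = s.n_elem ? s.max() : 0.0;
  uword r = 0;
  for (uword i = 0; i < s.n_elem; ++i)
    if (s(i) > tol * std::max(1.0, smax)) ++r;
  if (r < d - 1) return 0.0; // flat facet, zero measure
  mat Q = C * V.cols(0, d - 2);
  if (d - 1 == 1) return Q.col(0).max() - Q.col(0).min();
  return hull_volume_rec(Q, tol, nullptr);
}

// simplex facet (d points in R^d): (d-1)-volume = sqrt(det(E E')) / (d-1)!
static double simplex_facet_area(const mat &E) {
  mat G = E * E.t();
  double g = det(G);
  if (g < 0) g = 0;
  double fact = 1.0;
  for (uword i = 2; i <= E.n_rows; ++i) fact *= (double)i;
  return std::sqrt(g) / fact;
}

static double det_small(const mat &M) {
  const uword n = M.n_rows;
  if (n == 1) return M(0, 0);
  if (n == 2) return M(0, 0) * M(1, 1) - M(0, 1) * M(1, 0);
  if (n == 3)
    return M(0, 0) * (M(1, 1) * M(2, 2) - M(1, 2) * M(2, 1)) -
           M(0, 1) * (M(1, 0) * M(2, 2) - M(1, 2) * M(2, 0)) +
           M(0, 2) * (M(1, 0) * M(2, 1) - M(1, 1) * M(2, 0));
  if (n == 4) {
    double det = 0.0;
    mat sub(3, 3);
    for (uword c = 0; c < 4; ++c) {
      uword cc = 0;
      for (uword j = 0; j < 4; ++j) {
        if (j == c) continue;
        for (uword i = 1; i < 4; ++i) sub(i - 1, cc) = M(i, j);
        ++cc;
      }
      det += ((c % 2) ? -1.0 : 1.0) * M(0, c) * det_small(sub);
    }
    return det;
  }
  return det(M);
}

// unit normal of the affine span of rows idx of P via cofactor expansion
// (generalized cross product); returns false when the subset is affinely
// degenerate (edge matrix rank < d-1).
static bool subset_normal(const mat &P, const uvec &idx, double tol,
                          vec &normal, double &offset, mat &E) {
  const uword d = P.n_cols;
  E.set_size(d - 1, d);
  for (uword i = 1; i < d; ++i)
    E.row(i - 1) = P.row(idx(i)) - P.row(idx(0));
  normal.set_size(d);
  mat sub(d - 1, d - 1);
  for (uword c = 0; c < d; ++c) {
    uword cc = 0;
    for (uword j = 0; j < d; ++j) {
      if (j == c) continue;
      sub.col(cc++) = E.col(j);
    }
    normal(c) = ((c % 2) ? -1.0 : 1.0) * det_small(sub);
  }
  double nn = norm(normal, 2);
  double escale = norm(E, "fro");
  if (escale == 0.0) return false;
  // cofactors scale like escale^(d-1); a tiny ratio means degeneracy
  double ref = std::pow(escale / std::sqrt((double)(d - 1)), (double)(d - 1));
  if (nn <= tol * std::max(1.0, ref)) return false;
  normal /= nn;
  offset = dot(normal, P.row(idx(0)).t());
  return true;
}

static bool next_combination(uvec &idx, uword n) {
  const uword k = idx.n_elem;
  for (uword i = k; i-- > 0;) {
    if (idx(i) < n - k + i) {
      ++idx(i);
      for (uword j = i + 1; j < k; ++j) idx(j) = idx(j - 1) + 1;
      return true;
    }
  }
  return false;
}

static double hull_volume_rec(const mat &P, double tol, std::set<uword> *verts) {
  const uword n = P.n_rows, d = P.n_cols;
  if (d == 1) return P.col(0).max() - P.col(0).min();
  rowvec centroid = mean(P, 0);
  double scale = 1.0;
  {
    mat C = P.each_row() - centroid;
    scale = std::max(1.0, norm(C, "fro") / std::sqrt((double)n));
  }
  const double atol = tol * scale;

  uvec idx = regspace<uvec>(0, d - 1);
  vec normal;
  double offset;
  mat E;
  double vol = 0.0;
  do {
    if (!subset_normal(P, idx, tol, normal, offset, E)) continue;
    vec s = P * normal - offset;
    bool pos = false, neg = false;
    for (uword k = 0; k < n && !(pos && neg); ++k) {
      if (s(k) > atol) pos = true;
      else if (s(k) < -atol) neg = true;
    }
    if (pos && neg) continue; // not a supporting hyperplane

    uvec onplane = find(abs(s) <= atol); // sorted; includes idx
    double area;
    if (onplane.n_elem > d) {
      // coplanar facet: count it exactly once, at the lexicographically
      // first affinely independent d-subset of the coplanar set
      uvec probe = regspace<uvec>(0, d - 1);
      bool canonical = false;
      vec nrm2;
      double off2;
      mat E2;
      do {
        uvec cand = onplane(probe);
        if (!subset_normal(P, cand, tol, nrm2, off2, E2)) continue;
        canonical = all(cand == idx);
        break;
      } while (next_combination(probe, onplane.n_elem));
      if (!canonical) continue;
      area = facet_volume(P.rows(onplane), tol);
    } else {
      area = simplex_facet_area(E);
    }
    double h = std::abs(dot(normal, centroid.t()) - offset);
    vol += area * h / (double)d;
    if (verts)
      for (uword k = 0; k < onplane.n_elem; ++k) verts->insert(onplane(k));
  } while (next_combination(idx, n));
  return vol;
}

//' @rdname hull_volume
//' @keywords internal
// [[Rcpp::export(.convhull_cpp, rng = false)]]
Rcpp::List convhull_cpp(const arma::mat &points, double tol = 1e-9) {
  const uword d = points.n_cols;
  // deduplicate rows (within tolerance) keeping first occurrences
  std::vector<uword> keep;
  for (uword i = 0; i < points.n_rows; ++i) {
    bool dup = false;
    for (uword j : keep) {
      if (norm(points.row(i) - points.row(j), 2) <= tol) { dup = true; break; }
    }
    if (!dup) keep.push_back(i);
  }
  uvec keep_idx = conv_to<uvec>::from(keep);
  mat P = points.rows(keep_idx);

  // rank of the centered configuration decides degeneracy
  bool degenerate = P.n_rows < d + 1;
  if (!degenerate) {
    mat C = P.each_row() - mean(P, 0);
    vec s = svd(C);
    double smax = s.n_elem ? s.max() : 0.0;
    uword r = 0;
    for (uword i = 0; i < s.n_elem; ++i)
      if (s(i) > tol * std::max(1.0, smax)) ++r;
    degenerate = r < d;
  }
  if (degenerate) {
    return Rcpp::List::create(
        Rcpp::Named("volume") = NA_REAL,
        Rcpp::Named("vertices") = Rcpp::IntegerVector(0),
        Rcpp::Named("degenerate") = true,
        Rcpp::Named("n_unique") = (int)P.n_rows);
  }

  std::set<uword> verts;
  double vol = hull_volume_rec(P, tol, &verts);
  Rcpp::IntegerVector vr;
  for (uword v : verts) vr.push_back((int)keep_idx(v) + 1); // 1-based, original rows
  return Rcpp::List::create(
      Rcpp::Named("volume") = vol,
      Rcpp::Named("vertices") = vr,
      Rcpp::Named("degenerate") = false,
      Rcpp::Named("n_unique") = (int)P.n_rows);
}
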