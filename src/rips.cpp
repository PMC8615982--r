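// Vietoris-Rips persistent homology (dimensions 0-2) on a point cloud given
// by its distance matrix. Standard boundary-matrix reduction over Z/2 with a
// pivot-to-column map; simplices enumerated up to dimension 3 (tetrahedra,
// needed to kill 2-cycles), filtration value = longest pairwise distance.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Simplex {
  double filt;
  int dim;
  int v[4]; // vertex ids, ascending; unused = -1
};

inline bool simplex_less(const Simplex &a, const Simplex &b) {
  if (a.filt != b.filt) return a.filt < b.filt;
  if (a.dim != b.dim) return a.dim < b.dim;
  for (int k = 0; k < 4; ++k) {
    if (a.v[k] != b.v[k]) return a.v[k] < b.v[k];
  }
  return false;
}

// symmetric difference of two sorted index vectors (Z/2 column addition)
void add_column(std::vector<int> &a, const std::vector<int> &b) {
  std::vector<int> out;
  out.reserve(a.size() + b.size());
  std::set_symmetric_difference(a.begin(), a.end(), b.begin(), b.end(),
                                std::back_inserter(out));
  a.swap(out);
}

} // namespace

// [[Rcpp::export]]
List rips_persistence_cpp(NumericMatrix dmat, double max_radius,
                          int max_dim = 2, double max_simplices = 5e6) {
  const int n = dmat.nrow();
  std::vector<std::vector<bool>> adj(n, std::vector<bool>(n, false));
  std::vector<Simplex> simplices;

  for (int i = 0; i < n; ++i) {
    Simplex s{0.0, 0, {i, -1, -1, -1}};
    simplices.push_back(s);
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (dmat(i, j) <= max_radius) {
        adj[i][j] = adj[j][i] = true;
        Simplex s{dmat(i, j), 1, {i, j, -1, -1}};
        simplices.push_back(s);
      }
    }
  }
  if (max_dim >= 1) {
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        if (!adj[i][j]) continue;
        for (int k = j + 1; k < n; ++k) {
          if (adj[i][k] && adj[j][k]) {
            double f = std::max(dmat(i, j), std::max(dmat(i, k), dmat(j, k)));
            Simplex s{f, 2, {i, j, k, -1}};
            simplices.push_back(s);
            if ((double)simplices.size() > max_simplices)
              stop("Rips complex too large; lower max_radius");
            if (max_dim >= 2) {
              for (int l = k + 1; l < n; ++l) {
                if (adj[i][l] && adj[j][l] && adj[k][l]) {
                  double g = std::max(
                      f, std::max(dmat(i, l),
                                  std::max(dmat(j, l), dmat(k, l))));
                  Simplex t{g, 3, {i, j, k, l}};
                  simplices.push_back(t);
                  if ((double)simplices.size() > max_simplices)
                    stop("Rips complex too large; lower max_radius");
                }
              }
            }
          }
        }
      }
    }
  }

  const int m = (int)simplices.size();
  std::vector<int> order(m);
  for (int i = 0; i < m; ++i) order[i] = i;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    return simplex_less(simplices[a], simplices[b]);
  });
  std::vector<int> pos(m);
  for (int i = 0; i < m; ++i) pos[order[i]] = i;

  // hash from vertex key to sorted position, per dimension
  auto key = [n](const int *v, int dim) -> int64_t {
    int64_t k = 0;
    for (int a = 0; a <= dim; ++a) k = k * (int64_t)n + v[a];
    return k;
  };
  std::unordered_map<int64_t, int> index0, index1, index2;
  for (int i = 0; i < m; ++i) {
    const Simplex &s = simplices[order[i]];
    if (s.dim == 0) index0[key(s.v, 0)] = i;
    else if (s.dim == 1) index1[key(s.v, 1)] = i;
    else if (s.dim == 2) index2[key(s.v, 2)] = i;
  }

  std::vector<int> pivot_col(m, -1);          // pivot row -> killer column
  std::vector<std::vector<int>> reduced(m);   // reduced columns
  std::vector<char> is_creator(m, 0);
  std::vector<double> birth_of(m, 0.0);
  // intervals per homology dimension
  std::vector<std::vector<double>> births(3), deaths(3);

  for (int ci = 0; ci < m; ++ci) {
    const Simplex &s = simplices[order[ci]];
    birth_of[ci] = s.filt;
    if (s.dim == 0) {
      is_creator[ci] = 1;
      continue;
    }
    std::vector<int> col;
    int fv[4];
    for (int drop = 0; drop <= s.dim; ++drop) {
      int t = 0;
      for (int a = 0; a <= s.dim; ++a) {
        if (a != drop) fv[t++] = s.v[a];
      }
      int idx;
      if (s.dim == 1) idx = index0[key(fv, 0)];
      else if (s.dim == 2) idx = index1[key(fv, 1)];
      else idx = index2[key(fv, 2)];
      col.push_back(idx);
    }
    std::sort(col.begin(), col.end());
    while (!col.empty()) {
      int piv = col.back();
      if (pivot_col[piv] < 0) break;
      add_column(col, reduced[pivot_col[piv]]);
    }
    if (col.empty()) {
      is_creator[ci] = 1; // creates a (dim)-cycle
    } else {
      int piv = col.back();
      pivot_col[piv] = ci;
      reduced[ci] = col;
      is_creator[piv] = 0; // the cycle created at piv dies here
      int hdim = s.dim - 1;
      double b = birth_of[piv], d = s.filt;
      if (d > b) { // drop zero-persistence pairs
        births[hdim].push_back(b);
        deaths[hdim].push_back(d);
      }
    }
  }
  // essential classes: creators never killed
  for (int ci = 0; ci < m; ++ci) {
    if (is_creator[ci] && pivot_col[ci] < 0) {
      int d = simplices[order[ci]].dim;
      if (d <= 2) {
        births[d].push_back(birth_of[ci]);
        deaths[d].push_back(R_PosInf);
      }
    }
  }

  List out(3);
  for (int h = 0; h < 3; ++h) {
    NumericMatrix iv(births[h].size(), 2);
    for (size_t r = 0; r < births[h].size(); ++r) {
      iv(r, 0) = births[h][r];
      iv(r, 1) = deaths[h][r];
    }
    colnames(iv) = CharacterVector::create("birth", "death");
    out[h] = iv;
  }
  out.names() = CharacterVector::create("h0", "h1", "h2");
  return out;
}
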