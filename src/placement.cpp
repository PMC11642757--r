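#include <Rcpp.h>
using namespace Rcpp;

// Seed-and-grow placement of aneuploid cells on a fixed geometry.
//
// nbr is an n_cells x (n_cells - 1) matrix of 0-based cell ids: row i lists
// every other cell ordered by increasing chordal distance from cell i (ties
// broken by id). Clusters grow along their *seed's* ordering, so dispersal 0
// (one seed) yields a single contiguous patch and dispersal 1 (one seed per
// aneuploid cell) reduces to a uniform random subset.
//
// All randomness flows through R's RNG (unif_rand), so results are
// reproducible under set.seed().

static inline int rand_int(int n) {
  // uniform on {0, ..., n-1}; guards against unif_rand() == 1.0
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

static void place_labels(const IntegerMatrix& nbr, int n_aneuploid,
                         double dispersal, std::vector<int>& labels,
                         std::vector<int>& seeds, std::vector<int>& ptr,
                         std::vector<int>& perm) {
  const int n = nbr.nrow();
  std::fill(labels.begin(), labels.end(), 0);
  if (n_aneuploid <= 0) return;
  if (n_aneuploid >= n) { std::fill(labels.begin(), labels.end(), 1); return; }

  // number of cluster seeds: round half away from zero, clamped to [1, k]
  int s = (int)std::floor(dispersal * n_aneuploid + 0.5);
  if (s < 1) s = 1;
  if (s > n_aneuploid) s = n_aneuploid;

  // draw s distinct seed cells (partial Fisher-Yates)
  for (int i = 0; i < n; ++i) perm[i] = i;
  for (int i = 0; i < s; ++i) {
    int j = i + rand_int(n - i);
    std::swap(perm[i], perm[j]);
    seeds[i] = perm[i];
    labels[perm[i]] = 1;
    ptr[i] = 0;
  }

  int marked = s;
  while (marked < n_aneuploid) {
    int c = rand_int(s);
    int row = seeds[c];
    int p = ptr[c];
    while (labels[nbr(row, p)]) ++p;  // skip cells already aneuploid
    labels[nbr(row, p)] = 1;
    ptr[c] = p + 1;
    ++marked;
  }
}

// [[Rcpp::export]]
IntegerVector cpp_place_labels(const IntegerMatrix& nbr, int n_aneuploid,
                               double dispersal) {
  const int n = nbr.nrow();
  std::vector<int> labels(n), seeds(n), ptr(n), perm(n);
  place_labels(nbr, n_aneuploid, dispersal, labels, seeds, ptr, perm);
  return IntegerVector(labels.begin(), labels.end());
}

// Tally, for every possible aneuploid cell count 0..n_cells, the biopsy
// aneuploid-count distribution at a fixed biopsy (0-based cell ids) over
// n_rep independent placements. Rows 0 and n_cells are deterministic and
// filled without simulation.
// [[Rcpp::export]]
IntegerMatrix cpp_biopsy_count_table(const IntegerMatrix& nbr,
                                     const IntegerVector& biopsy_cells,
                                     double dispersal, int n_rep) {
  const int n = nbr.nrow();
  const int b = biopsy_cells.size();
  IntegerMatrix out(n + 1, b + 1);
  std::vector<int> labels(n), seeds(n), ptr(n), perm(n);
  out(0, 0) = n_rep;
  out(n, b) = n_rep;
  for (int k = 1; k < n; ++k) {
    for (int r = 0; r < n_rep; ++r) {
      place_labels(nbr, k, dispersal, labels, seeds, ptr, perm);
      int cnt = 0;
      for (int j = 0; j < b; ++j) cnt += labels[biopsy_cells[j]];
      out(k, cnt) += 1;
    }
    if (k % 32 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// For each embryo (given its aneuploid cell count), place labels once and
// take two biopsies: the first at a fixed cell set, the second at a
// uniformly drawn index cell plus its biopsy_size - 1 nearest neighbours
// (overlap with the first biopsy permitted). Returns an n x 2 matrix of
// biopsy aneuploid counts.
// [[Rcpp::export]]
IntegerMatrix cpp_two_biopsies(const IntegerMatrix& nbr,
                               const IntegerVector& biopsy1_cells,
                               const IntegerVector& n_aneuploid,
                               double dispersal) {
  const int n = nbr.nrow();
  const int b = biopsy1_cells.size();
  const int m = n_aneuploid.size();
  IntegerMatrix out(m, 2);
  std::vector<int> labels(n), seeds(n), ptr(n), perm(n);
  for (int e = 0; e < m; ++e) {
    int k = n_aneuploid[e];
    if (k <= 0) { out(e, 0) = 0; out(e, 1) = 0; continue; }
    if (k >= n) { out(e, 0) = b; out(e, 1) = b; continue; }
    place_labels(nbr, k, dispersal, labels, seeds, ptr, perm);
    int c1 = 0;
    for (int j = 0; j < b; ++j) c1 += labels[biopsy1_cells[j]];
    int idx2 = rand_int(n);
    int c2 = labels[idx2];
    for (int j = 0; j < b - 1; ++j) c2 += labels[nbr(idx2, j)];
    out(e, 0) = c1;
    out(e, 1) = c2;
    if (e % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
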