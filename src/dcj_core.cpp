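#include <Rcpp.h>
#include <vector>
#include <array>
#include <utility>
using namespace Rcpp;

// A genome over n genes is an extremity-neighbour vector nb of length 2n
// (1-based on the R side): gene g owns tail extremity 2g-1 and head
// extremity 2g; nb[e] is the extremity adjacent to e, or 0 for a telomere.
// Internally we use 0-based extremities with -1 for telomeres.
//
// The adjacency graph of genomes A and B has one vertex per adjacency or
// telomere of either genome and one edge per extremity; components are
// cycles or paths and give the distance n - (C + I/2), where I counts
// paths with an odd number of edges.

static std::vector<int> to0(const IntegerVector& nb) {
  std::vector<int> v(nb.size());
  for (int i = 0; i < nb.size(); ++i) v[i] = nb[i] - 1;
  return v;
}

struct Decomp {
  int C = 0, I = 0;
  // per-extremity component id and per-component type:
  // 0 cycle, 1 odd path, 2 even path ending in two A-telomeres,
  // 3 even path ending in two B-telomeres
  std::vector<int> comp;
  std::vector<int> ctype;
};

// Walk the path whose first edge is extremity e; firstB says whether the
// walk leaves e through its B-side vertex.  Returns the edge count.
static int walk_path(int e, bool firstB, const int* A, const int* B,
                     std::vector<char>& vis, int id, std::vector<int>* comp) {
  int edges = 0, cur = e;
  bool sideB = firstB;
  for (;;) {
    vis[cur] = 1;
    if (comp) (*comp)[cur] = id;
    ++edges;
    int nxt = sideB ? B[cur] : A[cur];
    if (nxt < 0) break;
    cur = nxt;
    sideB = !sideB;
  }
  return edges;
}

static Decomp decompose(const int* A, const int* B, int n2, bool want_comp) {
  Decomp d;
  std::vector<char> vis(n2, 0);
  std::vector<int>* cp = nullptr;
  if (want_comp) { d.comp.assign(n2, -1); cp = &d.comp; }
  int id = 0;
  // paths with at least one endpoint telomeric in A (all odd paths, plus
  // even paths bounded by two A-telomeres)
  for (int e = 0; e < n2; ++e)
    if (!vis[e] && A[e] < 0) {
      int edges = walk_path(e, true, A, B, vis, id, cp);
      if (edges % 2) d.I++;
      if (want_comp) { d.ctype.push_back(edges % 2 ? 1 : 2); ++id; }
    }
  // remaining paths: both endpoints telomeric in B, always even length
  for (int e = 0; e < n2; ++e)
    if (!vis[e] && B[e] < 0) {
      int edges = walk_path(e, false, A, B, vis, id, cp);
      if (edges % 2) d.I++;  // unreachable, defensive
      if (want_comp) { d.ctype.push_back(edges % 2 ? 1 : 3); ++id; }
    }
  // cycles
  for (int e = 0; e < n2; ++e)
    if (!vis[e]) {
      d.C++;
      int cur = e;
      bool sideB = true;
      do {
        vis[cur] = 1;
        if (cp) (*cp)[cur] = id;
        cur = sideB ? B[cur] : A[cur];
        sideB = !sideB;
      } while (cur != e);
      if (want_comp) { d.ctype.push_back(0); ++id; }
    }
  return d;
}

// [[Rcpp::export]]
IntegerVector cpp_dcj_counts(IntegerVector nbA, IntegerVector nbB) {
  if (nbA.size() != nbB.size()) stop("genomes have different gene counts");
  std::vector<int> A = to0(nbA), B = to0(nbB);
  Decomp d = decompose(A.data(), B.data(), (int)A.size(), false);
  return IntegerVector::create(d.C, d.I);
}

// [[Rcpp::export]]
int cpp_dcj_distance(IntegerVector nbA, IntegerVector nbB) {
  if (nbA.size() != nbB.size()) stop("genomes have different gene counts");
  std::vector<int> A = to0(nbA), B = to0(nbB);
  Decomp d = decompose(A.data(), B.data(), (int)A.size(), false);
  if (d.I % 2 != 0) stop("internal error: odd-path count is odd");
  return (int)A.size() / 2 - d.C - d.I / 2;
}

static int dist_of(const std::vector<int>& A, const int* B, int n2) {
  Decomp d = decompose(A.data(), B, n2, false);
  return n2 / 2 - d.C - d.I / 2;
}

// recombine two elements of A (adjacencies or telomeres), variant 0/1:
// elements {p1,q1} and {p2,q2} (q = -1 for a telomere) are replaced by
// {p1,p2},{q1,q2} (variant 0) or {p1,q2},{q1,p2} (variant 1); pairing a
// -1 with an extremity leaves a telomere, pairing -1 with -1 is nothing.
static void recombine(std::vector<int>& A, int p1, int q1, int p2, int q2,
                      int variant) {
  int a1 = p1, b1 = (variant == 0) ? p2 : q2;
  int a2 = q1, b2 = (variant == 0) ? q2 : p2;
  if (a1 >= 0) A[a1] = b1;
  if (b1 >= 0) A[b1] = a1;
  if (a2 >= 0) A[a2] = b2;
  if (b2 >= 0) A[b2] = a2;
}

// Apply one optimal DCJ step from A toward B, chosen uniformly at random
// among ALL optimal operations.  Within each adjacency-graph component
// with K elements of A, every unordered pair of A-elements admits exactly
// one splitting recombination that raises C + I/2 by one; even paths
// bounded by two B-telomeres additionally allow each of their K
// A-adjacencies to be cut.  Components are drawn proportionally to their
// operation counts, so the choice is uniform without materializing the
// O(n^2) candidate list; the correct recombination variant is resolved by
// a trial distance evaluation.
static bool one_step(std::vector<int>& A, const int* B, int n2) {
  Decomp d = decompose(A.data(), B, n2, true);
  int ncomp = (int)d.ctype.size();
  // A-elements per component
  std::vector<std::vector<std::pair<int, int> > > elems(ncomp);
  for (int p = 0; p < n2; ++p) {
    if (A[p] < 0) elems[d.comp[p]].push_back(std::make_pair(p, -1));
    else if (A[p] > p) elems[d.comp[p]].push_back(std::make_pair(p, A[p]));
  }
  std::vector<double> nops(ncomp);
  double total = 0.0;
  for (int c = 0; c < ncomp; ++c) {
    double K = (double)elems[c].size();
    nops[c] = K * (K - 1) / 2 + (d.ctype[c] == 3 ? K : 0);
    total += nops[c];
  }
  if (total < 0.5) return false;  // genomes already identical
  double u = unif_rand() * total;
  int c = 0;
  while (c < ncomp - 1 && u >= nops[c]) { u -= nops[c]; ++c; }
  while (nops[c] < 0.5) ++c;  // guard against fp edge effects
  int K = (int)elems[c].size();
  long pairs = (long)K * (K - 1) / 2;
  long idx = (long)u;
  if (idx >= pairs + (d.ctype[c] == 3 ? K : 0))
    idx = pairs + (d.ctype[c] == 3 ? K : 0) - 1;
  if (idx >= pairs) {
    // cut an A-adjacency of a B-telomere-bounded even path
    std::pair<int, int> el = elems[c][idx - pairs];
    A[el.first] = -1;
    A[el.second] = -1;
    return true;
  }
  // unrank the element pair
  int i = 0;
  long before = 0;
  while (before + (K - 1 - i) <= idx) { before += K - 1 - i; ++i; }
  int j = i + 1 + (int)(idx - before);
  std::pair<int, int> e1 = elems[c][i], e2 = elems[c][j];
  if (e1.second < 0 && e2.second < 0) {
    // join the two telomeres of an even path: the only variant
    A[e1.first] = e2.first;
    A[e2.first] = e1.first;
    return true;
  }
  int d0 = n2 / 2 - d.C - d.I / 2;
  recombine(A, e1.first, e1.second, e2.first, e2.second, 0);
  if (dist_of(A, B, n2) == d0 - 1) return true;
  // restore the original elements and take the other variant
  if (e1.second >= 0) { A[e1.first] = e1.second; A[e1.second] = e1.first; }
  else A[e1.first] = -1;
  if (e2.second >= 0) { A[e2.first] = e2.second; A[e2.second] = e2.first; }
  else A[e2.first] = -1;
  recombine(A, e1.first, e1.second, e2.first, e2.second, 1);
  if (dist_of(A, B, n2) != d0 - 1)
    stop("internal error: no optimal recombination variant");
  return true;
}

// [[Rcpp::export]]
IntegerVector cpp_sample_path(IntegerVector nbA, IntegerVector nbB, int k) {
  if (nbA.size() != nbB.size()) stop("genomes have different gene counts");
  std::vector<int> A = to0(nbA), B = to0(nbB);
  for (int i = 0; i < k; ++i)
    if (!one_step(A, B.data(), (int)A.size()))
      stop("k exceeds the DCJ distance between the genomes");
  IntegerVector out(A.size());
  for (size_t i = 0; i < A.size(); ++i) out[i] = A[i] + 1;
  return out;
}

// [[Rcpp::export]]
int cpp_fitness3(IntegerVector nb, IntegerVector nb1, IntegerVector nb2,
                 IntegerVector nb3) {
  return cpp_dcj_distance(nb, nb1) + cpp_dcj_distance(nb, nb2) +
         cpp_dcj_distance(nb, nb3);
}

// [[Rcpp::export]]
IntegerMatrix cpp_pairwise_distances(List nbs) {
  int m = nbs.size();
  IntegerMatrix d(m, m);
  std::vector<IntegerVector> v(m);
  for (int i = 0; i < m; ++i) v[i] = as<IntegerVector>(nbs[i]);
  for (int i = 0; i < m; ++i)
    for (int j = i + 1; j < m; ++j)
      d(i, j) = d(j, i) = cpp_dcj_distance(v[i], v[j]);
  return d;
}

// Full component decomposition for the user-facing adjacency graph:
// returns, per component, its type and edge count, plus the ordered edge
// (extremity) chain of each component.
// [[Rcpp::export]]
List cpp_components(IntegerVector nbA, IntegerVector nbB) {
  if (nbA.size() != nbB.size()) stop("genomes have different gene counts");
  std::vector<int> A = to0(nbA), B = to0(nbB);
  int n2 = (int)A.size();
  std::vector<char> vis(n2, 0);
  std::vector<std::string> type;
  List chains;
  std::vector<int> chain;

  // record the walk from edge e, entering through side firstB
  // (mirrors walk_path but keeps the edge order)
  struct Walker {
    const int *A, *B;
    std::vector<char>& vis;
    Walker(const int* a, const int* b, std::vector<char>& v)
        : A(a), B(b), vis(v) {}
    void path(int e, bool firstB, std::vector<int>& out) {
      int cur = e;
      bool sideB = firstB;
      for (;;) {
        vis[cur] = 1;
        out.push_back(cur + 1);
        int nxt = sideB ? B[cur] : A[cur];
        if (nxt < 0) break;
        cur = nxt;
        sideB = !sideB;
      }
    }
    void cycle(int e, std::vector<int>& out) {
      int cur = e;
      bool sideB = true;
      do {
        vis[cur] = 1;
        out.push_back(cur + 1);
        cur = sideB ? B[cur] : A[cur];
        sideB = !sideB;
      } while (cur != e);
    }
  } w(A.data(), B.data(), vis);

  std::vector<std::vector<int> > all;
  for (int e = 0; e < n2; ++e)
    if (!vis[e] && A[e] < 0) {
      chain.clear();
      w.path(e, true, chain);
      type.push_back(chain.size() % 2 ? "odd_path" : "even_path");
      all.push_back(chain);
    }
  for (int e = 0; e < n2; ++e)
    if (!vis[e] && B[e] < 0) {
      chain.clear();
      w.path(e, false, chain);
      type.push_back(chain.size() % 2 ? "odd_path" : "even_path");
      all.push_back(chain);
    }
  for (int e = 0; e < n2; ++e)
    if (!vis[e]) {
      chain.clear();
      w.cycle(e, chain);
      type.push_back("cycle");
      all.push_back(chain);
    }

  List out_chains(all.size());
  CharacterVector out_type(all.size());
  IntegerVector out_edges(all.size());
  for (size_t i = 0; i < all.size(); ++i) {
    out_chains[i] = wrap(all[i]);
    out_type[i] = type[i];
    out_edges[i] = (int)all[i].size();
  }
  return List::create(_["type"] = out_type, _["edges"] = out_edges,
                      _["extremities"] = out_chains);
}
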