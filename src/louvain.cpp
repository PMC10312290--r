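#include <Rcpp.h>
using namespace Rcpp;

// Louvain-style greedy optimisation of a partition quality that is additive
// over same-community pairs of a dense symmetric gain matrix B:
//   Q(M) = sum_{i,j : M_i == M_j} B(i, j)   (diagonal included).
// The signed-modularity matrix is built in R; this core is agnostic to it.

// One full sweep of single-node best moves. A node may move to any occupied
// community or out into an empty one. Returns true if anything moved.
static bool sweep_moves(const std::vector<double> &B, int n,
                        std::vector<int> &comm, const std::vector<int> &order) {
  std::vector<double> acc(n);
  std::vector<char> used(n);
  bool moved = false;
  for (int k = 0; k < n; ++k) {
    int i = order[k];
    std::fill(acc.begin(), acc.end(), 0.0);
    std::fill(used.begin(), used.end(), 0);
    const double *Bi = &B[(size_t)i * n];
    for (int j = 0; j < n; ++j)
      if (j != i) {
        acc[comm[j]] += Bi[j];
        used[comm[j]] = 1;
      }
    int cur = comm[i];
    int best = cur;
    double best_acc = used[cur] ? acc[cur] : 0.0;  // singleton already
    for (int c = 0; c < n; ++c) {
      if (!used[c] || c == cur) continue;
      if (acc[c] > best_acc + 1e-12) {
        best_acc = acc[c];
        best = c;
      }
    }
    // empty community (isolate i) has attachment 0
    if (0.0 > best_acc + 1e-12) {
      for (int c = 0; c < n; ++c)
        if (!used[c] && c != cur) {
          best = c;
          best_acc = 0.0;
          break;
        }
    }
    if (best != cur) {
      comm[i] = best;
      moved = true;
    }
  }
  return moved;
}

static void shuffle_order(std::vector<int> &order) {
  // Fisher-Yates using R's RNG so set.seed() governs determinism
  int n = (int)order.size();
  for (int i = n - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(order[i], order[j]);
  }
}

static std::vector<int> relabel(const std::vector<int> &comm, int n,
                                int &ncomm) {
  std::vector<int> map(n, -1);
  ncomm = 0;
  std::vector<int> out(n);
  for (int i = 0; i < n; ++i) {
    if (map[comm[i]] == -1) map[comm[i]] = ncomm++;
    out[i] = map[comm[i]];
  }
  return out;
}

// [[Rcpp::export(name = ".louvain_gain")]]
IntegerVector louvain_gain(NumericMatrix Bmat, bool shuffle = true) {
  int n0 = Bmat.nrow();
  std::vector<double> B(Bmat.begin(), Bmat.end());
  int n = n0;
  std::vector<int> node2cur(n0);  // original node -> current-level node
  for (int i = 0; i < n0; ++i) node2cur[i] = i;

  GetRNGstate();
  for (int level = 0; level < 100; ++level) {
    std::vector<int> comm(n);
    std::vector<int> order(n);
    for (int i = 0; i < n; ++i) comm[i] = order[i] = i;
    int pass = 0;
    bool moved = true;
    while (moved && pass < 1000) {
      if (shuffle) shuffle_order(order);
      moved = sweep_moves(B, n, comm, order);
      ++pass;
    }
    int ncomm;
    std::vector<int> lab = relabel(comm, n, ncomm);
    for (int i = 0; i < n0; ++i) node2cur[i] = lab[node2cur[i]];
    if (ncomm == n) break;  // no merges: converged
    std::vector<double> Bn((size_t)ncomm * ncomm, 0.0);
    for (int i = 0; i < n; ++i) {
      const double *Bi = &B[(size_t)i * n];
      for (int j = 0; j < n; ++j)
        Bn[(size_t)lab[i] * ncomm + lab[j]] += Bi[j];
    }
    B.swap(Bn);
    n = ncomm;
  }
  PutRNGstate();

  IntegerVector out(n0);
  for (int i = 0; i < n0; ++i) out[i] = node2cur[i] + 1;
  return out;
}

// Kernighan-Lin style refinement: deterministic sweeps of single-node best
// moves on the full gain matrix until stable, starting from a given partition.
// [[Rcpp::export(name = ".finetune_gain")]]
IntegerVector finetune_gain(NumericMatrix Bmat, IntegerVector membership) {
  int n = Bmat.nrow();
  std::vector<double> B(Bmat.begin(), Bmat.end());
  std::vector<int> comm(n), order(n);
  for (int i = 0; i < n; ++i) {
    comm[i] = membership[i] - 1;
    order[i] = i;
  }
  int pass = 0;
  while (sweep_moves(B, n, comm, order) && pass < 1000) ++pass;
  int ncomm;
  std::vector<int> lab = relabel(comm, n, ncomm);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = lab[i] + 1;
  return out;
}
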