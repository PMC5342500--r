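// MCMC kernel for score-based Bayesian-network structure learning.
// Single-edge add/delete/reverse plus parent-swap proposals, Gaussian-BIC
// family scores from precomputed sufficient statistics, annealed Metropolis
// acceptance. Uses R's RNG stream, so set.seed() on the R side makes every
// chain fully reproducible.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

// solve S b = y for a small symmetric positive-definite system by Gaussian
// elimination with partial pivoting; ridge fallback on near-singularity
bool solve_small(std::vector<double> S, std::vector<double> y, int k,
                 std::vector<double> &b) {
  for (int attempt = 0; attempt < 2; ++attempt) {
    std::vector<double> A(S);
    b = y;
    bool ok = true;
    std::vector<int> perm(k);
    for (int i = 0; i < k; ++i) perm[i] = i;
    for (int col = 0; col < k && ok; ++col) {
      int piv = col;
      double best = std::fabs(A[col * k + col]);
      for (int r = col + 1; r < k; ++r) {
        double v = std::fabs(A[r * k + col]);
        if (v > best) { best = v; piv = r; }
      }
      if (best < 1e-10) { ok = false; break; }
      if (piv != col) {
        for (int c = 0; c < k; ++c) std::swap(A[col * k + c], A[piv * k + c]);
        std::swap(b[col], b[piv]);
      }
      for (int r = col + 1; r < k; ++r) {
        double f = A[r * k + col] / A[col * k + col];
        if (f == 0.0) continue;
        for (int c = col; c < k; ++c) A[r * k + c] -= f * A[col * k + c];
        b[r] -= f * b[col];
      }
    }
    if (ok) {
      for (int r = k - 1; r >= 0; --r) {
        double s = b[r];
        for (int c = r + 1; c < k; ++c) s -= A[r * k + c] * b[c];
        b[r] = s / A[r * k + r];
      }
      return true;
    }
    for (int i = 0; i < k; ++i) S[i * k + i] += 1e-8;  // ridge retry
  }
  return false;
}

struct Scorer {
  const NumericMatrix &C;   // crossprod(cbind(1, t(data))): (p+1) x (p+1)
  int n;                    // samples
  std::vector<std::unordered_map<uint64_t, double> > memo;
  Scorer(const NumericMatrix &C_, int n_, int p) : C(C_), n(n_), memo(p) {}

  double operator()(int j, const std::vector<int> &parents) {
    uint64_t key = 0;
    for (int u : parents) key |= (uint64_t(1) << u);
    auto &m = memo[j];
    auto hit = m.find(key);
    if (hit != m.end()) return hit->second;
    int k = (int)parents.size() + 1;
    std::vector<int> idx(k);
    idx[0] = 0;
    for (int t = 0; t < k - 1; ++t) idx[t + 1] = parents[t] + 1;
    std::vector<double> S(k * k), y(k), b;
    int yj = j + 1;
    for (int a = 0; a < k; ++a) {
      y[a] = C(idx[a], yj);
      for (int c = 0; c < k; ++c) S[a * k + c] = C(idx[a], idx[c]);
    }
    double rss;
    if (solve_small(S, y, k, b)) {
      double dot = 0;
      for (int a = 0; a < k; ++a) dot += b[a] * y[a];
      rss = C(yj, yj) - dot;
    } else {
      rss = C(yj, yj) - C(0, yj) * C(0, yj) / C(0, 0);  // marginal fallback
    }
    if (rss < 1e-12) rss = 1e-12;
    double kk = (double)parents.size() + 2.0;
    double sc = -n / 2.0 * (std::log(2.0 * M_PI * rss / n) + 1.0) -
                kk / 2.0 * std::log((double)n);
    m[key] = sc;
    return sc;
  }
};

inline int rand_int(int p) {
  int v = (int)(unif_rand() * p);
  return v >= p ? p - 1 : v;
}

// is `to` reachable from `from` along children lists?
bool has_path(const std::vector<std::vector<int> > &children, int from,
              int to, int p) {
  if (from == to) return true;
  std::vector<char> visited(p, 0);
  std::vector<int> stack{from};
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    if (visited[v]) continue;
    visited[v] = 1;
    for (int w : children[v]) {
      if (w == to) return true;
      if (!visited[w]) stack.push_back(w);
    }
  }
  return false;
}

void reachable(const std::vector<std::vector<int> > &children, int from,
               std::vector<char> &visited) {
  std::fill(visited.begin(), visited.end(), 0);
  std::vector<int> stack{from};
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    if (visited[v]) continue;
    visited[v] = 1;
    for (int w : children[v]) if (!visited[w]) stack.push_back(w);
  }
}

void erase_val(std::vector<int> &v, int x) {
  for (size_t t = 0; t < v.size(); ++t)
    if (v[t] == x) { v.erase(v.begin() + t); return; }
}

void insert_sorted(std::vector<int> &v, int x) {
  v.insert(std::upper_bound(v.begin(), v.end(), x), x);
}

}  // namespace

// [[Rcpp::export(name = ".mcmc_chain_cpp")]]
List mcmc_chain_cpp(NumericMatrix C, int n_samples, LogicalMatrix banned,
                    int n_iter, int burn_in, int max_parents,
                    double init_density, double swap_prob,
                    double anneal_from, bool output_best) {
  int p = C.nrow() - 1;
  if (p > 60) stop("the compiled sampler supports at most 60 genes");
  Scorer scorer(C, n_samples, p);

  std::vector<std::vector<int> > parents(p), children(p);
  std::vector<char> amat(p * p, 0);

  // random initial DAG honoring the constraints: random order, forward
  // edges with probability 2 * init_density / (p - 1)
  std::vector<int> perm(p);
  for (int i = 0; i < p; ++i) perm[i] = i;
  for (int i = p - 1; i > 0; --i) std::swap(perm[i], perm[rand_int(i + 1)]);
  double p_init = 2.0 * init_density / (p - 1);
  if (p_init > 1) p_init = 1;
  for (int a = 0; a < p - 1; ++a)
    for (int b = a + 1; b < p; ++b) {
      int u = perm[a], v = perm[b];
      if (!banned(u, v) && (int)parents[v].size() < max_parents &&
          unif_rand() < p_init) {
        amat[u * p + v] = 1;
        insert_sorted(parents[v], u);
        insert_sorted(children[u], v);
      }
    }

  std::vector<double> node_score(p);
  double total = 0;
  for (int j = 0; j < p; ++j) {
    node_score[j] = scorer(j, parents[j]);
    total += node_score[j];
  }
  double best_score = total;
  std::vector<char> best_amat(amat);
  long accepted = 0;
  std::vector<char> visited(p);
  const double log2c = std::log(2.0);

  for (int it = 1; it <= n_iter; ++it) {
    double temp = 1.0;
    if (anneal_from > 1 && burn_in > 0 && it <= burn_in)
      temp = std::pow(anneal_from, 1.0 - (double)(it - 1) / burn_in);

    if (swap_prob > 0 && unif_rand() < swap_prob) {
      // parent swap: replace one parent of j by a legal non-parent
      // (symmetric proposal: candidate sets have equal size both ways)
      int j = rand_int(p);
      if (!parents[j].empty()) {
        int u = parents[j][rand_int((int)parents[j].size())];
        reachable(children, j, visited);  // downstream of j, incl. j
        std::vector<int> cand;
        for (int v = 0; v < p; ++v)
          if (!visited[v] && !banned(v, j) && !amat[v * p + j])
            cand.push_back(v);
        if (!cand.empty()) {
          int v = cand[rand_int((int)cand.size())];
          std::vector<int> new_pj(parents[j]);
          erase_val(new_pj, u);
          insert_sorted(new_pj, v);
          double delta = scorer(j, new_pj) - node_score[j];
          if (std::log(unif_rand()) < delta / temp) {
            amat[u * p + j] = 0;
            amat[v * p + j] = 1;
            parents[j] = new_pj;
            erase_val(children[u], j);
            insert_sorted(children[v], j);
            node_score[j] += delta;
            total += delta;
            ++accepted;
          }
        }
      }
    } else {
      int i = rand_int(p);
      int j = rand_int(p - 1);
      if (j >= i) ++j;
      if (amat[i * p + j]) {
        if (unif_rand() < 0.5) {  // delete i -> j
          std::vector<int> new_pj(parents[j]);
          erase_val(new_pj, i);
          double delta = scorer(j, new_pj) - node_score[j];
          if (std::log(unif_rand()) < (delta + log2c) / temp) {
            amat[i * p + j] = 0;
            parents[j] = new_pj;
            erase_val(children[i], j);
            node_score[j] += delta;
            total += delta;
            ++accepted;
          }
        } else {  // reverse i -> j
          if (!banned(j, i) && (int)parents[i].size() < max_parents) {
            erase_val(children[i], j);
            bool cyc = has_path(children, i, j, p);
            if (!cyc) {
              std::vector<int> new_pj(parents[j]), new_pi(parents[i]);
              erase_val(new_pj, i);
              insert_sorted(new_pi, j);
              double dj = scorer(j, new_pj) - node_score[j];
              double di = scorer(i, new_pi) - node_score[i];
              if (std::log(unif_rand()) < (dj + di) / temp) {
                amat[i * p + j] = 0;
                amat[j * p + i] = 1;
                parents[j] = new_pj;
                parents[i] = new_pi;
                insert_sorted(children[j], i);
                node_score[j] += dj;
                node_score[i] += di;
                total += dj + di;
                ++accepted;
              } else {
                insert_sorted(children[i], j);
              }
            } else {
              insert_sorted(children[i], j);
            }
          }
        }
      } else {  // add i -> j
        if (!banned(i, j) && (int)parents[j].size() < max_parents &&
            !amat[j * p + i] && !has_path(children, j, i, p)) {
          std::vector<int> new_pj(parents[j]);
          insert_sorted(new_pj, i);
          double delta = scorer(j, new_pj) - node_score[j];
          if (std::log(unif_rand()) < (delta - log2c) / temp) {
            amat[i * p + j] = 1;
            parents[j] = new_pj;
            insert_sorted(children[i], j);
            node_score[j] += delta;
            total += delta;
            ++accepted;
          }
        }
      }
    }
    if (output_best && it > burn_in && total > best_score) {
      best_score = total;
      best_amat = amat;
    }
  }

  const std::vector<char> &out = output_best ? best_amat : amat;
  LogicalMatrix res(p, p);
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j) res(i, j) = out[i * p + j] != 0;
  return List::create(_["amat"] = res,
                      _["score"] = output_best ? best_score : total,
                      _["acceptance_rate"] = (double)accepted / n_iter);
}
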