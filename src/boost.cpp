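// Gradient-boosted trees for binary outcomes (logistic loss, histogram
// split finding), interventional TreeSHAP against an explicit background,
// and a silhouette score kernel. Kept deliberately small: depth-limited
// exact-greedy-on-bins trees are all the pipeline needs, and the explicit
// split structure is what makes the Shapley attribution exactly testable.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <functional>
#include <cmath>
using namespace Rcpp;

namespace {

struct TreeArrays {
  // feature < 0 marks a leaf; children indices are global
  std::vector<int> feature, left, right;
  std::vector<double> threshold, value;
  std::vector<int> roots;
};

struct BuildCtx {
  const std::vector<uint8_t> &bins; // column-major n x d bin indices
  int n;
  const std::vector<std::vector<double>> &thr; // candidate thresholds per feature
  std::vector<double> &grad, &hess;
  std::vector<double> &margin;
  TreeArrays &out;
  int max_depth;
  double lambda, eta, min_child_weight;
};

// rows/g/h are aligned compact arrays for this node (g/h gathered once at
// the root so the histogram pass streams contiguous memory)
int build_node(BuildCtx &c, std::vector<int> &rows, std::vector<double> &g,
               std::vector<double> &h, int depth, double Gtot, double Htot) {
  const int d = (int)c.thr.size();
  const size_t m = rows.size();
  int best_f = -1, best_s = -1;
  double best_gain = 0.0;
  const double parent_score = Gtot * Gtot / (Htot + c.lambda);

  if (depth < c.max_depth && m >= 2) {
    double Gb[256], Hb[256];
    for (int f = 0; f < d; ++f) {
      const int nb = (int)c.thr[f].size();
      if (nb == 0) continue;
      std::fill(Gb, Gb + nb + 1, 0.0);
      std::fill(Hb, Hb + nb + 1, 0.0);
      const uint8_t *bc = c.bins.data() + (size_t)f * c.n;
      for (size_t i = 0; i < m; ++i) {
        const int b = bc[rows[i]];
        Gb[b] += g[i];
        Hb[b] += h[i];
      }
      double GL = 0.0, HL = 0.0;
      for (int s = 0; s < nb; ++s) { // split: left iff bin <= s i.e. x < thr[s]
        GL += Gb[s]; HL += Hb[s];
        const double GR = Gtot - GL, HR = Htot - HL;
        if (HL < c.min_child_weight || HR < c.min_child_weight) continue;
        const double gain = 0.5 * (GL * GL / (HL + c.lambda) +
                                   GR * GR / (HR + c.lambda) - parent_score);
        if (gain > best_gain + 1e-12) {
          best_gain = gain; best_f = f; best_s = s;
        }
      }
    }
  }

  const int id = (int)c.out.feature.size();
  c.out.feature.push_back(-1);
  c.out.left.push_back(-1);
  c.out.right.push_back(-1);
  c.out.threshold.push_back(0.0);
  c.out.value.push_back(0.0);

  if (best_f < 0) { // leaf
    const double w = -c.eta * Gtot / (Htot + c.lambda);
    c.out.value[id] = w;
    for (size_t i = 0; i < m; ++i) c.margin[rows[i]] += w;
    return id;
  }

  std::vector<int> lrows, rrows;
  std::vector<double> lg, lh, rg, rh;
  lrows.reserve(m); lg.reserve(m); lh.reserve(m);
  double GL = 0.0, HL = 0.0;
  const uint8_t *bc = c.bins.data() + (size_t)best_f * c.n;
  for (size_t i = 0; i < m; ++i) {
    if (bc[rows[i]] <= best_s) {
      lrows.push_back(rows[i]); lg.push_back(g[i]); lh.push_back(h[i]);
      GL += g[i]; HL += h[i];
    } else {
      rrows.push_back(rows[i]); rg.push_back(g[i]); rh.push_back(h[i]);
    }
  }
  rows.clear(); rows.shrink_to_fit();
  g.clear(); g.shrink_to_fit();
  h.clear(); h.shrink_to_fit();
  c.out.feature[id] = best_f;
  c.out.threshold[id] = c.thr[best_f][best_s];
  const int lid = build_node(c, lrows, lg, lh, depth + 1, GL, HL);
  const int rid = build_node(c, rrows, rg, rh, depth + 1,
                             Gtot - GL, Htot - HL);
  c.out.left[id] = lid;
  c.out.right[id] = rid;
  return id;
}

// row: pointer to a gathered dense feature vector for one instance
double predict_row(const TreeArrays &t, const double *row) {
  double m = 0.0;
  for (int root : t.roots) {
    int node = root;
    int f;
    while ((f = t.feature[node]) >= 0)
      node = (row[f] < t.threshold[node]) ? t.left[node] : t.right[node];
    m += t.value[node];
  }
  return m;
}

void gather_row(const NumericMatrix &X, int i, std::vector<double> &buf) {
  const int d = X.ncol(), n = X.nrow();
  const double *base = REAL(X);
  for (int f = 0; f < d; ++f) buf[f] = base[(size_t)f * n + i];
}

TreeArrays unpack(const List &model) {
  TreeArrays t;
  IntegerVector f = model["feature"], l = model["left"], r = model["right"],
                ro = model["roots"];
  NumericVector th = model["threshold"], v = model["value"];
  t.feature.assign(f.begin(), f.end());
  t.left.assign(l.begin(), l.end());
  t.right.assign(r.begin(), r.end());
  t.threshold.assign(th.begin(), th.end());
  t.value.assign(v.begin(), v.end());
  t.roots.assign(ro.begin(), ro.end());
  return t;
}

} // namespace

// [[Rcpp::export]]
List cpp_boost_fit(NumericMatrix X, NumericVector y, int nrounds,
                   int max_depth, double eta, double lambda,
                   double min_child_weight, double scale_pos_weight,
                   int n_bins) {
  const int n = X.nrow(), d = X.ncol();

  if (n_bins > 255) stop("n_bins must be at most 255");

  // candidate thresholds from column quantiles, then bin indices
  std::vector<std::vector<double>> thr(d);
  std::vector<uint8_t> bins((size_t)n * d);
  std::vector<double> col(n);
  for (int f = 0; f < d; ++f) {
    for (int i = 0; i < n; ++i) col[i] = X(i, f);
    std::sort(col.begin(), col.end());
    std::vector<double> cand;
    for (int q = 1; q < n_bins; ++q) {
      const double v = col[(size_t)((double)q / n_bins * (n - 1))];
      if (cand.empty() || v > cand.back()) cand.push_back(v);
    }
    // drop a threshold equal to the minimum: it would never send rows left
    while (!cand.empty() && cand.front() <= col[0]) cand.erase(cand.begin());
    thr[f] = cand;
    // bin = number of thresholds <= v, so "left of split s" is bin <= s
    // exactly when v < thr[s]
    uint8_t *bc = bins.data() + (size_t)f * n;
    for (int i = 0; i < n; ++i) {
      const double v = X(i, f);
      bc[i] = (uint8_t)(std::upper_bound(thr[f].begin(), thr[f].end(), v) -
                        thr[f].begin());
    }
  }

  std::vector<double> margin(n, 0.0), grad(n), hess(n), w(n);
  for (int i = 0; i < n; ++i) w[i] = (y[i] > 0.5) ? scale_pos_weight : 1.0;

  TreeArrays out;
  BuildCtx ctx{bins, n, thr, grad, hess, margin, out,
               max_depth, lambda, eta, min_child_weight};

  for (int round = 0; round < nrounds; ++round) {
    double Gtot = 0.0, Htot = 0.0;
    for (int i = 0; i < n; ++i) {
      const double p = 1.0 / (1.0 + std::exp(-margin[i]));
      grad[i] = w[i] * (p - y[i]);
      hess[i] = std::max(w[i] * p * (1.0 - p), 1e-16);
      Gtot += grad[i]; Htot += hess[i];
    }
    std::vector<int> rows(n);
    std::vector<double> g(grad), h(hess);
    for (int i = 0; i < n; ++i) rows[i] = i;
    out.roots.push_back(build_node(ctx, rows, g, h, 0, Gtot, Htot));
  }

  return List::create(
      _["feature"] = IntegerVector(out.feature.begin(), out.feature.end()),
      _["threshold"] = NumericVector(out.threshold.begin(), out.threshold.end()),
      _["left"] = IntegerVector(out.left.begin(), out.left.end()),
      _["right"] = IntegerVector(out.right.begin(), out.right.end()),
      _["value"] = NumericVector(out.value.begin(), out.value.end()),
      _["roots"] = IntegerVector(out.roots.begin(), out.roots.end()),
      _["n_features"] = d);
}

// [[Rcpp::export]]
NumericVector cpp_boost_predict(List model, NumericMatrix X) {
  TreeArrays t = unpack(model);
  const int n = X.nrow();
  NumericVector out(n);
  std::vector<double> buf(X.ncol());
  for (int i = 0; i < n; ++i) {
    gather_row(X, i, buf);
    out[i] = predict_row(t, buf.data());
  }
  return out;
}

// Interventional (marginal-expectation) TreeSHAP against an explicit
// background sample. For each (explained row x, background row b) pair and
// each root-to-leaf path, the leaf value enters the coalition game as a
// unanimity-style term: reachable for coalitions S that contain every
// feature where only x satisfies the path (set U) and exclude every feature
// where only b satisfies it (set D). Shapley weights of such a term have
// the closed form used below; contributions are averaged over background.
// [[Rcpp::export]]
List cpp_tree_shap(List model, NumericMatrix Xe, NumericMatrix B) {
  TreeArrays t = unpack(model);
  const int n = Xe.nrow(), m = B.nrow(), d = Xe.ncol();
  NumericMatrix phi(n, d);

  // factorial weight tables up to depth 16
  const int MD = 17;
  double fact[2 * MD];
  fact[0] = 1.0;
  for (int i = 1; i < 2 * MD; ++i) fact[i] = fact[i - 1] * i;

  struct PathCond { int feature; double thr; bool go_left; };
  struct Path { std::vector<PathCond> conds; double value; };

  // enumerate all root-to-leaf paths once per model
  std::vector<Path> paths;
  std::vector<PathCond> stack_conds;
  std::function<void(int)> walk = [&](int node) {
    if (t.feature[node] < 0) {
      if (t.value[node] != 0.0)
        paths.push_back({stack_conds, t.value[node]});
      return;
    }
    stack_conds.push_back({t.feature[node], t.threshold[node], true});
    walk(t.left[node]);
    stack_conds.back().go_left = false;
    walk(t.right[node]);
    stack_conds.pop_back();
  };
  for (int root : t.roots) walk(root);

  // dense row buffers (column-major matrix access is slow in the pair loop)
  std::vector<std::vector<double>> xe(n, std::vector<double>(d));
  std::vector<std::vector<double>> bg(m, std::vector<double>(d));
  for (int i = 0; i < n; ++i) gather_row(Xe, i, xe[i]);
  for (int j = 0; j < m; ++j) gather_row(B, j, bg[j]);

  // per-pair evaluation
  std::vector<int> ufeat(MD), dfeat(MD);
  std::vector<int> pf(MD);
  std::vector<bool> xall(MD), ball(MD);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      for (const Path &p : paths) {
        int npf = 0;
        bool reachable = true;
        for (const PathCond &c : p.conds) {
          const bool xok = (xe[i][c.feature] < c.thr) == c.go_left;
          const bool bok = (bg[j][c.feature] < c.thr) == c.go_left;
          int k = 0;
          for (; k < npf; ++k) if (pf[k] == c.feature) break;
          if (k == npf) { pf[npf] = c.feature; xall[npf] = true; ball[npf] = true; ++npf; }
          xall[k] = xall[k] && xok;
          ball[k] = ball[k] && bok;
        }
        int u = 0, dd = 0;
        for (int k = 0; k < npf; ++k) {
          if (!xall[k] && !ball[k]) { reachable = false; break; }
          if (xall[k] && !ball[k]) ufeat[u++] = pf[k];
          else if (!xall[k] && ball[k]) dfeat[dd++] = pf[k];
        }
        if (!reachable || (u == 0 && dd == 0)) continue;
        const double denom = fact[u + dd];
        if (u > 0) {
          const double wU = p.value * fact[u - 1] * fact[dd] / denom;
          for (int k = 0; k < u; ++k) phi(i, ufeat[k]) += wU;
        }
        if (dd > 0) {
          const double wD = p.value * fact[u] * fact[dd - 1] / denom;
          for (int k = 0; k < dd; ++k) phi(i, dfeat[k]) -= wD;
        }
      }
    }
  }
  for (int i = 0; i < n; ++i)
    for (int f = 0; f < d; ++f) phi(i, f) /= m;

  double base = 0.0;
  for (int j = 0; j < m; ++j) base += predict_row(t, bg[j].data());
  base /= m;

  return List::create(_["phi"] = phi, _["base"] = base);
}

// Mean silhouette width, Euclidean metric; singleton clusters score 0.
// [[Rcpp::export]]
double cpp_silhouette(NumericMatrix X, IntegerVector labels, int k) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<int> size(k, 0);
  for (int i = 0; i < n; ++i) size[labels[i]]++;
  double total = 0.0;
  std::vector<double> csum(k);
  for (int i = 0; i < n; ++i) {
    std::fill(csum.begin(), csum.end(), 0.0);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double s2 = 0.0;
      for (int f = 0; f < d; ++f) {
        const double diff = X(i, f) - X(j, f);
        s2 += diff * diff;
      }
      csum[labels[j]] += std::sqrt(s2);
    }
    const int li = labels[i];
    if (size[li] <= 1) continue; // s = 0 for singletons
    const double a = csum[li] / (size[li] - 1);
    double b = R_PosInf;
    for (int c = 0; c < k; ++c)
      if (c != li && size[c] > 0) b = std::min(b, csum[c] / size[c]);
    const double mx = std::max(a, b);
    if (mx > 0) total += (b - a) / mx;
  }
  return total / n;
}
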