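#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Single-pass ancestry linking over time-ordered edges.
//
// Each sample node starts with one segment (0, L) tagged with its own id.
// Edges arrive ordered by (parent time, parent, child, left), so by the time
// an edge (l, r, p, c) is processed, node c's segment list is complete: it
// holds exactly the sample material currently mapped to c. The parts of
// those segments falling inside [l, r) move up to p. When p is one of the
// requested ancestors the pieces are emitted as output rows and are NOT
// forwarded further, which implements the most-recent-ancestor rule: a
// position is linked to the youngest requested ancestor on its path.
//
// Per-node lists are kept sorted by (sample, left) with exactly-adjacent
// same-sample pieces coalesced, and a node's list is freed as soon as its
// last child-edge has been processed (it can receive nothing more).

struct Seg {
  double l, r;
  int s;
};

// [[Rcpp::export]]
List link_ancestors_cpp(NumericVector e_left, NumericVector e_right,
                        IntegerVector e_parent, IntegerVector e_child,
                        int n_nodes, IntegerVector samples,
                        LogicalVector is_ancestor, double L) {
  std::vector<std::vector<Seg>> state(n_nodes);
  for (int i = 0; i < samples.size(); ++i) {
    state[samples[i]].push_back({0.0, L, samples[i]});
  }

  const int ne = e_left.size();
  std::vector<int> remaining(n_nodes, 0);
  for (int i = 0; i < ne; ++i) remaining[e_child[i]]++;

  std::vector<double> out_l, out_r;
  std::vector<int> out_a, out_s;
  std::vector<Seg> inter, merged;

  for (int i = 0; i < ne; ++i) {
    const int c = e_child[i], p = e_parent[i];
    std::vector<Seg> &cs = state[c];
    if (!cs.empty()) {
      const double el = e_left[i], er = e_right[i];
      inter.clear();
      for (const Seg &sg : cs) {
        const double il = sg.l > el ? sg.l : el;
        const double ir = sg.r < er ? sg.r : er;
        if (il < ir) inter.push_back({il, ir, sg.s});
      }
      if (!inter.empty()) {
        if (is_ancestor[p]) {
          for (const Seg &sg : inter) {
            out_l.push_back(sg.l);
            out_r.push_back(sg.r);
            out_a.push_back(p);
            out_s.push_back(sg.s);
          }
        } else {
          // merge the (sample, left)-sorted intersections into p's sorted
          // list, coalescing exactly-adjacent pieces of the same sample
          std::vector<Seg> &ps = state[p];
          merged.clear();
          merged.reserve(ps.size() + inter.size());
          size_t a = 0, b = 0;
          auto push = [&](const Seg &sg) {
            if (!merged.empty()) {
              Seg &bk = merged.back();
              if (bk.s == sg.s && bk.r == sg.l) {
                bk.r = sg.r;
                return;
              }
            }
            merged.push_back(sg);
          };
          while (a < ps.size() || b < inter.size()) {
            bool take_a;
            if (a >= ps.size()) take_a = false;
            else if (b >= inter.size()) take_a = true;
            else take_a = (ps[a].s < inter[b].s) ||
                          (ps[a].s == inter[b].s && ps[a].l <= inter[b].l);
            push(take_a ? ps[a++] : inter[b++]);
          }
          ps.swap(merged);
        }
      }
    }
    if (--remaining[c] == 0) {
      std::vector<Seg>().swap(state[c]);  // prune: c can receive nothing more
    }
  }

  return List::create(
      _["left"] = NumericVector(out_l.begin(), out_l.end()),
      _["right"] = NumericVector(out_r.begin(), out_r.end()),
      _["ancestor"] = IntegerVector(out_a.begin(), out_a.end()),
      _["sample"] = IntegerVector(out_s.begin(), out_s.end()));
}
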