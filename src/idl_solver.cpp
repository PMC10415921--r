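// A small complete solver for CNF formulas over Integer Difference Logic
// (IDL) atoms x_i - x_j <= c. Used to resolve the node-ordering constraint
// systems produced by the Wheeler graph encodings.
//
// Method: DPLL(T) with a difference-constraint theory core and eager
// theory propagation. A feasible potential function (one integer per
// variable, satisfying every asserted constraint) is maintained at all
// times via incremental Bellman-Ford relaxation; asserting a constraint
// either repairs the potentials or exposes a negative cycle, detected
// incrementally (a new arc j->i is in a negative cycle iff the repair
// cascade it triggers reaches j again). Unit clauses are installed in bulk
// (deduplicated to the tightest bound per variable pair) followed by one
// global repair. Propagation probes every clause woken by a potential
// change: a clause with no theory-consistent literal is a conflict, one
// with exactly one forces that literal. Decisions are only made on clauses
// the current model violates after propagation reaches a fixpoint; if no
// clause is violated the potentials themselves are a model. Backtracking
// is chronological.
//
// Variable 0 is a fixed reference point; reported values are pot[i]-pot[0].

#include <Rcpp.h>
#include <chrono>
#include <cstdint>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

namespace {

struct Arc { int head; int w; };

class IdlCore {
public:
  int nv;
  std::vector<std::vector<Arc>> adj;   // adj[j]: constraints x_h - x_j <= w
  std::vector<long long> pot;
  std::vector<std::pair<int, long long>> pot_trail;
  std::vector<int> arc_trail;
  std::vector<uint32_t> relax_epoch;
  std::vector<int> relax_count;
  std::vector<char> in_queue;
  uint32_t epoch = 0;

  IdlCore(int nvars, const std::vector<long long>& init)
      : nv(nvars), adj(nvars + 1), pot(init),
        relax_epoch(nvars + 1, 0), relax_count(nvars + 1, 0),
        in_queue(nvars + 1, 0) {}

  int bump(int u) {
    if (relax_epoch[u] != epoch) { relax_epoch[u] = epoch; relax_count[u] = 0; }
    return ++relax_count[u];
  }

  void add_arc(int i, int j, int c) {
    adj[j].push_back({i, c});
    arc_trail.push_back(j);
  }

  // Repair potentials starting from seed nodes whose in-arcs may be
  // violated; false on negative cycle. watch_tail >= 0 enables the
  // incremental single-arc cycle test; otherwise a relaxation-count bound
  // is used (bulk phase).
  bool repair(std::vector<int> queue, int watch_tail = -1) {
    ++epoch;
    for (int u : queue) in_queue[u] = 1;
    size_t qh = 0;
    while (qh < queue.size()) {
      int u = queue[qh++];
      in_queue[u] = 0;
      if (watch_tail < 0 && bump(u) > nv + 1) { clear_inq(queue, qh); return false; }
      for (const Arc& a : adj[u]) {
        if (pot[a.head] > pot[u] + a.w) {
          if (a.head == watch_tail) { clear_inq(queue, qh); return false; }
          set_pot(a.head, pot[u] + a.w);
          if (!in_queue[a.head]) { in_queue[a.head] = 1; queue.push_back(a.head); }
        }
      }
    }
    return true;
  }

  void clear_inq(const std::vector<int>& queue, size_t qh) {
    for (size_t t = qh; t < queue.size(); ++t) in_queue[queue[t]] = 0;
  }

  bool assert_con(int i, int j, int c) {
    add_arc(i, j, c);
    if (pot[i] <= pot[j] + c) return true;
    set_pot(i, pot[j] + c);
    return repair({i}, j);
  }

  void set_pot(int v, long long val) {
    pot_trail.push_back({v, pot[v]});
    pot[v] = val;
  }

  // undo to the marks; collect the variables whose potential was restored
  void backtrack(size_t pot_mark, size_t arc_mark, std::vector<int>* touched) {
    while (pot_trail.size() > pot_mark) {
      int v = pot_trail.back().first;
      pot[v] = pot_trail.back().second;
      pot_trail.pop_back();
      if (touched) touched->push_back(v);
    }
    while (arc_trail.size() > arc_mark) {
      adj[arc_trail.back()].pop_back();
      arc_trail.pop_back();
    }
  }
};

struct Frame {
  int clause;              // clause index branched on
  int next_lit;            // next position in its literal order to try
  size_t pot_mark, arc_mark, res_mark;
};

}  // namespace

// [[Rcpp::export(name = ".idl_solve_cpp")]]
List idl_solve_cpp(int nvars,
                   IntegerVector cl_start,   // 0-based offsets, length K+1
                   IntegerVector li, IntegerVector lj, IntegerVector lc,
                   IntegerVector init_pot,   // length nvars+1 (var 0 first)
                   double timeout_sec) {
  const int K = cl_start.size() - 1;
  std::vector<long long> init(nvars + 1);
  for (int v = 0; v <= nvars; ++v) init[v] = init_pot[v];
  IdlCore st(nvars, init);
  auto t0 = std::chrono::steady_clock::now();
  auto timed_out = [&]() {
    return std::chrono::duration<double>(
      std::chrono::steady_clock::now() - t0).count() > timeout_sec;
  };

  // ---- preprocessing --------------------------------------------------
  std::vector<int> lits_i, lits_j, lits_c, starts;
  starts.push_back(0);
  std::unordered_map<uint64_t, int> units;  // (i, j) -> tightest c
  bool unsat = false;
  for (int k = 0; k < K && !unsat; ++k) {
    bool taut = false;
    std::vector<int> keep;
    for (int t = cl_start[k]; t < cl_start[k + 1]; ++t) {
      if (li[t] == lj[t]) {
        if (lc[t] >= 0) { taut = true; break; }  // 0 <= c: always true
        continue;                                 // always false: drop
      }
      keep.push_back(t);
    }
    if (taut) continue;
    if (keep.empty()) { unsat = true; break; }
    if (keep.size() == 1) {
      int t = keep[0];
      uint64_t key = (uint64_t)li[t] * (uint64_t)(nvars + 1) + (uint64_t)lj[t];
      auto it = units.find(key);
      if (it == units.end()) units.emplace(key, lc[t]);
      else if (lc[t] < it->second) it->second = lc[t];
      continue;
    }
    for (int t : keep) {
      lits_i.push_back(li[t]); lits_j.push_back(lj[t]); lits_c.push_back(lc[t]);
    }
    starts.push_back((int)lits_i.size());
  }

  long long n_decisions = 0, n_assert = 0, n_probes = 0;
  std::string status = "unknown";

  // ---- bulk unit installation -----------------------------------------
  if (!unsat) {
    std::vector<int> seeds;
    for (const auto& kv : units) {
      int i = (int)(kv.first / (uint64_t)(nvars + 1));
      int j = (int)(kv.first % (uint64_t)(nvars + 1));
      st.add_arc(i, j, kv.second);
      ++n_assert;
      if (st.pot[i] > st.pot[j] + kv.second) {
        st.set_pot(i, st.pot[j] + kv.second);
        seeds.push_back(i);
      }
    }
    if (!st.repair(seeds)) unsat = true;
  }

  const int nK = (int)starts.size() - 1;
  std::vector<char> resolved(nK, 0);
  std::vector<int> res_trail;              // resolved clause indices, stack
  std::vector<std::vector<int>> occ(nvars + 1);
  std::vector<char> dirty(nK, 0);
  std::vector<int> dq;                     // dirty queue
  size_t dh = 0;

  if (!unsat && nK > 0) {
    for (int k = 0; k < nK; ++k)
      for (int t = starts[k]; t < starts[k + 1]; ++t) {
        occ[lits_i[t]].push_back(k);
        occ[lits_j[t]].push_back(k);
      }
    for (auto& o : occ) {
      std::sort(o.begin(), o.end());
      o.erase(std::unique(o.begin(), o.end()), o.end());
    }
    dq.reserve(2 * nK);
    for (int k = 0; k < nK; ++k) { dirty[k] = 1; dq.push_back(k); }
  }

  auto wake_vars_from = [&](size_t pot_mark) {
    for (size_t t = pot_mark; t < st.pot_trail.size(); ++t) {
      int v = st.pot_trail[t].first;
      for (int kk : occ[v])
        if (!dirty[kk] && !resolved[kk]) { dirty[kk] = 1; dq.push_back(kk); }
    }
  };
  auto wake_clauses_of = [&](const std::vector<int>& vars) {
    for (int v : vars)
      for (int kk : occ[v])
        if (!dirty[kk] && !resolved[kk]) { dirty[kk] = 1; dq.push_back(kk); }
  };

  // propagate dirty clauses to fixpoint; false on conflict
  long long steps = 0;
  bool gave_up = false;
  auto propagate = [&]() -> bool {
    while (dh < dq.size()) {
      if (((++steps) & 0xFF) == 0) {
        if (timed_out()) { gave_up = true; return true; }
        Rcpp::checkUserInterrupt();
      }
      int k = dq[dh++];
      dirty[k] = 0;
      if (resolved[k]) continue;
      int ok_count = 0, ok_lit = -1;
      for (int t = starts[k]; t < starts[k + 1]; ++t) {
        // a literal the current potentials satisfy is consistent for free
        if (st.pot[lits_i[t]] - st.pot[lits_j[t]] <= lits_c[t]) {
          ++ok_count; ok_lit = t; if (ok_count > 1) break;
          continue;
        }
        size_t pm = st.pot_trail.size(), am = st.arc_trail.size();
        ++n_probes;
        bool ok = st.assert_con(lits_i[t], lits_j[t], lits_c[t]);
        st.backtrack(pm, am, nullptr);
        if (ok) { ++ok_count; ok_lit = t; if (ok_count > 1) break; }
      }
      if (ok_count == 0) return false;
      if (ok_count == 1) {
        size_t pm = st.pot_trail.size();
        ++n_assert;
        if (!st.assert_con(lits_i[ok_lit], lits_j[ok_lit], lits_c[ok_lit]))
          return false;
        resolved[k] = 1;
        res_trail.push_back(k);
        wake_vars_from(pm);
      }
    }
    if (dh == dq.size()) { dq.clear(); dh = 0; }  // compact
    return true;
  };

  if (!unsat && nK == 0) status = "sat";
  if (!unsat && nK > 0) {
    std::vector<Frame> stack;
    std::vector<std::vector<int>> try_order;
    int scan = 0, clean = 0;
    bool need_propagate = true, done = false;
    std::vector<int> touched;

    // resolve a conflict: chronologically try the next literal of the
    // deepest frame with alternatives left; false when the stack empties
    auto resolve_conflict = [&]() -> bool {
      for (;;) {
        if (stack.empty()) return false;
        Frame& f = stack.back();
        touched.clear();
        st.backtrack(f.pot_mark, f.arc_mark, &touched);
        while (res_trail.size() > f.res_mark) {
          resolved[res_trail.back()] = 0;
          res_trail.pop_back();
        }
        wake_clauses_of(touched);
        const std::vector<int>& tord = try_order.back();
        bool advanced = false;
        while (f.next_lit < (int)tord.size()) {
          int t = tord[f.next_lit++];
          ++n_assert;
          size_t pm = st.pot_trail.size();
          if (st.assert_con(lits_i[t], lits_j[t], lits_c[t])) {
            wake_vars_from(pm);
            advanced = true;
            break;
          }
          touched.clear();
          st.backtrack(f.pot_mark, f.arc_mark, &touched);
          wake_clauses_of(touched);
          if (timed_out()) { gave_up = true; return true; }
        }
        if (advanced) return true;
        stack.pop_back();
        try_order.pop_back();
      }
    };

    while (!done) {
      if (need_propagate) {
        need_propagate = false;
        if (!propagate()) {
          if (!resolve_conflict()) { status = "unsat"; done = true; }
          if (gave_up) done = true;
          need_propagate = true;
          clean = 0;
          continue;
        }
        if (gave_up) { done = true; continue; }
        clean = 0;
      }
      // scan for a clause violated by the current model
      int viol = -1;
      while (clean < nK) {
        int k = scan;
        if (!resolved[k]) {
          bool sat = false;
          for (int t = starts[k]; t < starts[k + 1]; ++t) {
            if (st.pot[lits_i[t]] - st.pot[lits_j[t]] <= lits_c[t]) {
              sat = true; break;
            }
          }
          if (!sat) { viol = k; break; }
        }
        ++clean;
        scan = (scan + 1 == nK) ? 0 : scan + 1;
        if (((++steps) & 0x3FF) == 0) {
          if (timed_out()) { gave_up = true; break; }
          Rcpp::checkUserInterrupt();
        }
      }
      if (gave_up) { done = true; continue; }
      if (viol < 0) { status = "sat"; done = true; continue; }
      // decide: branch on the violated clause, last literal first (for the
      // two-literal Wheeler clauses this prefers re-aligning the
      // destination pair, the propagation direction of the co-lex order),
      // then by slack
      std::vector<int> ord;
      for (int t = starts[viol + 1] - 1; t >= starts[viol]; --t) ord.push_back(t);
      std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
        long long sa = st.pot[lits_i[a]] - st.pot[lits_j[a]] - lits_c[a];
        long long sb = st.pot[lits_i[b]] - st.pot[lits_j[b]] - lits_c[b];
        return sa < sb;
      });
      stack.push_back({viol, 0, st.pot_trail.size(), st.arc_trail.size(),
                       res_trail.size()});
      try_order.push_back(ord);
      ++n_decisions;
      Frame& f = stack.back();
      bool ok = false;
      while (f.next_lit < (int)try_order.back().size()) {
        int t = try_order.back()[f.next_lit++];
        ++n_assert;
        size_t pm = st.pot_trail.size();
        if (st.assert_con(lits_i[t], lits_j[t], lits_c[t])) {
          wake_vars_from(pm);
          ok = true;
          break;
        }
        touched.clear();
        st.backtrack(f.pot_mark, f.arc_mark, &touched);
        wake_clauses_of(touched);
        if (timed_out()) { gave_up = true; break; }
      }
      if (gave_up) { done = true; continue; }
      if (!ok) {
        stack.pop_back();
        try_order.pop_back();
        if (!resolve_conflict()) { status = "unsat"; done = true; }
        if (gave_up) done = true;
      }
      need_propagate = true;
    }
    if (gave_up) status = "unknown";
  }
  if (unsat) status = "unsat";

  IntegerVector model(nvars);
  if (status == "sat") {
    for (int v = 1; v <= nvars; ++v)
      model[v - 1] = (int)(st.pot[v] - st.pot[0]);
  }
  return List::create(_["status"] = status,
                      _["model"] = model,
                      _["decisions"] = (double)n_decisions,
                      _["probes"] = (double)n_probes,
                      _["assertions"] = (double)n_assert);
}
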