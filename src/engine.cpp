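// Event-driven SIS engine: sequential next-reaction baseline and the
// epoch-synchronized partitioned variant (border-summary and ghost-cell
// exchange), sharing one set of event primitives.
//
// Event identities (at most one live event per key):
//   REC(v)          id = v                       v in [0, n)
//   INF_LOCAL(u->w) id = n + j                   j = directed-edge slot of w
//                                                in u's adjacency (CSR)
//   INF_REMOTE(Q->v) id = n + 2E + bp            bp = border-pair slot (v, Q)
//
// The queue is an indexed binary min-heap on scheduled time, with true
// removal by key (no tombstones).  Ties (measure-zero under continuous
// draws) break on the integer event id, which orders REC < INF_LOCAL <
// INF_REMOTE and then by a fixed (source, target) encoding, so runs are
// deterministic under a seed.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <random>
#include <algorithm>

using namespace Rcpp;

namespace {

const int KIND_REC = 0;
const int KIND_INF_LOCAL = 1;
const int KIND_INF_REMOTE = 2;

inline uint64_t splitmix64(uint64_t& x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// Per-process random stream.  Inverse-CDF exponentials on top of
// mt19937_64 keep draws bitwise reproducible across platforms.
struct Stream {
  std::mt19937_64 gen;
  void seed(uint64_t master, uint64_t part) {
    uint64_t s = master ^ (0xD1B54A32D192ED03ULL * (part + 1));
    uint64_t a = splitmix64(s);
    (void)splitmix64(s);
    gen.seed(a);
  }
  double unif01() {  // in (0, 1)
    return (static_cast<double>(gen() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double expo(double rate) { return -std::log(unif01()) / rate; }
};

struct Engine {
  // graph (CSR over sorted adjacency)
  int n;
  std::vector<int> off, nbr;
  std::vector<int> esrc;  // source vertex of directed edge slot j
  std::vector<int> erev;  // slot of the reverse directed edge
  int n_dir_edges;

  // partition
  int M;
  std::vector<int> part;

  // border pairs: CSR per vertex over remote parts with >= 1 neighbor
  std::vector<int> boff;      // size n+1
  std::vector<int> bQ;        // remote part of border pair
  std::vector<int> bcnt;      // n_{Q->v}
  std::vector<double> brate;  // current-epoch Inf(Q->v) rate
  std::vector<int> border_verts;

  // channels (ordered process pairs with cross edges)
  std::vector<int> chan_idx;            // M*M -> channel id or -1
  std::vector<int> chan_from, chan_to;  // sender, receiver
  std::vector<int> chan_N;              // N_{P->Q}
  std::vector<int> chan_boff;           // offsets into chan_blist
  std::vector<int> chan_blist;          // B_{P->Q} vertex lists
  std::vector<long long> chan_msgs;
  long long total_msgs = 0;

  // state
  std::vector<uint8_t> state;  // 0 = SUS, 1 = INF
  int n_inf = 0;

  // event store + indexed heap
  int n_events;
  std::vector<double> tm;
  std::vector<int> heap, pos;

  // rng
  std::vector<Stream> rng;

  double beta, gamma;
  bool validate;

  // log
  std::vector<double> ev_t;
  std::vector<int> ev_kind, ev_src, ev_tgt;

  // ---- heap primitives -------------------------------------------------
  bool less_ev(int a, int b) const {
    if (tm[a] != tm[b]) return tm[a] < tm[b];
    return a < b;
  }
  void sift_up(int i) {
    int id = heap[i];
    while (i > 0) {
      int p = (i - 1) >> 1;
      if (less_ev(id, heap[p])) { heap[i] = heap[p]; pos[heap[i]] = i; i = p; }
      else break;
    }
    heap[i] = id; pos[id] = i;
  }
  void sift_down(int i) {
    int id = heap[i];
    int sz = (int)heap.size();
    for (;;) {
      int c = 2 * i + 1;
      if (c >= sz) break;
      if (c + 1 < sz && less_ev(heap[c + 1], heap[c])) ++c;
      if (less_ev(heap[c], id)) { heap[i] = heap[c]; pos[heap[i]] = i; i = c; }
      else break;
    }
    heap[i] = id; pos[id] = i;
  }
  void push_ev(int id, double t) {
    tm[id] = t;
    heap.push_back(id);
    pos[id] = (int)heap.size() - 1;
    sift_up(pos[id]);
  }
  void remove_ev(int id) {
    int i = pos[id];
    int last = heap.back();
    heap.pop_back();
    pos[id] = -1;
    if (last != id) {
      heap[i] = last; pos[last] = i;
      sift_down(i);
      sift_up(i);
    }
  }

  // ---- setup -----------------------------------------------------------
  void init_graph(const IntegerVector& off_, const IntegerVector& nbr_) {
    off.assign(off_.begin(), off_.end());
    nbr.assign(nbr_.begin(), nbr_.end());
    n = (int)off.size() - 1;
    n_dir_edges = (int)nbr.size();
    esrc.resize(n_dir_edges);
    for (int v = 0; v < n; ++v)
      for (int j = off[v]; j < off[v + 1]; ++j) esrc[j] = v;
    erev.resize(n_dir_edges);
    for (int j = 0; j < n_dir_edges; ++j) {
      int u = esrc[j], w = nbr[j];
      // adjacency is sorted: binary-search u in w's list
      const int* lo = nbr.data() + off[w];
      const int* hi = nbr.data() + off[w + 1];
      const int* it = std::lower_bound(lo, hi, u);
      erev[j] = (int)(it - nbr.data());
    }
  }

  void init_partition(const IntegerVector& part_, int M_) {
    M = M_;
    part.assign(part_.begin(), part_.end());
    boff.assign(n + 1, 0);
    std::vector<int> tmp_cnt(M, 0);
    std::vector<int> seenQ;
    std::vector<std::vector<int>> vQ(n), vC(n);
    for (int v = 0; v < n; ++v) {
      seenQ.clear();
      int P = part[v];
      for (int j = off[v]; j < off[v + 1]; ++j) {
        int Q = part[nbr[j]];
        if (Q != P) {
          if (tmp_cnt[Q] == 0) seenQ.push_back(Q);
          tmp_cnt[Q]++;
        }
      }
      std::sort(seenQ.begin(), seenQ.end());
      for (int Q : seenQ) { vQ[v].push_back(Q); vC[v].push_back(tmp_cnt[Q]); tmp_cnt[Q] = 0; }
      boff[v + 1] = boff[v] + (int)vQ[v].size();
      if (!vQ[v].empty()) border_verts.push_back(v);
    }
    bQ.reserve(boff[n]); bcnt.reserve(boff[n]);
    for (int v = 0; v < n; ++v) {
      bQ.insert(bQ.end(), vQ[v].begin(), vQ[v].end());
      bcnt.insert(bcnt.end(), vC[v].begin(), vC[v].end());
    }
    brate.assign(boff[n], 0.0);

    // channels: (P, Q) has a channel iff some vertex of P borders Q
    chan_idx.assign((size_t)M * M, -1);
    std::vector<std::vector<int>> blists;
    for (int v : border_verts) {
      int P = part[v];
      for (int b = boff[v]; b < boff[v + 1]; ++b) {
        int Q = bQ[b];
        int key = P * M + Q;
        if (chan_idx[key] == -1) {
          chan_idx[key] = (int)chan_from.size();
          chan_from.push_back(P); chan_to.push_back(Q);
          blists.emplace_back();
        }
        blists[chan_idx[key]].push_back(v);
      }
    }
    chan_boff.assign(chan_from.size() + 1, 0);
    for (size_t c = 0; c < blists.size(); ++c) {
      std::sort(blists[c].begin(), blists[c].end());
      chan_boff[c + 1] = chan_boff[c] + (int)blists[c].size();
    }
    chan_blist.reserve(chan_boff.back());
    chan_N.resize(chan_from.size());
    for (size_t c = 0; c < blists.size(); ++c) {
      chan_blist.insert(chan_blist.end(), blists[c].begin(), blists[c].end());
      chan_N[c] = (int)blists[c].size();
    }
    chan_msgs.assign(chan_from.size(), 0);
  }

  void init_events(const IntegerVector& states) {
    state.assign(states.begin(), states.end());
    n_inf = 0;
    for (int v = 0; v < n; ++v) if (state[v]) ++n_inf;
    n_events = n + n_dir_edges + (boff.empty() ? 0 : boff[n]);
    tm.assign(n_events, 0.0);
    pos.assign(n_events, -1);
    heap.clear();
    // initial schedule at t = 0: recoveries for infected vertices, then
    // local infection clocks toward their susceptible local neighbors
    for (int v = 0; v < n; ++v) {
      if (!state[v]) continue;
      Stream& s = rng[part[v]];
      if (gamma > 0) push_ev(v, s.expo(gamma));
      if (beta > 0) {
        for (int j = off[v]; j < off[v + 1]; ++j) {
          int w = nbr[j];
          if (!state[w] && part[w] == part[v]) push_ev(n + j, s.expo(beta));
        }
      }
    }
  }

  // ---- event semantics ---------------------------------------------------
  void log_event(double t, int kind, int src, int tgt) {
    ev_t.push_back(t); ev_kind.push_back(kind);
    ev_src.push_back(src); ev_tgt.push_back(tgt);
  }

  void do_infect(int v, double t) {
    state[v] = 1; ++n_inf;
    Stream& s = rng[part[v]];
    // cancel all competing infection events targeting v
    for (int j = off[v]; j < off[v + 1]; ++j) {
      int rid = n + erev[j];  // INF_LOCAL(nbr[j] -> v)
      if (pos[rid] != -1) remove_ev(rid);
    }
    for (int b = boff[v]; b < boff[v + 1]; ++b) {
      int rid = n + n_dir_edges + b;
      if (pos[rid] != -1) remove_ev(rid);
    }
    if (gamma > 0) push_ev(v, t + s.expo(gamma));
    if (beta > 0) {
      for (int j = off[v]; j < off[v + 1]; ++j) {
        int w = nbr[j];
        if (!state[w] && part[w] == part[v]) push_ev(n + j, t + s.expo(beta));
      }
    }
  }

  void do_recover(int v, double t) {
    state[v] = 0; --n_inf;
    Stream& s = rng[part[v]];
    // v is no longer infectious: cancel its outgoing local clocks
    for (int j = off[v]; j < off[v + 1]; ++j)
      if (pos[n + j] != -1) remove_ev(n + j);
    // infected local neighbors now threaten v
    if (beta > 0) {
      for (int j = off[v]; j < off[v + 1]; ++j) {
        int u = nbr[j];
        if (state[u] && part[u] == part[v]) push_ev(n + erev[j], t + s.expo(beta));
      }
    }
    // remote pressure resumes at the current epoch's border rates
    for (int b = boff[v]; b < boff[v + 1]; ++b) {
      double r = brate[b];
      if (r > 0) push_ev(n + n_dir_edges + b, t + s.expo(r));
    }
  }

  void handle(int id, double t) {
    if (id < n) {
      log_event(t, KIND_REC, -1, id);
      do_recover(id, t);
    } else if (id < n + n_dir_edges) {
      int j = id - n;
      log_event(t, KIND_INF_LOCAL, esrc[j], nbr[j]);
      do_infect(nbr[j], t);
    } else {
      int b = id - n - n_dir_edges;
      int v = 0;  // locate owning vertex of border pair b
      v = border_pair_vertex(b);
      log_event(t, KIND_INF_REMOTE, bQ[b], v);
      do_infect(v, t);
    }
    if (validate) check_invariants(t);
  }

  // owner lookup for a border-pair slot (binary search on boff)
  int border_pair_vertex(int b) const {
    int lo = 0, hi = n;
    while (hi - lo > 1) {
      int mid = (lo + hi) >> 1;
      if (boff[mid] <= b) lo = mid; else hi = mid;
    }
    return lo;
  }

  void check_invariants(double t) {
    for (int v = 0; v < n; ++v) {
      bool has_rec = pos[v] != -1;
      if (state[v] && gamma > 0 && !has_rec)
        stop("invariant violated: infected vertex without pending recovery");
      if (!state[v] && has_rec)
        stop("invariant violated: recovery pending for susceptible vertex");
    }
    for (int j = 0; j < n_dir_edges; ++j) {
      if (pos[n + j] == -1) continue;
      if (!state[esrc[j]])
        stop("invariant violated: local infection clock from susceptible source");
      if (state[nbr[j]])
        stop("invariant violated: infection clock targeting infected vertex");
      if (part[esrc[j]] != part[nbr[j]])
        stop("invariant violated: local infection clock across parts");
    }
    if (!boff.empty())
      for (int b = 0; b < boff[n]; ++b)
        if (pos[n + n_dir_edges + b] != -1 && state[border_pair_vertex(b)])
          stop("invariant violated: remote infection clock targeting infected vertex");
    (void)t;
  }

  // ---- epoch machinery ---------------------------------------------------
  // Payloads are a pure function of the state at the epoch's start time.
  void send_phase(bool ghost) {
    for (size_t c = 0; c < chan_from.size(); ++c) {
      long long words = ghost ? (chan_N[c] + 63) / 64 : 1;
      chan_msgs[c] += words;
      total_msgs += words;
    }
  }

  // Receive + apply: recompute the Inf(Q->v) clocks from the fresh
  // border information, removing clocks whose rate vanished.  A clock
  // whose rate is unchanged is left in place: its residual time is
  // still exponential at that rate (memorylessness), so only genuinely
  // new values trigger a re-draw.
  void apply_messages(double t0, bool ghost) {
    std::vector<double> ratio;  // summary mode: n_{Q->P} / N_{Q->P} per channel
    if (!ghost) {
      ratio.assign(chan_from.size(), 0.0);
      for (size_t c = 0; c < chan_from.size(); ++c) {
        int ninf = 0;
        for (int k = chan_boff[c]; k < chan_boff[c + 1]; ++k)
          if (state[chan_blist[k]]) ++ninf;
        ratio[c] = (double)ninf / (double)chan_N[c];
      }
    }
    std::vector<int> ghost_cnt(ghost ? M : 0, 0);
    for (int v : border_verts) {
      int P = part[v];
      if (ghost) {
        for (int b = boff[v]; b < boff[v + 1]; ++b) ghost_cnt[bQ[b]] = 0;
        for (int j = off[v]; j < off[v + 1]; ++j) {
          int u = nbr[j];
          if (part[u] != P && state[u]) ghost_cnt[part[u]]++;
        }
      }
      Stream& s = rng[P];
      for (int b = boff[v]; b < boff[v + 1]; ++b) {
        int Q = bQ[b];
        double r;
        if (ghost) {
          r = beta * ghost_cnt[Q];
        } else {
          int c = chan_idx[Q * M + P];  // channel (Q -> P)
          r = bcnt[b] * ratio[c] * beta;
        }
        if (state[v]) { brate[b] = r; continue; }  // no Inf(Q->v) while infected
        if (r == brate[b]) continue;  // unchanged value: keep the clock
        brate[b] = r;
        int id = n + n_dir_edges + b;
        if (pos[id] != -1) remove_ev(id);
        if (r > 0) push_ev(id, t0 + s.expo(r));
      }
    }
  }

  // run the (shared-heap emulation of the) local engines over [t0, t1)
  void drain_until(double t1, long& next_l, long L_obs, double dobs,
                   std::vector<int>& counts) {
    while (!heap.empty()) {
      int id = heap[0];
      double t = tm[id];
      if (t >= t1) break;
      while (next_l <= L_obs && next_l * dobs < t) {
        counts.push_back(n_inf);
        ++next_l;
      }
      remove_ev(id);
      handle(id, t);
    }
  }
};

List finish(Engine& E, long& next_l, long L_obs,
            std::vector<int>& counts) {
  while (next_l <= L_obs) {
    counts.push_back(E.n_inf);
    ++next_l;
  }
  return List::create(
      _["time"] = NumericVector(E.ev_t.begin(), E.ev_t.end()),
      _["kind"] = IntegerVector(E.ev_kind.begin(), E.ev_kind.end()),
      _["source"] = IntegerVector(E.ev_src.begin(), E.ev_src.end()),
      _["target"] = IntegerVector(E.ev_tgt.begin(), E.ev_tgt.end()),
      _["counts"] = IntegerVector(counts.begin(), counts.end()),
      _["final_states"] = IntegerVector(E.state.begin(), E.state.end()));
}

}  // namespace

// [[Rcpp::export(name = ".cpp_run_sequential")]]
List cpp_run_sequential(IntegerVector off, IntegerVector nbr,
                        IntegerVector states, double beta, double gamma,
                        double horizon, double dobs, double seed,
                        bool validate) {
  Engine E;
  E.beta = beta; E.gamma = gamma; E.validate = validate;
  E.init_graph(off, nbr);
  E.M = 1;
  E.part.assign(E.n, 0);
  E.boff.assign(E.n + 1, 0);
  E.rng.resize(1);
  E.rng[0].seed((uint64_t)seed, 0);
  E.init_events(states);

  std::vector<int> counts;
  long next_l = 0;
  long L_obs = (long)std::floor(horizon / dobs + 1e-9);
  E.drain_until(horizon, next_l, L_obs, dobs, counts);
  return finish(E, next_l, L_obs, counts);
}

// [[Rcpp::export(name = ".cpp_run_partitioned")]]
List cpp_run_partitioned(IntegerVector off, IntegerVector nbr,
                         IntegerVector states, IntegerVector part, int M,
                         double beta, double gamma, double delta,
                         double horizon, bool ghost, double dobs,
                         double seed, bool validate) {
  Engine E;
  E.beta = beta; E.gamma = gamma; E.validate = validate;
  E.init_graph(off, nbr);
  E.rng.resize(M);
  for (int p = 0; p < M; ++p) E.rng[p].seed((uint64_t)seed, p);
  E.init_partition(part, M);
  E.init_events(states);

  std::vector<int> counts;
  long next_l = 0;
  long L_obs = (long)std::floor(horizon / dobs + 1e-9);
  int L = (int)std::ceil(horizon / delta - 1e-12);
  for (int l = 0; l < L; ++l) {
    double t0 = l * delta;
    double t1 = std::min((l + 1) * delta, horizon);
    if (M > 1) {
      E.send_phase(ghost);
      E.apply_messages(t0, ghost);
    }
    E.drain_until(t1, next_l, L_obs, dobs, counts);
  }
  List out = finish(E, next_l, L_obs, counts);
  out["n_epochs"] = L;
  out["total_messages"] = (double)E.total_msgs;
  out["chan_from"] = IntegerVector(E.chan_from.begin(), E.chan_from.end());
  out["chan_to"] = IntegerVector(E.chan_to.begin(), E.chan_to.end());
  out["chan_messages"] =
      NumericVector(E.chan_msgs.begin(), E.chan_msgs.end());
  out["chan_border_size"] = IntegerVector(E.chan_N.begin(), E.chan_N.end());
  return out;
}
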