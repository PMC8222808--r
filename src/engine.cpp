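// Synchronous Boolean network engine.
//
// Networks arrive compiled to postfix bytecode, one program per node, over
// 0-based variable slots (the free nodes in declared order). Opcodes:
//   >= 0 push variable, -1 NOT, -2 AND, -3 OR, -4 push FALSE, -5 push TRUE.
//
// States are encoded as integers with bit i = node i; they are passed to and
// from R as doubles (exact for < 2^53; the engine caps out far below that).

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

static const int OP_NOT = -1, OP_AND = -2, OP_OR = -3, OP_FALSE = -4, OP_TRUE = -5;

// Scalar evaluation of one program on one state.
static inline bool eval_program(const int *code, int len, uint64_t state) {
  bool stack[64];
  int sp = 0;
  for (int k = 0; k < len; ++k) {
    int op = code[k];
    if (op >= 0) {
      stack[sp++] = (state >> op) & 1ULL;
    } else if (op == OP_NOT) {
      stack[sp - 1] = !stack[sp - 1];
    } else if (op == OP_AND) {
      --sp; stack[sp - 1] = stack[sp - 1] && stack[sp];
    } else if (op == OP_OR) {
      --sp; stack[sp - 1] = stack[sp - 1] || stack[sp];
    } else if (op == OP_FALSE) {
      stack[sp++] = false;
    } else {
      stack[sp++] = true;
    }
  }
  return stack[0];
}

static inline uint64_t step_state(const int *code, const int *offsets, int n,
                                  uint64_t state) {
  uint64_t nxt = 0;
  for (int i = 0; i < n; ++i) {
    if (eval_program(code + offsets[i], offsets[i + 1] - offsets[i], state))
      nxt |= (1ULL << i);
  }
  return nxt;
}

// Word-parallel evaluation: each uint64 lane is one of 64 consecutive states.
static inline uint64_t eval_program_words(const int *code, int len,
                                          const uint64_t *vars) {
  uint64_t stack[64];
  int sp = 0;
  for (int k = 0; k < len; ++k) {
    int op = code[k];
    if (op >= 0) {
      stack[sp++] = vars[op];
    } else if (op == OP_NOT) {
      stack[sp - 1] = ~stack[sp - 1];
    } else if (op == OP_AND) {
      --sp; stack[sp - 1] &= stack[sp];
    } else if (op == OP_OR) {
      --sp; stack[sp - 1] |= stack[sp];
    } else if (op == OP_FALSE) {
      stack[sp++] = 0ULL;
    } else {
      stack[sp++] = ~0ULL;
    }
  }
  return stack[0];
}

// In-place 64x64 bit-matrix transpose, LSB-first convention:
// on exit, bit r of A[c] equals bit c of the original A[r].
static void transpose64(uint64_t A[64]) {
  uint64_t m = 0x00000000FFFFFFFFULL;
  for (int j = 32; j; j >>= 1, m ^= m << j) {
    for (int k = 0; k < 64; k = ((k | j) + 1) & ~j) {
      uint64_t t = ((A[k] >> j) ^ A[k + j]) & m;
      A[k + j] ^= t;
      A[k] ^= (t << j);
    }
  }
}

// Bit patterns of the low 6 state-index bits across a 64-state block.
static const uint64_t LOWPAT[6] = {
  0xAAAAAAAAAAAAAAAAULL, 0xCCCCCCCCCCCCCCCCULL, 0xF0F0F0F0F0F0F0F0ULL,
  0xFF00FF00FF00FF00ULL, 0xFFFF0000FFFF0000ULL, 0xFFFFFFFF00000000ULL
};

// Fill succ[0 .. 2^n - 1] with the synchronous successor of every state.
static void successor_table(const int *code, const int *offsets, int n,
                            std::vector<uint32_t> &succ) {
  uint64_t total = 1ULL << n;
  succ.resize(total);
  if (n < 6) {
    for (uint64_t s = 0; s < total; ++s)
      succ[s] = (uint32_t) step_state(code, offsets, n, s);
    return;
  }
  uint64_t nblocks = total >> 6;
  std::vector<uint64_t> vars(n);
  uint64_t rows[64];
  uint32_t mask = (n == 32) ? 0xFFFFFFFFu : ((1u << n) - 1u);
  for (uint64_t b = 0; b < nblocks; ++b) {
    for (int j = 0; j < 6; ++j) vars[j] = LOWPAT[j];
    for (int j = 6; j < n; ++j)
      vars[j] = ((b >> (j - 6)) & 1ULL) ? ~0ULL : 0ULL;
    for (int j = 0; j < 64; ++j) rows[j] = 0ULL;
    for (int i = 0; i < n; ++i)
      rows[i] = eval_program_words(code + offsets[i],
                                   offsets[i + 1] - offsets[i], vars.data());
    // rows[i] bit t = next value of node i in state (b*64+t); transpose so
    // rows[t] bit i = node i, i.e. rows[t] = successor encoding of state t.
    transpose64(rows);
    uint64_t base = b << 6;
    for (int t = 0; t < 64; ++t)
      succ[base + t] = (uint32_t) rows[t] & mask;
    if ((b & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
}

// [[Rcpp::export(name = ".bn_step_cpp")]]
NumericVector bn_step_cpp(IntegerVector code, IntegerVector offsets, int n,
                          NumericVector states) {
  R_xlen_t m = states.size();
  NumericVector out(m);
  for (R_xlen_t k = 0; k < m; ++k)
    out[k] = (double) step_state(code.begin(), offsets.begin(), n,
                                 (uint64_t) states[k]);
  return out;
}

// [[Rcpp::export(name = ".bn_eval_node_cpp")]]
LogicalVector bn_eval_node_cpp(IntegerVector code, NumericVector states) {
  R_xlen_t m = states.size();
  LogicalVector out(m);
  for (R_xlen_t k = 0; k < m; ++k)
    out[k] = eval_program(code.begin(), code.size(), (uint64_t) states[k]);
  return out;
}

// Follow the trajectory from s0 until a state repeats. Returns the cycle (in
// visit order, starting at the first in-cycle state) and the transient length.
// [[Rcpp::export(name = ".bn_trajectory_cpp")]]
List bn_trajectory_cpp(IntegerVector code, IntegerVector offsets, int n,
                       double s0) {
  std::unordered_map<uint64_t, R_xlen_t> seen;
  std::vector<uint64_t> path;
  uint64_t v = (uint64_t) s0;
  while (seen.find(v) == seen.end()) {
    seen[v] = (R_xlen_t) path.size();
    path.push_back(v);
    v = step_state(code.begin(), offsets.begin(), n, v);
  }
  R_xlen_t start = seen[v];
  R_xlen_t period = (R_xlen_t) path.size() - start;
  NumericVector cycle(period);
  for (R_xlen_t k = 0; k < period; ++k) cycle[k] = (double) path[start + k];
  return List::create(_["cycle"] = cycle, _["transient"] = (double) start);
}

// Exhaustive attractor/basin enumeration over all 2^n states.
// [[Rcpp::export(name = ".bn_exhaustive_cpp")]]
List bn_exhaustive_cpp(IntegerVector code, IntegerVector offsets, int n) {
  if (n < 1 || n > 30) stop("exhaustive enumeration supports 1..30 free nodes");
  uint64_t total = 1ULL << n;
  std::vector<uint32_t> succ;
  successor_table(code.begin(), offsets.begin(), n, succ);

  // labels: 0 unvisited, >0 attractor id, <0 encodes 1-based path position.
  std::vector<int32_t> labels(total, 0);
  std::vector<uint32_t> path;
  std::vector< std::vector<uint32_t> > cycles;
  std::vector<double> basins;

  for (uint64_t s0 = 0; s0 < total; ++s0) {
    if (labels[s0] != 0) continue;
    path.clear();
    uint32_t v = (uint32_t) s0;
    while (labels[v] == 0) {
      labels[v] = -(int32_t)(path.size() + 1);
      path.push_back(v);
      v = succ[v];
    }
    int32_t id;
    if (labels[v] < 0) {
      // new cycle discovered on the current path
      size_t pos = (size_t)(-labels[v]) - 1;
      cycles.emplace_back(path.begin() + pos, path.end());
      basins.push_back(0.0);
      id = (int32_t) cycles.size();
    } else {
      id = labels[v];
    }
    basins[id - 1] += (double) path.size();
    for (size_t k = 0; k < path.size(); ++k) labels[path[k]] = id;
    if ((s0 & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  R_xlen_t na = (R_xlen_t) cycles.size();
  List states(na);
  NumericVector basin_sizes(na);
  for (R_xlen_t a = 0; a < na; ++a) {
    const std::vector<uint32_t> &cy = cycles[a];
    NumericVector st(cy.size());
    for (size_t k = 0; k < cy.size(); ++k) st[k] = (double) cy[k];
    states[a] = st;
    basin_sizes[a] = basins[a];
  }
  return List::create(_["states"] = states, _["basin_sizes"] = basin_sizes);
}

// Hamming distance between paired state encodings (n <= 53 bits).
// [[Rcpp::export(name = ".bn_hamming_cpp")]]
IntegerVector bn_hamming_cpp(NumericVector a, NumericVector b) {
  R_xlen_t m = a.size();
  IntegerVector out(m);
  for (R_xlen_t k = 0; k < m; ++k) {
    uint64_t x = ((uint64_t) a[k]) ^ ((uint64_t) b[k]);
    int c = 0;
    while (x) { x &= x - 1; ++c; }
    out[k] = c;
  }
  return out;
}
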