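#include <Rcpp.h>
#include <vector>
#include <array>

using namespace Rcpp;

// Exhaustive full-cover Numberlink solver (testing oracle).
//
// Cells are indexed row-major, key = row * w + col, 0-based.  Paths are
// assigned to pairs depth-first: pair i's path is grown from dot a until
// it reaches dot b (length >= 3 cells); other pairs' dots are impassable;
// a complete assignment is a solution iff every cell is covered.

namespace {

struct Ctx {
  int w, h, n, npairs;
  std::vector<int> owner;                 // -1 free, -2 foreign dot, else pair
  std::vector<std::array<int, 2>> dots;   // {a, b} per pair
  std::vector<std::vector<int>> cur;      // current partial paths
  std::vector<std::vector<std::vector<int>>> sols;
  int max_solutions;
  bool truncated = false;

  bool full() const {
    for (int c = 0; c < n; ++c)
      if (owner[c] < 0 && owner[c] != -2) return false;
    return true;
  }

  void record() {
    if ((int)sols.size() >= max_solutions) { truncated = true; return; }
    sols.push_back(cur);
  }

  void solve_pair(int i);

  void extend(int i) {
    if (truncated) return;
    int u = cur[i].back();
    int b = dots[i][1];
    int uc = u % w, ur = u / w;
    const int dc[4] = {1, -1, 0, 0};
    const int dr[4] = {0, 0, 1, -1};
    for (int d = 0; d < 4; ++d) {
      int vc = uc + dc[d], vr = ur + dr[d];
      if (vc < 0 || vc >= w || vr < 0 || vr >= h) continue;
      int v = vr * w + vc;
      if (v == b) {
        if ((int)cur[i].size() >= 2) {    // total length >= 3 incl. b
          cur[i].push_back(v);
          solve_pair(i + 1);
          cur[i].pop_back();
        }
        continue;
      }
      if (owner[v] != -1) continue;       // occupied or a dot
      owner[v] = i;
      cur[i].push_back(v);
      extend(i);
      cur[i].pop_back();
      owner[v] = -1;
    }
  }
};

void Ctx::solve_pair(int i) {
  if (truncated) return;
  if (i == npairs) {
    if (full()) record();
    return;
  }
  cur[i].assign(1, dots[i][0]);
  extend(i);
  cur[i].clear();
}

}  // namespace

// [[Rcpp::export]]
List nl_solve_cpp(int w, int h, IntegerMatrix dots, int max_solutions) {
  Ctx ctx;
  ctx.w = w; ctx.h = h; ctx.n = w * h;
  ctx.npairs = dots.nrow();
  ctx.max_solutions = max_solutions;
  ctx.owner.assign(ctx.n, -1);
  ctx.cur.assign(ctx.npairs, {});
  for (int i = 0; i < ctx.npairs; ++i) {
    int a = dots(i, 1) * w + dots(i, 0);
    int b = dots(i, 3) * w + dots(i, 2);
    ctx.dots.push_back({a, b});
    ctx.owner[a] = -2;  // dots are impassable for other pairs
    ctx.owner[b] = -2;
  }
  ctx.solve_pair(0);
  if (ctx.truncated)
    warning("solution enumeration truncated at max_solutions");
  List out(ctx.sols.size());
  for (size_t s = 0; s < ctx.sols.size(); ++s) {
    List paths(ctx.npairs);
    for (int i = 0; i < ctx.npairs; ++i)
      paths[i] = IntegerVector(ctx.sols[s][i].begin(), ctx.sols[s][i].end());
    out[s] = paths;
  }
  return out;
}
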