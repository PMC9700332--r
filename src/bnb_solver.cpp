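// Exact solver for the bounded-variable models this package builds:
// branch-and-bound over the integer variables with bounds-consistency
// propagation on the linear rows, an interval-arithmetic lower bound for the
// convex separable quadratic objective sum_r (A_r v - b_r)^2, and a phase-1
// simplex to decide the continuous subproblem left at a leaf (real-weight
// mode).  All variables are bounded, which the propagation relies on.

#include <Rcpp.h>
#include <vector>
#include <deque>
#include <chrono>
#include <cmath>

using namespace Rcpp;

static const double FEAS_TOL = 1e-6;
static const double BIG = 1e30;

struct SparseRow {
  std::vector<int> col;
  std::vector<double> coef;
  double lb, ub;
};

class BnbSolver {
public:
  int n;                              // number of variables
  std::vector<SparseRow> rows;
  std::vector<std::vector<int> > colRows;  // column -> incident rows
  std::vector<char> isInt;
  std::vector<int> branchOrder;       // 0-based columns, in priority order
  // quadratic objective: sum_r (qrow_r . v - qb_r)^2
  std::vector<SparseRow> qrows;       // lb/ub unused
  std::vector<double> qb;
  bool hasQuad;

  double timeLimit;
  double nodeLimit;
  std::chrono::steady_clock::time_point t0;

  bool found, limitHit;
  double bestObj;
  std::vector<double> bestSol;
  double nodes;

  BnbSolver() : hasQuad(false), found(false), limitHit(false),
                bestObj(BIG), nodes(0) {}

  double elapsed() const {
    return std::chrono::duration<double>(
      std::chrono::steady_clock::now() - t0).count();
  }

  // Bounds-consistency propagation; returns false on proven infeasibility.
  bool propagate(std::vector<double>& lb, std::vector<double>& ub) {
    std::deque<int> queue;
    std::vector<char> inq(rows.size(), 1);
    for (size_t r = 0; r < rows.size(); ++r) queue.push_back((int)r);
    int guard = 0, guardMax = 200 * (int)rows.size() + 1000;
    while (!queue.empty()) {
      if (++guard > guardMax) break;  // fixpoint guard; sound either way
      int r = queue.front(); queue.pop_front(); inq[r] = 0;
      const SparseRow& row = rows[r];
      double minact = 0.0, maxact = 0.0;
      for (size_t t = 0; t < row.col.size(); ++t) {
        double a = row.coef[t]; int j = row.col[t];
        if (a > 0) { minact += a * lb[j]; maxact += a * ub[j]; }
        else       { minact += a * ub[j]; maxact += a * lb[j]; }
      }
      double tolr = FEAS_TOL * (1.0 + std::fabs(row.ub) + std::fabs(row.lb));
      if (row.ub < BIG / 2 && minact > row.ub + tolr) return false;
      if (row.lb > -BIG / 2 && maxact < row.lb - tolr) return false;
      for (size_t t = 0; t < row.col.size(); ++t) {
        double a = row.coef[t]; int j = row.col[t];
        if (ub[j] - lb[j] < 1e-12) continue;
        double mwo, Mwo;  // activity excluding j
        if (a > 0) { mwo = minact - a * lb[j]; Mwo = maxact - a * ub[j]; }
        else       { mwo = minact - a * ub[j]; Mwo = maxact - a * lb[j]; }
        double newlb = -BIG, newub = BIG;
        if (a > 0) {
          if (row.ub < BIG / 2) newub = (row.ub - mwo) / a;
          if (row.lb > -BIG / 2) newlb = (row.lb - Mwo) / a;
        } else {
          if (row.ub < BIG / 2) newlb = (row.ub - mwo) / a;
          if (row.lb > -BIG / 2) newub = (row.lb - Mwo) / a;
        }
        bool changed = false;
        if (isInt[j]) {
          if (newub < BIG / 2) {
            double v = std::floor(newub + FEAS_TOL);
            if (v < ub[j] - 0.5) { ub[j] = v; changed = true; }
          }
          if (newlb > -BIG / 2) {
            double v = std::ceil(newlb - FEAS_TOL);
            if (v > lb[j] + 0.5) { lb[j] = v; changed = true; }
          }
        } else {
          if (newub < BIG / 2 && newub < ub[j] - 1e-9) { ub[j] = newub; changed = true; }
          if (newlb > -BIG / 2 && newlb > lb[j] + 1e-9) { lb[j] = newlb; changed = true; }
        }
        if (lb[j] > ub[j] + FEAS_TOL) return false;
        if (changed) {
          // re-queue rows touching j, and recompute this row's activity
          for (size_t q = 0; q < colRows[j].size(); ++q) {
            int rr = colRows[j][q];
            if (!inq[rr]) { inq[rr] = 1; queue.push_back(rr); }
          }
          minact = 0.0; maxact = 0.0;
          for (size_t t2 = 0; t2 < row.col.size(); ++t2) {
            double a2 = row.coef[t2]; int j2 = row.col[t2];
            if (a2 > 0) { minact += a2 * lb[j2]; maxact += a2 * ub[j2]; }
            else        { minact += a2 * ub[j2]; maxact += a2 * lb[j2]; }
          }
        }
      }
    }
    return true;
  }

  double quadLowerBound(const std::vector<double>& lb,
                        const std::vector<double>& ub) const {
    double s = 0.0;
    for (size_t r = 0; r < qrows.size(); ++r) {
      double lo = 0.0, hi = 0.0;
      for (size_t t = 0; t < qrows[r].col.size(); ++t) {
        double a = qrows[r].coef[t]; int j = qrows[r].col[t];
        if (a > 0) { lo += a * lb[j]; hi += a * ub[j]; }
        else       { lo += a * ub[j]; hi += a * lb[j]; }
      }
      double b = qb[r];
      if (b < lo - 1e-12) s += (lo - b) * (lo - b);
      else if (b > hi + 1e-12) s += (hi - b) * (hi - b);
    }
    return s;
  }

  double quadValue(const std::vector<double>& v) const {
    double s = 0.0;
    for (size_t r = 0; r < qrows.size(); ++r) {
      double a = -qb[r];
      for (size_t t = 0; t < qrows[r].col.size(); ++t)
        a += qrows[r].coef[t] * v[qrows[r].col[t]];
      s += a * a;
    }
    return s;
  }

  bool pointFeasible(const std::vector<double>& v) const {
    for (size_t r = 0; r < rows.size(); ++r) {
      double act = 0.0;
      for (size_t t = 0; t < rows[r].col.size(); ++t)
        act += rows[r].coef[t] * v[rows[r].col[t]];
      double tolr = FEAS_TOL * (1.0 + std::fabs(act));
      if (rows[r].ub < BIG / 2 && act > rows[r].ub + tolr) return false;
      if (rows[r].lb > -BIG / 2 && act < rows[r].lb - tolr) return false;
    }
    return true;
  }

  void accept(const std::vector<double>& v) {
    if (hasQuad) {
      double obj = quadValue(v);
      if (obj < bestObj - 1e-9) { bestObj = obj; bestSol = v; found = true; }
    } else if (!found) {
      bestSol = v; found = true;
    }
  }

  // Phase-1 dense tableau simplex (Bland's rule) for the continuous
  // subproblem at a leaf: decides feasibility of the free continuous
  // variables given the fixed integer assignment, and fills in values.
  bool solveContinuousLeaf(const std::vector<double>& lb,
                           const std::vector<double>& ub,
                           std::vector<double>& point) {
    std::vector<int> freeCols;
    for (int j = 0; j < n; ++j)
      if (!isInt[j] && ub[j] - lb[j] > 1e-9) freeCols.push_back(j);
    if (freeCols.empty()) return true;
    std::vector<int> colPos(n, -1);
    for (size_t t = 0; t < freeCols.size(); ++t) colPos[freeCols[t]] = (int)t;
    int nf = (int)freeCols.size();

    // build inequalities G y <= h over y_j = v_j - lb_j, plus y <= U
    std::vector<std::vector<double> > G;
    std::vector<double> h;
    for (size_t r = 0; r < rows.size(); ++r) {
      bool touches = false;
      double base = 0.0;
      std::vector<double> g(nf, 0.0);
      for (size_t t = 0; t < rows[r].col.size(); ++t) {
        int j = rows[r].col[t]; double a = rows[r].coef[t];
        if (colPos[j] >= 0) { g[colPos[j]] = a; base += a * lb[j]; touches = true; }
        else base += a * point[j];
      }
      if (!touches) continue;
      if (rows[r].ub < BIG / 2) { G.push_back(g); h.push_back(rows[r].ub - base); }
      if (rows[r].lb > -BIG / 2) {
        std::vector<double> gn(nf);
        for (int t = 0; t < nf; ++t) gn[t] = -g[t];
        G.push_back(gn); h.push_back(base - rows[r].lb);
      }
    }
    for (int t = 0; t < nf; ++t) {
      std::vector<double> g(nf, 0.0); g[t] = 1.0;
      G.push_back(g); h.push_back(ub[freeCols[t]] - lb[freeCols[t]]);
    }
    int m = (int)G.size();
    // tableau columns: nf free vars, m slacks, artificials appended
    int nart = 0;
    for (int i = 0; i < m; ++i) if (h[i] < -1e-11) ++nart;
    int ncols = nf + m + nart;
    std::vector<std::vector<double> > T(m, std::vector<double>(ncols + 1, 0.0));
    std::vector<int> basis(m);
    std::vector<double> cost(ncols, 0.0);
    int ai = 0;
    for (int i = 0; i < m; ++i) {
      double sgn = (h[i] < -1e-11) ? -1.0 : 1.0;
      for (int t = 0; t < nf; ++t) T[i][t] = sgn * G[i][t];
      T[i][nf + i] = sgn * 1.0;
      T[i][ncols] = sgn * h[i];
      if (sgn < 0) {
        T[i][nf + m + ai] = 1.0;
        basis[i] = nf + m + ai;
        cost[nf + m + ai] = 1.0;
        ++ai;
      } else basis[i] = nf + i;
    }
    // reduced costs z = c_B B^-1 A - c ; maintain objective row
    std::vector<double> objRow(ncols + 1, 0.0);
    for (int i = 0; i < m; ++i)
      if (cost[basis[i]] > 0.5)
        for (int c = 0; c <= ncols; ++c) objRow[c] += T[i][c];
    for (int c = 0; c < ncols; ++c) objRow[c] -= cost[c];

    int iterMax = 200 * (m + ncols) + 1000;
    for (int iter = 0; iter < iterMax; ++iter) {
      int piv = -1;
      for (int c = 0; c < ncols; ++c)      // Bland: first positive
        if (objRow[c] > 1e-9) { piv = c; break; }
      if (piv < 0) break;
      int prow = -1; double best = BIG;
      for (int i = 0; i < m; ++i)
        if (T[i][piv] > 1e-9) {
          double ratio = T[i][ncols] / T[i][piv];
          if (ratio < best - 1e-12 ||
              (ratio < best + 1e-12 && (prow < 0 || basis[i] < basis[prow]))) {
            best = ratio; prow = i;
          }
        }
      if (prow < 0) break;  // unbounded phase-1: cannot happen, bail out
      double pv = T[prow][piv];
      for (int c = 0; c <= ncols; ++c) T[prow][c] /= pv;
      for (int i = 0; i < m; ++i)
        if (i != prow && std::fabs(T[i][piv]) > 1e-12) {
          double f = T[i][piv];
          for (int c = 0; c <= ncols; ++c) T[i][c] -= f * T[prow][c];
        }
      double f = objRow[piv];
      if (std::fabs(f) > 1e-12)
        for (int c = 0; c <= ncols; ++c) objRow[c] -= f * T[prow][c];
      basis[prow] = piv;
    }
    if (objRow[ncols] > 1e-6) return false;  // artificials remain: infeasible
    std::vector<double> y(nf, 0.0);
    for (int i = 0; i < m; ++i)
      if (basis[i] < nf) y[basis[i]] = T[i][ncols];
    for (int t = 0; t < nf; ++t) {
      double v = lb[freeCols[t]] + std::max(0.0, y[t]);
      if (v > ub[freeCols[t]]) v = ub[freeCols[t]];
      point[freeCols[t]] = v;
    }
    return true;
  }

  void dfs(std::vector<double> lb, std::vector<double> ub) {
    if (limitHit || (found && !hasQuad)) return;
    nodes += 1;
    if (nodes > nodeLimit) { limitHit = true; return; }
    if (((long long)nodes & 255LL) == 0 && elapsed() > timeLimit) {
      limitHit = true; return;
    }
    if (!propagate(lb, ub)) return;
    if (hasQuad && quadLowerBound(lb, ub) >= bestObj - 1e-9) return;

    // cheap probe: all variables at their lower bound
    {
      std::vector<double> cand(lb);
      if (pointFeasible(cand)) {
        accept(cand);
        if (!hasQuad && found) return;
      }
    }

    int bj = -1;
    for (size_t t = 0; t < branchOrder.size(); ++t) {
      int j = branchOrder[t];
      if (isInt[j] && ub[j] - lb[j] > 0.5) { bj = j; break; }
    }
    if (bj < 0) {
      // all integer variables fixed; settle remaining continuous ones
      std::vector<double> point(lb);
      for (int j = 0; j < n; ++j)
        if (isInt[j]) point[j] = std::floor(lb[j] + 0.5);
      bool needLP = false;
      for (int j = 0; j < n; ++j)
        if (!isInt[j] && ub[j] - lb[j] > 1e-9) { needLP = true; break; }
      if (needLP && !solveContinuousLeaf(lb, ub, point)) return;
      if (pointFeasible(point)) accept(point);
      return;
    }

    double l = lb[bj], u = ub[bj];
    if (u - l <= 15.5) {
      // enumerate values; binaries try 1 first (constructs paths eagerly)
      std::vector<double> vals;
      if (l >= -0.5 && u <= 1.5) { vals.push_back(u); vals.push_back(l); }
      else for (double v = l; v <= u + 0.25; v += 1.0) vals.push_back(v);
      for (size_t t = 0; t < vals.size(); ++t) {
        std::vector<double> lb2(lb), ub2(ub);
        lb2[bj] = ub2[bj] = vals[t];
        dfs(lb2, ub2);
        if (limitHit || (found && !hasQuad)) return;
      }
    } else {
      double mid = std::floor((l + u) / 2.0);
      {
        std::vector<double> lb2(lb), ub2(ub);
        ub2[bj] = mid;
        dfs(lb2, ub2);
        if (limitHit || (found && !hasQuad)) return;
      }
      {
        std::vector<double> lb2(lb), ub2(ub);
        lb2[bj] = mid + 1.0;
        dfs(lb2, ub2);
      }
    }
  }
};

// [[Rcpp::export(name = ".bnb_solve_cpp")]]
List bnb_solve(IntegerVector conI, IntegerVector conJ, NumericVector conV,
               int nRows, int nCols,
               NumericVector rowLb, NumericVector rowUb,
               NumericVector colLb, NumericVector colUb,
               LogicalVector varInt, IntegerVector branchOrder,
               Nullable<NumericMatrix> quadA_, NumericVector quadB,
               double timeLimit, double nodeLimit) {
  BnbSolver S;
  S.n = nCols;
  S.t0 = std::chrono::steady_clock::now();
  S.timeLimit = timeLimit > 0 ? timeLimit : BIG;
  S.nodeLimit = nodeLimit > 0 ? nodeLimit : BIG;

  S.rows.assign(nRows, SparseRow());
  for (int r = 0; r < nRows; ++r) {
    S.rows[r].lb = std::isfinite(rowLb[r]) ? rowLb[r] : -BIG;
    S.rows[r].ub = std::isfinite(rowUb[r]) ? rowUb[r] : BIG;
  }
  for (int t = 0; t < conI.size(); ++t) {
    int r = conI[t] - 1, j = conJ[t] - 1;
    if (conV[t] != 0.0) {
      S.rows[r].col.push_back(j);
      S.rows[r].coef.push_back(conV[t]);
    }
  }
  S.colRows.assign(nCols, std::vector<int>());
  for (int r = 0; r < nRows; ++r)
    for (size_t t = 0; t < S.rows[r].col.size(); ++t)
      S.colRows[S.rows[r].col[t]].push_back(r);

  S.isInt.assign(nCols, 0);
  for (int j = 0; j < nCols; ++j) S.isInt[j] = varInt[j] ? 1 : 0;
  S.branchOrder.clear();
  for (int t = 0; t < branchOrder.size(); ++t)
    S.branchOrder.push_back(branchOrder[t] - 1);

  if (quadA_.isNotNull()) {
    NumericMatrix Q(quadA_);
    S.hasQuad = Q.nrow() > 0;
    for (int r = 0; r < Q.nrow(); ++r) {
      SparseRow qr; qr.lb = -BIG; qr.ub = BIG;
      for (int j = 0; j < Q.ncol(); ++j)
        if (Q(r, j) != 0.0) { qr.col.push_back(j); qr.coef.push_back(Q(r, j)); }
      S.qrows.push_back(qr);
      S.qb.push_back(quadB[r]);
    }
  }

  std::vector<double> lb(nCols), ub(nCols);
  for (int j = 0; j < nCols; ++j) {
    lb[j] = colLb[j]; ub[j] = colUb[j];
    if (S.isInt[j]) { lb[j] = std::ceil(lb[j] - FEAS_TOL); ub[j] = std::floor(ub[j] + FEAS_TOL); }
  }
  S.dfs(lb, ub);

  int status;
  if (S.limitHit) status = 2;                       // limit hit
  else if (S.found) status = 0;                     // solved to completion
  else status = 1;                                  // proven infeasible
  // a run cut short by a limit may still carry an incumbent
  List out = List::create(
    _["status"] = status,
    _["hasSolution"] = S.found,
    _["solution"] = S.found ? NumericVector(S.bestSol.begin(), S.bestSol.end())
                            : NumericVector(0),
    _["objective"] = S.hasQuad && S.found ? S.bestObj : NA_REAL,
    _["nodes"] = S.nodes,
    _["wallTime"] = S.elapsed());
  return out;
}
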