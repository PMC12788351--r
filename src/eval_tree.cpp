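#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Postfix GP-tree evaluator over a patch matrix.
//
// ops:  opcode per node in postfix order
//       0 = constant (aux = value), 1 = pixel terminal (aux = 1-based column),
//       2.. = functions in the fixed registry order (see R/primitives.R).
// aux:  constant value or pixel index per node (unused for functions).
// P:    n x n_pixels patch matrix.
//
// Semantics mirror the R reference interpreter exactly: protected division
// returns 1 for |denominator| < 1e-12; SquareRoot is signed; conditional
// comparisons with NaN take the "else" branch; only the root is clipped to
// [0, 1] with NaN mapping to 0.

enum Op {
  OP_CONST = 0, OP_PIXEL = 1,
  OP_ADD = 2, OP_SUB, OP_MUL, OP_PDIV,
  OP_MINUS, OP_SQUARE, OP_TRI, OP_SQRT, OP_COMPL,
  OP_MIN3, OP_MIN6, OP_MIN9, OP_MAX3, OP_MAX6, OP_MAX9,
  OP_ITE, OP_ILARGER, OP_IRANGE
};

static int op_arity(int op) {
  switch (op) {
    case OP_CONST: case OP_PIXEL: return 0;
    case OP_MINUS: case OP_SQUARE: case OP_TRI: case OP_SQRT: case OP_COMPL:
      return 1;
    case OP_ADD: case OP_SUB: case OP_MUL: case OP_PDIV: return 2;
    case OP_MIN3: case OP_MAX3: case OP_ITE: return 3;
    case OP_ILARGER: return 4;
    case OP_MIN9: case OP_MAX9: return 9;
    case OP_MIN6: case OP_MAX6: return 6;
    case OP_IRANGE: return 5;
  }
  return -1;
}

// [[Rcpp::export(name = ".eval_postfix")]]
NumericVector eval_postfix(IntegerVector ops, NumericVector aux,
                           NumericMatrix P) {
  const int n = P.nrow();
  const int n_ops = ops.size();

  // precompute the required stack depth, validating the program
  int sp_max = 0, sp_chk = 0;
  for (int k = 0; k < n_ops; ++k) {
    const int ar = op_arity(ops[k]);
    if (ar < 0) stop("unknown opcode %d", ops[k]);
    if (sp_chk < ar) stop("stack underflow at node %d", k + 1);
    sp_chk += 1 - ar;
    if (sp_chk > sp_max) sp_max = sp_chk;
  }
  if (sp_chk != 1) stop("malformed postfix program");

  std::vector<std::vector<double>> pool(sp_max);
  for (auto &b : pool) b.resize(n);
  int sp = 0;

  for (int k = 0; k < n_ops; ++k) {
    const int op = ops[k];
    const int ar = op_arity(op);

    if (op == OP_CONST) {
      std::fill(pool[sp].begin(), pool[sp].end(), aux[k]);
      ++sp;
      continue;
    }
    if (op == OP_PIXEL) {
      const int col = (int)aux[k] - 1;
      if (col < 0 || col >= P.ncol()) stop("pixel index out of range");
      const double *src = &P(0, col);
      std::copy(src, src + n, pool[sp].begin());
      ++sp;
      continue;
    }

    // write the result in place over the first argument's buffer
    std::vector<double> *a = &pool[sp - ar];
    std::vector<double> &out = pool[sp - ar];

    switch (op) {
      case OP_ADD:
        for (int i = 0; i < n; ++i) out[i] = a[0][i] + a[1][i];
        break;
      case OP_SUB:
        for (int i = 0; i < n; ++i) out[i] = a[0][i] - a[1][i];
        break;
      case OP_MUL:
        for (int i = 0; i < n; ++i) out[i] = a[0][i] * a[1][i];
        break;
      case OP_PDIV:
        for (int i = 0; i < n; ++i) {
          out[i] = std::abs(a[1][i]) < 1e-12 ? 1.0 : a[0][i] / a[1][i];
        }
        break;
      case OP_MINUS:
        for (int i = 0; i < n; ++i) out[i] = -a[0][i];
        break;
      case OP_SQUARE:
        for (int i = 0; i < n; ++i) out[i] = a[0][i] * a[0][i];
        break;
      case OP_TRI:
        // std::pow matches R's `^` bit for bit (R has a fast path only for ^2)
        for (int i = 0; i < n; ++i) out[i] = std::pow(a[0][i], 3.0);
        break;
      case OP_SQRT:
        for (int i = 0; i < n; ++i) {
          const double x = a[0][i];
          out[i] = (x > 0) - (x < 0) ? std::copysign(std::sqrt(std::abs(x)), x)
                                     : x * 0.0; // sign(0) = 0, NaN stays NaN
        }
        break;
      case OP_COMPL:
        for (int i = 0; i < n; ++i) out[i] = 1.0 - a[0][i];
        break;
      case OP_MIN3: case OP_MIN6: case OP_MIN9: {
        for (int i = 0; i < n; ++i) {
          double m = a[0][i];
          for (int j = 1; j < ar; ++j) {
            const double x = a[j][i];
            // pmin semantics: NaN propagates
            if (std::isnan(x) || x < m) m = std::isnan(x) ? x : std::min(m, x);
          }
          out[i] = m;
        }
        break;
      }
      case OP_MAX3: case OP_MAX6: case OP_MAX9: {
        for (int i = 0; i < n; ++i) {
          double m = a[0][i];
          for (int j = 1; j < ar; ++j) {
            const double x = a[j][i];
            if (std::isnan(x) || x > m) m = std::isnan(x) ? x : std::max(m, x);
          }
          out[i] = m;
        }
        break;
      }
      case OP_ITE:
        for (int i = 0; i < n; ++i) {
          out[i] = (a[0][i] > 0.5) ? a[1][i] : a[2][i];
        }
        break;
      case OP_ILARGER:
        for (int i = 0; i < n; ++i) {
          out[i] = (a[0][i] > a[1][i]) ? a[2][i] : a[3][i];
        }
        break;
      case OP_IRANGE:
        for (int i = 0; i < n; ++i) {
          out[i] = (a[1][i] <= a[0][i] && a[0][i] < a[2][i]) ? a[3][i] : a[4][i];
        }
        break;
      default:
        stop("unknown opcode %d", op);
    }
    sp -= ar - 1;
  }

  NumericVector res(n);
  for (int i = 0; i < n; ++i) {
    double v = pool[0][i];
    if (std::isnan(v)) v = 0.0;
    res[i] = v < 0.0 ? 0.0 : (v > 1.0 ? 1.0 : v);
  }
  return res;
}
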