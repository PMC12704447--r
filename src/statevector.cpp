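#include <Rcpp.h>
using namespace Rcpp;

// Real-valued statevector simulation of the real-amplitude ansatz:
// an initial y-rotation layer, then `reps` blocks of (reverse-linear CNOT
// chain + y-rotation layer). All gates (Ry, CNOT) have real matrix elements,
// so the state stays in R^(2^n) throughout. Qubit 0 is the least significant
// bit of the basis index. Parameters are layer-major: layer l uses
// theta[l*n + q] on qubit q.

static void apply_ry(std::vector<double> &psi, int n, int q, double theta) {
  const double c = std::cos(theta / 2.0), s = std::sin(theta / 2.0);
  const size_t stride = (size_t)1 << q;
  const size_t dim = psi.size();
  for (size_t base = 0; base < dim; base += 2 * stride) {
    for (size_t k = 0; k < stride; ++k) {
      const size_t i0 = base + k, i1 = i0 + stride;
      const double a = psi[i0], b = psi[i1];
      psi[i0] = c * a - s * b;
      psi[i1] = s * a + c * b;
    }
  }
}

static void apply_cnot(std::vector<double> &psi, int n, int control,
                       int target) {
  const size_t cmask = (size_t)1 << control;
  const size_t tmask = (size_t)1 << target;
  const size_t dim = psi.size();
  for (size_t i = 0; i < dim; ++i) {
    // visit each swapped pair once: control bit set, target bit clear
    if ((i & cmask) && !(i & tmask)) {
      std::swap(psi[i], psi[i | tmask]);
    }
  }
}

// [[Rcpp::export]]
NumericVector real_amplitudes_state(int num_qubits, NumericVector theta,
                                    int reps) {
  if (num_qubits < 0) stop("num_qubits must be nonnegative");
  if (reps < 1) stop("reps must be at least 1");
  if (theta.size() != (R_xlen_t)((reps + 1) * num_qubits))
    stop("theta must have length (reps + 1) * num_qubits");
  if (num_qubits == 0) return NumericVector::create(1.0);
  if (num_qubits > 26) stop("statevector too large");

  const size_t dim = (size_t)1 << num_qubits;
  std::vector<double> psi(dim, 0.0);
  psi[0] = 1.0;

  int par = 0;
  for (int q = 0; q < num_qubits; ++q) apply_ry(psi, num_qubits, q, theta[par++]);
  for (int rep = 0; rep < reps; ++rep) {
    // reverse-linear entangling chain: controls n-2 down to 0, target c+1
    for (int c = num_qubits - 2; c >= 0; --c)
      apply_cnot(psi, num_qubits, c, c + 1);
    for (int q = 0; q < num_qubits; ++q)
      apply_ry(psi, num_qubits, q, theta[par++]);
  }
  return NumericVector(psi.begin(), psi.end());
}
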