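# Independent numerical oracle for the spongy-layer four-flux system:
# global Crank-Nicolson collocation of the full 4x4 linear ODE with its
# two-point boundary conditions (downward flows prescribed at the top,
# upward flows at the bottom), assembled as one sparse banded linear
# system. Unlike initial-value shooting this is stable at any optical
# depth, since growing and decaying modes are never marched explicitly.
# Kept free of any package internals except the parameter meanings.

km_ode_oracle <- function(IC_h, IS_h, JC_hl, JS_hl,
                          l, a_Sp, s_Sp, f, beta_I1, beta_I2,
                          x1_out = seq(0, l, length.out = 5)) {
  c1 <- cos(beta_I1); c2 <- cos(beta_I2)
  L <- matrix(c(
    -(a_Sp + s_Sp) / c1, 0, 0, 0,
    0, (a_Sp + s_Sp) / c2, 0, 0,
    f * s_Sp / c1, (1 - f) * s_Sp / c2,
    -2 * (a_Sp + s_Sp * (1 - f)), 2 * s_Sp * (1 - f),
    -(1 - f) * s_Sp / c1, -f * s_Sp / c2,
    -2 * s_Sp * (1 - f), 2 * (a_Sp + s_Sp * (1 - f))),
    nrow = 4, byrow = TRUE)
  lam_max <- max(abs(L)) * 2 + 1
  # step chosen so the second-order truncation error is well below 1e-6
  m <- min(60000L, max(4000L, ceiling(1200 * lam_max * l)))
  dx <- l / m
  # trapezoidal step: -(I + dx/2 L) y_i + (I - dx/2 L) y_{i+1} = 0
  Aml <- -(diag(4) + dx / 2 * L)
  Amr <- (diag(4) - dx / 2 * L)
  ii <- rep(1:4, each = 4); jj <- rep(1:4, times = 4)   # block row/col
  iv <- rep(0:(m - 1), each = 16)
  rows <- c(4 * iv + rep(ii, m), 4 * iv + rep(ii, m),
            4L * m + 1:4)
  cols <- c(4 * iv + rep(jj, m), 4 * iv + 4 + rep(jj, m),
            c(1L, 3L, 4L * m + 2L, 4L * m + 4L))
  vals <- c(rep(as.vector(t(Aml)), m), rep(as.vector(t(Amr)), m),
            rep(1, 4))
  A <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                            dims = c(4L * (m + 1L), 4L * (m + 1L)))
  b <- c(rep(0, 4L * m), IC_h, IS_h, JC_hl, JS_hl)
  y <- as.vector(Matrix::solve(A, b))
  x1_out <- c(0, x1_out, l)
  flows <- t(vapply(x1_out, function(x) {
    i0 <- min(max(floor(x / dx), 0), m - 1)
    tt <- x / dx - i0
    (1 - tt) * y[4 * i0 + 1:4] + tt * y[4 * (i0 + 1) + 1:4]
  }, numeric(4)))
  colnames(flows) <- c("I_C", "J_C", "I_S", "J_S")
  list(x1 = x1_out, flows = flows)
}

# default pea-leaf geometry used across tests
default_params <- function(...) leaf_params(...)
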