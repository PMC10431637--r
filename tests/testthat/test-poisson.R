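test_that("divergence of a field matches the stride-2 Laplacian", {
  # zero field
  z <- vector_field(matrix(0, 6, 6), matrix(0, 6, 6))
  expect_equal(divergence_rhs(z), matrix(0, 6, 6))
  # U = x^2: stride-2 second difference (U(i-2) - 2U(i) + U(i+2))/4 * 4... the
  # divergence of its exact gradient is 2 away from the 2-pixel border frame
  U <- matrix(rep((1:12)^2, each = 10), nrow = 10)
  f <- divergence_rhs(nabla_transform(U))
  expect_equal(f[3:8, 3:10], matrix(2, 6, 8))
  # linear ramp: second derivative zero on the interior
  U <- matrix(rep(1:12, each = 10), nrow = 10)
  f <- divergence_rhs(nabla_transform(U))
  expect_equal(f[3:8, 3:10], matrix(0, 6, 8))
})

test_that("assemble_b scales by stencil", {
  f <- matrix(c(2, 0), 5, 6)
  expect_equal(assemble_b(f), 4 * f)
  expect_equal(assemble_b(f, "standard_5point"), f)
  expect_identical(dim(assemble_b(f)), dim(f))
})

test_that("jacobi_step performs one synchronous stride-2 sweep", {
  # fixed point at zero
  sys <- poisson_system(matrix(0, 5, 5))
  sys <- jacobi_step(sys)
  expect_equal(sys$U, matrix(0, 5, 5))
  expect_identical(sys$m, 1L)
  # b = 4 at the center of a 5x5: one step gives (0+0+0+0+4)/4 = 1 there
  b <- matrix(0, 5, 5); b[3, 3] <- 4
  sys <- jacobi_step(poisson_system(b))
  expected <- matrix(0, 5, 5); expected[3, 3] <- 1
  expect_equal(sys$U, expected)
  # arbitrary state matches the loop oracle, both stencils
  set.seed(31)
  for (s in c(2L, 1L)) {
    stencil <- if (s == 2L) "paper_stride2" else "standard_5point"
    b <- random_image(9); U0 <- random_image(9)
    sys <- jacobi_step(poisson_system(b, U0 = U0, stencil = stencil))
    expect_equal(sys$U, oracle_jacobi_step(U0, b, s = s), tolerance = 1e-14)
  }
})

test_that("jacobi_solve matches a dense direct solve of the linear system", {
  set.seed(17)
  for (n in c(8L, 12L)) {
    b <- random_image(n) - 0.5
    sol <- jacobi_solve(b, tol = 1e-10, max_iter = 50000)
    expect_true(sol$info$converged)
    expect_lt(max(abs(sol$U - oracle_direct_solve(b, s = 2L))), 1e-8)
  }
  # 5-point stencil against its own dense assembly
  b <- random_image(10) - 0.5
  sol <- jacobi_solve(b, tol = 1e-10, max_iter = 50000,
                      stencil = "standard_5point")
  expect_lt(max(abs(sol$U - oracle_direct_solve(b, s = 1L))), 1e-8)
})

test_that("jacobi_solve edge behavior and diagnostics", {
  # b = 0 converges immediately with U = 0
  sol <- jacobi_solve(matrix(0, 6, 6))
  expect_true(sol$info$converged)
  expect_identical(sol$info$iterations, 0L)
  expect_equal(sol$U, matrix(0, 6, 6))
  # starting from the exact solution: residual below tol at once
  set.seed(2)
  b <- random_image(8) - 0.5
  exact <- oracle_direct_solve(b, 2L)
  sol <- jacobi_solve(b, tol = 1e-8, U0 = exact)
  expect_identical(sol$info$iterations, 0L)
  # non-convergence warns (classed) but still returns
  expect_warning(sol <- jacobi_solve(b, tol = 1e-12, max_iter = 3),
                 class = "nablafuse_nonconvergence")
  expect_false(sol$info$converged)
  # residual history is non-increasing after the initial transient
  sol <- jacobi_solve(b, tol = 1e-10, max_iter = 5000)
  r <- sol$info$residuals
  expect_true(all(diff(r[10:length(r)]) <= 1e-13))
})

test_that("parity classes never exchange information (stride-2)", {
  set.seed(41)
  b <- random_image(11) - 0.5
  joint <- jacobi_solve(b, tol = 1e-11, max_iter = 20000)$U
  acc <- matrix(0, 11, 11)
  row <- matrix(seq_len(11), 11, 11)
  col <- matrix(seq_len(11), 11, 11, byrow = TRUE)
  for (pr in 0:1) for (pc in 0:1) {
    mask <- (row %% 2 == pr) & (col %% 2 == pc)
    bp <- b; bp[!mask] <- 0
    acc <- acc + jacobi_solve(bp, tol = 1e-11, max_iter = 20000)$U
  }
  expect_equal(acc, joint, tolerance = 1e-9)
})

test_that("convergence factor and iteration bound follow the closed forms", {
  expect_equal(convergence_factor(1), cos(pi / 2))
  expect_equal(convergence_factor(3), cos(pi / 4))
  n <- 1:60
  cf <- convergence_factor(n)
  expect_true(all(diff(cf) > 0) && all(cf < 1) && cf[1] < 1e-15)
  expect_error(convergence_factor(0), ">= 1")

  expect_identical(iteration_bound(255L, 0.5), 6641L)
  # alpha -> 1 drives the bound toward zero
  expect_lte(iteration_bound(10L, 0.999), 1L)
  # the bound is the least integer STRICTLY above the closed-form value
  for (case in list(c(255, 0.5), c(64, 0.01), c(9, 0.3))) {
    v <- 2 * (1 - case[2]) * ((case[1] + 1) / pi)^2
    m <- iteration_bound(as.integer(case[1]), case[2])
    expect_true(m > v && m - 1 <= v)
  }
  expect_error(iteration_bound(10L, 1), "strictly inside")
  expect_error(iteration_bound(10L, 0), "strictly inside")
})

test_that("reconstruct inverts the transform on smooth round trips", {
  gc <- make_gradient_case(64)
  rec <- reconstruct(gc$field, dc_reference = mean(gc$image),
                     max_iter = 4000)
  expect_lt(rmse(rec, gc$image), 0.05)       # frozen threshold
  expect_lt(rmse(rec, gc$image), 5e-4)       # measured headroom at 4000 sweeps
  # 5-point carries an O(h^2) stencil mismatch: worse than stride-2 here,
  # but still within the frozen round-trip threshold
  rec5 <- suppressWarnings(
    reconstruct(gc$field, stencil = "standard_5point",
                dc_reference = mean(gc$image), max_iter = 4000))
  expect_lt(rmse(rec5, gc$image), 0.05)
  expect_lte(rmse(rec, gc$image), rmse(rec5, gc$image))
})

test_that("reconstruct handles degenerate fields and DC modes", {
  z <- vector_field(matrix(0, 8, 8), matrix(0, 8, 8))
  rec <- reconstruct(z, dc_mode = "match_mean", dc_reference = 0.5)
  expect_equal(unclass(rec), matrix(0.5, 8, 8), ignore_attr = TRUE)
  # minmax maps a non-constant reconstruction onto [0, 1]
  gc <- make_gradient_case(32)
  rec <- reconstruct(gc$field, dc_mode = "minmax", max_iter = 2000)
  expect_equal(range(rec), c(0, 1))
})

test_that("bilinear images are harmonic for the composed stencil", {
  gc <- make_gradient_case(16, kind = "bilinear")
  f <- divergence_rhs(gc$field)
  expect_equal(f[3:14, 3:14], matrix(0, 12, 12), tolerance = 1e-14)
})
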