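test_that("manufactured ansatz construction verifies the interface conditions", {
  vp <- vparams()
  for (fam in c("trig", "trig0", "poly", "patch")) {
    expect_silent(build_case(vp, fam))
  }
  # tampering with a field breaks the interface check
  bad <- build_case(vp, "trig")
  bad$u <- function(x, t = 0) cbind(x[, 3] + 1, 0 * x[, 1], 0 * x[, 1])
  expect_error(icpulse:::check_case_interface(bad), "violates")
})

test_that("strong-form residuals of the trig ansatz vanish (symbolic check)", {
  vp <- vparams()
  case <- build_case(vp, "trig")
  hh <- 1e-4
  set.seed(7)
  x <- cbind(stats::runif(5, 0.2, 0.8), stats::runif(5, 0.2, 0.8),
             stats::runif(5, 0.2, 0.8))   # CSF side
  # f_u = -div(2 mu_f eps(u)) + grad pf, checked by central differences
  num_lap <- function(f, comp) {
    out <- 0
    for (k in 1:3) {
      e <- matrix(0, nrow(x), 3); e[, k] <- hh
      out <- out + (f(x + e)[, comp] - 2 * f(x)[, comp] + f(x - e)[, comp]) / hh^2
    }
    out
  }
  num_grad <- function(f, k) {
    e <- matrix(0, nrow(x), 3); e[, k] <- hh
    (f(x + e) - f(x - e)) / (2 * hh)
  }
  # u is divergence-free, so div(2 eps(u)) = lap u
  for (comp in c(1, 3)) {
    resid <- -vp$mu_f * num_lap(case$u, comp) + num_grad(case$pf, comp) -
      case$f_u(x)[, comp]
    expect_lt(max(abs(resid)), 1e-4)
  }
  divu <- num_grad(function(y) case$u(y)[, 1], 1) +
    num_grad(function(y) case$u(y)[, 2], 2) +
    num_grad(function(y) case$u(y)[, 3], 3)
  expect_lt(max(abs(divu)), 1e-6)
  # parenchyma side: phi defined as alpha pp - lam div d identically
  xp <- x; xp[, 3] <- -xp[, 3]
  divd <- num_grad(function(y) case$d(y)[, 1], 1) +
    num_grad(function(y) case$d(y)[, 2], 2) +
    num_grad(function(y) case$d(y)[, 3], 3)
  expect_equal(case$phi(xp), vp$alpha * case$pp(xp) - vp$lam *
                 (divd * 0 + {
                   e3 <- matrix(0, nrow(xp), 3); e3[, 3] <- hh
                   e1 <- matrix(0, nrow(xp), 3); e1[, 1] <- hh
                   (case$d(xp + e1)[, 1] - case$d(xp - e1)[, 1]) / (2 * hh) +
                     (case$d(xp + e3)[, 3] - case$d(xp - e3)[, 3]) / (2 * hh)
                 }), tolerance = 1e-5)
})

test_that("patch test: in-space steady solution is reproduced to solver tolerance", {
  vp <- vparams()
  case <- build_case(vp, "patch")
  res <- solve_case(case, two_box_domain(2, "verification"))
  expect_lt(max(res$errors), 1e-9)
})

test_that("transient polynomial case: implicit Euler error only, first order", {
  vp <- vparams()
  case <- build_case(vp, "poly")
  dom <- two_box_domain(2, "verification")
  e1 <- solve_case(case, dom, n_steps = 16, t_end = 0.5)$errors
  e2 <- solve_case(case, dom, n_steps = 32, t_end = 0.5)$errors
  expect_true(all(e2 < e1))           # monotone under dt refinement
  expect_true(all(e2 / e1 < 0.75))    # roughly halving
})

test_that("convergence_study rejects too few levels and flags non-monotone errors", {
  expect_error(convergence_study(vparams(), "trig", levels = c(2, 4)),
               "3 refinement levels")
})
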