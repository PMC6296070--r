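test_that("reference preset carries the published constants and rejects bad input", {
  p <- gut_params()
  expect_equal(p[["k_a"]], 12)
  expect_equal(p[["k_bn"]], 4.7)
  expect_equal(p[["k_B"]], 2.9)
  expect_equal(p[["k_Bo"]], 130)
  expect_equal(gut_params(k_Bo = 300)[["k_Bo"]], 300)

  expect_error(gut_params(k_zz = 1), "k_zz")
  expect_error(gut_params(k_B = -1), "nonnegative")
  expect_error(gut_params(k_B = 0), "strictly positive")
  # k_a = 0 is allowed: it is neither a denominator nor a decay rate
  expect_silent(gut_params(k_a = 0))
})

test_that("core rhs vanishes at the published inflamed state", {
  p <- gut_params()
  x <- unname(inflamed_ref)
  f <- gut_rhs(x, p, "core")
  # the N, R, T, L equations do not involve the lumen drive
  expect_lt(max(abs(f[c("N", "R", "T", "L")])), 1e-4)

  # direct inversion of the butyrate balance: the unique k_Bo with dB = 0
  kinv <- p[["k_B"]] * x[5] /
    (p[["k_bt"]]^2 / (x[3]^2 + p[["k_bt"]]^2) + p[["k_d"]])
  expect_gt(kinv, 129)
  expect_lt(kinv, 131)
  f2 <- gut_rhs(x, gut_params(k_Bo = kinv), "core")
  expect_lt(abs(f2[["B"]]), 1e-10)
})

test_that("Hill numerators vanish where their substrates are zero", {
  p <- gut_params()
  f <- gut_rhs(c(0, 0, 0, 0, 1), p, "core")
  expect_identical(unname(f[["N"]]), 0)   # no cytokine drive
  expect_identical(unname(f[["R"]]), 0)   # repressor production needs N
  # dN/dT = 0 at T = 0: the cubic Hill term is flat at the origin
  J <- gut_jacobian(c(0.5, 1, 0, 1, 1), p, "core")
  expect_identical(J["N", "T"], 0)
})

test_that("analytic Jacobian matches central finite differences", {
  p <- gut_params()
  set.seed(11)
  for (variant in c("base", "core", "extended")) {
    n <- length(state_names(variant))
    for (rep in 1:20) {
      x <- c(runif(1, 0.05, 0.95), runif(n - 1, 0.5, 30))
      J <- gut_jacobian(x, p, variant)
      h <- 1e-6
      Jfd <- matrix(0, n, n)
      for (k in seq_len(n)) {
        e <- numeric(n); e[k] <- h * max(1, abs(x[k]))
        Jfd[, k] <- (gutswitch:::rhs_eval(x + e, p, variant) -
                       gutswitch:::rhs_eval(x - e, p, variant)) / (2 * e[k])
      }
      denom <- pmax(abs(Jfd), 1)
      expect_lt(max(abs(J - Jfd) / denom), 1e-5)
    }
  }
})

test_that("the repressor equation is linear: constant Jacobian row", {
  p <- gut_params()
  set.seed(3)
  for (rep in 1:5) {
    x <- c(runif(1), runif(4, 0, 50))
    J <- gut_jacobian(x, p, "core")
    expect_equal(unname(J["R", ]), c(5, -0.5, 0, 0, 0))
  }
})

test_that("variants disagree only in the documented terms", {
  p <- gut_params()
  x <- c(0.3, 2, 10, 0.5, 8)
  fc <- gut_rhs(x, p, "core")
  fe <- gut_rhs(x, p, "extended")
  # only the butyrate equation differs, by the feedback Hill factor
  expect_equal(fc[c("N", "R", "T", "L")], fe[c("N", "R", "T", "L")])
  tr <- p[["k_Bo"]] * p[["k_bt"]]^2 / (x[3]^2 + p[["k_bt"]]^2)
  expect_equal(unname(fe[["B"]] - fc[["B"]]),
               tr * (x[5]^2 / (x[5]^2 + p[["k_2B"]]^2) - 1))
  # base variant: 4 states, constant LPS influx
  fb <- gut_rhs(x[1:4], p, "base")
  expect_length(fb, 4)
  expect_equal(unname(fb[["L"]]), p[["k_bl"]] - p[["k_l"]] * x[4])
})

test_that("state validation enforces the admissible region and dimensions", {
  p <- gut_params()
  expect_error(gut_rhs(c(0.5, 1, 1, 1), p, "core"), "5 state components")
  expect_error(gut_rhs(c(0.5, 1, 1, 1, 1), p, "base"), "4 state components")
  expect_error(gut_rhs(c(-0.1, 1, 1, 1, 1), p, "core"), "nonnegative")
  expect_error(gut_rhs(c(1.2, 1, 1, 1, 1), p, "core"), "\\[0, 1\\]")
})

test_that("parameter presets round-trip through the config format", {
  p <- gut_params(k_Bo = 77)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_params_config(p, path, variant = "extended")
  back <- read_params_config(path)
  expect_equal(as.numeric(back$params), as.numeric(p))
  expect_equal(back$variant, "extended")
  # unknown keys rejected
  cfg <- yaml::read_yaml(path)
  cfg$k_zz <- 1
  yaml::write_yaml(cfg, path)
  expect_error(read_params_config(path), "k_zz")
})
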