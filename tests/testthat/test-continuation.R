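test_that("the scalar saddle-node test problem is refined exactly", {
  # dx/dt = mu - x^2: fold at (x, mu) = (0, 0), q = p = 1, a = -1
  sys <- list(f = function(x, pv) pv - x^2,
              J = function(x, pv) matrix(-2 * x, 1, 1),
              gp = function(x, pv) 1,
              n = 1L)
  fold <- gutswitch:::refine_fold_sys(sys, 0.4, 0.16)
  expect_equal(fold$x, 0, tolerance = 1e-10)
  expect_equal(fold$pv, 0, tolerance = 1e-10)
  expect_equal(abs(fold$q), 1, tolerance = 1e-12)
  a <- gutswitch:::normal_form_sys(sys, fold$x, fold$pv, fold$q,
                                   fold$p_vec)
  expect_equal(a * sign(fold$q), -1, tolerance = 1e-6)
})

test_that("lumen-butyrate continuation finds the two published folds", {
  br <- ref_branch()
  expect_length(br$folds, 2)
  kf <- vapply(br$folds, function(f) f$param_value, numeric(1))
  # printed as approximate thresholds ~55 and ~200
  expect_lt(rel_err(kf[1], 55), 0.10)
  expect_lt(rel_err(kf[2], 200), 0.10)
  expect_true(all(vapply(br$folds, function(f) f$residual,
                         numeric(1)) < 1e-10))
  # each fold has a single near-zero, real critical eigenvalue
  for (f in br$folds) {
    crit <- sort(abs(Re(f$eigenvalues)))
    expect_lt(crit[1], 1e-8)
    expect_gt(crit[2], 1e-3)
  }
})

test_that("fold normal-form coefficients match the published values", {
  br <- ref_branch()
  a <- vapply(br$folds, function(f) f$a, numeric(1))
  # stable-side orientation: both negative (stable flanking layers)
  expect_true(all(a < 0))
  expect_lt(rel_err(abs(a[1]), 0.1079160), 1e-3)
  expect_lt(rel_err(abs(a[2]), 0.01114689), 1e-3)
})

test_that("branch points are equilibria with the stability pattern of a hysteresis", {
  br <- ref_branch()
  p <- gut_params()
  idx <- round(seq(1, nrow(br$points), length.out = 40))
  for (i in idx) {
    x <- as.numeric(br$points[i, state_names("core")])
    pv <- br$points$param[i]
    f <- gutswitch:::rhs_eval(x, gut_params(k_Bo = pv), "core")
    expect_lt(max(abs(f) / pmax(1, abs(x))), 1e-8)
  }
  expect_setequal(unique(br$points$layer), c("lower", "middle", "upper"))
  expect_true(all(br$points$stability[br$points$layer != "middle"] ==
                    "stable"))
  expect_true(all(br$points$stability[br$points$layer == "middle"] ==
                    "unstable"))
  # no imaginary-axis crossings away from the folds
  expect_equal(nrow(br$hopf), 0)
})

test_that("lumen LPS is a one-way switch: a single fold, inflamed layer everywhere", {
  br <- kbl_branch()
  expect_length(br$folds, 1)
  expect_gt(br$folds[[1]]$param_value, 0)
  # the low-butyrate layer spans the whole nonnegative range: decreasing
  # LPS never recovers the high-butyrate state
  lower <- br$points[br$points$layer == "lower", ]
  expect_lt(min(lower$param), 0.2)
  expect_gt(max(lower$param), 9)
  # and it persists at the right end of the range
  fps10 <- find_fixed_points(gut_params(k_bl = 10), "core",
                             spec = search_spec(n_grid = 3, K = 1e3))
  expect_true(any(vapply(fps10, function(f) {
    f$stability == "stable" && f$state[["B"]] < 10
  }, logical(1))))
  # the high-butyrate layer exists only below the fold
  upper <- br$points[br$points$layer == "upper", ]
  expect_lt(max(upper$param), br$folds[[1]]$param_value + 1e-6)
})

test_that("the upper layer approaches the linear large-drive asymptote", {
  spec <- search_spec(n_grid = 3, K = 1e3)
  B_at <- function(kBo) {
    fps <- find_fixed_points(gut_params(k_Bo = kBo), "core", spec = spec)
    expect_length(fps, 1)
    fps[[1]]$state[["B"]]
  }
  slope <- (B_at(1000) - B_at(900)) / 100
  p <- gut_params()
  expect_lt(rel_err(slope, (1 + p[["k_d"]]) / p[["k_B"]]), 0.02)
})

test_that("the mucin feedback widens the bistable window", {
  iv_core <- bistable_interval(ref_branch())
  iv_ext <- bistable_interval(ext_branch())
  expect_gt(diff(iv_ext), diff(iv_core))
  expect_gt(iv_ext[2], iv_core[2])
  # the multiplicative feedback factor <= 1 shifts both folds right;
  # the left fold cannot move below the core model's
  expect_gt(iv_ext[1], iv_core[1])
})

test_that("branch export round-trips the layer structure", {
  br <- ref_branch()
  path <- withr::local_tempfile(fileext = ".csv")
  write_branch_csv(br, path)
  back <- utils::read.csv(path)
  expect_named(back, c("k_Bo", "N", "R", "T", "L", "B", "stability",
                       "sweep", "layer"))
  expect_equal(nrow(back), nrow(br$points))
  jpath <- withr::local_tempfile(fileext = ".json")
  write_folds_json(br, jpath)
  folds <- jsonlite::read_json(jpath)
  expect_length(folds, 2)
  expect_equal(folds[[1]]$param_value, br$folds[[1]]$param_value)
})
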