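test_that("pulse protocols validate their segments", {
  segs <- data.frame(t_start = c(50, 200), t_end = c(170, 270),
                     k_Bo = c(210, 50))
  pr <- pulse_protocol(130, segs)
  expect_s3_class(pr, "gut_protocol")
  expect_error(pulse_protocol(-1), "nonnegative")
  expect_error(pulse_protocol(130, data.frame(t_start = 5, t_end = 5,
                                              k_Bo = 1)),
               "t_start < t_end")
  expect_error(pulse_protocol(130, data.frame(t_start = c(0, 5),
                                              t_end = c(10, 15),
                                              k_Bo = c(1, 2))),
               "overlap")
  expect_error(pulse_protocol(130, data.frame(t_start = 0, t_end = 10,
                                              k_Bo = -2)),
               "nonnegative")
})

test_that("a zero-length time span returns exactly the initial state", {
  tr <- simulate_model(unname(inflamed_ref), gut_params(), "core",
                       t_span = c(5, 5))
  expect_equal(nrow(tr), 1)
  expect_equal(as.numeric(tr[1, 2:6]), unname(inflamed_ref))
})

test_that("a stable equilibrium is held to solver accuracy", {
  fp <- ref_fps()[[1]]
  tr <- simulate_model(as.numeric(fp$state), gut_params(), "core",
                       t_span = c(0, 100))
  dev <- apply(tr[, names(fp$state)], 1, function(x) {
    max(abs(x - fp$state) / pmax(abs(fp$state), 1e-6))
  })
  expect_lt(max(dev), 1e-6)
})

test_that("endpoint classification resolves exact matches and rejects distant states", {
  fps <- ref_fps()
  tr <- data.frame(time = 0, t(as.numeric(fps[[3]]$state)))
  expect_identical(classify_endpoint(tr, fps), 3L)
  far <- data.frame(time = 0, t(c(0.5, 5, 5, 1, 30)))
  expect_identical(classify_endpoint(far, fps), "unresolved")
  expect_error(classify_endpoint(tr, list()), "nonempty")
})

test_that("drive history selects the attractor at identical final drive", {
  p <- gut_params()
  stable <- ref_stable()
  x0 <- as.numeric(stable[[1]]$state)
  # same final constant drive 130, different histories
  high <- pulse_protocol(130, data.frame(t_start = 50, t_end = 170,
                                         k_Bo = 210))
  low <- pulse_protocol(130, data.frame(t_start = 50, t_end = 170,
                                        k_Bo = 50))
  tr_high <- simulate_model(x0, p, "core", c(0, 300), high)
  tr_low <- simulate_model(as.numeric(stable[[2]]$state), p, "core",
                           c(0, 300), low)
  expect_identical(classify_endpoint(tr_high, stable), 2L)
  expect_identical(classify_endpoint(tr_low, stable), 1L)
})

test_that("extreme constant drives are monostable from random starts", {
  p <- gut_params()
  set.seed(31)
  fps_hi <- find_fixed_points(gut_params(k_Bo = 300), "core",
                              spec = search_spec(n_grid = 3, K = 1e3))
  fps_lo <- find_fixed_points(gut_params(k_Bo = 20), "core",
                              spec = search_spec(n_grid = 3, K = 1e3))
  expect_length(fps_hi, 1)
  expect_length(fps_lo, 1)
  for (rep in 1:20) {
    x0 <- c(runif(1), runif(4, 0.1, 40))
    tr <- simulate_model(x0, gut_params(k_Bo = 300), "core", c(0, 400),
                         dt = 10)
    expect_identical(classify_endpoint(tr, fps_hi), 1L)
    tr2 <- simulate_model(x0, gut_params(k_Bo = 20), "core", c(0, 400),
                          dt = 10)
    expect_identical(classify_endpoint(tr2, fps_lo), 1L)
  }
})

test_that("positive orthant is invariant along random trajectories", {
  set.seed(32)
  rep <- verify_orthant_invariance(gut_params(), "core", n_traj = 50)
  expect_true(rep$pass)
  expect_gt(rep$worst_min, -1e-6)
  expect_lt(rep$worst_N, 1 + 1e-6)
})

test_that("trajectories round-trip through CSV with the applied drive", {
  proto <- pulse_protocol(130, data.frame(t_start = 10, t_end = 20,
                                          k_Bo = 210))
  tr <- simulate_model(unname(inflamed_ref), gut_params(), "core",
                       c(0, 30), proto)
  expect_equal(unique(tr$k_Bo_applied[tr$time >= 10 & tr$time < 20]), 210)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- read_trajectory_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(tr), tolerance = 1e-12)
})

test_that("protocol segments outside the time span are rejected", {
  proto <- pulse_protocol(130, data.frame(t_start = 10, t_end = 20,
                                          k_Bo = 210))
  expect_error(simulate_model(unname(inflamed_ref), gut_params(), "core",
                              c(0, 15), proto),
               "inside t_span")
})
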