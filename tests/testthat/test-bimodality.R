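test_that("the input density is a unit-mass truncated Gaussian on its grid", {
  p <- input_density(130, 40)
  expect_lt(abs(gutswitch:::trapz(p$grid, p$dens) - 1), 1e-6)
  expect_equal(p$pdf(-5), 0)
  expect_error(input_density(130, 0), "sd must be positive")
})

test_that("identity and linear maps reproduce the closed-form transform", {
  pd <- input_density(130, 40)
  xs <- seq(0, 400, length.out = 201)

  tfi <- transform_density(synthetic_branch(xs, xs), pd)
  tab <- tfi$layers$stable
  expect_lt(max(abs(tab$q - pd$pdf(tab$y))), 1e-14)

  tfl <- transform_density(synthetic_branch(xs, 2 * xs), pd)
  tab <- tfl$layers$stable
  expect_lt(max(abs(tab$q - pd$pdf(tab$y / 2) / 2)), 1e-14)
  # total probability mass preserved under the linear map
  expect_lt(abs(tfl$retained_mass - 1), 1e-9)
})

test_that("a fold-straddling Gaussian becomes bimodal and matches Monte Carlo", {
  br <- wide_branch()
  pd <- input_density(130, 40)
  tf <- transform_density(br, pd)
  expect_length(tf$modes, 2)
  foldB <- sort(vapply(br$folds, function(f) f$state[["B"]], numeric(1)))
  # one mode below the fold butyrate of the lower layer, one above the
  # fold butyrate of the upper layer
  expect_lt(tf$modes[1], foldB[1])
  expect_gt(tf$modes[2], foldB[2])
  expect_lt(tf$mass_error, 1e-3)

  set.seed(41)
  ys <- sample_transformed(tf, br, 1e5)
  expect_lt(tv_distance(ys, tf), 0.03)
})

test_that("conditional coverage conserves probability mass", {
  br <- wide_branch()
  pd <- input_density(130, 40)
  tf <- transform_density(br, pd, coverage = "conditional")
  # transformed + fold-excluded mass accounts for the input mass except
  # the sliver of support below the branch range
  expect_lt(abs(tf$retained_mass + tf$excluded_mass - 1), 1e-3)
  expect_lt(tf$mass_error, 1e-3)
  # the two principal modes persist
  foldB <- sort(vapply(br$folds, function(f) f$state[["B"]], numeric(1)))
  expect_true(any(tf$modes < foldB[1]))
  expect_true(any(tf$modes > foldB[2]))
  set.seed(42)
  ys <- sample_transformed(tf, br, 1e5)
  expect_lt(tv_distance(ys, tf), 0.03)
})

test_that("a density supported beyond the bistable window stays unimodal", {
  br <- cached("br_460", trace_branch(gut_params(), "core", "k_Bo",
                                      c(5, 460)))
  tf <- transform_density(br, input_density(400, 10))
  expect_length(tf$modes, 1)
})

test_that("halving the branch spacing leaves the density unchanged", {
  pd <- input_density(130, 40)
  h <- function(x) 40 + 30 * tanh((x - 130) / 60)
  xs1 <- seq(0, 400, length.out = 150)
  xs2 <- seq(0, 400, length.out = 300)
  q1 <- transform_density(synthetic_branch(xs1, h(xs1)), pd)$q_combined
  q2 <- transform_density(synthetic_branch(xs2, h(xs2)), pd)$q_combined
  expect_lt(max(abs(q1 - q2)), 1e-3)
})

test_that("invalid weights and non-invertible layers are rejected", {
  pd <- input_density(130, 40)
  xs <- seq(0, 400, length.out = 100)
  expect_error(transform_density(wide_branch(), pd,
                                 weights = c(lower = 0.7, upper = 0.7)),
               "sum to 1")
  wiggly <- synthetic_branch(xs, sin(xs / 20))
  expect_error(transform_density(wiggly, pd), "not monotone")
})

test_that("density export writes grid and summary", {
  br <- wide_branch()
  tf <- transform_density(br, input_density(130, 40))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_density_csv(tf, csv)
  back <- utils::read.csv(csv)
  expect_named(back, c("y", "q_upper", "q_lower", "q_combined"))
  js <- withr::local_tempfile(fileext = ".json")
  write_density_summary_json(tf, js)
  summ <- jsonlite::read_json(js)
  expect_length(summ$modes, 2)
  expect_equal(summ$coverage, "fair")
})
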