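# Equilibrium location, linear stability, and the invariant-box /
# positive-orthant verification suite.

# Scaled residual: per-component |rhs| / max(1, |state|), so that the
# ~4 orders of magnitude spread between the inflamed and non-inflamed
# states does not distort the convergence test.
scaled_residual <- function(f, x) {
  max(abs(f) / pmax(1, abs(x)))
}

# Damped Newton on rhs = 0 with the analytic Jacobian.  Returns the
# refined state or NULL on failure.
newton_refine <- function(x0, params, variant, tol = 1e-12, maxit = 60) {
  x <- x0
  f <- rhs_eval(x, params, variant)
  for (i in seq_len(maxit)) {
    if (scaled_residual(f, x) < tol) break
    J <- jac_eval(x, params, variant)
    dx <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(dx) || any(!is.finite(dx))) return(NULL)
    lambda <- 1
    repeat {
      xn <- x + lambda * dx
      fn <- rhs_eval(xn, params, variant)
      if (all(is.finite(fn)) && sum(fn^2) < sum(f^2)) break
      lambda <- lambda / 2
      if (lambda < 1e-8) return(NULL)
    }
    x <- xn
    f <- fn
    if (max(abs(x)) > 1e10) return(NULL)
  }
  if (scaled_residual(rhs_eval(x, params, variant), x) < 1e-9) x else NULL
}

#' Multistart grid for equilibrium search
#'
#' Defines the grid of Newton starting points used by
#' [find_fixed_points()]: `N` on a fixed set of values spanning the unit
#' interval, the remaining components log-spaced between `lower` and `K`.
#'
#' @param n_grid points per non-N component.
#' @param K upper bound of the search box (also the invariant-box bound).
#' @param lower lower bound for the log-spaced components.
#' @param N_grid values for the N component.
#' @return list of class `"gut_search_spec"`.
#' @export
search_spec <- function(n_grid = 4, K = 1e4, lower = 1e-4,
                        N_grid = c(0.001, 0.01, 0.1, 0.5, 0.9)) {
  stopifnot(n_grid >= 2, K > lower, lower > 0)
  structure(list(n_grid = n_grid, K = K, lower = lower, N_grid = N_grid),
            class = "gut_search_spec")
}

start_grid <- function(spec, variant) {
  g <- exp(seq(log(spec$lower), log(spec$K), length.out = spec$n_grid))
  if (variant == "base") {
    grid <- expand.grid(N = spec$N_grid, R = g, T = g, L = g)
  } else {
    grid <- expand.grid(N = spec$N_grid, R = g, T = g, L = g, B = g)
  }
  as.matrix(grid)
}

#' Locate all equilibria at a fixed parameter set
#'
#' Runs damped Newton from every point of a multistart grid, keeps
#' converged roots in the closed positive orthant (with `N <= 1`),
#' deduplicates them, and classifies linear stability from the analytic
#' Jacobian.  Deterministic given the grid.
#'
#' @param params a [gut_params()] vector.
#' @param variant model variant.
#' @param spec a [search_spec()].
#' @param tol_stab classification threshold on eigenvalue real parts.
#' @return list of class `"gut_fixed_points"`; each element is a
#'   `"gut_fixed_point"` list with `state`, `eigenvalues`, `stability`
#'   (`"stable"`, `"unstable"` or `"marginal"`), `residual`, `params`,
#'   `variant`.  Sorted by the last state component (B for core/extended).
#' @examples
#' \donttest{
#' fps <- find_fixed_points(gut_params(k_Bo = 130), "core")
#' length(fps)  # 3 in the bistable window
#' }
#' @export
find_fixed_points <- function(params, variant = "core",
                              spec = search_spec(), tol_stab = 1e-8) {
  variant <- match_variant(variant)
  validate_params(params)
  starts <- start_grid(spec, variant)
  roots <- list()
  for (i in seq_len(nrow(starts))) {
    x <- newton_refine(starts[i, ], params, variant)
    if (is.null(x)) next
    if (any(x < -1e-9) || x[1] > 1 + 1e-9) next
    x <- pmax(x, 0)
    dup <- any(vapply(roots, function(r) {
      max(abs(r - x) / pmax(1, abs(r))) < 1e-6
    }, logical(1)))
    if (!dup) roots[[length(roots) + 1L]] <- x
  }
  roots <- roots[order(vapply(roots, function(r) r[length(r)], numeric(1)))]
  fps <- lapply(roots, function(x) {
    st <- stability_of(x, params, variant, tol_stab = tol_stab,
                       check_residual = FALSE)
    structure(list(
      state = stats::setNames(x, state_names(variant)),
      eigenvalues = st$eigenvalues,
      stability = st$stability,
      residual = scaled_residual(rhs_eval(x, params, variant), x),
      params = params, variant = variant
    ), class = "gut_fixed_point")
  })
  structure(fps, class = "gut_fixed_points")
}

#' Linear stability of an equilibrium
#'
#' Eigenvalues of the analytic Jacobian and the derived stability class:
#' `"stable"` if all real parts are below `-tol_stab`, `"unstable"` if
#' any exceeds `+tol_stab`, otherwise `"marginal"` (with a warning).
#'
#' @param state equilibrium state vector.
#' @param params,variant as in [gut_rhs()].
#' @param tol_stab threshold on eigenvalue real parts.
#' @param check_residual if `TRUE`, error when `state` is not an
#'   equilibrium to scaled residual 1e-6.
#' @return list with `eigenvalues` (complex) and `stability`.
#' @export
stability_of <- function(state, params, variant = "core", tol_stab = 1e-8,
                         check_residual = TRUE) {
  variant <- match_variant(variant)
  state <- as.numeric(state)
  if (check_residual) {
    res <- scaled_residual(rhs_eval(state, params, variant), state)
    if (res > 1e-6) {
      stop("state is not an equilibrium (scaled residual ", signif(res, 3),
           ")", call. = FALSE)
    }
  }
  ev <- eigen(jac_eval(state, params, variant), only.values = TRUE)$values
  re <- Re(ev)
  stability <- if (all(re < -tol_stab)) {
    "stable"
  } else if (any(re > tol_stab)) {
    "unstable"
  } else {
    warning("marginal equilibrium: |Re(lambda)| <= tol_stab", call. = FALSE)
    "marginal"
  }
  list(eigenvalues = ev, stability = stability)
}

#' @export
print.gut_fixed_point <- function(x, ...) {
  cat(sprintf("<%s equilibrium, %s>\n", x$variant, x$stability))
  print(signif(x$state, 6))
  cat("max Re(lambda) =", signif(max(Re(x$eigenvalues)), 4),
      " residual =", signif(x$residual, 2), "\n")
  invisible(x)
}

#' @export
print.gut_fixed_points <- function(x, ...) {
  cat(length(x), "equilibrium(a):\n")
  for (fp in x) print(fp)
  invisible(x)
}

#' Invariant box for the existence argument
#'
#' The compact box `P`: `0 <= N <= 1`, `0 <= L <= L0 = k_bl/k_l + delta`,
#' `0 <= R, T, B <= K`, into which the vector field points on every face,
#' so a fixed point exists in its interior.  `u` and `d` are the max/min
#' of all constants; `d > 0` guarantees outward flow from the origin.
#'
#' @param params a [gut_params()] vector.
#' @param delta slack above the LPS equilibrium ceiling `k_bl/k_l`.
#' @param K upper bound for R, T, B (must exceed `L0`).
#' @param epsilon radius of the origin ball checked for repulsivity.
#' @return list of class `"gut_box"` with `L0`, `K`, `delta`, `epsilon`,
#'   `u`, `d`.
#' @export
invariant_box <- function(params, delta = 1, K = 1e4, epsilon = 1e-4) {
  validate_params(params)
  L0 <- params[["k_bl"]] / params[["k_l"]] + delta
  if (K <= L0) stop("K must exceed L0 = k_bl/k_l + delta", call. = FALSE)
  if (delta <= 0 || epsilon <= 0) {
    stop("delta and epsilon must be positive", call. = FALSE)
  }
  core_consts <- setdiff(PARAM_NAMES, "k_2B")
  structure(list(
    L0 = L0, K = K, delta = delta, epsilon = epsilon,
    u = max(params[core_consts]), d = min(params[core_consts])
  ), class = "gut_box")
}

#' Verify invariance of the box and repulsivity of the origin
#'
#' Numerical counterpart of the analytical existence argument: samples
#' points uniformly on each face of the box `P` and checks that the
#' normal component of the vector field points into the box (strictly on
#' the upper faces `N = 1`, `L = L0`, `R = T = B = K`; non-outward on the
#' coordinate faces, where some components vanish identically), and that
#' in the ball of radius `epsilon` around the origin both `dL/dt` and
#' `dB/dt` are strictly positive, so no equilibrium sits there.
#'
#' @param params,variant as in [gut_rhs()] (core or extended).
#' @param box an [invariant_box()].
#' @param n_samples sample points per face.
#' @return list of class `"gut_box_report"`: `pass` (overall), `faces`
#'   (data frame with per-face worst margins; positive margin = inward),
#'   `origin_ball` (pass flag and worst dL/dt, dB/dt margins).
#' @export
verify_box_invariance <- function(params, variant = "core",
                                  box = invariant_box(params),
                                  n_samples = 200) {
  variant <- match_variant(variant)
  if (variant == "base") {
    stop("box verification is defined for the 5-variable variants",
         call. = FALSE)
  }
  validate_params(params)
  upper <- c(N = 1, R = box$K, T = box$K, L = box$L0, B = box$K)
  nm <- state_names(variant)
  face_rows <- list()
  for (i in seq_along(nm)) {
    for (side in c("lower", "upper")) {
      margins <- numeric(n_samples)
      for (s in seq_len(n_samples)) {
        x <- stats::runif(5) * upper
        x[i] <- if (side == "lower") 0 else upper[i]
        f <- rhs_eval(x, params, variant)
        # inward = positive margin on both sides
        margins[s] <- if (side == "lower") f[i] else -f[i]
      }
      worst <- min(margins)
      ok <- if (side == "upper") worst > 0 else worst >= -1e-12
      face_rows[[length(face_rows) + 1L]] <- data.frame(
        face = paste0(nm[i], "_", side), worst_margin = worst, pass = ok)
    }
  }
  faces <- do.call(rbind, face_rows)
  # origin ball: all components <= epsilon
  worst_L <- Inf; worst_B <- Inf
  for (s in seq_len(n_samples)) {
    x <- stats::runif(5) * box$epsilon
    f <- rhs_eval(x, params, variant)
    worst_L <- min(worst_L, f[4])
    worst_B <- min(worst_B, f[5])
  }
  origin <- list(pass = worst_L > 0 && worst_B > 0,
                 worst_dL = worst_L, worst_dB = worst_B)
  structure(list(pass = all(faces$pass) && origin$pass,
                 faces = faces, origin_ball = origin, box = box),
            class = "gut_box_report")
}

#' @export
print.gut_box_report <- function(x, ...) {
  cat("Invariant-box verification:", if (x$pass) "PASS" else "FAIL", "\n")
  print(x$faces, row.names = FALSE)
  cat(sprintf("origin ball (eps=%g): %s  (worst dL=%.3g, dB=%.3g)\n",
              x$box$epsilon, if (x$origin_ball$pass) "PASS" else "FAIL",
              x$origin_ball$worst_dL, x$origin_ball$worst_dB))
  invisible(x)
}
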