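# Right-hand sides, analytic Jacobians and parameter derivatives of the
# three model variants.
#
# States: N nuclear NF-kB fraction (dimensionless, in [0,1]), R repressor,
# T cytokines, L within-cell LPS, B within-cell butyrate (core/extended).
#
# base:      dN = k_a T^3/(T^3+k_s^3) (1-N) - k_ai R N/(N+k_r)
#            dR = k_b N - k_br R
#            dT = k_p N^2/(N^2+k_n^2) - k_t T + k_tl L
#            dL = k_bl - k_l L
# core:      as base but butyrate blocks nuclear NF-kB entry
#            (k_ai R -> k_ai R + k_bn B), LPS influx is gated by butyrate
#            (k_bl -> k_bl k_lb^2/(B^2+k_lb^2)), and
#            dB = k_Bo k_bt^2/(T^2+k_bt^2) + k_d k_Bo - k_B B
# extended:  as core, with the transporter term multiplied by the
#            positive-feedback Hill factor B^2/(B^2+k_2B^2)
#            (butyrate -> mucin -> SCFA producers -> lumen butyrate).

check_state <- function(state, variant, tol = 0) {
  variant <- match_variant(variant)
  n_expect <- if (variant == "base") 4L else 5L
  if (length(state) != n_expect) {
    stop("variant '", variant, "' expects ", n_expect,
         " state components, got ", length(state), call. = FALSE)
  }
  if (any(!is.finite(state))) stop("non-finite state", call. = FALSE)
  if (any(state < -tol)) {
    stop("state components must be nonnegative", call. = FALSE)
  }
  if (state[1] > 1 + tol) {
    stop("N must lie in [0, 1]", call. = FALSE)
  }
  invisible(state)
}

# Unchecked evaluation, shared by the integrator and the solvers (which
# may probe slightly outside the admissible region during refinement).
rhs_eval <- function(state, p, variant) {
  N <- state[1]; R <- state[2]; T <- state[3]; L <- state[4]
  hillT <- T^3 / (T^3 + p[["k_s"]]^3)
  satN <- N / (N + p[["k_r"]])
  dT <- p[["k_p"]] * N^2 / (N^2 + p[["k_n"]]^2) - p[["k_t"]] * T +
    p[["k_tl"]] * L
  dR <- p[["k_b"]] * N - p[["k_br"]] * R
  if (variant == "base") {
    dN <- p[["k_a"]] * hillT * (1 - N) - p[["k_ai"]] * R * satN
    dL <- p[["k_bl"]] - p[["k_l"]] * L
    return(c(dN, dR, dT, dL))
  }
  B <- state[5]
  dN <- p[["k_a"]] * hillT * (1 - N) -
    (p[["k_ai"]] * R + p[["k_bn"]] * B) * satN
  dL <- p[["k_bl"]] * p[["k_lb"]]^2 / (B^2 + p[["k_lb"]]^2) -
    p[["k_l"]] * L
  transport <- p[["k_Bo"]] * p[["k_bt"]]^2 / (T^2 + p[["k_bt"]]^2)
  if (variant == "extended") {
    transport <- transport * B^2 / (B^2 + p[["k_2B"]]^2)
  }
  dB <- transport + p[["k_d"]] * p[["k_Bo"]] - p[["k_B"]] * B
  c(dN, dR, dT, dL, dB)
}

jac_eval <- function(state, p, variant) {
  N <- state[1]; R <- state[2]; T <- state[3]
  n <- if (variant == "base") 4L else 5L
  J <- matrix(0, n, n)
  hillT <- T^3 / (T^3 + p[["k_s"]]^3)
  dhillT <- 3 * T^2 * p[["k_s"]]^3 / (T^3 + p[["k_s"]]^3)^2
  satN <- N / (N + p[["k_r"]])
  dsatN <- p[["k_r"]] / (N + p[["k_r"]])^2
  inhib <- if (variant == "base") p[["k_ai"]] * R else
    p[["k_ai"]] * R + p[["k_bn"]] * state[5]
  J[1, 1] <- -p[["k_a"]] * hillT - inhib * dsatN
  J[1, 2] <- -p[["k_ai"]] * satN
  J[1, 3] <- p[["k_a"]] * dhillT * (1 - N)
  J[2, 1] <- p[["k_b"]]
  J[2, 2] <- -p[["k_br"]]
  J[3, 1] <- p[["k_p"]] * 2 * N * p[["k_n"]]^2 / (N^2 + p[["k_n"]]^2)^2
  J[3, 3] <- -p[["k_t"]]
  J[3, 4] <- p[["k_tl"]]
  J[4, 4] <- -p[["k_l"]]
  if (variant == "base") return(J)
  B <- state[5]
  J[1, 5] <- -p[["k_bn"]] * satN
  J[4, 5] <- -p[["k_bl"]] * 2 * B * p[["k_lb"]]^2 / (B^2 + p[["k_lb"]]^2)^2
  hillB <- B^2 / (B^2 + p[["k_2B"]]^2)
  dhillB <- 2 * B * p[["k_2B"]]^2 / (B^2 + p[["k_2B"]]^2)^2
  satT <- p[["k_bt"]]^2 / (T^2 + p[["k_bt"]]^2)
  dsatT <- -2 * T * p[["k_bt"]]^2 / (T^2 + p[["k_bt"]]^2)^2
  if (variant == "extended") {
    J[5, 3] <- p[["k_Bo"]] * dsatT * hillB
    J[5, 5] <- p[["k_Bo"]] * satT * dhillB - p[["k_B"]]
  } else {
    J[5, 3] <- p[["k_Bo"]] * dsatT
    J[5, 5] <- -p[["k_B"]]
  }
  J
}

#' Time derivatives of the model
#'
#' Evaluates the right-hand side of the selected model variant.
#'
#' @param state named or unnamed state vector: `(N, R, T, L)` for the base
#'   variant, `(N, R, T, L, B)` for core/extended.  Components must be
#'   nonnegative and `N` must not exceed 1.
#' @param params a [gut_params()] vector.
#' @param variant one of `"base"`, `"core"`, `"extended"`.
#' @return numeric vector of time derivatives, named as the state.
#' @examples
#' p <- gut_params()
#' gut_rhs(c(N = 0.2, R = 2, T = 20, L = 0.3, B = 6), p, "core")
#' @export
gut_rhs <- function(state, params, variant = "core") {
  variant <- match_variant(variant)
  validate_params(params)
  state <- as.numeric(state)
  check_state(state, variant)
  stats::setNames(rhs_eval(state, params, variant), state_names(variant))
}

#' Analytic Jacobian of the model
#'
#' Partial derivatives of [gut_rhs()] with respect to the state, needed
#' for stability classification, Newton refinement and continuation.
#'
#' @inheritParams gut_rhs
#' @return square numeric matrix (4x4 base, 5x5 core/extended) with
#'   dimnames the state names.
#' @export
gut_jacobian <- function(state, params, variant = "core") {
  variant <- match_variant(variant)
  validate_params(params)
  state <- as.numeric(state)
  check_state(state, variant)
  nm <- state_names(variant)
  J <- jac_eval(state, params, variant)
  dimnames(J) <- list(nm, nm)
  J
}

# d rhs / d (free parameter), analytic for the two continuation
# parameters; central finite difference for any other constant.
param_deriv <- function(state, p, variant, free_param) {
  n <- if (variant == "base") 4L else 5L
  g <- numeric(n)
  if (variant != "base" && free_param == "k_Bo") {
    T <- state[3]; B <- state[5]
    tr <- p[["k_bt"]]^2 / (T^2 + p[["k_bt"]]^2)
    if (variant == "extended") tr <- tr * B^2 / (B^2 + p[["k_2B"]]^2)
    g[5] <- tr + p[["k_d"]]
  } else if (free_param == "k_bl") {
    if (variant == "base") {
      g[4] <- 1
    } else {
      B <- state[5]
      g[4] <- p[["k_lb"]]^2 / (B^2 + p[["k_lb"]]^2)
    }
  } else {
    h <- 1e-6 * max(1, abs(p[[free_param]]))
    pp <- pm <- p
    pp[[free_param]] <- p[[free_param]] + h
    pm[[free_param]] <- max(0, p[[free_param]] - h)
    g <- (rhs_eval(state, pp, variant) - rhs_eval(state, pm, variant)) /
      (pp[[free_param]] - pm[[free_param]])
  }
  g
}
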