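# Pseudo-arclength continuation of equilibrium branches, saddle-node
# (fold) detection and refinement via a bordered extended system, and the
# quadratic fold normal-form coefficient.

# A continuation "system": closures over everything except (x, pval).
make_sys <- function(params, variant, free_param) {
  if (!free_param %in% PARAM_NAMES) {
    stop("unknown free parameter: ", free_param, call. = FALSE)
  }
  setp <- function(pval) { p <- params; p[[free_param]] <- pval; p }
  list(
    f  = function(x, pval) rhs_eval(x, setp(pval), variant),
    J  = function(x, pval) jac_eval(x, setp(pval), variant),
    gp = function(x, pval) param_deriv(x, setp(pval), variant, free_param),
    n  = length(state_names(variant))
  )
}

# Unit tangent of the branch at (x, pval) via a bordered solve against a
# reference tangent (orientation carried over from `ref`).
branch_tangent <- function(sys, x, pval, ref) {
  n <- sys$n
  A <- rbind(cbind(sys$J(x, pval), sys$gp(x, pval)), ref)
  tau <- tryCatch(solve(A, c(rep(0, n), 1)), error = function(e) NULL)
  if (is.null(tau)) return(NULL)
  tau / sqrt(sum(tau^2))
}

#' Trace an equilibrium branch by pseudo-arclength continuation
#'
#' Predictor--corrector continuation of `rhs = 0` against a free
#' parameter (`k_Bo`, lumen butyrate, or `k_bl`, lumen LPS), with
#' adaptive arclength step.  Folds are detected as sign changes of the
#' parameter component of the branch tangent, refined by a bordered
#' extended system ([refine_fold()]), and annotated with the quadratic
#' normal-form coefficient ([fold_normal_form()]).  If the first sweep
#' does not cover the requested range on all layers (the lumen-LPS
#' hysteresis is disconnected on `k_bl >= 0`), additional sweeps are
#' started from equilibria at the other end of the range.
#'
#' @param params a [gut_params()] vector.
#' @param variant model variant.
#' @param free_param `"k_Bo"` or `"k_bl"` (any constant is accepted; the
#'   parameter is clamped to nonnegative values).
#' @param range length-2 parameter range to cover.
#' @param step_init,step_min,step_max arclength step control.
#' @param max_points safety cap on accepted points per sweep.
#' @param orientation null-vector orientation for the normal form:
#'   `"stable"` orients q from the fold towards the adjacent stable
#'   layer (so `a < 0` certifies a stable flanking layer), `"positive_B"`
#'   gives q a positive last (butyrate) component.
#' @return list of class `"gut_branch"`: `points` (data frame with the
#'   parameter, state components, `stability`, `layer`, `sweep`),
#'   `folds` (list of `"gut_fold"`), `hopf` (data frame of imaginary-axis
#'   crossings away from folds, normally empty), plus metadata.
#' @examples
#' \donttest{
#' br <- trace_branch(gut_params(), "core", "k_Bo", c(10, 300))
#' sapply(br$folds, function(f) f$param_value)
#' }
#' @export
trace_branch <- function(params, variant = "core", free_param = "k_Bo",
                         range = c(10, 300), step_init = 0.5,
                         step_min = 1e-3, step_max = 5,
                         max_points = 8000,
                         orientation = c("stable", "positive_B")) {
  variant <- match_variant(variant)
  orientation <- match.arg(orientation)
  validate_params(params)
  if (length(range) != 2 || range[1] >= range[2]) {
    stop("range must be increasing", call. = FALSE)
  }
  if (range[1] < 0) stop("range must be nonnegative", call. = FALSE)
  sys <- make_sys(params, variant, free_param)
  n <- sys$n
  spec_small <- search_spec(n_grid = 3, K = 1e3)

  starts_cache <- new.env(parent = emptyenv())
  starts_at <- function(pval) {
    key <- format(pval, digits = 15)
    if (!is.null(starts_cache[[key]])) return(starts_cache[[key]])
    p <- params; p[[free_param]] <- pval
    fps <- find_fixed_points(p, variant, spec = spec_small)
    starts_cache[[key]] <- fps
    fps
  }

  sweep_points <- list()   # each: matrix [x..., pval, tau_p, n_unstable]
  all_pts <- function() do.call(rbind, sweep_points)

  # Is the equilibrium (x, pval) already on a traced layer?  Compares
  # against points with nearby parameter values; layers are well
  # separated in state space away from folds.
  on_existing <- function(x, pval) {
    pts <- all_pts()
    if (is.null(pts) || !nrow(pts)) return(FALSE)
    win <- max(2 * step_max, 0.02 * diff(range))
    near <- abs(pts[, n + 1] - pval) < win
    if (!any(near)) return(FALSE)
    any(apply(pts[near, seq_len(n), drop = FALSE], 1, function(r) {
      max(abs(r - x) / pmax(1, abs(r))) < 0.05
    }))
  }

  run_sweep <- function(x0, p0, dir) {
    tau <- branch_tangent(sys, x0, p0, c(rep(0, n), 1))
    if (is.null(tau)) return(NULL)
    if (sign(tau[n + 1]) != sign(dir)) tau <- -tau
    z <- c(x0, p0)
    h <- step_init
    rows <- matrix(NA_real_, max_points, n + 3)
    nev <- eigen(sys$J(x0, p0), only.values = TRUE)$values
    rows[1, ] <- c(z, tau[n + 1], sum(Re(nev) > 0))
    cnt <- 1L
    while (cnt < max_points) {
      zp <- z + h * tau
      ok <- FALSE
      for (it in 1:15) {
        x <- zp[seq_len(n)]; pv <- zp[n + 1]
        Fv <- c(sys$f(x, pv), sum(tau * (zp - z)) - h)
        if (max(abs(Fv)) < 1e-10) { ok <- TRUE; break }
        A <- rbind(cbind(sys$J(x, pv), sys$gp(x, pv)), tau)
        step <- tryCatch(solve(A, Fv), error = function(e) NULL)
        if (is.null(step) || any(!is.finite(step))) break
        zp <- zp - step
      }
      # reject corrector landings far from the predictor: they can skip
      # straight past a fold, leaving it undetected
      if (ok && sqrt(sum((zp - z)^2)) > 3 * h) ok <- FALSE
      if (!ok) {
        h <- h / 2
        if (h < step_min) break
        next
      }
      tnew <- branch_tangent(sys, zp[seq_len(n)], zp[n + 1], tau)
      if (is.null(tnew)) break
      if (sum(tnew * tau) < 0) tnew <- -tnew
      z <- zp; tau <- tnew
      cnt <- cnt + 1L
      nev <- eigen(sys$J(z[seq_len(n)], z[n + 1]), only.values = TRUE)$values
      rows[cnt, ] <- c(z, tau[n + 1], sum(Re(nev) > 0))
      h <- min(step_max, h * 1.4)
      pv <- z[n + 1]
      if (pv > range[2] + 2 * step_max || pv < max(0, range[1] - 2 * step_max))
        break
      if (pv < 1e-10 && tau[n + 1] < 0) break  # clamp at nonnegative params
    }
    rows[seq_len(cnt), , drop = FALSE]
  }

  # first sweep: from an equilibrium at the left end of the range, upward
  fps_left <- starts_at(range[1])
  if (!length(fps_left)) stop("no starting equilibrium at range[1]",
                              call. = FALSE)
  sw <- run_sweep(as.numeric(fps_left[[1]]$state), range[1], +1)
  if (!is.null(sw)) sweep_points[[1]] <- cbind(sw, 1)
  # coverage sweeps from both ends, for layers not yet visited
  sweep_id <- 1L
  for (end in c(range[2], range[1])) {
    for (fp in starts_at(end)) {
      x0 <- as.numeric(fp$state)
      if (on_existing(x0, end)) next
      sw <- run_sweep(x0, end, if (end == range[2]) -1 else +1)
      if (!is.null(sw)) {
        sweep_id <- sweep_id + 1L
        sweep_points[[length(sweep_points) + 1L]] <- cbind(sw, sweep_id)
      }
    }
  }

  pts <- all_pts()
  colnames(pts) <- c(state_names(variant), "param", "tau_p", "n_unstable",
                     "sweep")

  # fold detection per sweep: tangent parameter component changes sign
  folds <- list()
  hopf_rows <- list()
  for (sid in unique(pts[, "sweep"])) {
    sp <- pts[pts[, "sweep"] == sid, , drop = FALSE]
    if (nrow(sp) < 3) next
    tp <- sp[, "tau_p"]
    idx <- which(tp[-1] * tp[-length(tp)] < 0)
    for (i in idx) {
      guess_x <- (sp[i, seq_len(n)] + sp[i + 1, seq_len(n)]) / 2
      guess_p <- (sp[i, "param"] + sp[i + 1, "param"]) / 2
      fold <- tryCatch(
        refine_fold(guess_x, guess_p, params, variant, free_param),
        error = function(e) NULL)
      if (is.null(fold)) next
      if (fold$param_value < range[1] - 1e-6 ||
          fold$param_value > range[2] + 1e-6) next
      # orient q, then attach the normal-form coefficient
      q <- fold$q
      if (orientation == "stable") {
        side <- c(i, i + 1)[which(sp[c(i, i + 1), "n_unstable"] == 0)]
        if (length(side)) {
          secant <- sp[side[1], seq_len(n)] - fold$state
          if (sum(secant * q) < 0) q <- -q
        } else if (q[n] < 0) q <- -q
      } else {
        if (q[n] < 0) q <- -q
      }
      fold$q <- q
      fold <- fold_normal_form(fold, params, variant)
      dup <- any(vapply(folds, function(f0) {
        abs(f0$param_value - fold$param_value) <
          1e-4 * max(1, abs(fold$param_value))
      }, logical(1)))
      if (!dup) folds[[length(folds) + 1L]] <- fold
    }
    # Hopf monitoring: unstable-count jumps by 2 (a complex pair crossing
    # the imaginary axis) away from tangent sign changes
    du <- diff(sp[, "n_unstable"])
    for (i in which(abs(du) >= 2)) {
      hopf_rows[[length(hopf_rows) + 1L]] <- data.frame(
        sweep = sid, param = sp[i + 1, "param"])
    }
  }
  folds <- folds[order(vapply(folds, function(f) f$param_value, numeric(1)))]

  keep <- pts[, "param"] >= range[1] - 1e-9 & pts[, "param"] <= range[2] + 1e-9
  pts <- pts[keep, , drop = FALSE]
  points <- as.data.frame(pts[, c(n + 1, seq_len(n)), drop = FALSE])
  names(points) <- c("param", state_names(variant))
  points$stability <- ifelse(pts[, "n_unstable"] == 0, "stable", "unstable")
  points$sweep <- as.integer(pts[, "sweep"])
  points$layer <- assign_layers(points, variant, folds)

  structure(list(
    free_param = free_param, range = range, points = points, folds = folds,
    hopf = if (length(hopf_rows)) do.call(rbind, hopf_rows) else
      data.frame(sweep = integer(0), param = numeric(0)),
    params = params, variant = variant, orientation = orientation
  ), class = "gut_branch")
}

# Unstable points form the middle layer.  Stable points are banded by
# the folds' butyrate coordinates (the folds are the layer boundaries);
# the lowest band is "lower", the highest "upper".  Banding is immune to
# overlapping continuation sweeps.
assign_layers <- function(points, variant, folds) {
  nm <- state_names(variant)
  last <- nm[length(nm)]
  layer <- rep("middle", nrow(points))
  stable <- points$stability == "stable"
  if (!length(folds)) {
    layer[stable] <- "stable"
    return(layer)
  }
  foldB <- sort(vapply(folds, function(f) f$state[[last]], numeric(1)))
  band <- findInterval(points[[last]], foldB)
  bands <- sort(unique(band[stable]))
  for (k in seq_along(bands)) {
    lab <- if (length(bands) == 1) {
      "stable"
    } else if (k == 1) "lower" else if (k == length(bands)) "upper" else
      paste0("stable", k)
    layer[stable & band == bands[k]] <- lab
  }
  layer
}

#' Refine a saddle-node (fold) point
#'
#' Newton iteration on the bordered extended system
#' `{rhs = 0, J q = 0, <q,q> = 1}` in the unknowns (state, free
#' parameter, right null vector q), starting from an approximate fold
#' location.  The left null vector p is computed from the transposed
#' Jacobian and normalised to `<p,q> = 1`.
#'
#' @param state,param_value approximate fold state and parameter.
#' @param params,variant,free_param as in [trace_branch()].
#' @param tol residual tolerance of the extended system.
#' @return list of class `"gut_fold"` with `param_value`, `state`, `q`,
#'   `p_vec`, `eigenvalues`, `residual`, `free_param`, `variant`.
#' @export
refine_fold <- function(state, param_value, params, variant = "core",
                        free_param = "k_Bo", tol = 1e-10) {
  variant <- match_variant(variant)
  sys <- make_sys(params, variant, free_param)
  res <- refine_fold_sys(sys, state, param_value, tol)
  structure(list(
    free_param = free_param, param_value = res$pv,
    state = stats::setNames(res$x, state_names(variant)),
    q = res$q, p_vec = res$p_vec, eigenvalues = res$eigenvalues,
    residual = res$residual, variant = variant
  ), class = "gut_fold")
}

# Generic bordered-system fold refinement, independent of the model.
# `sys` is a list with f(x, pval), J(x, pval), gp(x, pval) and n.
refine_fold_sys <- function(sys, state, param_value, tol = 1e-10) {
  n <- sys$n
  x <- as.numeric(state)
  param_value <- as.numeric(param_value)
  ev <- eigen(sys$J(x, param_value))
  i0 <- which.min(abs(Re(ev$values)))
  q <- Re(ev$vectors[, i0])
  q <- q / sqrt(sum(q^2))
  z <- c(x, param_value, q)
  Fv <- NULL
  for (it in 1:60) {
    x <- z[seq_len(n)]; pv <- z[n + 1]; q <- z[(n + 2):(2 * n + 1)]
    J <- sys$J(x, pv)
    Fv <- c(sys$f(x, pv), as.numeric(J %*% q), sum(q^2) - 1)
    if (max(abs(Fv)) < tol) break
    hh <- 1e-6
    dJq <- matrix(0, n, n)
    for (k in seq_len(n)) {
      e <- numeric(n); e[k] <- hh
      dJq[, k] <- (sys$J(x + e, pv) %*% q - sys$J(x - e, pv) %*% q) / (2 * hh)
    }
    dJq_p <- (sys$J(x, pv + hh) %*% q - sys$J(x, pv - hh) %*% q) / (2 * hh)
    A <- rbind(
      cbind(J, sys$gp(x, pv), matrix(0, n, n)),
      cbind(dJq, dJq_p, J),
      c(rep(0, n), 0, 2 * q))
    step <- tryCatch(solve(A, Fv), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      stop("fold refinement: singular extended system", call. = FALSE)
    }
    z <- z - step
  }
  if (max(abs(Fv)) >= 1e-8) {
    stop("fold refinement did not converge (residual ",
         signif(max(abs(Fv)), 3), ")", call. = FALSE)
  }
  x <- z[seq_len(n)]; pv <- z[n + 1]; q <- z[(n + 2):(2 * n + 1)]
  J <- sys$J(x, pv)
  evs <- eigen(J, only.values = TRUE)$values
  # left null vector, normalised <p,q> = 1
  el <- eigen(t(J))
  j0 <- which.min(abs(Re(el$values)))
  pvec <- Re(el$vectors[, j0])
  pvec <- pvec / sum(pvec * q)
  list(x = x, pv = pv, q = q, p_vec = pvec, eigenvalues = evs,
       residual = max(abs(Fv)))
}

# a = 1/2 <p, B2(q,q)> with B2 a central second difference along q.
normal_form_sys <- function(sys, x, pv, q, pvec, h = 1e-4) {
  B2qq <- (sys$f(x + h * q, pv) + sys$f(x - h * q, pv) -
             2 * sys$f(x, pv)) / h^2
  0.5 * sum(pvec * B2qq)
}

#' Quadratic normal-form coefficient at a fold
#'
#' Computes `a = 1/2 <p, B2(q, q)>`, where `B2` is the bilinear second
#' derivative of the right-hand side at the fold (evaluated as a central
#' second difference along q), with `<q,q> = 1` and `<p,q> = 1`.  The
#' sign of `a` flips with `q -> -q`; the orientation stored in the fold
#' (see [trace_branch()]) is used as-is.  On the reduced one-dimensional
#' dynamics `dw/dt = a w^2 + O(3)` the coefficient governs which side of
#' the fold carries equilibria and their stability.
#'
#' @param fold a `"gut_fold"` from [refine_fold()] (with `q` oriented).
#' @param params,variant as in [trace_branch()].
#' @param h second-difference step.
#' @return the fold with element `a` attached.
#' @export
fold_normal_form <- function(fold, params, variant = fold$variant,
                             h = 1e-4) {
  variant <- match_variant(variant)
  sys <- make_sys(params, variant, fold$free_param)
  x <- as.numeric(fold$state); pv <- fold$param_value
  q <- fold$q
  # re-normalise p to the (possibly re-oriented) q: <p, q> = 1
  pvec <- fold$p_vec / sum(fold$p_vec * q)
  a <- normal_form_sys(sys, x, pv, q, pvec, h)
  if (abs(a) < 1e-12) {
    warning("degenerate fold: |a| < 1e-12", call. = FALSE)
  }
  fold$a <- a
  fold
}

#' @export
print.gut_fold <- function(x, ...) {
  cat(sprintf("<fold in %s at %s = %.6f>\n", x$variant, x$free_param,
              x$param_value))
  print(signif(x$state, 6))
  if (!is.null(x$a)) cat("normal-form a =", signif(x$a, 7), "\n")
  invisible(x)
}

#' @export
print.gut_branch <- function(x, ...) {
  cat(sprintf("<equilibrium branch vs %s on [%g, %g]: %d points, %d fold(s)>\n",
              x$free_param, x$range[1], x$range[2], nrow(x$points),
              length(x$folds)))
  for (f in x$folds) {
    cat(sprintf("  fold at %s = %.4f  (a = %s)\n", x$free_param,
                f$param_value,
                if (is.null(f$a)) "?" else signif(f$a, 7)))
  }
  invisible(x)
}

#' The bistable parameter interval of a branch
#'
#' For a branch with two folds, the open interval between their
#' parameter values, inside which three equilibria coexist.
#'
#' @param branch a `"gut_branch"`.
#' @return length-2 numeric (sorted fold parameter values).
#' @export
bistable_interval <- function(branch) {
  if (length(branch$folds) != 2) {
    stop("branch has ", length(branch$folds), " fold(s), need 2",
         call. = FALSE)
  }
  sort(vapply(branch$folds, function(f) f$param_value, numeric(1)))
}

#' Write a branch as CSV / folds as JSON
#'
#' Branch CSV columns: `param` (renamed to the free parameter), state
#' components, `stability`, `layer`, `sweep`.  Fold JSON: per fold the
#' parameter value, state, normal-form coefficient and residual.
#'
#' @param branch a `"gut_branch"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_branch_csv <- function(branch, path) {
  df <- branch$points
  names(df)[1] <- branch$free_param
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_branch_csv
#' @export
write_folds_json <- function(branch, path) {
  folds <- lapply(branch$folds, function(f) {
    list(free_param = f$free_param, param_value = f$param_value,
         state = as.list(f$state), a = f$a, residual = f$residual)
  })
  jsonlite::write_json(folds, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
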