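# Change-of-variables transform of a lumen-butyrate density through the
# stable layers of the hysteresis: q(y) = w(x) p(x) / |h'(x)| at
# y = h(x), where h maps lumen butyrate (the free parameter) to the
# equilibrium within-cell butyrate on a stable layer.

#' Input density of lumen butyrate
#'
#' A Gaussian density for the lumen butyrate level `x = k_Bo`, truncated
#' to a nonnegative support interval and renormalised on its evaluation
#' grid (so it integrates to 1 there).
#'
#' @param mean,sd Gaussian location and spread (sd > 0).
#' @param lo,hi support bounds; defaults to `mean +/- 5 sd`, clipped at 0.
#' @param n_grid evaluation grid size.
#' @return list of class `"gut_input_density"` with `grid`, `dens`
#'   (values on the grid), and `pdf` (vectorised density function, 0
#'   outside the support).
#' @examples
#' p <- input_density(130, 40)
#' sum(diff(p$grid) * (head(p$dens, -1) + tail(p$dens, -1)) / 2)  # ~1
#' @export
input_density <- function(mean = 130, sd = 40, lo = NULL, hi = NULL,
                          n_grid = 2001) {
  if (sd <= 0) stop("sd must be positive", call. = FALSE)
  if (is.null(lo)) lo <- max(0, mean - 5 * sd)
  if (is.null(hi)) hi <- mean + 5 * sd
  if (hi <= lo) stop("need hi > lo", call. = FALSE)
  grid <- seq(lo, hi, length.out = n_grid)
  Z <- stats::pnorm(hi, mean, sd) - stats::pnorm(lo, mean, sd)
  dens <- stats::dnorm(grid, mean, sd) / Z
  pdf <- function(x) {
    ifelse(x >= lo & x <= hi, stats::dnorm(x, mean, sd) / Z, 0)
  }
  structure(list(family = "gaussian", mean = mean, sd = sd, lo = lo,
                 hi = hi, grid = grid, dens = dens, pdf = pdf, Z = Z),
            class = "gut_input_density")
}

trapz <- function(x, y) {
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

# exact probability mass of the truncated Gaussian on [a, b]
input_mass <- function(p, a, b) {
  a <- max(a, p$lo); b <- min(b, p$hi)
  if (b <= a) return(0)
  (stats::pnorm(b, p$mean, p$sd) - stats::pnorm(a, p$mean, p$sd)) / p$Z
}

# Stable-layer geometry of a branch: per layer a monotone spline
# x -> B and its inverse, plus the covered parameter domain.
branch_layers <- function(branch) {
  nm <- state_names(branch$variant)
  last <- nm[length(nm)]
  labs <- setdiff(unique(branch$points$layer), "middle")
  out <- list()
  for (lab in labs) {
    pts <- branch$points[branch$points$layer == lab, ]
    pts <- pts[order(pts$param), ]
    x <- pts$param
    y <- pts[[last]]
    # collapse near-duplicate parameter values (overlapping sweeps)
    keep <- c(TRUE, diff(x) > 1e-8 * max(1, max(abs(x))))
    x <- x[keep]; y <- y[keep]
    if (length(x) < 4) next
    dy <- diff(y)
    tol <- 1e-7 * max(abs(y))
    if (!(all(dy >= -tol) || all(dy <= tol))) {
      stop("layer '", lab, "' is not monotone in ", last,
           "; cannot invert h", call. = FALSE)
    }
    increasing <- mean(dy) >= 0
    # enforce strict monotonicity in y for the inverse spline
    keep <- if (increasing) c(TRUE, diff(cummax(y)) > 0) else
      c(TRUE, diff(cummin(y)) < 0)
    x <- x[keep]; y <- y[keep]
    h <- stats::splinefun(x, y, method = "monoH.FC")
    hinv <- if (increasing) {
      stats::splinefun(y, x, method = "monoH.FC")
    } else {
      stats::splinefun(rev(y), rev(x), method = "monoH.FC")
    }
    out[[lab]] <- list(label = lab, domain = range(x), y_range = range(y),
                       h = h, hinv = hinv, increasing = increasing)
  }
  if (!length(out)) stop("branch has no stable layer", call. = FALSE)
  out
}

# Per-x weight of a stable layer.  "fair": the supplied weight wherever
# the layer exists (the draws whose layer is absent at x are lost, as in
# the fair-coin sampling picture).  "conditional": weights renormalised
# over the layers available at x, so all mass outside the exclusion
# zones is retained.
layer_weight_fun <- function(layers, weights, coverage) {
  labs <- names(layers)
  avail <- function(lab, x) {
    x >= layers[[lab]]$domain[1] & x <= layers[[lab]]$domain[2]
  }
  function(x, lab) {
    a <- avail(lab, x)
    if (length(labs) == 1) return(as.numeric(a))
    if (coverage == "fair") return(ifelse(a, weights[[lab]], 0))
    wsum <- rep(0, length(x))
    for (ly in labs) wsum <- wsum + ifelse(avail(ly, x), weights[[ly]], 0)
    ifelse(a & wsum > 0, weights[[lab]] / wsum, 0)
  }
}

# Exclusion windows are per layer: a fold cuts only the layer that
# terminates there (where h' diverges); other layers pass through that
# parameter region smoothly and keep their mass.
fold_exclusion_zones <- function(branch, fold_exclusion, layers) {
  zones <- lapply(layers, function(ly) matrix(numeric(0), ncol = 2))
  for (f in branch$folds) {
    xf <- f$param_value
    half <- fold_exclusion * xf
    for (lab in names(layers)) {
      if (min(abs(xf - layers[[lab]]$domain)) <= half + 1e-6) {
        zones[[lab]] <- rbind(zones[[lab]], c(xf - half, xf + half))
      }
    }
  }
  zones
}

in_zones <- function(x, zones) {
  if (!nrow(zones)) return(rep(FALSE, length(x)))
  out <- rep(FALSE, length(x))
  for (k in seq_len(nrow(zones))) {
    out <- out | (x > zones[k, 1] & x < zones[k, 2])
  }
  out
}

#' Transform a lumen-butyrate density through the hysteresis
#'
#' Implements the change of variables `q(y) = w(x) p(x) / |h'(x)|` with
#' `y = h(x)` separately for each stable layer of the branch (the middle
#' layer is unstable and carries no probability), where `h` is a
#' monotone cubic spline through the layer's branch points.  Grid points
#' within a relative `fold_exclusion` window of a fold parameter value
#' are dropped: there `h'` diverges and the state jumps to the other
#' layer rather than settling.
#'
#' Two readings of the layer weights are provided.  With
#' `coverage = "fair"` (the default) the layers carry the fixed
#' `weights` over their whole domains -- each system picks a layer by an
#' independent fair coin, and draws whose layer does not exist at their
#' lumen level are lost.  With `coverage = "conditional"` the weights
#' are renormalised over the layers that exist at each lumen level, so
#' outside the bistable window all mass follows the only remaining
#' layer and the transformed mass equals the input mass minus the
#' fold-neighbourhood exclusions; the price is a density step where a
#' layer's domain ends.
#'
#' @param branch a `"gut_branch"` (folds computed) or any branch whose
#'   stable layers are monotone in the free parameter.
#' @param p an [input_density()].
#' @param weights named weights for the stable layers (default equal
#'   halves for `lower`/`upper`); nonnegative, summing to 1.
#' @param fold_exclusion relative half-width of the excluded window
#'   around each fold parameter value.
#' @param coverage `"fair"` or `"conditional"` (see above).
#' @param n_y size of the uniform output grid in y.
#' @return list of class `"gut_density_transform"`: `y` (grid),
#'   `q_lower`, `q_upper`, `q_combined` (densities; absent layers are
#'   zero), `layers` (per-layer x/y/q tables), `retained_mass` (exact
#'   mass carried by the transformed density), `excluded_mass` (input
#'   mass inside the fold windows), `mass_error` (quadrature check of
#'   the combined density against `retained_mass`), `modes` (y locations
#'   of local maxima of the combined density), plus the inputs.
#' @export
transform_density <- function(branch, p,
                              weights = c(lower = 0.5, upper = 0.5),
                              fold_exclusion = 0.01,
                              coverage = c("fair", "conditional"),
                              n_y = 2048) {
  coverage <- match.arg(coverage)
  if (!inherits(p, "gut_input_density")) {
    stop("p must be an input_density()", call. = FALSE)
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop("weights must be nonnegative and sum to 1", call. = FALSE)
  }
  layers <- branch_layers(branch)
  if (length(layers) > 1 && !all(names(layers) %in% names(weights))) {
    stop("weights must name the stable layers: ",
         paste(names(layers), collapse = ", "), call. = FALSE)
  }
  wfun <- layer_weight_fun(layers, weights, coverage)
  zones <- fold_exclusion_zones(branch, fold_exclusion, layers)

  # Per-layer evaluation is done on the y side through the inverse map
  # x = g(y): near a fold h'(x) diverges while g'(y) -> 0, so the
  # quotient p/h' = p * |g'| stays well conditioned.
  layer_tabs <- list()
  for (lab in names(layers)) {
    ly <- layers[[lab]]
    xlo <- max(ly$domain[1], p$lo); xhi <- min(ly$domain[2], p$hi)
    if (xhi <= xlo) next
    ends <- sort(c(ly$h(xlo), ly$h(xhi)))
    yy <- seq(ends[1], ends[2], length.out = n_y)
    x <- pmin(pmax(ly$hinv(yy), ly$domain[1]), ly$domain[2])
    gp <- ly$hinv(yy, deriv = 1)
    excl <- in_zones(x, zones[[lab]])
    bad <- !excl & (!is.finite(gp) | abs(gp) > 1e12)
    if (any(bad)) {
      stop("derivative underflow: |h'| < 1e-12 outside exclusion zones",
           call. = FALSE)
    }
    qy <- wfun(x, lab) * p$pdf(x) * abs(gp)
    qy[excl] <- 0
    layer_tabs[[lab]] <- data.frame(x = x, y = yy, q = qy)
  }
  if (!length(layer_tabs)) stop("density support misses every layer",
                                call. = FALSE)

  y_all <- unlist(lapply(layer_tabs, function(t) t$y))
  y <- seq(min(y_all), max(y_all), length.out = n_y)
  q_of <- function(lab) {
    t <- layer_tabs[[lab]]
    if (is.null(t)) return(numeric(n_y))
    out <- rep(0, n_y)
    inside <- y >= min(t$y) & y <= max(t$y)
    out[inside] <- stats::approx(t$y, t$q, xout = y[inside], rule = 2)$y
    out
  }
  q_by_layer <- lapply(names(layer_tabs), q_of)
  names(q_by_layer) <- names(layer_tabs)
  q_combined <- Reduce(`+`, q_by_layer)

  # exact mass accounting on the x side (truncated-Gaussian CDF over the
  # piecewise-constant weight segments); excluded = mass dropped inside
  # the fold windows of the layer it would have followed
  bps <- sort(unique(c(p$lo, p$hi,
                       unlist(lapply(zones, as.numeric)),
                       unlist(lapply(layers, `[[`, "domain")))))
  retained <- 0; excluded <- 0
  for (lab in names(layers)) {
    for (k in seq_len(length(bps) - 1)) {
      a <- bps[k]; b <- bps[k + 1]
      mid <- (a + b) / 2
      m <- wfun(mid, lab) * input_mass(p, a, b)
      if (in_zones(mid, zones[[lab]])) excluded <- excluded + m else
        retained <- retained + m
    }
  }
  excluded_mass <- excluded
  grid_mass <- sum(vapply(layer_tabs, function(t) trapz(t$y, t$q),
                          numeric(1)))

  structure(list(
    y = y,
    q_lower = if (!is.null(q_by_layer$lower)) q_by_layer$lower else
      rep(0, n_y),
    q_upper = if (!is.null(q_by_layer$upper)) q_by_layer$upper else
      rep(0, n_y),
    q_combined = q_combined,
    layers = layer_tabs,
    retained_mass = retained,
    excluded_mass = excluded_mass,
    mass_error = abs(grid_mass - retained),
    modes = find_modes(y, q_combined),
    weights = weights, fold_exclusion = fold_exclusion,
    coverage = coverage,
    input = p, free_param = branch$free_param
  ), class = "gut_density_transform")
}

# Local maxima of a sampled density, ignoring numerical ripple below
# 1e-3 of the peak.
find_modes <- function(y, q) {
  thr <- 1e-3 * max(q)
  s <- sign(diff(q))
  # carry flat segments forward so plateaus count once
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  idx <- which(s[-length(s)] > 0 & s[-1] < 0) + 1
  idx <- idx[q[idx] > thr]
  y[idx]
}

#' @export
print.gut_density_transform <- function(x, ...) {
  cat("<density transform through the hysteresis (", x$coverage,
      " coverage)>\n", sep = "")
  cat("  modes at y =", paste(signif(x$modes, 4), collapse = ", "), "\n")
  cat(sprintf("  transformed mass %.4f (excluded near folds %.4f)\n",
              x$retained_mass, x$excluded_mass))
  invisible(x)
}

#' Monte-Carlo sample of the within-cell butyrate distribution
#'
#' Independent check of [transform_density()]: draws lumen butyrate
#' values from the input density (inverse-CDF of the truncated
#' Gaussian), drops draws inside the fold-exclusion windows, picks a
#' stable layer by the transform's weights (draws whose chosen layer
#' does not exist at their lumen level are dropped under `"fair"`
#' coverage, renormalised under `"conditional"`), and maps each kept
#' draw through that layer's h.  Uses the current RNG state.
#'
#' @param transform a `"gut_density_transform"`.
#' @param branch the branch the transform was built from.
#' @param n number of draws.
#' @return numeric vector of within-cell butyrate values (length <= n).
#' @export
sample_transformed <- function(transform, branch, n = 1e5) {
  p <- transform$input
  layers <- branch_layers(branch)
  wfun <- layer_weight_fun(layers, transform$weights, transform$coverage)
  zones <- fold_exclusion_zones(branch, transform$fold_exclusion, layers)
  u <- stats::runif(n, stats::pnorm(p$lo, p$mean, p$sd),
                    stats::pnorm(p$hi, p$mean, p$sd))
  x <- stats::qnorm(u, p$mean, p$sd)
  labs <- names(layers)
  y <- rep(NA_real_, length(x))
  done <- rep(FALSE, length(x))
  pick <- stats::runif(length(x))
  cumw <- rep(0, length(x))
  for (lab in labs) {
    w <- wfun(x, lab)
    sel <- !done & pick < cumw + w & w > 0
    done <- done | sel
    # draws landing in the chosen layer's fold window are dropped
    keep <- sel & !in_zones(x, zones[[lab]])
    y[keep] <- layers[[lab]]$h(x[keep])
    cumw <- cumw + w
  }
  y[!is.na(y)]
}

#' Total-variation distance between samples and a transformed density
#'
#' Bins the Monte-Carlo draws on the transform's y-range and compares
#' bin masses with the integrated density (both normalised), returning
#' `0.5 * sum |p_bin - q_bin|`.
#'
#' @param y_samples draws from [sample_transformed()].
#' @param transform a `"gut_density_transform"`.
#' @param n_bins histogram resolution.
#' @return total-variation distance in `[0, 1]`.
#' @export
tv_distance <- function(y_samples, transform, n_bins = 60) {
  lo <- min(transform$y); hi <- max(transform$y)
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  y_samples <- pmin(pmax(y_samples, lo), hi)
  emp <- tabulate(findInterval(y_samples, breaks, all.inside = TRUE),
                  nbins = n_bins)
  emp <- emp / sum(emp)
  qb <- numeric(n_bins)
  for (k in seq_len(n_bins)) {
    sel <- transform$y >= breaks[k] & transform$y <= breaks[k + 1]
    if (sum(sel) >= 2) {
      qb[k] <- trapz(transform$y[sel], transform$q_combined[sel])
    }
  }
  qb <- qb / sum(qb)
  0.5 * sum(abs(emp - qb))
}

#' Write a density transform as CSV / summary JSON
#'
#' CSV columns: `y`, `q_upper`, `q_lower`, `q_combined`.  The JSON
#' summary holds mode locations, transformed and excluded mass, and the
#' weights.
#'
#' @param transform a `"gut_density_transform"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_density_csv <- function(transform, path) {
  utils::write.csv(data.frame(
    y = transform$y, q_upper = transform$q_upper,
    q_lower = transform$q_lower, q_combined = transform$q_combined),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_density_csv
#' @export
write_density_summary_json <- function(transform, path) {
  jsonlite::write_json(list(
    modes = transform$modes,
    retained_mass = transform$retained_mass,
    excluded_mass = transform$excluded_mass,
    coverage = transform$coverage,
    weights = as.list(transform$weights),
    fold_exclusion = transform$fold_exclusion
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
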