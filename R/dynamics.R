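# Stiff time integration under constant or pulsed lumen-butyrate drive,
# and endpoint classification against candidate attractors.

#' Piecewise-constant lumen-butyrate pulse protocol
#'
#' The lumen butyrate level `k_Bo` is held at `baseline` except during
#' the given segments, each of which overrides it on `[t_start, t_end)`.
#' Segments must be ordered and non-overlapping with nonnegative levels.
#'
#' @param baseline baseline `k_Bo` value.
#' @param segments data frame with columns `t_start`, `t_end`, `k_Bo`
#'   (or `NULL` for a constant drive).
#' @return list of class `"gut_protocol"`.
#' @examples
#' pulse_protocol(130, data.frame(
#'   t_start = c(50, 200), t_end = c(170, 270), k_Bo = c(200, 50)))
#' @export
pulse_protocol <- function(baseline, segments = NULL) {
  if (baseline < 0) stop("baseline k_Bo must be nonnegative", call. = FALSE)
  if (is.null(segments)) {
    segments <- data.frame(t_start = numeric(0), t_end = numeric(0),
                           k_Bo = numeric(0))
  }
  need <- c("t_start", "t_end", "k_Bo")
  if (!all(need %in% names(segments))) {
    stop("segments need columns t_start, t_end, k_Bo", call. = FALSE)
  }
  segments <- segments[order(segments$t_start), need, drop = FALSE]
  if (any(segments$t_end <= segments$t_start)) {
    stop("each segment needs t_start < t_end", call. = FALSE)
  }
  if (any(segments$k_Bo < 0)) {
    stop("segment k_Bo values must be nonnegative", call. = FALSE)
  }
  if (nrow(segments) > 1 &&
      any(segments$t_start[-1] < segments$t_end[-nrow(segments)])) {
    stop("protocol segments overlap", call. = FALSE)
  }
  structure(list(baseline = baseline, segments = segments),
            class = "gut_protocol")
}

protocol_value <- function(protocol, t) {
  v <- rep(protocol$baseline, length(t))
  for (i in seq_len(nrow(protocol$segments))) {
    seg <- protocol$segments[i, ]
    v[t >= seg$t_start & t < seg$t_end] <- seg$k_Bo
  }
  v
}

# Breakpoints of the drive inside [t0, t1]
protocol_breaks <- function(protocol, t0, t1) {
  b <- sort(unique(c(protocol$segments$t_start, protocol$segments$t_end)))
  b[b > t0 & b < t1]
}

#' Integrate the model
#'
#' Stiff integration (deSolve `lsoda` with the analytic Jacobian) of the
#' selected variant over `t_span`, optionally driven by a piecewise
#' constant lumen-butyrate [pulse_protocol()].  Integration is restarted
#' at every drive discontinuity so pulse edges are hard edges, not
#' smoothed over by step control.
#'
#' @param initial initial state (see [gut_rhs()] for the layout).
#' @param params,variant as in [gut_rhs()].
#' @param t_span length-2 numeric, start and end time.
#' @param protocol a [pulse_protocol()] or `NULL` (constant `k_Bo` from
#'   `params`).
#' @param dt reporting grid spacing (dense output; internal steps are
#'   adaptive).
#' @param rtol,atol solver tolerances.
#' @return data frame of class `"gut_trajectory"` with columns `time`,
#'   the state components, and `k_Bo_applied`.
#' @examples
#' \donttest{
#' p <- gut_params()
#' tr <- simulate_model(c(0.18, 1.8, 20, 0.35, 6), p, "core", c(0, 50))
#' tail(tr, 2)
#' }
#' @export
simulate_model <- function(initial, params, variant = "core",
                           t_span = c(0, 100), protocol = NULL,
                           dt = 1, rtol = 1e-8, atol = 1e-10) {
  variant <- match_variant(variant)
  validate_params(params)
  initial <- as.numeric(initial)
  check_state(initial, variant, tol = 1e-12)
  if (length(t_span) != 2 || t_span[2] < t_span[1]) {
    stop("t_span must be (t0, t1) with t1 >= t0", call. = FALSE)
  }
  nm <- state_names(variant)
  if (is.null(protocol)) {
    protocol <- pulse_protocol(params[["k_Bo"]])
  }
  if (!inherits(protocol, "gut_protocol")) {
    stop("protocol must be a pulse_protocol()", call. = FALSE)
  }
  if (nrow(protocol$segments) &&
      (min(protocol$segments$t_start) < t_span[1] ||
       max(protocol$segments$t_end) > t_span[2])) {
    stop("protocol segments must lie inside t_span", call. = FALSE)
  }
  if (t_span[1] == t_span[2]) {
    out <- data.frame(time = t_span[1], t(initial),
                      k_Bo_applied = protocol_value(protocol, t_span[1]))
    names(out) <- c("time", nm, "k_Bo_applied")
    class(out) <- c("gut_trajectory", "data.frame")
    return(out)
  }
  edges <- c(t_span[1], protocol_breaks(protocol, t_span[1], t_span[2]),
             t_span[2])
  rows <- list()
  x <- initial
  for (k in seq_len(length(edges) - 1)) {
    a <- edges[k]; b <- edges[k + 1]
    kBo <- protocol_value(protocol, a)
    pseg <- params
    pseg[["k_Bo"]] <- kBo
    times <- unique(c(seq(a, b, by = dt), b))
    sol <- deSolve::lsoda(
      y = x, times = times,
      func = function(t, y, parms) list(rhs_eval(y, parms, variant)),
      parms = pseg,
      jacfunc = function(t, y, parms) jac_eval(y, parms, variant),
      jactype = "fullusr", rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) {
      stop("stiff integrator failed on segment [", a, ", ", b, "]",
           call. = FALSE)
    }
    seg_df <- as.data.frame(sol)
    names(seg_df) <- c("time", nm)
    seg_df$k_Bo_applied <- kBo
    # each edge row is kept once, labelled with the incoming drive value
    if (k < length(edges) - 1) seg_df <- seg_df[-nrow(seg_df), , drop = FALSE]
    rows[[k]] <- seg_df
    x <- as.numeric(sol[nrow(sol), -1])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("gut_trajectory", "data.frame")
  out
}

#' Classify the endpoint of a trajectory against candidate attractors
#'
#' Compares the final state with each candidate equilibrium using a
#' per-component relative tolerance with an absolute floor (the
#' non-inflamed N is ~2e-5, where a pure relative test would be
#' meaninglessly strict).
#'
#' @param traj a [simulate_model()] trajectory.
#' @param candidates a `"gut_fixed_points"` list, or list of state
#'   vectors.
#' @param tol relative tolerance per component.
#' @param abs_floor absolute tolerance floor.
#' @return index (integer) of the matching candidate, or
#'   `"unresolved"` if none matches.
#' @export
classify_endpoint <- function(traj, candidates, tol = 1e-2,
                              abs_floor = 1e-6) {
  if (!length(candidates)) stop("candidates must be nonempty", call. = FALSE)
  states <- lapply(candidates, function(c) {
    if (inherits(c, "gut_fixed_point")) as.numeric(c$state) else as.numeric(c)
  })
  nstate <- length(states[[1]])
  final <- as.numeric(traj[nrow(traj), 1 + seq_len(nstate)])
  ok <- vapply(states, function(s) {
    all(abs(final - s) <= tol * abs(s) + abs_floor)
  }, logical(1))
  if (!any(ok)) return("unresolved")
  dist <- vapply(states, function(s) {
    max(abs(final - s) / pmax(abs(s), abs_floor))
  }, numeric(1))
  dist[!ok] <- Inf
  which.min(dist)
}

#' Write / read a trajectory as CSV
#'
#' Columns: `time`, state components, `k_Bo_applied`.
#'
#' @param traj a trajectory data frame.
#' @param path file path.
#' @return `path` (writer) / the trajectory (reader), invisibly visible.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("gut_trajectory", "data.frame")
  out
}
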