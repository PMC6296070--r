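# Structured configuration, JSON writers/readers, the verification
# suite, and the end-to-end driver that regenerates every analysis
# artifact of the reference parameterisation.

CONFIG_KEYS <- c("experiment", "variant", "preset", "overrides", "seed",
                 "outdir", "simulate", "continue", "transform")
EXPERIMENTS <- c("simulate", "equilibria", "continue", "transform",
                 "verify", "reproduce")

#' Load a run configuration
#'
#' Reads a YAML run configuration, applies preset defaults before
#' overrides, and validates every key.  Top-level keys: `experiment`
#' (one of simulate, equilibria, continue, transform, verify,
#' reproduce), `variant`, `preset`, `overrides` (named `k_*` values),
#' `seed`, `outdir`, and per-experiment blocks `simulate`
#' (`t_span`, `protocol` with `baseline` and `segments`), `continue`
#' (`free_param`, `from`, `to`), `transform` (`mean`, `sd`,
#' `fold_exclusion`).  Unknown keys are rejected by name.
#'
#' @param path YAML file.
#' @return validated list of class `"gut_config"` with resolved `params`.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a key-value mapping", call. = FALSE)
  bad <- setdiff(names(cfg), CONFIG_KEYS)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cfg$experiment)) stop("config needs 'experiment'",
                                    call. = FALSE)
  cfg$experiment <- match.arg(cfg$experiment, EXPERIMENTS)
  cfg$variant <- match_variant(if (is.null(cfg$variant)) "core" else
    cfg$variant)
  if (is.null(cfg$preset)) cfg$preset <- "reference"
  overrides <- if (is.null(cfg$overrides)) list() else cfg$overrides
  if (length(overrides)) {
    bad <- setdiff(names(overrides), PARAM_NAMES)
    if (length(bad)) {
      stop("overrides name unknown parameter(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  cfg$params <- do.call(gut_params,
                        c(overrides, list(preset = cfg$preset)))
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$outdir)) cfg$outdir <- "."
  structure(cfg, class = "gut_config")
}

#' Execute a run configuration
#'
#' Dispatches a [load_config()] object to the corresponding analysis and
#' writes its artifacts into `cfg$outdir`.
#'
#' @param cfg a `"gut_config"`.
#' @return the computed object (trajectory, equilibria, branch,
#'   transform, verification report, or full report), invisibly.
#' @export
run_config <- function(cfg) {
  if (!inherits(cfg, "gut_config")) stop("cfg must come from load_config()",
                                         call. = FALSE)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  out <- switch(cfg$experiment,
    equilibria = {
      fps <- find_fixed_points(cfg$params, cfg$variant)
      write_fixed_points_json(fps, file.path(cfg$outdir, "equilibria.json"))
      fps
    },
    simulate = {
      blk <- cfg$simulate
      t_span <- if (is.null(blk$t_span)) c(0, 350) else as.numeric(blk$t_span)
      proto <- if (is.null(blk$protocol)) NULL else {
        segs <- if (is.null(blk$protocol$segments)) NULL else
          do.call(rbind, lapply(blk$protocol$segments, as.data.frame))
        pulse_protocol(blk$protocol$baseline, segs)
      }
      init <- if (is.null(blk$initial)) {
        fps <- find_fixed_points(cfg$params, cfg$variant)
        st <- fps[vapply(fps, function(f) f$stability == "stable",
                         logical(1))]
        as.numeric(st[[1]]$state)  # inflamed (lowest B) stable state
      } else as.numeric(blk$initial)
      tr <- simulate_model(init, cfg$params, cfg$variant, t_span, proto)
      write_trajectory_csv(tr, file.path(cfg$outdir, "trajectory.csv"))
      tr
    },
    `continue` = {
      blk <- cfg$continue
      fp <- if (is.null(blk$free_param)) "k_Bo" else blk$free_param
      rng <- c(if (is.null(blk$from)) 10 else blk$from,
               if (is.null(blk$to)) 300 else blk$to)
      br <- trace_branch(cfg$params, cfg$variant, fp, rng)
      write_branch_csv(br, file.path(cfg$outdir, "branch.csv"))
      write_folds_json(br, file.path(cfg$outdir, "folds.json"))
      br
    },
    transform = {
      blk <- cfg$transform
      br <- trace_branch(cfg$params, cfg$variant, "k_Bo",
                         c(5, max(400, (blk$mean %||% 130) +
                                    5 * (blk$sd %||% 40))))
      p <- input_density(blk$mean %||% 130, blk$sd %||% 40)
      tr <- transform_density(br, p,
                              fold_exclusion = blk$fold_exclusion %||% 0.01)
      write_density_csv(tr, file.path(cfg$outdir, "density.csv"))
      write_density_summary_json(tr, file.path(cfg$outdir,
                                               "density_summary.json"))
      tr
    },
    verify = run_verification(cfg$params, cfg$variant,
                              file.path(cfg$outdir, "verify.json")),
    reproduce = reproduce_analysis(cfg$outdir, cfg$params, seed = cfg$seed)
  )
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read equilibria as JSON
#'
#' Per equilibrium: the state, eigenvalues as (re, im) pairs, stability
#' tag and scaled residual norm.
#'
#' @param fps a `"gut_fixed_points"` list.
#' @param path file path.
#' @return `path` (writer) / list of equilibrium records (reader).
#' @export
write_fixed_points_json <- function(fps, path) {
  recs <- lapply(fps, function(fp) {
    list(state = as.list(fp$state),
         eigenvalues = lapply(fp$eigenvalues, function(z) {
           list(re = Re(z), im = Im(z))
         }),
         stability = fp$stability,
         residual = fp$residual,
         variant = fp$variant)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fixed_points_json
#' @export
read_fixed_points_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Positive-orthant invariance check
#'
#' Integrates the model from random admissible starts and verifies that
#' every component stays nonnegative (and N below 1) for the whole span,
#' up to solver tolerance.
#'
#' @param params,variant as in [gut_rhs()].
#' @param n_traj number of random starts (uses the current RNG state).
#' @param t_span integration span per trajectory.
#' @param tol tolerated solver-level violation.
#' @return list with `pass`, `worst_min` (most negative component seen)
#'   and `worst_N` (largest N seen).
#' @export
verify_orthant_invariance <- function(params, variant = "core",
                                      n_traj = 50, t_span = c(0, 100),
                                      tol = 1e-6) {
  nm <- state_names(variant)
  worst_min <- Inf; worst_N <- -Inf
  for (i in seq_len(n_traj)) {
    x0 <- c(stats::runif(1),
            exp(stats::runif(length(nm) - 1, log(1e-3), log(100))))
    tr <- simulate_model(x0, params, variant, t_span, dt = 5)
    sts <- as.matrix(tr[, nm])
    worst_min <- min(worst_min, min(sts))
    worst_N <- max(worst_N, max(sts[, "N"]))
  }
  list(pass = worst_min > -tol && worst_N < 1 + tol,
       worst_min = worst_min, worst_N = worst_N)
}

# Box + orthant verification bundle used by `verify` and `reproduce`.
run_verification <- function(params, variant, path = NULL, n_traj = 50,
                             n_samples = 200) {
  box <- verify_box_invariance(params, variant, n_samples = n_samples)
  orth <- verify_orthant_invariance(params, variant, n_traj = n_traj)
  rep <- list(pass = box$pass && orth$pass,
              box = list(pass = box$pass,
                         worst_margins = stats::setNames(
                           box$faces$worst_margin, box$faces$face),
                         origin_ball = box$origin_ball),
              orthant = orth)
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  rep
}

#' Regenerate the full analysis
#'
#' Runs, in order: equilibrium location at the bistable operating point;
#' lumen-butyrate continuation with folds and normal forms; lumen-LPS
#' continuation; the pulse-switching simulation; the extended-model
#' continuation; the density transform; and the invariance verification
#' suite.  Each stage writes its CSV/JSON artifact into `outdir`;
#' failures are recorded per stage without aborting the rest.  The
#' machine-readable summary is written to `report.json`.
#'
#' @param outdir output directory.
#' @param params parameter set (core constants; the extended stage uses
#'   the same set with its `k_2B`).
#' @param seed RNG seed for the Monte-Carlo parts.
#' @return the report list, invisibly.
#' @export
reproduce_analysis <- function(outdir, params = gut_params(), seed = 1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  report <- list(seed = seed)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      warning("stage '", name, "' failed: ", conditionMessage(e),
              call. = FALSE)
      list(error = conditionMessage(e))
    })
    report[[name]] <<- res
    res
  }

  fps <- stage("equilibria", {
    f <- find_fixed_points(params, "core")
    write_fixed_points_json(f, file.path(outdir, "equilibria.json"))
    list(n = length(f),
         stability = vapply(f, function(x) x$stability, character(1)),
         states = lapply(f, function(x) as.list(x$state)))
  })

  br_core <- tryCatch(trace_branch(params, "core", "k_Bo", c(10, 300)),
                      error = function(e) e)
  stage("continuation_kBo", {
    if (inherits(br_core, "error")) stop(conditionMessage(br_core))
    write_branch_csv(br_core, file.path(outdir, "branch_kBo.csv"))
    write_folds_json(br_core, file.path(outdir, "folds_kBo.json"))
    list(n_folds = length(br_core$folds),
         folds = lapply(br_core$folds, function(f) {
           list(k_Bo = f$param_value, a = f$a)
         }))
  })

  stage("continuation_kbl", {
    br <- trace_branch(params, "core", "k_bl", c(0, 10))
    write_branch_csv(br, file.path(outdir, "branch_kbl.csv"))
    write_folds_json(br, file.path(outdir, "folds_kbl.json"))
    list(n_folds = length(br$folds),
         folds = lapply(br$folds, function(f) {
           list(k_bl = f$param_value, a = f$a)
         }))
  })

  stage("pulse_switching", {
    f <- find_fixed_points(params, "core")
    stable <- f[vapply(f, function(x) x$stability == "stable", logical(1))]
    # the high pulse must clear the right fold (~200.12): 210 does, the
    # fold-level value 200 sits marginally inside the bistable window
    proto <- pulse_protocol(params[["k_Bo"]], data.frame(
      t_start = c(50, 200), t_end = c(170, 270), k_Bo = c(210, 50)))
    tr <- simulate_model(as.numeric(stable[[1]]$state), params, "core",
                         c(0, 350), proto)
    write_trajectory_csv(tr, file.path(outdir, "pulse_trajectory.csv"))
    # classify on the baseline windows, after relaxation at k_Bo = 130
    after_high <- classify_endpoint(tr[tr$time <= 200, ], stable)
    at_end <- classify_endpoint(tr, stable)
    list(after_high_pulse = after_high, at_end = at_end,
         switched = identical(after_high, 2L) && identical(at_end, 1L))
  })

  stage("continuation_extended", {
    if (inherits(br_core, "error")) stop(conditionMessage(br_core))
    br <- trace_branch(params, "extended", "k_Bo", c(10, 500))
    write_branch_csv(br, file.path(outdir, "branch_extended.csv"))
    write_folds_json(br, file.path(outdir, "folds_extended.json"))
    core_iv <- bistable_interval(br_core)
    ext_iv <- bistable_interval(br)
    # the feedback Hill factor shifts both folds right and widens the
    # window (it cannot move the left fold leftwards; see the vignette)
    list(core_interval = core_iv, extended_interval = ext_iv,
         broadened = diff(ext_iv) > diff(core_iv) &&
           ext_iv[2] > core_iv[2])
  })

  stage("density_transform", {
    br <- trace_branch(params, "core", "k_Bo", c(5, 400))
    p <- input_density(130, 40)
    tf <- transform_density(br, p)
    write_density_csv(tf, file.path(outdir, "density.csv"))
    write_density_summary_json(tf, file.path(outdir,
                                             "density_summary.json"))
    list(n_modes = length(tf$modes), modes = tf$modes,
         retained_mass = tf$retained_mass)
  })

  stage("verification", run_verification(params, "core",
                                         file.path(outdir, "verify.json")))

  write_report_json(report, file.path(outdir, "report.json"))
  invisible(report)
}

#' Write / read the analysis report
#'
#' @param report list from [reproduce_analysis()].
#' @param path file path.
#' @return `path` (writer) / the report list (reader).
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
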