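#' @keywords internal
"_PACKAGE"

# All rate/threshold constants of the model, in canonical order.
PARAM_NAMES <- c(
  "k_a", "k_s", "k_ai", "k_r", "k_bn", "k_b", "k_br", "k_n", "k_p", "k_t",
  "k_tl", "k_bl", "k_lb", "k_l", "k_bt", "k_d", "k_B", "k_Bo", "k_2B"
)

# Constants that appear in denominators or as decay rates and must be
# strictly positive.
STRICT_POSITIVE <- c(
  "k_s", "k_r", "k_n", "k_br", "k_t", "k_l", "k_B", "k_bt", "k_lb"
)

MODEL_VARIANTS <- c("base", "core", "extended")

# Reference parameterisation of the published qualitative model.  k_Bo is
# the lumen butyrate level at the bistable operating point; k_2B (the Hill
# threshold of the extended model's transporter feedback) is a package
# default, chosen so that the extended model's bistable window strictly
# contains the core model's (see the methods vignette).
PRESETS <- list(
  reference = c(
    k_a = 12, k_s = 1.0, k_ai = 5, k_r = 0.5, k_bn = 4.7, k_b = 5,
    k_br = 0.5, k_n = 0.2, k_p = 7, k_t = 0.2, k_tl = 2.8, k_bl = 1.02,
    k_lb = 3.4, k_l = 0.7, k_bt = 2.1, k_d = 0.125, k_B = 2.9,
    k_Bo = 130, k_2B = 5.0
  )
)

#' Model parameter sets
#'
#' Constructs the full set of rate and threshold constants of the
#' inflammation--butyrate model as an immutable named vector.  All
#' constants are nonnegative; those appearing in Hill denominators or as
#' first-order decay rates must be strictly positive.  The model is
#' qualitative, so units are arbitrary concentration/time units.
#'
#' The `"reference"` preset is the published parameterisation of the
#' hysteresis analysis (`k_a = 12`, ..., `k_B = 2.9`), completed with
#' `k_Bo = 130` (lumen butyrate at the bistable operating point) and
#' `k_2B = 5` (extended-model Hill threshold, a package default).
#'
#' @param ... named overrides of individual constants, e.g. `k_Bo = 200`.
#' @param preset name of a built-in preset; currently `"reference"`.
#' @return a named numeric vector of class `"gut_params"` with one entry
#'   per constant.
#' @examples
#' p <- gut_params()
#' p[["k_a"]]
#' gut_params(k_Bo = 300)[["k_Bo"]]
#' @export
gut_params <- function(..., preset = "reference") {
  if (!preset %in% names(PRESETS)) {
    stop("unknown preset: '", preset, "'", call. = FALSE)
  }
  p <- PRESETS[[preset]]
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("parameter overrides must be named", call. = FALSE)
    }
    bad <- setdiff(names(overrides), PARAM_NAMES)
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    p[names(overrides)] <- vapply(overrides, as.numeric, numeric(1))
  }
  validate_params(p)
  structure(p, class = "gut_params")
}

#' Validate a parameter vector
#'
#' Checks that every constant of [gut_params()] is present, finite and
#' nonnegative, and that denominator/decay constants are strictly
#' positive.  Called by all model-facing functions.
#'
#' @param p named numeric vector of parameters.
#' @return `p`, invisibly, if valid; otherwise an error.
#' @export
validate_params <- function(p) {
  missing <- setdiff(PARAM_NAMES, names(p))
  if (length(missing)) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(p), PARAM_NAMES)
  if (length(extra)) {
    stop("unknown parameter(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  v <- as.numeric(p[PARAM_NAMES])
  if (any(!is.finite(v))) {
    stop("parameters must be finite", call. = FALSE)
  }
  if (any(v < 0)) {
    stop("parameters must be nonnegative: ",
         paste(PARAM_NAMES[v < 0], collapse = ", "), call. = FALSE)
  }
  zp <- STRICT_POSITIVE[p[STRICT_POSITIVE] <= 0]
  if (length(zp)) {
    stop("parameters must be strictly positive: ",
         paste(zp, collapse = ", "), call. = FALSE)
  }
  invisible(p)
}

match_variant <- function(variant) {
  match.arg(variant, MODEL_VARIANTS)
}

#' State variable names of a model variant
#'
#' The base variant tracks the four inflammatory species
#' (N = nuclear NF-kB fraction, R = repressor, T = cytokines,
#' L = within-cell LPS); the core and extended variants add
#' B = within-cell butyrate.
#'
#' @param variant one of `"base"`, `"core"`, `"extended"`.
#' @return character vector of state names.
#' @export
state_names <- function(variant = "core") {
  variant <- match_variant(variant)
  if (variant == "base") c("N", "R", "T", "L") else c("N", "R", "T", "L", "B")
}

#' @export
print.gut_params <- function(x, ...) {
  cat("Model parameters (", length(x), " constants):\n", sep = "")
  print(unclass(x))
  invisible(x)
}

#' Read a parameter preset from a YAML config file
#'
#' The file holds one key per constant (`k_a: 12` etc.) plus an optional
#' `variant` key; unknown keys are rejected.  Missing constants are
#' filled from the `"reference"` preset.
#'
#' @param path file to read.
#' @return list with elements `params` ([gut_params()]) and `variant`.
#' @seealso [write_params_config()]
#' @export
read_params_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a key-value mapping", call. = FALSE)
  variant <- if (!is.null(cfg$variant)) match_variant(cfg$variant) else "core"
  cfg$variant <- NULL
  bad <- setdiff(names(cfg), PARAM_NAMES)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  p <- do.call(gut_params, cfg)
  list(params = p, variant = variant)
}

#' Write a parameter set to a YAML config file
#'
#' @param params a [gut_params()] vector.
#' @param path file to write.
#' @param variant model variant tag stored alongside the constants.
#' @return `path`, invisibly.
#' @export
write_params_config <- function(params, path, variant = "core") {
  validate_params(params)
  variant <- match_variant(variant)
  out <- c(as.list(setNames(as.numeric(params[PARAM_NAMES]), PARAM_NAMES)),
           list(variant = variant))
  yaml::write_yaml(out, path)
  invisible(path)
}
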