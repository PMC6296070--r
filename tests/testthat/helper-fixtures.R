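# Shared fixtures.  Expensive objects (continuation branches, multistart
# equilibrium scans) are memoised so each is computed once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

ref_fps <- function() {
  cached("fps130", find_fixed_points(gut_params(), "core"))
}

ref_stable <- function() {
  fps <- ref_fps()
  fps[vapply(fps, function(f) f$stability == "stable", logical(1))]
}

ref_branch <- function() {
  cached("br_kBo", trace_branch(gut_params(), "core", "k_Bo", c(10, 300)))
}

wide_branch <- function() {
  cached("br_wide", trace_branch(gut_params(), "core", "k_Bo", c(5, 400)))
}

kbl_branch <- function() {
  cached("br_kbl", trace_branch(gut_params(), "core", "k_bl", c(0, 10)))
}

ext_branch <- function() {
  cached("br_ext", trace_branch(gut_params(), "extended", "k_Bo",
                                c(10, 500)))
}

# Published reference states of the two stable equilibria at the
# bistable operating point (lumen butyrate 130).
inflamed_ref <- c(N = 0.178369, R = 1.783690, T = 20.365623,
                  L = 0.347144, B = 6.079745)
noninflamed_ref <- c(N = 0.00002003, R = 0.00020025, T = 0.09248014,
                     L = 0.00660570, B = 50.382992)

# Synthetic single-layer branch with a prescribed map x -> y, for
# closed-form transform checks.
synthetic_branch <- function(x, y, variant = "core") {
  pts <- data.frame(param = x, N = 0, R = 0, T = 0, L = 0, B = y,
                    stability = "stable", sweep = 1L, layer = "stable")
  structure(list(free_param = "k_Bo", range = range(x), points = pts,
                 folds = list(), params = gut_params(), variant = variant),
            class = "gut_branch")
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)
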