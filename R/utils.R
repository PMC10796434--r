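#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream.  All seeded package entry points funnel through here.
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Deterministic, platform-independent string hash (31-polynomial mod a
# Mersenne prime); used for fingerprint bit assignment and per-entity seeds.
str_hash <- function(s) {
  h <- 0
  for (cd in utf8ToInt(s)) h <- (h * 31 + cd) %% 2147483647
  h
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
}

# Locate the python interpreter used by the scikit-learn and rdkit bridges.
dacsaug_python <- function() {
  p <- getOption("dacsaug.python", Sys.getenv("DACSAUG_PYTHON", ""))
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) p <- Sys.which("python")
  if (!nzchar(p))
    stop("no python interpreter found; set options(dacsaug.python=) ",
         "to use the classifier/descriptor backends", call. = FALSE)
  unname(p)
}

bridge_script <- function(name) {
  path <- system.file("python", name, package = "dacsaug")
  if (!nzchar(path)) {
    # during devtools::load_all() the package root layout is used
    path <- file.path("inst", "python", name)
  }
  if (!file.exists(path)) stop("bridge script not found: ", name, call. = FALSE)
  path
}
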