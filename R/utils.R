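# internal helpers shared across modules

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed` and
#' restores the caller's RNG state afterwards, so seeded package functions
#' do not perturb the session stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
#' @examples
#' with_seed(1, runif(2))
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage seed from a master seed
#'
#' Deterministically maps a master seed and a stage name to a 31-bit seed,
#' so every random step of a pipeline is reproducible from one number.
#'
#' @param master Integer master seed.
#' @param stage Character stage label.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "background")
derive_seed <- function(master, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 2147483647
  as.integer((as.numeric(master) %% 2147483647 + h) %% 2147483647)
}

# nearest-rank percentile: the ceiling(p/100 * n)-th smallest value
pct_nearest <- function(x, p) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) stop("no non-missing values", call. = FALSE)
  sort(x)[min(n, max(1L, as.integer(ceiling(p / 100 * n))))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
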