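#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. Keeps run-level simulation
# reproducible without clobbering the session RNG.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a per-run seed from a dataset seed; kept below 2^31.
derive_seed <- function(seed, index) {
  (as.double(seed) + 99991 * as.double(index)) %% 2147483647
}

stopifnot_finite <- function(x, what = deparse(substitute(x))) {
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", what), call. = FALSE)
  }
  invisible(x)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# near-integer test used for cycle/bin alignment checks
is_whole <- function(x, tol = 1e-8) {
  abs(x - round(x)) < tol
}

volts_to_uV <- function(x) x * 1e6
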