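#' @keywords internal
"_PACKAGE"

# Run `code` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All stochastic generators in the package go
# through this so that a fixed seed gives byte-identical output without
# clobbering the user's random stream.
with_local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

stop_domain <- function(...) {
  stop(..., call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_domain(name, " must be a single finite number")
  }
  if (x < lower || (!allow_zero && x == lower)) {
    stop_domain(name, " must be ", if (allow_zero) ">= " else "> ", lower,
                " (got ", format(x), ")")
  }
  invisible(x)
}

# 12 significant digits everywhere a number is serialized, so that
# write -> read round-trips are stable across platforms.
format_num <- function(x) trimws(formatC(x, digits = 12, format = "g"))
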