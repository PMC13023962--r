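# internal helpers shared across the package

# evaluate expr under a private RNG stream; global .Random.seed is restored
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed), seed >= 0)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# deterministic sub-seed for hierarchical simulation (region i, subject j,
# channel k); kept strictly below 2^31 - 1
sub_seed <- function(seed, i, j = 0L, k = 0L) {
  m <- 2147483647
  s <- (as.double(seed) %% m)
  s <- (s * 1000003 + i * 10007 + j * 101 + k * 7 + 11) %% m
  as.integer(s)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_scalar <- function(x, field, lower = -Inf, upper = Inf,
                         integer = FALSE, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stop_field(field, "must not be NULL")
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  if (x < lower) stop_field(field, sprintf("must be >= %s", lower))
  if (x > upper) stop_field(field, sprintf("must be <= %s", upper))
  if (integer && x != round(x)) stop_field(field, "must be an integer")
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# collinear input is a legitimate case (an exact power law); silence only
# lm's perfect-fit advisory, pass every other warning through
quiet_perfect_fit <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}
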