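# Internal helpers shared across modules.

# Evaluate `expr` under a private RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so generators do not perturb user randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministically derive a sub-seed from a master seed and a stream label,
# so each generator draws from its own stream and adding, say, neurons does
# not perturb the behavioral schedule.
derive_seed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(salt)) * seq_along(utf8ToInt(as.character(salt))))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483399 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# semicolon-joined seconds <-> numeric vector, the trial-table lick encoding
join_times <- function(x) {
  if (length(x) == 0L) return("")
  paste(format(x, trim = TRUE, scientific = FALSE, digits = 10), collapse = ";")
}

split_times <- function(s) {
  if (is.na(s) || !nzchar(s)) return(numeric(0))
  as.numeric(strsplit(s, ";", fixed = TRUE)[[1L]])
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

check_prob <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop_config("'%s' must be a probability in [0, 1], got %s", name,
                paste(format(p), collapse = ","))
  }
  p
}

check_pos <- function(x, name, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) stop_config("'%s' must be a %s number", name,
                       if (strict) "positive" else "non-negative")
  x
}
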