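# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# round-half-up (0.5 always rounds away from zero toward +Inf for the
# non-negative counts used here); base round() is round-half-even
round_half_up <- function(x) floor(x + 0.5)

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_count_like <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0)
}

is_whole <- function(x, tol = 1e-8) {
  all(abs(x - round(x)) < tol)
}

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
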