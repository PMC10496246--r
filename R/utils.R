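# shared internal helpers: classed errors and small numerics

nr_stop <- function(class, msg, ...) {
  stop(structure(class = c(class, "noderad_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

nr_warn <- function(msg, ...) warning(sprintf(msg, ...), call. = FALSE)

# population variance / sd (divide by n)
pop_var <- function(x) mean((x - mean(x))^2)
pop_sd <- function(x) sqrt(pop_var(x))

# 0 * log2(0) := 0
xlog2 <- function(p) ifelse(p > 0, log2(p), 0)

# half-up rounding to integer
round_half_up <- function(x) floor(x + 0.5)

# seeded evaluation that restores the caller's RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
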