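# Internal helpers: classed errors and local RNG scope.

sm_stop <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "skinmorph_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

validation_error <- function(msg) sm_stop("skinmorph_validation_error", msg)
degenerate_error <- function(msg) sm_stop("skinmorph_degenerate_error", msg)
undefined_error  <- function(msg) sm_stop("skinmorph_undefined_error", msg)

check <- function(cond, msg) if (!isTRUE(cond)) validation_error(msg)

# Run `expr` under a given seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 1 && x == floor(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
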