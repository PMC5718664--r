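`%||%` <- function(a, b) if (is.null(a)) b else a

# round-half-up; base round() is round-half-even
round_half_up <- function(x) floor(x + 0.5)

stop_qa <- function(class, msg, ...) {
  stop(structure(class = c(class, "catphanqa_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# Run code with a temporary RNG seed, restoring global RNG state afterwards.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
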