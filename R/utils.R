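# internal helpers shared across modules

# classed conditions so callers/tests can distinguish failure kinds
abort_contrp <- function(msg, class) {
  stop(structure(
    class = c(class, "contrp_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_data   <- function(msg) abort_contrp(msg, "contrp_data_error")
abort_format <- function(msg) abort_contrp(msg, "contrp_format_error")
abort_config <- function(msg) abort_contrp(msg, "contrp_config_error")
abort_io     <- function(msg) abort_contrp(msg, "contrp_io_error")

# run `expr` under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic child seed kept inside 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 2654435761 + 97 * as.double(k)) %% 2147483647)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == round(x) && x >= 1

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
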