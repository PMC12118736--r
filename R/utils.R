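# Internal helpers shared across modules.

#' @importFrom withr with_seed
run_seeded <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Derive a child seed from a parent seed and a stream index; keeps every
# stochastic step independently and reproducibly seeded while staying in
# 32-bit integer range.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 1103L + as.integer(stream) * 12289L) %% 2147483123L
}

stop_ironmap <- function(msg, class, data = NULL) {
  cond <- structure(
    class = c(class, "ironmap_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), data = data)
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coordinates are pixel-centered and 0-based throughout: pixel (i, j) of a
# matrix sits at (i - 1, j - 1) in index space.
pixel_grid <- function(shape) {
  list(
    x = matrix(rep(seq_len(shape[1]) - 1, shape[2]), shape[1], shape[2]),
    y = matrix(rep(seq_len(shape[2]) - 1, each = shape[1]), shape[1], shape[2])
  )
}

is_flag <- function(x) is.logical(x) && length(x) == 1 && !is.na(x)
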