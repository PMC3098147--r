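`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. `seed = NULL` uses the current stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' @noRd
stop_txq <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "txq_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

# physical nm coordinate of 1-based voxel index i is (i - 0.5) * pitch;
# these two helpers convert between the conventions
#' @noRd
nm_to_index <- function(x_nm, pitch) x_nm / pitch + 0.5

#' @noRd
index_to_nm <- function(i, pitch) (i - 0.5) * pitch
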