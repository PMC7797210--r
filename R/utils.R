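# internal helpers shared across modules

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
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
  force(expr)
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

# Otsu threshold restricted to a vector of intensities (EBImage::otsu wants a
# rectangular image, so within-mask thresholding goes through a column matrix).
otsu_threshold <- function(values, levels = 256L) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2L) {
    stop("Otsu thresholding needs at least two distinct intensities; ",
         "use a fixed threshold for constant images", call. = FALSE)
  }
  rng <- range(values)
  EBImage::otsu(matrix(values, ncol = 1L), range = rng, levels = levels)
}
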