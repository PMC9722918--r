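# internal helpers shared across modules

# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards.
# All generators route their randomness through this so that identical specs
# yield bit-identical outputs regardless of the surrounding session.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == round(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# contiguous relabelling of an integer label matrix (0 stays background)
relabel_map <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0L) return(matrix(0L, nrow(labels), ncol(labels)))
  out <- matrix(match(labels, ids, nomatch = 0L), nrow(labels), ncol(labels))
  storage.mode(out) <- "integer"
  out
}

n_labels <- function(labels) length(unique(labels[labels > 0]))

# Gaussian blur with edge-replicate padding: avoids both the kernel-larger-
# than-image failure mode and circular wrap-around at image borders.
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  p <- 2L * as.integer(ceiling(3 * sigma)) + 2L
  rows <- c(rep(1L, p), seq_len(nrow(m)), rep(nrow(m), p))
  cols <- c(rep(1L, p), seq_len(ncol(m)), rep(ncol(m), p))
  padded <- m[rows, cols, drop = FALSE]
  blurred <- as.matrix(EBImage::gblur(EBImage::Image(padded), sigma = sigma))
  blurred[p + seq_len(nrow(m)), p + seq_len(ncol(m)), drop = FALSE]
}
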