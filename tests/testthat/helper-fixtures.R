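# programmatic fixtures shared across test files

# binary disc mask centred in a square canvas
disc_mask <- function(radius_px, pad = 6L) {
  n <- 2L * (radius_px + pad) + 1L
  c0 <- radius_px + pad + 1L
  g <- expand.grid(r = seq_len(n), c = seq_len(n))
  m <- matrix(0, n, n)
  m[sqrt((g$r - c0)^2 + (g$c - c0)^2) <= radius_px] <- 1
  m
}

square_mask <- function(side_px, pad = 6L) {
  n <- side_px + 2L * pad
  m <- matrix(0, n, n)
  m[pad + seq_len(side_px), pad + seq_len(side_px)] <- 1
  m
}

# two discs of radius r joined by a 1-pixel bridge
dumbbell_mask <- function(r = 8L, gap = 8L) {
  h <- 2L * r + 13L
  wdt <- 4L * r + gap + 13L
  cy <- (h + 1L) %/% 2L
  c1 <- r + 7L
  c2 <- wdt - r - 6L
  g <- expand.grid(rr = seq_len(h), cc = seq_len(wdt))
  m <- matrix(0, h, wdt)
  m[sqrt((g$rr - cy)^2 + (g$cc - c1)^2) <= r] <- 1
  m[sqrt((g$rr - cy)^2 + (g$cc - c2)^2) <= r] <- 1
  m[cy, c1:c2] <- 1
  m
}

# brute-force Euclidean distance transform (independent of EBImage)
brute_distmap <- function(mask) {
  fg <- which(mask > 0, arr.ind = TRUE)
  bg <- which(mask <= 0, arr.ind = TRUE)
  d <- matrix(0, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(fg)))
    d[fg[i, 1], fg[i, 2]] <-
      sqrt(min((fg[i, 1] - bg[, 1])^2 + (fg[i, 2] - bg[, 2])^2))
  d
}

# brute-force saddle height between two peak pixels of a height map: the
# largest level L at which both peaks lie in one connected component of the
# superlevel set {d >= L}. The prominence of the lower peak is its height
# minus this saddle; two h-maxima exist iff that prominence >= h.
brute_saddle <- function(d, p1, p2) {
  same_component <- function(level) {
    lev <- (d >= level) * 1
    comp <- EBImage::bwlabel(EBImage::Image(lev))
    comp <- matrix(as.integer(round(as.matrix(comp))), nrow(d), ncol(d))
    comp[p1[1], p1[2]] == comp[p2[1], p2[2]] && comp[p1[1], p1[2]] > 0
  }
  levels <- sort(unique(d[d > 0]))
  saddle <- 0
  for (L in levels) {
    if (same_component(L)) saddle <- L else break
  }
  saddle
}

# dense grid-search cosinor oracle: minimal SSE over an (M, A, Phi) grid
grid_cosinor_sse <- function(t, y, period = 24,
                             n_m = 201, n_a = 201, n_phi = 241) {
  m0 <- mean(y); s <- stats::sd(y)
  Mg <- seq(m0 - 3 * s, m0 + 3 * s, length.out = n_m)
  Ag <- seq(0, 3 * s, length.out = n_a)
  phis <- seq(0, period, length.out = n_phi + 1)[seq_len(n_phi)]
  sy2 <- sum(y^2); sy <- sum(y); n <- length(y)
  best <- Inf
  for (ph in phis) {
    cc <- cos(2 * pi * (t - ph) / period)
    sc <- sum(cc); scc <- sum(cc^2); syc <- sum(y * cc)
    sse <- outer(n * Mg^2 - 2 * Mg * sy, Ag^2 * scc - 2 * Ag * syc, "+") +
      2 * outer(Mg, Ag) * sc + sy2
    best <- min(best, min(sse))
  }
  best
}

default_params <- function(...) segmentation_params(...)

noiseless_fixture <- function(seed, n_mito = 6L, n_cells = 1L) {
  generate_mito_image(synthetic_image_spec(
    n_cells = n_cells, mito_per_cell = n_mito, noise_sd = 0, seed = seed))
}
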