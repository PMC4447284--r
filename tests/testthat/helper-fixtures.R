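# Shared fixtures: everything is generated in code at test time.

# A small synthetic world (60 x 60 cells) for cheap pipeline tests.
small_world_spec <- function(seed = 20150601, ...) {
  world_spec(bbox = c(107, 107.5, 11.5, 12), resolution = 30,
             length_scale = 8, seed = seed, ...)
}

# A tiny grid stack with hand-set layers.
toy_stack <- function(nr = 10, nc = 10, layers = list()) {
  grid_stack(west = 0, north = 1, cellsize = 1 / nr, nrow = nr, ncol = nc,
             layers = layers)
}

# Row/column coordinate matrices (row 1 = north).
rowmat <- function(nr, nc) matrix(rep(seq_len(nr), nc), nr, nc)
colmat <- function(nr, nc) matrix(rep(seq_len(nc), each = nr), nr, nc)

# Independent brute-force p-distance oracle: per-column scan.
p_distance_oracle <- function(a, b) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  acgt <- c("A", "C", "G", "T")
  n <- 0L; mism <- 0L
  for (i in seq_along(av)) {
    if (av[i] %in% acgt && bv[i] %in% acgt) {
      n <- n + 1L
      if (av[i] != bv[i]) mism <- mism + 1L
    }
  }
  list(distance = mism / n, n_compared = n)
}

random_dna <- function(n, len, seed) {
  with_seed <- nichesplit:::with_seed
  with_seed(seed, {
    alph <- c("A", "C", "G", "T", "-", "N")
    sapply(seq_len(n), function(i)
      paste(sample(alph, len, replace = TRUE, prob = c(rep(0.23, 4), 0.04, 0.04)),
            collapse = ""))
  })
}
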