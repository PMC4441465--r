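# Independent oracles and fixture generators, deliberately written as plain
# loops so they share no code with the implementation they check.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force overlapping 3-mer counter
count_trinucleotides <- function(s) {
  words <- substring(s, 1:(nchar(s) - 2), 3:nchar(s))
  table(factor(words, levels = cgrmap:::trinucleotide_alphabet()))
}

# chaos-game trajectory by direct loop iteration
loop_trajectory <- function(s) {
  corners <- list(A = c(0, 0), C = c(0, 1), G = c(1, 1), T = c(1, 0))
  p <- c(0.5, 0.5)
  out <- matrix(NA_real_, nchar(s), 2)
  letters <- strsplit(s, "")[[1]]
  for (i in seq_along(letters)) {
    p <- (p + corners[[letters[i]]]) / 2
    out[i, ] <- p
  }
  out
}

# black-pixel set predicted by quantizing trajectory points i >= k
trajectory_pixel_set <- function(s, k) {
  traj <- loop_trajectory(s)
  side <- 2^k
  keep <- seq_len(nrow(traj)) >= k
  col <- floor(side * traj[keep, 1])
  row <- side - 1 - floor(side * traj[keep, 2])
  sort(unique(row * side + col))
}

black_pixel_set <- function(img) {
  hits <- which(unclass(img) == 0L, arr.ind = TRUE)
  side <- nrow(img)
  sort(unique((hits[, "row"] - 1) * side + (hits[, "col"] - 1)))
}

# per-window SSIM by direct loops over every valid window position
naive_mean_ssim <- function(a, b, params = cgrmap::ssim_params()) {
  ws <- params$window_side
  half <- (ws - 1) / 2
  g <- exp(-((-half:half)^2) / (2 * params$window_sigma^2))
  W <- outer(g, g)
  W <- W / sum(W)
  C1 <- (params$K1 * params$L)^2
  C2 <- (params$K2 * params$L)^2
  nr <- nrow(a) - ws + 1
  nc <- ncol(a) - ws + 1
  vals <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      Pa <- a[i:(i + ws - 1), j:(j + ws - 1)]
      Pb <- b[i:(i + ws - 1), j:(j + ws - 1)]
      mua <- sum(W * Pa)
      mub <- sum(W * Pb)
      va <- sum(W * Pa * Pa) - mua^2
      vb <- sum(W * Pb * Pb) - mub^2
      cab <- sum(W * Pa * Pb) - mua * mub
      vals[i, j] <- ((2 * mua * mub + C1) * (2 * cab + C2)) /
        ((mua^2 + mub^2 + C1) * (va + vb + C2))
    }
  }
  mean(vals)
}

random_image <- function(side, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(sample(0:255, side * side, replace = TRUE), side, side)
}

checkerboard <- function(side) {
  255L * ((outer(seq_len(side), seq_len(side), `+`)) %% 2L)
}
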