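# Classical (Torgerson) multidimensional scaling, Stress-1 with
# linear-regression disparities, and the [-1, 1] map scaling.

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centres the squared distances, `B = -1/2 * J (D o D) J` with
#' `J = I - (1/n) 11'`, eigendecomposes `B`, and takes the eigenvectors of
#' the `q` algebraically largest eigenvalues scaled by the square roots of
#' the (non-negative-clamped) eigenvalues. DSSIM matrices are generally
#' non-Euclidean, so negative eigenvalues are expected; they are clamped to
#' zero for coordinate construction and reported in full in `eigenvalues`.
#' The sign of each eigenvector is fixed so its largest-magnitude entry is
#' positive, making maps reproducible across runs and platforms.
#'
#' @param D symmetric distance matrix with id dimnames (see
#'   [validate_distance_matrix()]).
#' @param q embedding dimension, `1 <= q <= n - 1` (default 2).
#' @return A list of class `"map_configuration"` with `ids`, `coords`
#'   (n x q, unscaled), `eigenvalues` (all n, descending), `q`, and
#'   `scaled = FALSE`.
#' @examples
#' pts <- cbind(c(0, 0, 1, 1), c(0, 1, 1, 0))
#' D <- as.matrix(dist(pts)); dimnames(D) <- list(letters[1:4], letters[1:4])
#' cfg <- classical_mds(D, q = 2)
#' max(abs(as.matrix(dist(cfg$coords)) - D)) # ~1e-15
#' @export
classical_mds <- function(D, q = 2) {
  validate_distance_matrix(D)
  n <- nrow(D)
  q <- as.integer(q)
  if (q < 1L || q > n - 1L) stop("'q' must be between 1 and n - 1 = ", n - 1L)
  D2 <- D * D
  rm <- rowMeans(D2)
  B <- -0.5 * (D2 - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + mean(D2))
  e <- eigen(B, symmetric = TRUE) # values already in decreasing order
  lambda <- e$values[seq_len(q)]
  # eigenvalues within rounding error of zero count as zero
  tol <- max(abs(e$values), 0) * 1e-12
  lambda[lambda <= tol] <- 0
  n_pos <- sum(lambda > 0)
  if (n_pos < q) {
    warning("only ", n_pos, " positive eigenvalue(s) for q = ", q,
            "; deficient axes filled with zeros")
  }
  coords <- e$vectors[, seq_len(q), drop = FALSE] %*%
    diag(sqrt(lambda), nrow = q)
  for (j in seq_len(q)) { # sign convention: largest-magnitude entry positive
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("dim", seq_len(q))
  structure(
    list(ids = rownames(D), coords = coords, eigenvalues = e$values,
         q = q, scaled = FALSE),
    class = "map_configuration"
  )
}

#' Kruskal Stress-1 of a map configuration
#'
#' Disparities are the linear transform `f(delta) = a * delta + b` with
#' `a`, `b` fitted by ordinary least squares of the realized map distances
#' `d(i, j)` on the input distances `delta(i, j)` over all unordered pairs.
#' Stress-1 is `sqrt(sum (f(delta) - d)^2 / sum d^2)`. It is computed on the
#' unscaled coordinates: the subsequent per-axis \[-1, 1\] scaling is
#' anisotropic and would change the `d(i, j)`.
#'
#' @param D the input distance matrix.
#' @param config a `"map_configuration"` from [classical_mds()] on the same
#'   ids (unscaled).
#' @return List with `stress1`, `a` (slope), `b` (intercept).
#' @export
stress1 <- function(D, config) {
  validate_distance_matrix(D)
  if (!identical(rownames(D), config$ids)) {
    stop("configuration ids do not match the distance matrix")
  }
  delta <- D[lower.tri(D)]
  d <- as.vector(dist(config$coords)) # same pair ordering as lower.tri
  if (isTRUE(all.equal(stats::var(delta), 0)) || length(delta) < 2L) {
    warning("all input distances equal; regression undefined, using a = 0")
    a <- 0
    b <- mean(d)
  } else {
    fit <- lm.fit(cbind(1, delta), d)
    b <- fit$coefficients[[1L]]
    a <- fit$coefficients[[2L]]
  }
  denom <- sum(d^2)
  if (denom == 0) {
    warning("all map distances are zero; Stress-1 reported as 0")
    return(list(stress1 = 0, a = a, b = if (is.finite(b)) b else 0))
  }
  list(stress1 = sqrt(sum((a * delta + b - d)^2) / denom), a = a, b = b)
}

#' Scale a map so every axis spans [-1, 1]
#'
#' Each axis is independently affinely mapped,
#' `x_sca = 2 (x - x_min) / (x_max - x_min) - 1`, so its minimum lands on -1
#' and its maximum on +1. A degenerate axis (max == min) is set to all
#' zeros with a warning. The per-axis (min, max) pairs used are recorded in
#' `scaling_record`.
#'
#' @param config an unscaled `"map_configuration"`.
#' @return The configuration with scaled `coords`, `scaled = TRUE` and
#'   `scaling_record` (2 x q matrix, rows `min` and `max`).
#' @export
scale_map <- function(config) {
  if (isTRUE(config$scaled)) return(config)
  coords <- config$coords
  rec <- matrix(NA_real_, 2L, ncol(coords),
                dimnames = list(c("min", "max"), colnames(coords)))
  for (j in seq_len(ncol(coords))) {
    mn <- min(coords[, j])
    mx <- max(coords[, j])
    rec[, j] <- c(mn, mx)
    if (mx == mn) {
      warning("axis ", j, " is degenerate (max == min); set to 0")
      coords[, j] <- 0
    } else {
      coords[, j] <- 2 * (coords[, j] - mn) / (mx - mn) - 1
    }
  }
  config$coords <- coords
  config$scaled <- TRUE
  config$scaling_record <- rec
  config
}

#' @export
print.map_configuration <- function(x, ...) {
  cat("Map configuration: ", length(x$ids), " points in ", x$q,
      " dimension(s)", if (isTRUE(x$scaled)) ", scaled to [-1, 1]", "\n",
      sep = "")
  ev <- x$eigenvalues
  cat("Leading eigenvalues:", paste(signif(head(ev, 5), 4), collapse = ", "),
      if (length(ev) > 5) "...", "\n")
  invisible(x)
}
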