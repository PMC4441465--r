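# Structural similarity (SSIM) and the DSSIM distance between CGR images.
#
# SSIM is computed per window position over Gaussian-weighted local moments,
#   SSIM = (2 mu_A mu_B + C1)(2 cov_AB + C2) /
#          ((mu_A^2 + mu_B^2 + C1)(var_A + var_B + C2)),
# with C3 = C2 / 2 folded into the two-term form. Only windows fully inside
# the image contribute ("valid" border handling), there is no downsampling
# pre-stage, and images enter as 8-bit intensities with dynamic range L = 255.
# The mean over the local map is the SSIM index; DSSIM = 1 - SSIM in [0, 2].

#' SSIM windowing and stabilization parameters
#'
#' Defaults follow the canonical SSIM reference implementation: an 11 x 11
#' Gaussian window with sigma 1.5 and stabilization constants
#' `C1 = (K1 L)^2`, `C2 = (K2 L)^2` with `K1 = 0.01`, `K2 = 0.03` and
#' dynamic range `L = 255` (8-bit intensities).
#'
#' @param window_side odd window side length in pixels, >= 3.
#' @param window_sigma standard deviation of the Gaussian weighting, pixels.
#' @param K1,K2 small positive stabilization factors.
#' @param L dynamic range of the intensities.
#' @return List of class `"ssim_params"` including the derived `C1`, `C2`.
#' @export
ssim_params <- function(window_side = 11, window_sigma = 1.5,
                        K1 = 0.01, K2 = 0.03, L = 255) {
  window_side <- as.integer(window_side)
  if (window_side < 3L || window_side %% 2L == 0L) {
    stop("'window_side' must be odd and >= 3")
  }
  if (K1 <= 0 || K2 <= 0 || L <= 0 || window_sigma <= 0) {
    stop("'K1', 'K2', 'L' and 'window_sigma' must be positive")
  }
  structure(
    list(window_side = window_side, window_sigma = window_sigma,
         K1 = K1, K2 = K2, L = L,
         C1 = (K1 * L)^2, C2 = (K2 * L)^2, C3 = (K2 * L)^2 / 2),
    class = "ssim_params"
  )
}

# normalized 1-D Gaussian kernel; the 2-D window is its outer product
gaussian_kernel <- function(params) {
  half <- (params$window_side - 1L) / 2L
  g <- exp(-((-half:half)^2) / (2 * params$window_sigma^2))
  g / sum(g)
}

as_intensity <- function(img) {
  m <- unclass(img)
  if (!is.matrix(m)) stop("image must be a matrix of intensities")
  storage.mode(m) <- "double"
  m
}

check_ssim_input <- function(a, b, params) {
  if (!all(dim(a) == dim(b))) {
    stop("images differ in size: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  }
  if (min(dim(a)) < params$window_side) {
    stop("image side ", min(dim(a)), " smaller than SSIM window (",
         params$window_side, ")")
  }
}

# Gaussian-weighted local mean and raw second moment of one image;
# cached per image when many pairs share it.
ssim_moments <- function(img, params) {
  kern <- gaussian_kernel(params)
  m <- as_intensity(img)
  mu <- conv2_sep_valid(m, kern)
  list(mu = mu, e2 = conv2_sep_valid(m * m, kern), img = m, kern = kern)
}

ssim_from_moments <- function(ma, mb, params) {
  cross <- conv2_sep_valid(ma$img * mb$img, ma$kern)
  va <- ma$e2 - ma$mu^2
  vb <- mb$e2 - mb$mu^2
  cab <- cross - ma$mu * mb$mu
  num <- (2 * ma$mu * mb$mu + params$C1) * (2 * cab + params$C2)
  den <- (ma$mu^2 + mb$mu^2 + params$C1) * (va + vb + params$C2)
  mean(num / den)
}

#' Mean structural similarity between two grayscale images
#'
#' @param a,b intensity matrices (0..255) of identical size, each side at
#'   least `params$window_side`.
#' @param params an [ssim_params()] object.
#' @return The SSIM index, a number in \[-1, 1\] (1 for identical images).
#' @examples
#' a <- matrix(runif(256, 0, 255), 16)
#' mean_ssim(a, a)
#' @export
mean_ssim <- function(a, b, params = ssim_params()) {
  a <- as_intensity(a)
  b <- as_intensity(b)
  check_ssim_input(a, b, params)
  ssim_from_moments(ssim_moments(a, params), ssim_moments(b, params), params)
}

#' Structural dissimilarity (DSSIM) distance between two images
#'
#' `DSSIM = 1 - SSIM`, in \[0, 2\]: 0 between identical images, ~1 between
#' an all-black and an all-white image, and 2 in the limit of two perfectly
#' anti-correlated images of equal luminance. Symmetric in its arguments.
#'
#' @inheritParams mean_ssim
#' @return A number in \[0, 2\].
#' @export
dssim <- function(a, b, params = ssim_params()) {
  1 - mean_ssim(a, b, params)
}

#' Pairwise DSSIM distance matrix of a set of images
#'
#' Computes `dssim()` for every unordered pair and mirrors the result into a
#' symmetric matrix with zero diagonal. Per-image window moments are cached,
#' so each pair costs a single cross-moment convolution. Pairs are
#' independent; they are evaluated in a fixed order so the result is
#' deterministic.
#'
#' @param images list of equally-sized intensity matrices (e.g. from
#'   [cgr_encode()]); ids are taken from list names or `source_id`
#'   attributes.
#' @param params an [ssim_params()] object.
#' @param progress optional function called as `progress(done, total)` after
#'   each pair.
#' @return Symmetric numeric matrix with the ids as dimnames.
#' @export
pairwise_distances <- function(images, params = ssim_params(), progress = NULL) {
  n <- length(images)
  if (n < 2L) stop("need at least 2 images")
  ids <- names(images)
  if (is.null(ids)) {
    ids <- vapply(images, function(im) attr(im, "source_id") %||% NA_character_,
                  character(1))
    if (anyNA(ids)) ids <- paste0("img", seq_len(n))
  }
  dims <- vapply(images, dim, integer(2))
  if (any(dims != dims[, 1L])) {
    bad <- which(apply(dims != dims[, 1L], 2L, any))[1L]
    stop("image dimensions differ: '", ids[1L], "' is ",
         paste(dims[, 1L], collapse = "x"), " but '", ids[bad], "' is ",
         paste(dims[, bad], collapse = "x"))
  }
  moments <- lapply(images, ssim_moments, params = params)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  total <- n * (n - 1L) / 2L
  done <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- 1 - ssim_from_moments(moments[[i]], moments[[j]], params)
      D[i, j] <- d
      D[j, i] <- d
      done <- done + 1L
      if (!is.null(progress)) progress(done, total)
    }
  }
  D
}

#' Validate a DSSIM distance matrix
#'
#' Checks symmetry, zero diagonal, the \[0, 2\] range and the presence of
#' ids, returning the matrix invisibly.
#'
#' @param D square numeric matrix with dimnames.
#' @param tol tolerance for symmetry and diagonal checks.
#' @export
validate_distance_matrix <- function(D, tol = 1e-8) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (is.null(rownames(D))) stop("distance matrix must carry sequence ids")
  if (max(abs(D - t(D))) > tol) stop("distance matrix is not symmetric")
  if (max(abs(diag(D))) > tol) stop("distance matrix diagonal is not zero")
  if (min(D) < -tol || max(D) > 2 + tol) stop("distances must lie in [0, 2]")
  invisible(D)
}

#' Write / read a distance matrix as TSV
#'
#' Tab-separated square matrix with a header row and a first column of ids;
#' values are written at full float precision.
#'
#' @param D symmetric distance matrix with id dimnames.
#' @param path output path.
#' @return `path` (write) or the matrix (read).
#' @export
write_distance_matrix <- function(D, path) {
  validate_distance_matrix(D)
  df <- data.frame(id = rownames(D), D, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  D <- as.matrix(df[, -1L, drop = FALSE])
  rownames(D) <- df[[1L]]
  colnames(D) <- colnames(df)[-1L]
  storage.mode(D) <- "double"
  validate_distance_matrix(D)
  D
}

#' Write a distance matrix in PHYLIP square format
#'
#' First line holds the number of taxa; each following line an id padded to
#' 10 characters and the full row of distances, for interoperability with
#' phylogenetics tools.
#'
#' @param D symmetric distance matrix with id dimnames.
#' @param path output path.
#' @export
write_phylip_distances <- function(D, path) {
  validate_distance_matrix(D)
  lines <- c(
    sprintf("%5d", nrow(D)),
    vapply(seq_len(nrow(D)), function(i) {
      paste0(sprintf("%-10s", rownames(D)[i]),
             paste(sprintf("%.10f", D[i, ]), collapse = "  "))
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}
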