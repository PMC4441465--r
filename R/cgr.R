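# Chaos Game Representation of DNA sequences.
#
# Corner layout (unit square, y up): A = (0,0), C = (0,1), G = (1,1),
# T = (1,0) -- A, C, G, T clockwise starting from the bottom-left corner.
# The chaos game starts at the centre (0.5, 0.5) and each letter moves the
# current point halfway toward its corner. At raster resolution 2^k x 2^k
# every pixel corresponds bijectively to one k-mer: a pixel is black (0) iff
# its k-mer occurs in the sequence, else white (255).

cgr_corners <- function() {
  matrix(c(0, 0, # A
           0, 1, # C
           1, 1, # G
           1, 0  # T
  ), ncol = 2L, byrow = TRUE, dimnames = list(BASES, c("x", "y")))
}

#' Corner coordinates of a base in the CGR unit square
#'
#' @param base one of `"A"`, `"C"`, `"G"`, `"T"` (vectorized).
#' @return Matrix with columns `x`, `y` (y increases upward):
#'   A (0,0), C (0,1), G (1,1), T (1,0).
#' @export
cgr_corner <- function(base) {
  idx <- match(toupper(base), BASES)
  if (anyNA(idx)) stop("not a DNA base: ", base[which(is.na(idx))[1L]])
  cgr_corners()[idx, , drop = FALSE]
}

#' Chaos-game trajectory of a sequence
#'
#' Iterates the chaos game: starting from the centre `p0 = (0.5, 0.5)` (not
#' emitted), each residue `s_i` maps `p_i = (p_{i-1} + corner(s_i)) / 2`.
#' The trajectory is the verification oracle tying the iterative chaos game
#' to the k-mer raster of [cgr_encode()]; it is not used to rasterize.
#'
#' @param x residue string or one-row [seq_records] entry, non-empty.
#' @return Matrix with one row per residue and columns `x`, `y`.
#' @examples
#' cgr_trajectory("ACGT")
#' @export
cgr_trajectory <- function(x) {
  residues <- residues_of(x)
  if (nchar(residues) == 0L) stop("empty sequence has no trajectory")
  corners <- cgr_corner(strsplit(residues, "", fixed = TRUE)[[1]])
  # p_i = 0.5 * p_{i-1} + corner_i / 2 is a linear recursion
  px <- as.numeric(filter(corners[, "x"] / 2, 0.5, method = "recursive",
                          init = 0.5))
  py <- as.numeric(filter(corners[, "y"] / 2, 0.5, method = "recursive",
                          init = 0.5))
  cbind(x = px, y = py)
}

# x-bit: A,C -> 0; G,T -> 1 (right half of the square)
# y-bit: A,T -> 0; C,G -> 1 (upper half of the square)
xbit <- function(codes) as.integer(codes >= 2L)
ybit <- function(codes) as.integer(codes == 1L | codes == 2L)

#' Raster cell of a k-mer
#'
#' Maps each k-mer to its (row, col) pixel on the 2^k x 2^k CGR raster.
#' The letter at position `p` of the word contributes bit `2^(p-1)` to each
#' axis index, so the *last* letter selects the coarsest quadrant. Rows are
#' counted from the top of the raster (standard image convention); the
#' unit-square y axis points up, and the flip between the two lives here.
#' The map is a bijection between the 4^k words and the 4^k cells.
#'
#' @param word character vector of k-mers (all of length `k`).
#' @param k word length / resolution exponent.
#' @return Matrix with columns `row`, `col`, 0-based.
#' @examples
#' kmer_to_pixel(c("AC", "CG", "GT"), k = 2)
#' @export
kmer_to_pixel <- function(word, k) {
  if (any(nchar(word) != k)) {
    stop("word length must equal k = ", k, ": ", word[which(nchar(word) != k)[1L]])
  }
  codes <- lapply(strsplit(toupper(word), "", fixed = TRUE), function(ch) {
    idx <- match(ch, BASES)
    if (anyNA(idx)) stop("not a DNA word: ", paste(ch, collapse = ""))
    idx - 1L
  })
  w <- 2^(seq_len(k) - 1L)
  col <- vapply(codes, function(cd) sum(xbit(cd) * w), numeric(1))
  yidx <- vapply(codes, function(cd) sum(ybit(cd) * w), numeric(1))
  cbind(row = 2^k - 1 - yidx, col = col)
}

#' Encode a sequence as a CGR occurrence raster
#'
#' Builds the 2^k x 2^k image in which the pixel of every k-mer occurring as
#' a sliding window of the sequence is black (0) and all others are white
#' (255). Encoding enumerates the k-mer windows directly; the chaos-game
#' trajectory is used only as an independent oracle (the first k-1 trajectory
#' points carry the start-point transient and are deliberately not plotted).
#'
#' With `mode = "counts"` pixel intensity instead encodes log-scaled window
#' counts (darkest = most frequent); this grayscale variant is an extension
#' and not used by the distance pipeline defaults.
#'
#' @param x residue string or one-row [seq_records] entry.
#' @param k resolution exponent (image side 2^k); default 9 (512 x 512).
#' @param mode `"binary"` (occurrence, default) or `"counts"`.
#' @param id source id stored in the image (defaults to the record id).
#' @return Integer matrix of class `"cgr"` with intensities in 0..255 and
#'   attributes `k`, `source_id`. `occupied_count()` gives the number of
#'   black (occurring) pixels.
#' @examples
#' img <- cgr_encode("ACGT", k = 2)
#' occupied_count(img) # 3 distinct 2-mers
#' @export
cgr_encode <- function(x, k = 9, mode = c("binary", "counts"), id = NULL) {
  mode <- match.arg(mode)
  residues <- residues_of(x)
  if (is.null(id)) {
    id <- if (is.data.frame(x)) x$id else if (is.list(x) && !is.null(x$id)) x$id else NA_character_
  }
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  n <- nchar(residues)
  if (n < k) {
    stop("sequence ", if (!is.na(id)) paste0("'", id, "' ") else "",
         "is shorter (", n, ") than k = ", k)
  }
  codes <- base_codes(residues)
  xb <- xbit(codes)
  yb <- ybit(codes)
  n_win <- n - k + 1L
  col <- numeric(n_win)
  yidx <- numeric(n_win)
  for (j in 0:(k - 1L)) { # letter j+1 of each window, weight 2^j
    col <- col + xb[(1L + j):(n_win + j)] * 2^j
    yidx <- yidx + yb[(1L + j):(n_win + j)] * 2^j
  }
  side <- 2L^k
  row <- side - 1 - yidx
  pix <- matrix(255L, nrow = side, ncol = side)
  if (mode == "binary") {
    pix[cbind(row + 1, col + 1)] <- 0L
  } else {
    counts <- table(row * side + col)
    cell <- as.numeric(names(counts))
    # log-scaled counts mapped to darkness; max count -> 0, single hit -> dark grey
    shade <- 255L - as.integer(round(255 * log1p(as.numeric(counts)) /
                                       log1p(max(counts))))
    pix[cbind(cell %/% side + 1, cell %% side + 1)] <- shade
  }
  structure(pix, k = k, source_id = id, class = c("cgr", class(pix)))
}

#' Number of occupied (black) pixels of a CGR image
#' @param image a `"cgr"` image (or any intensity matrix).
#' @return Integer count of pixels with intensity 0.
#' @export
occupied_count <- function(image) sum(unclass(image) == 0L)

#' @export
print.cgr <- function(x, ...) {
  cat("CGR image ", nrow(x), "x", ncol(x), " (k = ", attr(x, "k"),
      "), source: ", attr(x, "source_id") %||% "<unnamed>",
      ", occupied pixels: ", occupied_count(x), "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Plot a CGR image
#' @param x a `"cgr"` image.
#' @param ... passed to [graphics::image()].
#' @export
plot.cgr <- function(x, ...) {
  m <- unclass(x)
  # transpose/flip so the raster appears with row 1 at the top
  graphics::image(t(m[nrow(m):1, , drop = FALSE]), col = gray.colors(256, 0, 1),
                  zlim = c(0, 255), axes = FALSE, asp = 1, ...)
  invisible(x)
}

#' Write a CGR image to a lossless grayscale file
#'
#' PNG (via the png package) and binary PGM (P5) are supported; both
#' round-trip the 8-bit pixel grid exactly.
#'
#' @param image a `"cgr"` image or intensity matrix (0..255).
#' @param path output path; format inferred from the extension when
#'   `format = "auto"`.
#' @param format `"auto"`, `"PNG"` or `"PGM"`.
#' @return `path`, invisibly.
#' @export
render_cgr <- function(image, path, format = c("auto", "PNG", "PGM")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     png = "PNG", pgm = "PGM",
                     stop("cannot infer image format from path: ", path))
  }
  m <- unclass(image)
  storage.mode(m) <- "integer"
  if (any(m < 0L | m > 255L)) stop("intensities must lie in 0..255")
  if (format == "PNG") {
    png::writePNG(m / 255, target = path)
  } else {
    con <- file(path, open = "wb")
    on.exit(close(con))
    header <- sprintf("P5\n%d %d\n255\n", ncol(m), nrow(m))
    writeBin(charToRaw(header), con)
    writeBin(as.raw(t(m)), con) # PGM is row-major from the top row
  }
  invisible(path)
}

#' Read a grayscale image written by [render_cgr()]
#'
#' @param path PNG or PGM file.
#' @return Integer intensity matrix (0..255).
#' @export
read_cgr_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    return(matrix(as.integer(round(m * 255)), nrow = nrow(m)))
  }
  if (ext != "pgm") stop("unsupported image format: ", path)
  bytes <- readBin(path, what = "raw", n = file.size(path))
  # header: "P5" <ws> width <ws> height <ws> maxval <single ws> data
  ws <- bytes %in% charToRaw(" \t\r\n")
  tok <- character(0)
  i <- 1L
  while (length(tok) < 4L && i <= length(bytes)) {
    while (i <= length(bytes) && ws[i]) i <- i + 1L
    j <- i
    while (j <= length(bytes) && !ws[j]) j <- j + 1L
    tok <- c(tok, rawToChar(bytes[i:(j - 1L)]))
    i <- j
  }
  if (!identical(tok[1L], "P5")) stop("not a binary PGM (P5) file: ", path)
  wd <- as.integer(tok[2L]); ht <- as.integer(tok[3L])
  if (as.integer(tok[4L]) != 255L) stop("only 8-bit PGM supported")
  data <- bytes[(i + 1L):(i + wd * ht)] # i is the single ws after maxval
  matrix(as.integer(data), nrow = ht, ncol = wd, byrow = TRUE)
}
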