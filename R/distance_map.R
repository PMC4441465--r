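#' Fit a Molecular Distance Map
#'
#' End-to-end alignment-free comparison of DNA sequences: each sequence is
#' encoded as a CGR occurrence raster ([cgr_encode()]), every pair of
#' rasters is compared with DSSIM ([pairwise_distances()]), and the distance
#' matrix is embedded by classical MDS ([classical_mds()]) with Kruskal
#' Stress-1 reporting ([stress1()]) and per-axis \[-1, 1\] scaling
#' ([scale_map()]). Spatial proximity on the resulting map reflects
#' similarity of k-mer composition; no alignment is involved, so sequences
#' of very different lengths and origins are comparable.
#'
#' @param x input sequences: a [seq_records] collection, a character vector
#'   of FASTA paths, or a precomputed symmetric distance matrix with id
#'   dimnames (skips the CGR/DSSIM stages).
#' @param k CGR resolution exponent; images are 2^k x 2^k and compare k-mer
#'   occurrence (default 9, i.e. 512 x 512).
#' @param q embedding dimension (default 2).
#' @param params SSIM parameters, see [ssim_params()].
#' @param metadata optional data frame with columns `id`, `name`, `group`
#'   used for plotting; matched to sequences by `id`.
#' @param keep_images keep the CGR rasters in the returned object.
#' @param progress optional `function(done, total)` progress hook for the
#'   pairwise stage.
#' @return An object of class `"distance_map"`: a list with `ids`, `coords`
#'   (scaled), `coords_unscaled`, `eigenvalues`, `stress1`, `regression`
#'   (`a`, `b`), `scaling_record`, `distances` (the DSSIM matrix),
#'   `seq_summary`, `metadata`, `k`, `q` and the matched `call`. Methods:
#'   `print`, `summary`, `plot`.
#' @examples
#' sim <- simulate_markov_family(2, 3, length = 2000, order = 1,
#'                               divergence = 0.8, seed = 1)
#' m <- distance_map(sim$records, k = 5, metadata = sim$metadata)
#' m
#' @export
distance_map <- function(x, k = 9, q = 2, params = ssim_params(),
                         metadata = NULL, keep_images = FALSE,
                         progress = NULL) {
  cl <- match.call()
  seq_summary <- NULL
  images <- NULL
  if (is.matrix(x) && is.numeric(x)) {
    validate_distance_matrix(x)
    D <- x
  } else {
    records <- if (is.character(x) && all(file.exists(x))) {
      do.call(rbind, lapply(x, read_fasta))
    } else {
      as_seq_records(x)
    }
    if (nrow(records) < 3L) stop("need at least 3 sequences, got ", nrow(records))
    images <- lapply(seq_len(nrow(records)), function(i) {
      cgr_encode(records[i, , drop = FALSE], k = k)
    })
    names(images) <- records$id
    seq_summary <- data.frame(
      id = records$id,
      length = nchar(records$residues),
      skipped_count = records$skipped_count,
      occupied_count = vapply(images, occupied_count, integer(1)),
      stringsAsFactors = FALSE
    )
    D <- pairwise_distances(images, params, progress = progress)
  }

  cfg <- classical_mds(D, q = q)
  st <- stress1(D, cfg)
  scaled <- scale_map(cfg)

  meta <- NULL
  if (!is.null(metadata)) {
    meta <- metadata[match(rownames(D), metadata$id), , drop = FALSE]
  }
  structure(
    list(ids = rownames(D),
         coords = scaled$coords,
         coords_unscaled = cfg$coords,
         eigenvalues = cfg$eigenvalues,
         stress1 = st$stress1,
         regression = c(a = st$a, b = st$b),
         scaling_record = scaled$scaling_record,
         distances = D,
         seq_summary = seq_summary,
         metadata = meta,
         images = if (keep_images) images else NULL,
         k = if (is.null(seq_summary)) NA_integer_ else k,
         q = q,
         call = cl),
    class = "distance_map"
  )
}

# mean over unordered pairs (diagonal excluded)
mean_pairwise_distance <- function(D) mean(D[upper.tri(D)])

#' @export
print.distance_map <- function(x, digits = 4, ...) {
  n <- length(x$ids)
  cat("Molecular Distance Map of ", n, " sequences",
      if (!is.na(x$k)) paste0(" (CGR k = ", x$k, ")"), "\n", sep = "")
  cat("  average DSSIM distance: ",
      format(round(mean_pairwise_distance(x$distances), digits), nsmall = digits),
      "\n", sep = "")
  cat("  MDS Stress-1 (", x$q, "D): ",
      format(round(x$stress1, digits), nsmall = digits),
      if (x$stress1 <= 0.2) "  [within the conventional 0.20 benchmark]",
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.distance_map <- function(object, ...) {
  D <- object$distances
  off <- D[upper.tri(D)]
  out <- list(
    n = length(object$ids),
    k = object$k,
    q = object$q,
    distance_min = min(off),
    distance_max = max(off),
    distance_mean = mean(off),
    stress1 = object$stress1,
    regression = object$regression,
    eigenvalues = head(object$eigenvalues, 10)
  )
  class(out) <- "summary.distance_map"
  out
}

#' @export
print.summary.distance_map <- function(x, ...) {
  cat("Molecular Distance Map summary\n")
  cat("  sequences:        ", x$n, "\n")
  if (!is.na(x$k)) cat("  CGR resolution:    2^", x$k, " = ",
                       2^x$k, " pixels per side\n", sep = "")
  cat("  DSSIM distances:   min ", format(round(x$distance_min, 4), nsmall = 4),
      ", mean ", format(round(x$distance_mean, 4), nsmall = 4),
      ", max ", format(round(x$distance_max, 4), nsmall = 4), "\n", sep = "")
  cat("  Stress-1 (", x$q, "D):     ",
      format(round(x$stress1, 4), nsmall = 4), "\n", sep = "")
  cat("  disparity fit:     f(delta) = ",
      signif(x$regression[["a"]], 4), " * delta + ",
      signif(x$regression[["b"]], 4), "\n", sep = "")
  cat("  leading eigenvalues:",
      paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Plot a Molecular Distance Map
#'
#' Scatter of the (scaled) first two map dimensions. When the object carries
#' metadata, points are coloured by `group` and the legend lists each group
#' with its sequence count in parentheses.
#'
#' @param x a `"distance_map"` object.
#' @param dims which two dimensions to draw (default `c(1, 2)`).
#' @param cex point size.
#' @param legend_pos legend position keyword, or `NA` to suppress.
#' @param ... passed to [graphics::plot.default()].
#' @export
plot.distance_map <- function(x, dims = c(1, 2), cex = 0.9,
                              legend_pos = "topright", ...) {
  coords <- x$coords[, dims, drop = FALSE]
  groups <- if (!is.null(x$metadata)) x$metadata$group else rep("all", length(x$ids))
  groups[is.na(groups)] <- "(unassigned)"
  lev <- sort(unique(groups))
  pal <- hcl.colors(max(length(lev), 2L), palette = "Dark 3")[seq_along(lev)]
  col <- pal[match(groups, lev)]
  plot.default(coords[, 1L], coords[, 2L], col = col, pch = 19, cex = cex,
               xlab = paste0("dimension ", dims[1L]),
               ylab = paste0("dimension ", dims[2L]),
               xlim = c(-1.05, 1.05), ylim = c(-1.05, 1.05), asp = 1, ...)
  if (!is.na(legend_pos) && length(lev) > 0L) {
    counts <- table(factor(groups, levels = lev))
    legend(legend_pos, legend = sprintf("%s (%d)", lev, as.integer(counts)),
           col = pal, pch = 19, cex = 0.8, bty = "n")
  }
  invisible(x)
}
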