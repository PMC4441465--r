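# End-to-end pipeline run with on-disk products and a run manifest.

#' Run the full FASTA -> CGR -> DSSIM -> MDS pipeline to an output directory
#'
#' Executes the stages in order and writes every product under `output_dir`:
#' `images/` (one lossless grayscale CGR per sequence, optional),
#' `distances.tsv` and `distances.phylip` (the DSSIM matrix),
#' `coords.tsv` (scaled map coordinates), `diagnostics.json` (eigenvalue
#' spectrum, Stress-1, disparity regression, scaling record),
#' `manifest.json` (tool version, resolved configuration, per-sequence and
#' matrix summaries, timestamps) and `map.png` (the plotted map, optional).
#' Reruns with the same inputs and configuration produce byte-identical
#' `distances.tsv` and `coords.tsv`.
#'
#' @param input FASTA path(s), a directory of FASTA files, or a
#'   [seq_records] collection.
#' @param output_dir directory for the run products (created if needed).
#' @param metadata optional metadata data frame or TSV path (columns `id`,
#'   `name`, `group`).
#' @param k CGR resolution exponent (default 9).
#' @param q MDS embedding dimension (default 2).
#' @param params SSIM parameters ([ssim_params()]).
#' @param seed integer recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters when the caller simulated the inputs).
#' @param write_images write per-sequence CGR images under `images/`.
#' @param image_format `"PGM"` (bit-exact reference) or `"PNG"`.
#' @param plot write `map.png`.
#' @param verbose log per-stage progress messages.
#' @return The fitted [distance_map()] object, invisibly, with the manifest
#'   attached as attribute `"manifest"`.
#' @export
run_map <- function(input, output_dir, metadata = NULL, k = 9, q = 2,
                    params = ssim_params(), seed = 0, write_images = TRUE,
                    image_format = c("PGM", "PNG"), plot = TRUE,
                    verbose = FALSE) {
  image_format <- match.arg(image_format)
  t0 <- Sys.time()
  say <- function(...) if (verbose) message("[cgrmap] ", ...)

  say("stage 1/4: reading sequences")
  records <- resolve_input(input)
  if (nrow(records) < 3L) {
    stop("pipeline needs at least 3 sequences after cleaning, got ",
         nrow(records))
  }
  short <- nchar(records$residues) < k
  if (any(short)) {
    stop("stage cgr: sequence '", records$id[which(short)[1L]],
         "' is shorter than k = ", k)
  }
  if (is.character(metadata) && length(metadata) == 1L) {
    metadata <- read_metadata(metadata)
  }

  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  say("stage 2/4: encoding ", nrow(records), " CGR images (k = ", k, ")")
  say("stage 3/4: pairwise DSSIM (", nrow(records) * (nrow(records) - 1) / 2,
      " pairs)")
  fit <- distance_map(records, k = k, q = q, params = params,
                      metadata = metadata, keep_images = TRUE,
                      progress = if (verbose) {
                        function(done, total) {
                          if (done %% 50L == 0L || done == total) {
                            say("  pair ", done, "/", total)
                          }
                        }
                      })

  say("stage 4/4: writing products to ", output_dir)
  if (write_images) {
    img_dir <- file.path(output_dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    ext <- tolower(image_format)
    for (id in names(fit$images)) {
      render_cgr(fit$images[[id]], file.path(img_dir, paste0(id, ".", ext)),
                 format = image_format)
    }
  }
  write_distance_matrix(fit$distances, file.path(output_dir, "distances.tsv"))
  write_phylip_distances(fit$distances, file.path(output_dir, "distances.phylip"))
  coords_df <- data.frame(id = fit$ids, fit$coords, check.names = FALSE,
                          stringsAsFactors = FALSE)
  write.table(coords_df, file.path(output_dir, "coords.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  diagnostics <- list(
    eigenvalues = fit$eigenvalues,
    stress1 = fit$stress1,
    regression = as.list(fit$regression),
    scaling_record = lapply(seq_len(ncol(fit$scaling_record)), function(j) {
      list(axis = colnames(fit$scaling_record)[j],
           min = fit$scaling_record["min", j],
           max = fit$scaling_record["max", j])
    })
  )
  jsonlite::write_json(diagnostics, file.path(output_dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  D <- fit$distances
  off <- D[upper.tri(D)]
  manifest <- list(
    tool = list(name = "cgrmap", version = as.character(packageVersion("cgrmap"))),
    config = list(k = k, q = q, seed = seed,
                  ssim = unclass(params)[c("window_side", "window_sigma",
                                           "K1", "K2", "L")],
                  border = "valid (windows fully inside the image)",
                  write_images = write_images, image_format = image_format,
                  plot = plot),
    sequences = fit$seq_summary,
    matrix = list(n = nrow(D), min_distance = min(off), max_distance = max(off),
                  mean_distance = mean(off)),
    stress1 = fit$stress1,
    warnings = character(0),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")

  if (plot) {
    png(file.path(output_dir, "map.png"), width = 900, height = 900, res = 120)
    plot(fit, main = sprintf("n = %d, mean DSSIM = %.4f, Stress-1 = %.2f",
                             nrow(D), mean(off), fit$stress1))
    dev.off()
  }
  say("done: n = ", nrow(D), ", mean DSSIM = ", round(mean(off), 4),
      ", Stress-1 = ", round(fit$stress1, 4))
  fit$images <- NULL
  attr(fit, "manifest") <- manifest
  invisible(fit)
}

resolve_input <- function(input) {
  if (inherits(input, "seq_records") || is.data.frame(input)) {
    return(as_seq_records(input))
  }
  if (is.character(input)) {
    paths <- unlist(lapply(input, function(p) {
      if (dir.exists(p)) {
        list.files(p, pattern = "\\.(fa|fasta|fna)$", full.names = TRUE)
      } else {
        p
      }
    }))
    if (length(paths) == 0L) stop("no FASTA files found in input")
    return(do.call(rbind, lapply(paths, read_fasta)))
  }
  stop("cannot interpret pipeline input")
}

resolve_matrix <- function(m) {
  if (is.character(m) && length(m) == 1L) m <- read_distance_matrix(m)
  validate_distance_matrix(m)
  m
}

lookup_id <- function(D, id) {
  ids <- rownames(D)
  if (!id %in% ids) {
    near <- agrep(id, ids, max.distance = 0.3, value = TRUE)
    stop("unknown sequence id '", id, "'",
         if (length(near)) paste0("; near matches: ",
                                  paste(head(near, 5), collapse = ", ")))
  }
  id
}

#' Look up one pairwise distance in a stored matrix
#'
#' @param matrix a distance matrix or the path of a `distances.tsv` file.
#' @param id_a,id_b sequence ids present in the matrix.
#' @return The stored distance (full precision); the 4-decimal display
#'   convention is applied by the CLI and by `print`.
#' @export
query_distance <- function(matrix, id_a, id_b) {
  D <- resolve_matrix(matrix)
  lookup_id(D, id_a)
  lookup_id(D, id_b)
  D[id_a, id_b]
}

#' Rank all sequences by distance from one sequence
#'
#' Ascending by distance, ties broken lexicographically by id; suitable for
#' plotting distance-from-reference curves.
#'
#' @param matrix a distance matrix or the path of a `distances.tsv` file.
#' @param id reference sequence id.
#' @return Data frame with columns `id`, `distance`, nearest first.
#' @export
rank_distances <- function(matrix, id) {
  D <- resolve_matrix(matrix)
  lookup_id(D, id)
  others <- setdiff(rownames(D), id)
  d <- D[id, others]
  ord <- order(d, others)
  data.frame(id = others[ord], distance = unname(d[ord]),
             stringsAsFactors = FALSE)
}
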