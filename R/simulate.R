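# Sequence randomization and synthetic-family simulation.
#
# The trinucleotide-preserving shuffle operates on the order-2 de Bruijn
# multigraph of a sequence: nodes are the 16 dinucleotides, and every
# overlapping trinucleotide XYZ contributes one edge XY -> YZ labelled Z.
# Any sequence with the same length and the same trinucleotide counts as the
# input is exactly an Eulerian path in this multigraph starting from the
# input's first dinucleotide, so sampling a uniform Eulerian path samples
# uniformly from the preserving randomizations.

BASES <- c("A", "C", "G", "T")

# dinucleotide node index 1..16 from two base codes (0..3)
dinuc_index <- function(b1, b2) 4L * b1 + b2 + 1L

base_codes <- function(residues) {
  match(strsplit(residues, "", fixed = TRUE)[[1]], BASES) - 1L
}

#' Shuffle a sequence preserving its trinucleotide counts exactly
#'
#' Produces a random sequence of identical length and identical overlapping
#' trinucleotide profile (see [trinucleotide_profile()]). The default method
#' draws a uniform random Eulerian path on the order-2 de Bruijn multigraph
#' of the input (nodes = dinucleotides, edges = trinucleotide occurrences),
#' with the start node fixed to the input's first dinucleotide: the
#' preservation is exact, not merely in expectation. The arborescence of
#' last-exit edges is sampled by Wilson's loop-erased random walk, so the
#' path is uniform without rejection.
#'
#' `method = "markov"` instead samples an order-2 Markov chain whose
#' transition probabilities are estimated from the input's trinucleotide
#' counts; it preserves the profile only in expectation and is provided for
#' comparison.
#'
#' @param x residue string or one-row [seq_records] entry, length >= 3.
#' @param seed integer seed; the output is deterministic given the seed.
#' @param method `"eulerian"` (exact preservation, default) or `"markov"`.
#' @return A single residue string of the same length as the input.
#' @examples
#' s <- shuffle_trinucleotides("ACGTACGTACGTAAATTTCCCGGG", seed = 1)
#' identical(trinucleotide_profile(s),
#'           trinucleotide_profile("ACGTACGTACGTAAATTTCCCGGG"))
#' @export
shuffle_trinucleotides <- function(x, seed = 0, method = c("eulerian", "markov")) {
  method <- match.arg(method)
  residues <- residues_of(x)
  n <- nchar(residues)
  if (n < 3L) stop("sequence too short to shuffle (length ", n, ", need >= 3)")
  set.seed(as.integer(seed))
  codes <- base_codes(residues)
  if (method == "markov") return(markov_resample(codes))
  eulerian_shuffle(codes)
}

eulerian_shuffle <- function(codes) {
  n <- length(codes)
  # edge multiplicities: cnt[u, z+1] = number of trinucleotides (node u, letter z)
  u_seq <- dinuc_index(codes[1:(n - 2L)], codes[2:(n - 1L)])
  z_seq <- codes[3:n]
  cnt <- matrix(0L, nrow = 16L, ncol = 4L)
  for (i in seq_along(u_seq)) {
    cnt[u_seq[i], z_seq[i] + 1L] <- cnt[u_seq[i], z_seq[i] + 1L] + 1L
  }
  s <- dinuc_index(codes[1L], codes[2L])
  t <- dinuc_index(codes[n - 1L], codes[n])
  # target node of edge (u = XY, letter z) is YZ
  targets <- matrix(0L, nrow = 16L, ncol = 4L)
  for (u in 1:16) {
    y <- (u - 1L) %% 4L
    targets[u, ] <- dinuc_index(rep(y, 4L), 0:3)
  }
  out_deg <- rowSums(cnt)
  active <- which(out_deg > 0L)

  # Wilson's algorithm: sample the arborescence of last exits toward t,
  # with probability proportional to the product of edge multiplicities.
  last_exit <- rep(NA_integer_, 16L) # letter code 0..3, for u != t
  if (length(setdiff(active, t)) > 0L) {
    intree <- rep(FALSE, 16L)
    intree[t] <- TRUE
    nxt <- rep(NA_integer_, 16L)
    for (u in setdiff(active, t)) {
      v <- u
      while (!intree[v]) {
        nxt[v] <- sample.int(4L, 1L, prob = cnt[v, ]) - 1L
        v <- targets[v, nxt[v] + 1L]
      }
      v <- u
      while (!intree[v]) {
        intree[v] <- TRUE
        v <- targets[v, nxt[v] + 1L]
      }
    }
    last_exit <- nxt
  }

  # Per-node exit order: uniform shuffle of the edge multiset, with the
  # arborescence edge forced last (for u != t).
  exits <- vector("list", 16L)
  for (u in active) {
    letters <- rep(0:3, times = cnt[u, ])
    if (u != t) {
      drop_at <- which(letters == last_exit[u])[1L]
      letters <- c(sample_vec(letters[-drop_at]), last_exit[u])
    } else {
      letters <- sample_vec(letters)
    }
    exits[[u]] <- letters
  }

  # Walk the Eulerian path from s, consuming each node's exits in order.
  out <- integer(n)
  out[1:2] <- codes[1:2]
  ptr <- rep(1L, 16L)
  cur <- s
  for (i in 3:n) {
    z <- exits[[cur]][ptr[cur]]
    ptr[cur] <- ptr[cur] + 1L
    out[i] <- z
    cur <- targets[cur, z + 1L]
  }
  paste(BASES[out + 1L], collapse = "")
}

# sample() without its length-1 surprise
sample_vec <- function(x) {
  if (length(x) <= 1L) x else x[sample.int(length(x))]
}

# Order-2 Markov resampling from the input's own trinucleotide counts.
markov_resample <- function(codes) {
  n <- length(codes)
  u_seq <- dinuc_index(codes[1:(n - 2L)], codes[2:(n - 1L)])
  z_seq <- codes[3:n]
  cnt <- matrix(0, nrow = 16L, ncol = 4L)
  for (i in seq_along(u_seq)) {
    cnt[u_seq[i], z_seq[i] + 1L] <- cnt[u_seq[i], z_seq[i] + 1L] + 1
  }
  marginal <- tabulate(z_seq + 1L, nbins = 4L)
  if (sum(marginal) == 0) marginal <- rep(1, 4L)
  out <- integer(n)
  out[1:2] <- codes[1:2]
  cur <- dinuc_index(codes[1L], codes[2L])
  for (i in 3:n) {
    p <- cnt[cur, ]
    if (sum(p) == 0) p <- marginal # context never seen with an exit
    z <- sample.int(4L, 1L, prob = p) - 1L
    out[i] <- z
    cur <- dinuc_index((cur - 1L) %% 4L, z)
  }
  paste(BASES[out + 1L], collapse = "")
}

#' Simulate families of Markov-generated DNA sequences
#'
#' Draws one random order-`order` Markov transition table per family and
#' samples sequences from it. Family tables are convex perturbations of a
#' shared base table: `T_f = (1 - divergence) * base + divergence * R_f`
#' with `base` and each `R_f` drawn independently from a flat Dirichlet per
#' context row. `divergence = 0` therefore gives every family the identical
#' generative law; `divergence = 1` gives fully independent laws.
#'
#' @param families number of families.
#' @param per_family sequences per family.
#' @param length sequence length in bases.
#' @param order Markov order, one of 0, 1, 2.
#' @param divergence in \[0, 1\]; how far family laws are pulled apart.
#' @param seed integer seed; output is fully reproducible.
#' @return List with `records` (a [seq_records] collection) and `metadata`
#'   (data frame with columns `id`, `name`, `group`; `group` is the family).
#' @examples
#' sim <- simulate_markov_family(2, 3, length = 500, order = 1,
#'                               divergence = 0.5, seed = 1)
#' table(sim$metadata$group)
#' @export
simulate_markov_family <- function(families, per_family, length,
                                   order = 2, divergence = 0.5, seed = 0) {
  stopifnot(families >= 1, per_family >= 1, length >= 1)
  order <- as.integer(order)
  if (!order %in% 0:2) stop("'order' must be 0, 1 or 2")
  if (divergence < 0 || divergence > 1) stop("'divergence' must be in [0, 1]")
  if (length <= order) stop("'length' must exceed the Markov order")
  set.seed(as.integer(seed))

  n_ctx <- 4L^order
  base <- dirichlet_rows(n_ctx)
  tables <- lapply(seq_len(families), function(f) {
    (1 - divergence) * base + divergence * dirichlet_rows(n_ctx)
  })

  ids <- character(0)
  seqs <- character(0)
  groups <- character(0)
  for (f in seq_len(families)) {
    cum <- t(apply(tables[[f]], 1L, cumsum))
    for (j in seq_len(per_family)) {
      ids <- c(ids, sprintf("fam%02d_seq%02d", f, j))
      groups <- c(groups, sprintf("family%02d", f))
      seqs <- c(seqs, sample_markov_chain(cum, length, order))
    }
  }
  records <- seq_records(ids, seqs)
  metadata <- data.frame(id = ids, name = ids, group = groups,
                         stringsAsFactors = FALSE)
  list(records = records, metadata = metadata)
}

dirichlet_rows <- function(n_ctx) {
  m <- matrix(rgamma(n_ctx * 4L, shape = 1), nrow = n_ctx)
  m / rowSums(m)
}

sample_markov_chain <- function(cum, length, order) {
  out <- integer(length)
  if (order > 0L) {
    out[seq_len(order)] <- sample.int(4L, order, replace = TRUE) - 1L
  }
  mod <- 4L^max(order - 1L, 0L)
  ctx <- 0L
  if (order > 0L) {
    for (i in seq_len(order)) ctx <- ctx * 4L + out[i]
  }
  u <- runif(length - order)
  for (i in (order + 1L):length) {
    row <- ctx + 1L
    z <- (u[i - order] > cum[row, 1L]) + (u[i - order] > cum[row, 2L]) +
      (u[i - order] > cum[row, 3L])
    out[i] <- z
    if (order > 0L) ctx <- (ctx %% mod) * 4L + z
  }
  paste(BASES[out + 1L], collapse = "")
}
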