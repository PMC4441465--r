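test_that("corners sit at A=(0,0), C=(0,1), G=(1,1), T=(1,0)", {
  expect_equal(unname(cgr_corner("A")), matrix(c(0, 0), 1))
  expect_equal(unname(cgr_corner("C")), matrix(c(0, 1), 1))
  expect_equal(unname(cgr_corner("G")), matrix(c(1, 1), 1))
  expect_equal(unname(cgr_corner("T")), matrix(c(1, 0), 1))
  expect_error(cgr_corner("N"), "not a DNA base")
})

test_that("the chaos game iterates halfway toward each corner from the centre", {
  expect_equal(cgr_trajectory("A"), cbind(x = 0.25, y = 0.25))
  # hand iteration of p_i = (p_{i-1} + corner) / 2 for "ACGT"
  expect_equal(cgr_trajectory("ACGT"),
               cbind(x = c(0.25, 0.125, 0.5625, 0.78125),
                     y = c(0.25, 0.625, 0.8125, 0.40625)))
  # repeated A contracts geometrically toward the A corner
  traj <- cgr_trajectory(strrep("A", 20))
  expect_equal(traj[, "x"], 0.5 * 2^-(1:20))
  expect_equal(traj[, "y"], 0.5 * 2^-(1:20))
  # agreement with the direct-loop oracle, and confinement to the unit square
  set.seed(5)
  for (i in 1:10) {
    s <- random_dna(200)
    traj <- cgr_trajectory(s)
    expect_equal(unname(traj), loop_trajectory(s), tolerance = 1e-12)
    expect_true(all(traj >= 0 & traj <= 1))
  }
  expect_error(cgr_trajectory(""), "empty")
})

test_that("k-mers map to the cells their trajectories end in", {
  expect_equal(kmer_to_pixel("A", 1), cbind(row = 1, col = 0))
  expect_equal(kmer_to_pixel(c("AC", "CG", "GT"), 2),
               cbind(row = c(1, 0, 2), col = c(0, 2, 3)))
  expect_error(kmer_to_pixel("ACG", 2), "length")
  # trajectory-quantization oracle on random words
  set.seed(13)
  for (i in 1:200) {
    k <- sample(2:8, 1)
    w <- random_dna(k)
    final <- loop_trajectory(w)[k, ]
    expect_equal(
      unname(kmer_to_pixel(w, k)),
      cbind(2^k - 1 - floor(2^k * final[2]), floor(2^k * final[1])),
      info = w
    )
  }
})

test_that("kmer_to_pixel is a bijection over the 4^k words", {
  bases <- c("A", "C", "G", "T")
  for (k in 1:4) {
    words <- apply(do.call(expand.grid, rep(list(bases), k)), 1, paste,
                   collapse = "")
    px <- kmer_to_pixel(words, k)
    expect_true(all(px >= 0 & px <= 2^k - 1))
    expect_equal(nrow(unique(px)), 4^k)
  }
})

test_that("cgr_encode marks exactly the occurring k-mers", {
  img <- cgr_encode("ACGT", k = 2)
  expect_s3_class(img, "cgr")
  expect_equal(dim(img), c(4L, 4L))
  expect_equal(occupied_count(img), 3L)
  blacks <- which(unclass(img) == 0L, arr.ind = TRUE) - 1L
  expect_equal(blacks[order(blacks[, "row"]), , drop = FALSE],
               cbind(row = c(0L, 1L, 2L), col = c(2L, 0L, 3L)),
               ignore_attr = TRUE)
  expect_error(cgr_encode(seq_records("tiny", "ACG"), k = 5), "tiny")
})

test_that("occupied pixels equal distinct k-mer counts and respect bounds", {
  set.seed(23)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    s <- random_dna(sample(k:800, 1))
    img <- cgr_encode(s, k = k)
    n_distinct <- length(unique(substring(s, 1:(nchar(s) - k + 1), k:nchar(s))))
    expect_equal(occupied_count(img), n_distinct)
    expect_lte(occupied_count(img), min(4^k, nchar(s) - k + 1))
  }
})

test_that("black pixels at resolution k imply black suffix pixels below k", {
  set.seed(31)
  for (i in 1:8) {
    s <- random_dna(400)
    for (k in 2:5) {
      words <- unique(substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))
      for (j in c(1, k - 1)) {
        sub_img <- cgr_encode(s, k = j)
        suffixes <- unique(substring(words, k - j + 1, k))
        px <- kmer_to_pixel(suffixes, j)
        expect_true(all(unclass(sub_img)[px + 1L] == 0L))
      }
    }
  }
})

test_that("appending residues never turns a black pixel white", {
  set.seed(37)
  s <- random_dna(300)
  longer <- paste0(s, random_dna(100))
  for (k in c(2, 4, 6)) {
    a <- unclass(cgr_encode(s, k = k))
    b <- unclass(cgr_encode(longer, k = k))
    expect_true(all(b[a == 0L] == 0L))
  }
})

test_that("count-weighted grayscale mode darkens frequent k-mers", {
  img <- cgr_encode(strrep("ACGT", 50), k = 2, mode = "counts")
  expect_true(all(img >= 0 & img <= 255))
  # the most frequent k-mers reach full black, absent ones stay white
  expect_true(any(img == 0L))
  expect_true(any(img == 255L))
})

test_that("rendered images round-trip bit-exactly through PGM and PNG", {
  imgs <- list(
    all_white = matrix(255L, 8, 8),
    acgt = unclass(cgr_encode("ACGT", k = 2)),
    random = random_image(32, seed = 3)
  )
  for (nm in names(imgs)) {
    for (fmt in c("pgm", "png")) {
      path <- withr::local_tempfile(fileext = paste0(".", fmt))
      render_cgr(imgs[[nm]], path)
      expect_equal(read_cgr_image(path), imgs[[nm]], ignore_attr = TRUE,
                   info = paste(nm, fmt))
    }
  }
  big <- random_image(512, seed = 4)
  path <- withr::local_tempfile(fileext = ".pgm")
  render_cgr(big, path, format = "PGM")
  expect_identical(read_cgr_image(path), big)
})
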