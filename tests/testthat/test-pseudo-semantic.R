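test_that("letter encoding bins |SCD| values onto the alphabet", {
  enc <- encoding_config()                 # 26 letters over [0, 0.52]
  expect_equal(encode_profile(rep(0, 5), enc), "AAAAA")
  expect_equal(encode_profile(0.21, enc), "K")      # floor(0.21/0.02) = 10
  expect_equal(encode_profile(0.52, enc), "Z")      # top edge -> last letter
  expect_equal(encode_profile(0.519999, enc), "Z")
  # concatenation order and length: 16-carbon sn-1 + 18-carbon sn-2
  s <- encode_profile(list(rep(0.2, 16), rep(0.3, 18)), enc)
  expect_equal(nchar(s), 34)
  expect_equal(substr(s, 1, 16), strrep("K", 16))
  # out-of-range values clamp with a warning
  expect_warning(sz <- encode_profile(c(0.1, 0.9), enc), "clamped")
  expect_equal(sz, "FZ")
  expect_error(encode_profile(numeric(), enc), "empty profile")
})

test_that("encoding is monotone: one bin width raises every letter", {
  enc <- encoding_config()
  set.seed(3)
  v <- runif(30, 0, 0.49)
  a <- strsplit(encode_profile(v, enc), "")[[1]]
  b <- strsplit(encode_profile(v + enc$bin_width, enc), "")[[1]]
  expect_true(all(match(b, LETTERS) > match(a, LETTERS)))
})

test_that("k-mer sets equal brute-force enumeration", {
  expect_setequal(kmer_set("ABCD", 2, 2), c("AB", "BC", "CD"))
  expect_setequal(kmer_set("AAAA", 2, 3), c("AA", "AAA"))
  expect_error(kmer_set("A", 2, 8), "short string")

  set.seed(41)
  for (i in 1:20) {
    s <- paste(sample(LETTERS[1:5], sample(10:40, 1), replace = TRUE),
               collapse = "")
    expect_setequal(kmer_set(s, 2, 8), brute_kmers(s, 2, 8))
  }
})

test_that("overlap coefficient handles identity, disjointness and containment", {
  expect_equal(overlap_coefficient(c("AB", "BC"), c("AB", "BC")), 1)
  expect_equal(overlap_coefficient(c("AB"), c("CD", "DE")), 0)
  expect_equal(overlap_coefficient(c("AB", "BC"), c("BC", "CD", "DE")), 0.5)
  # containment saturates at 1
  expect_equal(overlap_coefficient(c("AB", "BC"), c("AB", "BC", "CD")), 1)
  expect_error(overlap_coefficient(character(), "AB"), "empty set")
  set.seed(14)
  for (i in 1:10) {
    a <- sample(LETTERS, sample(2:10, 1))
    b <- sample(LETTERS, sample(2:10, 1))
    expect_identical(overlap_coefficient(a, b), overlap_coefficient(b, a))
  }
})

test_that("distance matrix matches element-wise brute force", {
  set.seed(8)
  strings <- vapply(1:3, function(i)
    paste(sample(LETTERS[1:6], 25, replace = TRUE), collapse = ""),
    character(1))
  D <- string_distance_matrix(strings)$d
  expect_equal(diag(D), rep(0, 3), ignore_attr = TRUE)
  expect_identical(D, t(D))
  for (i in 1:2) for (j in (i + 1):3) {
    a <- brute_kmers(strings[i], 2, 8)
    b <- brute_kmers(strings[j], 2, 8)
    expect_equal(D[i, j], 1 - sum(a %in% b) / min(length(a), length(b)))
  }
  # disjoint alphabets are at maximal distance
  D2 <- string_distance_matrix(c("ABABABAB", "CDCDCDCD"))$d
  expect_equal(D2[1, 2], 1)
  # a string against itself is at distance 0
  D3 <- string_distance_matrix(c("QRSTU", "QRSTU"))$d
  expect_equal(D3[1, 2], 0)
})

test_that("per-k averaging and duplicate removal are available", {
  s <- c(a = "ABCABC", b = "ABCDEF", b2 = "ABCDEF")
  Dk <- string_distance_matrix(s, pooling = "per_k")
  expect_true(all(Dk$d >= 0 & Dk$d <= 1))
  expect_identical(Dk$d, t(Dk$d))
  Dd <- string_distance_matrix(s, drop_duplicates = TRUE)
  expect_equal(nrow(Dd$d), 2)
})

test_that("t-SNE embedding is deterministic and respects tight groups", {
  set.seed(66)
  n <- 20
  grp <- rep(1:2, each = n / 2)
  D <- matrix(0.95, n, n)
  D[grp == 1, grp == 1] <- 0.05
  D[grp == 2, grp == 2] <- 0.05
  D <- D + matrix(runif(n * n, 0, 0.01), n, n)
  D <- (D + t(D)) / 2
  diag(D) <- 0

  e1 <- embed_2d(D, seed = 7, perplexity = 4)
  e2 <- embed_2d(D, seed = 7, perplexity = 4)
  expect_identical(e1$coords, e2$coords)

  # every embedded point has its nearest neighbour within its own group
  for (i in seq_len(n)) {
    d2 <- colSums((t(e1$coords) - e1$coords[i, ])^2)
    d2[i] <- Inf
    expect_equal(grp[which.min(d2)], grp[i])
  }

  expect_error(embed_2d(matrix(0, 3, 3), perplexity = 5),
               "configuration error")
})

test_that("silhouette reflects separation, indifference and bad groupings", {
  n <- 12
  grp <- rep(c("a", "b"), each = n / 2)
  D <- matrix(1, n, n)
  D[grp == "a", grp == "a"] <- 0
  D[grp == "b", grp == "b"] <- 0
  diag(D) <- 0
  expect_equal(cluster_quality(D, grp), 1)

  # all distances equal: no structure, silhouette exactly 0
  De <- matrix(0.7, n, n); diag(De) <- 0
  expect_equal(cluster_quality(De, grp), 0)

  expect_error(cluster_quality(D, rep("a", n)), "at least 2 groups")

  # permuted labels on structured distances hover near zero
  set.seed(10)
  perms <- replicate(20, cluster_quality(D, sample(grp)))
  expect_lt(max(abs(perms)), 0.5)
  expect_lt(abs(mean(perms)), 0.2)
})
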