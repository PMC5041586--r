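test_that("markersig concatenates copy numbers in marker order", {
  expect_identical(markersig(c(2, 1, 1)), "211")
  expect_identical(markersig(c(0, 0, 0)), "000")
  expect_identical(markersig(rev(c(2, 1, 1))), "112")
  expect_error(markersig(c(2, 12)), "delimiter")
  expect_identical(markersig(c(2, 12), delim = "-"), "2-12")
})

test_that("the genotype regex enumerates all per-marker haplotype values", {
  expect_identical(regex_pattern(c(2, 1, 1)), "(2|1|0)(1|0)(1|0)")
  expect_identical(regex_pattern(0), "(0)")
  expect_error(regex_pattern(c(1, 10)), "single-digit")
})

test_that("regex matching is equivalent to element-wise dominance", {
  set.seed(20)
  for (rep in 1:50) {
    n_m <- sample(1:6, 1)
    g <- sample(0:3, n_m, replace = TRUE)
    h <- sample(0:3, n_m, replace = TRUE)
    matches <- grepl(paste0("^", regex_pattern(g), "$"),
                     paste(h, collapse = ""))
    expect_identical(matches, all(h <= g))
  }
})

test_that("library matching returns exactly the dominated signatures", {
  lib <- suppressWarnings(haplotype_library(
    c("a", "b", "c"), rbind(c(1, 1, 0), c(1, 0, 1), c(2, 1, 1)),
    c("m1", "m2", "m3"), frequency = c(.4, .3, .01)))
  expect_identical(match_library(c(2, 1, 1), lib), 1:3)
  expect_length(match_library(c(0, 0, 0), lib), 0L)
  lib2 <- suppressWarnings(haplotype_library(
    "h", matrix(c(2, 0), 1), c("m1", "m2"), frequency = 1))
  expect_length(match_library(c(1, 1), lib2), 0L)
})

test_that("matrix subtraction yields the complementary signature", {
  expect_identical(complement(c(2, 1, 1), c(1, 1, 0)), c(1L, 0L, 1L))
  expect_identical(complement(c(2, 1, 1), c(2, 1, 1)), c(0L, 0L, 0L))
  expect_null(complement(c(1, 0), c(1, 1)))
})

test_that("pair enumeration ranks by combined frequency", {
  lib <- suppressWarnings(haplotype_library(
    c("a", "b", "c", "null"),
    rbind(c(1, 1, 0), c(1, 0, 1), c(2, 1, 1), c(0, 0, 0)),
    c("m1", "m2", "m3"), frequency = c(.4, .3, .01, .005)))
  pr <- enumerate_pairs(c(2, 1, 1), lib)
  expect_equal(nrow(pr), 2L)
  expect_equal(pr$haplotype_1, c("a", "c"))
  expect_equal(pr$haplotype_2, c("b", "null"))
  expect_equal(pr$combined_frequency, c(0.12, 5e-05))

  hom <- suppressWarnings(haplotype_library(
    "h", matrix(c(1, 1), 1), c("m1", "m2"), frequency = 0.5))
  ph <- enumerate_pairs(c(2, 2), hom)
  expect_equal(ph$haplotype_1, "h")
  expect_equal(ph$haplotype_2, "h")
  expect_equal(ph$combined_frequency, 0.25)

  lib3 <- suppressWarnings(haplotype_library(
    c("one", "two"), matrix(c(1, 2), 2, 1), "m1", frequency = c(.6, .4)))
  p3 <- enumerate_pairs(3L, lib3)
  expect_equal(nrow(p3), 1L)
  expect_setequal(c(p3$haplotype_1, p3$haplotype_2), c("one", "two"))
})

test_that("pair enumeration agrees with the brute-force oracle", {
  set.seed(77)
  for (rep in 1:150) {
    lib <- random_library(sample(2:12, 1), sample(1:6, 1))
    i <- sample(length(lib), 2, replace = TRUE)
    g <- lib$signatures[i[1], ] + lib$signatures[i[2], ]
    got <- enumerate_pairs(g, lib)
    want <- brute_force_pairs(g, lib)
    expect_identical(pair_key_set(got), pair_key_set(want))
    # conservation: every emitted pair sums exactly to the genotype
    for (r in seq_len(nrow(got))) {
      s <- lib$signatures[match(got$haplotype_1[r], lib$haplotype_id), ] +
           lib$signatures[match(got$haplotype_2[r], lib$haplotype_id), ]
      expect_identical(unname(s), unname(g))
    }
    # the generating pair is always reported
    truekey <- paste(sort(lib$haplotype_id[i]), collapse = "|")
    expect_true(truekey %in% pair_key_set(got))
  }
})

test_that("sample resolution partitions into resolved and unresolved", {
  lib <- suppressWarnings(haplotype_library(
    c("a", "b"), rbind(c(1, 0), c(0, 1)), c("m1", "m2"),
    frequency = c(.5, .5)))
  r <- resolve_sample(c(1, 1), lib, "S1")
  expect_equal(r$status, "RESOLVED")
  expect_equal(nrow(r$best), 1L)

  u <- resolve_sample(c(3, 0), lib, "S2")
  expect_equal(u$status, "UNRESOLVED")
  expect_identical(u$single_matches, "a")

  e <- resolve_sample(c(1, 1), suppressWarnings(haplotype_library(
    character(0), matrix(0L, 0, 2), c("m1", "m2"))), "S3")
  expect_equal(e$status, "UNRESOLVED")
  expect_length(e$single_matches, 0L)
})

test_that("tied best pairs are all reported", {
  lib <- suppressWarnings(haplotype_library(
    c("a", "b", "c", "d"),
    rbind(c(1, 0), c(0, 1), c(1, 1), c(0, 0)),
    c("m1", "m2"), frequency = c(.2, .2, .1, .4)))
  r <- resolve_sample(c(1, 1), lib, "S")
  expect_equal(nrow(r$pairs), 2L)           # {a,b} and {c,d}, both 0.04
  expect_equal(nrow(r$best), 2L)
})

test_that("the trio filter keeps transmissible pairs only", {
  child <- data.frame(haplotype_1 = c("a", "a"), haplotype_2 = c("b", "c"),
                      stringsAsFactors = FALSE)
  father <- data.frame(haplotype_1 = "a", haplotype_2 = "x")
  mother <- data.frame(haplotype_1 = "b", haplotype_2 = "y")
  kept <- pedigree_filter(child, father, mother)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$haplotype_2, "b")

  none <- pedigree_filter(child,
                          data.frame(haplotype_1 = "u", haplotype_2 = "v"),
                          mother)
  expect_equal(nrow(none), 0L)
})

test_that("simulated trios always keep the child's true pair", {
  lib <- fixture_library()
  set.seed(13)
  for (rep in 1:20) {
    f <- sample(length(lib), 2, replace = TRUE, prob = lib$frequency)
    m <- sample(length(lib), 2, replace = TRUE, prob = lib$frequency)
    ch <- c(sample(f, 1), sample(m, 1))
    gf <- lib$signatures[f[1], ] + lib$signatures[f[2], ]
    gm <- lib$signatures[m[1], ] + lib$signatures[m[2], ]
    gc <- lib$signatures[ch[1], ] + lib$signatures[ch[2], ]
    kept <- pedigree_filter(enumerate_pairs(gc, lib),
                            enumerate_pairs(gf, lib),
                            enumerate_pairs(gm, lib))
    truekey <- paste(sort(lib$haplotype_id[ch]), collapse = "|")
    expect_true(truekey %in% pair_key_set(kept))
  }
})

test_that("calls project onto library loci with consensus over region assays", {
  p <- kir_panel()
  lib <- fixture_library()
  calls <- data.frame(
    sample_id = "S1",
    marker_id = c("3DL1e4", "3DL1e9", "3DL2e4", "3DL2e9"),
    predicted_cn = c(2L, 2L, 1L, 2L), stringsAsFactors = FALSE)
  pr <- project_genotypes(calls, p, lib$markers)
  expect_equal(pr$genotypes["S1", "3DL1"], 2L)
  expect_true(is.na(pr$genotypes["S1", "3DL2"]))
  expect_equal(pr$blocked$marker, "3DL2")
})
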