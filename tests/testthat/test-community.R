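test_that("relative-abundance normalization is exact and idempotent", {
  counts <- toy_abundance(matrix(c(2, 3, 5), nrow = 3,
                                 dimnames = list(c("a", "b", "c"), "s1")))
  norm <- normalize_relative_abundance(counts)
  expect_equal(norm$abundance, c(20, 30, 50))

  single <- toy_abundance(matrix(7, 1, dimnames = list("a", "s1")))
  expect_equal(normalize_relative_abundance(single)$abundance, 100)

  expect_equal(normalize_relative_abundance(norm), norm)

  zero <- toy_abundance(matrix(c(1, 0), 1, dimnames = list("a", c("s1", "s2"))))
  expect_error(normalize_relative_abundance(zero), "s2")
})

test_that("archaea:bacteria ratios follow the abundance sums", {
  tax <- tibble::tibble(
    feature = c("a1", "a2", "b1", "b2", "x1"),
    domain = c("Archaea", "Archaea", "Bacteria", "Bacteria", "Eukaryota")
  )
  m <- matrix(c(25, 25, 25, 25, 0,
                70, 10, 15, 5, 0,
                40, 10, 20, 10, 20),
              nrow = 5,
              dimnames = list(tax$feature, c("s1", "s2", "s3")))
  tbl <- toy_abundance(m, sites = c(s1 = "A", s2 = "B", s3 = "B"))
  r <- archaea_bacteria_ratio(tbl, tax)
  expect_equal(r$ratio[r$sample == "s1"], 1)
  expect_equal(r$ratio[r$sample == "s2"], 4)
  expect_equal(r$ratio[r$sample == "s3"], 50 / 30) # "other" excluded
  expect_equal(r$other[r$sample == "s3"], 20)

  # invariant to feature order
  shuffled <- tbl[sample(nrow(tbl)), ]
  r2 <- archaea_bacteria_ratio(shuffled, tax)
  expect_equal(dplyr::arrange(r2, sample), dplyr::arrange(r, sample))

  # site means
  rs <- archaea_bacteria_ratio(tbl, tax, by = "site")
  expect_equal(rs$ratio[rs$site == "B"], mean(c(4, 50 / 30)))

  none <- toy_abundance(matrix(c(50, 50), 2,
                               dimnames = list(c("a1", "a2"), "s1")))
  expect_warning(rz <- archaea_bacteria_ratio(none, tax), "zero bacterial")
  expect_true(is.infinite(rz$ratio))
})

test_that("MAG quality filter uses inclusive bounds", {
  mags <- tibble::tibble(
    id = paste0("m", 1:5),
    completeness = c(90, 75, 60, 70, 95),
    contamination = c(1, 6, 0, 5, 4.9)
  )
  kept <- filter_mags(mags)
  expect_setequal(kept$id, c("m1", "m4", "m5"))
  expect_true("m4" %in% kept$id)  # exactly 70 / 5.0 kept
  expect_false("m3" %in% kept$id) # completeness below cutoff
})

test_that("species dereplication is single-linkage with inclusive thresholds", {
  mags <- tibble::tibble(
    id = c("A", "B", "C", "D"),
    completeness = c(80, 95, 90, 85),
    contamination = c(0, 4, 1, 0)
  )
  # chain A-B, B-C; D isolated; one edge exactly at the boundary
  pairs <- tibble::tibble(
    id1 = c("A", "B", "A"),
    id2 = c("B", "C", "D"),
    ani = c(95.0, 99, 94.9),
    coverage = c(10.0, 50, 60)
  )
  out <- dereplicate_species(mags, pairs)
  expect_equal(out$cluster[out$id == "A"], out$cluster[out$id == "B"])
  expect_equal(out$cluster[out$id == "B"], out$cluster[out$id == "C"])
  expect_false(out$cluster[out$id == "D"] == out$cluster[out$id == "A"])

  # brute-force connected components oracle
  adj <- matrix(FALSE, 4, 4, dimnames = list(mags$id, mags$id))
  for (k in seq_len(nrow(pairs))) {
    if (pairs$ani[k] >= 95 && pairs$coverage[k] >= 10) {
      adj[pairs$id1[k], pairs$id2[k]] <- TRUE
      adj[pairs$id2[k], pairs$id1[k]] <- TRUE
    }
  }
  reach <- diag(4) > 0 | adj
  for (r in 1:4) reach <- reach | (reach %*% reach) > 0
  oracle_same <- outer(seq_len(4), seq_len(4),
                       Vectorize(function(i, j) reach[i, j]))
  got_same <- outer(out$cluster, out$cluster, "==")
  expect_equal(unname(got_same), unname(oracle_same))

  # representative maximizes completeness - 5 * contamination
  cl <- out$cluster[out$id == "A"]
  reps <- out$id[out$representative & out$cluster == cl]
  expect_equal(reps, "C") # scores: A 80, B 75, C 85

  # no edges at all: every MAG its own species
  lone <- dereplicate_species(mags, pairs[0, ])
  expect_equal(length(unique(lone$cluster)), 4)
  expect_true(all(lone$representative))
})

test_that("specialized MAGs need mean abundance strictly above 10% in a site", {
  m <- matrix(c(18, 2, 10,
                16, 4, 10,
                1, 9, 10,
                3, 11, 10),
              nrow = 3,
              dimnames = list(c("magA", "magB", "magC"),
                              c("s1", "s2", "s3", "s4")))
  tbl <- toy_abundance(m, sites = c(s1 = "X", s2 = "X", s3 = "Y", s4 = "Y"))
  sel <- select_specialized_mags(tbl)
  # site means: magA X=17 Y=2; magB X=3 Y=10; magC constant 10 (strict >)
  expect_setequal(sel, "magA")

  # brute-force recomputation of the rule
  oracle <- character(0)
  for (f in rownames(m)) {
    for (s in c("X", "Y")) {
      cols <- if (s == "X") c("s1", "s2") else c("s3", "s4")
      if (mean(m[f, cols]) > 10) oracle <- union(oracle, f)
    }
  }
  expect_setequal(sel, oracle)
})

test_that("Bray-Curtis matches the hand formula and its axioms", {
  two <- toy_abundance(matrix(c(1, 2, 3, 2, 2, 1), nrow = 3,
                              dimnames = list(c("f1", "f2", "f3"),
                                              c("s1", "s2"))))
  d <- bray_curtis(two)
  expect_equal(d["s1", "s2"], 3 / 11, tolerance = 1e-12)

  same <- toy_abundance(matrix(c(5, 5, 5, 5), nrow = 2,
                               dimnames = list(c("f1", "f2"), c("s1", "s2"))))
  expect_equal(bray_curtis(same)["s1", "s2"], 0)

  disjoint <- toy_abundance(matrix(c(10, 0, 0, 10), nrow = 2,
                                   dimnames = list(c("f1", "f2"),
                                                   c("s1", "s2"))))
  expect_equal(bray_curtis(disjoint)["s1", "s2"], 1)

  withr::with_seed(12, {
    m <- matrix(runif(40, 0, 10), nrow = 8,
                dimnames = list(paste0("f", 1:8), paste0("s", 1:5)))
    tbl <- toy_abundance(m)
    d <- bray_curtis(tbl)
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0 & d <= 1))
    # independent double-loop recomputation of the formula
    oracle <- matrix(0, 5, 5)
    for (i in 1:5) for (j in 1:5) {
      oracle[i, j] <- sum(abs(m[, i] - m[, j])) / sum(m[, i] + m[, j])
    }
    expect_equal(unname(d), oracle, tolerance = 1e-12)
    # invariance to feature permutation (sample order realigned)
    d2 <- bray_curtis(tbl[sample(nrow(tbl)), ])
    expect_equal(d2[rownames(d), colnames(d)], d)
  })
})
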