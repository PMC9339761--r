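test_that("per-population diversity matches hand-evaluated formulas", {
  # two identical individuals: no diversity
  counts1 <- matrix(c(2L), 1, 1, dimnames = list("H1", "P1"))
  states <- matrix("A", 1, 1, dimnames = list("H1", NULL))
  info <- data.frame(locus = "l1", kind = "substitution", start = 1, end = 1,
                     length_bp = 1, stringsAsFactors = FALSE)
  cat1 <- catalog_from_counts(counts1, data.frame(
    population = "P1", species = "sp1", latitude = 0, longitude = 0),
    states = states, info = info, L = 100L)
  d1 <- population_diversity(cat1)
  expect_equal(d1$h, 1L)
  expect_equal(d1$Hd, 0)
  expect_equal(d1$pi, 0)

  # two different haplotypes, one substitution, L = 100
  counts2 <- matrix(c(1L, 1L), 2, 1, dimnames = list(c("H1", "H2"), "P1"))
  states2 <- matrix(c("A", "G"), 2, 1, dimnames = list(c("H1", "H2"), NULL))
  cat2 <- catalog_from_counts(counts2, data.frame(
    population = "P1", species = "sp1", latitude = 0, longitude = 0),
    states = states2, info = info, L = 100L)
  d2 <- population_diversity(cat2)
  expect_equal(d2$Hd, 1)
  expect_equal(d2$pi, 0.01)

  # n = 4 with counts (2, 2): Hd = (4/3)(1 - 1/2)
  counts3 <- matrix(c(2L, 2L), 2, 1, dimnames = list(c("H1", "H2"), "P1"))
  cat3 <- catalog_from_counts(counts3, data.frame(
    population = "P1", species = "sp1", latitude = 0, longitude = 0),
    states = states2, info = info, L = 100L)
  expect_equal(population_diversity(cat3)$Hd, 2 / 3, tolerance = 1e-12)
})

test_that("hS/hT behave at the fixation and identical-population limits", {
  cnt <- matrix(c(10L, 0L, 0L, 10L), 2, 2,
                dimnames = list(c("H1", "H2"), c("P1", "P2")))
  r <- multi_population_diversity(cnt)
  expect_equal(r$hS, 0)
  expect_gt(r$hT, 0)

  # identical internal composition: hT approaches hS at n = 50
  cnt2 <- matrix(c(25L, 25L, 25L, 25L), 2, 2,
                 dimnames = list(c("H1", "H2"), c("P1", "P2")))
  r2 <- multi_population_diversity(cnt2)
  expect_lt(abs(r2$hT - r2$hS), 0.02)
})

test_that("hS/hT/GST/NST match the loop-written oracle to 1e-9", {
  set.seed(101)
  for (rep in 1:5) {
    K <- sample(3:8, 1)
    H <- sample(3:6, 1)
    cnt <- matrix(rpois(H * K, 3) + 1L, H, K,
                  dimnames = list(paste0("H", 1:H), paste0("P", 1:K)))
    d <- matrix(sample(1:5, H * H, TRUE), H, H,
                dimnames = list(rownames(cnt), rownames(cnt)))
    d[lower.tri(d)] <- t(d)[lower.tri(d)]
    diag(d) <- 0
    got <- differentiation(cnt, d, n_perm = 0)
    want <- oracle_hs_ht(cnt, d)
    expect_equal(got$hS, want$hS, tolerance = 1e-9)
    expect_equal(got$hT, want$hT, tolerance = 1e-9)
    expect_equal(got$gst, want$gst, tolerance = 1e-9)
    expect_equal(got$nst, want$nst, tolerance = 1e-9)
  }
})

test_that("GST and NST respect their structural invariants", {
  cnt <- matrix(c(10L, 0L, 0L, 10L), 2, 2,
                dimnames = list(c("H1", "H2"), c("P1", "P2")))
  d <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("H1", "H2"), c("H1", "H2")))
  r <- differentiation(cnt, d, n_perm = 0)
  expect_equal(r$gst, 1)
  expect_equal(r$nst, 1)

  # constant inter-haplotype distances carry no extra signal: NST = GST
  set.seed(33)
  cnt2 <- matrix(rpois(4 * 5, 2) + 1L, 4, 5,
                 dimnames = list(paste0("H", 1:4), paste0("P", 1:5)))
  dc <- matrix(3, 4, 4, dimnames = list(rownames(cnt2), rownames(cnt2)))
  diag(dc) <- 0
  r2 <- differentiation(cnt2, dc, n_perm = 0)
  expect_equal(r2$nst, r2$gst, tolerance = 1e-12)

  # GST invariant to haplotype relabeling; NST invariant to distance scaling
  d4 <- matrix(sample(1:4, 16, TRUE), 4, 4)
  d4[lower.tri(d4)] <- t(d4)[lower.tri(d4)]; diag(d4) <- 0
  dimnames(d4) <- dimnames(dc)
  r3 <- differentiation(cnt2, d4, n_perm = 0)
  perm <- c(3, 1, 4, 2)
  r4 <- differentiation(cnt2[perm, ], d4[perm, perm], n_perm = 0)
  expect_equal(r4$gst, r3$gst, tolerance = 1e-12)
  r5 <- differentiation(cnt2, d4 * 7, n_perm = 0)
  expect_equal(r5$nst, r3$nst, tolerance = 1e-12)

  # duplicating every individual moves the estimates only by the bias term
  r6 <- differentiation(cnt2 * 2L, d4, n_perm = 0)
  expect_equal(r6$gst, r3$gst, tolerance = 0.05)
  expect_equal(r6$nst, r3$nst, tolerance = 0.05)
})

test_that("populations below the size floor are excluded with a warning", {
  cnt <- matrix(c(5L, 5L, 1L, 0L, 4L, 6L), 2, 3,
                dimnames = list(c("H1", "H2"), c("P1", "P2", "P3")))
  expect_warning(r <- multi_population_diversity(cnt), "n < 2")
  expect_equal(r$K, 2L)
  expect_error(suppressWarnings(multi_population_diversity(
    matrix(c(1L, 0L, 1L, 1L), 2, 2,
           dimnames = list(c("H1", "H2"), c("P1", "P2"))))),
    "at least 2")
})

test_that("diversity-vs-coordinate regressions flag flat and perfect fits", {
  ps <- data.frame(population = paste0("P", 1:6), h = 1L,
                   Hd = rep(0.5, 6), pi = NA_real_)
  co <- data.frame(population = paste0("P", 1:6),
                   latitude = seq(20, 45, length.out = 6),
                   longitude = seq(100, 120, length.out = 6))
  tr <- suppressWarnings(geo_trend(ps, co, measures = "Hd"))
  expect_true(all(tr$p_value == 1))

  ps2 <- ps; ps2$Hd <- 2 * co$latitude
  tr2 <- suppressWarnings(geo_trend(ps2, co, measures = "Hd"))
  lin <- tr2[tr2$predictor == "latitude" & tr2$form == "linear", ]
  expect_equal(lin$r_squared, 1, tolerance = 1e-9)
  expect_lt(lin$p_value, 1e-9)

  co3 <- co; co3$latitude <- 30
  expect_error(suppressWarnings(geo_trend(ps2, co3, measures = "Hd")),
               "constant predictor")
})
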