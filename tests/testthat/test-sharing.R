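test_that("gene identity follows the normalised-identity definition", {
  expect_equal(gene_identity(c(.5, .5, 0), c(.5, .5, 0)), 1)
  expect_equal(gene_identity(c(1, 0), c(0, 1)), 0)
  expect_equal(gene_identity(c(.5, .5, 0), c(.5, 0, .5)), 0.5)
  expect_equal(gene_identity(c(.5, .5, 0), c(.5, 0, .5), method = "raw"), 0.25)
  expect_true(is.na(gene_identity(c(0, 0), c(1, 0))))
})

test_that("haplotype exclusion removes carriers and empty populations", {
  cnt <- matrix(c(4L, 0L, 2L, 2L, 0L, 3L), 2, 3,
                dimnames = list(c("H1", "H2"), c("P1", "P2", "P3")))
  ct <- toy_catalog(cnt, species = c("spA", "spB", "spA"))
  red <- exclude_haplotype(ct, "H1")
  expect_false("P1" %in% red$pops$population)  # fixed for H1: dropped
  expect_equal(unname(red$counts["H2", "P2"]), 2L)
  expect_equal(red$pops$n, c(2L, 3L))

  # excluding a label nobody carries is a no-op
  red2 <- exclude_haplotype(ct, "H99")
  expect_equal(red2$counts, ct$counts)

  cnt3 <- matrix(c(4L, 0L, 0L, 3L), 2, 2,
                 dimnames = list(c("H1", "H2"), c("P1", "P2")))
  ct3 <- toy_catalog(cnt3, species = c("spA", "spB"))
  expect_error(exclude_haplotype(ct3, "H1"), "empties an entire species")
})

test_that("wilcoxon rank-sum matches hand counts and handles degeneracy", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcoxon_rank_sum(c(2, 2, 2), c(2, 2, 2)), 1)
})

test_that("exact wilcoxon equals exhaustive enumeration up to n = 8", {
  set.seed(19)
  for (rep in 1:6) {
    na <- sample(3:8, 1); nb <- sample(3:8, 1)
    x <- sample(seq(0.01, 0.99, by = 0.01), na)
    y <- sample(setdiff(seq(0.01, 0.99, by = 0.01), x), nb)
    expect_equal(wilcoxon_rank_sum(x, y), oracle_wilcoxon(x, y),
                 tolerance = 1e-12, info = paste("rep", rep))
  }
})

test_that("pair grouping respects the strict 300-km threshold and G1 within G2", {
  cnt <- matrix(c(3L, 1L, 0L, 2L, 2L, 0L, 0L, 0L, 4L, 1L, 0L, 3L), 3, 4,
                dimnames = list(c("H1", "H2", "H3"),
                                c("P1", "P2", "P3", "P4")))
  # species alternate along a line of longitude; adjacent pops ~96 km apart
  ct <- toy_catalog(cnt, species = c("spA", "spB", "spA", "spB"),
                    lon = c(100, 101, 108, 109))
  pr <- pair_identities(ct, threshold_km = 300)
  expect_true(all(pr$species_x != pr$species_y))
  expect_true(all(pr$group[pr$distance_km < 300] == "G2"))
  expect_true(all(pr$group[pr$distance_km >= 300] == "G3"))
  # G1 pairs (sharing) all have positive identity
  expect_true(all(pr$J[pr$group == "G2" & pr$shares_any] > 0))

  st <- sharing_test(ct, threshold_km = 300)
  tb <- st$table[st$table$species_pair == "all", ]
  expect_lte(tb$N1, tb$N2)
  # raising the threshold never decreases N2
  tb2 <- sharing_test(ct, threshold_km = 500)$table
  expect_gte(tb2$N2[tb2$species_pair == "all"], tb$N2)
})

test_that("identical compositions give unit identities and a flat test", {
  cnt <- matrix(rep(c(2L, 2L), 4), 2, 4,
                dimnames = list(c("H1", "H2"), paste0("P", 1:4)))
  ct <- toy_catalog(cnt, species = c("spA", "spB", "spA", "spB"),
                    lon = c(100, 101, 110, 111))
  tb <- sharing_test(ct)$table
  row <- tb[tb$species_pair == "all", ]
  expect_equal(row$M1, 1)
  expect_equal(row$M2, 1)
  expect_equal(row$M3, 1)
  expect_equal(row$P23, 1)
})

test_that("pooled records equal the union of species-pair records", {
  ds <- simulate_dataset(sim_params(seed = 31, introgression_rate = 0.5))
  ct <- truth_catalog(ds)
  st <- sharing_test(ct)
  tb <- st$table
  pooled <- tb[tb$species_pair == "all", ]
  parts <- tb[tb$species_pair != "all", ]
  expect_equal(pooled$N2, sum(parts$N2))
  expect_equal(pooled$N3, sum(parts$N3))
  expect_equal(nrow(st$pairs), pooled$N2 + pooled$N3)
  expect_false(any(duplicated(st$pairs[, c("pop_x", "pop_y")])))
})

test_that("sharing-pair enumeration reports shared labels at close range", {
  cnt <- matrix(c(3L, 1L, 0L, 2L, 2L, 0L, 0L, 2L, 2L), 3, 3,
                dimnames = list(c("H1", "H5", "H7"), c("P1", "P2", "P3")))
  ct <- toy_catalog(cnt, species = c("spA", "spB", "spB"),
                    lon = c(100, 101, 115))
  pr <- enumerate_sharing_pairs(ct, threshold_km = 300)
  expect_equal(nrow(pr), 1L)
  expect_setequal(strsplit(pr$shared, ",")[[1]], c("H1", "H5"))

  pr2 <- enumerate_sharing_pairs(ct, threshold_km = 300, exclude_label = c("H1", "H5"))
  expect_equal(nrow(pr2), 0L)

  cnt0 <- matrix(c(3L, 0L, 0L, 2L), 2, 2,
                 dimnames = list(c("H1", "H2"), c("P1", "P2")))
  ct0 <- toy_catalog(cnt0, species = c("spA", "spB"), lon = c(100, 101))
  expect_equal(nrow(enumerate_sharing_pairs(ct0, 300)), 0L)
})
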