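test_that("substitution calling codes polymorphic base columns only", {
  expect_equal(ncol(call_substitutions(aln_from_strings(c("ACGT", "ACGT")))$states), 0L)

  ch <- call_substitutions(aln_from_strings(c("ACGT", "ACCT")))
  expect_equal(ch$info$start, 3L)
  expect_setequal(unique(ch$states[, 1]), c("G", "C"))

  # N recorded as missing, column still coded
  ch2 <- call_substitutions(aln_from_strings(c("AAAA", "AAAA", "AGAA", "ANAA")))
  expect_equal(ncol(ch2$states), 1L)
  expect_equal(unname(ch2$states[, 1]), c("A", "A", "G", NA))

  # base-vs-gap columns belong to indels, not substitutions
  ch3 <- call_substitutions(aln_from_strings(c("AC-T", "ACGT")))
  expect_equal(ncol(ch3$states), 0L)
})

test_that("simple gap coding treats indels as single events with nesting rules", {
  ch <- code_indels(aln_from_strings(c("ACGTACGT", "ACG--CGT")))
  expect_equal(ncol(ch$states), 1L)
  expect_equal(ch$info$start, 4L)
  expect_equal(ch$info$end, 5L)
  expect_equal(ch$info$length_bp, 2L)
  expect_equal(unname(ch$states[, 1]), c("A", "T"))

  ch2 <- code_indels(aln_from_strings(c("ACGTACGT", "ACG--CGT", "ACG--CGT")))
  expect_equal(ncol(ch2$states), 1L)
  expect_equal(unname(ch2$states[, 1]), c("A", "T", "T"))

  # a gap strictly containing another indel leaves the bearer missing for
  # the contained character; the two indels are distinct characters
  ch3 <- code_indels(aln_from_strings(c("ACGTACGT", "ACG--CGT", "AC----GT")))
  expect_equal(ncol(ch3$states), 2L)
  co <- ch3$info[order(ch3$info$start), ]
  wide <- which(ch3$info$start == 3L)
  narrow <- which(ch3$info$start == 4L)
  expect_equal(unname(ch3$states[, narrow]), c("A", "T", NA))
  expect_equal(unname(ch3$states[, wide]), c("A", NA, "T"))
})

test_that("mononucleotide-repeat masking suppresses length variation only", {
  # homopolymer length variation is not coded as an indel
  a <- aln_from_strings(c("AAAAAAGT", "AAAA--GT"))
  mask <- mask_mononucleotide_repeats(a, 5L)
  expect_true(all(mask[1:6]))
  expect_false(any(mask[7:8]))
  expect_equal(ncol(code_indels(a, mask)$states), 0L)

  expect_false(any(mask_mononucleotide_repeats(
    aln_from_strings(c("ACGTACGT", "ACGTACGT")), 5L)))

  # a substitution inside a run remains callable
  a2 <- aln_from_strings(c("TAAAAAAAG", "TAAAGAAAG"))
  ch <- code_alignment(a2, mask_min_run = 5L)
  expect_equal(ncol(ch$states), 1L)
  expect_equal(ch$info$kind, "substitution")
})

test_that("inversion detection rewrites the minority orientation", {
  base <- "ACTTGACGTA"
  inv <- paste0(substr(base, 1, 2),
                paste(rev_comp(strsplit(substr(base, 3, 6), "")[[1]]), collapse = ""),
                substr(base, 7, 10))
  res <- apply_inversion(aln_from_strings(c(base, base, inv)), c(3, 6))
  expect_equal(ncol(res$characters$states), 1L)
  expect_equal(unname(res$characters$states[, 1]), c("A", "A", "T"))
  # the inverted row is rewritten to the majority orientation
  expect_equal(unname(res$alignment[3, ]), unname(res$alignment[1, ]))

  same <- apply_inversion(aln_from_strings(c(base, base)), c(3, 6))
  expect_equal(ncol(same$characters$states), 0L)
  expect_equal(unname(same$alignment[1, ]), strsplit(base, "")[[1]])

  expect_error(apply_inversion(aln_from_strings(c(base, base)), c(8, 20)),
               "out of bounds")
})

test_that("haplotype collapsing is deterministic, exact and tie-stable", {
  a <- aln_from_strings(c("ACGT", "ACGT", "AGGT", "AGGT"), "l1",
                        c("a", "b", "c", "d"))
  tb <- pops_df(c("a", "b", "c", "d"), c("P1", "P1", "P2", "P2"))
  ds <- cp_dataset(list(a), tb)
  cat <- collapse_haplotypes(code_loci(ds), ds$populations)
  # tie on counts: first-seen state vector takes H1
  expect_equal(unname(cat$assignment$haplotype[1]), "H1")
  expect_equal(nrow(cat$counts), 2L)
  expect_equal(sum(cat$counts), 4L)

  a3 <- aln_from_strings(rep("ACGT", 3), "l1", c("a", "b", "c"))
  ds3 <- cp_dataset(list(a3), pops_df(c("a", "b", "c"), "P1"))
  cat3 <- collapse_haplotypes(code_loci(ds3), ds3$populations)
  expect_equal(nrow(cat3$counts), 1L)
  expect_equal(unname(rowSums(cat3$counts)), 3L)
})

test_that("individuals with missing states are excluded with a warning", {
  a <- aln_from_strings(c("ACGT", "AGGT", "ANGT"), "l1", c("a", "b", "c"))
  ds <- cp_dataset(list(a), pops_df(c("a", "b", "c"), "P1"))
  expect_warning(cat <- collapse_haplotypes(code_loci(ds), ds$populations),
                 "excluded")
  expect_equal(cat$excluded, "c")
  expect_equal(sum(cat$counts), 2L)
})

test_that("a user-supplied label map renames frequency-ranked labels", {
  a <- aln_from_strings(c("ACGT", "ACGT", "AGGT"), "l1", c("a", "b", "c"))
  ds <- cp_dataset(list(a), pops_df(c("a", "b", "c"), "P1"))
  cat <- collapse_haplotypes(code_loci(ds), ds$populations,
                             label_map = c(H1 = "Hap_common", H2 = "Hap_rare"))
  expect_setequal(rownames(cat$counts), c("Hap_common", "Hap_rare"))
  expect_equal(unname(rowSums(cat$counts)["Hap_common"]), 2L)
})

test_that("dropping a monomorphic column never changes the catalog", {
  set.seed(11)
  base <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
  v <- strsplit(base, "")[[1]]
  v2 <- v; v2[7] <- setdiff(c("A", "C", "G", "T"), v[7])[1]
  ids <- paste0("i", 1:6)
  strings <- c(base, base, paste(v2, collapse = ""), base,
               paste(v2, collapse = ""), base)
  tb <- pops_df(ids, rep(c("P1", "P2"), each = 3))
  ds <- cp_dataset(list(aln_from_strings(strings, "l1", ids)), tb)
  cm <- code_loci(ds)
  cat1 <- collapse_haplotypes(cm, ds$populations)
  # appending an invariant column to the alignment adds no character
  strings_b <- paste0(strings, "A")
  ds_b <- cp_dataset(list(aln_from_strings(strings_b, "l1", ids)), tb)
  cm_b <- code_loci(ds_b)
  expect_equal(ncol(cm_b$states), ncol(cm$states))
  cat2 <- collapse_haplotypes(cm_b, ds_b$populations)
  expect_equal(cat1$counts, cat2$counts)
})
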