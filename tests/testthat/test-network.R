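test_that("hamming distances count every coded character as one step", {
  st <- rbind(a = c("A", "A", "A"), b = c("A", "A", "A"))
  expect_equal(unname(hamming_matrix(st)["a", "b"]), 0L)
  st2 <- rbind(a = c("A", "C", "G", "T"), b = c("T", "C", "C", "A"))
  expect_equal(unname(hamming_matrix(st2)[1, 2]), 3L)

  set.seed(3)
  m <- matrix(sample(c("A", "T"), 5 * 7, TRUE), 5, 7,
              dimnames = list(paste0("h", 1:5), NULL))
  d <- hamming_matrix(m)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(d[i, j], sum(m[i, ] != m[j, ]))
  }
  m[2, 3] <- NA
  expect_error(hamming_matrix(m), "missing")
})

test_that("minimum spanning network keeps all tied links", {
  d2 <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  e <- minimum_spanning_network(d2)
  expect_equal(nrow(e), 1L)

  d3 <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(d3) <- 0
  expect_equal(nrow(minimum_spanning_network(d3)), 3L)  # full tie triangle
})

test_that("MSN equals the union of exhaustively enumerated MSTs", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 6
    d <- matrix(0L, n, n, dimnames = list(paste0("h", 1:n), paste0("h", 1:n)))
    vals <- sample(1:4, n * (n - 1) / 2, TRUE)
    d[upper.tri(d)] <- vals
    d <- d + t(d)
    got <- msn_edge_keys(minimum_spanning_network(d), rownames(d))
    expect_equal(got, oracle_msn(d), info = paste("seed", seed))
  }
})

test_that("median joining adds hand-verified medians and prunes degree-2 ones", {
  # median of the triplet already observed: star, no node added
  st <- rbind(h1 = c("0", "0", "0"), h2 = c("0", "0", "1"), h3 = c("0", "1", "0"))
  net <- median_joining(st)
  expect_equal(sum(!net$observed), 0L)
  expect_equal(nrow(net$edges), 2L)
  expect_setequal(net$edges$from == "h1" | net$edges$to == "h1", TRUE)

  # 110/101/011: the majority median 111 completes a star
  st2 <- rbind(h1 = c("1", "1", "0"), h2 = c("1", "0", "1"), h3 = c("0", "1", "1"))
  net2 <- median_joining(st2)
  expect_equal(sum(!net2$observed), 1L)
  mv <- rownames(net2$states)[!net2$observed]
  expect_equal(unname(net2$states[mv, ]), c("1", "1", "1"))
  expect_equal(nrow(net2$edges), 3L)
  expect_true(all(net2$edges$mutations == 1L))
})

test_that("a planted star genealogy yields a star network on the ancestor", {
  k <- 6
  anc <- rep("A", k)
  st <- rbind(anc = anc)
  for (i in 1:k) {
    tip <- anc; tip[i] <- "T"
    st <- rbind(st, tip)
  }
  rownames(st) <- c("anc", paste0("t", 1:k))
  net <- median_joining(st)
  expect_equal(sum(!net$observed), 0L)
  expect_equal(nrow(net$edges), k)
  expect_true(all(net$edges$from == "anc" | net$edges$to == "anc"))
})

test_that("the MJ network displays the observed-haplotype MSN", {
  set.seed(21)
  m <- matrix(sample(c("A", "T"), 7 * 9, TRUE, prob = c(.7, .3)), 7, 9,
              dimnames = list(paste0("h", 1:7), NULL))
  m <- m[!duplicated(apply(m, 1, paste, collapse = "")), ]
  net <- median_joining(m)
  msn <- minimum_spanning_network(hamming_matrix(m))
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE)
  for (k in seq_len(nrow(msn))) {
    sp <- igraph::distances(g, msn$from[k], msn$to[k],
                            weights = igraph::E(g)$mutations)
    expect_equal(unname(sp[1, 1]), msn$weight[k])
  }
  # a duplicated haplotype row is merged and never changes topology
  net2 <- median_joining(rbind(m, dup = m[1, ]))
  expect_equal(nrow(net2$edges), nrow(net$edges))
  expect_equal(sum(net2$observed), sum(net$observed))
})

test_that("edge mutation counts equal endpoint Hamming distances", {
  set.seed(5)
  m <- matrix(sample(c("A", "G", "T"), 6 * 8, TRUE), 6, 8,
              dimnames = list(paste0("h", 1:6), NULL))
  m <- m[!duplicated(apply(m, 1, paste, collapse = "")), ]
  net <- median_joining(m)
  d <- hamming_matrix(net$states)
  for (k in seq_len(nrow(net$edges))) {
    expect_equal(net$edges$mutations[k], d[net$edges$from[k], net$edges$to[k]])
  }
  # every median vector has degree >= 3 after pruning
  deg <- table(c(net$edges$from, net$edges$to))
  mv <- rownames(net$states)[!net$observed]
  if (length(mv)) expect_true(all(deg[mv] >= 3))
})

test_that("diagnostic characters cut the network into labelled lineages", {
  st <- rbind(a = c("A", "A"), b = c("G", "A"), c = c("G", "T"))
  colnames(st) <- c("ch1", "ch2")
  net <- median_joining(st)
  part <- cut_lineages(net, "ch1", labels = c("L1", "L2"))
  expect_equal(unname(unclass(part)[c("a", "b", "c")]), c("L1", "L2", "L2"))

  part0 <- cut_lineages(net, character(0))
  expect_equal(length(unique(unclass(part0))), 1L)

  stm <- st; stm[, 2] <- "A"
  netm <- median_joining(stm)
  expect_error(cut_lineages(netm, "ch2"), "monomorphic")
})

test_that("planted lineage diagnostics recover the generator partition", {
  ds <- simulate_dataset(sim_params(seed = 60))
  ct <- collapse_haplotypes(code_loci(ds), ds$populations)
  net <- median_joining(ct)
  info <- ct$info
  diag_chars <- colnames(ct$states)[
    (info$kind == "substitution" & info$locus == "locusA" &
       info$start == ds$truth$pool$diag_substitution) |
      (info$kind == "indel" & info$length_bp == 8L)]
  expect_equal(length(diag_chars), 2L)
  part <- cut_lineages(net, diag_chars)
  obs <- names(part)[net$observed]
  # map observed haplotypes back to generator labels via individuals
  truth_of <- ds$truth$assignment$haplotype[
    match(ct$assignment$individual_id, ds$truth$assignment$individual_id)]
  pool_hap <- ds$truth$pool$haplotypes
  hap_lineage <- vapply(obs, function(h) {
    gen_labels <- unique(truth_of[ct$assignment$haplotype == h])
    lineages <- unique(pool_hap$lineage[pool_hap$label %in% gen_labels])
    expect_equal(length(lineages), 1L)
    lineages
  }, "")
  # the cut components coincide with the planted lineages
  tab <- table(unclass(part)[obs], hap_lineage)
  expect_equal(nrow(tab), 3L)
  expect_true(all(rowSums(tab > 0) == 1L))
  expect_true(all(colSums(tab > 0) == 1L))
})
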