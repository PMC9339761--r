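# Fixtures built in code and independent oracle implementations used across
# the suite. Oracles are literal loop transcriptions of the published
# formulas, kept free of any code shared with the package internals.

aln_from_strings <- function(strings, locus = "loc1", ids = NULL) {
  if (is.null(ids)) ids <- paste0("i", seq_along(strings))
  m <- do.call(rbind, strsplit(toupper(strings), ""))
  rownames(m) <- ids
  cp_alignment(m, locus)
}

write_fasta_tmp <- function(strings, ids = NULL) {
  if (is.null(ids)) ids <- paste0("i", seq_along(strings))
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), strings)), path)
  path
}

pops_df <- function(ids, pop, species = "sp1", lat = 30, lon = 110) {
  data.frame(individual_id = ids, population_code = pop, species = species,
             latitude = lat, longitude = lon, stringsAsFactors = FALSE)
}

# small catalog straight from a count matrix (populations on a line of
# longitude so inter-population distances are easy to reason about)
toy_catalog <- function(counts, species = NULL, lon = NULL) {
  P <- ncol(counts)
  if (is.null(species)) species <- rep(c("spA", "spB"), length.out = P)
  if (is.null(lon)) lon <- 100 + seq_len(P)
  catalog_from_counts(counts, data.frame(
    population = colnames(counts), species = species,
    latitude = rep(30, P), longitude = lon, stringsAsFactors = FALSE))
}

# ---- oracle: multi-population gene diversity (explicit loops) ----------

oracle_hs_ht <- function(counts, d = NULL) {
  K <- ncol(counts)
  n <- colSums(counts)
  hk <- numeric(K)
  vk <- numeric(K)
  for (k in 1:K) {
    x <- counts[, k] / n[k]
    s <- 0
    v <- 0
    for (i in seq_along(x)) for (j in seq_along(x)) {
      if (i != j) s <- s + x[i] * x[j]
      if (!is.null(d) && i != j) v <- v + x[i] * x[j] * d[i, j]
    }
    hk[k] <- n[k] / (n[k] - 1) * s
    vk[k] <- n[k] / (n[k] - 1) * v
  }
  hS <- unname(mean(hk))
  vS <- unname(mean(vk))
  xbar <- rowSums(sweep(counts, 2, n, "/")) / K
  ntil <- K / sum(1 / n)
  hT <- unname(1 - sum(xbar^2) + hS / (K * ntil))
  out <- list(hS = hS, hT = hT, gst = (hT - hS) / hT)
  if (!is.null(d)) {
    vT <- 0
    for (i in seq_along(xbar)) for (j in seq_along(xbar)) {
      vT <- vT + xbar[i] * xbar[j] * d[i, j]
    }
    vT <- unname(vT + vS / (K * ntil))
    out$vS <- vS; out$vT <- vT; out$nst <- (vT - vS) / vT
  }
  out
}

# ---- oracle: AMOVA via individual-level loops and an EMS linear solve ---

oracle_amova3 <- function(hap, pop, sp, d) {
  d2 <- d[hap, hap]^2
  N <- length(hap)
  pops <- unique(pop)
  sps <- unique(sp)
  ss_within <- function(members) {
    if (length(members) < 2) return(0)
    s <- 0
    for (a in members) for (b in members) s <- s + d2[a, b]
    s / (2 * length(members))
  }
  ss_tot <- ss_within(1:N)
  ss_wp <- sum(sapply(pops, function(p) ss_within(which(pop == p))))
  ss_wg <- sum(sapply(sps, function(g) ss_within(which(sp == g))))
  SS <- c(ag = ss_tot - ss_wg, ap = ss_wg - ss_wp, wp = ss_wp)
  P <- length(pops); G <- length(sps)
  df <- c(ag = G - 1, ap = P - G, wp = N - P)
  MS <- SS / df
  n_p <- sapply(pops, function(p) sum(pop == p))
  names(n_p) <- pops
  sp_of_pop <- sapply(pops, function(p) unique(sp[pop == p]))
  N_g <- sapply(sps, function(g) sum(sp == g))
  A <- sum(sapply(sps, function(g) {
    sum(n_p[sp_of_pop == g]^2) / N_g[which(sps == g)]
  }))
  n1 <- (N - A) / df["ap"]
  n2 <- (A - sum(n_p^2) / N) / df["ag"]
  n3 <- (N - sum(N_g^2) / N) / df["ag"]
  # E[MS] = coef %*% (sigma_a, sigma_b, sigma_c); solve numerically
  coef <- rbind(c(n3, n2, 1),
                c(0, n1, 1),
                c(0, 0, 1))
  vc <- solve(coef, MS)
  names(vc) <- c("a", "b", "c")
  list(SS = SS, df = df, vc = vc,
       F_CT = vc["a"] / sum(vc),
       F_SC = vc["b"] / (vc["b"] + vc["c"]),
       F_ST = (vc["a"] + vc["b"]) / sum(vc))
}

# ---- oracle: spatial autocorrelation r by literal transcription ---------

oracle_autocorr <- function(d2, geo, width, n_classes) {
  n <- nrow(d2)
  C <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    C[i, j] <- -0.5 * (d2[i, j] - mean(d2[i, ]) - mean(d2[, j]) + mean(d2))
  }
  r <- rep(NA_real_, n_classes)
  for (h in 1:n_classes) {
    num <- 0; den <- 0; npair <- 0
    for (i in 1:n) for (j in 1:n) {
      if (i == j) next
      cls <- floor(geo[i, j] / width) + 1
      if (cls != h) next
      num <- num + C[i, j]
      den <- den + C[i, i]
      npair <- npair + 1
    }
    if (npair > 0 && den != 0) r[h] <- num / den
  }
  r
}

# ---- oracle: union of all minimum spanning trees by Prufer enumeration --

oracle_msn <- function(d) {
  n <- nrow(d)
  stopifnot(n >= 3, n <= 6)
  seqs <- as.matrix(expand.grid(rep(list(1:n), n - 2)))
  best <- Inf
  union_edges <- character()
  for (row in seq_len(nrow(seqs))) {
    prufer <- seqs[row, ]
    degree <- rep(1, n)
    for (v in prufer) degree[v] <- degree[v] + 1
    edges <- matrix(0L, n - 1, 2)
    deg <- degree
    avail <- rep(TRUE, n)
    pseq <- prufer
    for (k in seq_along(pseq)) {
      leaf <- min(which(avail & deg == 1))
      edges[k, ] <- c(leaf, pseq[k])
      deg[leaf] <- deg[leaf] - 1
      deg[pseq[k]] <- deg[pseq[k]] - 1
      avail[leaf] <- FALSE
    }
    last <- which(avail & deg == 1)
    edges[n - 1, ] <- last
    w <- sum(d[edges])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]),
                 sep = "-")
    if (w < best - 1e-9) {
      best <- w
      union_edges <- key
    } else if (abs(w - best) <= 1e-9) {
      union_edges <- union(union_edges, key)
    }
  }
  sort(union_edges)
}

msn_edge_keys <- function(edges, nodes) {
  i <- match(edges$from, nodes)
  j <- match(edges$to, nodes)
  sort(paste(pmin(i, j), pmax(i, j), sep = "-"))
}

# ---- oracle: exact two-sided Mann-Whitney by exhaustive enumeration -----

oracle_wilcoxon <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  nb <- length(b)
  u_of <- function(av, bv) sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  u_obs <- u_of(a, b)
  sets <- combn(length(pooled), na)
  us <- apply(sets, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  mu <- na * nb / 2
  # two-sided: double the smaller tail, capped at 1
  p_lo <- mean(us <= u_obs + 1e-9)
  p_hi <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}
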