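#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Distance-based variance decomposition over haplotypic data, two-level
#' (among/within populations) or three-level (among species, among
#' populations within species, within populations). Sums of squares are
#' computed from squared inter-individual distances (`d^2`, with `d` the
#' coded mutation count between haplotypes): the within-group sum of squared
#' distances over all pairs divided by the group size. Variance components
#' come from the expected mean squares with the usual unequal-sample-size
#' coefficients; negative components are reported as computed (with a
#' warning), not zeroed, and the percentages of variation use the signed
#' total. Fixation indices: `F_CT = VC_a / V`, `F_SC = VC_b / (VC_b +
#' VC_c)`, `F_ST = (VC_a + VC_b) / V` (three-level) or `F_ST = VC_a / V`
#' (two-level).
#'
#' Permutation p-values (default 10,000 permutations, +1 correction):
#' `F_ST` (two-level) permutes individuals among populations; `F_CT`
#' permutes whole populations among species; `F_SC` permutes individuals
#' among populations within species; three-level `F_ST` permutes individuals
#' among all populations.
#'
#' @param catalog A `haplotype_catalog`, or a data frame like
#'   `catalog$assignment` (columns `haplotype`, `population`, and optionally
#'   `species`).
#' @param d Inter-haplotype distance matrix (mutation counts); defaults to
#'   the catalog's Hamming matrix. Distances are squared internally.
#' @param three_level Use the species stratum (default: yes when a `species`
#'   column with >1 level is present).
#' @param n_perm Permutations for the significance tests (default 10,000; 0
#'   skips them).
#' @param seed Optional RNG seed.
#' @return A `haplo_amova`: list with `table` (source, df, SS, VC, PV),
#'   `indices` (named vector of fixation indices), `p_values`, `n_perm`.
#' @export
amova <- function(catalog, d = NULL, three_level = NULL, n_perm = 10000L,
                  seed = NULL) {
  if (inherits(catalog, "haplotype_catalog")) {
    if (is.null(d)) d <- hamming_matrix(catalog)
    asg <- catalog$assignment
  } else {
    asg <- as.data.frame(catalog)
  }
  stopifnot(!is.null(d), all(c("haplotype", "population") %in% names(asg)))
  if (is.null(three_level)) {
    three_level <- "species" %in% names(asg) && length(unique(asg$species)) > 1L
  }
  d2 <- d^2
  hap <- match(asg$haplotype, rownames(d2))
  if (anyNA(hap)) stop("haplotype absent from distance matrix")
  pop <- factor(asg$population)
  if (nlevels(pop) < 2L) stop("need at least 2 populations")
  if (!is.null(seed)) set.seed(seed)
  if (three_level) {
    sp <- factor(asg$species)
    if (nlevels(sp) < 2L) stop("a stratum with <2 units: single species")
    pops_per_sp <- rowSums(table(sp, pop) > 0L)
    if (any(pops_per_sp < 2L)) stop("a stratum with <2 units: species with one population")
    res <- amova3_fit(hap, pop, sp, d2, nrow(d2))
    p <- c(F_CT = NA_real_, F_SC = NA_real_, F_ST = NA_real_)
    if (n_perm > 0L) {
      p["F_CT"] <- amova_perm(n_perm, res$indices["F_CT"], function() {
        # permute whole populations among species (keep pop composition)
        pop_sp <- tapply(as.integer(sp), pop, function(v) v[1L])
        perm_sp <- setNames(sample(unname(pop_sp)), names(pop_sp))
        sp_new <- factor(levels(sp)[perm_sp[as.character(pop)]], levels = levels(sp))
        amova3_fit(hap, pop, sp_new, d2, nrow(d2))$indices["F_CT"]
      })
      p["F_SC"] <- amova_perm(n_perm, res$indices["F_SC"], function() {
        # permute individuals among populations within each species
        idx <- seq_along(hap)
        for (s in levels(sp)) {
          sel <- which(sp == s)
          idx[sel] <- sel[sample.int(length(sel))]
        }
        amova3_fit(hap[idx], pop, sp, d2, nrow(d2))$indices["F_SC"]
      })
      p["F_ST"] <- amova_perm(n_perm, res$indices["F_ST"], function() {
        idx <- sample.int(length(hap))
        amova3_fit(hap[idx], pop, sp, d2, nrow(d2))$indices["F_ST"]
      })
    }
  } else {
    res <- amova2_fit(hap, pop, d2, nrow(d2))
    p <- c(F_ST = NA_real_)
    if (n_perm > 0L) {
      p["F_ST"] <- amova_perm(n_perm, res$indices["F_ST"], function() {
        idx <- sample.int(length(hap))
        amova2_fit(hap[idx], pop, d2, nrow(d2))$indices["F_ST"]
      })
    }
  }
  if (any(res$table$VC < 0)) {
    warning("negative variance component(s) reported as computed")
  }
  structure(list(table = res$table, indices = res$indices, p_values = p,
                 n_perm = n_perm), class = "haplo_amova")
}

amova_perm <- function(n_perm, obs, fn) {
  if (is.na(obs)) return(NA_real_)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    v <- fn()
    if (!is.na(v) && v >= obs) exceed <- exceed + 1L
  }
  (exceed + 1L) / (n_perm + 1L)
}

# Sum over unordered individual pairs of squared distance within one group,
# divided by group size, computed from haplotype counts: SS_g = c' D2 c / (2 n).
ss_group <- function(cnt, d2) {
  n <- sum(cnt)
  as.numeric(t(cnt) %*% d2 %*% cnt) / (2 * n)
}

hap_counts_by <- function(hap, grp, n_hap) {
  m <- vapply(split(hap, grp), function(h) tabulate(h, n_hap), numeric(n_hap))
  if (is.null(dim(m))) m <- matrix(m, nrow = n_hap, dimnames = list(NULL, names(m)))
  m
}

amova2_fit <- function(hap, pop, d2, n_hap) {
  N <- length(hap)
  P <- nlevels(pop)
  cnt_p <- hap_counts_by(hap, pop, n_hap)   # n_hap x P
  n_p <- colSums(cnt_p)
  cnt_t <- rowSums(cnt_p)
  ss_total <- ss_group(cnt_t, d2)
  ss_wp <- sum(vapply(seq_len(P), function(k) ss_group(cnt_p[, k], d2), 0))
  ss_ap <- ss_total - ss_wp
  df_ap <- P - 1L
  df_wp <- N - P
  ms_wp <- ss_wp / df_wp
  ms_ap <- ss_ap / df_ap
  n_prime <- (N - sum(n_p^2) / N) / df_ap
  vc_c <- ms_wp
  vc_a <- (ms_ap - ms_wp) / n_prime
  tot <- vc_a + vc_c
  fst <- if (tot == 0) NA_real_ else vc_a / tot
  table <- data.frame(
    source = c("Among populations", "Within populations"),
    df = c(df_ap, df_wp), SS = c(ss_ap, ss_wp), VC = c(vc_a, vc_c),
    PV = 100 * c(vc_a, vc_c) / tot, stringsAsFactors = FALSE)
  list(table = table, indices = c(F_ST = fst))
}

amova3_fit <- function(hap, pop, sp, d2, n_hap) {
  N <- length(hap)
  P <- nlevels(droplevels(pop))
  G <- nlevels(droplevels(sp))
  cnt_p <- hap_counts_by(hap, pop, n_hap)
  n_p <- colSums(cnt_p)
  pop_sp <- tapply(as.character(sp), pop, function(v) v[1L])  # species of each pop
  cnt_t <- rowSums(cnt_p)
  ss_total <- ss_group(cnt_t, d2)
  ss_wp <- sum(vapply(seq_len(ncol(cnt_p)), function(k) ss_group(cnt_p[, k], d2), 0))
  sp_levels <- unique(pop_sp)
  cnt_g <- vapply(sp_levels, function(s) {
    rowSums(cnt_p[, pop_sp == s, drop = FALSE])
  }, numeric(n_hap))
  N_g <- colSums(cnt_g)
  ss_wg <- sum(vapply(seq_along(sp_levels), function(g) ss_group(cnt_g[, g], d2), 0))
  ss_ag <- ss_total - ss_wg
  ss_apwg <- ss_wg - ss_wp
  df_ag <- G - 1L
  df_apwg <- P - G
  df_wp <- N - P
  ms_wp <- ss_wp / df_wp
  ms_apwg <- ss_apwg / df_apwg
  ms_ag <- ss_ag / df_ag
  sum_np2_by_g <- vapply(sp_levels, function(s) {
    sum(n_p[pop_sp == s]^2) / sum(n_p[pop_sp == s])
  }, 0)
  n1 <- (N - sum(sum_np2_by_g)) / df_apwg
  n2 <- (sum(sum_np2_by_g) - sum(n_p^2) / N) / df_ag
  n3 <- (N - sum(N_g^2) / N) / df_ag
  vc_c <- ms_wp
  vc_b <- (ms_apwg - vc_c) / n1
  vc_a <- (ms_ag - vc_c - n2 * vc_b) / n3
  tot <- vc_a + vc_b + vc_c
  indices <- c(
    F_CT = if (tot == 0) NA_real_ else vc_a / tot,
    F_SC = if ((vc_b + vc_c) == 0) NA_real_ else vc_b / (vc_b + vc_c),
    F_ST = if (tot == 0) NA_real_ else (vc_a + vc_b) / tot)
  table <- data.frame(
    source = c("Among species", "Among populations within species",
               "Within populations"),
    df = c(df_ag, df_apwg, df_wp), SS = c(ss_ag, ss_apwg, ss_wp),
    VC = c(vc_a, vc_b, vc_c), PV = 100 * c(vc_a, vc_b, vc_c) / tot,
    stringsAsFactors = FALSE)
  list(table = table, indices = indices)
}

#' @export
print.haplo_amova <- function(x, ...) {
  tb <- x$table
  tb$SS <- round(tb$SS, 2)
  tb$VC <- round(tb$VC, 4)
  tb$PV <- round(tb$PV, 2)
  print(tb, row.names = FALSE)
  for (nm in names(x$indices)) {
    cat(sprintf("%s = %.4f", nm, x$indices[nm]))
    if (!is.na(x$p_values[nm])) cat(sprintf("  (p = %.4g)", x$p_values[nm]))
    cat("\n")
  }
  invisible(x)
}
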