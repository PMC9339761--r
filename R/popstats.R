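#' Per-population diversity
#'
#' For every population: the number of distinct haplotypes `h`, Nei's
#' unbiased haplotype (gene) diversity
#' `Hd = n (1 - sum p_i^2) / (n - 1)` (0 when `n = 1`), and nucleotide
#' diversity per site
#' `pi = n / (n - 1) * sum_{i<j} 2 p_i p_j d_ij / L`,
#' where `d_ij` counts substitution differences only (indel and inversion
#' characters are excluded from `pi`, following the convention of counting
#' gap-free sites) and `L` is the total aligned length.
#'
#' @param catalog A `haplotype_catalog`.
#' @return Data frame: `population`, `species`, `n`, `h`, `Hd`, `pi`
#'   (`pi` is `NA` if the catalog has no state vectors or no length).
#' @export
population_diversity <- function(catalog) {
  cnt <- catalog$counts
  if (any(colSums(cnt) == 0L)) stop("population with n = 0")
  d_sub <- NULL
  if (!is.null(catalog$states) && !is.null(catalog$info) && !is.null(catalog$L)) {
    d_sub <- hamming_matrix(catalog, which = "substitution")
  }
  out <- lapply(seq_len(ncol(cnt)), function(k) {
    ck <- cnt[, k]
    n <- sum(ck)
    p <- ck / n
    h <- sum(ck > 0L)
    Hd <- if (n > 1L) n * (1 - sum(p^2)) / (n - 1L) else 0
    pi <- NA_real_
    if (!is.null(d_sub)) {
      pi <- if (n > 1L) (n / (n - 1L)) * as.numeric(t(p) %*% d_sub %*% p) / catalog$L else 0
    }
    data.frame(population = colnames(cnt)[k],
               species = catalog$pops$species[k],
               n = n, h = h, Hd = Hd, pi = pi, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Unbiased multi-population gene-diversity estimators (population-weighted
# equally, i.e. the unweighted variant): per-population
# h_k = n_k (1 - sum x_ki^2) / (n_k - 1); hS = mean_k h_k;
# hT = 1 - sum_i xbar_i^2 + hS / (K * n_tilde), n_tilde = harmonic mean n_k.
# With a distance matrix the analogous v-statistics replace the identity
# kernel, giving vS / vT and hence NST.
pons_petit <- function(counts, d = NULL) {
  n_k <- colSums(counts)
  K <- ncol(counts)
  if (K < 2L) stop("need at least 2 populations")
  X <- sweep(counts, 2L, n_k, "/")
  corr <- n_k / (n_k - 1)
  h_k <- corr * (1 - colSums(X^2))
  hS <- mean(h_k)
  n_tilde <- K / sum(1 / n_k)
  xbar <- rowMeans(X)
  hT <- 1 - sum(xbar^2) + hS / (K * n_tilde)
  out <- list(hS = hS, hT = hT, n_tilde = n_tilde, K = K,
              gst = (hT - hS) / hT)
  if (!is.null(d)) {
    v_k <- corr * colSums((d %*% X) * X)
    vS <- mean(v_k)
    vT <- as.numeric(t(xbar) %*% d %*% xbar) + vS / (K * n_tilde)
    out$vS <- vS
    out$vT <- vT
    out$nst <- (vT - vS) / vT
  }
  out
}

#' Average within-population and total gene diversity
#'
#' Unbiased multi-population estimators of the average within-population
#' gene diversity `hS` and total gene diversity `hT`, treating populations
#' equally regardless of sample size (the conventional unweighted variant)
#' and applying the small-sample correction through the harmonic mean sample
#' size. Standard errors are delete-one jackknife over populations.
#' Populations with fewer than two individuals are excluded with a warning
#' (the unbiased per-population estimate is undefined there).
#'
#' @param counts Haplotype x population count matrix, or a
#'   `haplotype_catalog`.
#' @return List: `hS`, `hT`, `se_hS`, `se_hT`, `K`, `n_tilde`.
#' @export
multi_population_diversity <- function(counts) {
  counts <- counts_of(counts)
  counts <- drop_small_pops(counts)
  pp <- pons_petit(counts)
  jk <- jackknife_pops(counts, function(cc) {
    r <- pons_petit(cc)
    c(r$hS, r$hT)
  })
  list(hS = pp$hS, hT = pp$hT, se_hS = jk[1L], se_hT = jk[2L],
       K = pp$K, n_tilde = pp$n_tilde)
}

#' Population differentiation: GST and NST with a permutation test
#'
#' `GST = (hT - hS) / hT` ignores the relationships between haplotypes;
#' `NST` is the analogous coefficient computed from mean pairwise haplotype
#' distances within (`vS`) and overall (`vT`). `NST` significantly above
#' `GST` indicates phylogeographic structure: related haplotypes co-occur
#' within populations. Significance is assessed by permuting the haplotype
#' identities of the distance matrix (`n_perm` times, default 10,000) and
#' recomputing `NST`; the one-tailed p-value carries the +1 correction.
#'
#' @param counts Haplotype x population count matrix, or a
#'   `haplotype_catalog` (whose Hamming matrix is then used).
#' @param d Inter-haplotype distance matrix (ignored if `counts` is a
#'   catalog with state vectors).
#' @param n_perm Number of permutations (default 10,000).
#' @param seed Optional RNG seed for reproducible permutation.
#' @return A `differentiation_result`: list with `gst`, `nst`, `se_gst`,
#'   `se_nst`, `p_value`, `n_perm`, `hS`, `hT`, `se_hS`, `se_hT`, `vS`,
#'   `vT`, `K` (SEs are delete-one jackknife over populations).
#' @export
differentiation <- function(counts, d = NULL, n_perm = 10000L, seed = NULL) {
  if (inherits(counts, "haplotype_catalog")) {
    if (is.null(d)) d <- hamming_matrix(counts)
    counts <- counts_of(counts)
  }
  stopifnot(!is.null(d))
  counts <- drop_small_pops(counts)
  d <- d[rownames(counts), rownames(counts)]
  pp <- pons_petit(counts, d)
  if (pp$hT <= 0) stop("GST undefined: total diversity hT = 0")
  if (!is.null(seed)) set.seed(seed)
  nh <- nrow(counts)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    sig <- sample.int(nh)
    nst_p <- pons_petit(counts, d[sig, sig])$nst
    if (!is.na(nst_p) && nst_p >= pp$nst) exceed <- exceed + 1L
  }
  p <- (exceed + 1L) / (n_perm + 1L)
  jk <- jackknife_pops(counts, function(cc) {
    r <- pons_petit(cc, d)
    c(r$gst, r$nst, r$hS, r$hT)
  })
  structure(list(gst = pp$gst, nst = pp$nst, se_gst = jk[1L], se_nst = jk[2L],
                 p_value = p, n_perm = n_perm, hS = pp$hS, hT = pp$hT,
                 se_hS = jk[3L], se_hT = jk[4L],
                 vS = pp$vS, vT = pp$vT, K = pp$K),
            class = "differentiation_result")
}

#' @export
print.differentiation_result <- function(x, ...) {
  cat(sprintf("GST = %.3f (SE %.3f), NST = %.3f (SE %.3f)\n",
              x$gst, x$se_gst, x$nst, x$se_nst))
  cat(sprintf("permutation test NST > GST: p = %.4g (%d permutations, %d populations)\n",
              x$p_value, x$n_perm, x$K))
  invisible(x)
}

counts_of <- function(x) {
  if (inherits(x, "haplotype_catalog")) x$counts else x
}

drop_small_pops <- function(counts) {
  small <- colSums(counts) < 2L
  if (any(small)) {
    warning("excluding population(s) with n < 2: ",
            paste(colnames(counts)[small], collapse = ", "))
    counts <- counts[, !small, drop = FALSE]
  }
  if (ncol(counts) < 2L) stop("need at least 2 populations with n >= 2")
  counts
}

jackknife_pops <- function(counts, stat) {
  K <- ncol(counts)
  if (K < 3L) return(rep(NA_real_, length(stat(counts))))
  reps <- vapply(seq_len(K), function(k) stat(counts[, -k, drop = FALSE]),
                 numeric(length(stat(counts))))
  if (is.null(dim(reps))) reps <- matrix(reps, nrow = 1L)
  apply(reps, 1L, function(v) sqrt((K - 1) / K * sum((v - mean(v))^2)))
}

#' Trend of diversity with latitude and longitude
#'
#' Ordinary least squares of each per-population diversity measure on
#' latitude and on longitude, in linear and quadratic form, with t-test
#' p-values for the slope terms. Used to check for geographic diversity
#' gradients.
#'
#' @param pop_stats Output of [population_diversity()] (needs columns
#'   `population`, plus the measures) .
#' @param coords Data frame with `population`, `latitude`, `longitude`.
#' @param measures Which columns of `pop_stats` to regress (default
#'   `c("h", "Hd", "pi")`, skipping all-`NA` columns).
#' @return Data frame: `measure`, `predictor`, `form`, `term`, `estimate`,
#'   `p_value`, `r_squared`.
#' @export
geo_trend <- function(pop_stats, coords, measures = c("h", "Hd", "pi")) {
  if (nrow(pop_stats) < 4L) stop("need at least 4 populations")
  df <- merge(pop_stats, coords[, c("population", "latitude", "longitude")],
              by = "population")
  rows <- list()
  for (m in measures) {
    y <- df[[m]]
    if (is.null(y) || all(is.na(y))) next
    flat <- var(y, na.rm = TRUE) == 0  # no variation: slope 0, p undefined
    for (pred in c("latitude", "longitude")) {
      x <- df[[pred]]
      if (var(x) == 0) stop("constant predictor: ", pred)
      for (form in c("linear", "quadratic")) {
        fml <- if (form == "linear") y ~ x else y ~ x + I(x^2)
        fit <- lm(fml)
        sm <- summary(fit)
        ct <- sm$coefficients
        terms <- rownames(ct)[-1L]
        for (tm in terms) {
          p <- ct[tm, 4L]
          if (is.nan(p)) p <- 1
          rows[[length(rows) + 1L]] <- data.frame(
            measure = m, predictor = pred, form = form, term = tm,
            estimate = if (flat) 0 else ct[tm, 1L],
            p_value = if (flat) 1 else p,
            r_squared = if (flat) 0 else sm$r.squared,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}
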