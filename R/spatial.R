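#' Great-circle distance (haversine)
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorised).
#' @param radius_km Earth radius; default the IUGG mean radius 6371.0088 km.
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2, radius_km = 6371.0088) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * radius_km * asin(pmin(1, sqrt(a)))
}

#' Pairwise great-circle distance matrix
#'
#' @param lat,lon Coordinate vectors (decimal degrees).
#' @param names Optional dimnames.
#' @return Symmetric km distance matrix.
#' @export
geo_distance_matrix <- function(lat, lon, names = NULL) {
  n <- length(lat)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    m[i, ] <- haversine_km(lat[i], lon[i], lat, lon)
  }
  m <- (m + t(m)) / 2  # exact symmetry
  diag(m) <- 0
  if (!is.null(names)) dimnames(m) <- list(names, names)
  m
}

#' Assign pair distances to distance classes
#'
#' Half-open bins `[0, w)`, `[w, 2w)`, ...; pairs beyond the last bin are
#' excluded (class `NA`).
#'
#' @param d_km Numeric distances.
#' @param width_km Class width (default 50 km).
#' @param n_classes Number of classes (default 20).
#' @return Integer class index (1-based) or `NA` beyond the last class.
#' @export
distance_classes <- function(d_km, width_km = 50, n_classes = 20L) {
  stopifnot(width_km > 0)
  cl <- floor(d_km / width_km) + 1L
  cl[cl > n_classes] <- NA_integer_
  as.integer(cl)
}

#' Multivariate spatial autocorrelogram
#'
#' The individual-level autocorrelation coefficient `r` per distance class:
#' the squared genetic distance matrix is double-centred into a
#' covariance-like matrix `C`
#' (`c_ij = -(d2_ij - rowmean_i - rowmean_j + grandmean) / 2`), and for each
#' class `h`, `r(h) = sum_{i != j in h} c_ij / sum_{i != j in h} c_ii` (the
#' diagonal weighted by the number of pairs each individual enters).
#'
#' @param gen_d2 Squared genetic distance matrix between individuals
#'   (conventionally the squared haplotype Hamming distance).
#' @param geo_km Geographic km distance matrix between the same individuals.
#' @param width_km Distance-class width (default 50 km).
#' @param n_classes Number of classes (default 20).
#' @return Data frame: `class`, `lo_km`, `hi_km`, `n_pairs`, `r` (`NA` and
#'   flagged when a class has no pairs or when all genotypes are identical).
#' @export
autocorrelogram <- function(gen_d2, geo_km, width_km = 50, n_classes = 20L) {
  stopifnot(identical(dim(gen_d2), dim(geo_km)))
  C <- double_centre(gen_d2)
  pr <- which(upper.tri(C), arr.ind = TRUE)
  cl <- distance_classes(geo_km[upper.tri(geo_km)], width_km, n_classes)
  diagC <- diag(C)
  all_zero <- all(abs(C) < 1e-12)
  out <- lapply(seq_len(n_classes), function(h) {
    sel <- which(!is.na(cl) & cl == h)
    n_pairs <- length(sel)
    r <- NA_real_
    if (n_pairs > 0L && !all_zero) {
      r <- r_of_pairs(C, diagC, pr[sel, 1L], pr[sel, 2L])
    }
    data.frame(class = h, lo_km = (h - 1) * width_km, hi_km = h * width_km,
               n_pairs = n_pairs, r = r)
  })
  do.call(rbind, out)
}

double_centre <- function(d2) {
  rm <- rowMeans(d2)
  gm <- mean(d2)
  -(sweep(sweep(d2, 1L, rm), 2L, rm) + gm) / 2
}

r_of_pairs <- function(C, diagC, ii, jj) {
  num <- 2 * sum(C[ii + (jj - 1L) * nrow(C)])
  den <- sum(diagC[ii]) + sum(diagC[jj])
  if (den == 0) return(NA_real_)
  num / den
}

#' Permutation bounds and bootstrap CIs for an autocorrelogram
#'
#' Permutation: the individual-to-location mapping is shuffled wholesale
#' (one shuffle per replicate, shared across classes), `r` recomputed per
#' class; the 2.5/97.5 percentiles of the null give the bounds, and positive
#' structure is inferred when the observed `r` lies above the upper bound.
#' The one-tailed permutation p also uses the +1 correction. Bootstrap:
#' pairs within a class are resampled with replacement; the 2.5/97.5
#' percentiles give the CI, significant when it excludes zero. A class with
#' fewer than 2 pairs is flagged and its bootstrap skipped.
#'
#' @param gen_d2,geo_km,width_km,n_classes As in [autocorrelogram()].
#' @param n_perm Permutations (default 9999).
#' @param n_boot Bootstrap replicates (default 9999).
#' @param seed Optional RNG seed.
#' @return The [autocorrelogram()] frame plus `perm_lo`, `perm_hi`,
#'   `p_perm`, `boot_lo`, `boot_hi`, `significant` (above permutation upper
#'   bound).
#' @export
autocorr_inference <- function(gen_d2, geo_km, width_km = 50, n_classes = 20L,
                               n_perm = 9999L, n_boot = 9999L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- autocorrelogram(gen_d2, geo_km, width_km, n_classes)
  n <- nrow(gen_d2)
  C <- double_centre(gen_d2)
  diagC <- diag(C)
  pr <- which(upper.tri(C), arr.ind = TRUE)
  cl <- distance_classes(geo_km[upper.tri(geo_km)], width_km, n_classes)
  by_class <- split(seq_along(cl), factor(cl, levels = seq_len(n_classes)))
  perm_mat <- matrix(NA_real_, n_perm, n_classes)
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    ii <- p[pr[, 1L]]
    jj <- p[pr[, 2L]]
    for (h in seq_len(n_classes)) {
      sel <- by_class[[h]]
      if (!length(sel)) next
      perm_mat[b, h] <- r_of_pairs(C, diagC, ii[sel], jj[sel])
    }
  }
  boot_lo <- boot_hi <- rep(NA_real_, n_classes)
  for (h in seq_len(n_classes)) {
    sel <- by_class[[h]]
    if (length(sel) < 2L || n_boot < 1L) next
    ii <- pr[sel, 1L]; jj <- pr[sel, 2L]
    cij <- C[cbind(ii, jj)]
    dsum <- diagC[ii] + diagC[jj]
    reps <- vapply(seq_len(n_boot), function(b) {
      take <- sample.int(length(sel), replace = TRUE)
      den <- sum(dsum[take])
      if (den == 0) NA_real_ else 2 * sum(cij[take]) / den
    }, 0)
    qs <- quantile(reps, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    boot_lo[h] <- qs[1L]; boot_hi[h] <- qs[2L]
  }
  safe_q <- function(v, p) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    quantile(v, p, names = FALSE)
  }
  perm_lo <- apply(perm_mat, 2L, safe_q, 0.025)
  perm_hi <- apply(perm_mat, 2L, safe_q, 0.975)
  p_perm <- vapply(seq_len(n_classes), function(h) {
    if (is.na(base$r[h])) return(NA_real_)
    (sum(perm_mat[, h] >= base$r[h], na.rm = TRUE) + 1L) / (n_perm + 1L)
  }, 0)
  base$perm_lo <- unname(perm_lo)
  base$perm_hi <- unname(perm_hi)
  base$p_perm <- p_perm
  base$boot_lo <- boot_lo
  base$boot_hi <- boot_hi
  base$significant <- !is.na(base$r) & base$r > base$perm_hi
  base
}

#' Individual-level squared genetic distance matrix
#'
#' Expands the inter-haplotype distance matrix to individuals via their
#' haplotype assignment and squares it (the haploid convention for the
#' autocorrelation analysis); `method = "mismatch"` uses a 0/1 identity
#' distance instead.
#'
#' @param catalog A `haplotype_catalog`.
#' @param method `"squared"` (default) or `"mismatch"`.
#' @param exclude Optional haplotype label(s) whose carriers are dropped
#'   (e.g. the most widespread haplotype, for the sensitivity re-run).
#' @return List with `gen_d2` (individuals x individuals), `geo_km`, and
#'   `assignment` (the individuals used).
#' @export
individual_distances <- function(catalog, method = c("squared", "mismatch"),
                                 exclude = NULL) {
  method <- match.arg(method)
  asg <- catalog$assignment
  if (!is.null(exclude)) asg <- asg[!(asg$haplotype %in% exclude), , drop = FALSE]
  if (nrow(asg) < 2L) stop("fewer than 2 individuals after exclusion")
  d <- hamming_matrix(catalog)
  hd <- if (method == "squared") d^2 else (d > 0) + 0
  idx <- match(asg$haplotype, rownames(hd))
  gen_d2 <- hd[idx, idx, drop = FALSE]
  pop_idx <- match(asg$population, catalog$pops$population)
  geo_km <- geo_distance_matrix(catalog$pops$latitude[pop_idx],
                                catalog$pops$longitude[pop_idx])
  dimnames(gen_d2) <- dimnames(geo_km) <- list(asg$individual_id, asg$individual_id)
  list(gen_d2 = gen_d2, geo_km = geo_km, assignment = asg)
}
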