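#' Gene identity between two populations
#'
#' Similarity of two haplotype frequency vectors over the common haplotype
#' universe. The default is the normalised (Nei) identity
#' `J = sum(x_i y_i) / sqrt(sum(x_i^2) * sum(y_i^2))`, bounded in `[0, 1]`
#' (1 = identical composition, 0 = disjoint haplotype sets); `method =
#' "raw"` gives the unnormalised `sum(x_i y_i)` used in parts of the older
#' literature.
#'
#' @param x,y Frequency vectors over the same haplotype ordering, each
#'   summing to 1.
#' @param method `"nei"` (default) or `"raw"`.
#' @return The identity `J`, or `NA` if either vector is all zero.
#' @export
gene_identity <- function(x, y, method = c("nei", "raw")) {
  method <- match.arg(method)
  sx <- sum(x^2); sy <- sum(y^2)
  if (sx == 0 || sy == 0) return(NA_real_)
  num <- sum(x * y)
  if (method == "raw") num else num / sqrt(sx * sy)
}

#' Remove all carriers of a haplotype
#'
#' Drops every individual carrying the given haplotype(s) and recomputes
#' population frequencies; populations left empty are dropped (so pair
#' counts shrink downstream). Removing a haplotype no population carries is
#' a no-op.
#'
#' @param catalog A `haplotype_catalog`.
#' @param label Haplotype label(s) to exclude.
#' @return The reduced `haplotype_catalog`.
#' @export
exclude_haplotype <- function(catalog, label) {
  keep_h <- !(rownames(catalog$counts) %in% label)
  cnt <- catalog$counts[keep_h, , drop = FALSE]
  keep_p <- colSums(cnt) > 0L
  emptied_species <- setdiff(catalog$pops$species,
                             catalog$pops$species[keep_p])
  if (length(emptied_species)) {
    stop("exclusion empties an entire species: ",
         paste(emptied_species, collapse = ", "))
  }
  catalog$counts <- cnt[, keep_p, drop = FALSE]
  catalog$pops <- catalog$pops[keep_p, , drop = FALSE]
  rownames(catalog$pops) <- NULL
  catalog$pops$n <- colSums(catalog$counts)
  catalog$assignment <- catalog$assignment[
    !(catalog$assignment$haplotype %in% label) &
      catalog$assignment$population %in% catalog$pops$population, , drop = FALSE]
  if (!is.null(catalog$states)) {
    catalog$states <- catalog$states[keep_h, , drop = FALSE]
  }
  catalog
}

#' All heterospecific population-pair identities
#'
#' One record per pair of populations belonging to different species:
#' great-circle distance, gene identity `J`, whether the pair shares at
#' least one haplotype, and its distance/sharing group — `G1`: `<
#' threshold_km` and sharing; `G2`: `< threshold_km` regardless of sharing
#' (`G1` is a subset); `G3`: `>= threshold_km`.
#'
#' @param catalog A `haplotype_catalog` (apply [exclude_haplotype()] first
#'   for the exclusion mode; sharing is evaluated after exclusion).
#' @param threshold_km Distance threshold (default 300, strict `<`).
#' @param method Identity variant, see [gene_identity()].
#' @return Data frame: `pop_x`, `pop_y`, `species_x`, `species_y`,
#'   `species_pair`, `distance_km`, `J`, `shares_any`, `group`
#'   (`"G3"`/`"G2"`; `shares_any` marks `G1` membership within `G2`).
#' @export
pair_identities <- function(catalog, threshold_km = 300, method = "nei") {
  pops <- catalog$pops
  cnt <- catalog$counts
  freq <- sweep(cnt, 2L, colSums(cnt), "/")
  P <- nrow(pops)
  idx <- which(upper.tri(matrix(0, P, P)), arr.ind = TRUE)
  het <- pops$species[idx[, 1L]] != pops$species[idx[, 2L]]
  idx <- idx[het, , drop = FALSE]
  if (nrow(idx) == 0L) {
    stop("need populations from at least 2 species")
  }
  d_km <- haversine_km(pops$latitude[idx[, 1L]], pops$longitude[idx[, 1L]],
                       pops$latitude[idx[, 2L]], pops$longitude[idx[, 2L]])
  J <- vapply(seq_len(nrow(idx)), function(k) {
    gene_identity(freq[, idx[k, 1L]], freq[, idx[k, 2L]], method)
  }, 0)
  shares <- vapply(seq_len(nrow(idx)), function(k) {
    any(cnt[, idx[k, 1L]] > 0L & cnt[, idx[k, 2L]] > 0L)
  }, TRUE)
  sp_x <- pops$species[idx[, 1L]]
  sp_y <- pops$species[idx[, 2L]]
  sp_lo <- pmin(sp_x, sp_y)
  sp_hi <- pmax(sp_x, sp_y)
  out <- data.frame(
    pop_x = pops$population[idx[, 1L]], pop_y = pops$population[idx[, 2L]],
    species_x = sp_x, species_y = sp_y,
    species_pair = paste(sp_lo, sp_hi, sep = "-"),
    distance_km = d_km, J = J, shares_any = shares,
    group = ifelse(d_km < threshold_km, "G2", "G3"),
    stringsAsFactors = FALSE)
  dropped <- is.na(out$J)
  if (any(dropped)) {
    message(sum(dropped), " pair(s) dropped: population emptied by exclusion")
    out <- out[!dropped, , drop = FALSE]
  }
  out
}

#' Distance-stratified test of interspecific gene identity
#'
#' The core sharing analysis: interspecific gene identities are grouped into
#' nearby-and-sharing (`J1`), nearby (`J2`, superset of `J1`), and distant
#' (`J3`) pairs, and the group distributions are compared with two-sided
#' Wilcoxon rank-sum tests (`P12`, `P13`, `P23`). Shared ancestral
#' polymorphism predicts no difference between nearby and distant pairs
#' (`P23` non-significant); introgression predicts an excess of identity
#' between nearby heterospecific populations (`M2 > M3`), typically visible
#' only after excluding the most widespread ancestral haplotype.
#'
#' @param catalog A `haplotype_catalog`.
#' @param threshold_km Distance threshold in km (default 300, strict `<`).
#' @param exclude Optional haplotype label(s) removed (all carriers dropped)
#'   before the analysis; sharing status is evaluated after exclusion.
#' @param method Identity variant, see [gene_identity()].
#' @return A `sharing_result`: list with `table` (one row per species pair
#'   plus `"all"`: `N1 M1 N2 M2 N3 M3 P12 P13 P23`), `pairs` (the
#'   pair-identity records), `threshold_km`, `exclude`.
#' @export
sharing_test <- function(catalog, threshold_km = 300, exclude = NULL,
                         method = "nei") {
  if (length(unique(catalog$pops$species)) < 2L) stop("need at least 2 species")
  if (!is.null(exclude)) catalog <- exclude_haplotype(catalog, exclude)
  pairs <- pair_identities(catalog, threshold_km, method)
  groups <- c(split(pairs, pairs$species_pair), list(all = pairs))
  rows <- lapply(names(groups), function(g) {
    pr <- groups[[g]]
    J1 <- pr$J[pr$group == "G2" & pr$shares_any]
    J2 <- pr$J[pr$group == "G2"]
    J3 <- pr$J[pr$group == "G3"]
    data.frame(
      species_pair = g,
      N1 = length(J1), M1 = mean_or_na(J1),
      N2 = length(J2), M2 = mean_or_na(J2),
      N3 = length(J3), M3 = mean_or_na(J3),
      P12 = wilcox_or_na(J1, J2), P13 = wilcox_or_na(J1, J3),
      P23 = wilcox_or_na(J2, J3), stringsAsFactors = FALSE)
  })
  structure(list(table = do.call(rbind, rows), pairs = pairs,
                 threshold_km = threshold_km, exclude = exclude,
                 method = method),
            class = "sharing_result")
}

mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
wilcox_or_na <- function(a, b) {
  if (!length(a) || !length(b)) return(NA_real_)
  wilcoxon_rank_sum(a, b)
}

#' @export
print.sharing_result <- function(x, ...) {
  cat("Interspecific gene identity by distance group (threshold",
      x$threshold_km, "km",
      if (!is.null(x$exclude)) paste0("; excluding ", paste(x$exclude, collapse = ", ")),
      ")\n")
  tb <- x$table
  num <- vapply(tb, is.numeric, TRUE)
  tb[num] <- lapply(tb[num], function(v) ifelse(is.na(v), NA, round(v, 3)))
  print(tb, row.names = FALSE)
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact distribution when both samples have 20 or fewer observations and
#' there are no ties; normal approximation with the tie correction
#' otherwise.
#'
#' @param a,b Numeric samples.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  stopifnot(length(a) > 0L, length(b) > 0L)
  if (length(unique(c(a, b))) == 1L) return(1)  # fully tied: no evidence
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && length(a) <= 20L && length(b) <= 20L
  suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = FALSE)$p.value)
}

#' Enumerate nearby interspecific sharing pairs
#'
#' All heterospecific population pairs closer than the threshold that share
#' at least one haplotype other than the globally excluded label(s). Unlike
#' [exclude_haplotype()], the exclusion here only masks the label when
#' assessing sharing; no individuals are removed.
#'
#' @param catalog A `haplotype_catalog`.
#' @param threshold_km Distance threshold (default 300, strict `<`).
#' @param exclude_label Haplotype label(s) ignored when assessing sharing
#'   (e.g. the most widespread ancestral haplotype).
#' @return Data frame: `pop_x`, `pop_y`, `species_x`, `species_y`,
#'   `species_pair`, `distance_km`, `shared` (comma-joined labels).
#' @export
enumerate_sharing_pairs <- function(catalog, threshold_km = 300,
                                    exclude_label = NULL) {
  pops <- catalog$pops
  cnt <- catalog$counts
  if (!is.null(exclude_label)) {
    cnt <- cnt[!(rownames(cnt) %in% exclude_label), , drop = FALSE]
  }
  P <- nrow(pops)
  rows <- list()
  for (i in seq_len(P - 1L)) {
    for (j in (i + 1L):P) {
      if (pops$species[i] == pops$species[j]) next
      d <- haversine_km(pops$latitude[i], pops$longitude[i],
                        pops$latitude[j], pops$longitude[j])
      if (d >= threshold_km) next
      shared <- rownames(cnt)[cnt[, i] > 0L & cnt[, j] > 0L]
      if (!length(shared)) next
      sp <- sort(c(pops$species[i], pops$species[j]))
      rows[[length(rows) + 1L]] <- data.frame(
        pop_x = pops$population[i], pop_y = pops$population[j],
        species_x = pops$species[i], species_y = pops$species[j],
        species_pair = paste(sp[1L], sp[2L], sep = "-"),
        distance_km = d, shared = paste(shared, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(pop_x = character(), pop_y = character(),
                      species_x = character(), species_y = character(),
                      species_pair = character(), distance_km = numeric(),
                      shared = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
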