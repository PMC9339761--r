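#' Run the full haplotype-sharing analysis
#'
#' Convenience wrapper chaining every stage on an assembled dataset: coding,
#' haplotype collapsing, the median-joining network, per-population
#' diversity, GST/NST differentiation with its permutation test, three-level
#' AMOVA (when more than one species is present), the spatial
#' autocorrelogram with permutation/bootstrap inference, the
#' distance-stratified sharing test with and without the most widespread
#' haplotype, and the nearby-sharing pair list.
#'
#' @param dataset A `cp_dataset`.
#' @param threshold_km Sharing-test distance threshold (default 300).
#' @param width_km,n_classes Autocorrelogram distance classes (defaults 50
#'   km x 20).
#' @param n_perm Permutations for the GST/NST and AMOVA tests (default
#'   10,000).
#' @param n_perm_spatial,n_boot_spatial Autocorrelogram inference replicates
#'   (default 9999).
#' @param seed RNG seed used for every randomised stage.
#' @return Named list of stage results (also accepted by
#'   [write_outputs()]): `catalog`, `network`, `diversity`,
#'   `differentiation` (per species and pooled), `amova`, `correlogram`,
#'   `sharing` (both exclusion modes), `pairs`.
#' @export
run_pipeline <- function(dataset, threshold_km = 300, width_km = 50,
                         n_classes = 20L, n_perm = 10000L,
                         n_perm_spatial = 9999L, n_boot_spatial = 9999L,
                         seed = 1L) {
  cm <- code_loci(dataset)
  catalog <- collapse_haplotypes(cm, dataset$populations)
  network <- median_joining(catalog)
  diversity <- population_diversity(catalog)
  d <- hamming_matrix(catalog)
  species <- sort(unique(catalog$pops$species))
  diff_rows <- list()
  for (sp in c(as.list(species), list(species))) {
    sel <- catalog$pops$species %in% sp
    cnt <- catalog$counts[, sel, drop = FALSE]
    cnt <- cnt[rowSums(cnt) > 0L, , drop = FALSE]
    dr <- differentiation(cnt, d[rownames(cnt), rownames(cnt)],
                          n_perm = n_perm, seed = seed)
    diff_rows[[length(diff_rows) + 1L]] <- data.frame(
      species = paste(sp, collapse = "+"), K = dr$K,
      hT = dr$hT, se_hT = dr$se_hT, hS = dr$hS, se_hS = dr$se_hS,
      GST = dr$gst, se_GST = dr$se_gst, NST = dr$nst, se_NST = dr$se_nst,
      p_NST_gt_GST = dr$p_value, stringsAsFactors = FALSE)
  }
  differentiation_tb <- do.call(rbind, diff_rows)
  am <- NULL
  if (length(species) > 1L) {
    am <- amova(catalog, d, n_perm = n_perm, seed = seed)
  }
  idists <- individual_distances(catalog)
  correlogram <- autocorr_inference(idists$gen_d2, idists$geo_km,
                                    width_km = width_km,
                                    n_classes = n_classes,
                                    n_perm = n_perm_spatial,
                                    n_boot = n_boot_spatial, seed = seed)
  top <- rownames(catalog$counts)[which.max(rowSums(catalog$counts))]
  sharing_all <- sharing_test(catalog, threshold_km)
  sharing_excl <- sharing_test(catalog, threshold_km, exclude = top)
  sharing_tb <- rbind(cbind(exclusion = "none", sharing_all$table),
                      cbind(exclusion = paste0("excl_", top), sharing_excl$table))
  pairs <- enumerate_sharing_pairs(catalog, threshold_km, exclude_label = top)
  list(catalog = catalog, network = network, diversity = diversity,
       differentiation = differentiation_tb, amova = am,
       correlogram = correlogram, sharing = sharing_tb, pairs = pairs,
       sharing_details = list(none = sharing_all, excluded = sharing_excl),
       top_haplotype = top)
}
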