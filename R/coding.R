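#' Mask mononucleotide repeats
#'
#' Length variation in mononucleotide repeats (homopolymer microsatellites)
#' is prone to homoplasy, so indels inside such runs are excluded from
#' character coding. A run is measured per sequence on the gapless bases
#' (gaps are ignored when counting), and every alignment column spanned by a
#' run of at least `min_run` identical bases in any sequence is masked.
#' The mask suppresses indel characters only; a substitution to a different
#' base inside a run remains callable.
#'
#' @param alignment A `cp_alignment`.
#' @param min_run Minimum homopolymer length to mask (default 5).
#' @return Logical vector, one element per alignment column; `TRUE` = masked.
#' @export
mask_mononucleotide_repeats <- function(alignment, min_run = 5L) {
  stopifnot(min_run >= 2L)
  L <- ncol(alignment)
  mask <- logical(L)
  for (r in seq_len(nrow(alignment))) {
    row <- alignment[r, ]
    keep <- row != "-"
    bases <- row[keep]
    cols <- which(keep)
    if (length(bases) == 0L) next
    rl <- rle(bases)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    long <- which(rl$lengths >= min_run & rl$values %in% c("A", "C", "G", "T"))
    for (k in long) {
      # span in alignment coordinates, including any gap columns inside it
      mask[cols[starts[k]]:cols[ends[k]]] <- TRUE
    }
  }
  mask
}

#' Call substitution characters
#'
#' One coded character per alignment column with two or more distinct bases.
#' Columns whose only polymorphism is base-versus-gap belong to indels and
#' are not substitution characters. `N` and gap states are recorded as
#' missing for the individuals bearing them.
#'
#' @param alignment A `cp_alignment`.
#' @return A `coded_characters` object (possibly with zero characters).
#' @export
call_substitutions <- function(alignment) {
  locus <- attr(alignment, "locus")
  states <- list()
  info <- list()
  for (j in seq_len(ncol(alignment))) {
    col <- alignment[, j]
    obs <- col[col %in% c("A", "C", "G", "T")]
    if (length(unique(obs)) < 2L) next
    st <- ifelse(col %in% c("A", "C", "G", "T"), col, NA_character_)
    states[[length(states) + 1L]] <- st
    info[[length(info) + 1L]] <- data.frame(
      locus = locus, kind = "substitution", start = j, end = j,
      length_bp = 1L, stringsAsFactors = FALSE)
  }
  new_coded_characters(states, info, alignment)
}

#' Code indels by simple gap coding
#'
#' Each maximal gap run with identical start and end coordinates across its
#' bearers becomes one binary character (`A` = gap absent, `T` = gap
#' present), so an indel counts as a single mutation event regardless of
#' length. A sequence whose own gap overlaps a character's coordinates
#' without matching them exactly (nested or partially overlapping gaps) is
#' scored missing for that character. Runs that are entirely inside the
#' homopolymer mask, and runs touching the alignment ends (treated as
#' missing data, not indels), are not coded.
#'
#' @param alignment A `cp_alignment`.
#' @param mask Optional logical column mask from
#'   [mask_mononucleotide_repeats()].
#' @return A `coded_characters` object.
#' @export
code_indels <- function(alignment, mask = NULL) {
  locus <- attr(alignment, "locus")
  L <- ncol(alignment)
  if (is.null(mask)) mask <- logical(L)
  runs_by_row <- lapply(seq_len(nrow(alignment)), function(r) {
    gap_runs(alignment[r, ])
  })
  all_runs <- unique(do.call(rbind, c(list(matrix(integer(), 0, 2)), runs_by_row)))
  if (nrow(all_runs)) {
    terminal <- all_runs[, 1L] == 1L | all_runs[, 2L] == L
    masked <- vapply(seq_len(nrow(all_runs)), function(i) {
      all(mask[all_runs[i, 1L]:all_runs[i, 2L]])
    }, TRUE)
    all_runs <- all_runs[!terminal & !masked, , drop = FALSE]
    all_runs <- all_runs[order(all_runs[, 1L], all_runs[, 2L]), , drop = FALSE]
  }
  states <- list()
  info <- list()
  for (i in seq_len(nrow(all_runs))) {
    s <- all_runs[i, 1L]; e <- all_runs[i, 2L]
    st <- vapply(runs_by_row, function(rr) {
      if (nrow(rr) == 0L) return("A")
      exact <- any(rr[, 1L] == s & rr[, 2L] == e)
      if (exact) return("T")
      overlaps <- any(rr[, 1L] <= e & rr[, 2L] >= s)
      if (overlaps) NA_character_ else "A"
    }, "")
    states[[length(states) + 1L]] <- st
    info[[length(info) + 1L]] <- data.frame(
      locus = locus, kind = "indel", start = s, end = e,
      length_bp = e - s + 1L, stringsAsFactors = FALSE)
  }
  new_coded_characters(states, info, alignment)
}

gap_runs <- function(row) {
  rl <- rle(row == "-")
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  cbind(starts, ends)[rl$values, , drop = FALSE]
}

#' Detect and recode an inversion region
#'
#' Rows whose region is closer to the reverse complement of the
#' majority-orientation consensus than to the consensus itself are rewritten
#' to the reverse complement of the region, and one binary character records
#' orientation (`A` = majority orientation, `T` = inverted), so the
#' inversion counts as a single mutation event. The region is supplied in
#' the configuration (1-based inclusive); it is not auto-detected.
#'
#' @param alignment A `cp_alignment`.
#' @param region Integer vector `c(start, end)`.
#' @return List with `alignment` (reoriented) and `characters` (a
#'   `coded_characters` object with one character, or zero if orientation is
#'   monomorphic).
#' @export
apply_inversion <- function(alignment, region) {
  s <- region[[1L]]; e <- region[[2L]]
  if (s < 1L || e > ncol(alignment) || s >= e) {
    stop("inversion region out of bounds: ", s, "-", e)
  }
  seg <- alignment[, s:e, drop = FALSE]
  # orientation is called against the first row (deterministic reference);
  # the majority-orientation flip below makes the result reference-free
  ref <- seg[1L, ]
  rc_ref <- rev_comp(ref)
  score <- function(x, template) sum(x == template & x %in% c("A", "C", "G", "T"))
  inverted <- vapply(seq_len(nrow(seg)), function(r) {
    score(seg[r, ], rc_ref) > score(seg[r, ], ref)
  }, TRUE)
  if (any(inverted)) {
    # majority orientation keeps state A; flip the minority if detection put
    # the majority on the reverse strand
    if (mean(inverted) > 0.5) inverted <- !inverted
    for (r in which(inverted)) {
      alignment[r, s:e] <- rev_comp(alignment[r, s:e])
    }
  }
  if (length(unique(inverted)) < 2L) {
    return(list(alignment = alignment,
                characters = new_coded_characters(list(), list(), alignment)))
  }
  st <- ifelse(inverted, "T", "A")
  ch <- new_coded_characters(
    list(st),
    list(data.frame(locus = attr(alignment, "locus"), kind = "inversion",
                    start = s, end = e, length_bp = e - s + 1L,
                    stringsAsFactors = FALSE)),
    alignment)
  list(alignment = alignment, characters = ch)
}

#' Reverse complement of a character vector of bases
#' @param x Character vector over `A,C,G,T,-,N`.
#' @return Reverse-complemented vector.
#' @export
rev_comp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", `-` = "-", N = "N")
  rev(unname(comp[x]))
}

new_coded_characters <- function(states, info, alignment) {
  if (length(states)) {
    m <- do.call(cbind, states)
    rownames(m) <- rownames(alignment)
    inf <- do.call(rbind, info)
  } else {
    m <- matrix(character(), nrow = nrow(alignment), ncol = 0L,
                dimnames = list(rownames(alignment), NULL))
    inf <- data.frame(locus = character(), kind = character(),
                      start = integer(), end = integer(),
                      length_bp = integer(), stringsAsFactors = FALSE)
  }
  structure(list(states = m, info = inf), class = "coded_characters")
}

#' @export
print.coded_characters <- function(x, ...) {
  cat("<coded_characters>", ncol(x$states), "characters (",
      paste(names(table(x$info$kind)), table(x$info$kind), collapse = ", "),
      ") over", nrow(x$states), "individuals\n")
  invisible(x)
}

#' Code one aligned locus into characters
#'
#' Runs the full per-locus coding stack: inversion detection/recoding (if a
#' region is configured), homopolymer masking, substitution calling and
#' simple gap coding. Characters that end up monomorphic are dropped.
#'
#' @param alignment A `cp_alignment`.
#' @param inversion Optional `c(start, end)` inversion region.
#' @param mask_min_run Homopolymer mask threshold (default 5).
#' @return A `coded_characters` object; the (possibly reoriented) alignment
#'   is attached as attribute `alignment`.
#' @export
code_alignment <- function(alignment, inversion = NULL, mask_min_run = 5L) {
  inv_chars <- NULL
  if (!is.null(inversion)) {
    res <- apply_inversion(alignment, inversion)
    alignment <- res$alignment
    inv_chars <- res$characters
  }
  mask <- mask_mononucleotide_repeats(alignment, mask_min_run)
  subs <- call_substitutions(alignment)
  inds <- code_indels(alignment, mask)
  out <- bind_characters(list(subs, inds, inv_chars), alignment)
  out <- drop_monomorphic(out)
  attr(out, "alignment") <- alignment
  out
}

bind_characters <- function(pieces, alignment) {
  pieces <- Filter(Negate(is.null), pieces)
  states <- do.call(cbind, lapply(pieces, function(p) p$states))
  info <- do.call(rbind, lapply(pieces, function(p) p$info))
  if (is.null(states)) return(new_coded_characters(list(), list(), alignment))
  structure(list(states = states, info = info), class = "coded_characters")
}

drop_monomorphic <- function(ch) {
  if (ncol(ch$states) == 0L) return(ch)
  keep <- apply(ch$states, 2L, function(col) length(unique(col[!is.na(col)])) >= 2L)
  ch$states <- ch$states[, keep, drop = FALSE]
  ch$info <- ch$info[keep, , drop = FALSE]
  rownames(ch$info) <- NULL
  ch
}

#' Code all loci of a dataset into one character matrix
#'
#' @param dataset A `cp_dataset`.
#' @return A `coded_matrix`: list with `states` (individuals x characters),
#'   `info` (per-character provenance), and `L` (total aligned length in bp,
#'   used as the per-site denominator for nucleotide diversity).
#' @export
code_loci <- function(dataset) {
  cfgs <- config_by_locus(dataset)
  ids <- dataset$populations$individual_id
  pieces <- lapply(names(dataset$alignments), function(nm) {
    aln <- dataset$alignments[[nm]]
    aln <- cp_alignment(aln[ids, , drop = FALSE], nm)  # common row order
    cfg <- cfgs[[nm]]
    code_alignment(aln,
                   inversion = cfg$inversion,
                   mask_min_run = cfg$mask_min_run %||% 5L)
  })
  states <- do.call(cbind, lapply(pieces, function(p) p$states))
  info <- do.call(rbind, lapply(pieces, function(p) p$info))
  if (is.null(states)) {
    states <- matrix(character(), nrow = length(ids), ncol = 0L,
                     dimnames = list(ids, NULL))
  }
  colnames(states) <- paste(info$locus, info$kind, info$start, sep = ".")
  structure(list(states = states, info = info,
                 L = sum(vapply(dataset$alignments, ncol, 0L))),
            class = "coded_matrix")
}

config_by_locus <- function(dataset) {
  out <- setNames(vector("list", length(dataset$alignments)),
                  names(dataset$alignments))
  loci_cfg <- dataset$config$loci
  for (lc in loci_cfg) {
    if (!is.null(lc$name) && lc$name %in% names(out)) {
      inv <- NULL
      if (!is.null(lc$inversion)) inv <- c(lc$inversion$start, lc$inversion$end)
      out[[lc$name]] <- list(inversion = inv, mask_min_run = lc$mask_min_run)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.coded_matrix <- function(x, ...) {
  cat("<coded_matrix>", nrow(x$states), "individuals x", ncol(x$states),
      "characters; total aligned length", x$L, "bp\n")
  invisible(x)
}

#' Collapse individuals into haplotypes
#'
#' Individuals with identical state vectors share a haplotype. A missing
#' state matches nothing: individuals with any missing state at a retained
#' character are excluded from the catalog with a warning, so haplotype
#' identity stays exact. Labels are `H1, H2, ...` by descending total count,
#' ties broken by first occurrence in input order; a user-supplied label map
#' (named vector, default label -> custom label) is accepted for runs that
#' reproduce an external numbering.
#'
#' @param coded A `coded_matrix` (from [code_loci()]) or `coded_characters`.
#' @param populations A `population_table` covering the coded individuals.
#' @param label_map Optional named character vector renaming the
#'   frequency-ranked default labels.
#' @return A `haplotype_catalog`: list with `states` (haplotype x character),
#'   `info`, `counts` (haplotype x population), `pops` (population-level
#'   metadata with sample sizes), `assignment` (individual-level table),
#'   `L`, `excluded` (IDs dropped for missing data).
#' @export
collapse_haplotypes <- function(coded, populations, label_map = NULL) {
  populations <- validate_population_table(as.data.frame(populations))
  states <- coded$states
  stopifnot(nrow(states) >= 1L)
  states <- states[populations$individual_id, , drop = FALSE]
  has_na <- apply(states, 1L, anyNA)
  excluded <- rownames(states)[has_na]
  if (length(excluded)) {
    warning(length(excluded),
            " individual(s) excluded for missing states: ",
            paste(head(excluded, 5L), collapse = ", "),
            if (length(excluded) > 5L) ", ..." else "")
  }
  keep <- !has_na
  states <- states[keep, , drop = FALSE]
  pt <- populations[keep, , drop = FALSE]
  if (nrow(states) == 0L) stop("no individuals left after missing-data exclusion")
  key <- apply(states, 1L, paste, collapse = "\r")
  first_seen <- !duplicated(key)
  uniq_key <- key[first_seen]
  tot <- as.vector(table(factor(key, levels = uniq_key)))
  ord <- order(-tot, seq_along(uniq_key))
  uniq_key <- uniq_key[ord]
  tot <- tot[ord]
  labels <- paste0("H", seq_along(uniq_key))
  if (!is.null(label_map)) {
    hit <- labels %in% names(label_map)
    labels[hit] <- unname(label_map[labels[hit]])
  }
  assignment_lab <- labels[match(key, uniq_key)]
  hap_states <- states[match(uniq_key, key), , drop = FALSE]
  rownames(hap_states) <- labels
  pop_levels <- unique(pt$population_code)
  counts <- table(factor(assignment_lab, levels = labels),
                  factor(pt$population_code, levels = pop_levels))
  counts <- matrix(as.integer(counts), nrow = length(labels),
                   dimnames = list(labels, pop_levels))
  pops <- unique(populations[, c("population_code", "species", "latitude", "longitude")])
  pops <- pops[match(pop_levels, pops$population_code), , drop = FALSE]
  rownames(pops) <- NULL
  names(pops)[1L] <- "population"
  pops$n <- colSums(counts)
  assignment <- data.frame(individual_id = pt$individual_id,
                           population = pt$population_code,
                           species = pt$species,
                           haplotype = assignment_lab,
                           stringsAsFactors = FALSE)
  structure(list(states = hap_states, info = coded$info, counts = counts,
                 pops = pops, assignment = assignment, L = coded$L,
                 excluded = excluded),
            class = "haplotype_catalog")
}

#' Build a catalog directly from a haplotype count table
#'
#' Entry point for reproduction runs where the per-population haplotype
#' table (and optionally the inter-haplotype distance matrix) comes from an
#' external source rather than from sequence coding.
#'
#' @param counts Haplotype x population integer matrix with dimnames.
#' @param pops Data frame with columns `population`, `species`, `latitude`,
#'   `longitude` (one row per column of `counts`).
#' @param states Optional haplotype x character state matrix.
#' @param info Optional per-character provenance (needed for
#'   substitution-only distances).
#' @param L Optional total aligned length (bp), for nucleotide diversity.
#' @return A `haplotype_catalog`.
#' @export
catalog_from_counts <- function(counts, pops, states = NULL, info = NULL, L = NULL) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)), !is.null(colnames(counts)))
  pops <- as.data.frame(pops)
  stopifnot(all(c("population", "species", "latitude", "longitude") %in% names(pops)))
  pops <- pops[match(colnames(counts), pops$population), , drop = FALSE]
  rownames(pops) <- NULL
  pops$n <- colSums(counts)
  idx <- which(counts > 0, arr.ind = TRUE)
  assignment <- data.frame(
    individual_id = unlist(lapply(seq_len(nrow(idx)), function(k) {
      paste0(colnames(counts)[idx[k, 2L]], "_", rownames(counts)[idx[k, 1L]],
             "_", seq_len(counts[idx[k, 1L], idx[k, 2L]]))
    })),
    population = rep(colnames(counts)[idx[, 2L]], counts[idx]),
    species = rep(pops$species[idx[, 2L]], counts[idx]),
    haplotype = rep(rownames(counts)[idx[, 1L]], counts[idx]),
    stringsAsFactors = FALSE)
  structure(list(states = states, info = info, counts = counts, pops = pops,
                 assignment = assignment, L = L, excluded = character()),
            class = "haplotype_catalog")
}

#' @export
print.haplotype_catalog <- function(x, ...) {
  cat("<haplotype_catalog>", nrow(x$counts), "haplotypes,",
      sum(x$counts), "individuals,", ncol(x$counts), "populations,",
      length(unique(x$pops$species)), "species\n")
  shared <- sum(vapply(seq_len(nrow(x$counts)), function(i) {
    length(unique(x$pops$species[x$counts[i, ] > 0])) > 1L
  }, TRUE))
  cat("  shared by >1 species:", shared, "haplotypes\n")
  invisible(x)
}

#' @export
summary.haplotype_catalog <- function(object, ...) {
  ht <- haplotype_table(object)
  ht[order(-ht$total), c("haplotype", "total", "species")]
}
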