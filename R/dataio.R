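#' Read an aligned FASTA locus
#'
#' Reads one pre-aligned non-coding locus. Sequences must be equal length
#' (the alignment is an input, not something this package computes) and may
#' only contain `A`, `C`, `G`, `T`, `-` (gap) and `N` (missing). Lowercase is
#' normalised to uppercase.
#'
#' @param path Path to a FASTA file with at least one record.
#' @param locus_name Name used for this locus in coded characters and outputs.
#' @return A `cp_alignment`: a character matrix (individuals x alignment
#'   columns, single characters) with attributes `locus` and row names equal
#'   to the sequence IDs.
#' @export
read_alignment <- function(path, locus_name) {
  if (!file.exists(path)) stop("no records: file not found: ", path)
  recs <- ape::read.FASTA(path)
  if (length(recs) == 0L) stop("no records in ", path)
  chars <- lapply(as.character(recs), toupper)
  lens <- lengths(chars)
  if (length(unique(lens)) != 1L) {
    stop("not aligned: sequence lengths differ (", paste(unique(lens), collapse = ", "),
         ") in ", path)
  }
  ids <- names(recs)
  if (anyDuplicated(ids)) stop("duplicate sequence ids in ", path)
  m <- do.call(rbind, chars)
  rownames(m) <- ids
  cp_alignment(m, locus_name)
}

#' Construct an alignment object from a character matrix
#'
#' @param m Character matrix, one row per individual, one alignment column per
#'   matrix column, entries in `A,C,G,T,-,N`.
#' @param locus_name Locus label.
#' @return A `cp_alignment`.
#' @export
cp_alignment <- function(m, locus_name) {
  stopifnot(is.matrix(m), is.character(m), ncol(m) > 0L, !is.null(rownames(m)))
  bad <- which(!m %in% c("A", "C", "G", "T", "-", "N"))
  if (length(bad)) {
    pos <- arrayInd(bad[1L], dim(m))
    stop("bad character '", m[bad[1L]], "' at row ", rownames(m)[pos[1L]],
         ", column ", pos[2L], " of locus ", locus_name)
  }
  structure(m, locus = locus_name, class = c("cp_alignment", "matrix", "array"))
}

#' @export
print.cp_alignment <- function(x, ...) {
  cat("<cp_alignment> locus", attr(x, "locus"), "-", nrow(x), "sequences x",
      ncol(x), "bp\n")
  invisible(x)
}

#' Read the population metadata table
#'
#' Tab-separated with header columns `individual_id`, `population_code`,
#' `species`, `latitude`, `longitude` (decimal degrees, WGS84). Each
#' population must map to exactly one species and one coordinate pair.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with one row per individual (class
#'   `population_table`).
#' @export
read_population_table <- function(path) {
  tb <- read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  validate_population_table(tb)
}

#' Validate (and class) a population metadata table
#'
#' @param tb Data frame with columns `individual_id`, `population_code`,
#'   `species`, `latitude`, `longitude`.
#' @return The validated table, classed `population_table`.
#' @export
validate_population_table <- function(tb) {
  need <- c("individual_id", "population_code", "species", "latitude", "longitude")
  miss <- setdiff(need, names(tb))
  if (length(miss)) stop("population table missing columns: ", paste(miss, collapse = ", "))
  tb$individual_id <- as.character(tb$individual_id)
  tb$population_code <- as.character(tb$population_code)
  tb$species <- as.character(tb$species)
  tb$latitude <- as.numeric(tb$latitude)
  tb$longitude <- as.numeric(tb$longitude)
  if (anyDuplicated(tb$individual_id)) {
    stop("duplicate individual_id: ",
         paste(unique(tb$individual_id[duplicated(tb$individual_id)]), collapse = ", "))
  }
  if (any(!is.finite(tb$latitude)) || any(abs(tb$latitude) > 90)) {
    stop("latitude out of range [-90, 90]")
  }
  if (any(!is.finite(tb$longitude)) || any(abs(tb$longitude) > 180)) {
    stop("longitude out of range [-180, 180]")
  }
  for (col in c("species", "latitude", "longitude")) {
    n_per_pop <- tapply(tb[[col]], tb$population_code, function(v) length(unique(v)))
    if (any(n_per_pop > 1L)) {
      stop("population(s) with inconsistent ", col, ": ",
           paste(names(n_per_pop)[n_per_pop > 1L], collapse = ", "))
    }
  }
  class(tb) <- c("population_table", "data.frame")
  tb
}

#' Assemble a dataset of alignments plus metadata
#'
#' All loci must cover exactly the same individuals, and every individual in
#' the metadata must be present in every alignment (samples sequenced at both
#' loci are assumed; anything else is a hard error).
#'
#' @param alignments List of `cp_alignment` objects (one per locus).
#' @param populations A `population_table`.
#' @param config Optional per-locus coding configuration, as returned by
#'   [read_config()] (inversion regions, homopolymer mask threshold).
#' @return A `cp_dataset` list with elements `alignments`, `populations`,
#'   `config`.
#' @export
cp_dataset <- function(alignments, populations, config = NULL) {
  stopifnot(length(alignments) >= 1L)
  populations <- validate_population_table(as.data.frame(populations))
  ids <- rownames(alignments[[1L]])
  for (a in alignments) {
    if (!identical(sort(rownames(a)), sort(ids))) {
      stop("individual sets differ across loci")
    }
  }
  absent <- setdiff(populations$individual_id, ids)
  if (length(absent)) {
    stop("individuals in metadata absent from alignment: ",
         paste(head(absent, 5L), collapse = ", "))
  }
  extra <- setdiff(ids, populations$individual_id)
  if (length(extra)) {
    stop("individuals in alignment absent from metadata: ",
         paste(head(extra, 5L), collapse = ", "))
  }
  names(alignments) <- vapply(alignments, attr, "", "locus")
  structure(list(alignments = alignments, populations = populations,
                 config = config),
            class = "cp_dataset")
}

#' @export
print.cp_dataset <- function(x, ...) {
  cat("<cp_dataset>", length(x$alignments), "loci (",
      paste(names(x$alignments), collapse = ", "), ");",
      nrow(x$populations), "individuals,",
      length(unique(x$populations$population_code)), "populations,",
      length(unique(x$populations$species)), "species\n")
  invisible(x)
}

#' Read a YAML coding configuration
#'
#' Layout:
#' ```yaml
#' loci:
#'   - name: atpB-rbcL
#'     mask_min_run: 5
#'   - name: trnH-psbA
#'     inversion: {start: 120, end: 151}
#'     mask_min_run: 5
#' seed: 42
#' ```
#'
#' @param path YAML file path.
#' @return Parsed list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' Write pipeline outputs to a directory
#'
#' Writes whatever completed stage results are supplied: the haplotype table
#' (per-population counts + species occupancy), the network (GraphML and a
#' plain edge list with mutation counts), diversity/differentiation and AMOVA
#' tables, the sharing-test table and the nearby-sharing pair list. All
#' tables are UTF-8 TSV; a write-then-read round trip of the haplotype table
#' reproduces the counts exactly.
#'
#' @param results Named list; recognised elements: `catalog`
#'   (`haplotype_catalog`), `network` (`haplo_network`), `diversity`
#'   (data frame), `differentiation` (data frame), `amova` (data frame or
#'   `haplo_amova`), `sharing` (data frame), `pairs` (data frame),
#'   `correlogram` (data frame).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the character vector of files written.
#' @export
write_outputs <- function(results, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  if (file.access(out_dir, 2L) != 0L) stop("output directory not writable: ", out_dir)
  written <- character()
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write_tsv(df, p)
    written <<- c(written, p)
  }
  if (!is.null(results$catalog)) emit(haplotype_table(results$catalog), "haplotypes.tsv")
  if (!is.null(results$network)) {
    gp <- file.path(out_dir, "network.graphml")
    write_network_graphml(results$network, gp)
    written <- c(written, gp)
    emit(network_edge_list(results$network), "network_edges.tsv")
  }
  if (!is.null(results$diversity)) emit(results$diversity, "population_diversity.tsv")
  if (!is.null(results$differentiation)) emit(results$differentiation, "differentiation.tsv")
  if (!is.null(results$amova)) {
    am <- results$amova
    if (inherits(am, "haplo_amova")) am <- am$table
    emit(am, "amova.tsv")
  }
  if (!is.null(results$correlogram)) emit(results$correlogram, "correlogram.tsv")
  if (!is.null(results$sharing)) emit(results$sharing, "sharing_test.tsv")
  if (!is.null(results$pairs)) emit(results$pairs, "sharing_pairs.tsv")
  invisible(written)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
}

#' Tabulate a haplotype catalog
#'
#' One row per haplotype: label, total count, per-population counts, and
#' species occupancy (comma-joined species list).
#'
#' @param catalog A `haplotype_catalog`.
#' @return A data frame suitable for TSV export; [read_haplotype_table()]
#'   inverts it losslessly.
#' @export
haplotype_table <- function(catalog) {
  cnt <- catalog$counts
  occ <- vapply(seq_len(nrow(cnt)), function(i) {
    paste(sort(unique(catalog$pops$species[cnt[i, ] > 0])), collapse = ",")
  }, "")
  df <- data.frame(haplotype = rownames(cnt), total = rowSums(cnt),
                   species = occ, stringsAsFactors = FALSE, check.names = FALSE)
  cbind(df, as.data.frame(cnt, check.names = FALSE), row.names = NULL)
}

#' Read back a written haplotype table
#'
#' @param path TSV written by [write_outputs()] / [haplotype_table()].
#' @return List with `counts` (haplotype x population integer matrix) and
#'   `species` (named character vector of occupancy strings).
#' @export
read_haplotype_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("haplotype", "total", "species")
  cnt <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  storage.mode(cnt) <- "integer"
  rownames(cnt) <- df$haplotype
  list(counts = cnt, species = setNames(df$species, df$haplotype))
}
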