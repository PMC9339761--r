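#' Simulation parameters
#'
#' Defaults emulate the sampling design and haplotype structure the analysis
#' assumes: three species sampled over a shared landscape (33, 19 and 41
#' populations; 5-19 individuals each) and a pool of 27 haplotypes in three
#' plastid lineages - three high-frequency ancestral cores (sampling mass
#' 0.39/0.16/0.11, the typical widespread-internal-haplotype pattern),
#' eight low-frequency ancestral satellites shared randomly across species
#' (total mass 0.176), and sixteen rare tip haplotypes private to one
#' species within one refugium cluster (remaining mass, about 1% each).
#' Cores and satellites are assigned with geography-independent
#' probabilities; within-population fixation is strong (dominance 0.9,
#' giving the high-GST regime). Loci are non-coding, 726 and 614 aligned
#' bp. Lineage diagnostics
#' are planted as one A/G transition (first locus) and one 8-bp indel
#' (second locus); one tip carries a 32-bp inversion and two tips carry
#' private 5-6 bp indels so the whole coding stack is exercised.
#' Introgression, when switched on, copies a tip haplotype between
#' heterospecific populations closer than `introgression_radius_km`, at a
#' frequency drawn from `Beta(1, 3)`.
#'
#' @param seed RNG seed (mandatory).
#' @param pops_per_species Populations per species.
#' @param n_per_pop Range (min, max) of individuals per population.
#' @param tips_per_lineage Private tip haplotypes per lineage (A, B, C).
#' @param n_satellites Number of ancestral low-frequency satellites shared
#'   randomly across species.
#' @param core_freqs Global sampling mass of the three lineage cores.
#' @param satellite_mass Total sampling mass of the ancestral satellites;
#'   the remainder of the unit mass goes to the private tips.
#' @param dominance Within-population frequency of the dominant haplotype;
#'   the remaining individuals draw again from the same local pool, which
#'   also creates the low-frequency tip singletons seen in real samples.
#' @param introgression_rate Fraction of eligible nearby heterospecific
#'   population pairs receiving a copied tip haplotype. The default 0.1
#'   gives the default dataset both sharing modes at the low prevalence of
#'   local sharing seen in real range-wide surveys, while keeping
#'   among-population differentiation in the published 0.66-0.89 band;
#'   0 = ancestral sharing only, the null regime.
#' @param introgression_radius_km Radius within which introgression can act.
#' @param n_clusters Number of refugium clusters on the landscape.
#' @param cluster_sd_deg Spread (degrees) of populations around their
#'   cluster centre.
#' @param bbox Landscape bounding box `c(lat_min, lat_max, lon_min,
#'   lon_max)`.
#' @param locus_lengths Aligned lengths of the two loci (bp).
#' @param mask_min_run Homopolymer mask threshold carried into the dataset
#'   config.
#' @return A `sim_params` list.
#' @export
sim_params <- function(seed,
                       pops_per_species = c(33L, 19L, 41L),
                       n_per_pop = c(5L, 19L),
                       tips_per_lineage = c(A = 6L, B = 7L, C = 3L),
                       n_satellites = 8L,
                       core_freqs = c(A = 0.16, B = 0.39, C = 0.11),
                       satellite_mass = 0.176,
                       dominance = 0.9,
                       introgression_rate = 0.1,
                       introgression_radius_km = 300,
                       n_clusters = 6L,
                       cluster_sd_deg = 1.0,
                       bbox = c(23, 41, 100, 122),
                       locus_lengths = c(726L, 614L),
                       mask_min_run = 5L) {
  stopifnot(!missing(seed), length(pops_per_species) >= 2L,
            introgression_rate >= 0, introgression_rate <= 1,
            all(core_freqs > 0), sum(core_freqs) + satellite_mass < 1,
            dominance > 0, dominance <= 1)
  structure(list(seed = as.integer(seed),
                 pops_per_species = pops_per_species,
                 n_per_pop = n_per_pop,
                 tips_per_lineage = tips_per_lineage,
                 n_satellites = n_satellites,
                 core_freqs = core_freqs, satellite_mass = satellite_mass,
                 dominance = dominance,
                 introgression_rate = introgression_rate,
                 introgression_radius_km = introgression_radius_km,
                 n_clusters = n_clusters, cluster_sd_deg = cluster_sd_deg,
                 bbox = bbox, locus_lengths = locus_lengths,
                 mask_min_run = mask_min_run),
            class = "sim_params")
}

#' Simulate the haplotype pool (actual sequences)
#'
#' Builds a root sequence per locus (free of homopolymer runs), derives the
#' three lineage cores by planting the diagnostic mutations (core B is the
#' root; core A differs by one A/G transition in locus 1; core C by an 8-bp
#' deletion in locus 2), and derives satellites and tips from their lineage
#' core by 1-3 private substitutions (mostly one, matching the near-star
#' shape of observed plastid networks) - except one lineage-A tip and one
#' lineage-B tip that instead carry a private 5- or 6-bp deletion, and one
#' lineage-C tip that carries the 32-bp inversion in reversed orientation.
#' All mutation sites are distinct and avoid each other's regions, so the
#' coding module must recover exactly the planted characters.
#'
#' @param params A `sim_params` (its `seed` is used).
#' @return List with `sequences` (per haplotype: list of per-locus character
#'   vectors), `haplotypes` (data frame: `label`, `lineage`, `type`,
#'   `steps`), `inversion` (locus index + region), `n_characters` (planted
#'   polymorphic character count), `locus_names`.
#' @export
simulate_haplotype_pool <- function(params) {
  set.seed(params$seed)
  L <- params$locus_lengths
  locus_names <- c("locusA", "locusB")
  roots <- lapply(L, random_sequence)
  # reserved regions (locus 2): diagnostic 8-bp deletion and 32-bp inversion
  del_start <- 101L; del_end <- 108L
  inv_start <- 201L; inv_end <- 232L
  stopifnot(L[2L] > inv_end + 20L)
  # make the inversion region strongly non-palindromic so orientation
  # detection is unambiguous
  roots[[2L]][inv_start:inv_end] <- non_palindromic_segment(inv_end - inv_start + 1L)
  forbidden <- list(integer(), c(del_start:del_end, inv_start:inv_end))
  used <- list(integer(), integer())
  draw_site <- function(locus) {
    ok <- setdiff(seq_len(L[locus]), c(forbidden[[locus]], used[[locus]]))
    s <- sample(ok, 1L)
    used[[locus]] <<- c(used[[locus]], s)
    s
  }
  mutate <- function(seqs, locus, site) {
    cur <- seqs[[locus]][site]
    nb <- c(if (site > 1L) seqs[[locus]][site - 1L],
            if (site < L[locus]) seqs[[locus]][site + 1L])
    choices <- setdiff(c("A", "C", "G", "T"), c(cur, nb))
    seqs[[locus]][site] <- sample(choices, 1L)
    seqs
  }
  core_B <- roots
  diag_site <- draw_site(1L)
  core_A <- core_B
  core_A[[1L]][diag_site] <- if (core_B[[1L]][diag_site] == "A") "G" else "A"
  if (!core_B[[1L]][diag_site] %in% c("A", "G")) {
    core_A[[1L]][diag_site] <- "A"
    core_B[[1L]][diag_site] <- "G"
    roots <- core_B
  }
  core_C <- core_B
  core_C[[2L]][del_start:del_end] <- "-"
  cores <- list(A = core_A, B = core_B, C = core_C)
  tips_n <- params$tips_per_lineage
  labels <- c("coreA", "coreB", "coreC")
  seqs <- cores
  names(seqs) <- labels
  hap_rows <- data.frame(label = labels, lineage = c("A", "B", "C"),
                         type = "core", steps = 0L, stringsAsFactors = FALSE)
  n_sub_sites <- 1L  # the A|B diagnostic
  derive_subs <- function(s, steps) {
    for (k in seq_len(steps)) {
      locus <- sample(1:2, 1L)
      s <- mutate(s, locus, draw_site(locus))
      n_sub_sites <<- n_sub_sites + 1L
    }
    s
  }
  draw_steps <- function() sample(1:3, 1L, prob = c(0.7, 0.2, 0.1))
  sat_lineage <- sample(names(cores), params$n_satellites, replace = TRUE)
  for (t in seq_len(params$n_satellites)) {
    lab <- paste0("sat", t)
    steps <- draw_steps()
    seqs[[lab]] <- derive_subs(cores[[sat_lineage[t]]], steps)
    hap_rows <- rbind(hap_rows, data.frame(
      label = lab, lineage = sat_lineage[t], type = "satellite",
      steps = steps, stringsAsFactors = FALSE))
  }
  special <- list(A = "indel5", B = "indel6", C = "inversion")
  for (ln in names(tips_n)) {
    for (t in seq_len(tips_n[[ln]])) {
      lab <- paste0("tip", ln, t)
      s <- cores[[ln]]
      if (t == 1L && !is.null(special[[ln]])) {
        kind <- special[[ln]]
        if (kind == "indel5") {
          st <- pick_indel_start(5L, L[2L], forbidden[[2L]], used[[2L]])
          s[[2L]][st:(st + 4L)] <- "-"
          forbidden[[2L]] <- c(forbidden[[2L]], st:(st + 4L))
        } else if (kind == "indel6") {
          st <- pick_indel_start(6L, L[1L], forbidden[[1L]], used[[1L]])
          s[[1L]][st:(st + 5L)] <- "-"
          forbidden[[1L]] <- c(forbidden[[1L]], st:(st + 5L))
        } else {
          s[[2L]][inv_start:inv_end] <- rev_comp(s[[2L]][inv_start:inv_end])
        }
        steps <- 1L
      } else {
        steps <- draw_steps()
        s <- derive_subs(s, steps)
      }
      seqs[[lab]] <- s
      hap_rows <- rbind(hap_rows, data.frame(
        label = lab, lineage = ln, type = "tip", steps = steps,
        stringsAsFactors = FALSE))
    }
  }
  n_characters <- n_sub_sites + 3L + 1L  # substitutions + 3 indels + inversion
  list(sequences = seqs, haplotypes = hap_rows,
       inversion = list(locus = 2L, start = inv_start, end = inv_end),
       n_characters = n_characters, locus_names = locus_names,
       diag_substitution = diag_site)
}

random_sequence <- function(len) {
  bases <- c("A", "C", "G", "T")
  out <- character(len)
  out[1L] <- sample(bases, 1L)
  for (i in 2L:len) {
    # forbid runs of 3 identical bases so homopolymer masking stays inert
    banned <- if (i > 2L && out[i - 1L] == out[i - 2L]) out[i - 1L] else character()
    out[i] <- sample(setdiff(bases, banned), 1L)
  }
  out
}

non_palindromic_segment <- function(len) {
  repeat {
    seg <- random_sequence(len)
    if (sum(seg == rev_comp(seg)) < len / 4) return(seg)
  }
}

pick_indel_start <- function(len, L, forbidden, used) {
  repeat {
    st <- sample(10:(L - len - 10L), 1L)
    span <- st:(st + len - 1L)
    # keep one flanking column clear so gap runs never touch other features
    if (!any(c(span, st - 1L, st + len) %in% c(forbidden, used))) return(st)
  }
}

#' Simulate a full dataset with ground truth
#'
#' Places refugium cluster centres on the landscape (at least 500 km apart),
#' scatters populations of each species around them, and assigns haplotypes:
#' each population draws a dominant haplotype from the global pool (lineage
#' cores with their global mass, geography-independent; otherwise one of the
#' tips assigned to the population's own species-by-cluster cell), and each
#' individual carries the dominant with probability `dominance`, otherwise a
#' random core. Tips are therefore private to one species and one cluster
#' unless introgression copies them: for a `Bernoulli(introgression_rate)`
#' subset of heterospecific population pairs within the radius where one
#' population carries a tip, that tip is copied into the other population at
#' a `Beta(1, 3)` frequency (at least one individual). All introgression
#' events are recorded in the ground truth.
#'
#' @param params A `sim_params`.
#' @return A `cp_dataset` whose `truth` element holds the generator
#'   bookkeeping: `pool` (see [simulate_haplotype_pool()]), `assignment`
#'   (per individual: generator haplotype label), `events` (introgression
#'   records), `tip_cells`, `params`.
#' @export
simulate_dataset <- function(params) {
  pool <- simulate_haplotype_pool(params)  # seeds the RNG
  n_sp <- length(params$pops_per_species)
  species <- paste0("sp", seq_len(n_sp))
  centers <- place_clusters(params)
  pops <- list()
  for (s in seq_len(n_sp)) {
    for (p in seq_len(params$pops_per_species[s])) {
      cl <- sample.int(params$n_clusters, 1L)
      pops[[length(pops) + 1L]] <- data.frame(
        population = sprintf("%s_P%02d", species[s], p),
        species = species[s], cluster = cl,
        latitude = clamp(centers$lat[cl] + rnorm(1L, 0, params$cluster_sd_deg),
                         params$bbox[1L], params$bbox[2L]),
        longitude = clamp(centers$lon[cl] + rnorm(1L, 0, params$cluster_sd_deg),
                          params$bbox[3L], params$bbox[4L]),
        stringsAsFactors = FALSE)
    }
  }
  pops <- do.call(rbind, pops)
  P <- nrow(pops)
  hp <- pool$haplotypes
  tips <- hp$label[hp$type == "tip"]
  sats <- hp$label[hp$type == "satellite"]
  tip_cells <- data.frame(
    label = tips,
    species = sample(species, length(tips), replace = TRUE),
    cluster = sample.int(params$n_clusters, length(tips), replace = TRUE),
    stringsAsFactors = FALSE)
  cores <- hp$label[hp$type == "core"]
  core_p <- params$core_freqs / sum(params$core_freqs)
  core_mass <- sum(params$core_freqs)
  shared_mass <- core_mass + params$satellite_mass
  pops$n <- sample(params$n_per_pop[1L]:params$n_per_pop[2L], P, replace = TRUE)
  # per-population haplotype assignment
  assignment <- vector("list", P)
  dominant <- character(P)
  for (k in seq_len(P)) {
    cell_tips <- tip_cells$label[tip_cells$species == pops$species[k] &
                                   tip_cells$cluster == pops$cluster[k]]
    draw_local <- function() {
      u <- runif(1L)
      if (u < core_mass) {
        sample(cores, 1L, prob = core_p)
      } else if (u < shared_mass || !length(cell_tips)) {
        if (length(sats) == 1L) sats else sample(sats, 1L)
      } else if (length(cell_tips) == 1L) {
        cell_tips
      } else {
        sample(cell_tips, 1L)
      }
    }
    dom <- draw_local()
    dominant[k] <- dom
    n_k <- pops$n[k]
    # minors draw from the same local pool as the dominant, so co-resident
    # haplotype pairs are exchangeable draws - dominance concentrates
    # frequency without biasing co-occurrence toward particular haplotypes
    minor <- vapply(seq_len(n_k), function(i) draw_local(), "")
    hap <- ifelse(runif(n_k) < params$dominance, dom, minor)
    assignment[[k]] <- hap
  }
  # introgression between nearby heterospecific populations
  events <- list()
  protected <- lapply(seq_len(P), function(k) logical(pops$n[k]))
  if (params$introgression_rate > 0) {
    for (i in seq_len(P - 1L)) {
      for (j in (i + 1L):P) {
        if (pops$species[i] == pops$species[j]) next
        d <- haversine_km(pops$latitude[i], pops$longitude[i],
                          pops$latitude[j], pops$longitude[j])
        if (d >= params$introgression_radius_km) next
        tips_i <- unique(assignment[[i]][assignment[[i]] %in% tips])
        tips_j <- unique(assignment[[j]][assignment[[j]] %in% tips])
        has_i <- length(tips_i) > 0L
        has_j <- length(tips_j) > 0L
        if (!has_i && !has_j) next          # pair not eligible: nothing to give
        if (runif(1L) >= params$introgression_rate) next
        src <- if (has_i && has_j) sample(c(i, j), 1L) else if (has_i) i else j
        snk <- if (src == i) j else i
        src_tips <- if (src == i) tips_i else tips_j
        hap <- if (length(src_tips) == 1L) src_tips else sample(src_tips, 1L)
        n_snk <- pops$n[snk]
        n_copy <- max(1L, round(rbeta(1L, 1, 3) * n_snk))
        open <- which(!protected[[snk]])
        if (!length(open)) next
        take <- if (length(open) <= n_copy) open else sample(open, n_copy)
        assignment[[snk]][take] <- hap
        protected[[snk]][take] <- TRUE
        events[[length(events) + 1L]] <- data.frame(
          source = pops$population[src], sink = pops$population[snk],
          haplotype = hap, n_copies = length(take), distance_km = d,
          stringsAsFactors = FALSE)
      }
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(source = character(), sink = character(),
               haplotype = character(), n_copies = integer(),
               distance_km = numeric(), stringsAsFactors = FALSE)
  # flatten to individuals and emit sequences
  ind_pop <- rep(seq_len(P), pops$n)
  ind_id <- unlist(lapply(seq_len(P), function(k) {
    sprintf("%s_i%02d", pops$population[k], seq_len(pops$n[k]))
  }))
  ind_hap <- unlist(assignment)
  meta <- data.frame(individual_id = ind_id,
                     population_code = pops$population[ind_pop],
                     species = pops$species[ind_pop],
                     latitude = pops$latitude[ind_pop],
                     longitude = pops$longitude[ind_pop],
                     stringsAsFactors = FALSE)
  alignments <- lapply(1:2, function(locus) {
    m <- do.call(rbind, lapply(ind_hap, function(h) pool$sequences[[h]][[locus]]))
    rownames(m) <- ind_id
    cp_alignment(m, pool$locus_names[locus])
  })
  config <- list(loci = list(
    list(name = pool$locus_names[1L], mask_min_run = params$mask_min_run),
    list(name = pool$locus_names[2L], mask_min_run = params$mask_min_run,
         inversion = list(start = pool$inversion$start,
                          end = pool$inversion$end))))
  ds <- cp_dataset(alignments, meta, config)
  ds$truth <- list(pool = pool,
                   assignment = data.frame(individual_id = ind_id,
                                           population = pops$population[ind_pop],
                                           species = pops$species[ind_pop],
                                           haplotype = ind_hap,
                                           stringsAsFactors = FALSE),
                   pops = pops, tip_cells = tip_cells, dominant = dominant,
                   events = events, params = params)
  ds
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

place_clusters <- function(params, min_km = 500) {
  lat <- numeric(0); lon <- numeric(0)
  tries <- 0L
  while (length(lat) < params$n_clusters) {
    la <- runif(1L, params$bbox[1L] + 1.5, params$bbox[2L] - 1.5)
    lo <- runif(1L, params$bbox[3L] + 1.5, params$bbox[4L] - 1.5)
    tries <- tries + 1L
    if (!length(lat) || all(haversine_km(la, lo, lat, lon) >= min_km) ||
        tries > 500L) {
      lat <- c(lat, la); lon <- c(lon, lo)
    }
  }
  list(lat = lat, lon = lon)
}

#' Build a ground-truth haplotype catalog without sequence coding
#'
#' Collapses the generator's own haplotype assignment directly (bypassing
#' the coding stack), with inter-haplotype distances taken from the planted
#' mutation steps. Useful for fast replicate studies of the statistical
#' stages; the coding path is exercised by [code_loci()] on the same
#' dataset.
#'
#' @param dataset Output of [simulate_dataset()].
#' @return A `haplotype_catalog` whose labels are the generator labels.
#' @export
truth_catalog <- function(dataset) {
  tr <- dataset$truth
  asg <- tr$assignment
  labels <- unique(tr$pool$haplotypes$label)
  counts <- table(factor(asg$haplotype, levels = labels),
                  factor(asg$population, levels = tr$pops$population))
  counts <- matrix(as.integer(counts), nrow = length(labels),
                   dimnames = list(labels, tr$pops$population))
  keep <- rowSums(counts) > 0L
  counts <- counts[keep, , drop = FALSE]
  pops <- tr$pops[, c("population", "species", "latitude", "longitude")]
  cat <- catalog_from_counts(counts, pops)
  cat$assignment <- asg
  cat$states <- truth_states(tr$pool)[rownames(counts), , drop = FALSE]
  cat$info <- attr(cat$states, "info")
  cat$L <- sum(tr$params$locus_lengths)
  cat
}

# Character-state matrix of the planted pool, one column per planted
# character (substitution sites, the three indels, the inversion).
truth_states <- function(pool) {
  seqs <- pool$sequences
  labs <- names(seqs)
  cat2 <- function(locus) do.call(rbind, lapply(seqs, function(s) s[[locus]]))
  m1 <- cat2(1L); m2 <- cat2(2L)
  inv <- pool$inversion
  cols <- list(); info <- list()
  add <- function(st, kind, locus, startc) {
    cols[[length(cols) + 1L]] <<- st
    info[[length(info) + 1L]] <<- data.frame(locus = locus, kind = kind,
                                             start = startc,
                                             stringsAsFactors = FALSE)
  }
  for (locus in 1:2) {
    m <- if (locus == 1L) m1 else m2
    # substitution columns: >= 2 distinct bases
    gapfree <- apply(m, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
    inv_span <- if (locus == inv$locus) inv$start:inv$end else integer()
    for (j in which(gapfree)) {
      if (j %in% inv_span) next
      if (length(unique(m[, j])) >= 2L) add(m[, j], "substitution", locus, j)
    }
    # indel columns: gap runs (identical coordinates by construction)
    has_gap <- apply(m, 2L, function(col) any(col == "-"))
    runs <- rle(has_gap)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      add(ifelse(m[, starts[k]] == "-", "T", "A"), "indel", locus, starts[k])
    }
  }
  # inversion character: orientation relative to the majority
  seg <- m2[, inv$start:inv$end, drop = FALSE]
  ref <- seg[1L, ]
  same <- apply(seg, 1L, function(x) sum(x == ref) > length(ref) / 2)
  if (length(unique(same)) > 1L) add(ifelse(same, "A", "T"), "inversion", 2L, inv$start)
  st <- do.call(cbind, cols)
  rownames(st) <- labs
  inf <- do.call(rbind, info)
  inf$end <- inf$start
  inf$length_bp <- 1L
  colnames(st) <- paste(inf$locus, inf$kind, inf$start, sep = ".")
  attr(st, "info") <- inf
  st
}

#' Write a simulated dataset to disk
#'
#' FASTA per locus plus the metadata TSV, byte-stable for a fixed seed.
#'
#' @param dataset A `cp_dataset`.
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character()
  for (nm in names(dataset$alignments)) {
    aln <- dataset$alignments[[nm]]
    path <- file.path(dir, paste0(nm, ".fasta"))
    lines <- as.vector(rbind(paste0(">", rownames(aln)),
                             apply(aln, 1L, paste, collapse = "")))
    writeLines(lines, path)
    files <- c(files, path)
  }
  meta_path <- file.path(dir, "populations.tsv")
  write_tsv(dataset$populations, meta_path)
  invisible(c(files, meta_path))
}
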