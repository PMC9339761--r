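#' Pairwise Hamming distances between haplotypes
#'
#' Counts differing coded characters between state vectors. Indel and
#' inversion characters each contribute one mutation step, like a
#' substitution, because they were coded as single events.
#'
#' @param x A `haplotype_catalog` or a character state matrix (rows =
#'   haplotypes).
#' @param which `"all"` (default) or `"substitution"` to restrict to
#'   substitution characters (used for nucleotide diversity).
#' @return Symmetric integer matrix with zero diagonal.
#' @export
hamming_matrix <- function(x, which = c("all", "substitution")) {
  which <- match.arg(which)
  if (inherits(x, "haplotype_catalog")) {
    states <- x$states
    if (is.null(states)) stop("catalog carries no state vectors")
    if (which == "substitution") {
      states <- states[, x$info$kind == "substitution", drop = FALSE]
    }
  } else {
    states <- x
  }
  if (anyNA(states)) stop("missing state in haplotype vectors")
  n <- nrow(states)
  d <- matrix(0L, n, n, dimnames = list(rownames(states), rownames(states)))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dij <- sum(states[i, ] != states[j, ])
      d[i, j] <- d[j, i] <- as.integer(dij)
    }
  }
  d
}

#' Minimum spanning network
#'
#' The union of all minimum spanning trees over the given distance matrix:
#' an edge of weight `w` is kept whenever its endpoints are not already
#' connected by edges of weight `< w` (so all tied alternatives are
#' retained), relaxed by `epsilon`: edges are also kept if the endpoints are
#' unconnected at weight `< w - epsilon`.
#'
#' @param d Symmetric non-negative distance matrix with dimnames.
#' @param epsilon Non-negative integer relaxation (default 0).
#' @return Data frame of edges: `from`, `to`, `weight`.
#' @export
minimum_spanning_network <- function(d, epsilon = 0L) {
  stopifnot(isSymmetric(unname(d)), epsilon >= 0)
  nodes <- rownames(d)
  n <- length(nodes)
  if (n < 2L) {
    return(data.frame(from = character(), to = character(), weight = numeric(),
                      stringsAsFactors = FALSE))
  }
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[pairs]
  ord <- order(w, pairs[, 1L], pairs[, 2L])
  pairs <- pairs[ord, , drop = FALSE]
  w <- w[ord]
  keep <- logical(length(w))
  for (k in seq_along(w)) {
    # connectivity using strictly cheaper edges, relaxed by epsilon
    thr <- w[k] - epsilon
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    below <- which(w < thr)
    for (m in below) {
      ri <- find(pairs[m, 1L]); rj <- find(pairs[m, 2L])
      if (ri != rj) parent[ri] <- rj
    }
    keep[k] <- find(pairs[k, 1L]) != find(pairs[k, 2L])
  }
  data.frame(from = nodes[pairs[keep, 1L]], to = nodes[pairs[keep, 2L]],
             weight = w[keep], stringsAsFactors = FALSE)
}

#' Median-joining haplotype network
#'
#' Iteratively builds the minimum spanning network (MSN) over the current
#' node set, proposes median vectors (per-character majority state) for every
#' connected triplet, adds the medians whose connection cost is within
#' `epsilon` of the round's minimum, and removes inferred (unobserved) nodes
#' of degree two or less, until a fixpoint. The result always displays the
#' MSN over the observed haplotypes: every observed MSN link is present
#' either directly or as an equal-length path through median vectors. Ties are
#' resolved deterministically: nodes are kept in (observed-first, label)
#' order and candidate medians are processed in lexicographic state order.
#'
#' @param catalog A `haplotype_catalog` (or a state matrix whose rows are the
#'   observed haplotypes).
#' @param epsilon Non-negative integer (default 0, the usual network
#'   default).
#' @param max_iter Safety bound on median-addition rounds (default 50).
#' @return A `haplo_network`: list with `states` (node x character), `observed`
#'   (named logical), `edges` (`from`, `to`, `mutations`), `freq` (named
#'   totals, 0 for median vectors), `epsilon`.
#' @export
median_joining <- function(catalog, epsilon = 0L, max_iter = 50L) {
  if (inherits(catalog, "haplotype_catalog")) {
    states <- catalog$states
    freq <- rowSums(catalog$counts)
  } else {
    states <- catalog
    freq <- setNames(rep(1, nrow(states)), rownames(states))
  }
  stopifnot(nrow(states) >= 1L)
  # identical state vectors are one node: merge duplicates, summing totals
  dup_key <- apply(states, 1L, paste, collapse = "\r")
  if (anyDuplicated(dup_key)) {
    first <- !duplicated(dup_key)
    freq <- vapply(split(freq, dup_key), sum, 0)[dup_key[first]]
    states <- states[first, , drop = FALSE]
    names(freq) <- rownames(states)
  }
  observed_states <- states
  med_states <- states[0L, , drop = FALSE]
  blacklist <- character()
  key <- function(m) apply(m, 1L, paste, collapse = "\r")
  obs_keys <- key(observed_states)
  n_med <- 0L
  for (iter in seq_len(max_iter + 1L)) {
    if (iter > max_iter) {
      stop("median-joining did not converge within ", max_iter,
           " rounds; nodes = ", nrow(observed_states) + nrow(med_states))
    }
    nodes <- rbind(observed_states, med_states)
    d <- hamming_matrix(nodes)
    msn <- minimum_spanning_network(d, epsilon)
    deg <- degree_counts(rownames(nodes), msn)
    unobs <- rownames(med_states)
    prune <- unobs[deg[unobs] <= 2L]
    if (length(prune)) {
      blacklist <- c(blacklist, key(med_states[prune, , drop = FALSE]))
      med_states <- med_states[setdiff(rownames(med_states), prune), , drop = FALSE]
      next
    }
    cand <- propose_medians(nodes, msn)
    if (length(cand)) {
      ck <- names(cand)
      known <- c(obs_keys, key(med_states), blacklist)
      cand <- cand[!(ck %in% known)]
    }
    if (!length(cand)) break
    cost <- vapply(cand, function(m) {
      attr(m, "cost")
    }, 0)
    sel <- which(cost <= min(cost) + epsilon)
    sel <- sel[order(names(cand)[sel])]  # lexicographic state order
    for (s in sel) {
      n_med <- n_med + 1L
      m <- matrix(cand[[s]], nrow = 1L,
                  dimnames = list(paste0("mv", n_med), colnames(states)))
      med_states <- rbind(med_states, m)
    }
  }
  nodes <- rbind(observed_states, med_states)
  d <- hamming_matrix(nodes)
  msn <- minimum_spanning_network(d, epsilon)
  # the network must display the MSN over the observed haplotypes: keep any
  # observed link the medians did not resolve into an equal-length path
  obs_msn <- minimum_spanning_network(hamming_matrix(observed_states), epsilon)
  if (nrow(obs_msn)) {
    g <- igraph::graph_from_data_frame(msn, directed = FALSE,
                                       vertices = rownames(nodes))
    w <- if (nrow(msn)) msn$weight else numeric()
    sp <- igraph::distances(g, weights = w)
    missing_link <- vapply(seq_len(nrow(obs_msn)), function(k) {
      sp[obs_msn$from[k], obs_msn$to[k]] > obs_msn$weight[k]
    }, TRUE)
    if (any(missing_link)) {
      msn <- unique(rbind(msn, obs_msn[missing_link, , drop = FALSE]))
      msn <- msn[order(msn$weight, msn$from, msn$to), , drop = FALSE]
      rownames(msn) <- NULL
    }
  }
  names(msn)[names(msn) == "weight"] <- "mutations"
  observed <- setNames(c(rep(TRUE, nrow(observed_states)),
                         rep(FALSE, nrow(med_states))), rownames(nodes))
  freq_all <- setNames(rep(0, nrow(nodes)), rownames(nodes))
  freq_all[names(freq)] <- freq
  structure(list(states = nodes, observed = observed, edges = msn,
                 freq = freq_all, epsilon = epsilon),
            class = "haplo_network")
}

degree_counts <- function(nodes, edges) {
  deg <- setNames(integer(length(nodes)), nodes)
  if (nrow(edges)) {
    t1 <- table(factor(edges$from, levels = nodes))
    t2 <- table(factor(edges$to, levels = nodes))
    deg <- setNames(as.integer(t1 + t2), nodes)
  }
  deg
}

propose_medians <- function(nodes, msn) {
  adj <- split(c(msn$to, msn$from), c(msn$from, msn$to))
  out <- list()
  for (v in names(adj)) {
    nb <- sort(unique(adj[[v]]))
    if (length(nb) < 2L) next
    cmb <- combn(nb, 2L)
    for (c_i in seq_len(ncol(cmb))) {
      u <- cmb[1L, c_i]; w <- cmb[2L, c_i]
      m <- median_state(nodes[u, ], nodes[v, ], nodes[w, ])
      k <- paste(m, collapse = "\r")
      cost <- sum(m != nodes[u, ]) + sum(m != nodes[v, ]) + sum(m != nodes[w, ])
      if (is.null(out[[k]]) || attr(out[[k]], "cost") > cost) {
        attr(m, "cost") <- cost
        out[[k]] <- m
      }
    }
  }
  out
}

# Per-character majority of three state vectors; with three distinct states
# the central node's state is kept (deterministic tie rule).
median_state <- function(u, v, w) {
  out <- v
  same_uw <- u == w
  out[same_uw] <- u[same_uw]
  out
}

#' @export
print.haplo_network <- function(x, ...) {
  cat("<haplo_network>", sum(x$observed), "observed haplotypes +",
      sum(!x$observed), "median vectors;", nrow(x$edges), "edges (epsilon =",
      x$epsilon, ")\n")
  invisible(x)
}

#' Partition a network into lineages by diagnostic characters
#'
#' Removes every edge whose endpoints differ at any of the diagnostic
#' characters and labels the resulting connected components. Mirrors the
#' classical use of a single diagnostic transition and a diagnostic indel to
#' delimit plastid lineages.
#'
#' @param network A `haplo_network`.
#' @param diagnostic Character vector of column names of `network$states`
#'   (coded-character identifiers).
#' @param labels Optional labels assigned to components in order of their
#'   first node; defaults to `"A", "B", ...`.
#' @return A `lineage_partition`: named character vector node -> lineage,
#'   with the diagnostic characters as attribute.
#' @export
cut_lineages <- function(network, diagnostic, labels = NULL) {
  st <- network$states
  missing_chars <- setdiff(diagnostic, colnames(st))
  if (length(missing_chars)) {
    stop("unknown diagnostic character(s): ", paste(missing_chars, collapse = ", "))
  }
  for (ch in diagnostic) {
    if (length(unique(st[, ch])) < 2L) {
      stop("diagnostic character is monomorphic across network nodes: ", ch)
    }
  }
  edges <- network$edges
  if (nrow(edges)) {
    cut <- vapply(seq_len(nrow(edges)), function(k) {
      any(st[edges$from[k], diagnostic] != st[edges$to[k], diagnostic])
    }, TRUE)
    edges <- edges[!cut, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")], directed = FALSE,
                                     vertices = rownames(st))
  comp <- igraph::components(g)$membership
  comp <- comp[rownames(st)]
  if (is.null(labels)) labels <- LETTERS[seq_len(max(comp))]
  if (length(labels) < max(comp)) stop("need ", max(comp), " lineage labels")
  out <- setNames(labels[comp], rownames(st))
  attr(out, "diagnostic") <- diagnostic
  class(out) <- "lineage_partition"
  out
}

#' Convert a haplotype network to an igraph object
#'
#' Node attributes: `observed`, `total` (frequency), and `lineage` when a
#' partition is supplied; edge attribute `mutations`.
#'
#' @param network A `haplo_network`.
#' @param lineages Optional `lineage_partition`.
#' @return An `igraph` graph.
#' @export
as_igraph <- function(network, lineages = NULL) {
  verts <- data.frame(name = rownames(network$states),
                      observed = unname(network$observed),
                      total = unname(network$freq),
                      stringsAsFactors = FALSE)
  if (!is.null(lineages)) verts$lineage <- unname(unclass(lineages)[verts$name])
  igraph::graph_from_data_frame(network$edges, directed = FALSE, vertices = verts)
}

#' Write a network as GraphML
#'
#' @param network A `haplo_network`.
#' @param path Output file.
#' @param lineages Optional `lineage_partition` stored as a node attribute.
#' @return Invisibly, `path`.
#' @export
write_network_graphml <- function(network, path, lineages = NULL) {
  igraph::write_graph(as_igraph(network, lineages), path, format = "graphml")
  invisible(path)
}

#' Plain edge list of a haplotype network
#'
#' @param network A `haplo_network`.
#' @return Data frame `from`, `to`, `mutations`.
#' @export
network_edge_list <- function(network) {
  network$edges
}
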