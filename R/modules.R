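#' Maximal cliques of a graph
#'
#' All maximal cliques (Bron-Kerbosch with pivoting, via igraph),
#' returned in a deterministic order: each clique sorted by symbol,
#' cliques sorted by decreasing size then lexicographically.
#'
#' @param graph An undirected simple `igraph` graph with vertex names.
#' @param min_size Smallest clique size to return.
#' @return List of character vectors.
#' @export
maximal_cliques <- function(graph, min_size = 1L) {
  cl <- igraph::max_cliques(graph, min = min_size)
  cl <- lapply(cl, function(x) sort(igraph::V(graph)$name[x]))
  keys <- vapply(cl, paste, "", collapse = "|")
  cl[order(-lengths(cl), keys)]
}

community_key <- function(comm) paste(comm, collapse = "|")

# Modularity-style pair weight matrix B = A - k k' / 2m.
modularity_matrix <- function(graph) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  k <- igraph::degree(graph)
  m2 <- sum(k)
  list(B = A - outer(k, k) / m2, m2 = m2,
       genes = igraph::V(graph)$name)
}

#' Extended modularity of an overlapping cover
#'
#' EQ generalises Newman modularity to overlapping communities: each
#' vertex pair inside a community contributes
#' `(A[v,w] - k_v k_w / 2m) / (O_v O_w)` where `O_v` counts the
#' communities containing v, and the total is scaled by `1 / 2m`. A
#' single community spanning the whole graph with no overlap scores
#' exactly zero.
#'
#' @param graph An undirected simple `igraph` graph with vertex names.
#' @param cover List of character vectors (communities; overlap
#'   allowed) jointly covering every vertex.
#' @return The EQ value.
#' @export
extended_modularity <- function(graph, cover) {
  mm <- modularity_matrix(graph)
  uncovered <- setdiff(mm$genes, unlist(cover))
  if (length(uncovered)) {
    stop("cover misses vertex/vertices: ", paste(uncovered, collapse = ", "))
  }
  ov <- table(factor(unlist(cover), levels = mm$genes))
  eq <- 0
  for (comm in cover) {
    i <- match(comm, mm$genes)
    w <- 1 / as.numeric(ov[i])
    eq <- eq + sum((w %o% w) * mm$B[i, i, drop = FALSE])
  }
  eq / mm$m2
}

#' Overlapping hierarchical community detection (EAGLE)
#'
#' Agglomerative clique-based detection of overlapping, hierarchical
#' communities. The initial cover consists of all maximal cliques with
#' at least `clique_min` vertices plus a singleton for every vertex not
#' covered by those cliques (subordinate vertices). Pairs of
#' communities are then merged greedily, always the pair maximising the
#' modularity-style similarity
#' `S(C1, C2) = (1/2m) * sum_{v in C1, w in C2, v != w}
#' (A[v,w] - k_v k_w / 2m)`,
#' with ties broken by the lexicographically smallest pair, until one
#' community remains. Every level of the merge history is scored by
#' extended modularity EQ and the level with maximal EQ is returned as
#' the selected cover.
#'
#' @param graph An undirected simple `igraph` graph with vertex names
#'   and at least one edge.
#' @param clique_min Minimum size of initial maximal cliques.
#' @return A list of class `community_cover` with `communities` (the
#'   selected cover, each community sorted), `eq` (its extended
#'   modularity), `membership_counts` (named O_v vector), `dendrogram`
#'   (data frame of merges: `step`, `similarity`, `eq_after`) and
#'   `levels` (list of all covers along the merge history).
#' @export
eagle <- function(graph, clique_min = 4L) {
  genes <- igraph::V(graph)$name
  if (!length(genes)) stop("empty graph")
  cliques <- maximal_cliques(graph, min_size = clique_min)
  covered <- unique(unlist(cliques))
  singletons <- lapply(setdiff(genes, covered), function(g) g)
  comms <- c(cliques, singletons)
  comms <- comms[!duplicated(vapply(comms, community_key, ""))]
  mm <- modularity_matrix(graph)
  sim <- function(c1, c2) {
    i <- match(c1, mm$genes)
    j <- match(c2, mm$genes)
    s <- sum(mm$B[i, j, drop = FALSE])
    shared <- intersect(c1, c2)
    if (length(shared)) {
      d <- match(shared, mm$genes)
      s <- s - sum(diag(mm$B)[d])   # exclude v == w pairs
    }
    s / mm$m2
  }
  levels <- list(lapply(comms, identity))
  merges <- data.frame(step = integer(), similarity = numeric(),
                       eq_after = numeric())
  while (length(comms) > 1) {
    n <- length(comms)
    best <- NULL
    best_s <- -Inf
    keys <- vapply(comms, community_key, "")
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        s <- sim(comms[[a]], comms[[b]])
        pair_key <- paste(sort(c(keys[a], keys[b])), collapse = "<")
        if (s > best_s + 1e-12 ||
            (abs(s - best_s) <= 1e-12 && !is.null(best) &&
             pair_key < best$key)) {
          best <- list(a = a, b = b, key = pair_key)
          best_s <- s
        }
      }
    }
    merged <- sort(union(comms[[best$a]], comms[[best$b]]))
    comms <- comms[-c(best$a, best$b)]
    comms[[length(comms) + 1]] <- merged
    comms <- comms[!duplicated(vapply(comms, community_key, ""))]
    levels[[length(levels) + 1]] <- comms
    merges <- rbind(merges, data.frame(step = nrow(merges) + 1L,
                                       similarity = best_s,
                                       eq_after = NA_real_))
  }
  eqs <- vapply(levels, function(cv) extended_modularity(graph, cv), 0)
  if (nrow(merges)) merges$eq_after <- eqs[-1]
  sel <- which.max(eqs)
  cover <- levels[[sel]]
  ov <- table(factor(unlist(cover), levels = genes))
  structure(list(communities = cover, eq = eqs[sel],
                 membership_counts = stats::setNames(as.integer(ov), genes),
                 dendrogram = merges, levels = levels),
            class = "community_cover")
}

#' Read gene sets in GMT format
#'
#' One term per line: term id, description, then member genes,
#' tab-separated.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors; the `description` attribute
#'   of each element carries the second field.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) stop("malformed GMT line ", bad[1])
  sets <- lapply(fields, function(f) {
    genes <- f[-(1:2)]
    attr(genes, "description") <- f[2]
    genes
  })
  stats::setNames(sets, vapply(fields, `[[`, "", 1))
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors (optionally carrying a
#'   `description` attribute).
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- nm
    paste(c(nm, desc, as.character(sets[[nm]])), collapse = "\t")
  }, "")
  writeLines(lines, path)
}

#' Hypergeometric gene-set enrichment of a cluster
#'
#' One-sided hypergeometric upper-tail test of each gene set against a
#' fixed background (for the original study, the genes on the PPI
#' network). Reports the overlap count, the percentage of the cluster
#' in the term, the fold enrichment
#' `(overlap / cluster size) / (term size / background size)`, the raw
#' p-value and the Benjamini-Hochberg adjusted p-value. An EASE-style
#' variant (overlap reduced by one, as in DAVID) is available.
#'
#' @param cluster Character vector of cluster genes (subset of the
#'   background).
#' @param gene_sets Named list of character vectors (see
#'   [read_gmt()]); each set is intersected with the background.
#' @param background Character vector: the enrichment universe.
#' @param ease Use the conservative EASE score (overlap - 1).
#' @return Data frame sorted by p: `term_id`, `term_name`,
#'   `overlap_count`, `cluster_percent`, `fold_enrichment`, `p`,
#'   `adjusted_p`.
#' @export
enrich <- function(cluster, gene_sets, background, ease = FALSE) {
  if (!length(cluster)) stop("empty cluster")
  background <- unique(background)
  cluster <- unique(cluster)
  outside <- setdiff(cluster, background)
  if (length(outside)) {
    stop("cluster gene(s) outside the background: ",
         paste(utils::head(outside, 5), collapse = ", "))
  }
  n_bg <- length(background)
  n_cl <- length(cluster)
  rows <- lapply(names(gene_sets), function(term) {
    set <- intersect(gene_sets[[term]], background)
    ov <- length(intersect(set, cluster))
    eff <- if (ease) max(0, ov - 1) else ov
    p <- if (ov == 0) 1 else
      stats::phyper(eff - 1, length(set), n_bg - length(set), n_cl,
                    lower.tail = FALSE)
    desc <- attr(gene_sets[[term]], "description")
    data.frame(term_id = term,
               term_name = if (is.null(desc)) term else desc,
               overlap_count = ov,
               cluster_percent = ov / n_cl * 100,
               fold_enrichment = if (length(set)) {
                 (ov / n_cl) / (length(set) / n_bg)
               } else 0,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
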