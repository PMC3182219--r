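#' Load a protein-protein interaction network from an edge list
#'
#' Reads a tab-separated edge list of gene symbols. Both the plain
#' two-column dialect and the HPRD binary-interaction flat file (symbols
#' in columns 1 and 4) are understood; the dialect is auto-detected from
#' the column count unless given. Symbols are upper-cased, self-loops
#' removed, duplicate edges collapsed and isolated vertices dropped (a
#' random walk is undefined on them).
#'
#' @param path Path to the TSV file.
#' @param columns `"auto"`, `"plain"` (columns 1-2) or `"hprd"`
#'   (columns 1 and 4).
#' @param verbose Log vertex and edge counts.
#' @return An undirected simple `igraph` graph with vertex names.
#' @export
load_ppi <- function(path, columns = c("auto", "plain", "hprd"),
                     verbose = FALSE) {
  columns <- match.arg(columns)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_seen <- lengths(fields)
  if (any(ncol_seen < 2)) {
    stop("malformed edge list at line ",
         which(ncol_seen < 2)[1], ": fewer than 2 columns")
  }
  if (columns == "auto") {
    columns <- if (min(ncol_seen) >= 4) "hprd" else "plain"
  }
  idx <- if (columns == "hprd") c(1L, 4L) else c(1L, 2L)
  if (columns == "hprd" && any(ncol_seen < 4)) {
    stop("malformed edge list at line ", which(ncol_seen < 4)[1],
         ": HPRD dialect needs at least 4 columns")
  }
  from <- toupper(vapply(fields, `[[`, "", idx[1]))
  to <- toupper(vapply(fields, `[[`, "", idx[2]))
  g <- igraph::graph_from_data_frame(data.frame(from, to), directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  if (verbose) {
    message("PPI network: ", igraph::vcount(g), " vertices, ",
            igraph::ecount(g), " edges")
  }
  g
}

#' Assign each variant to a single gene by genomic context
#'
#' Resolves a variant that maps to several genes by the context
#' hierarchy coding > intronic > 5'UTR > 3'UTR > near gene (within 2 kb
#' of the 5' end or 0.5 kb of the 3' end). A purely intergenic variant
#' requires a curated override (for example from fine-mapping
#' literature) and is otherwise flagged unassigned.
#'
#' @param contexts Data frame with columns `variant_id`, `gene`,
#'   `context` (one of `"coding"`, `"intronic"`, `"utr5"`, `"utr3"`,
#'   `"near_gene"`, `"intergenic"`).
#' @param overrides Optional named character vector
#'   (variant_id -> gene) of curated assignments for intergenic
#'   variants.
#' @return Data frame with columns `variant_id`, `gene`, `basis`
#'   (winning context or `"curated"`/`"unassigned"`).
#' @export
assign_variant_gene <- function(contexts, overrides = NULL) {
  hierarchy <- c(coding = 1, intronic = 2, utr5 = 3, utr4 = NA,
                 utr3 = 4, near_gene = 5, intergenic = 6)
  hierarchy <- hierarchy[!is.na(hierarchy)]
  bad <- setdiff(unique(contexts$context), names(hierarchy))
  if (length(bad)) stop("unknown context class: ", paste(bad, collapse = ", "))
  rows <- lapply(split(contexts, contexts$variant_id), function(cc) {
    v <- cc$variant_id[1]
    ranks <- hierarchy[cc$context]
    genic <- cc[cc$context != "intergenic", , drop = FALSE]
    if (!nrow(genic)) {
      if (!is.null(overrides) && v %in% names(overrides)) {
        return(data.frame(variant_id = v, gene = overrides[[v]],
                          basis = "curated", stringsAsFactors = FALSE))
      }
      return(data.frame(variant_id = v, gene = NA_character_,
                        basis = "unassigned", stringsAsFactors = FALSE))
    }
    ranks <- hierarchy[genic$context]
    top <- genic[ranks == min(ranks), , drop = FALSE]
    if (length(unique(top$gene)) > 1) {
      stop("variant ", v, ": tie at context '", top$context[1],
           "' between genes ", paste(unique(top$gene), collapse = ", "),
           "; supply an override")
    }
    data.frame(variant_id = v, gene = top$gene[1], basis = top$context[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$variant_id), , drop = FALSE]
}

#' Random walk with restart on a gene network
#'
#' Iterates `p(t+1) = (1 - r) * t(M) p(t) + r * p(0)` where `M` is the
#' degree-normalised transition matrix (`M[v, w] = A[v, w] / k_v`) and
#' `p(0)` is uniform over the seed genes, until the L1 difference
#' between successive vectors is at most `tol`. Candidate (non-seed)
#' genes are ranked by their steady-state probability, ties broken by
#' symbol order.
#'
#' @param network An `igraph` graph with vertex names (see
#'   [load_ppi()]).
#' @param seeds Character vector of seed gene symbols, all present in
#'   the network.
#' @param r Restart probability in (0, 1\].
#' @param tol L1 convergence tolerance.
#' @param max_iter Maximum iterations.
#' @return A list of class `rwr_result` with `p` (named steady-state
#'   vector over all vertices), `seeds`, `r`, `iterations`, `residual`,
#'   `ranking` (data frame of non-seed genes: `gene`, `rank`,
#'   `probability`, `tied`).
#' @export
rwr <- function(network, seeds, r = 0.5, tol = 1e-10, max_iter = 10000L) {
  stopifnot(r > 0, r <= 1, length(seeds) >= 1)
  genes <- igraph::V(network)$name
  absent <- setdiff(seeds, genes)
  if (length(absent)) {
    stop("seed gene(s) absent from the network: ",
         paste(absent, collapse = ", "))
  }
  A <- igraph::as_adjacency_matrix(network, sparse = TRUE)
  k <- Matrix::rowSums(A)
  p0 <- numeric(length(genes))
  names(p0) <- genes
  p0[seeds] <- 1 / length(seeds)
  p <- p0
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # (t(M) p)_w = sum_v A[v, w] p_v / k_v ; A symmetric
    p_new <- (1 - r) * as.numeric(A %*% (p / k)) + r * p0
    res <- sum(abs(p_new - p))
    p <- p_new
    if (res <= tol) break
    if (iter >= max_iter) {
      stop("RWR did not converge in ", max_iter,
           " iterations (L1 residual ", signif(res, 3), ")")
    }
  }
  names(p) <- genes
  cand <- sort(setdiff(genes, seeds))
  pc <- p[cand]
  o <- order(-pc, cand)
  ranking <- data.frame(gene = cand[o], rank = seq_along(o),
                        probability = as.numeric(pc[o]),
                        stringsAsFactors = FALSE)
  ranking$tied <- duplicated(ranking$probability) |
    duplicated(ranking$probability, fromLast = TRUE)
  structure(list(p = p, seeds = seeds, r = r, iterations = iter,
                 residual = res, ranking = ranking),
            class = "rwr_result")
}

#' Leave-one-out cross-validation of network gene prioritization
#'
#' Each seed gene is withheld in turn, the walk is rerun from the
#' remaining seeds, and the rank of the withheld gene among itself plus
#' all non-seed genes is recorded. The ROC curve plots, for a sliding
#' rank threshold, the fraction of withheld genes recovered (TPR)
#' against the fraction of candidates above the threshold (FPR); the
#' AUC is the trapezoid area.
#'
#' @inheritParams rwr
#' @param include_left_out Whether the withheld gene competes against
#'   all non-seed genes plus itself (`TRUE`, default) or only the
#'   non-seed genes.
#' @return A list with `auc`, `ranks` (named vector, one per seed),
#'   `n_candidates`, `curve` (data frame `fpr`, `tpr`).
#' @export
loocv_roc <- function(network, seeds, r = 0.5, tol = 1e-10,
                      include_left_out = TRUE) {
  stopifnot(length(seeds) >= 2)
  genes <- igraph::V(network)$name
  non_seed <- setdiff(genes, seeds)
  ranks <- vapply(seeds, function(g) {
    res <- rwr(network, setdiff(seeds, g), r = r, tol = tol)
    pool <- c(non_seed, if (include_left_out) g)
    pv <- res$p[pool]
    o <- order(-pv, pool)
    which(pool[o] == g)
  }, 0L)
  n_cand <- length(non_seed) + as.integer(include_left_out)
  # TPR(k): fraction of withheld genes with rank <= k;
  # FPR(k): fraction of the candidate pool above the threshold.
  ks <- 0:n_cand
  tpr <- vapply(ks, function(k) mean(ranks <= k), 0)
  fpr <- ks / n_cand
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(auc = auc, ranks = ranks, n_candidates = n_cand,
       curve = data.frame(fpr = fpr, tpr = tpr))
}

#' Disease-associated subnetwork around the seed genes
#'
#' Induced subgraph on the seed genes plus the `top_k` highest-ranked
#' non-seed genes of a random walk result. Vertex attributes `seed`
#' (logical) and `rwr_rank` (NA for seeds) are attached.
#'
#' @inheritParams rwr
#' @param rwr_result Result of [rwr()] on the same network.
#' @param top_k Number of top-ranked non-seed genes to include.
#' @return An `igraph` subgraph.
#' @export
extract_subnetwork <- function(network, seeds, rwr_result, top_k = 100L) {
  ranking <- rwr_result$ranking
  if (top_k > nrow(ranking)) {
    stop("top_k (", top_k, ") exceeds the ", nrow(ranking),
         " non-seed genes available")
  }
  top <- ranking$gene[seq_len(top_k)]
  sub <- igraph::induced_subgraph(network, c(seeds, top))
  nm <- igraph::V(sub)$name
  igraph::V(sub)$seed <- nm %in% seeds
  rk <- stats::setNames(ranking$rank, ranking$gene)
  igraph::V(sub)$rwr_rank <- ifelse(nm %in% seeds, NA_integer_,
                                    as.integer(rk[nm]))
  sub
}
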