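#' Simulate a case-control cohort under the multiplicative risk model
#'
#' Draws genotypes for cases and controls by exact status-conditional
#' sampling under the constrained multiplicative model: case genotypes
#' come from per-locus tilted distributions (probability proportional
#' to genotype frequency times risk multiplier) with rejection
#' correcting for the risk cap, control genotypes from the population
#' distribution accepted with probability one minus the genotype risk.
#' No rare-disease shortcut is taken, so the exact-model AUC of the
#' same scenario is the true sampling oracle at any prevalence.
#'
#' @param scenario A [scenario_spec()] describing the loci (SNPs and/or
#'   one HLA block); additional-locus blocks are not allowed here.
#' @param n_case,n_control Numbers of subjects.
#' @param missing_rate Probability that any single genotype entry is
#'   set missing, uniformly at random.
#' @param seed Integer seed (mandatory; the generator is a pure
#'   function of configuration and seed).
#' @return A data frame: `subject_id`, `status` (1 case / 0 control),
#'   one column per SNP (`snp1`, ... or the row names of
#'   `scenario$snps`; dosage 0/1/2) and per HLA allele (`hla1`, ...;
#'   indicator count 0/1/2, summing to at most 2 per subject).
#' @export
gen_cohort <- function(scenario, n_case, n_control, missing_rate = 0.01,
                       seed) {
  if (!is.null(scenario$blocks) && nrow(scenario$blocks)) {
    stop("cohort simulation expects explicit loci, not additional-locus blocks")
  }
  snps <- scenario$snps
  hla <- scenario$hla
  loci <- genotype_locus_distributions(snps, hla)
  b <- calibrate_background(loci, scenario$prevalence,
                            scenario$calibration,
                            dist = if (scenario$calibration == "exact")
                              convolve_loci(loci) else NULL)
  n_snp <- if (is.null(snps)) 0L else nrow(snps)
  snp_names <- if (n_snp) {
    if (!is.null(snps$variant_id)) snps$variant_id
    else paste0("snp", seq_len(n_snp))
  }
  hla_names <- if (!is.null(hla) && nrow(hla)) {
    if (!is.null(hla$allele)) hla$allele else paste0("hla", seq_len(nrow(hla)))
  }
  withr_seed(seed, {
    cases <- sample_status_genotypes(loci, b, n_case, case = TRUE)
    controls <- sample_status_genotypes(loci, b, n_control, case = FALSE)
    g <- rbind(cases, controls)
    tab <- genotype_states_to_table(g, n_snp, snp_names, hla, hla_names)
    if (missing_rate > 0) {
      gm <- as.matrix(tab)
      miss <- matrix(stats::runif(length(gm)) < missing_rate, nrow(gm))
      gm[miss] <- NA_integer_
      tab <- as.data.frame(gm)
    }
    out <- data.frame(subject_id = sprintf("S%05d", seq_len(n_case + n_control)),
                      status = rep(c(1L, 0L), c(n_case, n_control)),
                      tab, stringsAsFactors = FALSE, check.names = FALSE)
  })
  out
}

# Sample per-locus genotype state indices given status (exact; see
# sample_status_risks for the acceptance logic).
sample_status_genotypes <- function(loci, b, n, case) {
  means <- vapply(loci, function(l) sum(l$multiplier * l$prob), 0)
  out <- NULL
  while (is.null(out) || nrow(out) < n) {
    m_take <- max((n - if (is.null(out)) 0L else nrow(out)) * 2L, 100L)
    states <- matrix(0L, m_take, length(loci))
    prod_mult <- rep(1, m_take)
    for (i in seq_along(loci)) {
      l <- loci[[i]]
      pr <- if (case) l$prob * l$multiplier / means[i] else l$prob
      idx <- sample.int(length(l$multiplier), m_take, replace = TRUE,
                        prob = pr)
      states[, i] <- idx
      prod_mult <- prod_mult * l$multiplier[idx]
    }
    uncapped <- b * prod_mult
    risk <- pmin(1, uncapped)
    acc <- if (case) stats::runif(m_take) < risk / uncapped
           else stats::runif(m_take) < (1 - risk)
    out <- rbind(out, states[acc, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# Convert per-locus state indices to dosage / HLA indicator columns.
genotype_states_to_table <- function(states, n_snp, snp_names, hla,
                                     hla_names) {
  cols <- list()
  for (i in seq_len(n_snp)) {
    cols[[snp_names[i]]] <- states[, i] - 1L   # states 1/2/3 -> dosage 0/1/2
  }
  if (!is.null(hla) && nrow(hla)) {
    # HLA block states enumerate unordered allele pairs (i <= j) over
    # the risk alleles plus the pooled other allele, in the order built
    # by genotype_locus_distributions.
    k <- nrow(hla) + 1L
    pairs <- do.call(rbind, lapply(seq_len(k), function(i) {
      cbind(i, i:k)
    }))
    st <- states[, n_snp + 1L]
    for (j in seq_len(nrow(hla))) {
      cols[[hla_names[j]]] <- (pairs[st, 1] == j) + (pairs[st, 2] == j)
    }
  }
  as.data.frame(cols, check.names = FALSE)
}

#' Simulate study-level meta-analysis records
#'
#' Each study draws a true log odds ratio from
#' `Normal(theta, tau2)`, sets the control risk-allele frequency to
#' `raf`, derives the case allele frequency through the allele-level
#' odds, and draws binomial allele counts.
#'
#' @param theta Mean log odds ratio across studies.
#' @param tau2 Between-study variance of the true log OR.
#' @param n_case_alleles,n_control_alleles Integer vectors of total
#'   allele counts per study (recycled to the same length).
#' @param raf Control-population risk allele frequency.
#' @param seed Integer seed.
#' @param ethnicity Optional vector of ethnicity labels per study.
#' @return Data frame of study records with allele-level 2x2 counts and
#'   the generating `true_log_or`.
#' @export
gen_meta_studies <- function(theta, tau2, n_case_alleles,
                             n_control_alleles, raf, seed,
                             ethnicity = "EastAsian") {
  stopifnot(tau2 >= 0, raf > 0, raf < 1)
  k <- max(length(n_case_alleles), length(n_control_alleles))
  n_case_alleles <- rep_len(n_case_alleles, k)
  n_control_alleles <- rep_len(n_control_alleles, k)
  withr_seed(seed, {
    true_lor <- stats::rnorm(k, theta, sqrt(tau2))
    odds_control <- raf / (1 - raf)
    p_case <- odds_control * exp(true_lor) /
      (1 + odds_control * exp(true_lor))
    out <- data.frame(
      study_id = sprintf("study%02d", seq_len(k)),
      variant_id = "sim_variant",
      ethnicity = rep_len(ethnicity, k),
      case_risk_alleles = stats::rbinom(k, n_case_alleles, p_case),
      case_total_alleles = n_case_alleles,
      control_risk_alleles = stats::rbinom(k, n_control_alleles, raf),
      control_total_alleles = n_control_alleles,
      true_log_or = true_lor,
      stringsAsFactors = FALSE
    )
  })
  out
}

#' Simulate a PPI-scale network with a planted seed-gene module
#'
#' A scale-free background graph (preferential attachment, matching the
#' heavy-tailed degree structure of curated interactome databases, or a
#' duplication-divergence variant) in which a chosen set of seed genes
#' is additionally wired among themselves with density
#' `planted_density`, creating the proximity structure that network
#' prioritization is meant to detect.
#'
#' @param n_vertices Number of genes.
#' @param edges_per_vertex Attachment parameter of the background model
#'   (expected edge count about `n_vertices * edges_per_vertex`).
#' @param model `"preferential_attachment"` or
#'   `"duplication_divergence"`.
#' @param planted_seeds Number of planted seed genes.
#' @param planted_density Edge probability among planted seeds (0 to
#'   plant nothing).
#' @param seed Integer seed.
#' @return A list with `network` (igraph, vertex names `G00001`, ...),
#'   `seed_genes` (character), `n_vertices`, `n_edges`.
#' @export
gen_ppi <- function(n_vertices = 9521L, edges_per_vertex = 4L,
                    model = c("preferential_attachment",
                              "duplication_divergence"),
                    planted_seeds = 19L, planted_density = 0.3,
                    seed) {
  model <- match.arg(model)
  withr_seed(seed, {
    g <- if (model == "preferential_attachment") {
      igraph::sample_pa(n_vertices, m = edges_per_vertex, directed = FALSE)
    } else {
      duplication_divergence_graph(n_vertices, edges_per_vertex)
    }
    igraph::V(g)$name <- sprintf("G%05d", seq_len(n_vertices))
    seeds <- sample(igraph::V(g)$name, planted_seeds)
    if (planted_density > 0 && planted_seeds >= 2) {
      pairs <- utils::combn(seeds, 2)
      add <- stats::runif(ncol(pairs)) < planted_density
      if (any(add)) {
        g <- igraph::add_edges(g, as.vector(pairs[, add, drop = FALSE]))
      }
    }
    g <- igraph::simplify(g)
    g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
    seeds <- intersect(seeds, igraph::V(g)$name)
  })
  list(network = g, seed_genes = seeds,
       n_vertices = igraph::vcount(g), n_edges = igraph::ecount(g))
}

# Minimal duplication-divergence growth: each new vertex copies a random
# existing vertex's edges, keeping each with probability 0.5, and always
# links to its template.
duplication_divergence_graph <- function(n, m_init) {
  g <- igraph::make_full_graph(min(n, m_init + 1L))
  while (igraph::vcount(g) < n) {
    tmpl <- sample.int(igraph::vcount(g), 1)
    nbrs <- as.integer(igraph::neighbors(g, tmpl))
    keep <- nbrs[stats::runif(length(nbrs)) < 0.5]
    g <- igraph::add_vertices(g, 1)
    v <- igraph::vcount(g)
    g <- igraph::add_edges(g, as.vector(rbind(v, c(tmpl, keep))))
  }
  g
}

#' Simulate gene sets in GMT form
#'
#' Random gene sets drawn from a gene universe, plus designated terms
#' that oversample a target cluster by a configurable factor, emulating
#' functionally enriched annotation categories.
#'
#' @param genes Gene universe (e.g. network vertex names).
#' @param n_terms Number of random terms.
#' @param size_range Integer range of term sizes.
#' @param enriched_cluster Genes of the cluster to enrich for (subset of
#'   `genes`); `NULL` for none.
#' @param enrichment_factor Sampling weight multiplier for cluster genes
#'   in the designated terms (1 = no enrichment).
#' @param n_enriched_terms Number of designated enriched terms.
#' @param seed Integer seed.
#' @return Named list of gene sets (writable with [write_gmt()]);
#'   enriched terms are named `ENR_...`.
#' @export
gen_gene_sets <- function(genes, n_terms = 50L, size_range = c(10L, 100L),
                          enriched_cluster = NULL, enrichment_factor = 1,
                          n_enriched_terms = 3L, seed) {
  if (!is.null(enriched_cluster)) {
    stopifnot(all(enriched_cluster %in% genes))
  }
  withr_seed(seed, {
    sets <- lapply(seq_len(n_terms), function(i) {
      sz <- sample(size_range[1]:size_range[2], 1)
      sort(sample(genes, sz))
    })
    names(sets) <- sprintf("TERM%03d", seq_len(n_terms))
    if (!is.null(enriched_cluster) && n_enriched_terms > 0) {
      w <- ifelse(genes %in% enriched_cluster, enrichment_factor, 1)
      enr <- lapply(seq_len(n_enriched_terms), function(i) {
        sz <- sample(size_range[1]:size_range[2], 1)
        sort(sample(genes, sz, prob = w))
      })
      names(enr) <- sprintf("ENR%03d", seq_len(n_enriched_terms))
      sets <- c(sets, enr)
    }
  })
  sets
}
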