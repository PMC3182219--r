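# Independent brute-force oracles used across the suite. Each is written
# from the definition of the quantity, not from the implementation path
# it checks.

# AUC by exhaustive comparison of every case-control pair.
bf_auc <- function(cases, controls) {
  s <- 0
  for (x in cases) for (y in controls) {
    s <- s + (x > y) + 0.5 * (x == y)
  }
  s / (length(cases) * length(controls))
}

# Exact HWE p-value by direct enumeration with the factorial formula.
bf_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- 2 * n_aa + n_Aa
  n_A <- 2 * n_AA + n_Aa
  if (n_a == 0 || n_A == 0) return(1)
  rare <- min(n_a, n_A)
  hs <- seq(rare %% 2, rare, by = 2)
  pr <- sapply(hs, function(h) {
    aa <- (rare - h) / 2
    AA <- n - aa - h
    exp(lfactorial(n) - lfactorial(AA) - lfactorial(h) - lfactorial(aa) +
          h * log(2) - (lfactorial(2 * n) - lfactorial(n_A) -
                          lfactorial(n_a)))
  })
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[hs == n_Aa] * (1 + 1e-12)])
}

# Upper binomial tail by term-by-term summation with exact coefficients.
bf_binom_tail <- function(k, n, alpha) {
  if (k == 0) return(1)
  sum(sapply(k:n, function(i) {
    choose(n, i) * alpha^i * (1 - alpha)^(n - i)
  }))
}

# Cochran's Q by direct summation.
bf_q <- function(log_or, se) {
  w <- 1 / se^2
  fe <- sum(w * log_or) / sum(w)
  sum(w * (log_or - fe)^2)
}

# AUC of a discrete risk distribution by summing over all support pairs.
bf_dist_auc <- function(dist) {
  s <- 0
  for (i in seq_along(dist$risk)) for (j in seq_along(dist$risk)) {
    cmp <- (dist$risk[i] > dist$risk[j]) + 0.5 * (dist$risk[i] == dist$risk[j])
    s <- s + dist$p_case[i] * dist$p_control[j] * cmp
  }
  s
}

# Hypergeometric upper tail by exact combinatorial summation.
bf_hyper_tail <- function(overlap, term, bg, cluster) {
  if (overlap == 0) return(1)
  ks <- overlap:min(term, cluster)
  sum(sapply(ks, function(k) {
    choose(term, k) * choose(bg - term, cluster - k) / choose(bg, cluster)
  }))
}

# All set partitions of a character vector (Bell-number enumeration).
bf_partitions <- function(xs) {
  if (length(xs) == 0) return(list(list()))
  rest <- bf_partitions(xs[-1])
  out <- list()
  for (p in rest) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(xs[1], q[[i]])
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(p, list(xs[1]))
  }
  out
}

# Maximal cliques by exhaustive subset checking (graphs <= 10 vertices).
bf_max_cliques <- function(graph) {
  vs <- igraph::V(graph)$name
  n <- length(vs)
  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  subsets <- lapply(seq_len(2^n - 1), function(mask) {
    vs[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
  })
  is_clique <- function(ss) {
    if (length(ss) <= 1) return(TRUE)
    all(A[ss, ss][upper.tri(diag(length(ss)))] == 1)
  }
  cliques <- Filter(is_clique, subsets)
  maximal <- Filter(function(ss) {
    !any(vapply(setdiff(vs, ss), function(v) {
      is_clique(c(ss, v))
    }, TRUE))
  }, cliques)
  lapply(maximal, sort)
}

# Fixed restart-walk point by direct linear solve:
# p = r (I - (1 - r) t(M))^{-1} p0.
bf_rwr_solve <- function(graph, seeds, r) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  k <- rowSums(A)
  M <- A / k
  n <- nrow(A)
  p0 <- numeric(n)
  names(p0) <- igraph::V(graph)$name
  p0[seeds] <- 1 / length(seeds)
  p <- r * solve(diag(n) - (1 - r) * t(M), p0)
  names(p) <- igraph::V(graph)$name
  p
}

# Small planted-module network: Erdos-Renyi background plus a densely
# wired seed set.
planted_network <- function(n = 150, p_bg = 0.02, n_seeds = 8,
                            p_seed = 0.9, seed = 1) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p_bg)
  igraph::V(g)$name <- sprintf("N%03d", seq_len(n))
  seeds <- sample(igraph::V(g)$name, n_seeds)
  pairs <- combn(seeds, 2)
  add <- runif(ncol(pairs)) < p_seed
  g <- igraph::add_edges(g, as.vector(pairs[, add, drop = FALSE]))
  g <- igraph::simplify(g)
  g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  list(network = g, seeds = intersect(seeds, igraph::V(g)$name))
}
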