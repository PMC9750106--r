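# Shared fixtures: the hand-checked worked examples and small oracles.

# CBN: A and B from root, C requires both (AND); all rates 1.
cbn_and_example <- function(l = c(A = 1, B = 1, C = 1)) {
  restriction_dag("CBN", c("A", "B", "C"),
                  parents = list(C = c("A", "B")),
                  relation = c(C = "AND"), param = l)
}

# CBN with two independent events (no edges).
cbn_two_independent <- function(l1 = 1, l2 = 1) {
  restriction_dag("CBN", c("E1", "E2"), param = c(E1 = l1, E2 = l2))
}

# OT: root -> A (0.8), A -> B (0.5).
ot_two_edge <- function(pA = 0.8, pB = 0.5) {
  restriction_dag("OT", c("A", "B"), parents = list(B = "A"),
                  param = c(A = pA, B = pB))
}

# OncoBN (disjunctive): roots A, B; C needs A OR B; all p = 0.5.
oncobn_or_example <- function() {
  restriction_dag("OncoBN", c("A", "B", "C"),
                  parents = list(C = c("A", "B")),
                  relation = c(C = "OR"), param = c(A = .5, B = .5, C = .5))
}

# H-ESBCN: roots A, B; C requires exactly one of A, B (XOR).
hesbcn_xor_example <- function() {
  restriction_dag("HESBCN", c("A", "B", "C"),
                  parents = list(C = c("A", "B")),
                  relation = c(C = "XOR"), param = c(A = 1, B = 1, C = 1))
}

random_any_model <- function(family, n, seed) {
  if (family == "MHN") random_mhn(n, seed = seed)
  else random_dag_model(family, n, seed = seed)
}

# Total-variation distance between a genotype_distribution and the empirical
# distribution of a 0/1 data matrix.
tv_empirical <- function(dist, data) {
  counts <- genotype_counts(data)
  emp <- as.numeric(counts) / sum(counts)
  p_at_obs <- distribution_probability(dist, attr(counts, "masks"))
  0.5 * (sum(abs(p_at_obs - emp)) + (1 - sum(p_at_obs)))
}

# Brute-force static reachability predicate: g is "statically reachable"
# when every event in g has its dependency satisfied within g minus itself.
static_reachable_masks <- function(dag) {
  n <- length(dag$events)
  ok <- vapply(0:(2L^n - 1L), function(g) {
    for (i in seq_len(n)) {
      b <- bitwShiftL(1L, i - 1L)
      if (bitwAnd(g, b) != 0L &&
          !dependency_satisfied(dag, dag$events[i], bitwAnd(g, bitwNot(b))))
        return(FALSE)
    }
    TRUE
  }, logical(1))
  sort(which(ok) - 1L)
}

# Brute-force maximum-weight arborescence by enumerating all parent
# assignments (root = node 1); for small matrices only.
brute_force_branching <- function(W) {
  n <- nrow(W)
  W[cbind(seq_len(n), seq_len(n))] <- -Inf
  W[, 1L] <- -Inf
  nodes <- 2:n
  choices <- lapply(nodes, function(v) seq_len(n)[-v])
  grid <- do.call(expand.grid, choices)
  best <- -Inf; best_par <- NULL
  for (r in seq_len(nrow(grid))) {
    par <- c(NA_integer_, as.integer(grid[r, ]))
    # acyclic check: follow parents up to the root
    ok <- TRUE
    for (v in nodes) {
      u <- v; steps <- 0L
      while (!is.na(par[u])) { u <- par[u]; steps <- steps + 1L
        if (steps > n) { ok <- FALSE; break } }
      if (!ok || u != 1L) { ok <- FALSE; break }
    }
    if (!ok) next
    w <- sum(W[cbind(par[nodes], nodes)])
    if (w > best) { best <- w; best_par <- par }
  }
  list(parent = best_par, weight = best)
}

branching_weight <- function(W, par) {
  W[cbind(seq_len(nrow(W)), seq_len(nrow(W)))] <- -Inf
  v <- which(!is.na(par))
  sum(W[cbind(par[v], v)])
}
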