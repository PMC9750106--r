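# Random model generation for simulation studies and property tests.
# DAGs are generated by drawing a random topological order and adding edges
# downward with a given density; parameter ranges default to rates in
# [0.5, 2] and probabilities in [0.1, 0.9] so that the expected number of
# events per sampled individual is moderate (neither all wild type nor all
# fully mutated).

#' Generate a random DAG-of-restrictions model
#'
#' OT models are random rooted trees (each event picks one parent among the
#' root and the events before it in a random topological order); CBN, OncoBN
#' and H-ESBCN models are random DAGs where each earlier event is a parent
#' of a later one with probability \code{edge_density}. Relations: CBN
#' multi-parent nodes are AND; OncoBN nodes all share one relation
#' (conjunctive = AND or disjunctive = OR, chosen by \code{oncobn_form});
#' H-ESBCN relations are drawn from \code{relation_mix}.
#'
#' @param family \code{"OT"}, \code{"CBN"}, \code{"OncoBN"} or
#'   \code{"HESBCN"}.
#' @param n number of events (>= 2).
#' @param seed optional integer seed.
#' @param edge_density probability of each possible non-root edge (DAG
#'   families other than OT; default 0.3).
#' @param rate_range range of uniform rates for timed families
#'   (default c(0.5, 2)).
#' @param prob_range range of uniform probabilities for untimed families
#'   (default c(0.1, 0.9)).
#' @param relation_mix named probabilities over c("AND", "OR", "XOR") for
#'   H-ESBCN multi-parent nodes (default uniform).
#' @param oncobn_form \code{"conjunctive"} (AND) or \code{"disjunctive"}
#'   (OR) for OncoBN multi-parent nodes.
#' @param events optional event names (default "E1".."En").
#' @return a valid \code{restriction_dag}.
#' @export
random_dag_model <- function(family, n, seed = NULL, edge_density = 0.3,
                             rate_range = c(0.5, 2),
                             prob_range = c(0.1, 0.9),
                             relation_mix = c(AND = 1, OR = 1, XOR = 1) / 3,
                             oncobn_form = c("conjunctive", "disjunctive"),
                             events = NULL) {
  family <- match.arg(family, .DAG_FAMILIES)
  oncobn_form <- match.arg(oncobn_form)
  stopifnot(n >= 2, n <= .MAX_EVENTS, edge_density >= 0, edge_density <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(events)) events <- paste0("E", seq_len(n))
  check_event_names(events)
  ord <- sample(events)                 # random topological order
  parents <- stats::setNames(rep(list(character(0)), n), events)
  relation <- stats::setNames(rep("SINGLE", n), events)
  mix <- relation_mix[relation_mix > 0]
  if (family == "HESBCN" &&
      (!length(mix) || !all(names(mix) %in% c("AND", "OR", "XOR"))))
    stop("relation_mix must put positive weight on AND, OR and/or XOR")
  for (k in seq_len(n)) {
    e <- ord[k]
    before <- ord[seq_len(k - 1L)]
    if (family == "OT") {
      pick <- sample(c("<root>", before), 1L)
      if (pick != "<root>") parents[[e]] <- pick
    } else if (length(before)) {
      sel <- before[stats::runif(length(before)) < edge_density]
      parents[[e]] <- sel
      if (length(sel) > 1L)
        relation[[e]] <- switch(family,
          CBN = "AND",
          OncoBN = if (oncobn_form == "conjunctive") "AND" else "OR",
          HESBCN = sample(names(mix), 1L, prob = mix))
    }
  }
  timed <- family %in% c("CBN", "HESBCN")
  rng <- if (timed) rate_range else prob_range
  param <- stats::setNames(stats::runif(n, rng[1], rng[2]), events)
  restriction_dag(family, events, parents, relation, param)
}

#' Generate a random mutual hazard network
#'
#' Diagonal (baseline log-hazard) entries are uniform on
#' \code{diagonal_range}; each off-diagonal entry is nonzero with
#' probability \code{1 - sparsity}, drawn uniformly from
#' \code{offdiagonal_range}.
#'
#' @param n number of events (>= 2).
#' @param seed optional integer seed.
#' @param diagonal_range default c(-3, 3).
#' @param offdiagonal_range default c(-2, 2).
#' @param sparsity probability that an off-diagonal entry is exactly 0
#'   (default 0.5).
#' @param events optional event names.
#' @return a valid \code{mhn_model}.
#' @export
random_mhn <- function(n, seed = NULL, diagonal_range = c(-3, 3),
                       offdiagonal_range = c(-2, 2), sparsity = 0.5,
                       events = NULL) {
  stopifnot(n >= 2, n <= .MAX_EVENTS, sparsity >= 0, sparsity <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(events)) events <- paste0("E", seq_len(n))
  theta <- matrix(0, n, n)
  off <- row(theta) != col(theta)
  nonzero <- off & matrix(stats::runif(n * n) >= sparsity, n, n)
  theta[nonzero] <- stats::runif(sum(nonzero), offdiagonal_range[1],
                                 offdiagonal_range[2])
  diag(theta) <- stats::runif(n, diagonal_range[1], diagonal_range[2])
  mhn_model(theta, events)
}

#' Generate a random model of any family
#'
#' Convenience dispatcher over [random_dag_model()] and [random_mhn()].
#'
#' @param family one of "OT", "CBN", "OncoBN", "HESBCN", "MHN".
#' @param n number of events.
#' @param seed optional integer seed.
#' @param ... passed to the family-specific generator.
#' @return a \code{cpm_model}.
#' @export
random_model <- function(family, n, seed = NULL, ...) {
  family <- match.arg(family, c(.DAG_FAMILIES, "MHN"))
  if (family == "MHN") random_mhn(n, seed = seed, ...)
  else random_dag_model(family, n, seed = seed, ...)
}
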