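# Exact genotype distributions for the untimed families (OT, OncoBN) via
# Bayesian-network factorisation over the DAG of restrictions. Edge weights
# are conditional probabilities of the child being present by observation
# time given its dependency is met (the Oncotree convention), so OT is the
# tree-restricted special case of conjunctive OncoBN and both share one code
# path.

#' Probability of a single genotype under an untimed model
#'
#' Bayes-net product over events: an event whose dependency is satisfied
#' within the genotype contributes its parameter p if present and (1 - p) if
#' absent; an event whose dependency is not satisfied contributes 0 if
#' present (the genotype violates the restrictions) and 1 if absent.
#'
#' @param dag an OT or OncoBN \code{restriction_dag}.
#' @param genotype genotype bit mask or character vector of present events.
#' @return probability in [0, 1].
#' @export
untimed_genotype_probability <- function(dag, genotype) {
  if (is_timed(dag))
    stop(dag$family,
         " is a timed family: use observation_distribution() instead")
  if (is.character(genotype)) genotype <- genotype_mask(genotype, dag$events)
  mask_untimed_probability(dag, as.integer(genotype))
}

#' @keywords internal
mask_untimed_probability <- function(dag, mask) {
  p <- 1
  for (i in seq_along(dag$events)) {
    present <- bitwAnd(mask, event_bit(i)) != 0L
    ok <- mask_dependency_satisfied(dag, i, mask)
    f <- if (ok) {
      if (present) dag$param[[i]] else 1 - dag$param[[i]]
    } else {
      if (present) 0 else 1
    }
    p <- p * f
    if (p == 0) break
  }
  p
}

#' Full genotype distribution of an untimed model
#'
#' Evaluates [untimed_genotype_probability()] over all 2^n genotypes. The
#' factorisation is a proper Bayesian network, so the result sums to 1
#' exactly (up to floating point).
#'
#' @param dag an OT or OncoBN \code{restriction_dag}.
#' @return a [genotype_distribution()].
#' @export
untimed_distribution <- function(dag) {
  if (is_timed(dag))
    stop(dag$family,
         " is a timed family: use observation_distribution() instead")
  masks <- all_genotype_masks(length(dag$events))
  p <- vapply(masks, function(m) mask_untimed_probability(dag, m), numeric(1))
  genotype_distribution(dag$events, masks, p)
}
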