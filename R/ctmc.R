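# Continuous-time Markov chain on the genotype lattice for the timed
# families (CBN, H-ESBCN, MHN). States are reachable genotypes in canonical
# order; the only transitions are single-event gains. The observation time is
# an independent Exponential(sampling_rate) censoring clock (default rate 1),
# never part of the rate matrix itself.

#' Rate of gaining one event from a genotype
#'
#' For the timed DAG families (CBN, H-ESBCN) the rate equals the event's
#' parameter when its parent dependency is satisfied within the genotype and
#' 0 otherwise. For MHN the rate is the product of the event's baseline
#' hazard and the multiplicative effects of the events already present:
#' \code{exp(theta[e, e] + sum(theta[e, i], i in genotype))}.
#'
#' @param model a timed \code{cpm_model} (CBN, H-ESBCN or MHN).
#' @param genotype genotype bit mask or character vector of present events.
#' @param event event name (must not already be in the genotype).
#' @return nonnegative rate.
#' @export
gain_rate <- function(model, genotype, event) {
  if (!is_timed(model))
    stop(model$family, " is an untimed family: no transition rates are defined")
  if (is.character(genotype)) genotype <- genotype_mask(genotype, model$events)
  i <- match(event, model$events)
  if (is.na(i))
    stop("unknown event '", event, "' -- model/data mismatch")
  if (bitwAnd(genotype, event_bit(i)) != 0L)
    stop("event '", event, "' is already present in the genotype")
  mask_gain_rate(model, as.integer(genotype), i)
}

#' @keywords internal
mask_gain_rate <- function(model, mask, event_idx) {
  if (inherits(model, "mhn_model")) {
    present <- which(bitwAnd(mask, event_bit(seq_along(model$events))) != 0L)
    exp(model$theta[event_idx, event_idx] +
          sum(model$theta[event_idx, present]))
  } else {
    if (mask_dependency_satisfied(model, event_idx, mask))
      model$param[[event_idx]] else 0
  }
}

#' @keywords internal
#' Gain rates from every reachable state: list(masks, rates [m x n], exit)
#' rates[g, e] is the rate of gaining event e from state masks[g]
#' (0 when e is present or its dependency is unsatisfied).
lattice_rates <- function(model, masks = reachable_genotypes(model)) {
  n <- length(model$events)
  m <- length(masks)
  rates <- matrix(0, m, n)
  for (gi in seq_len(m)) {
    g <- masks[gi]
    for (e in seq_len(n)) {
      if (bitwAnd(g, event_bit(e)) == 0L)
        rates[gi, e] <- mask_gain_rate(model, g, e)
    }
  }
  list(masks = masks, rates = rates, exit = rowSums(rates))
}

#' Transition rate matrix of the genotype-lattice CTMC
#'
#' Builds the generator Q over the reachable genotypes: \code{Q[g, h]} is the
#' gain rate from g to h for every h that adds exactly one event to g, and
#' the diagonal is minus the row sum, so rows sum to zero. The observation
#' clock is not part of Q: Q describes the evolutionary process only.
#'
#' @param model a timed \code{cpm_model}.
#' @return an object of class \code{rate_matrix}: list with \code{states}
#'   (genotype labels), \code{masks}, \code{events} and the matrix \code{Q}.
#' @export
rate_matrix <- function(model) {
  if (!is_timed(model))
    stop(model$family, " is an untimed family: no transition rates are defined")
  lr <- lattice_rates(model)
  m <- length(lr$masks)
  labels <- genotype_label(lr$masks, model$events)
  Q <- matrix(0, m, m, dimnames = list(labels, labels))
  idx <- match(seq_len(2L^length(model$events)) - 1L, lr$masks)
  for (gi in seq_len(m)) {
    for (e in which(lr$rates[gi, ] > 0)) {
      hi <- idx[bitwOr(lr$masks[gi], event_bit(e)) + 1L]
      Q[gi, hi] <- lr$rates[gi, e]
    }
  }
  diag(Q) <- -rowSums(Q)
  structure(list(states = labels, masks = lr$masks, events = model$events,
                 Q = Q),
            class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat("Transition rate matrix over", length(x$states), "reachable genotypes\n")
  print(round(x$Q, 4))
  invisible(x)
}

#' Jump-chain transition probabilities
#'
#' Competing-risks normalisation of a rate matrix: from a non-absorbing state
#' g, \code{P[g, h] = Q[g, h] / (-Q[g, g])}. Rows of absorbing states (no
#' outgoing gains) are all zero, not identity, so that path enumeration
#' terminates cleanly. The observation clock is excluded.
#'
#' @param rm a \code{rate_matrix}.
#' @return an object of class \code{transition_matrix}: list with
#'   \code{states}, \code{masks}, \code{events} and the matrix \code{P}.
#' @export
transition_matrix <- function(rm) {
  stopifnot(inherits(rm, "rate_matrix"))
  Q <- rm$Q
  P <- matrix(0, nrow(Q), ncol(Q), dimnames = dimnames(Q))
  exit <- -diag(Q)
  live <- exit > 0
  P[live, ] <- Q[live, , drop = FALSE] / exit[live]
  diag(P) <- 0
  structure(list(states = rm$states, masks = rm$masks, events = rm$events,
                 P = P),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("Jump-chain transition probabilities over", length(x$states),
      "reachable genotypes (absorbing rows are zero)\n")
  print(round(x$P, 4))
  invisible(x)
}

#' Genotype distribution at an exponential observation time
#'
#' Exact probability of observing each genotype when the accumulation process
#' starts at the wild type and is censored at an independent
#' Exponential(\code{sampling_rate}) time. Two independent computations are
#' provided: the lattice dynamic program (default) propagates
#' reach-probabilities rho(WT) = 1,
#' rho(h) = sum over predecessors g of rho(g) q(g,h) / (s + R(g)), and
#' returns P(g) = rho(g) s / (s + R(g)) with R(g) the total exit rate; the
#' linear-system route solves p = s e_WT' (sI - Q)^{-1} on the reachable
#' states. Both sum to 1 over the reachable genotypes.
#'
#' @param model a timed \code{cpm_model} (CBN, H-ESBCN or MHN).
#' @param sampling_rate positive rate of the exponential observation time
#'   (default 1, the standard convention).
#' @param method \code{"dp"} (lattice dynamic program) or \code{"linear"}
#'   (solve against the generator); the two agree to numerical precision and
#'   are cross-checked in the test suite.
#' @return a [genotype_distribution()].
#' @export
observation_distribution <- function(model, sampling_rate = 1,
                                     method = c("dp", "linear")) {
  method <- match.arg(method)
  if (!is_timed(model))
    stop(model$family,
         " is an untimed family: use untimed_distribution() instead")
  stopifnot(is.numeric(sampling_rate), sampling_rate > 0)
  lr <- lattice_rates(model)
  if (method == "linear") {
    rm <- rate_matrix(model)
    m <- length(rm$masks)
    A <- diag(sampling_rate, m) - t(rm$Q)
    p <- sampling_rate * solve(A, c(1, numeric(m - 1L)))
    return(genotype_distribution(model$events, rm$masks, p))
  }
  masks <- lr$masks          # canonical order: popcount then value
  m <- length(masks)
  idx <- match(seq_len(2L^length(model$events)) - 1L, masks)
  rho <- numeric(m)
  rho[1L] <- 1
  s <- sampling_rate
  for (gi in seq_len(m)) {
    denom <- s + lr$exit[gi]
    for (e in which(lr$rates[gi, ] > 0)) {
      hi <- idx[bitwOr(masks[gi], event_bit(e)) + 1L]
      rho[hi] <- rho[hi] + rho[gi] * lr$rates[gi, e] / denom
    }
  }
  p <- rho * s / (s + lr$exit)
  genotype_distribution(model$events, masks, p)
}
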