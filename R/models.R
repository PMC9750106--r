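# Model families for irreversible event accumulation:
#   OT      - oncogenetic tree (untimed; single parent per event)
#   CBN     - conjunctive Bayesian network (timed; AND dependencies)
#   OncoBN  - untimed DAG with AND or OR dependencies
#   HESBCN  - timed DAG with AND, OR or XOR dependencies
#   MHN     - mutual hazard network (timed; n x n log-hazard matrix, no DAG)
# Events are gained one at a time and never lost; a virtual root precedes all
# events and never appears in genotypes or data.

.DAG_FAMILIES <- c("OT", "CBN", "OncoBN", "HESBCN")
.RELATIONS <- c("SINGLE", "AND", "OR", "XOR")

#' Is a model family timed (rate-parameterised)?
#' @param model a \code{cpm_model}.
#' @return \code{TRUE} for CBN, H-ESBCN and MHN; \code{FALSE} for OT and OncoBN.
#' @export
is_timed <- function(model) UseMethod("is_timed")

#' @export
is_timed.restriction_dag <- function(model) model$family %in% c("CBN", "HESBCN")

#' @export
is_timed.mhn_model <- function(model) TRUE

#' Construct a DAG-of-restrictions model (OT, CBN, OncoBN or H-ESBCN)
#'
#' Each event has a set of parent events (empty set = child of the virtual
#' root), a dependency relation saying how multiple parents combine
#' (\code{AND}: all parents required; \code{OR}: at least one; \code{XOR}:
#' exactly one; \code{SINGLE} for at most one parent), and a parameter: an
#' exponential gain rate for the timed families (CBN, H-ESBCN) or a
#' conditional probability of presence by observation time for the untimed
#' families (OT, OncoBN).
#'
#' @param family one of \code{"OT"}, \code{"CBN"}, \code{"OncoBN"},
#'   \code{"HESBCN"}.
#' @param events ordered character vector of event names.
#' @param parents named list mapping event name to character vector of parent
#'   event names; events not listed are children of the root.
#' @param relation named character vector of relations per event; defaults to
#'   \code{"SINGLE"} for events with at most one parent. Required for
#'   multi-parent events.
#' @param param named numeric vector of per-event parameters (positive rates
#'   for timed families, probabilities in (0,1) for untimed families).
#' @param validate if \code{TRUE} (default) stop on any invariant violation.
#' @return an object of class \code{c("restriction_dag", "cpm_model")}.
#' @seealso [validate_model()], [mhn_model()]
#' @export
restriction_dag <- function(family, events, parents = list(), relation = NULL,
                            param, validate = TRUE) {
  family <- match.arg(family, .DAG_FAMILIES)
  check_event_names(events)
  full_parents <- stats::setNames(rep(list(character(0)), length(events)), events)
  if (length(parents)) {
    if (is.null(names(parents)) || any(!nzchar(names(parents))))
      stop("'parents' must be a named list")
    for (nm in names(parents))
      full_parents[[nm]] <- as.character(parents[[nm]])
  }
  full_rel <- stats::setNames(rep("SINGLE", length(events)), events)
  if (!is.null(relation)) {
    if (is.null(names(relation))) stop("'relation' must be named by event")
    full_rel[names(relation)] <- relation
  }
  if (is.null(names(param)))
    names(param) <- events[seq_along(param)]
  full_param <- stats::setNames(rep(NA_real_, length(events)), events)
  full_param[names(param)] <- as.numeric(param)
  model <- structure(list(family = family, events = events,
                          parents = full_parents, relation = full_rel,
                          param = full_param),
                     class = c("restriction_dag", "cpm_model"))
  if (validate) {
    v <- validate_model(model)
    if (length(v)) stop("invalid ", family, " model:\n  ",
                        paste(v, collapse = "\n  "))
  }
  model
}

#' Construct a mutual hazard network (MHN) model
#'
#' The MHN is fully specified by an n x n matrix of log-hazards Theta:
#' \code{theta[j, j]} is the log baseline hazard of event j and
#' \code{theta[j, i]} the log multiplicative (promoting or inhibiting) effect
#' of event i on the rate of event j. The rate of gaining event j from
#' genotype g is \code{exp(theta[j, j] + sum(theta[j, i] for i in g))}. There
#' is no DAG of restrictions: any finite real matrix is a valid model.
#'
#' @param theta numeric n x n matrix of log-hazards.
#' @param events character vector of event names; defaults to the row names of
#'   \code{theta} or generated names.
#' @param validate if \code{TRUE} (default) stop on invariant violations.
#' @return an object of class \code{c("mhn_model", "cpm_model")}.
#' @export
mhn_model <- function(theta, events = NULL, validate = TRUE) {
  theta <- as.matrix(theta)
  if (is.null(events)) {
    events <- rownames(theta)
    if (is.null(events)) events <- paste0("E", seq_len(nrow(theta)))
  }
  check_event_names(events)
  dimnames(theta) <- list(events, events)
  model <- structure(list(family = "MHN", events = events, theta = theta),
                     class = c("mhn_model", "cpm_model"))
  if (validate) {
    v <- validate_model(model)
    if (length(v)) stop("invalid MHN model:\n  ", paste(v, collapse = "\n  "))
  }
  model
}

#' Validate a model against its family's structural invariants
#'
#' Violations are returned as character descriptions (one per problem), not
#' thrown, so callers can inspect all problems at once. An empty character
#' vector means the model is valid.
#'
#' @param model a \code{restriction_dag} or \code{mhn_model}.
#' @return character vector of violation descriptions (possibly empty).
#' @export
validate_model <- function(model) UseMethod("validate_model")

#' @export
validate_model.restriction_dag <- function(model) {
  v <- character(0)
  ev <- model$events
  for (e in ev) {
    pa <- model$parents[[e]]
    bad <- setdiff(pa, ev)
    if (length(bad))
      v <- c(v, sprintf("node '%s': unknown parent(s) %s", e,
                        paste(bad, collapse = ", ")))
    if (e %in% pa) v <- c(v, sprintf("node '%s' is its own parent", e))
    if (anyDuplicated(pa)) v <- c(v, sprintf("node '%s': duplicated parents", e))
  }
  # acyclicity (and hence reachability of every node from the virtual root)
  if (!length(v) && !is_acyclic(model$parents, ev))
    v <- c(v, "restriction graph contains a cycle (events unreachable from root)")
  for (e in ev) {
    r <- model$relation[[e]]
    pa <- model$parents[[e]]
    if (!r %in% .RELATIONS)
      v <- c(v, sprintf("node '%s': unknown relation '%s'", e, r))
    if (length(pa) > 1L && r == "SINGLE")
      v <- c(v, sprintf("node '%s': relation SINGLE with %d parents", e, length(pa)))
    allowed <- switch(model$family,
                      OT = "SINGLE",
                      CBN = c("SINGLE", "AND"),
                      OncoBN = c("SINGLE", "AND", "OR"),
                      HESBCN = .RELATIONS)
    if (r %in% .RELATIONS && !r %in% allowed)
      v <- c(v, sprintf("node '%s': relation %s not allowed in family %s",
                        e, r, model$family))
    if (model$family == "OT" && length(pa) > 1L)
      v <- c(v, sprintf("node '%s' has %d parents; OT allows at most one",
                        e, length(pa)))
  }
  if (model$family == "OncoBN") {
    multi <- model$relation[vapply(model$parents, length, 1L) > 1L]
    if (length(unique(multi)) > 1L)
      v <- c(v, sprintf(
        "OncoBN multi-parent nodes must share one relation (found %s)",
        paste(unique(multi), collapse = ", ")))
  }
  p <- model$param
  if (anyNA(p)) {
    v <- c(v, sprintf("node '%s': missing parameter",
                      paste(ev[is.na(p)], collapse = "', '")))
  } else if (is_timed(model)) {
    bad <- ev[!is.finite(p) | p <= 0]
    if (length(bad))
      v <- c(v, sprintf("node '%s': rate must be a positive finite number",
                        bad))
  } else {
    bad <- ev[!is.finite(p) | p <= 0 | p >= 1]
    if (length(bad))
      v <- c(v, sprintf("node '%s': probability must lie in (0, 1)", bad))
  }
  v
}

#' @export
validate_model.mhn_model <- function(model) {
  v <- character(0)
  th <- model$theta
  n <- length(model$events)
  if (!is.numeric(th) || nrow(th) != n || ncol(th) != n)
    v <- c(v, sprintf("theta must be a numeric %d x %d matrix", n, n))
  else if (any(!is.finite(th))) {
    bad <- which(!is.finite(th), arr.ind = TRUE)
    v <- c(v, sprintf("theta[%d, %d] is not finite", bad[, 1], bad[, 2]))
  }
  v
}

#' @keywords internal
is_acyclic <- function(parents, events) {
  # Kahn topological sort on parent -> child edges
  indeg <- vapply(parents[events], length, 1L)
  children <- stats::setNames(rep(list(character(0)), length(events)), events)
  for (e in events) for (p in parents[[e]])
    children[[p]] <- c(children[[p]], e)
  queue <- events[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    e <- queue[1L]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in children[[e]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  seen == length(events)
}

#' Is an event's parent-dependency satisfied within a genotype?
#'
#' Decides whether \code{event} may be gained from \code{genotype}: with
#' relation SINGLE or AND all parents must be present, with OR at least one,
#' with XOR exactly one. Children of the virtual root (no parents) are always
#' gainable.
#'
#' @param dag a \code{restriction_dag}.
#' @param event event name.
#' @param genotype genotype as integer bit mask or character vector of present
#'   event names.
#' @return logical scalar.
#' @export
dependency_satisfied <- function(dag, event, genotype) {
  stopifnot(inherits(dag, "restriction_dag"))
  if (!event %in% dag$events)
    stop("unknown event '", event, "' -- model/data mismatch")
  if (is.character(genotype)) genotype <- genotype_mask(genotype, dag$events)
  mask_dependency_satisfied(dag, match(event, dag$events), as.integer(genotype))
}

#' @keywords internal
mask_dependency_satisfied <- function(dag, event_idx, mask) {
  pa <- dag$parents[[event_idx]]
  if (!length(pa)) return(TRUE)
  pidx <- match(pa, dag$events)
  present <- sum(bitwAnd(mask, event_bit(pidx)) != 0L)
  switch(dag$relation[[event_idx]],
         SINGLE = , AND = present == length(pa),
         OR = present >= 1L,
         XOR = present == 1L)
}

#' Genotypes reachable from the wild type under a model
#'
#' Breadth-first closure from WT under single-event gains; a gain of event e
#' from genotype g is allowed when e's dependency is satisfied within g (DAG
#' families) or always (MHN, which has no restrictions). Under XOR the
#' constraint applies at the moment the child is gained, so reachability is
#' path dependent and BFS (not a static predicate) is authoritative: a second
#' XOR parent may still be gained after the child.
#'
#' @param model a \code{cpm_model}.
#' @return integer vector of genotype bit masks in canonical order (always
#'   includes WT = 0).
#' @export
reachable_genotypes <- function(model) UseMethod("reachable_genotypes")

#' @export
reachable_genotypes.mhn_model <- function(model) {
  all_genotype_masks(length(model$events))
}

#' @export
reachable_genotypes.restriction_dag <- function(model) {
  n <- length(model$events)
  seen <- logical(2L^n)
  seen[1L] <- TRUE
  frontier <- 0L
  while (length(frontier)) {
    nxt <- integer(0)
    for (g in frontier) {
      for (i in seq_len(n)) {
        b <- event_bit(i)
        if (bitwAnd(g, b) == 0L && mask_dependency_satisfied(model, i, g)) {
          h <- bitwOr(g, b)
          if (!seen[h + 1L]) {
            seen[h + 1L] <- TRUE
            nxt <- c(nxt, h)
          }
        }
      }
    }
    frontier <- nxt
  }
  masks <- which(seen) - 1L
  masks[canonical_order(masks)]
}

#' @export
print.restriction_dag <- function(x, ...) {
  cat(sprintf("%s model (%s) over %d events: %s\n", x$family,
              if (is_timed(x)) "timed; rates" else "untimed; probabilities",
              length(x$events), paste(x$events, collapse = ", ")))
  for (e in x$events) {
    pa <- x$parents[[e]]
    cat(sprintf("  %s <- %s [%s] %s = %.4g\n", e,
                if (length(pa)) paste(pa, collapse = ", ") else "Root",
                x$relation[[e]],
                if (is_timed(x)) "rate" else "p", x$param[[e]]))
  }
  invisible(x)
}

#' @export
print.mhn_model <- function(x, ...) {
  cat(sprintf("MHN model over %d events (log-hazard matrix theta):\n",
              length(x$events)))
  print(round(x$theta, 4))
  invisible(x)
}

#' @export
coef.restriction_dag <- function(object, ...) object$param

#' @export
coef.mhn_model <- function(object, ...) object$theta

#' Predicted genotype distribution of a model
#'
#' Dispatches to [observation_distribution()] for the timed families (CBN,
#' H-ESBCN, MHN) and to [untimed_distribution()] for OT and OncoBN; optional
#' observational noise is applied as an exact flip-kernel convolution.
#'
#' @param object a \code{cpm_model}.
#' @param epsilon per-cell flip probability of observational (genotyping)
#'   error in [0, 0.5]; 0 (default) returns the pure model distribution.
#' @param sampling_rate rate of the exponential observation time (timed
#'   families only; default 1).
#' @param ... unused.
#' @return a [genotype_distribution()].
#' @export
predict.cpm_model <- function(object, epsilon = 0, sampling_rate = 1, ...) {
  d <- if (is_timed(object)) observation_distribution(object, sampling_rate)
       else untimed_distribution(object)
  if (epsilon > 0) d <- noisy_distribution(d, epsilon) else d
}

#' Simulate cross-sectional data from a model
#'
#' Draws \code{nsim} independent individuals from the model's predicted
#' genotype distribution (method \code{"exact"}) or by direct stochastic
#' simulation of the timed process (method \code{"gillespie"}), then applies
#' observational flip noise.
#'
#' @param object a \code{cpm_model}.
#' @param nsim number of individuals.
#' @param seed integer seed (optional).
#' @param epsilon observational flip probability in [0, 0.5].
#' @param method \code{"exact"} (sampling the analytic distribution) or
#'   \code{"gillespie"} (timed families only).
#' @param sampling_rate exponential observation rate for timed families.
#' @param ... unused.
#' @return binary matrix with one row per individual and event-named columns.
#' @export
simulate.cpm_model <- function(object, nsim = 1, seed = NULL, epsilon = 0,
                               method = c("exact", "gillespie"),
                               sampling_rate = 1, ...) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  data <- if (method == "gillespie")
    gillespie_sample(object, nsim, seed = NULL, sampling_rate = sampling_rate)
  else
    sample_genotypes(predict(object, sampling_rate = sampling_rate), nsim,
                     seed = NULL)
  if (epsilon > 0) data <- apply_noise(data, epsilon, seed = NULL)
  data
}
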