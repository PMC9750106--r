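# Evolutionary paths: WT -> absorbing-genotype sequences of single-event
# gains, with path probability = probability of that event order conditional
# on full progression to absorption. For the timed families the step
# probabilities come from the jump chain (competing-risks normalisation,
# observation clock excluded); untimed models define no dynamics, so the
# step probability of event e at genotype g is param(e) normalised over all
# currently satisfiable absent events -- a stated convention. Absorbing
# states need not be the all-events genotype (XOR and strongly inhibiting
# MHN models can dead-end earlier); paths end at any absorbing state.

#' Enumerate all evolutionary paths with their probabilities
#'
#' Depth-first enumeration of every WT-to-absorbing path on the reachable
#' genotype lattice. Probabilities multiply step probabilities along the
#' path and sum to 1 over all paths. Output is ordered by probability
#' (descending), ties broken lexicographically by path label.
#'
#' @param model any valid \code{cpm_model}.
#' @param max_paths guard against state-space explosion: error if the number
#'   of paths exceeds this cap (default 1e6); use [top_paths()] or a smaller
#'   model instead.
#' @return an object of class \code{evolutionary_paths}: a data frame with
#'   columns \code{path} (genotype labels joined by \code{" -> "}) and
#'   \code{probability}, with attribute \code{masks} holding the genotype
#'   mask sequence of each path.
#' @export
enumerate_paths <- function(model, max_paths = 1e6) {
  n <- length(model$events)
  if (is_timed(model)) {
    lr <- lattice_rates(model)
    step_fun <- function(gi) {
      r <- lr$rates[gi, ]
      if (lr$exit[gi] <= 0) return(NULL)
      e <- which(r > 0)
      list(events = e, prob = r[e] / lr$exit[gi])
    }
    masks <- lr$masks
  } else {
    masks <- reachable_genotypes(model)
    step_fun <- function(gi) {
      g <- masks[gi]
      e <- which(vapply(seq_len(n), function(i)
        bitwAnd(g, event_bit(i)) == 0L &&
          mask_dependency_satisfied(model, i, g), logical(1)))
      if (!length(e)) return(NULL)
      w <- model$param[e]
      list(events = e, prob = w / sum(w))
    }
  }
  idx <- match(seq_len(2L^n) - 1L, masks)
  paths <- vector("list", 0L)
  probs <- numeric(0)
  count <- 0L
  recurse <- function(gi, trail, prob) {
    st <- step_fun(gi)
    if (is.null(st)) {                       # absorbing state
      count <<- count + 1L
      if (count > max_paths)
        stop("more than ", max_paths, " evolutionary paths; raise ",
             "'max_paths' or truncate with top_paths()")
      paths[[count]] <<- trail
      probs[count] <<- prob
      return(invisible())
    }
    for (k in seq_along(st$events)) {
      h <- bitwOr(masks[gi], event_bit(st$events[k]))
      recurse(idx[h + 1L], c(trail, h), prob * st$prob[k])
    }
  }
  recurse(1L, 0L, 1)
  labels <- vapply(paths, function(ms)
    paste(genotype_label(ms, model$events), collapse = " -> "), character(1))
  ord <- order(-probs, labels)
  out <- data.frame(path = labels[ord], probability = probs[ord],
                    stringsAsFactors = FALSE)
  attr(out, "masks") <- paths[ord]
  attr(out, "events") <- model$events
  class(out) <- c("evolutionary_paths", "data.frame")
  out
}

#' First k evolutionary paths by probability
#'
#' @param model any valid \code{cpm_model}.
#' @param k number of paths to keep (0 gives an empty list; k larger than the
#'   number of paths gives all of them).
#' @param max_paths passed to [enumerate_paths()].
#' @return an \code{evolutionary_paths} object with at most k rows.
#' @export
top_paths <- function(model, k, max_paths = 1e6) {
  stopifnot(is.numeric(k), k >= 0)
  p <- enumerate_paths(model, max_paths = max_paths)
  k <- min(as.integer(k), nrow(p))
  out <- p[seq_len(k), , drop = FALSE]
  attr(out, "masks") <- attr(p, "masks")[seq_len(k)]
  attr(out, "events") <- attr(p, "events")
  class(out) <- class(p)
  out
}

#' @export
print.evolutionary_paths <- function(x, ...) {
  cat("Evolutionary paths (", nrow(x), "; probabilities sum to ",
      format(sum(x$probability)), ")\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Summed path probability per absorbing genotype
#'
#' @param paths an \code{evolutionary_paths} object.
#' @return named numeric vector: total probability of reaching each absorbing
#'   genotype, keyed by genotype label.
#' @export
absorbing_state_probabilities <- function(paths) {
  ends <- vapply(attr(paths, "masks"), function(m) m[length(m)], integer(1))
  tot <- tapply(paths$probability, ends, sum)
  stats::setNames(as.numeric(tot),
                  genotype_label(as.integer(names(tot)), attr(paths, "events")))
}
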