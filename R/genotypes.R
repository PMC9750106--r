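# Genotypes are encoded as integer bit masks over a fixed, ordered event set.
# Bit i (1-based, least significant first) corresponds to events[i].
# The canonical ordering used everywhere matrices and tables are emitted is
# (number of events, then numeric value of the bit pattern).

.MAX_EVENTS <- 12L

#' @keywords internal
check_event_names <- function(events) {
  if (!is.character(events) || length(events) < 1L)
    stop("'events' must be a character vector with at least one name")
  if (length(events) > .MAX_EVENTS)
    stop("at most ", .MAX_EVENTS, " events are supported (dense 2^n state space)")
  if (anyDuplicated(events))
    stop("event names must be unique")
  if (any(!nzchar(events)) || anyNA(events))
    stop("event names must be non-empty and non-missing")
  events
}

#' Number of set bits in each mask
#' @keywords internal
popcount <- function(masks) {
  masks <- as.integer(masks)
  out <- integer(length(masks))
  while (any(masks > 0L)) {
    out <- out + masks %% 2L
    masks <- masks %/% 2L
  }
  out
}

#' @keywords internal
event_bit <- function(i) bitwShiftL(1L, as.integer(i) - 1L)

#' Convert a set of event names to a genotype bit mask
#'
#' @param present character vector of event names present in the genotype
#'   (may be empty for the wild type).
#' @param events ordered character vector of all event names.
#' @return integer bit mask.
#' @export
genotype_mask <- function(present, events) {
  check_event_names(events)
  if (length(present) == 0L) return(0L)
  idx <- match(present, events)
  if (anyNA(idx))
    stop("unknown event(s): ", paste(present[is.na(idx)], collapse = ", "),
         " -- model/data mismatch")
  if (anyDuplicated(idx)) stop("duplicated event names in genotype")
  sum(event_bit(idx))
}

#' Event names present in a genotype bit mask
#'
#' @param mask integer bit mask.
#' @param events ordered character vector of all event names.
#' @export
mask_events <- function(mask, events) {
  events[bitwAnd(as.integer(mask), event_bit(seq_along(events))) != 0L]
}

#' Human-readable genotype labels
#'
#' Wild type (no events) is labelled \code{"WT"}; otherwise event names are
#' joined with \code{", "} in event-set order.
#'
#' @param masks integer vector of genotype bit masks.
#' @param events ordered character vector of all event names.
#' @return character vector of labels.
#' @export
genotype_label <- function(masks, events) {
  vapply(as.integer(masks), function(m) {
    if (m == 0L) "WT" else paste(mask_events(m, events), collapse = ", ")
  }, character(1))
}

#' @keywords internal
canonical_order <- function(masks) order(popcount(masks), masks)

#' All genotypes over n events in canonical order
#' @keywords internal
all_genotype_masks <- function(n) {
  masks <- 0:(2L^n - 1L)
  masks[canonical_order(masks)]
}

#' Genotype probability distribution
#'
#' Container for a probability mass over genotypes, stored in canonical order
#' (by number of events, then bit-pattern value). Genotypes not listed carry
#' probability zero.
#'
#' @param events ordered character vector of event names.
#' @param masks integer vector of genotype bit masks (distinct).
#' @param probs numeric vector of probabilities, same length as \code{masks};
#'   must be nonnegative and sum to 1 (tolerance 1e-9).
#' @return an object of class \code{genotype_distribution}: a data frame with
#'   columns \code{genotype} (label) and \code{probability}, plus attributes
#'   \code{events} and \code{masks}.
#' @export
genotype_distribution <- function(events, masks, probs) {
  check_event_names(events)
  masks <- as.integer(masks)
  if (length(masks) != length(probs)) stop("masks and probs length mismatch")
  if (anyDuplicated(masks)) stop("duplicated genotypes in distribution")
  if (any(probs < -1e-12)) stop("negative probability in distribution")
  probs <- pmax(probs, 0)
  if (abs(sum(probs) - 1) > 1e-9)
    stop("probabilities must sum to 1 (got ", format(sum(probs)), ")")
  ord <- canonical_order(masks)
  out <- data.frame(genotype = genotype_label(masks[ord], events),
                    probability = probs[ord],
                    stringsAsFactors = FALSE)
  attr(out, "events") <- events
  attr(out, "masks") <- masks[ord]
  class(out) <- c("genotype_distribution", "data.frame")
  out
}

#' @export
print.genotype_distribution <- function(x, ...) {
  cat("Genotype distribution over", length(attr(x, "events")), "events (",
      nrow(x), "genotypes with positive support listed )\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Look up genotype probabilities in a distribution
#'
#' @param dist a \code{genotype_distribution}.
#' @param masks integer genotype masks to query.
#' @return numeric vector; genotypes absent from the support return 0.
#' @export
distribution_probability <- function(dist, masks) {
  i <- match(as.integer(masks), attr(dist, "masks"))
  p <- dist$probability[i]
  p[is.na(i)] <- 0
  p
}

#' Expand a distribution to the full 2^n genotype lattice
#'
#' @keywords internal
full_prob_vector <- function(dist) {
  n <- length(attr(dist, "events"))
  p <- numeric(2L^n)
  p[attr(dist, "masks") + 1L] <- dist$probability
  p
}
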