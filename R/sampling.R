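# Finite-sample generation and observational (genotyping) error.
# Noise model: every cell of the individuals-by-events matrix is flipped
# independently with one probability epsilon in [0, 0.5] (no separate
# false-positive/false-negative rates). All randomness goes through R's
# default Mersenne-Twister generator; functions take an explicit seed and
# are byte-reproducible given the same seed and inputs.

#' @keywords internal
check_csd <- function(data) {
  if (!is.matrix(data)) data <- as.matrix(data)
  if (is.null(colnames(data))) stop("data must have event names as column names")
  check_event_names(colnames(data))
  if (!all(data %in% c(0L, 1L)))
    stop("cross-sectional data must be a 0/1 matrix")
  storage.mode(data) <- "integer"
  data
}

#' @keywords internal
masks_to_csd <- function(masks, events) {
  n <- length(events)
  m <- matrix(0L, length(masks), n, dimnames = list(NULL, events))
  for (j in seq_len(n))
    m[, j] <- as.integer(bitwAnd(masks, event_bit(j)) != 0L)
  m
}

#' @keywords internal
csd_to_masks <- function(data) {
  data <- check_csd(data)
  as.integer(data %*% event_bit(seq_len(ncol(data))))
}

#' Draw a finite cross-sectional sample from a genotype distribution
#'
#' @param dist a [genotype_distribution()].
#' @param N positive number of individuals.
#' @param seed optional integer seed for reproducibility.
#' @return N x n binary matrix with event names as column names.
#' @export
sample_genotypes <- function(dist, N, seed = NULL) {
  stopifnot(inherits(dist, "genotype_distribution"))
  if (!is.numeric(N) || N < 1) stop("N must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  masks <- attr(dist, "masks")
  draw <- sample.int(length(masks), size = N, replace = TRUE,
                     prob = dist$probability)
  masks_to_csd(masks[draw], attr(dist, "events"))
}

#' Apply observational flip noise to cross-sectional data
#'
#' Each cell is flipped (0 to 1 or 1 to 0) independently with probability
#' \code{epsilon}.
#'
#' @param data binary individuals-by-events matrix.
#' @param epsilon flip probability in [0, 0.5].
#' @param seed optional integer seed.
#' @return matrix of the same shape.
#' @export
apply_noise <- function(data, epsilon, seed = NULL) {
  data <- check_csd(data)
  stopifnot(is.numeric(epsilon), epsilon >= 0, epsilon <= 0.5)
  if (epsilon == 0) return(data)
  if (!is.null(seed)) set.seed(seed)
  flips <- matrix(stats::runif(length(data)) < epsilon, nrow(data), ncol(data))
  out <- (data + flips) %% 2L
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(data)
  out
}

#' Exact distribution after observational flip noise
#'
#' Convolves a genotype distribution with the symmetric per-cell flip kernel:
#' P'(h) = sum_g P(g) eps^d(g,h) (1-eps)^(n-d(g,h)) with d the Hamming
#' distance. Computed one bit at a time (each event's flip channel is
#' independent), which is exact and O(n 2^n).
#'
#' @param dist a [genotype_distribution()].
#' @param epsilon flip probability in [0, 0.5].
#' @return a [genotype_distribution()] over all 2^n genotypes (support may
#'   grow; at epsilon = 0.5 the result is uniform whatever the input).
#' @export
noisy_distribution <- function(dist, epsilon) {
  stopifnot(inherits(dist, "genotype_distribution"),
            is.numeric(epsilon), epsilon >= 0, epsilon <= 0.5)
  if (epsilon == 0) return(dist)
  events <- attr(dist, "events")
  n <- length(events)
  p <- full_prob_vector(dist)
  lattice <- 0:(2L^n - 1L)
  for (j in seq_len(n)) {
    flipped <- bitwXor(lattice, event_bit(j))
    p <- (1 - epsilon) * p + epsilon * p[flipped + 1L]
  }
  genotype_distribution(events, lattice, p)
}

#' Gillespie forward simulation of a timed model
#'
#' Simulates the generative story directly, per individual: draw an
#' observation time T ~ Exponential(\code{sampling_rate}), then run the
#' competing-exponentials gain process from the wild type (waiting times
#' Exponential(total exit rate), next event chosen with probability
#' proportional to its gain rate) until the clock passes T, and record the
#' genotype. With \code{until_absorption = TRUE} the observation clock is
#' ignored and each individual runs until it reaches an absorbing genotype
#' (used to check path probabilities). This simulator is the independent
#' stochastic oracle for [observation_distribution()] and
#' [enumerate_paths()].
#'
#' @param model a timed \code{cpm_model}.
#' @param N number of individuals.
#' @param seed optional integer seed.
#' @param sampling_rate positive exponential observation rate (default 1).
#' @param until_absorption run to absorption instead of censoring.
#' @return N x n binary matrix of observed genotypes.
#' @export
gillespie_sample <- function(model, N, seed = NULL, sampling_rate = 1,
                             until_absorption = FALSE) {
  if (!is_timed(model))
    stop(model$family, " is an untimed family: no stochastic dynamics defined")
  stopifnot(is.numeric(N), N >= 1)
  if (!is.null(seed)) set.seed(seed)
  lr <- lattice_rates(model)
  m <- length(lr$masks)
  state_of <- match(seq_len(2L^length(model$events)) - 1L, lr$masks)
  # per-state successor states and jump probabilities
  succ <- vector("list", m)
  for (gi in seq_len(m)) {
    e <- which(lr$rates[gi, ] > 0)
    if (length(e))
      succ[[gi]] <- list(
        to = state_of[bitwOr(lr$masks[gi], event_bit(e)) + 1L],
        prob = lr$rates[gi, e] / lr$exit[gi])
  }
  state <- rep(1L, N)
  t_left <- if (until_absorption) rep(Inf, N)
            else stats::rexp(N, rate = sampling_rate)
  active <- which(lr$exit[state] > 0)
  while (length(active)) {
    dt <- stats::rexp(length(active), rate = lr$exit[state[active]])
    if (until_absorption) {
      jump <- active
    } else {
      jumps <- dt < t_left[active]
      t_left[active] <- t_left[active] - dt
      jump <- active[jumps]
    }
    if (length(jump)) {
      for (gi in unique(state[jump])) {
        members <- jump[state[jump] == gi]
        s <- succ[[gi]]
        pick <- if (length(s$to) == 1L) rep(1L, length(members))
                else sample.int(length(s$to), length(members), replace = TRUE,
                                prob = s$prob)
        state[members] <- s$to[pick]
      }
    }
    active <- jump[lr$exit[state[jump]] > 0]
  }
  masks_to_csd(lr$masks[state], model$events)
}
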