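# Fitting the tractable families from cross-sectional 0/1 data:
#   fit_ot        - oncogenetic tree: Desper-style edge weights from padded
#                   pairwise frequencies + maximum-weight branching (Edmonds)
#   fit_mhn       - mutual hazard network: exact marginal likelihood on the
#                   2^n lattice, L1 penalty on off-diagonals, proximal
#                   gradient with analytic gradients
#   fit_cbn_rates - CBN exponential rates for a fixed DAG by quasi-Newton on
#                   log-rates; sampling rate fixed at 1 for identifiability
# All fits return a classed object with print/summary/coef/logLik/predict/
# simulate methods.

#' Log-likelihood of cross-sectional data under a model
#'
#' Computes sum over genotypes of N_g log P_model(g), where P_model comes
#' from the model's prediction path ([observation_distribution()] or
#' [untimed_distribution()], optionally convolved with flip noise). Can be
#' -Inf when the data contain genotypes the model forbids and epsilon = 0.
#'
#' @param model a \code{cpm_model}.
#' @param data binary individuals-by-events matrix (column order must match
#'   the model's events).
#' @param epsilon observational flip probability folded into the likelihood.
#' @param sampling_rate exponential observation rate (timed families).
#' @return log-likelihood (scalar).
#' @export
model_log_likelihood <- function(model, data, epsilon = 0, sampling_rate = 1) {
  data <- check_csd(data)
  if (!identical(colnames(data), model$events))
    stop("data column names do not match the model's events")
  masks <- csd_to_masks(data)
  tab <- table(masks)
  d <- predict(model, epsilon = epsilon, sampling_rate = sampling_rate)
  p <- distribution_probability(d, as.integer(names(tab)))
  sum(as.integer(tab) * log(p))
}

## ---- maximum-weight branching (Chu-Liu/Edmonds) ----

#' Maximum-weight branching (arborescence) rooted at a fixed node
#'
#' Chu-Liu/Edmonds algorithm on a dense weight matrix: \code{W[u, v]} is the
#' weight of edge u -> v. Every non-root node receives exactly one parent;
#' cycles among locally-best parents are contracted recursively.
#'
#' @param W square numeric weight matrix (\code{-Inf} forbids an edge).
#' @param root root node index (default 1).
#' @return integer vector of parent indices (\code{NA} for the root).
#' @export
max_weight_branching <- function(W, root = 1L) {
  n <- nrow(W)
  stopifnot(n == ncol(W), root >= 1L, root <= n)
  W[cbind(seq_len(n), seq_len(n))] <- -Inf
  W[, root] <- -Inf
  parent <- rep(NA_integer_, n)
  for (v in setdiff(seq_len(n), root)) parent[v] <- which.max(W[, v])
  cyc <- .find_cycle(parent, root)
  if (is.null(cyc)) return(parent)
  # contract the cycle into a super node and recurse
  keep <- setdiff(seq_len(n), cyc)
  k <- length(keep)
  new_id <- integer(n)
  new_id[keep] <- seq_len(k)
  new_id[cyc] <- k + 1L
  W2 <- matrix(-Inf, k + 1L, k + 1L)
  W2[seq_len(k), seq_len(k)] <- W[keep, keep]
  entry_for <- integer(k)   # best cycle entry vertex for each outside node
  for (ui in seq_len(k)) {
    u <- keep[ui]
    adj <- W[u, cyc] - W[cbind(parent[cyc], cyc)]
    best <- which.max(adj)
    entry_for[ui] <- cyc[best]
    W2[ui, k + 1L] <- adj[best]
  }
  exit_for <- integer(k)    # best cycle exit vertex towards each outside node
  for (vi in seq_len(k)) {
    v <- keep[vi]
    best <- which.max(W[cyc, v])
    exit_for[vi] <- cyc[best]
    W2[k + 1L, vi] <- W[cyc, v][best]
  }
  par2 <- max_weight_branching(W2, root = new_id[root])
  out <- rep(NA_integer_, n)
  for (vi in seq_len(k)) {
    v <- keep[vi]
    p2 <- par2[vi]
    if (is.na(p2)) next                 # root
    out[v] <- if (p2 == k + 1L) exit_for[vi] else keep[p2]
  }
  # cycle keeps its internal parents except at the chosen entry vertex
  out[cyc] <- parent[cyc]
  up <- par2[k + 1L]
  u_old <- keep[up]
  ventry <- entry_for[up]
  out[ventry] <- u_old
  out
}

#' @keywords internal
.find_cycle <- function(parent, root) {
  n <- length(parent)
  colour <- integer(n)                 # 0 unseen, 1 on stack, 2 done
  colour[root] <- 2L
  for (start in seq_len(n)) {
    v <- start
    path <- integer(0)
    while (colour[v] == 0L) {
      colour[v] <- 1L
      path <- c(path, v)
      v <- parent[v]
    }
    if (colour[v] == 1L)               # found a cycle; trim the tail
      return(path[seq(which(path == v), length(path))])
    colour[path] <- 2L
  }
  NULL
}

## ---- oncogenetic tree ----

#' Fit an oncogenetic tree to cross-sectional data
#'
#' Structure and parameters in one pass: (1) marginal and pairwise
#' frequencies with a pseudocount of 0.5 added to every cell of each 2 x 2
#' table; (2) Desper-style edge weights
#' w(i -> j) = 2 log p_ij - log(p_i + p_j) - log p_i - log p_j, with the
#' virtual root treated as an event present in every individual; (3)
#' maximum-weight branching rooted at the virtual root; (4) edge
#' probabilities p(child | parent) = p_{child and parent} / p_parent,
#' clipped to (0, 1).
#'
#' @param data binary individuals-by-events matrix (N >= 1, >= 1 event).
#' @return an object of class \code{cpm_fit} whose \code{model} is an OT
#'   \code{restriction_dag}. The reported log-likelihood can be \code{-Inf}
#'   when the data contain genotypes the fitted tree forbids.
#' @export
fit_ot <- function(data) {
  data <- check_csd(data)
  events <- colnames(data)
  n <- ncol(data)
  N <- nrow(data)
  ci <- colSums(data)
  const <- ci == 0L | ci == N
  if (any(const))
    stop("constant column(s) carry no tree information; remove event(s): ",
         paste(events[const], collapse = ", "))
  c11 <- crossprod(data)                       # pairwise joint counts
  Np <- N + 2
  p_i <- (ci + 1) / Np                         # padded marginals
  p_ij <- (c11 + 0.5) / Np                     # padded joint (diag unused)
  W <- matrix(-Inf, n + 1L, n + 1L)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    W[i + 1L, j + 1L] <- 2 * log(p_ij[i, j]) - log(p_i[i] + p_i[j]) -
      log(p_i[i]) - log(p_i[j])
  W[1L, -1L] <- log(p_i) - log(1 + p_i)        # root: p_root = 1, p_rj = p_j
  par <- max_weight_branching(W, root = 1L)
  parents <- list()
  prob <- numeric(n)
  for (j in seq_len(n)) {
    pj <- par[j + 1L]
    prob[j] <- if (pj == 1L) p_i[j] else {
      parents[[events[j]]] <- events[pj - 1L]
      p_ij[pj - 1L, j] / p_i[pj - 1L]
    }
  }
  prob <- pmin(pmax(prob, 1e-9), 1 - 1e-9)
  model <- restriction_dag("OT", events, parents,
                           param = stats::setNames(prob, events))
  new_cpm_fit(model, data,
              log_likelihood = model_log_likelihood(model, data),
              diagnostics = list(method = "ot-branching", iterations = 1L,
                                 converged = TRUE, penalty = 0,
                                 pseudocount = 0.5))
}

## ---- mutual hazard network ----

#' @keywords internal
#' Exact observed-genotype probabilities for an MHN theta, plus (optionally)
#' the gradient of sum(counts * log p) with respect to every theta entry.
#' counts is indexed like the canonical all-genotype mask order.
.mhn_dp <- function(theta, s, counts = NULL, gradient = FALSE) {
  n <- nrow(theta)
  masks <- all_genotype_masks(n)
  m <- length(masks)
  idx <- match(0:(m - 1L), masks)
  bits <- event_bit(seq_len(n))
  q <- matrix(0, m, n)
  for (gi in seq_len(m)) {
    g <- masks[gi]
    present <- which(bitwAnd(g, bits) != 0L)
    for (e in seq_len(n)) if (bitwAnd(g, bits[e]) == 0L)
      q[gi, e] <- exp(theta[e, e] + sum(theta[e, present]))
  }
  R <- rowSums(q)
  succ_e <- lapply(seq_len(m), function(gi) which(q[gi, ] > 0))
  succ_h <- lapply(seq_len(m), function(gi)
    idx[bitwOr(masks[gi], bits[succ_e[[gi]]]) + 1L])
  rho <- numeric(m)
  rho[1L] <- 1
  for (gi in seq_len(m)) {
    denom <- s + R[gi]
    es <- succ_e[[gi]]
    if (length(es))
      rho[succ_h[[gi]]] <- rho[succ_h[[gi]]] + rho[gi] * q[gi, es] / denom
  }
  p <- rho * s / (s + R)
  out <- list(masks = masks, p = p)
  if (!gradient) return(out)
  grad <- matrix(0, n, n)
  w <- counts / p                       # d LL / d p
  for (j in seq_len(n)) for (i in seq_len(n)) {
    active <- bitwAnd(masks, bits[j]) == 0L &
      (i == j | bitwAnd(masks, bits[i]) != 0L)
    dqj <- ifelse(active, q[, j], 0)    # derivative of q[, j]; dR = dqj
    drho <- numeric(m)
    for (gi in seq_len(m)) {
      if (rho[gi] == 0 && drho[gi] == 0) next
      denom <- s + R[gi]
      es <- succ_e[[gi]]
      if (!length(es)) next
      hs <- succ_h[[gi]]
      add <- drho[gi] * q[gi, es] / denom -
        rho[gi] * q[gi, es] * dqj[gi] / denom^2
      ej <- which(es == j)
      if (length(ej))
        add[ej] <- add[ej] + rho[gi] * dqj[gi] / denom
      drho[hs] <- drho[hs] + add
    }
    dp <- drho * s / (s + R) - rho * s * dqj / (s + R)^2
    grad[j, i] <- sum(w * dp)
  }
  out$grad <- grad
  out
}

#' Fit a mutual hazard network by penalised maximum likelihood
#'
#' Maximises sum_g N_g log p_theta(g) - lambda * sum_{i != j} |theta_ij|,
#' where p_theta is the exact genotype distribution at an Exponential(1)
#' observation time computed on the full 2^n lattice. Optimisation is
#' proximal gradient (soft-thresholding of the off-diagonals) with
#' backtracking line search and analytic gradients; the penalised objective
#' is non-increasing over accepted iterates. Initial theta: diagonal from
#' the per-event closed form log(f / (1 - f)), off-diagonals 0.
#'
#' @param data binary individuals-by-events matrix (n <= 12).
#' @param lambda_penalty nonnegative L1 penalty on off-diagonal entries
#'   (on the scale of the total, unnormalised log-likelihood).
#' @param seed optional integer seed (accepted for interface uniformity; the
#'   optimiser is deterministic given the data).
#' @param diagonal_only fit only baseline hazards, holding all off-diagonal
#'   interaction terms at 0 (an independent-rates model).
#' @param sampling_rate exponential observation rate (default 1).
#' @param max_iter,tol stopping rule: relative change of the penalised
#'   objective below \code{tol} (default 1e-8) or \code{max_iter} (500)
#'   iterations; non-convergence is flagged in the diagnostics, not thrown.
#' @return an object of class \code{cpm_fit} whose \code{model} is an
#'   \code{mhn_model}.
#' @export
fit_mhn <- function(data, lambda_penalty = 0, seed = NULL,
                    diagonal_only = FALSE, sampling_rate = 1,
                    max_iter = 500L, tol = 1e-8) {
  data <- check_csd(data)
  stopifnot(lambda_penalty >= 0)
  if (!is.null(seed)) set.seed(seed)
  events <- colnames(data)
  n <- ncol(data)
  N <- nrow(data)
  masks <- all_genotype_masks(n)
  obs <- csd_to_masks(data)
  counts <- as.numeric(table(factor(obs, levels = masks)))
  f <- pmin(pmax(colMeans(data), 0.5 / N), 1 - 0.5 / N)
  theta <- diag(log(f / (1 - f)), n)
  lam <- lambda_penalty / N                      # objective scaled by 1/N
  offdiag <- row(theta) != col(theta)
  smooth_obj <- function(th) {
    p <- .mhn_dp(th, sampling_rate)$p
    -sum(counts * log(p)) / N
  }
  penalty <- function(th) if (diagonal_only) 0 else lam * sum(abs(th[offdiag]))
  fcur <- smooth_obj(theta)
  Fcur <- fcur + penalty(theta)
  trace <- Fcur
  step <- 1
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    dp <- .mhn_dp(theta, sampling_rate, counts = counts, gradient = TRUE)
    grad <- -dp$grad / N
    repeat {
      cand <- theta - step * grad
      if (diagonal_only) {
        cand[offdiag] <- 0
      } else {
        cand[offdiag] <- sign(cand[offdiag]) *
          pmax(abs(cand[offdiag]) - step * lam, 0)
      }
      delta <- cand - theta
      fnew <- smooth_obj(cand)
      if (fnew <= fcur + sum(grad * delta) + sum(delta^2) / (2 * step) + 1e-12)
        break
      step <- step / 2
      if (step < 1e-12) break
    }
    Fnew <- fnew + penalty(cand)
    if (Fnew > Fcur + 1e-12) break               # cannot make progress
    theta <- cand
    relchange <- abs(Fcur - Fnew) / max(1, abs(Fcur))
    fcur <- fnew
    Fcur <- Fnew
    trace <- c(trace, Fcur)
    step <- step * 1.5
    if (relchange < tol) { converged <- TRUE; break }
  }
  model <- mhn_model(theta, events)
  new_cpm_fit(model, data,
              log_likelihood = sum(counts * log(.mhn_dp(theta,
                                                        sampling_rate)$p)),
              diagnostics = list(method = "mhn-proximal-gradient",
                                 iterations = iter, converged = converged,
                                 penalty = lambda_penalty,
                                 diagonal_only = diagonal_only,
                                 objective_trace = trace))
}

## ---- CBN rates for a fixed DAG ----

#' Fit CBN exponential gain rates under a fixed DAG of restrictions
#'
#' Maximises the observed-genotype log-likelihood under
#' [observation_distribution()] with the sampling rate fixed at 1 (rates are
#' only identified relative to the observation clock). Optimisation is
#' quasi-Newton (BFGS) over log-rates. Genotypes incompatible with the DAG
#' would have probability 0; the likelihood is therefore evaluated through
#' the flip-noise kernel with a small \code{epsilon} (default 0.001) so it
#' never hits log 0. Set \code{epsilon = 0} for the pure model likelihood
#' when all observed genotypes are reachable.
#'
#' @param data binary individuals-by-events matrix; column names must match
#'   the DAG's events.
#' @param dag a CBN \code{restriction_dag} fixing the structure.
#' @param epsilon observational flip probability folded into the likelihood.
#' @param max_iter BFGS iteration cap.
#' @return an object of class \code{cpm_fit} whose \code{model} is the input
#'   DAG with fitted rates.
#' @export
fit_cbn_rates <- function(data, dag, epsilon = 0.001, max_iter = 500L) {
  data <- check_csd(data)
  stopifnot(inherits(dag, "restriction_dag"), dag$family == "CBN")
  if (!identical(colnames(data), dag$events))
    stop("data column names do not match the DAG's events")
  n <- ncol(data)
  N <- nrow(data)
  obs <- csd_to_masks(data)
  tab <- table(obs)
  obs_masks <- as.integer(names(tab))
  obs_counts <- as.numeric(tab)
  if (epsilon == 0) {
    reach <- reachable_genotypes(dag)
    bad <- setdiff(obs_masks, reach)
    if (length(bad))
      stop("observed genotype(s) incompatible with the DAG (",
           paste(genotype_label(bad, dag$events), collapse = "; "),
           "); refit with epsilon > 0")
  }
  f <- pmin(pmax(colMeans(data), 0.5 / N), 1 - 0.5 / N)
  par0 <- log(f / (1 - f))                       # marginal-odds initial rates
  nll <- function(logl) {
    m <- dag
    m$param[] <- exp(logl)
    d <- predict(m, epsilon = epsilon)
    -sum(obs_counts * log(distribution_probability(d, obs_masks))) / N
  }
  opt <- stats::optim(par0, nll, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-12))
  model <- dag
  model$param[] <- exp(opt$par)
  new_cpm_fit(model, data,
              log_likelihood = -opt$value * N,
              diagnostics = list(method = "cbn-rate-bfgs",
                                 iterations = opt$counts[["function"]],
                                 converged = opt$convergence == 0,
                                 penalty = 0, epsilon = epsilon))
}

## ---- fit object and methods ----

#' @keywords internal
new_cpm_fit <- function(model, data, log_likelihood, diagnostics) {
  structure(list(model = model,
                 log_likelihood = log_likelihood,
                 diagnostics = diagnostics,
                 n_obs = nrow(data),
                 genotype_counts = genotype_counts(data),
                 call = sys.call(-1L)),
            class = "cpm_fit")
}

#' @export
print.cpm_fit <- function(x, ...) {
  cat(sprintf("Fitted %s model (%s) on %d individuals, %d events\n",
              x$model$family, x$diagnostics$method, x$n_obs,
              length(x$model$events)))
  cat(sprintf("log-likelihood: %.4f  (iterations: %d, converged: %s)\n",
              x$log_likelihood, x$diagnostics$iterations,
              x$diagnostics$converged))
  print(x$model)
  invisible(x)
}

#' @export
summary.cpm_fit <- function(object, ...) {
  cat(sprintf("Fitted %s model on %d individuals\n", object$model$family,
              object$n_obs))
  print(object$model)
  cat(sprintf("log-likelihood %.4f; penalty %.4g; %d iterations; converged: %s\n",
              object$log_likelihood, object$diagnostics$penalty,
              object$diagnostics$iterations, object$diagnostics$converged))
  cat("Observed genotype counts:\n")
  print(object$genotype_counts)
  invisible(object)
}

#' @export
coef.cpm_fit <- function(object, ...) coef(object$model)

#' @export
logLik.cpm_fit <- function(object, ...) {
  df <- if (inherits(object$model, "mhn_model")) {
    n <- length(object$model$events)
    if (isTRUE(object$diagnostics$diagonal_only)) n else n * n
  } else length(object$model$events)
  structure(object$log_likelihood, df = df, nobs = object$n_obs,
            class = "logLik")
}

#' @export
predict.cpm_fit <- function(object, ...) predict(object$model, ...)

#' @export
simulate.cpm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  simulate(object$model, nsim = nsim, seed = seed, ...)
}
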