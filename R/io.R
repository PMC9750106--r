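# Readers and writers for the artifact formats: cross-sectional data and
# genotype distributions as CSV, models as JSON (the single interchange
# format -- no binary formats), graphs as DOT text. Genotype labels follow
# one convention everywhere: "WT" for the wild type, otherwise event names
# joined by ", " in event-set order, rows/columns in canonical order.

#' Read cross-sectional 0/1 data from CSV
#'
#' Expects a header row of event names and 0/1 cells.
#'
#' @param path CSV file path.
#' @return binary matrix with event-named columns.
#' @export
read_csd <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(utils::read.csv(path, check.names = FALSE,
                                 colClasses = "character"),
                 error = function(e) stop("malformed CSV (", conditionMessage(e),
                                          "): ", path))
  if (nrow(df) == 0L) stop("empty data file (no rows): ", path)
  if (anyDuplicated(names(df)))
    stop("duplicate column names in ", path, ": ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
  m <- as.matrix(df)
  bad <- which(!m %in% c("0", "1"), arr.ind = FALSE)
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(m))
    stop(sprintf("non-binary cell '%s' at row %d, column '%s' in %s",
                 m[bad[1L]], rc[1L], names(df)[rc[2L]], path))
  }
  storage.mode(m) <- "integer"
  check_csd(m)
}

#' Write cross-sectional data to CSV
#'
#' @param data binary individuals-by-events matrix.
#' @param path output path.
#' @export
write_csd <- function(data, path) {
  data <- check_csd(data)
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' Tabulate genotype counts in a dataset
#'
#' @param data binary individuals-by-events matrix.
#' @return named integer vector of counts per observed genotype (canonical
#'   order), with the mask vector as attribute \code{masks}.
#' @export
genotype_counts <- function(data) {
  data <- check_csd(data)
  masks <- csd_to_masks(data)
  tab <- table(masks)
  u <- as.integer(names(tab))
  ord <- canonical_order(u)
  structure(stats::setNames(as.integer(tab)[ord],
                            genotype_label(u[ord], colnames(data))),
            masks = u[ord])
}

#' Reconstruct a dataset from genotype counts
#'
#' Inverse of [genotype_counts()] up to row order.
#'
#' @param counts named integer vector as returned by [genotype_counts()]
#'   (attribute \code{masks} required).
#' @param events event names.
#' @return binary matrix with one row per counted individual.
#' @export
counts_to_csd <- function(counts, events) {
  masks <- attr(counts, "masks")
  if (is.null(masks)) masks <- vapply(names(counts), function(lab) {
    if (lab == "WT") 0L
    else genotype_mask(strsplit(lab, ", ", fixed = TRUE)[[1L]], events)
  }, integer(1))
  masks_to_csd(rep(masks, counts), events)
}

#' Write a genotype distribution to CSV
#'
#' Columns \code{genotype} (label) and \code{probability}, canonical order.
#'
#' @param dist a [genotype_distribution()].
#' @param path output path.
#' @export
write_distribution_csv <- function(dist, path) {
  stopifnot(inherits(dist, "genotype_distribution"))
  utils::write.csv(as.data.frame(dist)[, c("genotype", "probability")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a rate or transition matrix to CSV with genotype labels
#'
#' Row and column headers are genotype labels ("WT", events joined by
#' ", "). For transition matrices, absorbing rows are all zero by
#' convention (not identity).
#'
#' @param x a \code{rate_matrix} or \code{transition_matrix}.
#' @param path output path.
#' @export
write_matrix_csv <- function(x, path) {
  m <- if (inherits(x, "rate_matrix")) x$Q
       else if (inherits(x, "transition_matrix")) x$P
       else stop("x must be a rate_matrix or transition_matrix")
  utils::write.csv(as.data.frame(m, check.names = FALSE), path,
                   row.names = TRUE)
  invisible(path)
}

#' Write evolutionary paths to CSV
#'
#' @param paths an \code{evolutionary_paths} object.
#' @param path output path.
#' @export
write_paths_csv <- function(paths, path) {
  stopifnot(inherits(paths, "evolutionary_paths"))
  utils::write.csv(as.data.frame(paths), path, row.names = FALSE)
  invisible(path)
}

## ---- model JSON ----

#' Serialise a model to JSON
#'
#' Schema: \code{{"family", "events", "nodes": [{"name", "parents",
#' "relation", "param"}]}} for the DAG families and \code{{"family": "MHN",
#' "events", "theta": [[...]]}} for MHN. Numbers are written at full
#' precision so that write/read round-trips are bit exact.
#'
#' @param model a \code{cpm_model}.
#' @param path optional output path; if missing the JSON text is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
write_model_json <- function(model, path = NULL) {
  obj <- if (inherits(model, "mhn_model")) {
    list(family = "MHN", events = model$events,
         theta = unname(model$theta))
  } else {
    list(family = model$family, events = model$events,
         nodes = lapply(model$events, function(e) list(
           name = e, parents = model$parents[[e]],
           relation = model$relation[[e]], param = model$param[[e]])))
  }
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(as.character(txt))
}

#' Read a model from JSON
#'
#' @param path JSON file path (or a JSON string).
#' @return a \code{cpm_model}.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  events <- unlist(obj$events)
  if (identical(obj$family, "MHN")) {
    theta <- do.call(rbind, lapply(obj$theta, unlist))
    return(mhn_model(theta, events))
  }
  parents <- list(); relation <- character(0); param <- numeric(0)
  for (nd in obj$nodes) {
    parents[[nd$name]] <- as.character(unlist(nd$parents))
    relation[[nd$name]] <- nd$relation
    param[[nd$name]] <- nd$param
  }
  restriction_dag(obj$family, events, parents, relation, param)
}

## ---- DOT export ----

#' Export a model, transition structure or path list as Graphviz DOT text
#'
#' DAGs of restrictions are drawn with the virtual root, each node annotated
#' with its relation (for multi-parent nodes) and parameter; rate and
#' transition matrices become weighted genotype graphs; path lists become
#' the union of their step edges annotated with path probabilities.
#'
#' @param object a \code{restriction_dag}, \code{mhn_model},
#'   \code{rate_matrix}, \code{transition_matrix} or
#'   \code{evolutionary_paths}.
#' @param ... unused.
#' @return a single DOT string.
#' @export
export_dot <- function(object, ...) UseMethod("export_dot")

#' @keywords internal
.dot_quote <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

#' @export
export_dot.restriction_dag <- function(object, ...) {
  lines <- c("digraph restrictions {", '  Root [shape=box];')
  for (e in object$events) {
    pa <- object$parents[[e]]
    rel <- object$relation[[e]]
    lab <- sprintf("%s\\n%s%s = %.4g", e,
                   if (length(pa) > 1L) paste0(rel, "; ") else "",
                   if (is_timed(object)) "rate" else "p", object$param[[e]])
    lines <- c(lines, sprintf("  %s [label=%s];", .dot_quote(e),
                              .dot_quote(lab)))
    from <- if (length(pa)) pa else "Root"
    for (p in from)
      lines <- c(lines, sprintf("  %s -> %s [label=%s];",
                                if (p == "Root") "Root" else .dot_quote(p),
                                .dot_quote(e),
                                .dot_quote(sprintf("%.4g", object$param[[e]]))))
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' @export
export_dot.mhn_model <- function(object, ...) {
  # no DAG: emit the weighted transition graph of the genotype lattice
  export_dot(rate_matrix(object))
}

#' @keywords internal
.dot_genotype_graph <- function(states, m, what) {
  lines <- c("digraph genotype_lattice {")
  for (s in states) lines <- c(lines, sprintf("  %s;", .dot_quote(s)))
  for (i in seq_along(states)) for (j in seq_along(states))
    if (i != j && m[i, j] > 0)
      lines <- c(lines, sprintf("  %s -> %s [label=%s];",
                                .dot_quote(states[i]), .dot_quote(states[j]),
                                .dot_quote(sprintf("%s=%.4g", what, m[i, j]))))
  paste(c(lines, "}"), collapse = "\n")
}

#' @export
export_dot.rate_matrix <- function(object, ...) {
  .dot_genotype_graph(object$states, object$Q, "rate")
}

#' @export
export_dot.transition_matrix <- function(object, ...) {
  .dot_genotype_graph(object$states, object$P, "p")
}

#' @export
export_dot.evolutionary_paths <- function(object, ...) {
  events <- attr(object, "events")
  lines <- c("digraph evolutionary_paths {")
  seen <- character(0)
  for (k in seq_len(nrow(object))) {
    ms <- attr(object, "masks")[[k]]
    labs <- genotype_label(ms, events)
    for (i in seq_len(length(labs) - 1L)) {
      key <- paste(labs[i], labs[i + 1L], sep = "|")
      if (!key %in% seen) {
        seen <- c(seen, key)
        lines <- c(lines, sprintf("  %s -> %s;", .dot_quote(labs[i]),
                                  .dot_quote(labs[i + 1L])))
      }
    }
  }
  paste(c(lines, "}"), collapse = "\n")
}
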