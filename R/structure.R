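## Two-slice network structures and greedy search.
##
## Every edge goes from a variable observed at slice t (a "parent") to a
## variable at slice t + 1 (a "child"), so the graph is acyclic by
## construction.  The conditional Gaussian restriction applies: a discrete
## child may have only discrete parents.

node_kinds <- function(df) {
  vapply(df, function(col) if (is.numeric(col)) "continuous" else "discrete",
         character(1))
}

#' Construct a two-slice network structure
#'
#' @param parent_sets Named list: child name -> character vector of parent
#'   names (possibly empty).  Children absent from the list get empty
#'   parent sets.
#' @param transitions A `dbn_transitions` giving the variable universe and
#'   node kinds.
#' @param children Child nodes at slice t + 1 (default: every column of
#'   `transitions$children`).
#' @param max_parents Cap on parents per child.
#' @return An object of class `dbn_structure`.
#' @export
dbn_structure <- function(parent_sets = list(), transitions,
                          children = NULL, max_parents = 3) {
  parent_kind <- node_kinds(transitions$parents)
  child_kind <- node_kinds(transitions$children)
  if (is.null(children)) children <- names(transitions$children)
  stopifnot(all(children %in% names(transitions$children)))
  sets <- stats::setNames(
    replicate(length(children), character(0), simplify = FALSE), children)
  for (ch in names(parent_sets)) {
    if (!ch %in% children) stop("unknown child node: ", ch)
    ps <- sort(unique(as.character(parent_sets[[ch]])))
    bad <- setdiff(ps, names(parent_kind))
    if (length(bad)) stop("unknown parent node(s): ",
                          paste(bad, collapse = ", "))
    sets[[ch]] <- ps
  }
  st <- structure(list(parent_sets = sets, children = children,
                       parent_kind = parent_kind, child_kind = child_kind,
                       max_parents = as.integer(max_parents)),
                  class = "dbn_structure")
  validate_structure(st)
  st
}

validate_structure <- function(st) {
  for (ch in st$children) {
    ps <- st$parent_sets[[ch]]
    if (length(ps) > st$max_parents) {
      stop("child '", ch, "' exceeds max_parents = ", st$max_parents)
    }
    if (!is.null(st$child_kind) && st$child_kind[[ch]] == "discrete" &&
        any(st$parent_kind[ps] != "discrete")) {
      stop("discrete child '", ch, "' has a continuous parent ",
           "(conditional Gaussian restriction)")
    }
  }
  invisible(st)
}

#' @export
print.dbn_structure <- function(x, ...) {
  ne <- sum(lengths(x$parent_sets))
  cat(sprintf("dbn_structure: %d children, %d edges (max %d parents)\n",
              length(x$children), ne, x$max_parents))
  for (ch in x$children) {
    ps <- x$parent_sets[[ch]]
    if (length(ps)) cat("  ", paste(ps, collapse = ", "), "->", ch, "\n")
  }
  invisible(x)
}

#' Edge list of a structure
#'
#' @param structure A `dbn_structure`.
#' @return Data frame with columns `parent`, `child` (one row per edge).
#' @export
structure_edges <- function(structure) {
  ch <- rep(names(structure$parent_sets),
            lengths(structure$parent_sets))
  pa <- unlist(structure$parent_sets, use.names = FALSE)
  out <- data.frame(parent = as.character(pa), child = as.character(ch),
                    stringsAsFactors = FALSE)
  out[order(out$parent, out$child), , drop = FALSE]
}

# Extract (y, X, config) for one child's family under a parent set.
family_data <- function(transitions, child, parents) {
  pk <- node_kinds(transitions$parents)
  cont <- parents[pk[parents] == "continuous"]
  disc <- parents[pk[parents] == "discrete"]
  X <- if (length(cont)) {
    as.matrix(transitions$parents[cont])
  } else NULL
  config <- if (length(disc)) {
    interaction(transitions$parents[disc], drop = FALSE, lex.order = TRUE)
  } else NULL
  y <- transitions$children[[child]]
  list(y = y, X = X, config = config,
       kind = if (is.numeric(y)) "continuous" else "discrete")
}

family_log_score <- function(transitions, child, parents, priors) {
  fd <- family_data(transitions, child, parents)
  if (fd$kind == "continuous") {
    family_log_score_continuous(fd$y, fd$X, fd$config, priors)
  } else {
    if (!is.null(fd$X)) {
      stop("discrete child '", child, "' has a continuous parent")
    }
    family_log_score_discrete(fd$y, fd$config, priors)
  }
}

#' Log network score (posterior likelihood of the data given the structure)
#'
#' The score decomposes over children: it is the sum of the family log
#' marginal likelihoods of each child given its parent set, so adding or
#' deleting an edge changes only the affected child's term.
#'
#' @param structure A `dbn_structure`.
#' @param transitions A `dbn_transitions`.
#' @param priors A [dbn_priors()].
#' @return Natural-log network score.
#' @export
network_log_score <- function(structure, transitions, priors) {
  validate_structure(structure)
  sum(vapply(structure$children, function(ch) {
    family_log_score(transitions, ch, structure$parent_sets[[ch]], priors)
  }, numeric(1)))
}

allowed_parents <- function(child_kind, parent_kind, parents) {
  if (child_kind == "discrete") {
    parents[parent_kind[parents] == "discrete"]
  } else {
    parents
  }
}

#' Greedy hill-climbing structure search
#'
#' Starting from the empty network, repeatedly applies the single edge
#' addition or deletion that most increases the network score, until no
#' move improves it by more than `tol`.  Moves respect the parent cap and
#' the conditional Gaussian restriction throughout.  Tie-breaking is
#' deterministic: larger gain first, then deletions before additions, then
#' lexicographic (parent, child) order.
#'
#' @param transitions A `dbn_transitions`.
#' @param priors A [dbn_priors()]; `priors$max_parents` caps parent sets.
#' @param children Candidate child nodes (default: all columns of
#'   `transitions$children`).
#' @param parents Candidate parent nodes (default: all columns of
#'   `transitions$parents`).
#' @param exclude Variables to drop from both candidate sets (supports
#'   sensitivity reruns without selected taxa or covariates).
#' @param tol Minimum score gain to accept a move.
#' @param trace Print accepted moves?
#' @return A `dbn_structure` with attributes `log_score` (final network
#'   score) and `score_trajectory` (score after each accepted move,
#'   starting with the empty network).
#' @export
hill_climb <- function(transitions, priors = dbn_priors(),
                       children = NULL, parents = NULL, exclude = NULL,
                       tol = 1e-9, trace = FALSE) {
  if (is.null(children)) children <- names(transitions$children)
  if (is.null(parents)) parents <- names(transitions$parents)
  children <- sort(setdiff(children, exclude))
  parents <- sort(setdiff(parents, exclude))
  stopifnot(length(children) > 0, length(parents) > 0)
  parent_kind <- node_kinds(transitions$parents)
  child_kind <- node_kinds(transitions$children)

  sets <- stats::setNames(
    replicate(length(children), character(0), simplify = FALSE), children)
  fam <- function(ch, ps) family_log_score(transitions, ch, ps, priors)
  cur <- vapply(children, function(ch) fam(ch, character(0)), numeric(1))
  traj <- sum(cur)

  moves_for <- function(ch) {
    ps <- sets[[ch]]
    cand <- allowed_parents(child_kind[[ch]], parent_kind, parents)
    out <- list()
    if (length(ps) < priors$max_parents) {
      for (p in setdiff(cand, ps)) {
        out[[length(out) + 1L]] <- data.frame(
          kind = "add", parent = p, child = ch,
          delta = fam(ch, sort(c(ps, p))) - cur[[ch]])
      }
    }
    for (p in ps) {
      out[[length(out) + 1L]] <- data.frame(
        kind = "delete", parent = p, child = ch,
        delta = fam(ch, setdiff(ps, p)) - cur[[ch]])
    }
    if (!length(out)) return(NULL)
    do.call(rbind, out)
  }

  cache <- stats::setNames(lapply(children, moves_for), children)
  repeat {
    all_moves <- do.call(rbind, cache[!vapply(cache, is.null, logical(1))])
    if (is.null(all_moves) || !nrow(all_moves)) break
    ord <- order(-all_moves$delta,
                 match(all_moves$kind, c("delete", "add")),
                 all_moves$parent, all_moves$child, method = "radix")
    best <- all_moves[ord[1], ]
    if (best$delta <= tol) break
    ch <- best$child
    sets[[ch]] <- if (best$kind == "add") {
      sort(c(sets[[ch]], best$parent))
    } else {
      setdiff(sets[[ch]], best$parent)
    }
    cur[[ch]] <- cur[[ch]] + best$delta
    traj <- c(traj, sum(cur))
    if (trace) {
      message(sprintf("%s %s -> %s  (delta = %.4f, score = %.4f)",
                      best$kind, best$parent, ch, best$delta, sum(cur)))
    }
    cache[[ch]] <- moves_for(ch)
  }

  st <- structure(list(parent_sets = sets, children = children,
                       parent_kind = parent_kind, child_kind = child_kind,
                       max_parents = priors$max_parents),
                  class = "dbn_structure")
  attr(st, "log_score") <- sum(cur)
  attr(st, "score_trajectory") <- traj
  st
}

#' Natural-log Bayes factor of a single edge
#'
#' Score of the structure minus the score of the same structure with the
#' edge removed; only the affected child's family is recomputed.  At a
#' hill-climbing optimum every retained edge has a nonnegative log Bayes
#' factor.
#'
#' @param structure A `dbn_structure` containing the edge.
#' @param edge Length-2 character vector `c(parent, child)`.
#' @param transitions A `dbn_transitions`.
#' @param priors A [dbn_priors()].
#' @return Natural-log Bayes factor.
#' @export
edge_bayes_factor <- function(structure, edge, transitions, priors) {
  stopifnot(length(edge) == 2)
  parent <- edge[[1]]; child <- edge[[2]]
  ps <- structure$parent_sets[[child]]
  if (is.null(ps) || !parent %in% ps) {
    stop("edge ", parent, " -> ", child, " not present in structure")
  }
  family_log_score(transitions, child, ps, priors) -
    family_log_score(transitions, child, setdiff(ps, parent), priors)
}

#' Edge report with Bayes factors
#'
#' @inheritParams edge_bayes_factor
#' @return Data frame with columns `parent`, `child`, `ln_bayes_factor`,
#'   sorted by decreasing Bayes factor.
#' @export
edge_report <- function(structure, transitions, priors) {
  ed <- structure_edges(structure)
  if (!nrow(ed)) {
    ed$ln_bayes_factor <- numeric(0)
    return(ed)
  }
  ed$ln_bayes_factor <- vapply(seq_len(nrow(ed)), function(i) {
    edge_bayes_factor(structure, c(ed$parent[i], ed$child[i]),
                      transitions, priors)
  }, numeric(1))
  ed[order(-ed$ln_bayes_factor, ed$parent, ed$child), , drop = FALSE]
}

#' Export a structure
#'
#' `write_structure_json()` writes the structure (children, parent sets,
#' node kinds, parent cap and, when present, the final score) as JSON.
#' `structure_dot()` renders a Graphviz DOT description of the two-slice
#' graph; `structure_graphml()` a minimal GraphML document.
#'
#' @param structure A `dbn_structure`.
#' @param path Output file.
#' @export
write_structure_json <- function(structure, path) {
  obj <- list(children = structure$children,
              parent_sets = structure$parent_sets,
              parent_kind = as.list(structure$parent_kind),
              max_parents = structure$max_parents,
              log_score = attr(structure, "log_score"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_structure_json
#' @export
read_structure_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sets <- lapply(obj$parent_sets, function(x) sort(as.character(x)))
  st <- structure(list(parent_sets = sets,
                       children = as.character(obj$children),
                       parent_kind = unlist(obj$parent_kind),
                       child_kind = NULL,
                       max_parents = as.integer(obj$max_parents)),
                  class = "dbn_structure")
  attr(st, "log_score") <- obj$log_score
  st
}

#' @rdname write_structure_json
#' @export
structure_dot <- function(structure) {
  ed <- structure_edges(structure)
  lines <- c("digraph dbn {", "  rankdir=LR;",
             sprintf("  \"%s [t]\" -> \"%s [t+1]\";", ed$parent, ed$child),
             "}")
  paste(lines, collapse = "\n")
}

#' @rdname write_structure_json
#' @export
structure_graphml <- function(structure) {
  ed <- structure_edges(structure)
  nodes <- unique(c(paste0(ed$parent, "_t"), paste0(ed$child, "_t1")))
  paste(c('<?xml version="1.0" encoding="UTF-8"?>',
          '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
          '  <graph edgedefault="directed">',
          sprintf('    <node id="%s"/>', nodes),
          sprintf('    <edge source="%s_t" target="%s_t1"/>',
                  ed$parent, ed$child),
          "  </graph>", "</graphml>"),
        collapse = "\n")
}
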