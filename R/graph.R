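#' Construct an admixture graph
#'
#' A rooted directed acyclic graph of populations. Drift edges carry
#' non-negative lengths in f2 drift units; an admixture node has exactly two
#' parents and a mixing weight `w` (the fraction of ancestry from `parentA`).
#' Every non-root node has either one drift parent or two admixture parents;
#' admixture legs carry no drift of their own (put drift on the child's
#' outgoing edge instead).
#'
#' @param edges data frame of drift edges with columns `parent`, `child` and
#'   optionally `label` (default `parent_child`) and `length` (default `NA`,
#'   i.e. unset).
#' @param admix data frame of admixture nodes with columns `child`,
#'   `parentA`, `parentB` and optionally `weight` (default `NA`) and `fixed`
#'   (logical, default `FALSE`; fixed weights are never re-optimized).
#' @param leaf_map optional named character vector mapping leaf nodes to
#'   population labels; defaults to the identity on leaves.
#' @return An object of class `admix_graph`.
#' @export
admix_graph <- function(edges, admix = NULL, leaf_map = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("parent", "child") %in% names(edges)))
  if (is.null(edges$label)) edges$label <- paste(edges$parent, edges$child,
                                                 sep = "_")
  if (is.null(edges$length)) edges$length <- NA_real_
  edges <- edges[c("label", "parent", "child", "length")]
  if (anyDuplicated(edges$label)) stop("duplicate edge labels")
  if (is.null(admix)) {
    admix <- data.frame(child = character(), parentA = character(),
                        parentB = character(), weight = numeric(),
                        fixed = logical(), stringsAsFactors = FALSE)
  } else {
    admix <- as.data.frame(admix, stringsAsFactors = FALSE)
    stopifnot(all(c("child", "parentA", "parentB") %in% names(admix)))
    if (is.null(admix$weight)) admix$weight <- NA_real_
    if (is.null(admix$fixed)) admix$fixed <- FALSE
    admix <- admix[c("child", "parentA", "parentB", "weight", "fixed")]
  }
  nodes <- unique(c(edges$parent, edges$child, admix$child,
                    admix$parentA, admix$parentB))
  drift_children <- edges$child
  admix_children <- admix$child
  if (length(intersect(drift_children, admix_children)))
    stop("node(s) with both a drift parent and admixture parents: ",
         paste(intersect(drift_children, admix_children), collapse = ", "))
  if (anyDuplicated(drift_children))
    stop("node(s) with more than one drift parent: ",
         paste(unique(drift_children[duplicated(drift_children)]),
               collapse = ", "))
  if (anyDuplicated(admix_children))
    stop("duplicated admixture node(s)")
  parented <- c(drift_children, admix_children)
  roots <- setdiff(nodes, parented)
  if (length(roots) != 1L)
    stop("graph must have exactly one root; found: ",
         paste(roots, collapse = ", "))
  has_child <- unique(c(edges$parent, admix$parentA, admix$parentB))
  leaves <- setdiff(nodes, has_child)
  if (is.null(leaf_map)) {
    leaf_map <- stats::setNames(leaves, leaves)
  } else {
    if (!all(names(leaf_map) %in% leaves))
      stop("leaf_map names must be leaf nodes")
    missing_leaves <- setdiff(leaves, names(leaf_map))
    leaf_map <- c(leaf_map, stats::setNames(missing_leaves, missing_leaves))
    leaf_map <- leaf_map[leaves]
  }
  g <- structure(list(nodes = nodes, root = roots, edges = edges,
                      admix = admix, leaves = leaves, leaf_map = leaf_map),
                 class = "admix_graph")
  g$topo <- topo_order(g)   # errors if cyclic; also proves reachability
  g
}

# Topological order, parents before children (Kahn's algorithm).
topo_order <- function(g) {
  nodes <- g$nodes
  parents <- lapply(stats::setNames(nodes, nodes), function(nd) {
    c(g$edges$parent[g$edges$child == nd],
      unlist(g$admix[g$admix$child == nd, c("parentA", "parentB")],
             use.names = FALSE))
  })
  indeg <- lengths(parents)
  children <- lapply(stats::setNames(nodes, nodes), function(nd) {
    c(g$edges$child[g$edges$parent == nd],
      g$admix$child[g$admix$parentA == nd | g$admix$parentB == nd])
  })
  order <- character(0)
  ready <- nodes[indeg == 0L]
  while (length(ready)) {
    nd <- ready[1]; ready <- ready[-1]
    order <- c(order, nd)
    for (ch in children[[nd]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) ready <- c(ready, ch)
    }
  }
  if (length(order) != length(nodes)) stop("graph contains a cycle")
  order
}

#' @export
print.admix_graph <- function(x, ...) {
  cat("admix_graph:", length(x$nodes), "nodes,", nrow(x$edges),
      "drift edges,", nrow(x$admix), "admixture node(s),",
      length(x$leaves), "leaves\n")
  cat("  root:", x$root, "\n")
  cat("  leaves:", paste(unname(x$leaf_map), collapse = ", "), "\n")
  invisible(x)
}

#' Number of admixture events in a graph
#' @param g an [admix_graph()].
#' @return Integer count of admixture nodes.
#' @export
n_admix <- function(g) nrow(g$admix)

#' Parse the admixture-graph text dialect
#'
#' One directive per line: `edge <label> <parent> <child> [length]`,
#' `admix <child> <parentA> <parentB> [weight] [fixed]`,
#' `label <leaf> <population>`. Blank lines and `#` comments are ignored.
#' A `root <node>` line is accepted and checked against the implied root.
#'
#' @param lines character vector of lines, or a single string with newlines.
#' @return An [admix_graph()].
#' @export
parse_graph <- function(lines) {
  if (length(lines) == 1L && grepl("\n", lines))
    lines <- strsplit(lines, "\n")[[1]]
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  tok <- strsplit(lines, "[ \t]+")
  edges <- list(); admix <- list(); labels <- character(); root <- NULL
  for (t in tok) {
    switch(t[1],
      edge = {
        edges[[length(edges) + 1L]] <- data.frame(
          label = t[2], parent = t[3], child = t[4],
          length = if (length(t) >= 5) as.numeric(t[5]) else NA_real_,
          stringsAsFactors = FALSE)
      },
      admix = {
        admix[[length(admix) + 1L]] <- data.frame(
          child = t[2], parentA = t[3], parentB = t[4],
          weight = if (length(t) >= 5) as.numeric(t[5]) else NA_real_,
          fixed = if (length(t) >= 6) as.logical(t[6]) else FALSE,
          stringsAsFactors = FALSE)
      },
      label = labels[t[2]] <- t[3],
      root = root <- t[2],
      stop("unknown graph directive: ", t[1])
    )
  }
  g <- admix_graph(do.call(rbind, edges),
                   if (length(admix)) do.call(rbind, admix) else NULL,
                   leaf_map = if (length(labels)) labels else NULL)
  if (!is.null(root) && !identical(root, g$root))
    stop("declared root ", root, " but graph implies root ", g$root)
  g
}

#' Read an admixture graph from a file
#' @param path file in the text dialect of [parse_graph()].
#' @return An [admix_graph()].
#' @export
read_graph <- function(path) parse_graph(readLines(path))

#' Serialize an admixture graph to its text dialect
#' @param g an [admix_graph()].
#' @return Character vector of lines (re-parseable by [parse_graph()]).
#' @export
format_graph <- function(g) {
  out <- paste("root", g$root)
  e <- g$edges
  len <- ifelse(is.na(e$length), "", paste0(" ", format(e$length, digits = 10,
                                                        scientific = FALSE)))
  out <- c(out, paste0("edge ", e$label, " ", e$parent, " ", e$child, len))
  if (nrow(g$admix)) {
    a <- g$admix
    w <- ifelse(is.na(a$weight), "",
                paste0(" ", format(a$weight, digits = 10,
                                   scientific = FALSE),
                       ifelse(a$fixed, " TRUE", "")))
    out <- c(out, paste0("admix ", a$child, " ", a$parentA, " ",
                         a$parentB, w))
  }
  named <- g$leaf_map[g$leaf_map != names(g$leaf_map)]
  if (length(named))
    out <- c(out, paste("label", names(named), unname(named)))
  out
}

#' Write an admixture graph to a file
#' @param g an [admix_graph()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graph <- function(g, path) {
  writeLines(format_graph(g), path)
  invisible(path)
}

# Path-probability matrix: edges x leaves; entry (e, X) is the probability
# that a lineage sampled from leaf X traverses drift edge e (product of
# admixture weights over the choices on the way to the root).
path_matrix <- function(g) {
  nodes <- g$topo
  nl <- length(g$leaves)
  P <- matrix(0, nrow = length(nodes), ncol = nl,
              dimnames = list(nodes, g$leaves))
  P[cbind(g$leaves, g$leaves)] <- 1
  if (anyNA(g$admix$weight) && nrow(g$admix))
    stop("unset admixture weight on node(s): ",
         paste(g$admix$child[is.na(g$admix$weight)], collapse = ", "))
  drift_parent <- stats::setNames(g$edges$parent, g$edges$child)
  ai <- match(nodes, g$admix$child)
  for (k in rev(seq_along(nodes))) {
    nd <- nodes[k]
    if (nd == g$root) next
    if (!is.na(ai[k])) {
      a <- g$admix[ai[k], ]
      P[a$parentA, ] <- P[a$parentA, ] + a$weight * P[nd, ]
      P[a$parentB, ] <- P[a$parentB, ] + (1 - a$weight) * P[nd, ]
    } else {
      P[drift_parent[nd], ] <- P[drift_parent[nd], ] + P[nd, ]
    }
  }
  A <- P[g$edges$child, , drop = FALSE]
  rownames(A) <- g$edges$label
  colnames(A) <- unname(g$leaf_map[g$leaves])
  A
}

#' Expected f-statistics under an admixture graph
#'
#' Computes, for each pair of leaf populations, the drift covariance
#' `C(X, Y) = sum_e length_e a_e(X) a_e(Y)` where `a_e(X)` is the
#' probability that a lineage from X traverses drift edge `e`. Expected
#' f-statistics follow: `f2(X,Y) = C(X,X) + C(Y,Y) - 2 C(X,Y)`, with f3 and
#' f4 by their linear identities in f2.
#'
#' @param g an [admix_graph()] with all lengths and weights set.
#' @return An object of class `graph_expectation` holding the leaf
#'   covariance matrix `C`; query it with [exp_f2()], [exp_f3()], [exp_f4()].
#' @export
expected_stats <- function(g) {
  if (anyNA(g$edges$length))
    stop("unset length on edge(s): ",
         paste(g$edges$label[is.na(g$edges$length)], collapse = ", "))
  A <- path_matrix(g)
  C <- crossprod(A * sqrt(pmax(g$edges$length, 0)))
  structure(list(C = C, populations = colnames(C), graph = g),
            class = "graph_expectation")
}

#' @export
print.graph_expectation <- function(x, ...) {
  cat("graph_expectation over", length(x$populations), "populations:",
      paste(utils::head(x$populations, 8), collapse = ", "),
      if (length(x$populations) > 8) "..." else "", "\n")
  invisible(x)
}

#' Expected f2 under a fitted/true graph
#' @param E a `graph_expectation` from [expected_stats()].
#' @param X,Y population labels.
#' @return Numeric expected value in drift units.
#' @export
exp_f2 <- function(E, X, Y) {
  unname(E$C[X, X] + E$C[Y, Y] - 2 * E$C[X, Y])
}

#' Expected f3 under a fitted/true graph
#' @inheritParams exp_f2
#' @param A,B population labels.
#' @export
exp_f3 <- function(E, X, A, B) {
  unname(E$C[X, X] - E$C[X, A] - E$C[X, B] + E$C[A, B])
}

#' Expected f4 under a fitted/true graph
#' @inheritParams exp_f2
#' @param A,B,C,D population labels.
#' @export
exp_f4 <- function(E, A, B, C, D) {
  unname(E$C[A, C] - E$C[A, D] - E$C[B, C] + E$C[B, D])
}
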