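#' Candidate attachment edges of a skeleton graph
#'
#' Drift edges onto which a target may be attached: all drift edges except
#' an excluded set, which defaults to the edges leaving the root (the basal
#' split carries no information about where below it a target attaches).
#'
#' @param skeleton an [admix_graph()].
#' @param excluded edge labels to exclude; default the root's child edges.
#' @return Character vector of candidate edge labels.
#' @export
candidate_edges <- function(skeleton,
                            excluded = root_edges(skeleton)) {
  bad <- setdiff(excluded, skeleton$edges$label)
  if (length(bad))
    stop("excluded edges not in the skeleton: ", paste(bad, collapse = ", "))
  setdiff(skeleton$edges$label, excluded)
}

#' Edges leaving the root of a graph
#' @param g an [admix_graph()].
#' @return Character vector of edge labels with the root as parent.
#' @export
root_edges <- function(g) g$edges$label[g$edges$parent == g$root]

#' Enumerate all attachment models of a target on a skeleton
#'
#' A model is an unordered set of 1-3 distinct candidate edges. Each chosen
#' edge is split by a new node; with one edge the target hangs from the
#' split node by a drift edge, with two or more the split nodes feed a
#' (cascade of) admixture node(s) from which the target hangs. With `E`
#' candidate edges there are `E + choose(E,2) + choose(E,3)` models at the
#' default three ancestry streams.
#'
#' @param skeleton an [admix_graph()].
#' @param target label of the population to attach (must not be in the
#'   skeleton).
#' @param max_waves maximum number of ancestry streams (edge-set size),
#'   at most 3.
#' @param excluded candidate-edge exclusion set (default: root edges).
#' @return A list of `attachment_model` objects (fields `target`, `edges`,
#'   `n_admix`, `derived_graph` — built lazily by
#'   [derive_attachment_graph()]).
#' @export
enumerate_attachments <- function(skeleton, target, max_waves = 3,
                                  excluded = root_edges(skeleton)) {
  if (max_waves > 3) stop("max_waves > 3 is outside the supported model space")
  if (max_waves < 1) stop("max_waves must be at least 1")
  if (target %in% unname(skeleton$leaf_map) || target %in% skeleton$nodes)
    stop("target already present in the skeleton")
  cand <- sort(candidate_edges(skeleton, excluded))
  models <- list()
  for (k in seq_len(min(max_waves, length(cand)))) {
    sets <- utils::combn(cand, k)
    for (c in seq_len(ncol(sets))) {
      models[[length(models) + 1L]] <- structure(
        list(target = target, edges = sets[, c], n_admix = k - 1L,
             derived_graph = NULL),
        class = "attachment_model")
    }
  }
  models
}

#' Derive the attachment graph of a candidate model
#'
#' Splits each chosen skeleton edge with a new node and hangs the target
#' below: directly (one edge) or from a cascade of admixture nodes (two or
#' three edges, in sorted edge order). Newly introduced drift lengths and
#' admixture weights are unset (lengths are refit; weights start free).
#'
#' @param skeleton an [admix_graph()].
#' @param model an `attachment_model` from [enumerate_attachments()].
#' @return The model with `derived_graph` set to an [admix_graph()].
#' @export
derive_attachment_graph <- function(skeleton, model) {
  edges <- skeleton$edges
  admix <- skeleton$admix
  target <- model$target
  chosen <- sort(model$edges)
  split_nodes <- character(0)
  for (i in seq_along(chosen)) {
    e <- match(chosen[i], edges$label)
    if (is.na(e)) stop("edge not in skeleton: ", chosen[i])
    sn <- paste0("split_", chosen[i])
    split_nodes <- c(split_nodes, sn)
    half <- edges$length[e] / 2
    upper <- data.frame(label = paste0(chosen[i], "_u"),
                        parent = edges$parent[e], child = sn,
                        length = half, stringsAsFactors = FALSE)
    lower <- data.frame(label = paste0(chosen[i], "_l"),
                        parent = sn, child = edges$child[e],
                        length = half, stringsAsFactors = FALSE)
    edges <- rbind(edges[-e, ], upper, lower)
  }
  k <- length(chosen)
  if (k == 1L) {
    hang <- split_nodes
  } else {
    mixes <- paste0("mix", seq_len(k - 1L), "_", target)
    admix <- rbind(admix, data.frame(
      child = mixes[1], parentA = split_nodes[1], parentB = split_nodes[2],
      weight = NA_real_, fixed = FALSE, stringsAsFactors = FALSE))
    if (k == 3L)
      admix <- rbind(admix, data.frame(
        child = mixes[2], parentA = mixes[1], parentB = split_nodes[3],
        weight = NA_real_, fixed = FALSE, stringsAsFactors = FALSE))
    hang <- mixes[k - 1L]
  }
  edges <- rbind(edges, data.frame(
    label = paste0("att_", target), parent = hang, child = target,
    length = 0, stringsAsFactors = FALSE))
  lm <- c(skeleton$leaf_map, stats::setNames(target, target))
  model$derived_graph <- admix_graph(edges, admix, leaf_map = lm)
  model
}

#' @export
print.attachment_model <- function(x, ...) {
  cat("attachment_model:", x$target, "on {",
      paste(x$edges, collapse = ", "), "} -", x$n_admix,
      "admixture wave(s)\n")
  invisible(x)
}

# Sequential model selection across admixture counts, then the tie rule
# within the winning count. `tab` needs columns n_admix, score,
# worst_residual, trifurcation. Returns indices of retained best models.
select_models <- function(tab) {
  ok <- which(!tab$trifurcation & is.finite(tab$score))
  if (!length(ok)) return(integer(0))
  counts <- sort(unique(tab$n_admix[ok]))
  champ <- NULL
  for (k in counts) {
    ik <- ok[tab$n_admix[ok] == k]
    best_k <- ik[which.max(tab$score[ik])]
    if (is.null(champ)) {
      champ <- best_k
      next
    }
    ll_gain <- tab$score[best_k] - tab$score[champ]
    wr_gain <- tab$worst_residual[champ] - tab$worst_residual[best_k]
    if (ll_gain > 10 || wr_gain > 0.5) champ <- best_k
  }
  kc <- tab$n_admix[champ]
  tied <- ok[tab$n_admix[ok] == kc &
               tab$score[ok] >= tab$score[champ] - 3]
  tied[order(tab$score[tied], decreasing = TRUE)]
}

#' Exhaustively map a target population onto a skeleton graph
#'
#' Enumerates every attachment model of the target (up to `max_waves`
#' ancestry streams), fits each derived graph to the observed f-statistics,
#' discards fits with trifurcations (zero-length internal edges), then
#' selects across admixture counts with the 10-log-unit / 0.5-SE rules and
#' within the winning count with the 3-log-unit tie rule. Branch lengths
#' are refit for every candidate; by default the skeleton's own admixture
#' weights are held at their values and only newly introduced weights are
#' optimized (see [graph_config()]).
#'
#' @param skeleton a fitted [admix_graph()] (lengths and weights set).
#' @param target population label present in `F` but not in the skeleton.
#' @param F a [freq_table()] with all skeleton populations and the target.
#' @param blocks a [block_partition()].
#' @param config a [graph_config()].
#' @param excluded candidate-edge exclusion set (default: root edges).
#' @return An object of class `mapping_report`: `target`, `models_tested`,
#'   `models` (per-model table of edges, n_admix, score, worst_residual,
#'   trifurcation, error), `best_models` (list of fitted
#'   `attachment_model`s retained by the selection rules, best first),
#'   `discarded_trifurcations`, `n_failed`.
#' @export
map_target <- function(skeleton, target, F, blocks,
                       config = graph_config(),
                       excluded = root_edges(skeleton)) {
  models <- enumerate_attachments(skeleton, target,
                                  max_waves = config$max_waves,
                                  excluded = excluded)
  pops <- c(unname(skeleton$leaf_map), target)
  base <- if (is.null(config$base)) pops[1] else config$base
  basis <- observed_basis(F, pops, blocks, base = base)
  n <- length(models)
  tab <- data.frame(model = seq_len(n),
                    edges = vapply(models, function(m)
                      paste(m$edges, collapse = "+"), character(1)),
                    n_admix = vapply(models, `[[`, integer(1), "n_admix"),
                    score = rep(NA_real_, n),
                    worst_residual = rep(NA_real_, n),
                    trifurcation = rep(FALSE, n),
                    error = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  fits <- vector("list", n)
  skel_free <- which(!skeleton$admix$fixed)
  for (i in seq_len(n)) {
    res <- tryCatch({
      m <- derive_attachment_graph(skeleton, models[[i]])
      g <- m$derived_graph
      free <- which(is.na(g$admix$weight) & !g$admix$fixed)
      if (config$refit_skeleton_weights)
        free <- union(free, which(!g$admix$fixed))
      core <- fit_graph_core(g, basis, config, free_weights = free)
      structure(list(graph = core$graph, score = core$score,
                     expected = core$expected,
                     n_admix = n_admix(core$graph)),
                class = "graph_fit_light")
    }, error = function(e) e)
    if (inherits(res, "error")) {
      tab$error[i] <- conditionMessage(res)
      next
    }
    tab$score[i] <- res$score
    tab$trifurcation[i] <- backbone_zero(res$graph, config$zero_tol)
    fits[[i]] <- res
  }
  # worst residuals only for fits that survive the trifurcation filter and
  # are within contention (cheap shortcut: compute for all non-failed fits)
  rf <- residual_functionals(basis$spec, basis$base, pops)
  se <- sqrt(pmax(rowSums((rf$L %*% basis$cov) * rf$L), 0))
  obs <- drop(rf$L %*% basis$est)
  for (i in seq_len(n)) {
    if (is.null(fits[[i]])) next
    z <- ifelse(se > 0, (obs - drop(rf$L %*% fits[[i]]$expected)) / se, 0)
    tab$worst_residual[i] <- max(abs(z))
  }
  keep <- select_models(tab)
  best <- lapply(keep, function(i) {
    m <- models[[i]]
    m$derived_graph <- fits[[i]]$graph
    m$score <- tab$score[i]
    m$worst_residual <- tab$worst_residual[i]
    m
  })
  structure(list(target = target, models_tested = n, models = tab,
                 best_models = best,
                 discarded_trifurcations = sum(tab$trifurcation,
                                               na.rm = TRUE),
                 n_failed = sum(!is.na(tab$error))),
            class = "mapping_report")
}

expected_basis_values <- function(E, spec) {
  vapply(seq_len(nrow(spec)), function(s) {
    if (spec$kind[s] == "f2") exp_f2(E, spec$p1[s], spec$p2[s])
    else exp_f3(E, spec$p1[s], spec$p2[s], spec$p3[s])
  }, numeric(1))
}

#' @export
print.mapping_report <- function(x, ...) {
  cat("mapping_report for", x$target, ":", x$models_tested,
      "models tested,", x$discarded_trifurcations,
      "trifurcation(s) discarded,", x$n_failed, "failed\n")
  if (length(x$best_models)) {
    b <- x$best_models[[1]]
    cat("  best: {", paste(b$edges, collapse = ", "), "} score",
        sprintf("%.2f", b$score), "worst residual",
        sprintf("%.2f", b$worst_residual), "\n")
    if (length(x$best_models) > 1)
      cat("  (", length(x$best_models) - 1, "tied model(s) retained )\n")
  } else cat("  no model survived the filters\n")
  invisible(x)
}

#' Build a skeleton graph by mapping populations one at a time
#'
#' Starting from a fitted core graph, maps each additional population with
#' [map_target()] and adopts the single best model before adding the next.
#' Fixed admixture weights (e.g. an archaic admixture proportion pinned at
#' 3%) are preserved throughout. An unresolved tie halts with an error
#' listing the tied models — adjudication is left to the analyst.
#'
#' @param F a [freq_table()].
#' @param core a fitted [admix_graph()] (the initial populations).
#' @param additions population labels to map, in order.
#' @param blocks a [block_partition()].
#' @param config a [graph_config()].
#' @return A list of class `skeleton_build`: `graph` (the final fitted
#'   skeleton), `steps` (per-addition mapping reports).
#' @export
build_skeleton <- function(F, core, additions, blocks,
                           config = graph_config()) {
  g <- core
  steps <- list()
  for (pop in additions) {
    report <- map_target(g, pop, F, blocks, config = config)
    if (length(report$best_models) == 0L)
      stop("no valid attachment model for ", pop)
    if (length(report$best_models) > 1L) {
      tied <- vapply(report$best_models, function(m)
        paste(m$edges, collapse = "+"), character(1))
      stop("unresolved tie while adding ", pop, ": ",
           paste(tied, collapse = " | "))
    }
    g <- report$best_models[[1]]$derived_graph
    steps[[pop]] <- report
  }
  structure(list(graph = g, steps = steps), class = "skeleton_build")
}

#' @export
print.skeleton_build <- function(x, ...) {
  cat("skeleton_build:", length(x$steps), "population(s) added\n")
  for (nm in names(x$steps)) {
    b <- x$steps[[nm]]$best_models[[1]]
    cat("  ", nm, "-> {", paste(b$edges, collapse = ", "), "}\n")
  }
  invisible(x)
}
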