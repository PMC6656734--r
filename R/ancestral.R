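# Ancestral gene-order reconstruction on a rooted tree by candidate
# parsimony, with per-node consistency labels and per-edge scenarios.
#
# At each internal node the candidate set is small (child orders, the
# reference arrangement and, in the refinement pass, the parent's
# order); the candidate minimising the summed scenario lengths over the
# incident edges wins. Ties are broken first towards the candidate
# closest to the reference (breakpoint distance), then towards the
# reference itself -- a derived-state-averse convention appropriate when
# the reference is the presumed ancestral arrangement.

# memoized pairwise scenario summary: event-count cost plus, for
# two-event scenarios, the intermediate order the scenario passes
# through (used to enrich the candidate set: when every incident edge of
# a node carries an event, the true ancestral order is such an
# intermediate, not any neighbour's order)
.pair_info <- function(a, b, cache) {
  key <- paste(go_key(a), "->", go_key(b))
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- if (go_key(a) == go_key(b)) {
    list(cost = 0L, mid = NULL)
  } else {
    sc <- infer_scenario(a, b)
    list(cost = if (sc$complete) length(sc$events) else sc$breakpoint,
         mid = if (sc$complete && length(sc$events) == 2) {
           apply_event(a, sc$events[[1]])
         })
  }
  cache[[key]] <- val
  val
}

.scenario_cost <- function(a, b, cache) .pair_info(a, b, cache)$cost

.pick_candidate <- function(cands, costs, ref_bp, ref_idx) {
  best <- which(costs == min(costs))
  resolved_by <- "unique"
  if (length(best) > 1) {
    bb <- best[ref_bp[best] == min(ref_bp[best])]
    if (length(bb) == 1) {
      best <- bb; resolved_by <- "reference_proximity"
    } else if (any(bb %in% ref_idx)) {
      best <- bb[bb %in% ref_idx][1]; resolved_by <- "reference"
    } else {
      best <- bb[1]; resolved_by <- "arbitrary"
    }
  }
  list(idx = best[1], resolved_by = resolved_by)
}

#' Reconstruct ancestral gene orders on a rooted tree
#'
#' Two-pass candidate parsimony: a bottom-up (postorder) pass assigns to
#' each internal node the candidate among {left child order, right child
#' order, reference} minimising the total number of inferred
#' rearrangement events to its children; a top-down refinement pass
#' re-evaluates every node with its parent's assigned order added to the
#' candidate set. Each internal node receives a consistency label:
#' `"consistent"` (the final choice is the unique cost minimiser, or a
#' tie resolved by the documented reference preference),
#' `"intermediate"` (the refinement pass overturned a uniquely-resolved
#' bottom-up choice), or `"fallback"` (a residual tie was broken
#' deterministically). Non-binary nodes are resolved arbitrarily with
#' zero-length edges first (reported via `message()`).
#'
#' @param tree A rooted `phylo` tree whose tip labels name the taxa.
#' @param leaf_orders Named list of canonical, gene-restricted
#'   `gene_order`s over a common gene set, one per tip.
#' @param reference Reference `gene_order` (default [ground_pattern()]
#'   restricted to the leaves' gene set).
#' @return Object of class `reconstructed_tree`: list with `tree`,
#'   `node_orders` (list indexed by ape node number), `node_labels`
#'   (named by internal node number), `edge_scenarios` (one per edge,
#'   in `tree$edge` row order), `reference`.
#' @export
reconstruct_ancestral <- function(tree, leaf_orders, reference = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!ape::is.binary(tree)) {
    message("resolving non-binary nodes arbitrarily with zero-length edges")
    tree <- ape::multi2di(tree, random = FALSE)
  }
  tips <- tree$tip.label
  missing <- setdiff(tips, names(leaf_orders))
  if (length(missing)) {
    stop("no gene order supplied for leaf/leaves: ",
         paste(missing, collapse = ", "))
  }
  leaf_orders <- lapply(leaf_orders[tips], canonicalize_gene_order)
  gset <- go_names(leaf_orders[[1]]$tokens)
  for (go in leaf_orders) {
    nm <- go_names(go$tokens)
    if (!setequal(nm, gset) || anyDuplicated(nm)) {
      stop("leaf orders are not over a common single-copy gene set; apply ",
           "restrict_to_shared_genes()")
    }
  }
  if (is.null(reference)) reference <- ground_pattern()
  ref <- gene_order(reference$tokens[go_names(reference$tokens) %in% gset],
                    taxon_id = "reference")
  if (!setequal(go_names(ref$tokens), gset)) {
    stop("reference does not cover the leaves' gene set")
  }

  ntip <- length(tips)
  nnode <- tree$Nnode
  root <- ntip + 1L
  kids <- vector("list", ntip + nnode)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[e, 2])
  }
  parent <- integer(ntip + nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]

  cache <- new.env(parent = emptyenv())
  node_orders <- vector("list", ntip + nnode)
  for (k in seq_len(ntip)) node_orders[[k]] <- leaf_orders[[k]]

  cost <- function(a, b) .scenario_cost(a, b, cache)
  ref_dist <- function(go) breakpoint_distance(go, ref)

  evaluate <- function(cands, neighbours) {
    keys <- vapply(cands, go_key, character(1))
    cands <- cands[!duplicated(keys)]
    # enrich with intermediates of two-event scenarios between candidates
    if (length(cands) > 1) {
      mids <- list()
      for (x in seq_along(cands)) {
        for (y in seq_along(cands)) {
          if (x == y) next
          mid <- .pair_info(cands[[x]], cands[[y]], cache)$mid
          if (!is.null(mid)) mids[[length(mids) + 1L]] <- mid
        }
      }
      cands <- c(cands, mids)
      keys <- vapply(cands, go_key, character(1))
      cands <- cands[!duplicated(keys)]
    }
    costs <- vapply(cands, function(cd)
      sum(vapply(neighbours, function(nb) cost(cd, nb), numeric(1))),
      numeric(1))
    rbp <- vapply(cands, ref_dist, numeric(1))
    ref_idx <- which(vapply(cands, function(cd) go_equal(cd, ref), logical(1)))
    pick <- .pick_candidate(cands, costs, rbp, ref_idx)
    list(order = cands[[pick$idx]], resolved_by = pick$resolved_by)
  }

  # bottom-up pass (postorder over internal nodes)
  internal <- (ntip + 1L):(ntip + nnode)
  depth_order <- internal[order(-ape::node.depth(tree)[internal])]
  # process deepest (closest to tips) first
  up_choice <- character(ntip + nnode)
  for (nd in rev(depth_order)) {
    ch <- kids[[nd]]
    cands <- c(lapply(ch, function(c2) node_orders[[c2]]), list(ref))
    ev <- evaluate(cands, lapply(ch, function(c2) node_orders[[c2]]))
    node_orders[[nd]] <- ev$order
    up_choice[nd] <- ev$resolved_by
  }

  # top-down refinement (preorder), parent order added to candidates
  labels <- stats::setNames(character(nnode), internal)
  pre <- internal[order(ape::node.depth(tree)[internal], decreasing = TRUE)]
  for (nd in pre) {
    ch <- kids[[nd]]
    neigh <- lapply(ch, function(c2) node_orders[[c2]])
    cands <- c(list(node_orders[[nd]]), lapply(ch, function(c2) node_orders[[c2]]),
               list(ref))
    if (nd != root) {
      cands <- c(cands, list(node_orders[[parent[nd]]]))
      neigh <- c(neigh, list(node_orders[[parent[nd]]]))
    }
    ev <- evaluate(cands, neigh)
    changed <- !go_equal(ev$order, node_orders[[nd]])
    node_orders[[nd]] <- ev$order
    labels[as.character(nd)] <-
      if (ev$resolved_by == "arbitrary") "fallback"
      else if (changed && up_choice[nd] == "unique") "intermediate"
      else "consistent"
  }

  edge_scenarios <- vector("list", nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    edge_scenarios[[e]] <- infer_scenario(node_orders[[tree$edge[e, 1]]],
                                          node_orders[[tree$edge[e, 2]]])
  }
  structure(list(tree = tree, node_orders = node_orders,
                 node_labels = labels, edge_scenarios = edge_scenarios,
                 reference = ref),
            class = "reconstructed_tree")
}

#' @export
print.reconstructed_tree <- function(x, ...) {
  nev <- vapply(x$edge_scenarios, function(s) length(s$events), integer(1))
  cat(sprintf("reconstructed tree: %d tips, %d internal nodes, %d events on %d edges\n",
              length(x$tree$tip.label), x$tree$Nnode, sum(nev), sum(nev > 0)))
  cat("node labels:", paste(sprintf("%s=%d", names(table(x$node_labels)),
                                    table(x$node_labels)), collapse = ", "), "\n")
  invisible(x)
}

#' Per-edge event summary of a reconstruction
#'
#' @param rt A `reconstructed_tree`.
#' @param group_labels Optional named vector taxon -> group for per-clade
#'   aggregation (attribute `"by_group"` of the result).
#' @return Data frame with one row per edge: `parent`, `child`,
#'   `n_events`, per-type counts, `complete`.
#' @export
edge_event_summary <- function(rt, group_labels = NULL) {
  tree <- rt$tree
  ntip <- length(tree$tip.label)
  node_name <- function(k) if (k <= ntip) tree$tip.label[k] else paste0("node", k)
  types <- c("T", "r", "rT", "tdrl", "d", "x")
  rows <- lapply(seq_len(nrow(tree$edge)), function(e) {
    sc <- rt$edge_scenarios[[e]]
    tc <- table(factor(vapply(sc$events, `[[`, character(1), "type"),
                       levels = types))
    cbind(data.frame(parent = node_name(tree$edge[e, 1]),
                     child = node_name(tree$edge[e, 2]),
                     n_events = length(sc$events),
                     complete = sc$complete, stringsAsFactors = FALSE),
          as.data.frame(as.list(tc)))
  })
  out <- do.call(rbind, rows)
  names(out)[5:10] <- paste0("n_", types)
  if (!is.null(group_labels)) {
    tipgrp <- group_labels[tree$tip.label]
    # an edge belongs to the group of the tips below it, when unique
    below <- function(nd) {
      if (nd <= ntip) return(tree$tip.label[nd])
      unlist(lapply(which(tree$edge[, 1] == nd),
                    function(e) below(tree$edge[e, 2])))
    }
    grp <- vapply(seq_len(nrow(tree$edge)), function(e) {
      g <- unique(tipgrp[below(tree$edge[e, 2])])
      if (length(g) == 1 && !is.na(g)) g else NA_character_
    }, character(1))
    out$group <- grp
    agg <- stats::aggregate(n_events ~ group, data = out[!is.na(out$group), ],
                            FUN = sum)
    attr(out, "by_group") <- agg
  }
  out
}
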