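# Inference of rearrangement scenarios between two gene orders.
#
# Strategy (deterministic, one scenario per pair):
#   (i)   equal orders -> empty scenario;
#   (ii)  exhaustive search for a single T, r or rT event, in preference
#         order r > T > rT, shorter segment first, then leftmost; gated
#         by the breakpoint distance (a single reversal changes at most
#         2 adjacencies, a (reverse) transposition at most 3);
#   (iii) all relative signs +1 -> minimum-length pure tdrl scenario via
#         radix partition of the ascending strips (ceil(log2 s) steps);
#   (iv)  otherwise reversals fixing each run of minus-strand genes,
#         followed by the tdrl steps; scenarios that accumulate more
#         than 8 events are flagged complete = FALSE.

# relative signed permutation of `target` w.r.t. `source` (both canonical,
# identical single-copy gene sets); source becomes the identity +1..+n
relative_perm <- function(source, target) {
  s_nm <- go_names(source$tokens); s_sg <- go_signs(source$tokens)
  t_nm <- go_names(target$tokens); t_sg <- go_signs(target$tokens)
  if (length(s_nm) != length(t_nm) || !setequal(s_nm, t_nm) ||
      anyDuplicated(s_nm) || anyDuplicated(t_nm)) {
    stop("orders have differing gene sets; apply restrict_to_shared_genes()")
  }
  k <- match(t_nm, s_nm)
  canon_int(as.integer(k * t_sg * s_sg[k]))
}

# breakpoint distance of a relative signed permutation to the identity
bp_int <- function(v) {
  n <- length(v)
  a <- v; b <- c(v[-1], v[1])
  ok <- (b == a + 1L) | (a == n & b == 1L) | (a == -1L & b == -n)
  sum(!ok)
}

# number of maximal ascending contiguous runs of an all-positive perm
.strips <- function(p) 1L + sum(diff(p) < 0L)

#' Minimum number of tandem duplication-random loss events
#'
#' For two orders whose relative permutation carries uniform +1 signs,
#' the tdrl distance equals `ceil(log2(s))` where `s` is the number of
#' maximal ascending contiguous runs of the relative permutation
#' (linearised at the anchor); a single tdrl can at most double the
#' number of realisable ascending runs, and a radix-partition
#' construction attains the bound.
#'
#' @param source A `gene_order`, or directly a relative permutation
#'   (integer vector over `1..n`), in which case `target` is ignored
#'   and the permutation is used as given (linear convention).
#' @param target Canonical `gene_order` over `source`'s gene set.
#' @return Integer; 0 iff the orders are equal.
#' @export
tdrl_min_count <- function(source, target = NULL) {
  t <- if (is.numeric(source)) {
    p <- as.integer(source)
    if (!setequal(p, seq_along(p))) stop("not a permutation of 1..n")
    p
  } else {
    relative_perm(canonicalize_gene_order(source),
                  canonicalize_gene_order(target))
  }
  if (any(t < 0)) {
    stop("relative permutation has mixed signs; use infer_scenario()")
  }
  s <- .strips(t)
  as.integer(ceiling(log2(s)))
}

# exhaustive single-event search on the identity -> t problem.
# Returns list(type, i, j, after) in source coordinates, or NULL.
search_single_event <- function(t, max_candidates = Inf) {
  n <- length(t)
  id <- seq_len(n)
  tried <- 0L
  for (len in seq_len(n - 1L)) {
    for (i in seq_len(n)) {
      j <- ((i + len - 2L) %% n) + 1L
      seg <- .seg_idx(i, j, n)
      tried <- tried + 1L
      if (tried > max_candidates) return(NULL)
      if (identical(canon_int(int_r(id, seg)), t)) {
        return(list(type = "r", i = i, j = j))
      }
    }
  }
  for (flip in c(FALSE, TRUE)) {
    for (len in seq_len(n - 2L)) {
      for (i in seq_len(n)) {
        j <- ((i + len - 2L) %% n) + 1L
        seg <- .seg_idx(i, j, n)
        rest <- setdiff(id, seg)
        prev <- ((i - 2L) %% n) + 1L
        for (after in rest) {
          if (!flip && after == prev) next  # no-op move
          tried <- tried + 1L
          if (tried > max_candidates) return(NULL)
          if (identical(canon_int(int_move(id, seg, after, flip)), t)) {
            return(list(type = if (flip) "rT" else "T",
                        i = i, j = j, after = after))
          }
        }
      }
    }
  }
  NULL
}

# tdrl radix rounds: returns list of event_tdrl over the full window that
# transform `cur` into `target` (both canonical, all relative signs +1)
.tdrl_round_events <- function(cur, target) {
  t <- relative_perm(cur, target)
  stopifnot(all(t > 0))
  s <- .strips(t)
  if (s == 1L) return(list())
  # strip id per gene, keyed by token name; t maps target positions to
  # current positions, so invert: gene at current position t[p] has rank p
  strip_of_rank <- cumsum(c(0L, diff(t) < 0L))     # 0-based strip ids, by
  # ... position along t; gene identity = current position value
  cur_nm <- go_names(cur$tokens)
  strip_id <- integer(length(t))
  strip_id[t] <- strip_of_rank                      # by current position
  names(strip_id) <- cur_nm
  rounds <- ceiling(log2(s))
  events <- vector("list", rounds)
  state <- cur
  for (b in seq_len(rounds)) {
    nm <- go_names(state$tokens)
    keep <- bitwAnd(strip_id[nm], bitwShiftL(1L, b - 1L)) == 0L
    events[[b]] <- event_tdrl(1L, length(nm), unname(keep))
    state <- apply_event(state, events[[b]])
  }
  attr(events, "final") <- state
  events
}

#' Infer a rearrangement scenario between two gene orders
#'
#' Produces one deterministic scenario (an ordered event list) that
#' transforms `source` into `target`, using the prioritised search
#' described in the package vignette: single-event search (r, then T,
#' then rT; shortest, leftmost segment preferred), a minimum-length pure
#' tdrl scenario when all relative strands agree, and otherwise
#' sign-fixing reversals followed by tdrl steps. Scenarios longer than 8
#' events are returned with `complete = FALSE` (hard cases are reported,
#' not trusted).
#'
#' @param source,target `gene_order`s over the same single-copy gene set.
#' @param max_single_search Cap on the number of single-event candidates
#'   examined (default unlimited).
#' @return An object of class `mgo_scenario`: list with elements
#'   `source`, `target`, `events`, `complete`, `breakpoint`.
#' @export
infer_scenario <- function(source, target, max_single_search = Inf) {
  source <- canonicalize_gene_order(source)
  target <- canonicalize_gene_order(target)
  t <- relative_perm(source, target)
  n <- length(t)
  bp <- bp_int(t)
  mk <- function(events, complete) {
    structure(list(source = source, target = target, events = events,
                   complete = complete, breakpoint = bp),
              class = "mgo_scenario")
  }
  if (bp == 0L && all(t == seq_len(n))) return(mk(list(), TRUE))

  if (bp <= 3L) {
    hit <- search_single_event(t, max_single_search)
    if (!is.null(hit)) {
      ev <- switch(hit$type,
        r = event_r(hit$i, hit$j),
        T = event_T(hit$i, hit$j, hit$after),
        rT = event_rT(hit$i, hit$j, hit$after))
      return(mk(list(ev), TRUE))
    }
  }

  events <- list()
  cur <- source
  if (any(t < 0)) {
    # reverse each maximal run of minus-strand genes (runs are disjoint,
    # so positions computed up front remain valid)
    sign_of <- integer(n)
    sign_of[abs(t)] <- sign(t)       # relative sign by source position
    neg <- sign_of < 0
    rle_ <- rle(neg)
    pos <- cumsum(c(1L, rle_$lengths))
    for (k in seq_along(rle_$values)) {
      if (rle_$values[k]) {
        ev <- event_r(pos[k], pos[k] + rle_$lengths[k] - 1L)
        events[[length(events) + 1L]] <- ev
        cur <- apply_event(cur, ev)
      }
    }
  }
  td <- .tdrl_round_events(cur, target)
  final <- if (length(td)) attr(td, "final") else cur
  events <- c(events, td)
  ok <- go_equal(final, target)
  mk(events, ok && length(events) <= 8L)
}

#' @export
print.mgo_scenario <- function(x, ...) {
  cat(sprintf("scenario %s -> %s: %d event(s)%s, breakpoint distance %d\n",
              x$source$taxon_id %||% "source", x$target$taxon_id %||% "target",
              length(x$events), if (x$complete) "" else " [incomplete]",
              x$breakpoint))
  for (e in x$events) print(e)
  invisible(x)
}

#' Replay a scenario's events over its source order
#' @param scenario An `mgo_scenario`.
#' @return The resulting canonical `gene_order`.
#' @export
replay_scenario <- function(scenario) {
  Reduce(apply_event, scenario$events, init = scenario$source)
}

#' Rearrangement event count from a reference order
#'
#' Scalar "MGO divergence": the length of the inferred scenario from the
#' reference (by default the ground pattern) to the order, falling back
#' to the breakpoint distance (flagged via attribute `"surrogate"`) when
#' the scenario is incomplete. The two orders are first restricted to
#' their shared single-copy genes.
#'
#' @param order A `gene_order`.
#' @param reference Reference `gene_order` (default [ground_pattern()]).
#' @return Integer count; 0 iff the order equals the reference.
#' @export
event_count_to_reference <- function(order, reference = ground_pattern()) {
  pair <- suppressMessages(
    restrict_to_shared_genes(list(ref = reference, obs = order)))
  sc <- infer_scenario(pair$ref, pair$obs)
  if (sc$complete) {
    structure(length(sc$events), surrogate = FALSE)
  } else {
    structure(sc$breakpoint, surrogate = TRUE)
  }
}
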