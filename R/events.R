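# Forward rearrangement operators on circular signed gene orders.
#
# Event taxonomy: transposition (T), reversal (r), reverse transposition
# (rT), tandem duplication-random loss (tdrl), duplication (d) and
# deletion (x). Operands are positions in the order the event is applied
# to; segments are contiguous circular runs `i..j` (wrapping allowed when
# i > j). Applying an event returns a re-canonicalised order.

#' Rearrangement event constructors
#'
#' @param i,j First and last position of the operand segment (1-based,
#'   inclusive, circular: `i > j` wraps past the origin).
#' @param after For `T`/`rT`/`d`: the segment is (re)inserted immediately
#'   after the gene currently at this position (which must lie outside
#'   the segment).
#' @param keep_first For `tdrl`: logical vector, one flag per gene of the
#'   window `i..j`, `TRUE` for genes retained in the first tandem copy,
#'   `FALSE` for those retained in the second.
#' @return A list of class `mgo_event`.
#' @name mgo_events
NULL

.mk_event <- function(type, ...) {
  structure(c(list(type = type), list(...)), class = "mgo_event")
}

#' @rdname mgo_events
#' @export
event_r <- function(i, j) .mk_event("r", i = i, j = j)

#' @rdname mgo_events
#' @export
event_T <- function(i, j, after) .mk_event("T", i = i, j = j, after = after)

#' @rdname mgo_events
#' @export
event_rT <- function(i, j, after) .mk_event("rT", i = i, j = j, after = after)

#' @rdname mgo_events
#' @export
event_tdrl <- function(i, j, keep_first) {
  .mk_event("tdrl", i = i, j = j, keep_first = as.logical(keep_first))
}

#' @rdname mgo_events
#' @export
event_d <- function(i, j) .mk_event("d", i = i, j = j)

#' @rdname mgo_events
#' @export
event_x <- function(i, j) .mk_event("x", i = i, j = j)

#' @export
print.mgo_event <- function(x, ...) {
  op <- switch(x$type,
    r = sprintf("reverse %d..%d", x$i, x$j),
    T = sprintf("move %d..%d after %d", x$i, x$j, x$after),
    rT = sprintf("move+flip %d..%d after %d", x$i, x$j, x$after),
    tdrl = sprintf("tdrl window %d..%d keep-first {%s}", x$i, x$j,
                   paste(which(x$keep_first), collapse = ",")),
    d = sprintf("tandem-duplicate %d..%d", x$i, x$j),
    x = sprintf("delete %d..%d", x$i, x$j))
  cat("event", x$type, "-", op, "\n")
  invisible(x)
}

.seg_idx <- function(i, j, n) {
  stopifnot(i >= 1, i <= n, j >= 1, j <= n)
  if (i <= j) i:j else c(i:n, 1:j)
}

#' Apply a rearrangement event to a gene order
#'
#' `r` reverses the segment and flips all its signs; `T` excises the
#' segment and reinserts it after the gene at position `after`; `rT`
#' additionally reverses and flips it; `tdrl` duplicates the window in
#' tandem and strikes one copy of each gene according to the bipartition
#' (equivalently: a stable partition of the window into kept-first genes
#' followed by kept-second genes, signs unchanged); `d` inserts a tandem
#' copy of the segment; `x` deletes the segment.
#'
#' @param order A `gene_order`.
#' @param event An `mgo_event`.
#' @return The rearranged, canonical `gene_order`.
#' @export
apply_event <- function(order, event) {
  v <- order$tokens
  n <- length(v)
  seg <- .seg_idx(event$i, event$j, n)
  if (length(seg) >= n && event$type %in% c("r", "T", "rT", "x")) {
    stop("operand segment must be a proper circular run")
  }
  out <- switch(event$type,
    r = {
      v[seg] <- rev(go_negate(v[seg])); v
    },
    T = .move_segment(v, seg, event$after, flip = FALSE),
    rT = .move_segment(v, seg, event$after, flip = TRUE),
    tdrl = {
      kf <- event$keep_first
      if (length(kf) != length(seg)) {
        stop("tdrl keep_first must have one flag per window gene")
      }
      if (!any(kf) || all(kf)) stop("tdrl bipartition must be non-trivial")
      v[seg] <- c(v[seg][kf], v[seg][!kf]); v
    },
    d = {
      append(v, v[seg], after = seg[length(seg)])
    },
    x = v[-seg],
    stop("unknown event type '", event$type, "'"))
  gene_order(out, taxon_id = order$taxon_id)
}

.move_segment <- function(v, seg, after, flip) {
  n <- length(v)
  if (after %in% seg) stop("insertion point lies inside the moved segment")
  piece <- v[seg]
  if (flip) piece <- rev(go_negate(piece))
  anchor_tok <- v[after]
  keep <- v[-seg]
  pos <- which(seq_len(n)[-seg] == after)
  append(keep, piece, after = pos)
}

# -- fast internal operators on signed integer vectors ---------------------
# Used by the scenario-inference search; value `k` stands for the gene at
# position k of the (identity-encoded) source, sign = relative strand.

canon_int <- function(v) {
  i <- which(abs(v) == 1L)
  n <- length(v)
  if (i > 1L) v <- v[c(i:n, seq_len(i - 1L))]
  if (v[1L] < 0L) {
    v <- -rev(v)
    i <- which(v == 1L)
    if (i > 1L) v <- v[c(i:n, seq_len(i - 1L))]
  }
  v
}

int_r <- function(v, seg) { v[seg] <- -rev(v[seg]); v }

int_move <- function(v, seg, after_pos, flip) {
  piece <- v[seg]
  if (flip) piece <- -rev(piece)
  keep <- v[-seg]
  pos <- which(seq_along(v)[-seg] == after_pos)
  append(keep, piece, after = pos)
}

int_tdrl <- function(v, seg, keep_first) {
  v[seg] <- c(v[seg][keep_first], v[seg][!keep_first])
  v
}
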