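# Canonical circular signed gene orders (MGOs) and operations on them:
# canonicalisation, pattern clustering, breakpoint distance, AMIGA.
#
# A gene order is stored as a character vector of signed tokens
# ("cox1", "-trnC", ...) read in forward-strand direction around the
# circle. Canonical form: rotated so the anchor gene comes first and
# reflected (reverse + sign flip = reading the other strand) if needed so
# the anchor carries sign +1. Two GenBank records that differ only by
# deposited strand or sequence start therefore yield identical objects.

#' Create a gene order
#'
#' @param tokens Character vector of signed tokens (`"-trnC"` style) in
#'   circular reading order.
#' @param taxon_id Taxon identifier.
#' @param canonical If `TRUE` (default) the order is canonicalised.
#' @return An object of class `gene_order`.
#' @export
gene_order <- function(tokens, taxon_id = NA_character_, canonical = TRUE) {
  stopifnot(is.character(tokens), length(tokens) >= 1)
  go <- structure(list(taxon_id = taxon_id, tokens = tokens),
                  class = "gene_order")
  if (canonical) go <- canonicalize_gene_order(go) else go
}

#' @export
print.gene_order <- function(x, ...) {
  cat("gene order", if (!is.na(x$taxon_id)) paste0("[", x$taxon_id, "]"),
      sprintf("(%d genes):\n", length(x$tokens)))
  cat(" ", paste(x$tokens, collapse = " "), "\n")
  invisible(x)
}

# signed-token helpers ------------------------------------------------------

go_signs <- function(tokens) ifelse(startsWith(tokens, "-"), -1L, 1L)
go_names <- function(tokens) sub("^-", "", tokens)
go_signed <- function(names, signs) paste0(ifelse(signs < 0, "-", ""), names)
go_negate <- function(tokens) {
  ifelse(startsWith(tokens, "-"), sub("^-", "", tokens), paste0("-", tokens))
}

go_key <- function(go) paste(go$tokens, collapse = " ")

#' Test equality of two gene orders as circular signed arrangements
#' @param a,b `gene_order` objects.
#' @return Logical.
#' @export
go_equal <- function(a, b) {
  identical(canonicalize_gene_order(a)$tokens, canonicalize_gene_order(b)$tokens)
}

.pick_anchor <- function(names) {
  for (cand in c("cox1", "cob", "rrnL")) if (cand %in% names) return(cand)
  sort(unique(names))[1]
}

#' Canonicalise a gene order
#'
#' Rotates the circular order so the anchor gene (`cox1`, falling back to
#' `cob`, `rrnL`, then the lexicographically smallest token) comes first,
#' and, if the anchor lies on the minus strand, reflects the whole order
#' (reverse the list and flip every sign: a circular molecule has no
#' intrinsic strand). Idempotent.
#'
#' @param go A `gene_order`.
#' @param anchor Optional anchor token; default picked as above.
#' @return Canonical `gene_order`.
#' @export
canonicalize_gene_order <- function(go, anchor = NULL) {
  if (!inherits(go, "gene_order")) stop("not a gene_order object")
  toks <- go$tokens
  nm <- go_names(toks)
  if (is.null(anchor)) anchor <- .pick_anchor(nm)
  if (!anchor %in% nm) {
    stop("anchor gene '", anchor, "' absent from order of taxon '",
         go$taxon_id, "'")
  }
  n <- length(toks)
  rotate <- function(v, i) if (i > 1) v[c(i:n, seq_len(i - 1))] else v
  # candidate representations: one rotation per plus-strand anchor copy,
  # in each orientation; lexicographically smallest key wins (this keeps
  # canonicalisation rotation- and reflection-invariant even when the
  # anchor gene is duplicated)
  cands <- list()
  for (v in list(toks, rev(go_negate(toks)))) {
    hits <- which(go_names(v) == anchor & !startsWith(v, "-"))
    for (i in hits) cands[[length(cands) + 1L]] <- rotate(v, i)
  }
  if (length(cands) == 0) {  # anchor present only on the minus strand of
    # both readings cannot happen; guard anyway
    stop("anchor gene '", anchor, "' has no usable copy")
  }
  keys <- vapply(cands, paste, character(1), collapse = " ")
  go$tokens <- cands[[order(keys)[1]]]
  go
}

#' Extract the gene order from an annotated mitogenome record
#'
#' Features of the requested classes are sorted by start coordinate
#' (an origin-spanning feature is placed by its start), mapped to signed
#' tokens, and canonicalised. Features with token `"unknown"` or
#' `"other"` (control region) are excluded.
#'
#' @param record A `mitogenome_record` from [read_genbank()] or
#'   [synthesize_records()].
#' @param gene_classes Subset of `c("PCG", "rRNA", "tRNA")`.
#' @return A canonical `gene_order`.
#' @export
extract_gene_order <- function(record,
                               gene_classes = c("PCG", "rRNA", "tRNA")) {
  f <- record$features
  f <- f[f$kind %in% gene_classes & !f$token %in% c("unknown", "other"), ,
         drop = FALSE]
  if (nrow(f) == 0) {
    stop("record '", record$taxon_id, "' has no features of the requested ",
         "classes")
  }
  f <- f[order(f$start), , drop = FALSE]
  gene_order(go_signed(f$token, f$strand), taxon_id = record$taxon_id)
}

#' Restrict a gene order to given gene classes
#' @param go A `gene_order`.
#' @param gene_classes Subset of `c("PCG", "rRNA", "tRNA")`.
#' @return Canonical `gene_order` over the retained genes.
#' @export
restrict_gene_classes <- function(go, gene_classes = c("PCG", "rRNA", "tRNA")) {
  keep <- gene_kind(go_names(go$tokens)) %in% gene_classes
  if (!any(keep)) stop("no genes of the requested classes remain")
  gene_order(go$tokens[keep], taxon_id = go$taxon_id)
}

#' Restrict a set of gene orders to their shared single-copy genes
#'
#' Genes absent from at least one taxon are deleted from all taxa; for a
#' gene duplicated within a taxon only the first copy in canonical
#' reading order is retained. Output orders are re-canonicalised. The
#' deletions performed are attached as attribute `"deletions"` (a data
#' frame taxon/token/reason) and reported via `message()`.
#'
#' @param orders A (named) list of `gene_order` objects.
#' @return List of restricted canonical orders, same names, with
#'   attribute `"deletions"`.
#' @export
restrict_to_shared_genes <- function(orders) {
  stopifnot(length(orders) >= 2)
  dels <- list()
  # collapse duplicates first (first copy in canonical reading order)
  orders <- lapply(orders, function(go) {
    go <- canonicalize_gene_order(go)
    nm <- go_names(go$tokens)
    dup <- duplicated(nm)
    if (any(dup)) {
      dels[[length(dels) + 1]] <<- data.frame(
        taxon = go$taxon_id, token = nm[dup], reason = "duplicate")
      go <- gene_order(go$tokens[!dup], taxon_id = go$taxon_id)
    }
    go
  })
  sets <- lapply(orders, function(go) go_names(go$tokens))
  shared <- Reduce(intersect, sets)
  if (length(shared) < 3) {
    stop("fewer than 3 genes shared by all taxa; orders are incomparable")
  }
  orders <- lapply(orders, function(go) {
    nm <- go_names(go$tokens)
    drop <- !nm %in% shared
    if (any(drop)) {
      dels[[length(dels) + 1]] <<- data.frame(
        taxon = go$taxon_id, token = nm[drop], reason = "unshared")
      go <- gene_order(go$tokens[!drop], taxon_id = go$taxon_id)
    }
    go
  })
  report <- if (length(dels)) do.call(rbind, dels) else
    data.frame(taxon = character(), token = character(), reason = character())
  if (nrow(report) > 0) {
    message(nrow(report), " gene copies removed while restricting to the ",
            length(shared), " shared single-copy genes")
  }
  attr(orders, "deletions") <- report
  orders
}

#' Cluster identical gene orders into MGO patterns
#'
#' Exact equality of canonical orders defines a pattern. The pattern equal
#' to the reference (ground pattern, restricted to the same gene set) is
#' labelled `"Gr"`; the remaining patterns are numbered within each group
#' prefix in order of first appearance (`"An1"` style).
#'
#' @param orders Named list of canonical, gene-restricted `gene_order`s.
#' @param prefix_map Optional named character vector taxon -> two-letter
#'   group prefix; default prefix `"Mg"` for all taxa.
#' @param reference Reference `gene_order`; default [ground_pattern()].
#' @return A data frame of class `mgo_patterns` with columns
#'   `pattern_id`, `count`, `exemplar`, `members`, and attribute
#'   `"assignment"` (named vector taxon -> pattern_id).
#' @export
cluster_patterns <- function(orders, prefix_map = NULL, reference = ground_pattern()) {
  if (is.null(names(orders)) || any(!nzchar(names(orders)))) {
    names(orders) <- vapply(orders, function(g) g$taxon_id, character(1))
  }
  taxa <- names(orders)
  if (is.null(prefix_map)) prefix_map <- stats::setNames(rep("Mg", length(taxa)), taxa)
  keys <- vapply(orders, go_key, character(1))

  gene_set <- go_names(orders[[1]]$tokens)
  ref_key <- NA_character_
  if (!is.null(reference)) {
    ref_toks <- reference$tokens[go_names(reference$tokens) %in% gene_set]
    if (setequal(go_names(ref_toks), gene_set)) {
      ref_key <- go_key(gene_order(ref_toks, taxon_id = "Gr"))
    }
  }

  ukeys <- unique(keys)  # order of first appearance
  counters <- list()
  ids <- character(length(ukeys))
  for (k in seq_along(ukeys)) {
    if (!is.na(ref_key) && ukeys[k] == ref_key) {
      ids[k] <- "Gr"
    } else {
      first_tax <- taxa[match(ukeys[k], keys)]
      pre <- unname(prefix_map[first_tax])
      if (is.na(pre)) pre <- "Mg"
      counters[[pre]] <- (counters[[pre]] %||% 0L) + 1L
      ids[k] <- paste0(pre, counters[[pre]])
    }
  }
  assignment <- stats::setNames(ids[match(keys, ukeys)], taxa)
  out <- data.frame(
    pattern_id = ids,
    count = as.integer(table(factor(keys, levels = ukeys))),
    exemplar = ukeys,
    members = vapply(ukeys, function(k) paste(taxa[keys == k], collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "assignment") <- assignment
  class(out) <- c("mgo_patterns", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signed circular breakpoint distance between two gene orders
#'
#' Counts the signed adjacencies of `o1` (circular, with `(x, y)`
#' identified with `(-y, -x)`) that are absent from `o2`. Symmetric, and a
#' metric on canonical orders over a fixed gene set.
#'
#' @param o1,o2 Canonical `gene_order`s over the identical gene set.
#' @return Integer distance.
#' @export
breakpoint_distance <- function(o1, o2) {
  n1 <- go_names(o1$tokens); n2 <- go_names(o2$tokens)
  if (!setequal(n1, n2) || anyDuplicated(n1) || anyDuplicated(n2) ||
      length(n1) != length(n2)) {
    stop("orders have differing gene sets; apply restrict_to_shared_genes()")
  }
  a1 <- .adjacency_keys(o1$tokens)
  a2 <- .adjacency_keys(o2$tokens)
  sum(!a1 %in% a2)
}

.adjacency_keys <- function(tokens) {
  n <- length(tokens)
  nxt <- c(tokens[-1], tokens[1])
  fwd <- paste(tokens, nxt)
  rev_ <- paste(go_negate(nxt), go_negate(tokens))
  ifelse(fwd <= rev_, fwd, rev_)
}

#' AMIGA: per-taxon fraction of identical gene arrangements
#'
#' For each taxon, the size of its MGO pattern divided by the dataset
#' size. Conventionally computed on protein-coding-gene-only patterns.
#'
#' @param patterns An `mgo_patterns` object.
#' @param n_taxa Dataset size (defaults to the number of clustered taxa).
#' @return Named numeric vector in `(0, 1]`, one value per taxon.
#' @export
amiga <- function(patterns, n_taxa = NULL) {
  assignment <- attr(patterns, "assignment")
  if (is.null(assignment)) stop("patterns object lacks a taxon assignment")
  if (is.null(n_taxa)) n_taxa <- length(assignment)
  sizes <- stats::setNames(patterns$count, patterns$pattern_id)
  val <- sizes[assignment]
  if (anyNA(val)) stop("taxon not present in any pattern")
  stats::setNames(as.numeric(val) / n_taxa, names(assignment))
}
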