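# Independent oracles and fixture builders used across the suite.

# GenBank ORIGIN block lines (60 bases per line, 10-base groups)
origin_lines <- function(seq) {
  n <- nchar(seq)
  vapply(seq(1, n, 60), function(p) {
    chunk <- substr(seq, p, min(p + 59, n))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    paste0(sprintf("%9d", p), " ", paste(groups, collapse = " "))
  }, character(1))
}

# a random circular signed order over single-letter tokens
random_order <- function(n, taxon_id = NA_character_) {
  toks <- sample(letters[seq_len(n)])
  signs <- sample(c(1, -1), n, replace = TRUE)
  gene_order(ifelse(signs < 0, paste0("-", toks), toks), taxon_id = taxon_id)
}

# a random single T/r/rT event valid for an order of length n
random_single_event <- function(n) {
  type <- sample(c("r", "T", "rT"), 1)
  i <- sample(n, 1)
  len <- sample(seq_len(n - 2), 1)
  j <- ((i + len - 2L) %% n) + 1L
  if (type == "r") return(event_r(i, j))
  seg <- if (i <= j) i:j else c(i:n, 1:j)
  prev <- ((i - 2L) %% n) + 1L
  pool <- setdiff(seq_len(n), c(seg, if (type == "T") prev))
  after <- pool[sample(length(pool), 1)]
  if (type == "T") event_T(i, j, after) else event_rT(i, j, after)
}

# exhaustive oracle: all single-event types (over every circular segment
# and insertion point) that transform `source` into `target`. Implemented
# test-locally on plain signed integer vectors, independently of the
# package's search code.
.or_canon <- function(v) {
  n <- length(v)
  i <- which(abs(v) == 1L)[1]
  if (i > 1L) v <- c(v[i:n], v[seq_len(i - 1L)])
  if (v[1L] < 0L) {
    v <- -rev(v)
    i <- which(v == 1L)[1]
    if (i > 1L) v <- c(v[i:n], v[seq_len(i - 1L)])
  }
  v
}

oracle_single_event_types <- function(source, target) {
  s <- source$tokens; tt <- target$tokens
  nm_s <- sub("^-", "", s); sg_s <- ifelse(startsWith(s, "-"), -1L, 1L)
  nm_t <- sub("^-", "", tt); sg_t <- ifelse(startsWith(tt, "-"), -1L, 1L)
  k <- match(nm_t, nm_s)
  tv <- .or_canon(as.integer(k * sg_t * sg_s[k]))
  n <- length(tv)
  id <- seq_len(n)
  types <- character()
  for (i in seq_len(n)) {
    for (len in seq_len(n - 1)) {
      j <- ((i + len - 2L) %% n) + 1L
      seg <- if (i <= j) i:j else c(i:n, 1:j)
      cand <- id; cand[seg] <- -rev(cand[seg])
      if (identical(.or_canon(cand), tv)) types <- c(types, "r")
      if (len <= n - 2) {
        keep <- id[-seg]
        for (ap in seq_along(keep)) {
          after_gene <- keep[ap]
          head_ <- keep[seq_len(ap)]
          tail_ <- if (ap < length(keep)) keep[(ap + 1):length(keep)] else integer()
          if (identical(.or_canon(c(head_, id[seg], tail_)), tv)) {
            types <- c(types, "T")
          }
          if (identical(.or_canon(c(head_, -rev(id[seg]), tail_)), tv)) {
            types <- c(types, "rT")
          }
        }
      }
    }
  }
  unique(types)
}

# BFS oracle for the whole-window tdrl distance on linear permutations:
# distance from the identity to every permutation of 1..n
tdrl_bfs_distances <- function(n) {
  key <- function(p) paste(p, collapse = ",")
  subsets <- lapply(1:(2^n - 2), function(m) {
    which(bitwAnd(m, bitwShiftL(1L, 0:(n - 1))) != 0)
  })
  dist <- new.env(parent = emptyenv())
  id <- seq_len(n)
  assign(key(id), 0L, envir = dist)
  frontier <- list(id)
  d <- 0L
  total <- factorial(n)
  while (length(frontier) && length(ls(dist)) < total) {
    d <- d + 1L
    nxt <- list()
    for (p in frontier) {
      for (s in subsets) {
        q <- c(p[s], p[-s])
        k <- key(q)
        if (is.null(dist[[k]])) {
          dist[[k]] <- d
          nxt[[length(nxt) + 1L]] <- q
        }
      }
    }
    frontier <- nxt
  }
  dist
}

# all permutations of 1..n
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

# simulate data from a one-factor model with given loadings
simulate_factor_data <- function(n, loadings, seed) {
  with_seed(seed, {
    f <- rnorm(n)
    X <- sapply(loadings, function(l) l * f + sqrt(1 - l^2) * rnorm(n))
    colnames(X) <- c("rtot_dist", "ml_dist", "ur_percent", "amiga", "su_skew")
    as.data.frame(X)
  })
}

# non-exported helpers used by tests
with_seed <- mitorder:::with_seed
go_key <- mitorder:::go_key
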