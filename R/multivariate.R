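# Correlation-matrix PCA over feature tables, and Spearman correlation
# tests linking gene-order divergence to habitat and substitution rates.

#' Principal component analysis on the Pearson correlation matrix
#'
#' Eigendecomposition of the correlation matrix of the numeric columns;
#' variance fractions are `eigenvalues / p`. Constant columns are
#' dropped (reported via `message()`). Deterministic sign convention:
#' the largest-magnitude loading of each component is positive.
#'
#' @param table Data frame or matrix of numeric features (a `taxon_id`
#'   column, if present, names the rows).
#' @return List with `loadings` (variables x components), `scores`
#'   (rows x components), `variance_fractions`, `dropped`.
#' @export
pca_correlation <- function(table) {
  rn <- NULL
  if (is.data.frame(table) && "taxon_id" %in% names(table)) {
    rn <- table$taxon_id
    table <- table[, setdiff(names(table), "taxon_id"), drop = FALSE]
  }
  X <- as.matrix(table)
  storage.mode(X) <- "double"
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0 | is.na(sds)]
  if (length(dropped)) {
    message("dropping constant column(s): ", paste(dropped, collapse = ", "))
    X <- X[, !(colnames(X) %in% dropped), drop = FALSE]
  }
  p <- ncol(X)
  if (p < 2) stop("fewer than 2 variable columns remain")
  R <- stats::cor(X)
  ei <- eigen(R, symmetric = TRUE)
  V <- ei$vectors
  for (j in seq_len(p)) {
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(colnames(X), paste0("PC", seq_len(p)))
  scores <- scale(X) %*% V
  rownames(scores) <- rn
  list(loadings = V, scores = scores,
       variance_fractions = pmax(ei$values, 0) / p, dropped = dropped)
}

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Spearman rank correlation with t and permutation p-values
#'
#' `rho` is the Pearson correlation of average ranks (ties allowed);
#' `p_t` uses `t = rho sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of
#' freedom; `p_perm` is a two-sided seeded permutation p-value with
#' add-one correction.
#'
#' @param x,y Numeric vectors of equal length (n >= 4).
#' @param n_perm Number of permutations (0 disables `p_perm`).
#' @param seed Optional seed for the permutations.
#' @return List `rho`, `p_t`, `p_perm`, `n`, `degenerate`.
#' @export
spearman_test <- function(x, y, n_perm = 0, seed = NULL) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4) stop("need at least 4 observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p_t = NA_real_, p_perm = NA_real_, n = n,
                degenerate = TRUE))
  }
  rho <- stats::cor(rx, ry)
  tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p_t <- 2 * stats::pt(-abs(tt), df = n - 2)
  p_perm <- NA_real_
  if (n_perm > 0) {
    rxc <- rx - mean(rx)
    denom <- sqrt(sum(rxc^2))
    hits <- with_seed(seed, {
      h <- 0L
      for (b in seq_len(n_perm)) {
        ryp <- ry[sample.int(n)]
        rb <- sum(rxc * (ryp - mean(ryp))) /
          (denom * sqrt(sum((ryp - mean(ryp))^2)))
        if (abs(rb) >= abs(rho) - 1e-12) h <- h + 1L
      }
      h
    })
    p_perm <- (1 + hits) / (n_perm + 1)
  }
  list(rho = rho, p_t = p_t, p_perm = p_perm, n = n, degenerate = FALSE)
}

#' Correlations of gene-order divergence with rates and habitat
#'
#' Computes a per-taxon MGO divergence (event count from the reference
#' via [event_count_to_reference()], with the breakpoint surrogate when
#' a scenario is incomplete) and tests its Spearman correlation against
#' every numeric rate column and, for each habitat category, against the
#' binary category-membership indicator.
#'
#' @param orders Named list of `gene_order`s.
#' @param reference Reference `gene_order` (default [ground_pattern()]).
#' @param rates Data frame with `taxon_id` plus numeric rate columns.
#' @param habitat Optional named character vector taxon -> category.
#' @param n_perm Permutations for `p_perm` (default 999).
#' @param seed Seed for the permutation tests.
#' @param p_adjust `"none"` (default; the tests are exploratory and
#'   two-sided) or `"BH"` for Benjamini-Hochberg adjusted columns.
#' @return Data frame `pairing`, `rho`, `p_t`, `p_perm`, `n`; the
#'   divergence vector is attached as attribute `"divergence"`.
#' @export
mgo_rate_correlation <- function(orders, reference = ground_pattern(), rates,
                                 habitat = NULL, n_perm = 999, seed = NULL,
                                 p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  taxa <- names(orders)
  taxa <- intersect(taxa, rates$taxon_id)
  if (length(taxa) < 4) stop("fewer than 4 taxa shared between orders and rates")
  div <- vapply(orders[taxa], function(go)
    as.numeric(event_count_to_reference(go, reference)), numeric(1))
  rows <- list()
  num_cols <- names(rates)[vapply(rates, is.numeric, logical(1))]
  rmat <- rates[match(taxa, rates$taxon_id), , drop = FALSE]
  sub_seed <- function(i) if (is.null(seed)) NULL else seed + i
  i <- 0L
  for (cl in num_cols) {
    i <- i + 1L
    st <- spearman_test(div, rmat[[cl]], n_perm = n_perm, seed = sub_seed(i))
    rows[[length(rows) + 1]] <- data.frame(
      pairing = paste0("divergence~", cl), rho = st$rho, p_t = st$p_t,
      p_perm = st$p_perm, n = st$n, stringsAsFactors = FALSE)
  }
  if (!is.null(habitat)) {
    hv <- habitat[taxa]
    for (cat in sort(unique(stats::na.omit(hv)))) {
      i <- i + 1L
      st <- spearman_test(div, as.numeric(hv == cat), n_perm = n_perm,
                          seed = sub_seed(i))
      rows[[length(rows) + 1]] <- data.frame(
        pairing = paste0("divergence~habitat:", cat), rho = st$rho,
        p_t = st$p_t, p_perm = st$p_perm, n = st$n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (p_adjust == "BH") {
    out$p_t_adj <- stats::p.adjust(out$p_t, method = "BH")
    out$p_perm_adj <- stats::p.adjust(out$p_perm, method = "BH")
  }
  attr(out, "divergence") <- div
  out
}
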