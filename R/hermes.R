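# Single-factor index of relative mitochondrial evolutionary speed.
#
# Five per-taxon variables -- root-to-tip distance (rtot_dist), path
# distance from the outgroup (ml_dist), percentage of unassigned
# regions (ur_percent), fraction of identical PCG arrangements (amiga)
# and strand-usage skew (su_skew) -- are standardised and summarised by
# a one-factor maximum-likelihood factor model fitted to their Pearson
# correlation matrix. Fit is reported with the likelihood-ratio
# chi-square (Bartlett correction), TLI, SRMR and RMSEA; per-taxon index
# scores use the regression (Thomson) method, oriented so the loading on
# rtot_dist is non-negative.

#' Root-to-tip and outgroup path distances
#'
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param outgroup Tip label of the outgroup; excluded from the output.
#' @return Data frame `taxon_id`, `rtot_dist` (sum of branch lengths on
#'   the root-to-leaf path), `ml_dist` (path length from the outgroup).
#' @export
tree_distances <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    bad <- if (is.null(tree$edge.length)) "all"
    else paste(which(is.na(tree$edge.length)), collapse = ",")
    stop("missing branch length on edge(s): ", bad)
  }
  if (!outgroup %in% tree$tip.label) {
    stop("outgroup '", outgroup, "' is not a tip of the tree")
  }
  ntip <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)[seq_len(ntip)]
  names(depths) <- tree$tip.label
  pd <- ape::cophenetic.phylo(tree)
  keep <- setdiff(tree$tip.label, outgroup)
  data.frame(taxon_id = keep,
             rtot_dist = unname(depths[keep]),
             ml_dist = unname(pd[outgroup, keep]),
             stringsAsFactors = FALSE)
}

#' Assemble the five index variables
#'
#' Merges tree distances, composition profile columns and AMIGA values;
#' taxa with any missing value (e.g. partial mitogenomes) are dropped
#' and reported via `message()`.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param outgroup Outgroup tip label.
#' @param profiles Data frame with `taxon_id`, `ur_percent`, `su_skew`.
#' @param amiga_values Named numeric vector from [amiga()].
#' @return Data frame `taxon_id`, `rtot_dist`, `ml_dist`, `ur_percent`,
#'   `amiga`, `su_skew`.
#' @export
hermes_variables <- function(tree, outgroup, profiles, amiga_values) {
  td <- tree_distances(tree, outgroup)
  df <- merge(td, profiles[, c("taxon_id", "ur_percent", "su_skew")],
              by = "taxon_id", sort = FALSE)
  df$amiga <- unname(amiga_values[df$taxon_id])
  df <- df[, c("taxon_id", "rtot_dist", "ml_dist", "ur_percent", "amiga",
               "su_skew")]
  drop <- !stats::complete.cases(df)
  if (any(drop)) {
    message("dropping ", sum(drop), " taxa with missing index variables: ",
            paste(df$taxon_id[drop], collapse = ", "))
    df <- df[!drop, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

# concentrated ML objective for a 1-factor model given uniquenesses psi
.fa_objective <- function(psi, R) {
  sc <- 1 / sqrt(psi)
  Rs <- sweep(sweep(R, 1, sc, `*`), 2, sc, `*`)
  th <- eigen(Rs, symmetric = TRUE, only.values = TRUE)$values
  rest <- th[-1]
  sum(rest - log(rest) - 1)
}

#' Fit the single-factor evolutionary-speed index
#'
#' Maximum-likelihood one-factor analysis of the 5x5 Pearson correlation
#' matrix: uniquenesses are optimised numerically over the concentrated
#' likelihood, loadings come from the leading eigen-structure of the
#' rescaled correlation matrix. Reported fit statistics:
#' `chi2_model = (n - 1 - (2p+5)/6 - 2k/3) F_ML` on
#' `df_model = ((p-k)^2 - (p+k))/2` degrees of freedom,
#' `chi2_null` from the Bartlett independence test on
#' `df_null = p(p-1)/2`, the Tucker-Lewis index, SRMR (root mean square
#' residual correlation over the lower triangle including the diagonal)
#' and RMSEA. A uniqueness pinned at its bound flags a Heywood case; a
#' non-significant independence test flags a degenerate fit. Scores are
#' regression (Thomson) scores, oriented so the `rtot_dist` loading is
#' non-negative.
#'
#' @param vars Data frame from [hermes_variables()] (or any data frame
#'   with a `taxon_id` column and the five numeric variables).
#' @param n Sample size (default `nrow(vars)`); must be at least 10.
#' @return Object of class `hermes_fit`: loadings, uniquenesses,
#'   communalities, `mean_communality`, `fit` (chi2_model, df_model,
#'   chi2_null, df_null, TLI, SRMR, RMSEA), per-taxon `scores`, `flags`.
#' @export
fit_hermes <- function(vars, n = nrow(vars)) {
  cols <- setdiff(names(vars), "taxon_id")
  X <- as.matrix(vars[, cols])
  storage.mode(X) <- "double"
  if (n < 10) stop("need at least 10 taxa to fit the index")
  if (anyNA(X)) stop("missing cells; drop incomplete taxa first")
  p <- ncol(X); k <- 1L
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant index variable(s): ",
         paste(cols[sds == 0], collapse = ", "))
  }
  R <- stats::cor(X)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) stop("correlation matrix is not positive definite")

  # independence (Bartlett) test first: when the correlation matrix is
  # statistically indistinguishable from identity the one-factor
  # likelihood is flat and boundary solutions are artefacts, so the
  # minimal-departure solution (unit uniquenesses) is reported instead
  chi2_null <- (n - 1 - (2 * p + 5) / 6) * (-determinant(R)$modulus[1])
  df_null <- p * (p - 1) / 2
  degenerate <- stats::pchisq(chi2_null, df_null, lower.tail = FALSE) > 0.05

  lower <- 0.005
  if (degenerate) {
    psi <- rep(1, p)
    f_min <- .fa_objective(psi, R)
    heywood <- FALSE
  } else {
    smc <- 1 - 1 / diag(solve(R))
    start <- pmax(pmin(1 - smc, 1), lower * 2)
    opt <- stats::optim(start, .fa_objective, R = R, method = "L-BFGS-B",
                        lower = lower, upper = 1)
    psi <- opt$par
    f_min <- opt$value
    heywood <- any(psi <= lower * 1.0001)
  }

  sc <- 1 / sqrt(psi)
  Rs <- sweep(sweep(R, 1, sc, `*`), 2, sc, `*`)
  ei <- eigen(Rs, symmetric = TRUE)
  lambda <- sqrt(psi) * ei$vectors[, 1] * sqrt(max(ei$values[1] - 1, 0))
  names(lambda) <- cols
  if (lambda[if ("rtot_dist" %in% cols) "rtot_dist" else cols[1]] < 0) {
    lambda <- -lambda
  }

  mult <- n - 1 - (2 * p + 5) / 6 - 2 * k / 3
  chi2_model <- mult * f_min
  df_model <- ((p - k)^2 - (p + k)) / 2
  tli <- ((chi2_null / df_null) - (chi2_model / df_model)) /
    ((chi2_null / df_null) - 1)
  rmsea <- sqrt(max(chi2_model - df_model, 0) / (df_model * (n - 1)))
  implied <- tcrossprod(lambda) + diag(psi)
  res <- (R - implied)[lower.tri(R, diag = TRUE)]
  srmr <- sqrt(mean(res^2))

  Z <- scale(X)
  scores <- as.numeric(Z %*% solve(R, lambda))
  names(scores) <- if ("taxon_id" %in% names(vars)) vars$taxon_id
  else rownames(vars)

  structure(list(
    loadings = lambda,
    uniquenesses = stats::setNames(psi, cols),
    communalities = stats::setNames(lambda^2, cols),
    mean_communality = mean(lambda^2),
    fit = list(chi2_model = chi2_model, df_model = df_model,
               chi2_null = chi2_null, df_null = df_null,
               TLI = tli, SRMR = srmr, RMSEA = rmsea),
    scores = scores,
    flags = list(heywood = heywood, degenerate = degenerate),
    n = n), class = "hermes_fit")
}

#' @export
print.hermes_fit <- function(x, ...) {
  cat("single-factor evolutionary-speed index (n =", x$n, ")\n")
  print(round(rbind(loading = x$loadings, communality = x$communalities), 3))
  cat(sprintf("mean communality %.3f | TLI %.3f SRMR %.3f RMSEA %.3f\n",
              x$mean_communality, x$fit$TLI, x$fit$SRMR, x$fit$RMSEA))
  if (x$flags$heywood) cat("flag: Heywood case (uniqueness at bound)\n")
  if (x$flags$degenerate) cat("flag: degenerate fit (variables nearly uncorrelated)\n")
  invisible(x)
}
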