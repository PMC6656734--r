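# Deterministic TSV/JSON writers (and matching readers) for every
# pipeline product. Re-reading a written gene-order table reproduces the
# object exactly.

#' Write gene orders as a TSV table
#'
#' Columns: `taxon_id`, `group`, `tokens` (space-separated signed
#' tokens, `"-trnC"` style).
#'
#' @param orders Named list of `gene_order`s.
#' @param path Output file.
#' @param groups Optional named vector taxon -> group label.
#' @return `path`, invisibly.
#' @export
write_gene_orders <- function(orders, path, groups = NULL) {
  taxa <- names(orders) %||% vapply(orders, function(g) g$taxon_id, character(1))
  df <- data.frame(
    taxon_id = taxa,
    group = if (is.null(groups)) NA_character_ else unname(groups[taxa]),
    tokens = vapply(orders, go_key, character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene orders written by [write_gene_orders()]
#' @param path TSV file.
#' @return Named list of `gene_order`s; groups in attribute `"groups"`.
#' @export
read_gene_orders <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  orders <- lapply(seq_len(nrow(df)), function(k) {
    gene_order(strsplit(df$tokens[k], " ")[[1]], taxon_id = df$taxon_id[k])
  })
  names(orders) <- df$taxon_id
  attr(orders, "groups") <- stats::setNames(df$group, df$taxon_id)
  orders
}

#' Write MGO patterns as a TSV table
#' @param patterns An `mgo_patterns` data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_patterns <- function(patterns, path) {
  utils::write.table(as.data.frame(patterns), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write composition profiles (or any data frame) as TSV
#' @param df Data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a fitted index as JSON
#'
#' Fixed, sorted key set: `communalities`, `fit`, `flags`, `loadings`,
#' `mean_communality`, `n`, `scores`, `uniquenesses`.
#'
#' @param fit A `hermes_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hermes_json <- function(fit, path) {
  obj <- list(
    communalities = as.list(fit$communalities),
    fit = fit$fit,
    flags = fit$flags,
    loadings = as.list(fit$loadings),
    mean_communality = fit$mean_communality,
    n = fit$n,
    scores = as.list(fit$scores),
    uniquenesses = as.list(fit$uniquenesses))
  jsonlite::write_json(obj[sort(names(obj))], path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a rearrangement scenario as JSON
#' @param scenario An `mgo_scenario`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scenario_json <- function(scenario, path) {
  ev <- lapply(scenario$events, function(e) {
    e2 <- unclass(e)
    e2$operand_tokens <- NULL
    e2
  })
  obj <- list(source = scenario$source$tokens,
              target = scenario$target$tokens,
              events = ev,
              complete = scenario$complete,
              breakpoint = scenario$breakpoint)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a set of pipeline products into a directory
#'
#' Dispatches on the class of each element: gene-order lists, pattern
#' tables, data frames, index fits and scenarios are written with their
#' dedicated writers; file names follow the element names.
#'
#' @param objects Named list of pipeline products.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the files written.
#' @export
write_tables <- function(objects, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  written <- character()
  for (nm in names(objects)) {
    x <- objects[[nm]]
    path <- if (inherits(x, "hermes_fit") || inherits(x, "mgo_scenario")) {
      file.path(out_dir, paste0(nm, ".json"))
    } else file.path(out_dir, paste0(nm, ".tsv"))
    if (inherits(x, "mgo_patterns")) write_patterns(x, path)
    else if (inherits(x, "hermes_fit")) write_hermes_json(x, path)
    else if (inherits(x, "mgo_scenario")) write_scenario_json(x, path)
    else if (is.list(x) && length(x) && inherits(x[[1]], "gene_order")) {
      write_gene_orders(x, path, groups = attr(x, "groups"))
    } else if (is.data.frame(x)) write_profile_table(x, path)
    else stop("no writer for object '", nm, "' of class ",
              paste(class(x), collapse = "/"))
    written <- c(written, path)
  }
  written
}
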