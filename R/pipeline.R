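# End-to-end orchestration: simulate or read a dataset, extract and
# cluster gene orders, reconstruct ancestral orders, compute composition
# profiles, fit the evolutionary-speed index, run PCA and the
# divergence-rate correlations, and write every stage's standard outputs
# plus a run manifest. Stages communicate only through documented files
# and return values, so mixed real/synthetic inputs are possible.

#' Run the full comparative-mitogenomics pipeline
#'
#' @param config Named list (or path to a YAML file, requires the
#'   `yaml` package) with entries:
#'   \describe{
#'     \item{simulate}{a [simulate_config()] list, or `NULL` to read
#'       GenBank files from `input_dir`.}
#'     \item{input_dir}{directory of `.gb` files (when not simulating).}
#'     \item{tree, outgroup}{`phylo`/newick path and outgroup tip (when
#'       not simulating; the simulator provides both).}
#'     \item{gene_classes}{classes used for MGO patterns (default all).}
#'     \item{stages}{character subset of `c("patterns", "ancestral",
#'       "composition", "hermes", "pca", "correlations")`.}
#'     \item{out_dir}{output directory.}
#'   }
#' @return Invisibly, a named list of all stage products.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  stages <- config$stages %||% c("patterns", "ancestral", "composition",
                                 "hermes", "pca", "correlations")
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  gene_classes <- config$gene_classes %||% c("PCG", "rRNA", "tRNA")
  if ("hermes" %in% stages &&
      !all(c("patterns", "composition") %in% stages)) {
    stop("the 'hermes' stage requires the 'patterns' and 'composition' stages")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  products <- list()
  if (!is.null(config$simulate)) {
    sim_cfg <- if (inherits(config$simulate, "sim_config")) config$simulate
    else do.call(simulate_config, config$simulate)
    sim <- simulate_dataset(sim_cfg, out_dir = file.path(out_dir, "data"))
    records <- sim$records
    tree <- sim$tree
    outgroup <- "outgroup"
    groups <- sim$groups
    rates <- sim$rates
    products$truth_events <- data.frame(
      taxon_id = names(sim$truth$path_events),
      planted_events = as.integer(sim$truth$path_events))
  } else {
    if (is.null(config$input_dir)) stop("config needs 'simulate' or 'input_dir'")
    files <- list.files(config$input_dir, pattern = "\\.(gb|gbk)$",
                        full.names = TRUE)
    if (!length(files)) stop("no GenBank files under ", config$input_dir)
    records <- lapply(files, read_genbank, quiet = TRUE)
    names(records) <- vapply(records, `[[`, character(1), "taxon_id")
    tree <- if (!is.null(config$tree)) {
      if (inherits(config$tree, "phylo")) config$tree
      else ape::read.tree(config$tree)
    }
    outgroup <- config$outgroup
    groups <- config$groups
    rates <- if (!is.null(config$rates)) {
      if (is.data.frame(config$rates)) config$rates
      else utils::read.delim(config$rates, stringsAsFactors = FALSE)
    }
    if (("hermes" %in% stages || "ancestral" %in% stages) && is.null(tree)) {
      stop("the requested stages require a tree")
    }
    if ("hermes" %in% stages && is.null(outgroup)) {
      stop("the 'hermes' stage requires an outgroup")
    }
  }

  orders <- lapply(records, extract_gene_order, gene_classes = gene_classes)
  orders <- suppressMessages(restrict_to_shared_genes(orders))
  products$gene_orders <- orders

  if ("patterns" %in% stages) {
    pats <- cluster_patterns(orders, prefix_map = groups)
    products$patterns <- pats
    pcg_orders <- suppressMessages(restrict_to_shared_genes(
      lapply(records, extract_gene_order, gene_classes = "PCG")))
    pcg_pats <- cluster_patterns(pcg_orders, prefix_map = groups)
    products$patterns_pcg <- pcg_pats
    products$amiga <- amiga(pcg_pats)
  }

  if ("ancestral" %in% stages && !is.null(tree)) {
    ingroup <- ape::drop.tip(tree, setdiff(tree$tip.label, names(orders)))
    rt <- reconstruct_ancestral(ingroup, orders[ingroup$tip.label])
    products$reconstruction <- rt
    products$edge_events <- edge_event_summary(rt, group_labels = groups)
  }

  if ("composition" %in% stages) {
    products$profiles <- composition_profiles(records)
  }

  if ("hermes" %in% stages) {
    vars <- hermes_variables(tree, outgroup, products$profiles,
                             products$amiga)
    products$hermes_vars <- vars
    products$hermes <- tryCatch(fit_hermes(vars), error = function(e) {
      message("index stage not fitted: ", conditionMessage(e))
      NULL
    })
    if (!is.null(products$hermes)) {
      products$hermes_scores <- data.frame(
        taxon_id = names(products$hermes$scores),
        score = unname(products$hermes$scores), stringsAsFactors = FALSE)
    }
  }

  if ("pca" %in% stages && "composition" %in% stages) {
    comp_cols <- c("taxon_id", "at_percent", "at_skew", "gc_skew", "su_skew",
                   "ur_percent")
    products$pca_composition <- pca_correlation(products$profiles[, comp_cols])
  }

  if ("correlations" %in% stages && !is.null(rates)) {
    products$correlations <- mgo_rate_correlation(
      orders, rates = rates,
      habitat = config$habitat,
      n_perm = config$n_perm %||% 999,
      seed = config$seed %||% 1)
  }

  writable <- Filter(function(x) {
    is.data.frame(x) || inherits(x, "hermes_fit") ||
      (is.list(x) && length(x) && inherits(x[[1]], "gene_order"))
  }, products)
  files <- write_tables(writable, out_dir)

  manifest <- list(
    package_version = as.character(utils::packageVersion("mitorder")),
    seed = config$seed %||% config$simulate$seed,
    stages = stages,
    files = sort(basename(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(products)
}
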