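# Seeded simulator of mitogenome evolution: a Yule tree with a grafted
# outgroup, per-branch planted rearrangement events applied to a root
# gene order, and synthetic annotated sequences with controllable
# composition -- plus the truth ledger needed for recovery tests.
#
# A single global seed feeds independent per-stage seeds (tree = seed,
# events = seed + 1, sequences = seed + 2, rates = seed + 3) so stages
# can be regenerated in isolation.

.default_gene_lengths <- function() {
  list(
    PCG = c(atp6 = 675, atp8 = 159, cob = 1137, cox1 = 1536, cox2 = 690,
            cox3 = 789, nad1 = 936, nad2 = 1002, nad3 = 354, nad4 = 1341,
            nad4l = 297, nad5 = 1713, nad6 = 522),
    rRNA = c(rrnS = 850, rrnL = 1350),
    tRNA_range = c(62L, 72L))
}

#' Simulation configuration
#'
#' Defaults emulate a decapod-like study: a Yule tree, a modest planted
#' event rate, the pancrustacean root arrangement, AT-rich sequences
#' (AT 70%, AT skew 0.05, GC skew -0.2), about 5% unassigned region and
#' genomes in the 15-18 kb range.
#'
#' @param n_taxa Number of ingroup taxa (>= 3).
#' @param seed Global seed.
#' @param birth Yule birth rate.
#' @param lambda Rearrangement events per unit branch length.
#' @param event_weights Named weights over types T, r, rT, tdrl, d, x.
#' @param root_order Root `gene_order` (default [ground_pattern()]).
#' @param at_percent,at_skew,gc_skew Sequence composition targets.
#' @param ur_percent Target percentage of unassigned region.
#' @param ur_jitter Relative per-taxon jitter on the UR target (URs vary
#'   widely across real taxa, e.g. multiple control regions or long
#'   intergenic spacers).
#' @param composition_noise Per-taxon Gaussian jitter SDs for
#'   `at_percent` (percentage points), `at_skew` and `gc_skew`.
#' @param codon_bias Multiplier (>= 0) favouring one codon per family so
#'   RSCU departs detectably from 1.
#' @param gene_len_jitter Relative jitter on per-gene default lengths.
#' @param branch_mode `"poisson"` (counts ~ Poisson(lambda * length)) or
#'   `"at_most_one"` (at most one event per branch, probability
#'   `1 - exp(-lambda * length)`).
#' @param disjoint_operands If `TRUE`, planted events avoid genes used
#'   by events on other branches (clean recovery regime).
#' @param clade_lambda Optional list of `list(tips=, lambda=)` overrides:
#'   edges entirely within the clade spanned by `tips` use that rate.
#' @param rate_noise_sd Noise SD for [make_rate_table()].
#' @return A list of class `sim_config`.
#' @export
simulate_config <- function(n_taxa = 20, seed = 1, birth = 1, lambda = 0.1,
                            event_weights = c(T = 0.35, r = 0.25, rT = 0.1,
                                              tdrl = 0.2, d = 0.05, x = 0.05),
                            root_order = NULL,
                            at_percent = 70, at_skew = 0.05, gc_skew = -0.2,
                            ur_percent = 5, ur_jitter = 0.3,
                            composition_noise = c(at_percent = 1.5,
                                                  at_skew = 0.02,
                                                  gc_skew = 0.02),
                            codon_bias = 1,
                            gene_len_jitter = 0.05,
                            branch_mode = c("poisson", "at_most_one"),
                            disjoint_operands = FALSE,
                            clade_lambda = NULL, rate_noise_sd = 0.2) {
  stopifnot(n_taxa >= 3, lambda >= 0, all(event_weights >= 0),
            sum(event_weights) > 0, at_percent >= 0, at_percent <= 100,
            abs(at_skew) <= 1, abs(gc_skew) <= 1,
            ur_percent >= 0, ur_percent < 100)
  structure(list(
    n_taxa = n_taxa, seed = as.integer(seed), birth = birth, lambda = lambda,
    event_weights = event_weights,
    root_order = root_order %||% ground_pattern(),
    at_percent = at_percent, at_skew = at_skew, gc_skew = gc_skew,
    ur_percent = ur_percent, ur_jitter = ur_jitter,
    composition_noise = composition_noise, codon_bias = codon_bias,
    gene_len_jitter = gene_len_jitter,
    branch_mode = match.arg(branch_mode),
    disjoint_operands = disjoint_operands,
    clade_lambda = clade_lambda, rate_noise_sd = rate_noise_sd),
    class = "sim_config")
}

#' Simulate a Yule tree with a grafted outgroup
#'
#' @param config A `sim_config`.
#' @return A rooted `phylo`; ingroup tips `t001...`, plus tip
#'   `"outgroup"` attached at the root.
#' @export
simulate_tree <- function(config) {
  with_seed(config$seed, {
    tr <- ape::rphylo(config$n_taxa, birth = config$birth, death = 0)
    tr$tip.label <- sprintf("t%03d", seq_len(config$n_taxa))
    h <- max(ape::node.depth.edgelength(tr))
    txt <- sub(";$", "", ape::write.tree(tr))
    newick <- sprintf("(%s:%.6f,outgroup:%.6f);", txt, 0.25 * h, 1.25 * h)
    ape::read.tree(text = newick)
  })
}

#' Two-letter group prefixes from the basal ingroup split
#'
#' Taxa in the two basal clades of the ingroup get prefixes `"Aa"` and
#' `"Ab"`; the outgroup gets `"Og"`.
#'
#' @param tree Tree from [simulate_tree()].
#' @param outgroup Outgroup tip label.
#' @return Named character vector taxon -> prefix.
#' @export
clade_groups <- function(tree, outgroup = "outgroup") {
  tips <- tree$tip.label
  out <- stats::setNames(rep("Aa", length(tips)), tips)
  out[outgroup] <- "Og"
  ing <- setdiff(tips, outgroup)
  if (length(ing) >= 2) {
    root <- length(tips) + 1L
    ing_root_kids <- tree$edge[tree$edge[, 1] == root, 2]
    ing_node <- ing_root_kids[ing_root_kids > length(tips)]
    if (length(ing_node) == 1) {
      kids <- tree$edge[tree$edge[, 1] == ing_node, 2]
      first <- kids[1]
      clade1 <- if (first <= length(tips)) tips[first]
      else ape::extract.clade(tree, first)$tip.label
      out[setdiff(ing, clade1)] <- "Ab"
    }
  }
  out
}

.edge_lambda <- function(tree, config) {
  lam <- rep(config$lambda, nrow(tree$edge))
  if (!is.null(config$clade_lambda)) {
    ntip <- length(tree$tip.label)
    below <- function(nd) {
      if (nd <= ntip) return(tree$tip.label[nd])
      unlist(lapply(tree$edge[tree$edge[, 1] == nd, 2], below))
    }
    for (cl in config$clade_lambda) {
      mrca <- if (length(cl$tips) == 1) match(cl$tips, tree$tip.label)
      else ape::getMRCA(tree, cl$tips)
      inside <- vapply(seq_len(nrow(tree$edge)), function(e) {
        all(below(tree$edge[e, 2]) %in% cl$tips)
      }, logical(1))
      lam[inside] <- cl$lambda
    }
  }
  lam
}

.random_event <- function(cur, config, used_genes) {
  n <- length(cur$tokens)
  w <- config$event_weights
  nm <- go_names(cur$tokens)
  for (attempt in seq_len(30)) {
    type <- sample(names(w), 1, prob = w)
    if (type == "x") {
      dup_pos <- which(duplicated(nm) | duplicated(nm, fromLast = TRUE))
      if (length(dup_pos) == 0) next
      pos <- dup_pos[duplicated(nm)][1]
      ev <- event_x(pos, pos)
      ev$operand_tokens <- nm[pos]
      return(ev)
    }
    if (type == "tdrl") {
      if (n < 4) next
      wlen <- sample(3:min(8, n - 1), 1)
      i <- sample(n, 1)
      j <- ((i + wlen - 2L) %% n) + 1L
      seg <- .seg_idx(i, j, n)
      if (config$disjoint_operands && any(nm[seg] %in% used_genes)) next
      kf <- sample(c(TRUE, FALSE), wlen, replace = TRUE)
      if (all(kf) || !any(kf)) kf[sample(wlen, 1)] <- !kf[1]
      if (all(kf) || !any(kf)) next
      ev <- event_tdrl(i, j, kf)
      ev$operand_tokens <- nm[seg]
      return(ev)
    }
    slen <- 1L + min(stats::rgeom(1, 0.5), min(4L, n - 2L))
    i <- sample(n, 1)
    j <- ((i + slen - 2L) %% n) + 1L
    seg <- .seg_idx(i, j, n)
    if (config$disjoint_operands && any(nm[seg] %in% used_genes)) next
    if (type == "r") {
      ev <- event_r(i, j)
    } else if (type == "d") {
      if (slen > 3) next
      ev <- event_d(i, j)
    } else {
      rest <- setdiff(seq_len(n), seg)
      prev <- ((i - 2L) %% n) + 1L
      cand <- setdiff(rest, if (type == "T") prev else integer())
      if (length(cand) == 0) next
      after <- cand[sample(length(cand), 1)]
      ev <- if (type == "T") event_T(i, j, after) else event_rT(i, j, after)
    }
    ev$operand_tokens <- nm[seg]
    return(ev)
  }
  NULL
}

#' Evolve gene orders along a tree by planted events
#'
#' Per branch, the event count is Poisson(`lambda` x branch length) (or
#' at most one, see [simulate_config()]); types are multinomial over the
#' configured weights; operands are uniform over valid segments with
#' geometric segment lengths. Duplication adds a tandem copy; deletion
#' only ever removes one copy of a currently-duplicated gene.
#'
#' @param tree Tree from [simulate_tree()].
#' @param config A `sim_config`.
#' @return List with `leaf_orders` (named list of `gene_order`) and
#'   `truth` (tree, per-edge planted events, all true node orders,
#'   per-edge and per-leaf event counts).
#' @export
evolve_orders <- function(tree, config) {
  with_seed(config$seed + 1L, {
    tree <- stats::reorder(tree, "cladewise")  # parents before children
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    node_orders <- vector("list", ntip + tree$Nnode)
    node_orders[[root]] <- canonicalize_gene_order(config$root_order)
    lam <- .edge_lambda(tree, config)
    events <- vector("list", nrow(tree$edge))
    used_genes <- character()
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      len <- tree$edge.length[e]
      k <- if (config$branch_mode == "poisson") {
        stats::rpois(1, lam[e] * len)
      } else stats::rbinom(1, 1, 1 - exp(-lam[e] * len))
      cur <- node_orders[[p]]
      evs <- list()
      while (length(evs) < k) {
        ev <- .random_event(cur, config, used_genes)
        if (is.null(ev)) break
        cur <- apply_event(cur, ev)
        evs[[length(evs) + 1L]] <- ev
        if (config$disjoint_operands) {
          used_genes <- union(used_genes, ev$operand_tokens)
        }
      }
      cur$taxon_id <- if (ch <= ntip) tree$tip.label[ch] else paste0("node", ch)
      node_orders[[ch]] <- cur
      events[[e]] <- evs
    }
    n_events <- vapply(events, length, integer(1))
    # planted events on the root-to-leaf path of every tip
    path_events <- stats::setNames(integer(ntip), tree$tip.label)
    for (tip in seq_len(ntip)) {
      nd <- tip; tot <- 0L
      while (nd != root) {
        e <- which(tree$edge[, 2] == nd)
        tot <- tot + n_events[e]
        nd <- tree$edge[e, 1]
      }
      path_events[tip] <- tot
    }
    leaf_orders <- stats::setNames(node_orders[seq_len(ntip)], tree$tip.label)
    list(leaf_orders = leaf_orders,
         truth = list(tree = tree, events = events,
                      node_orders = node_orders,
                      n_events_per_edge = n_events,
                      path_events = path_events))
  })
}

.base_probs <- function(config) {
  at <- config$at_percent / 100; gc <- 1 - at
  c(A = at / 2 * (1 + config$at_skew), T = at / 2 * (1 - config$at_skew),
    G = gc / 2 * (1 + config$gc_skew), C = gc / 2 * (1 - config$gc_skew))
}

.codon_probs <- function(config, base_probs = .base_probs(config)) {
  code <- .invert_mito_code()
  sense <- names(code)[code != "*"]
  pr <- vapply(sense, function(cd) {
    prod(base_probs[strsplit(cd, "")[[1]]])
  }, numeric(1))
  # bias one codon per synonymous family so RSCU departs from 1; each
  # family's total mass is preserved so the base composition barely moves
  if (config$codon_bias > 0) {
    for (a in unique(code[sense])) {
      fam <- sense[code[sense] == a]
      if (length(fam) < 2) next
      mass <- sum(pr[fam])
      top <- fam[which.max(pr[fam])]
      pr[top] <- pr[top] * (1 + config$codon_bias)
      pr[fam] <- pr[fam] * mass / sum(pr[fam])
    }
  }
  pr / sum(pr)
}

.rand_bases <- function(k, bp) {
  paste(sample(names(bp), k, replace = TRUE, prob = bp), collapse = "")
}

#' Synthesize annotated mitogenome records for a set of gene orders
#'
#' Gene lengths are drawn around field-typical defaults (total genome
#' about 15-18 kb); sequences are sampled to hit the configured AT%,
#' AT-skew and GC-skew in expectation; protein-coding genes are written
#' as valid CDS (ATG start, biased sense codons, TAA stop) on the strand
#' given by the gene order; one unassigned block realises the UR% target.
#' The deposited sequence starts at a random rotation of the circular
#' order, so canonicalisation is exercised on re-reading.
#'
#' @param leaf_orders Named list of `gene_order`s.
#' @param config A `sim_config`.
#' @param out_dir Optional directory: one GenBank flat file per taxon.
#' @return Named list of `mitogenome_record`s.
#' @export
synthesize_records <- function(leaf_orders, config, out_dir = NULL) {
  if (config$ur_percent >= 100) stop("infeasible ur_percent")
  gl <- .default_gene_lengths()
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  with_seed(config$seed + 2L, {
    records <- lapply(names(leaf_orders), function(tax) {
      # per-taxon composition targets: configured clade values plus
      # realistic between-taxon noise
      cn <- config$composition_noise %||% c(at_percent = 0, at_skew = 0,
                                            gc_skew = 0)
      cfg_t <- config
      cfg_t$at_percent <- min(max(config$at_percent +
                                    stats::rnorm(1, 0, cn[["at_percent"]]),
                                  5), 95)
      cfg_t$at_skew <- min(max(config$at_skew +
                                 stats::rnorm(1, 0, cn[["at_skew"]]), -0.9), 0.9)
      cfg_t$gc_skew <- min(max(config$gc_skew +
                                 stats::rnorm(1, 0, cn[["gc_skew"]]), -0.9), 0.9)
      ur_t <- config$ur_percent *
        stats::runif(1, 1 - (config$ur_jitter %||% 0),
                     1 + (config$ur_jitter %||% 0))
      # composition targets apply to the deposited (forward) strand:
      # minus-strand CDS are sampled from the complement-swapped measure
      # so their reverse-complemented genome text matches the target
      bp <- .base_probs(cfg_t)
      bp_rc <- c(A = unname(bp["T"]), T = unname(bp["A"]),
                 G = unname(bp["C"]), C = unname(bp["G"]))
      cp <- .codon_probs(cfg_t)
      cp_rc <- .codon_probs(cfg_t, base_probs = bp_rc)
      sense <- names(cp)
      go <- leaf_orders[[tax]]
      toks <- go$tokens
      n <- length(toks)
      start <- sample(n, 1)
      toks <- toks[c(start:n, seq_len(start - 1))]  # random deposited start
      nm <- go_names(toks); sg <- go_signs(toks)
      kind <- gene_kind(nm)
      jit <- function(x) x * stats::runif(length(x), 1 - config$gene_len_jitter,
                                         1 + config$gene_len_jitter)
      lens <- integer(n)
      for (k in seq_len(n)) {
        lens[k] <- if (kind[k] == "PCG") {
          max(60L, 3L * round(jit(gl$PCG[[nm[k]]]) / 3))
        } else if (kind[k] == "rRNA") {
          as.integer(round(jit(gl$rRNA[[nm[k]]])))
        } else sample(gl$tRNA_range[1]:gl$tRNA_range[2], 1)
      }
      ur_len <- as.integer(round(ur_t / (100 - ur_t) * sum(lens)))
      pieces <- character(n)
      for (k in seq_len(n)) {
        if (kind[k] == "PCG") {
          ncod <- lens[k] / 3
          s <- paste0("ATG",
                      paste(sample(sense, ncod - 2, replace = TRUE,
                                   prob = if (sg[k] < 0) cp_rc else cp),
                            collapse = ""),
                      "TAA")
          if (sg[k] < 0) {
            s <- as.character(Biostrings::reverseComplement(
              Biostrings::DNAString(s)))
          }
        } else {
          # non-coding gene text is sampled on the genome strand directly
          s <- .rand_bases(lens[k], bp)
        }
        pieces[k] <- s
      }
      starts <- cumsum(c(0L, lens[-n]))
      features <- data.frame(
        token = nm, kind = kind, strand = sg, start = starts,
        end = starts + lens, spans_origin = FALSE, raw_name = nm,
        stringsAsFactors = FALSE)
      seqn <- paste0(paste(pieces, collapse = ""),
                     if (ur_len > 0) .rand_bases(ur_len, bp) else "")
      rec <- mitogenome_record(tax, seqn, features)
      if (!is.null(out_dir)) {
        write_genbank(rec, file.path(out_dir, paste0(tax, ".gb")))
      }
      rec
    })
    stats::setNames(records, names(leaf_orders))
  })
}

#' Simulate index variables for two evolutionary regimes
#'
#' Generates the five evolutionary-speed variables for a
#' "ground-pattern-like" group (low tree distances, high AMIGA, little
#' unassigned sequence) and a "rearranged" group (the converse), as a
#' one-factor model: a latent speed factor shifted between groups drives
#' all five variables, AMIGA loading negatively (sharing an arrangement
#' is the signature of slow structural evolution). Used to validate the
#' index: fitting should separate the groups into two score modes.
#'
#' Note: the root-to-tip and outgroup distances are given independent
#' noise, emulating that in real use the outgroup ML distance is
#' estimated from sequence data rather than read off the same tree.
#'
#' @param n_per_group Taxa per regime.
#' @param seed Seed.
#' @param separation Latent-factor mean shift between regimes, in factor
#'   SD units.
#' @param loadings Loadings of (rtot_dist, ml_dist, ur_percent, amiga,
#'   su_skew) on the latent factor (amiga's sign is flipped internally).
#' @return Data frame as from [hermes_variables()] plus a `regime`
#'   column.
#' @export
simulate_hermes_regimes <- function(n_per_group = 60, seed = 1,
                                    separation = 2.5,
                                    loadings = c(0.8, 0.75, 0.5, 0.85, 0.4)) {
  with_seed(seed, {
    n <- 2 * n_per_group
    regime <- rep(c("ground", "rearranged"), each = n_per_group)
    f <- stats::rnorm(n, mean = ifelse(regime == "ground", -separation / 2,
                                       separation / 2))
    lam <- loadings * c(1, 1, 1, -1, 1)   # high amiga marks slow lineages
    z <- sapply(seq_along(lam), function(j) {
      lam[j] * f + sqrt(max(1 - lam[j]^2, 0.05)) * stats::rnorm(n)
    })
    df <- data.frame(
      taxon_id = sprintf("s%03d", seq_len(n)),
      rtot_dist = pmax(0.55 + 0.12 * z[, 1], 0.01),
      ml_dist = pmax(1.1 + 0.15 * z[, 2], 0.01),
      ur_percent = pmin(pmax(6 + 2.5 * z[, 3], 0.1), 40),
      amiga = pmin(pmax(0.5 + 0.2 * z[, 4], 0.02), 1),
      su_skew = pmin(pmax(0.1 + 0.15 * z[, 5], -1), 1),
      stringsAsFactors = FALSE)
    df$regime <- regime
    df
  })
}

#' Per-taxon substitution-rate table
#'
#' Stands in for externally-estimated lineage rates. In `"null"` mode
#' rates are lognormal and independent of the planted events; in
#' `"linked"` mode `rate = a + b * (planted events on the root-to-leaf
#' path) + noise`. The linkage coefficient is recorded as attribute
#' `"linkage"`.
#'
#' @param tree Tree from [simulate_tree()].
#' @param truth Truth ledger from [evolve_orders()].
#' @param config A `sim_config`.
#' @param mode `"null"` or `"linked"`.
#' @param a,b Intercept and slope for `"linked"` mode.
#' @return Data frame `taxon_id`, `rate`, `true_events`.
#' @export
make_rate_table <- function(tree, truth, config, mode = c("null", "linked"),
                            a = 1, b = 0.2) {
  mode <- match.arg(mode)
  ev <- truth$path_events
  with_seed(config$seed + 3L, {
    rate <- if (mode == "null") {
      stats::rlnorm(length(ev), meanlog = 0, sdlog = config$rate_noise_sd)
    } else {
      a + b * ev + stats::rnorm(length(ev), 0, config$rate_noise_sd)
    }
    out <- data.frame(taxon_id = names(ev), rate = as.numeric(rate),
                      true_events = as.integer(ev), stringsAsFactors = FALSE)
    attr(out, "linkage") <- if (mode == "null") 0 else b
    out
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: tree, planted gene orders, annotated records
#' (optionally written as GenBank files), rate table and truth ledger.
#'
#' @param config A `sim_config`.
#' @param out_dir Optional output directory (`genbank/`, `tree.nwk`,
#'   `rates.tsv` are written there).
#' @param rate_mode Passed to [make_rate_table()].
#' @return List `tree`, `groups`, `leaf_orders`, `records`, `rates`,
#'   `truth`, `config`.
#' @export
simulate_dataset <- function(config, out_dir = NULL,
                             rate_mode = c("null", "linked")) {
  rate_mode <- match.arg(rate_mode)
  tree <- simulate_tree(config)
  groups <- clade_groups(tree)
  evo <- evolve_orders(tree, config)
  gb_dir <- if (!is.null(out_dir)) file.path(out_dir, "genbank")
  records <- synthesize_records(evo$leaf_orders, config, out_dir = gb_dir)
  rates <- make_rate_table(tree, evo$truth, config, mode = rate_mode)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
    utils::write.table(rates, file.path(out_dir, "rates.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(tree = tree, groups = groups, leaf_orders = evo$leaf_orders,
       records = records, rates = rates, truth = evo$truth, config = config)
}
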