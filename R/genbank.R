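# GenBank flat-file reader and writer for annotated mitogenomes.
#
# Internal coordinates are 0-based, half-open, on the forward strand;
# conversion to/from GenBank's 1-based inclusive convention happens only
# here. Features written with origin-spanning join() notation get
# spans_origin = TRUE. Public mitogenome entries are notoriously
# inconsistent (wrong strands, missing genes, duplicated labels), so the
# reader surfaces a diagnostics list instead of silently repairing.

#' Construct a mitogenome record
#'
#' @param taxon_id Unique taxon identifier.
#' @param sequence Circular nucleotide string (may contain an `N` run for
#'   an assembly gap).
#' @param features Data frame with columns `token`, `kind`, `strand`,
#'   `start`, `end`, `spans_origin`, `raw_name`.
#' @param group_labels Optional named list/vector of grouping labels
#'   (infraorder, family, habitat, ...).
#' @param diagnostics Character vector of reader diagnostics.
#' @return Object of class `mitogenome_record`.
#' @export
mitogenome_record <- function(taxon_id, sequence, features,
                              group_labels = NULL, diagnostics = character()) {
  len <- nchar(sequence)
  stopifnot(is.data.frame(features))
  bad <- features$start < 0 | features$start >= len |
    (!features$spans_origin & features$end > len)
  if (any(bad)) stop("feature coordinates outside [0, length) for taxon ",
                     taxon_id)
  structure(list(taxon_id = taxon_id, sequence = toupper(sequence),
                 length = len, features = features,
                 group_labels = group_labels, diagnostics = diagnostics),
            class = "mitogenome_record")
}

#' @export
print.mitogenome_record <- function(x, ...) {
  cat(sprintf("mitogenome record '%s': %d bp, %d features, %d diagnostics\n",
              x$taxon_id, x$length, nrow(x$features), length(x$diagnostics)))
  invisible(x)
}

feature_length <- function(f, genome_len) {
  ifelse(f$spans_origin, (genome_len - f$start) + f$end, f$end - f$start)
}

.parse_location <- function(loc, genome_len) {
  strand <- 1L
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- -1L
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  spans <- FALSE
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",")[[1]]
    rng <- lapply(parts, function(p) as.integer(strsplit(trimws(p), "\\.\\.")[[1]]))
    if (length(rng) == 2 && rng[[1]][2] == genome_len && rng[[2]][1] == 1) {
      spans <- TRUE
      start1 <- rng[[1]][1]; end1 <- rng[[2]][2]
    } else {
      # non-origin join: take the envelope
      start1 <- min(vapply(rng, `[`, integer(1), 1))
      end1 <- max(vapply(rng, `[`, integer(1), 2))
    }
  } else {
    ab <- as.integer(strsplit(loc, "\\.\\.")[[1]])
    if (length(ab) == 1) ab <- c(ab, ab)
    start1 <- ab[1]; end1 <- ab[2]
  }
  if (anyNA(c(start1, end1))) stop("unparseable location: ", loc)
  list(start = start1 - 1L, end = end1, strand = strand, spans_origin = spans)
}

#' Read an annotated mitogenome from a GenBank flat file
#'
#' Parses `CDS`, `tRNA`, `rRNA` and `D-loop` features, normalises gene
#' names via [normalize_gene_name()] (preferring the `/gene` qualifier,
#' then `/product`), converts coordinates to the internal 0-based
#' half-open convention, and records origin-spanning `join()` locations.
#' Diagnostics (reported via `warning()` and stored on the record) cover
#' missing canonical genes, unknown or ambiguous names and duplicated
#' tokens -- the inconsistencies that public entries typically require
#' manual inspection for.
#'
#' @param path Path to a GenBank flat file.
#' @param taxon_id Optional taxon id; default the LOCUS name.
#' @param expected_genes Canonical tokens whose absence should be
#'   flagged (e.g. `gene_tokens("all")` for complete mitogenomes);
#'   `NULL` (default) disables the missing-gene check.
#' @param quiet Suppress diagnostic warnings.
#' @return A `mitogenome_record`.
#' @export
read_genbank <- function(path, taxon_id = NULL, expected_genes = NULL,
                         quiet = FALSE) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0) stop("not a GenBank flat file (no LOCUS line): ", path)
  locus_fields <- strsplit(trimws(locus[1]), "\\s+")[[1]]
  locus_name <- locus_fields[2]
  genome_len <- suppressWarnings(as.integer(locus_fields[3]))
  if (is.na(genome_len)) stop("LOCUS line declares no length: ", path)
  if (is.null(taxon_id)) taxon_id <- locus_name

  # sequence
  o <- grep("^ORIGIN", lines)
  seq <- ""
  if (length(o)) {
    end <- grep("^//", lines)
    end <- if (length(end)) end[end > o[1]][1] else length(lines) + 1L
    body <- lines[(o[1] + 1L):(end - 1L)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
  }
  if (nchar(seq) == 0) stop("GenBank file has no sequence: ", path)
  if (nchar(seq) != genome_len) {
    stop("sequence length ", nchar(seq), " disagrees with LOCUS length ",
         genome_len, ": ", path)
  }

  fstart <- grep("^FEATURES", lines)
  if (length(fstart) == 0) stop("no FEATURES table: ", path)
  fend <- if (length(o)) o[1] - 1L else length(lines)
  flines <- lines[(fstart[1] + 1L):fend]

  keys_wanted <- c("CDS", "tRNA", "rRNA", "D-loop", "misc_feature")
  feats <- list()
  i <- 1L
  while (i <= length(flines)) {
    ln <- flines[i]
    m <- regmatches(ln, regexec("^ {2,8}(\\S+)\\s+(\\S.*)$", ln))[[1]]
    if (length(m) == 3 && !grepl("^/", trimws(ln))) {
      key <- m[2]; loc <- gsub("\\s", "", m[3])
      quals <- character()
      j <- i + 1L
      while (j <= length(flines) &&
             (grepl("^\\s{9,}", flines[j]) || !nzchar(trimws(flines[j])))) {
        piece <- trimws(flines[j])
        if (startsWith(piece, "/")) quals <- c(quals, piece)
        else if (length(quals)) quals[length(quals)] <-
            paste0(quals[length(quals)], piece)
        else loc <- paste0(loc, piece)
        j <- j + 1L
      }
      if (key %in% keys_wanted && key != "misc_feature") {
        getq <- function(nmq) {
          hit <- grep(paste0("^/", nmq, "="), quals, value = TRUE)
          if (!length(hit)) return(NA_character_)
          gsub("\"", "", sub(paste0("^/", nmq, "="), "", hit[1]))
        }
        raw <- getq("gene")
        if (is.na(raw)) raw <- getq("product")
        if (is.na(raw)) raw <- getq("note")
        if (is.na(raw) && key == "D-loop") raw <- "control region"
        pl <- .parse_location(loc, genome_len)
        tok <- normalize_gene_name(raw %||% "")
        kind <- if (tok %in% gene_tokens("all")) gene_kind(tok)
        else switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA", "other")
        feats[[length(feats) + 1L]] <- data.frame(
          token = tok, kind = kind, strand = pl$strand, start = pl$start,
          end = pl$end, spans_origin = pl$spans_origin,
          raw_name = raw %||% NA_character_, stringsAsFactors = FALSE)
      }
      i <- j
    } else {
      i <- i + 1L
    }
  }
  if (length(feats) == 0) {
    stop("GenBank file contains no recognisable gene features: ", path)
  }
  features <- do.call(rbind, feats)

  diags <- character()
  unknown <- features$raw_name[features$token == "unknown"]
  if (length(unknown)) {
    diags <- c(diags, paste0("unknown/ambiguous gene name: ", unknown))
  }
  genes <- features$token[features$token %in% gene_tokens("all")]
  missing <- setdiff(expected_genes %||% character(), genes)
  if (length(missing)) {
    diags <- c(diags, paste0("missing canonical gene: ", missing))
  }
  dups <- unique(genes[duplicated(genes)])
  if (length(dups)) {
    diags <- c(diags, paste0("duplicated gene token: ", dups))
  }
  if (!quiet && length(diags)) {
    warning("taxon '", taxon_id, "': ", paste(diags, collapse = "; "),
            call. = FALSE)
  }
  mitogenome_record(taxon_id, seq, features, diagnostics = diags)
}

#' Export mitogenome sequences as FASTA
#'
#' @param records A `mitogenome_record` or list of them.
#' @param path Output FASTA file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "mitogenome_record")) records <- list(records)
  seqs <- Biostrings::DNAStringSet(vapply(records, `[[`, character(1),
                                          "sequence"))
  names(seqs) <- vapply(records, `[[`, character(1), "taxon_id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write a mitogenome record as a GenBank flat file
#'
#' Inverse of [read_genbank()] for records produced by this package
#' (notably the simulator); origin-spanning features are written with
#' `join()` notation.
#'
#' @param record A `mitogenome_record`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  len <- record$length
  w <- function(...) writeLines(sprintf(...), con)
  w("LOCUS       %s %d bp    DNA     circular INV 01-JAN-2000",
    record$taxon_id, len)
  w("DEFINITION  %s mitochondrion, complete genome (synthetic).",
    record$taxon_id)
  w("FEATURES             Location/Qualifiers")
  w("     source          1..%d", len)
  f <- record$features
  for (k in seq_len(nrow(f))) {
    start1 <- f$start[k] + 1L
    loc <- if (f$spans_origin[k]) {
      sprintf("join(%d..%d,1..%d)", start1, len, f$end[k])
    } else sprintf("%d..%d", start1, f$end[k])
    if (f$strand[k] < 0) loc <- sprintf("complement(%s)", loc)
    key <- switch(f$kind[k], PCG = "CDS", rRNA = "rRNA", tRNA = "tRNA",
                  "misc_feature")
    name <- if (!is.na(f$raw_name[k])) f$raw_name[k] else f$token[k]
    w("     %-15s %s", key, loc)
    w("                     /gene=\"%s\"", name)
    if (key == "CDS") w("                     /transl_table=5")
  }
  w("ORIGIN")
  s <- tolower(record$sequence)
  pos <- seq(1, len, by = 60)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59, len))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    w("%9d %s", p, paste(groups, collapse = " "))
  }
  w("//")
  invisible(path)
}
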