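# Gene nomenclature: the 40-token canonical vocabulary and the synonym
# lookup used everywhere downstream. Tokens follow the MITOS convention:
# 13 PCGs (cox1-3, cob, nad1-6, nad4l, atp6, atp8), 2 rRNAs (rrnS, rrnL),
# 22 tRNAs (trnX, with trnL1/trnL2 and trnS1/trnS2 split by codon family).

.pkg_env <- new.env(parent = emptyenv())

#' Canonical mitochondrial gene tokens
#'
#' @param kind One of `"all"`, `"PCG"`, `"rRNA"`, `"tRNA"`.
#' @return Character vector of canonical tokens.
#' @export
gene_tokens <- function(kind = c("all", "PCG", "rRNA", "tRNA")) {
  kind <- match.arg(kind)
  pcg <- c("atp6", "atp8", "cob", "cox1", "cox2", "cox3",
           "nad1", "nad2", "nad3", "nad4", "nad4l", "nad5", "nad6")
  rrna <- c("rrnS", "rrnL")
  trna <- c("trnA", "trnC", "trnD", "trnE", "trnF", "trnG", "trnH", "trnI",
            "trnK", "trnL1", "trnL2", "trnM", "trnN", "trnP", "trnQ", "trnR",
            "trnS1", "trnS2", "trnT", "trnV", "trnW", "trnY")
  switch(kind,
         all = c(pcg, rrna, trna),
         PCG = pcg, rRNA = rrna, tRNA = trna)
}

#' Gene class of a canonical token
#'
#' @param token Character vector of canonical tokens.
#' @return `"PCG"`, `"rRNA"`, `"tRNA"` or `"other"` per element.
#' @export
gene_kind <- function(token) {
  out <- rep("other", length(token))
  out[token %in% gene_tokens("PCG")] <- "PCG"
  out[token %in% gene_tokens("rRNA")] <- "rRNA"
  out[token %in% gene_tokens("tRNA")] <- "tRNA"
  out
}

.synonym_table <- function() {
  if (is.null(.pkg_env$synonyms)) {
    path <- system.file("extdata", "gene_synonyms.tsv", package = "mitorder",
                        mustWork = TRUE)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    .pkg_env$synonyms <- stats::setNames(tab$token, tab$raw)
  }
  .pkg_env$synonyms
}

# amino-acid letter for tRNA names given as 3-letter or full names
.aa3 <- c(ala = "A", arg = "R", asn = "N", asp = "D", cys = "C", gln = "Q",
          glu = "E", gly = "G", his = "H", ile = "I", leu = "L", lys = "K",
          met = "M", phe = "F", pro = "P", ser = "S", thr = "T", trp = "W",
          tyr = "Y", val = "V")

# Leucine/serine codon-family assignment from the anticodon. trnL1 reads
# CUN codons (anticodon UAG), trnL2 reads UUR (UAA); trnS1 reads AGN
# (UCU/GCU), trnS2 reads UCN (UGA).
.anticodon_family <- function(aa, anticodon) {
  ac <- chartr("u", "t", tolower(anticodon))
  if (aa == "L") {
    if (ac %in% c("tag", "cta")) return("trnL1")
    if (ac %in% c("taa", "tta")) return("trnL2")
  }
  if (aa == "S") {
    if (ac %in% c("tct", "gct", "aga", "agc")) return("trnS1")
    if (ac %in% c("tga", "tca")) return("trnS2")
  }
  NA_character_
}

#' Normalise a raw gene or product label to a canonical token
#'
#' Case-insensitive, synonym-aware mapping of GenBank `/gene` and
#' `/product` labels onto the 40-token vocabulary. Leucine and serine
#' tRNAs are disambiguated by an anticodon tag in the name (e.g.
#' `"trnL(uag)"`), or by an explicit `L1/L2/S1/S2` suffix; an
#' undisambiguated `trnL`/`trnS` maps to `"unknown"` (it is reported, not
#' guessed positionally). Control-region labels (`OH`, `D-loop`, ...) map
#' to `"other"`. Anything unrecognised maps to `"unknown"`; nothing is
#' dropped silently. The mapping is idempotent: canonical tokens map to
#' themselves.
#'
#' @param raw Character vector of labels.
#' @return Character vector of canonical tokens, `"other"` or `"unknown"`.
#' @examples
#' normalize_gene_name(c("COX1", "ND4L", "trnL(uag)", "16S rRNA", "orf42"))
#' @export
normalize_gene_name <- function(raw) {
  vapply(as.character(raw), .normalize_one, character(1), USE.NAMES = FALSE)
}

.normalize_one <- function(raw) {
  if (is.na(raw) || !nzchar(raw)) return("unknown")
  s <- tolower(trimws(raw))

  # canonical tokens and sentinels pass through unchanged (idempotence)
  if (s %in% c("other", "unknown")) return(s)
  canon <- gene_tokens("all")
  hit <- match(s, tolower(canon))
  if (!is.na(hit)) return(canon[hit])

  # tRNA forms: trnX, trnX(anticodon), trnX(codon family), trna-leu,
  # trna-leu (uaa), tRNA Ser 2
  ac <- NA_character_
  fam <- NA_character_
  m <- regmatches(s, regexec("\\(([acgutnry]{3})\\)", s))[[1]]
  if (length(m) == 2) {
    tag <- chartr("u", "t", m[2])
    fam <- switch(tag, ttr = "L2", tta = "L2", ctn = "L1",
                  agn = "S1", agy = "S1", tcn = "S2", NA_character_)
    if (is.na(fam)) ac <- m[2]
    s <- sub("\\([acgutnry]{3}\\)", "", s)
  }
  s2 <- gsub("[^a-z0-9]", "", s)

  if (grepl("^trn", s2)) {
    body <- sub("^trna?", "", s2)
    aa <- NA_character_
    idx <- NA_character_
    if (grepl("^[a-z]$", sub("[12]$", "", body)) && nchar(body) <= 2) {
      aa <- toupper(sub("[12]$", "", body))
      if (grepl("[12]$", body)) idx <- sub("^.*([12])$", "\\1", body)
    } else if (substr(body, 1, 3) %in% names(.aa3)) {
      aa <- .aa3[[substr(body, 1, 3)]]
      rest <- substr(body, 4, nchar(body))
      if (grepl("^[12]$", rest)) idx <- rest
    }
    if (!is.na(aa) && aa %in% c(.aa3, recursive = TRUE)) {
      if (aa %in% c("L", "S")) {
        if (!is.na(idx)) return(paste0("trn", aa, idx))
        if (!is.na(fam) && substr(fam, 1, 1) == aa) return(paste0("trn", fam))
        if (!is.na(ac)) {
          byac <- .anticodon_family(aa, ac)
          if (!is.na(byac)) return(byac)
        }
        return("unknown")  # ambiguous leucine/serine: reported, not guessed
      }
      tok <- paste0("trn", aa)
      if (tok %in% canon) return(tok)
    }
    return("unknown")
  }

  syn <- .synonym_table()
  if (s2 %in% names(syn)) return(unname(syn[[s2]]))
  "unknown"
}

#' The reference (ground-pattern) gene order
#'
#' The pancrustacean ancestral arrangement of the 37 mitochondrial genes,
#' anchored at `cox1` on the forward strand. Shipped as an editable text
#' file under `extdata`; pass `path` to substitute a different reference.
#'
#' @param path Optional path to a ground-pattern file (one signed token
#'   per line, `#` comments allowed).
#' @param gene_classes Gene classes to retain (default all).
#' @return A [gene_order] with `taxon_id = "Gr"`.
#' @export
ground_pattern <- function(path = NULL,
                           gene_classes = c("PCG", "rRNA", "tRNA")) {
  if (is.null(path)) {
    path <- system.file("extdata", "ground_pattern.txt", package = "mitorder",
                        mustWork = TRUE)
  }
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  go <- gene_order(lines, taxon_id = "Gr")
  restrict_gene_classes(go, gene_classes)
}
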