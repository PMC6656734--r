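# Per-taxon composition and asymmetry metrics: AT content, AT/GC skew,
# unassigned-region fraction, strand-usage skew, codon usage and RSCU
# under the invertebrate mitochondrial genetic code. All quantities are
# computed on the forward (deposited) strand of the whole molecule;
# assembly-gap N runs are excluded from every denominator.

.invert_mito_code <- function() {
  if (is.null(.pkg_env$gcode)) {
    .pkg_env$gcode <- Biostrings::getGeneticCode("5")  # invertebrate mito
  }
  .pkg_env$gcode
}

.base_counts <- function(sequence) {
  s <- Biostrings::DNAString(sequence)
  as.numeric(Biostrings::letterFrequency(s, c("A", "C", "G", "T")))
}

#' Whole-molecule base composition and skews
#'
#' `at_percent = 100 (A+T)/(A+C+G+T)`, `at_skew = (A-T)/(A+T)`,
#' `gc_skew = (G-C)/(G+C)`, all on the forward strand. A zero
#' denominator yields a flagged `NA` skew.
#'
#' @param record A `mitogenome_record`, or a plain nucleotide string.
#' @return List with `at_percent`, `at_skew`, `gc_skew`.
#' @export
base_composition <- function(record) {
  seq <- if (inherits(record, "mitogenome_record")) record$sequence else record
  cnt <- .base_counts(seq)
  a <- cnt[1]; cc <- cnt[2]; g <- cnt[3]; tt <- cnt[4]
  tot <- a + cc + g + tt
  if (tot == 0) stop("sequence contains no unambiguous bases")
  list(at_percent = 100 * (a + tt) / tot,
       at_skew = if (a + tt > 0) (a - tt) / (a + tt) else NA_real_,
       gc_skew = if (g + cc > 0) (g - cc) / (g + cc) else NA_real_)
}

# union length of feature intervals on the circular [0, len) axis
.covered_length <- function(features, len) {
  if (nrow(features) == 0) return(0L)
  iv <- list()
  for (k in seq_len(nrow(features))) {
    if (features$spans_origin[k]) {
      iv[[length(iv) + 1L]] <- c(features$start[k], len)
      iv[[length(iv) + 1L]] <- c(0L, features$end[k])
    } else {
      iv[[length(iv) + 1L]] <- c(features$start[k], features$end[k])
    }
  }
  m <- do.call(rbind, iv)
  m <- m[order(m[, 1]), , drop = FALSE]
  covered <- 0L; cur_s <- m[1, 1]; cur_e <- m[1, 2]
  for (k in seq_len(nrow(m))[-1]) {
    if (m[k, 1] <= cur_e) cur_e <- max(cur_e, m[k, 2])
    else { covered <- covered + (cur_e - cur_s); cur_s <- m[k, 1]; cur_e <- m[k, 2] }
  }
  covered + (cur_e - cur_s)
}

#' Percentage of the genome covered by no annotated gene
#'
#' Unassigned regions (URs) include the control region, which carries no
#' gene annotation. Overlapping features are counted once (interval
#' union).
#'
#' @param record A `mitogenome_record`.
#' @param count_control_region_as_gene If `TRUE`, annotated control
#'   regions (token `"other"`) count as assigned sequence; default
#'   `FALSE` (the control region carries no gene annotation).
#' @return UR percentage in `[0, 100]`.
#' @export
unassigned_fraction <- function(record, count_control_region_as_gene = FALSE) {
  f <- record$features
  if (!count_control_region_as_gene) {
    f <- f[f$token != "other", , drop = FALSE]
  }
  100 * (record$length - .covered_length(f, record$length)) / record$length
}

#' Strand usage skew
#'
#' `(L+ - L-)/(L+ + L-)` where `L+`/`L-` are the summed feature lengths
#' annotated on the plus and minus strand.
#'
#' @param record A `mitogenome_record`.
#' @return Skew in `[-1, 1]`.
#' @export
strand_usage_skew <- function(record) {
  f <- record$features[record$features$token != "other", , drop = FALSE]
  if (nrow(f) == 0) stop("record has no annotated gene features")
  lens <- feature_length(f, record$length)
  lp <- sum(lens[f$strand > 0]); lm <- sum(lens[f$strand < 0])
  (lp - lm) / (lp + lm)
}

.feature_seq <- function(record, k) {
  f <- record$features[k, ]
  s <- if (f$spans_origin) {
    paste0(substr(record$sequence, f$start + 1L, record$length),
           substr(record$sequence, 1L, f$end))
  } else substr(record$sequence, f$start + 1L, f$end)
  if (f$strand < 0) {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

#' Codon usage over all protein-coding genes
#'
#' Codons are read 5' to 3' on the coding strand of every PCG feature.
#' The initiation codon is counted as given; a trailing incomplete codon
#' (length not a multiple of 3, the usual polyadenylation-completed
#' stop) and a terminal stop codon are excluded; codons containing
#' ambiguous bases are skipped. An internal stop codon raises a warning
#' with its position (a likely annotation error) but is still counted.
#'
#' @param record A `mitogenome_record`.
#' @return Named integer vector of codon counts.
#' @export
codon_usage <- function(record) {
  code <- .invert_mito_code()
  stops <- names(code)[code == "*"]
  idx <- which(record$features$kind == "PCG")
  if (length(idx) == 0) stop("record has no protein-coding gene features")
  counts <- integer(0)
  for (k in idx) {
    s <- .feature_seq(record, k)
    if (nchar(s) < 6) next
    usable <- nchar(s) - nchar(s) %% 3
    cods <- substring(s, seq(1, usable, 3), seq(3, usable, 3))
    if (cods[length(cods)] %in% stops) cods <- cods[-length(cods)]
    internal <- which(cods %in% stops)
    if (length(internal)) {
      warning("taxon '", record$taxon_id, "', ",
              record$features$token[k], ": internal stop codon at codon ",
              paste(internal, collapse = ","), call. = FALSE)
    }
    cods <- cods[cods %in% names(code)]  # drop N-containing codons
    tab <- table(cods)
    counts <- c(counts, stats::setNames(as.integer(tab), names(tab)))
  }
  tapply_sum <- tapply(counts, names(counts), sum)
  out <- integer(length(code))
  names(out) <- names(code)
  out[names(tapply_sum)] <- as.integer(tapply_sum)
  out
}

#' Relative synonymous codon usage
#'
#' For codon `c` of an amino acid with `n_a` synonymous codons and
#' family total `N_a`: `rscu(c) = count(c) / (N_a / n_a)`. Defined over
#' sense codons of the invertebrate mitochondrial code; families with no
#' observations are omitted.
#'
#' @param codon_counts Named counts from [codon_usage()].
#' @return Named numeric vector of RSCU values.
#' @export
rscu <- function(codon_counts) {
  code <- .invert_mito_code()
  sense <- names(code)[code != "*"]
  counts <- codon_counts[sense]
  counts[is.na(counts)] <- 0
  aa <- code[sense]
  fam_tot <- tapply(counts, aa, sum)
  fam_n <- tapply(counts, aa, length)
  out <- numeric(0)
  for (a in names(fam_tot)) {
    if (fam_n[[a]] < 2 || fam_tot[[a]] == 0) next
    cs <- sense[aa == a]
    out <- c(out, stats::setNames(
      counts[cs] / (fam_tot[[a]] / fam_n[[a]]), cs))
  }
  out
}

#' Amino-acid frequencies implied by codon counts
#' @param codon_counts Named counts from [codon_usage()].
#' @return Named numeric vector summing to 1 (sense codons only).
#' @export
aa_frequencies <- function(codon_counts) {
  code <- .invert_mito_code()
  sense <- names(code)[code != "*"]
  counts <- codon_counts[sense]
  counts[is.na(counts)] <- 0
  tot <- tapply(counts, code[sense], sum)
  as.numeric(tot / sum(tot)) |> stats::setNames(names(tot))
}

#' Full composition profile of one mitogenome
#'
#' @param record A `mitogenome_record`.
#' @return A one-row data frame with `taxon_id`, `at_percent`,
#'   `at_skew`, `gc_skew`, `su_skew`, `ur_percent`, plus attributes
#'   `"codon_counts"`, `"rscu"`, `"aa_freq"`.
#' @export
composition_profile <- function(record) {
  bc <- base_composition(record)
  cc <- codon_usage(record)
  out <- data.frame(taxon_id = record$taxon_id,
                    at_percent = bc$at_percent, at_skew = bc$at_skew,
                    gc_skew = bc$gc_skew,
                    su_skew = strand_usage_skew(record),
                    ur_percent = unassigned_fraction(record),
                    stringsAsFactors = FALSE)
  attr(out, "codon_counts") <- cc
  attr(out, "rscu") <- rscu(cc)
  attr(out, "aa_freq") <- aa_frequencies(cc)
  out
}

#' Composition profiles for a set of records
#' @param records List of `mitogenome_record`s.
#' @return Data frame, one row per taxon; per-taxon codon counts, RSCU
#'   and amino-acid frequencies in attribute `"codon_tables"`.
#' @export
composition_profiles <- function(records) {
  rows <- lapply(records, composition_profile)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "codon_tables") <- lapply(rows, function(r) {
    list(codon_counts = attr(r, "codon_counts"), rscu = attr(r, "rscu"),
         aa_freq = attr(r, "aa_freq"))
  })
  names(attr(out, "codon_tables")) <- out$taxon_id
  out
}
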