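#' @name composition
#' @title Nucleotide composition and strand skews
#' @description Base counts, AT/GC content and AT/GC skews per sequence,
#'   per gene and per genome. `N` is excluded from all numerators and from
#'   the AT+GC denominator; the policy is recorded in the output so
#'   downstream tables are auditable. Percentages and skews are carried at
#'   full precision; rounding is purely presentational.
NULL

#' Base composition of a DNA sequence
#'
#' @param seq DNA string over `{A,C,G,T,N}`.
#' @return a one-row data frame with counts `A,C,G,T,N`, `AT_pct`,
#'   `GC_pct`, `AT_skew`, `GC_skew` and the `denominator_policy` string.
#'   Skews are `NA` when their denominator is zero (undefined, not zero).
#' @export
#' @examples
#' base_composition("AATG")
base_composition <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("empty sequence", call. = FALSE)
  seq <- toupper(seq)
  .check_dna(seq)
  fr <- Biostrings::alphabetFrequency(Biostrings::DNAString(seq))
  a <- fr[["A"]]; c_ <- fr[["C"]]; g <- fr[["G"]]; t <- fr[["T"]]
  n <- fr[["N"]]
  acgt <- a + c_ + g + t
  data.frame(
    A = a, C = c_, G = g, T = t, N = n,
    AT_pct = if (acgt > 0) 100 * (a + t) / acgt else NA_real_,
    GC_pct = if (acgt > 0) 100 * (g + c_) / acgt else NA_real_,
    AT_skew = if (a + t > 0) (a - t) / (a + t) else NA_real_,
    GC_skew = if (g + c_ > 0) (g - c_) / (g + c_) else NA_real_,
    denominator_policy = "N excluded from numerators and AT+GC denominator",
    stringsAsFactors = FALSE)
}

#' AT and GC skew of a sequence
#'
#' `AT_skew = (A - T)/(A + T)`, `GC_skew = (G - C)/(G + C)`; a zero
#' denominator yields `NA` (undefined), never 0.
#'
#' @param seq DNA string.
#' @return named numeric vector `c(AT_skew=, GC_skew=)`.
#' @export
#' @examples
#' skews("AAAT")
skews <- function(seq) {
  bc <- base_composition(seq)
  c(AT_skew = bc$AT_skew, GC_skew = bc$GC_skew)
}

#' Composition report for an annotated mitogenome
#'
#' One row per feature (gene-oriented sequence, ordered by start
#' coordinate) plus a whole-genome row.
#'
#' @param record a [mitogenome] record carrying a sequence.
#' @return data frame with a leading `unit` column followed by the
#'   [base_composition()] columns.
#' @export
composition_report <- function(record) {
  if (is.null(record$sequence)) stop("record carries no sequence",
                                     call. = FALSE)
  f <- record$features
  rows <- lapply(seq_len(nrow(f)), function(i) {
    cbind(unit = f$name[i],
          base_composition(extract_gene(record, f[i, ])),
          stringsAsFactors = FALSE)
  })
  rows[[length(rows) + 1L]] <- cbind(unit = "genome",
                                     base_composition(record$sequence),
                                     stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
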