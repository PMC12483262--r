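#' @name codon_usage
#' @title Codon usage and RSCU under the invertebrate mitochondrial code
#' @description Codon counting, relative synonymous codon usage (RSCU) and
#'   start/stop-codon classification for protein-coding genes. The engine
#'   is genetic-code generic; the default is NCBI translation table 5
#'   (invertebrate mitochondrial: `AGA`/`AGG` = Ser, `TGA` = Trp,
#'   `ATA` = Met; 62 sense codons, stop codons `TAA`/`TAG`).
NULL

#' Synonymous-family registry for a genetic code
#'
#' Built from the NCBI code registry shipped with Biostrings.
#'
#' @param code_table_id NCBI translation table number (default 5).
#' @return list with `code` (codon -> amino acid map, `*` marking stops),
#'   `stops`, `sense` codons, and `family_size` (amino acid -> number of
#'   synonymous codons).
#' @export
#' @examples
#' genetic_code_families(5)$family_size[c("L", "S")]
genetic_code_families <- function(code_table_id = 5) {
  code <- Biostrings::getGeneticCode(as.character(code_table_id))
  stops <- names(code)[code == "*"]
  sense <- names(code)[code != "*"]
  fam <- table(code[sense])
  list(code = code, stops = stops, sense = sense,
       family_size = setNames(as.integer(fam), names(fam)),
       id = code_table_id)
}

.split_codons <- function(cds) {
  n_full <- nchar(cds) %/% 3L
  if (n_full == 0L) return(character())
  substring(cds, 3L * seq_len(n_full) - 2L, 3L * seq_len(n_full))
}

#' Count sense codons across coding sequences
#'
#' Codons are read frame-0 from position 1 of each CDS. A trailing
#' incomplete codon (1-2 nt, the footprint of an incomplete stop) is
#' excluded, as are codons containing `N` and the stop codons of the code
#' table.
#'
#' @param cds_list character vector or list of CDS (5'->3'); names are
#'   used in error messages and per-gene scopes.
#' @param code_table_id NCBI translation table number.
#' @param scope label stored on the result (defaults to the gene name or
#'   `"pooled"`).
#' @return object of class `"codon_usage"`: list with `counts` (named
#'   integer over all sense codons), `code_table_id`, `scope`, `rscu`
#'   (filled by [rscu()]).
#' @export
#' @examples
#' codon_counts(c(gene1 = "ATGTTATAA"))$counts[c("ATG", "TTA")]
codon_counts <- function(cds_list, code_table_id = 5, scope = NULL) {
  cds_list <- as.list(cds_list)
  gc <- genetic_code_families(code_table_id)
  short <- vapply(cds_list, nchar, integer(1)) < 3L
  if (any(short)) {
    nm <- names(cds_list)[short]
    if (is.null(nm)) nm <- which(short)
    stop(sprintf("CDS shorter than one codon: %s",
                 paste(nm, collapse = ", ")), call. = FALSE)
  }
  counts <- setNames(integer(length(gc$sense)), gc$sense)
  for (cds in cds_list) {
    cod <- .split_codons(toupper(cds))
    cod <- cod[!grepl("N", cod, fixed = TRUE)]
    cod <- cod[cod %in% gc$sense]
    if (length(cod)) {
      tab <- table(cod)
      counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
    }
  }
  if (is.null(scope)) {
    scope <- if (length(cds_list) == 1L && !is.null(names(cds_list))) {
      names(cds_list)
    } else "pooled"
  }
  structure(list(counts = counts, code_table_id = code_table_id,
                 scope = scope, rscu = NULL),
            class = "codon_usage")
}

#' Fill relative synonymous codon usage values
#'
#' `RSCU[c] = X[c] / ((1/n) * sum of X over the synonymous family)`, where
#' `n` is the family size. A family whose total count is zero gets `NA`
#' (missing, not 0) for all of its codons.
#'
#' @param table a `"codon_usage"` object from [codon_counts()].
#' @return the same object with `$rscu` filled.
#' @export
rscu <- function(table) {
  stopifnot(inherits(table, "codon_usage"))
  gc <- genetic_code_families(table$code_table_id)
  aa <- gc$code[names(table$counts)]
  vals <- setNames(rep(NA_real_, length(table$counts)), names(table$counts))
  for (a in unique(aa)) {
    idx <- which(aa == a)
    tot <- sum(table$counts[idx])
    if (tot > 0) {
      vals[idx] <- table$counts[idx] / (tot / length(idx))
    }
  }
  table$rscu <- vals
  table
}

#' @export
print.codon_usage <- function(x, ...) {
  cat(sprintf("<codon_usage> scope '%s', code table %s, %d codons counted\n",
              x$scope, x$code_table_id, sum(x$counts)))
  invisible(x)
}

#' Per-codon usage table as a data frame
#'
#' @param x a `"codon_usage"` object (RSCU filled on the fly if absent).
#' @return data frame with columns `codon`, `amino_acid`, `count`, `RSCU`,
#'   `scope`.
#' @export
as.data.frame.codon_usage <- function(x, ...) {
  if (is.null(x$rscu)) x <- rscu(x)
  gc <- genetic_code_families(x$code_table_id)
  data.frame(codon = names(x$counts),
             amino_acid = unname(gc$code[names(x$counts)]),
             count = unname(x$counts),
             RSCU = unname(x$rscu),
             scope = x$scope,
             stringsAsFactors = FALSE)
}

.pcg_cds <- function(record) {
  f <- record$features
  pcg <- f[f$category == "PCG", , drop = FALSE]
  setNames(lapply(seq_len(nrow(pcg)),
                  function(i) extract_gene(record, pcg[i, ])),
           pcg$name)
}

#' Per-gene and pooled RSCU report for a mitogenome
#'
#' Emits both scopes the analyses need: one RSCU table per protein-coding
#' gene and one over the pooled PCGs.
#'
#' @param record a [mitogenome] record carrying a sequence.
#' @param code_table_id NCBI translation table number.
#' @return list with `per_gene` (data frame, all genes stacked) and
#'   `pooled` (data frame, scope `"all PCGs"`).
#' @export
rscu_report <- function(record, code_table_id = 5) {
  cds <- .pcg_cds(record)
  if (!length(cds)) stop("record has no PCG features", call. = FALSE)
  per_gene <- do.call(rbind, lapply(names(cds), function(g) {
    as.data.frame(rscu(codon_counts(cds[g], code_table_id, scope = g)))
  }))
  pooled <- as.data.frame(
    rscu(codon_counts(cds, code_table_id, scope = "all PCGs")))
  rownames(per_gene) <- rownames(pooled) <- NULL
  list(per_gene = per_gene, pooled = pooled)
}

#' Cumulative RSCU of one codon across the protein-coding genes
#'
#' Sums the per-gene RSCU of `codon` over every PCG of the record. Genes
#' in which the codon's synonymous family is entirely unobserved
#' contribute 0 and are listed in the `zero_family_genes` attribute.
#'
#' @param record a [mitogenome] record carrying a sequence.
#' @param codon 3-mer, must be a sense codon of the code table.
#' @param code_table_id NCBI translation table number.
#' @return numeric scalar with attribute `zero_family_genes`.
#' @export
cumulative_rscu <- function(record, codon, code_table_id = 5) {
  gc <- genetic_code_families(code_table_id)
  codon <- toupper(codon)
  if (codon %in% gc$stops) {
    stop(sprintf("'%s' is a stop codon under code table %s", codon,
                 code_table_id), call. = FALSE)
  }
  if (!codon %in% gc$sense) stop(sprintf("unknown codon '%s'", codon),
                                 call. = FALSE)
  cds <- .pcg_cds(record)
  vals <- vapply(names(cds), function(g) {
    rscu(codon_counts(cds[g], code_table_id, scope = g))$rscu[[codon]]
  }, numeric(1))
  zero <- names(vals)[is.na(vals)]
  structure(sum(vals, na.rm = TRUE), zero_family_genes = zero)
}

#' Classify start and stop codons of a coding sequence
#'
#' Annotation-driven classification: the start codon is the first 3 nt;
#' the stop is the final codon when the length is divisible by 3, and the
#' incomplete-stop notation `"T(AA)"` / `"TA(A)"` when 1 or 2 trailing
#' nucleotides remain (completed to `TAA` post-transcriptionally). The
#' `complete` flag is `FALSE` iff `length mod 3` is 1 or 2. A complete
#' final codon that is not a stop of the code table is flagged via
#' `stop_valid = FALSE`, not an error.
#'
#' @param cds CDS (5'->3'), length >= 4.
#' @param gene optional gene name carried into the result.
#' @param code_table_id NCBI translation table number.
#' @return list with `gene`, `start_codon`, `stop_codon`, `complete`,
#'   `stop_valid`.
#' @export
#' @examples
#' classify_start_stop("ATGAAATAA")
classify_start_stop <- function(cds, gene = NA_character_,
                                code_table_id = 5) {
  cds <- toupper(cds)
  if (nchar(cds) < 4L) stop("CDS shorter than 4 nt", call. = FALSE)
  gc <- genetic_code_families(code_table_id)
  n <- nchar(cds)
  r <- n %% 3L
  start <- substr(cds, 1L, 3L)
  if (r == 0L) {
    stop_codon <- substr(cds, n - 2L, n)
    complete <- TRUE
    stop_valid <- stop_codon %in% gc$stops
  } else {
    trailing <- substr(cds, n - r + 1L, n)
    stop_codon <- paste0(trailing, "(", substr("TAA", r + 1L, 3L), ")")
    complete <- FALSE
    stop_valid <- trailing == substr("TAA", 1L, r)
  }
  list(gene = gene, start_codon = start, stop_codon = stop_codon,
       complete = complete, stop_valid = stop_valid)
}

#' Start/stop classification table for all PCGs of a record
#'
#' @param record a [mitogenome] record carrying a sequence.
#' @param code_table_id NCBI translation table number.
#' @return data frame, one row per PCG.
#' @export
start_stop_table <- function(record, code_table_id = 5) {
  cds <- .pcg_cds(record)
  out <- do.call(rbind, lapply(names(cds), function(g) {
    cl <- classify_start_stop(cds[[g]], gene = g,
                              code_table_id = code_table_id)
    data.frame(gene = g, start_codon = cl$start_codon,
               stop_codon = cl$stop_codon, complete = cl$complete,
               stop_valid = cl$stop_valid, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Translate a CDS under a genetic code table
#'
#' Frame-0 translation dropping any trailing incomplete codon; codons
#' containing `N` translate to `X`.
#'
#' @param cds DNA string.
#' @param code_table_id NCBI translation table number.
#' @return character scalar of amino acids (`*` marks stops).
#' @export
translate_cds <- function(cds, code_table_id = 5) {
  gc <- genetic_code_families(code_table_id)
  cod <- .split_codons(toupper(cds))
  aa <- ifelse(grepl("N", cod, fixed = TRUE), "X", gc$code[cod])
  paste(aa, collapse = "")
}
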