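#' @name genome_io
#' @title Mitogenome input/output
#' @description Readers and writers for GenBank flat files, FASTA and
#'   tab-separated feature tables, plus strand/topology-aware gene
#'   extraction. Coordinates are 1-based inclusive throughout (GenBank
#'   convention); a feature whose `end` is smaller than its `start` wraps
#'   the origin of a circular genome.
NULL

.feature_columns <- c("name", "category", "strand", "start", "end", "size",
                      "start_codon", "stop_codon", "anticodon")

.synonym_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "gene_synonyms.tsv", package = "mitocomp")
      tab <- read.delim(path, stringsAsFactors = FALSE)
      cache <<- setNames(tab$canonical, tab$synonym)
    }
    cache
  }
})

#' Normalize a gene name to its canonical mitochondrial symbol
#'
#' Maps common annotation synonyms (`ND5`, `COI`, `COB`, `12S`, `D-loop`,
#' `tRNA-Ile`, ...) onto the canonical lower-case symbols used throughout
#' the package (`nad5`, `cox1`, `cytb`, `rrnS`, `CR`, `trnI`). Unknown
#' names pass through unchanged with a warning.
#'
#' @param name character vector of gene names.
#' @param quiet suppress the unknown-name warning.
#' @return character vector of canonical symbols.
#' @export
#' @examples
#' normalize_gene_name(c("ND5", "COI", "tRNA-Leu", "D-loop"))
normalize_gene_name <- function(name, quiet = FALSE) {
  syn <- .synonym_table()
  canonical <- c(paste0("nad", c(1:6, "4L")), paste0("cox", 1:3),
                 "atp6", "atp8", "cytb", "rrnS", "rrnL", "CR",
                 paste0("trn", c(LETTERS, "L1", "L2", "S1", "S2")))
  aa3 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
           Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
           Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
           Tyr = "Y", Val = "V")
  out <- vapply(name, function(nm) {
    nm0 <- trimws(nm)
    if (nm0 %in% canonical) return(nm0)
    key <- toupper(gsub("[[:space:]]", "", nm0))
    if (key %in% names(syn)) return(unname(syn[key]))
    # tRNA-Xxx and tRNA-Xxx(nnn) product-style names
    m <- regmatches(nm0, regexec("^[Tt][Rr][Nn][Aa]-([A-Za-z]{3})", nm0))[[1]]
    if (length(m) == 2L && m[2] %in% names(aa3)) {
      return(paste0("trn", aa3[[m[2]]]))
    }
    if (!quiet) {
      warning(sprintf("unrecognized gene name '%s' kept as-is", nm0),
              call. = FALSE)
    }
    nm0
  }, character(1), USE.NAMES = FALSE)
  out
}

.infer_category <- function(name) {
  ifelse(grepl("^(nad|cox|atp|cytb)", name), "PCG",
  ifelse(grepl("^trn", name), "tRNA",
  ifelse(grepl("^rrn", name), "rRNA",
  ifelse(name %in% c("CR", "D-loop"), "CR", "other"))))
}

#' Compute feature sizes from 1-based inclusive coordinates
#'
#' Non-wrapping features have size `end - start + 1`; a feature that wraps
#' the origin of a circular genome of length `L` has size
#' `(L - start + 1) + end`.
#'
#' @param start,end integer vectors of 1-based inclusive coordinates.
#' @param L genome length.
#' @return integer vector of sizes.
#' @export
feature_size <- function(start, end, L) {
  ifelse(end >= start, end - start + 1L, (L - start + 1L) + end)
}

#' Construct a mitogenome record
#'
#' The container every analysis consumes: an (optionally absent) circular
#' DNA sequence plus an ordered feature table. A record that mirrors a
#' complete mosquito mitogenome carries 37 functional genes (13 PCG, 22
#' tRNA, 2 rRNA) and one control region.
#'
#' @param id accession-like identifier.
#' @param species free-text species name.
#' @param sequence uppercase DNA over `{A,C,G,T,N}`, or `NULL` for a
#'   coordinates-only record (e.g. a published feature table).
#' @param features data frame with columns `name`, `strand`, `start`,
#'   `end` and optionally `category`, `size`, `start_codon`, `stop_codon`,
#'   `anticodon`.
#' @param circular logical; circular topology (default `TRUE`).
#' @param length genome length; defaults to `nchar(sequence)` or, for a
#'   sequence-less record, the maximum feature end.
#' @return object of class `"mitogenome"`.
#' @export
mitogenome <- function(id, species = "", sequence = NULL, features = NULL,
                       circular = TRUE, length = NULL) {
  if (!is.null(sequence)) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    sequence <- toupper(sequence)
    .check_dna(sequence, sprintf("sequence of '%s'", id))
  }
  L <- if (!is.null(length)) as.integer(length)
       else if (!is.null(sequence)) nchar(sequence)
       else if (!is.null(features) && nrow(features)) max(features$end)
       else 0L
  if (!is.null(sequence) && nchar(sequence) != L) {
    stop("declared length disagrees with the sequence", call. = FALSE)
  }
  if (is.null(features)) {
    features <- as.data.frame(setNames(
      list(character(), character(), character(), integer(), integer(),
           integer(), character(), character(), character()),
      .feature_columns))
  }
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "strand", "start", "end") %in% names(features)))
  if (is.null(features$category)) {
    features$category <- .infer_category(features$name)
  }
  for (col in c("start_codon", "stop_codon", "anticodon")) {
    if (is.null(features[[col]])) features[[col]] <- ""
    features[[col]][is.na(features[[col]])] <- ""
  }
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (nrow(features)) {
    if (!all(features$strand %in% c("+", "-"))) {
      stop("feature strand must be '+' or '-'", call. = FALSE)
    }
    if (any(features$start < 1L) || any(features$end > L) ||
        any(features$start > L)) {
      stop("feature coordinates outside [1, L]", call. = FALSE)
    }
    wraps <- features$end < features$start
    if (any(wraps) && !circular) {
      stop("start > end is only valid on a circular record", call. = FALSE)
    }
    features$size <- feature_size(features$start, features$end, L)
    pcg_short <- features$category == "PCG" & features$size < 3L
    if (any(pcg_short)) {
      stop(sprintf("PCG feature(s) shorter than one codon: %s",
                   paste(features$name[pcg_short], collapse = ", ")),
           call. = FALSE)
    }
    features <- features[order(features$start), , drop = FALSE]
    rownames(features) <- NULL
  }
  features <- features[, .feature_columns, drop = FALSE]
  structure(list(id = id, species = species, sequence = sequence,
                 circular = isTRUE(circular), features = features,
                 length = L),
            class = "mitogenome")
}

#' @export
print.mitogenome <- function(x, ...) {
  cat(sprintf("<mitogenome> %s%s\n", x$id,
              if (nzchar(x$species)) paste0(" (", x$species, ")") else ""))
  cat(sprintf("  %s, %d bp%s, %d features (%s)\n",
              if (x$circular) "circular" else "linear", x$length,
              if (is.null(x$sequence)) " [coordinates only]" else "",
              nrow(x$features),
              paste(sprintf("%d %s", table(x$features$category),
                            names(table(x$features$category))),
                    collapse = ", ")))
  invisible(x)
}

#' @export
length.mitogenome <- function(x) x$length

#' Read a tab-separated feature table
#'
#' Expects columns `name`, `strand`, `start`, `end` and optionally
#' `category`, `size`, `start_codon`, `stop_codon`, `anticodon`
#' (the layout of a published mitogenome annotation table). When a `size`
#' column is present it is cross-checked against the coordinates; any
#' mismatch is reported through a warning and the coordinate-derived size
#' wins.
#'
#' @param path TSV file path.
#' @param sequence optional DNA string the coordinates refer to.
#' @param id,species,circular record metadata, see [mitogenome()].
#' @return a [mitogenome] record.
#' @export
read_feature_table <- function(path, sequence = NULL, id = basename(path),
                               species = "", circular = TRUE) {
  tab <- read.delim(path, stringsAsFactors = FALSE, fill = TRUE,
                    na.strings = c("NA", ""))
  need <- c("name", "strand", "start", "end")
  if (!all(need %in% names(tab))) {
    stop(sprintf("feature table must have columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  dup <- duplicated(tab$name)
  if (any(dup)) {
    stop(sprintf("duplicated feature name(s): %s",
                 paste(unique(tab$name[dup]), collapse = ", ")),
         call. = FALSE)
  }
  declared <- if ("size" %in% names(tab)) as.integer(tab$size) else NULL
  L <- if (!is.null(sequence)) nchar(sequence) else {
    suppressWarnings(max(as.integer(tab$end), as.integer(tab$start)))
  }
  if (!circular && any(tab$end < tab$start)) {
    stop("start > end on a non-circular record", call. = FALSE)
  }
  rec <- mitogenome(id = id, species = species, sequence = sequence,
                    features = tab, circular = circular, length = L)
  if (!is.null(declared)) {
    m <- match(rec$features$name, tab$name)
    decl <- declared[m]
    off <- which(!is.na(decl) & decl != rec$features$size)
    if (length(off)) {
      warning(sprintf(
        "declared size disagrees with coordinates (coordinates win): %s",
        paste(sprintf("%s (declared %d, coords %d)", rec$features$name[off],
                      decl[off], rec$features$size[off]), collapse = "; ")),
        call. = FALSE)
    }
  }
  rec
}

#' Write a record's feature table as TSV
#'
#' @param record a [mitogenome] record.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(record, path) {
  write.table(record$features, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Recomputed intergenic spacing between consecutive features
#'
#' Always derived from the coordinates as `next.start - prev.end - 1`
#' (negative values indicate overlap); published intergenic columns are
#' ignored because they are frequently inconsistent with the coordinates
#' they accompany. The first feature's spacer is counted from position 1
#' (or from the last feature across the origin on a circular record).
#'
#' @param record a [mitogenome] record.
#' @return integer vector, one value per feature (spacing to the previous
#'   feature).
#' @export
intergenic_spacing <- function(record) {
  f <- record$features
  n <- nrow(f)
  if (n == 0L) return(integer())
  prev_end <- c(if (record$circular) f$end[n] - record$length else 0L,
                f$end[-n])
  as.integer(f$start - prev_end - 1L)
}

#' Extract a gene sequence from a mitogenome
#'
#' Returns the 5'->3' gene sequence: the forward slice for `+` features,
#' the reverse complement for `-` features. A feature whose `end` is
#' smaller than its `start` wraps the origin; the tail and head of the
#' circular sequence are concatenated before orientation.
#'
#' @param record a [mitogenome] record carrying a sequence.
#' @param feature a feature name or a single row of `record$features`.
#' @return character scalar, the oriented gene sequence.
#' @export
extract_gene <- function(record, feature) {
  if (is.null(record$sequence)) {
    stop("record carries no sequence", call. = FALSE)
  }
  if (is.character(feature) && length(feature) == 1L) {
    i <- match(feature, record$features$name)
    if (is.na(i)) stop(sprintf("no feature named '%s'", feature),
                       call. = FALSE)
    feature <- record$features[i, ]
  }
  start <- feature$start; end <- feature$end
  L <- record$length
  if (start < 1L || start > L || end < 1L || end > L) {
    stop("feature coordinates out of range", call. = FALSE)
  }
  if (end >= start) {
    s <- substr(record$sequence, start, end)
  } else {
    if (!record$circular) {
      stop("wrapping feature on a linear record", call. = FALSE)
    }
    s <- paste0(substr(record$sequence, start, L),
                substr(record$sequence, 1L, end))
  }
  if (identical(feature$strand, "-")) s <- revcomp(s)
  s
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readDNAStringSet` that returns plain
#' named character strings and rejects ambiguity codes other than `N`.
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  for (i in seq_along(out)) .check_dna(out[[i]], names(out)[i])
  out
}

#' Write sequences to FASTA
#'
#' Standard 70-column wrapped FASTA in the order given.
#'
#' @param seqs named character vector (or `DNAStringSet`) of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (length(seqs) == 0L) stop("no sequences to write", call. = FALSE)
  if (!methods::is(seqs, "DNAStringSet")) {
    if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
      stop("sequences must be named", call. = FALSE)
    }
    seqs <- Biostrings::DNAStringSet(unlist(seqs))
  }
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

# ---- GenBank flat files -----------------------------------------------------

#' Read a GenBank flat file into a mitogenome record
#'
#' A purpose-built reader for single-record GenBank flat files with
#' `CDS`/`tRNA`/`rRNA`/`misc_feature`/`D-loop` annotations. Gene names are
#' normalized via [normalize_gene_name()]; the circular flag is taken from
#' the `LOCUS` line; `complement(...)` and origin-spanning
#' `join(a..L,1..b)` locations are supported.
#'
#' @param path GenBank flat file.
#' @return a [mitogenome] record.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i)) stop("not a GenBank flat file: no LOCUS line",
                             call. = FALSE)
  locus <- lines[locus_i[1]]
  circular <- grepl("circular", locus, ignore.case = TRUE)
  id <- strsplit(trimws(sub("^LOCUS", "", locus)), "[[:space:]]+")[[1]][1]
  acc_i <- grep("^ACCESSION", lines)
  if (length(acc_i)) {
    acc <- strsplit(trimws(sub("^ACCESSION", "", lines[acc_i[1]])),
                    "[[:space:]]+")[[1]][1]
    if (!is.na(acc) && nzchar(acc)) id <- acc
  }
  org_i <- grep("^[[:space:]]+ORGANISM", lines)
  species <- if (length(org_i)) trimws(sub("^[[:space:]]+ORGANISM", "",
                                           lines[org_i[1]])) else ""

  origin_i <- grep("^ORIGIN", lines)
  if (!length(origin_i)) stop("GenBank record has no ORIGIN section",
                              call. = FALSE)
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[end_i > origin_i[1]][1] else length(lines) + 1L
  seq_lines <- lines[(origin_i[1] + 1L):(end_i - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("empty ORIGIN section", call. = FALSE)

  feat_i <- grep("^FEATURES", lines)
  feats <- list()
  if (length(feat_i)) {
    i <- feat_i[1] + 1L
    keep_keys <- c("CDS", "tRNA", "rRNA", "misc_feature", "D-loop", "gene")
    cur <- NULL
    flush <- function(cur) {
      if (is.null(cur) || cur$key == "gene") return(NULL)
      nm <- cur$gene
      if (is.null(nm)) nm <- cur$product
      if (is.null(nm) && cur$key == "D-loop") nm <- "CR"
      if (is.null(nm) && !is.null(cur$note)) nm <- cur$note
      if (is.null(nm)) return(NULL)
      nm <- normalize_gene_name(nm)
      cat_map <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                   misc_feature = "CR", "D-loop" = "CR")
      data.frame(name = nm, category = unname(cat_map[cur$key]),
                 strand = cur$strand, start = cur$start, end = cur$end,
                 stringsAsFactors = FALSE)
    }
    while (i <= length(lines) && !grepl("^(ORIGIN|CONTIG|BASE COUNT)", lines[i])) {
      ln <- lines[i]
      if (grepl("^ {5}[A-Za-z]", ln) && !grepl("^ {21}", ln)) {
        feats[[length(feats) + 1L]] <- flush(cur)
        key <- sub("^ {5}([^ ]+).*$", "\\1", ln)
        loc <- trimws(sub("^ {5}[^ ]+", "", ln))
        # location may continue on the next line(s)
        while (grepl("[,(]$", loc) && i < length(lines)) {
          i <- i + 1L
          loc <- paste0(loc, trimws(lines[i]))
        }
        if (key %in% keep_keys) {
          pl <- .parse_gb_location(loc, line = i)
          cur <- list(key = key, strand = pl$strand, start = pl$start,
                      end = pl$end)
        } else cur <- list(key = "gene")
      } else if (grepl("^ {21}/", ln) && !is.null(cur)) {
        q <- sub("^ {21}/", "", ln)
        if (grepl("^gene=", q)) cur$gene <- gsub("\"", "", sub("^gene=", "", q))
        if (grepl("^product=", q)) {
          cur$product <- gsub("\"", "", sub("^product=", "", q))
        }
        if (grepl("^note=", q) && is.null(cur$note)) {
          cur$note <- gsub("\"", "", sub("^note=", "", q))
        }
      }
      i <- i + 1L
    }
    feats[[length(feats) + 1L]] <- flush(cur)
  }
  feats <- do.call(rbind, feats)
  mitogenome(id = id, species = species, sequence = sequence,
             features = feats, circular = circular)
}

.parse_gb_location <- function(loc, line = NA) {
  strand <- "+"
  x <- loc
  if (grepl("^complement\\(", x)) {
    strand <- "-"
    x <- sub("^complement\\((.*)\\)$", "\\1", x)
  }
  if (grepl("^join\\(", x)) {
    x <- sub("^join\\((.*)\\)$", "\\1", x)
    parts <- strsplit(x, ",", fixed = TRUE)[[1]]
    rng <- lapply(parts, .parse_gb_span, line = line)
    # origin-spanning join: start of first span, end of last span
    return(list(strand = strand, start = rng[[1]]$start,
                end = rng[[length(rng)]]$end))
  }
  sp <- .parse_gb_span(x, line = line)
  list(strand = strand, start = sp$start, end = sp$end)
}

.parse_gb_span <- function(x, line = NA) {
  x <- gsub("[<>]", "", trimws(x))
  m <- regmatches(x, regexec("^([0-9]+)\\.\\.([0-9]+)$", x))[[1]]
  if (length(m) != 3L) {
    m1 <- regmatches(x, regexec("^([0-9]+)$", x))[[1]]
    if (length(m1) == 2L) {
      p <- as.integer(m1[2])
      return(list(start = p, end = p))
    }
    stop(sprintf("malformed GenBank location '%s' (line %s)", x, line),
         call. = FALSE)
  }
  list(start = as.integer(m[2]), end = as.integer(m[3]))
}

#' Write a mitogenome record as a GenBank flat file
#'
#' Emits a minimal but standards-shaped flat file (LOCUS, FEATURES with
#' CDS/tRNA/rRNA/misc_feature keys, ORIGIN) that [read_genbank()] parses
#' back to identical coordinates. Intended for fixtures and interchange,
#' not for submission.
#'
#' @param record a [mitogenome] record carrying a sequence.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  if (is.null(record$sequence)) stop("record carries no sequence",
                                     call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  topo <- if (record$circular) "circular" else "linear"
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s   UNA 01-JAN-2000",
                     record$id, record$length, topo), con)
  writeLines(sprintf("DEFINITION  %s mitochondrion.", record$species), con)
  writeLines(sprintf("ACCESSION   %s", record$id), con)
  writeLines("SOURCE      .", con)
  writeLines(sprintf("  ORGANISM  %s", record$species), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", record$length), con)
  key_map <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA", CR = "misc_feature")
  f <- record$features
  for (i in seq_len(nrow(f))) {
    span <- if (f$end[i] >= f$start[i]) {
      sprintf("%d..%d", f$start[i], f$end[i])
    } else {
      sprintf("join(%d..%d,1..%d)", f$start[i], record$length, f$end[i])
    }
    if (f$strand[i] == "-") span <- sprintf("complement(%s)", span)
    key <- key_map[[f$category[i]]]
    writeLines(sprintf("     %-15s %s", key, span), con)
    writeLines(sprintf("                     /gene=\"%s\"", f$name[i]), con)
  }
  writeLines("ORIGIN", con)
  s <- record$sequence
  for (pos in seq(1L, nchar(s), by = 60L)) {
    chunk <- substr(s, pos, min(pos + 59L, nchar(s)))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", pos, tolower(paste(blocks, collapse = " "))),
               con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Shipped annotation fixtures
#'
#' Feature tables transcribed from the published annotation of the two
#' Bangladeshi dengue-vector mitogenomes (accessions PQ197330 and
#' PQ197331). Three rows whose printed coordinates contradicted their own
#' printed size column were curated so that `size == end - start + 1`
#' holds for every row (see the package vignette).
#'
#' @param species `"aegypti"` or `"albopictus"`.
#' @return a coordinates-only [mitogenome] record.
#' @export
#' @examples
#' rec <- fixture_record("aegypti")
#' sum(rec$features$size[rec$features$category == "PCG"])
fixture_record <- function(species = c("aegypti", "albopictus")) {
  species <- match.arg(species)
  file <- switch(species,
    aegypti = "aedes_aegypti_PQ197330_features.tsv",
    albopictus = "aedes_albopictus_PQ197331_features.tsv")
  id <- switch(species, aegypti = "PQ197330", albopictus = "PQ197331")
  sp <- switch(species, aegypti = "Aedes aegypti",
               albopictus = "Aedes albopictus")
  read_feature_table(system.file("extdata", file, package = "mitocomp"),
                     id = id, species = sp)
}
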