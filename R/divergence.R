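#' @name divergence
#' @title Intraspecific divergence metrics
#' @description Pairwise global alignment, Kimura two-parameter (K80)
#'   distance, SNP counting, bp-per-SNP density and percent identity.
#'   Columns containing gaps or `N` are removed pairwise (pairwise
#'   deletion) everywhere; the policy is recorded in summary output.
NULL

.TS_PAIRS <- c("AG", "GA", "CT", "TC")

#' Global pairwise alignment (Needleman-Wunsch with affine gaps)
#'
#' Deterministic Gotoh alignment with match +1, mismatch -1 and affine
#' gap cost `-(gap_open + k * gap_extend)` for a gap of `k` residues
#' (defaults 5 and 1). Traceback ties are broken preferring diagonal over
#' up (gap in `b`) over left (gap in `a`). Intended as a desk-scale
#' aligner for short or near-identical sequences; large panels should be
#' aligned externally and read back as aligned FASTA.
#'
#' @param a,b DNA strings (non-empty).
#' @param idA,idB sequence identifiers.
#' @param match,mismatch,gap_open,gap_extend scoring parameters
#'   (penalties positive).
#' @return object of class `"pairwise_alignment"`: list with `idA`, `idB`,
#'   aligned strings `A` and `B`, `score`, `comparable_sites`.
#' @export
#' @examples
#' align_pair("ACGT", "ACT")
align_pair <- function(a, b, idA = "A", idB = "B", match = 1, mismatch = -1,
                       gap_open = 5, gap_extend = 1) {
  stopifnot(nzchar(a), nzchar(b))
  av <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  bv <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  gap1 <- -(gap_open + gap_extend)   # first residue of a gap
  ge <- -gap_extend
  M <- X <- Y <- matrix(NEG, n + 1L, m + 1L)
  M[1, 1] <- 0
  if (n >= 1L) X[2:(n + 1L), 1] <- gap1 + ge * (0:(n - 1L))
  if (m >= 1L) Y[1, 2:(m + 1L)] <- gap1 + ge * (0:(m - 1L))
  for (i in seq_len(n)) {
    s_row <- ifelse(bv == av[i], match, mismatch)
    for (j in seq_len(m)) {
      M[i + 1L, j + 1L] <- max(M[i, j], X[i, j], Y[i, j]) + s_row[j]
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] + gap1, X[i, j + 1L] + ge,
                               Y[i, j + 1L] + gap1)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] + gap1, Y[i + 1L, j] + ge,
                               X[i + 1L, j] + gap1)
    }
  }
  # traceback; tie preference diagonal (M) > up (X) > left (Y)
  tol <- 1e-9
  pick <- function(cands, target) which(abs(cands - target) < tol)[1]
  i <- n; j <- m
  finals <- c(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
  state <- which.max(finals)       # which.max takes the first of ties
  score <- finals[state]
  ra <- character(n + m); rb <- character(n + m); k <- n + m + 1L
  while (i > 0L || j > 0L) {
    if (state == 1L) {                 # M: diagonal move into (i, j)
      s <- if (av[i] == bv[j]) match else mismatch
      target <- M[i + 1L, j + 1L] - s
      prev <- c(M[i, j], X[i, j], Y[i, j])
      k <- k - 1L; ra[k] <- av[i]; rb[k] <- bv[j]
      i <- i - 1L; j <- j - 1L
      state <- pick(prev, target)
    } else if (state == 2L) {          # X: gap in b, consume a ("up")
      prev <- c(M[i, j + 1L] + gap1, X[i, j + 1L] + ge, Y[i, j + 1L] + gap1)
      target <- X[i + 1L, j + 1L]
      k <- k - 1L; ra[k] <- av[i]; rb[k] <- "-"
      i <- i - 1L
      state <- pick(prev, target)
    } else {                           # Y: gap in a, consume b ("left")
      prev <- c(M[i + 1L, j] + gap1, X[i + 1L, j] + gap1, Y[i + 1L, j] + ge)
      target <- Y[i + 1L, j + 1L]
      k <- k - 1L; ra[k] <- "-"; rb[k] <- bv[j]
      j <- j - 1L
      state <- pick(prev, target)
    }
    if (i == 0L && j == 0L) break
    if (i == 0L) state <- 3L else if (j == 0L) state <- 2L
  }
  ra <- ra[k:(n + m)]; rb <- rb[k:(n + m)]
  A <- paste(ra, collapse = ""); B <- paste(rb, collapse = "")
  comparable <- sum(ra %in% DNA_BASES & rb %in% DNA_BASES)
  structure(list(idA = idA, idB = idB, A = A, B = B, score = score,
                 comparable_sites = comparable),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %s vs %s, length %d, score %g\n",
              x$idA, x$idB, nchar(x$A), x$score))
  cat(" ", x$A, "\n ", x$B, "\n", sep = "")
  invisible(x)
}

.pair_site_stats <- function(sa, sb) {
  va <- strsplit(sa, "", fixed = TRUE)[[1]]
  vb <- strsplit(sb, "", fixed = TRUE)[[1]]
  if (length(va) != length(vb)) {
    stop("aligned sequences differ in length", call. = FALSE)
  }
  ok <- va %in% DNA_BASES & vb %in% DNA_BASES
  va <- va[ok]; vb <- vb[ok]
  diff <- va != vb
  pair <- paste0(va[diff], vb[diff])
  ts <- sum(pair %in% .TS_PAIRS)
  list(comparable = length(va), ts = ts, tv = sum(diff) - ts)
}

#' Kimura two-parameter distance from a pairwise alignment
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` with `P` the transition
#' (A<->G, C<->T) and `Q` the transversion proportion over comparable
#' sites. Columns containing a gap or `N` are excluded pairwise. When
#' `1 - 2P - Q <= 0` or `1 - 2Q <= 0` the distance is saturated: `d` is
#' `NA` and the `saturated` flag is set.
#'
#' @param aln a `"pairwise_alignment"`, or an aligned DNA string (then
#'   `b` must be the second aligned string).
#' @param b second aligned string when `aln` is a plain string.
#' @return object of class `"divergence_result"`: list with `P`, `Q`,
#'   `d_K2P`, `pid`, `transitions`, `transversions`, `comparable_sites`,
#'   `saturated`.
#' @export
#' @examples
#' a <- paste(rep("A", 100), collapse = "")
#' b <- paste(c(rep("G", 10), rep("A", 90)), collapse = "")
#' k2p(a, b)$d_K2P   # -0.5 * log(0.8)
k2p <- function(aln, b = NULL) {
  if (inherits(aln, "pairwise_alignment")) {
    sa <- aln$A; sb <- aln$B
  } else {
    stopifnot(is.character(aln), !is.null(b))
    sa <- toupper(aln); sb <- toupper(b)
  }
  st <- .pair_site_stats(sa, sb)
  if (st$comparable == 0L) stop("no comparable sites", call. = FALSE)
  P <- st$ts / st$comparable
  Q <- st$tv / st$comparable
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  saturated <- w1 <= 0 || w2 <= 0
  d <- if (saturated) NA_real_ else -0.5 * log(w1) - 0.25 * log(w2)
  structure(list(P = P, Q = Q, d_K2P = d,
                 pid = 100 * (1 - P - Q),
                 transitions = st$ts, transversions = st$tv,
                 comparable_sites = st$comparable, saturated = saturated),
            class = "divergence_result")
}

#' @export
print.divergence_result <- function(x, ...) {
  cat(sprintf(
    "<divergence_result> d_K2P = %s (P = %.4g, Q = %.4g, %d sites%s)\n",
    if (is.na(x$d_K2P)) "saturated" else sprintf("%.6g", x$d_K2P),
    x$P, x$Q, x$comparable_sites,
    if (x$saturated) ", saturated" else ""))
  invisible(x)
}

.aln_matrix <- function(seqs) {
  if (is.matrix(seqs)) return(seqs)
  seqs <- setNames(as.character(seqs), names(seqs))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: sequences differ in length", call. = FALSE)
  }
  m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

#' SNP count and density of a multiple alignment
#'
#' A column is a SNP when it holds at least two distinct bases among its
#' `{A,C,G,T}` entries (gaps and `N` ignored within the column). The
#' density denominator is the number of columns carrying at least two
#' comparable bases, so the metric is robust to ragged gap structure.
#'
#' @param seqs named character vector of equal-length aligned sequences
#'   (>= 2), or a character matrix (rows = sequences).
#' @return list with `snp_count`, `bp_per_snp` (`NA` when `snp_count` is
#'   0), `columns_compared`.
#' @export
snp_density <- function(seqs) {
  m <- .aln_matrix(seqs)
  if (nrow(m) < 2L) stop("need at least two sequences", call. = FALSE)
  base <- m %in% DNA_BASES
  dim(base) <- dim(m)
  n_base <- colSums(base)
  comparable_cols <- n_base >= 2L
  variable <- vapply(which(comparable_cols), function(j) {
    length(unique(m[base[, j], j])) >= 2L
  }, logical(1))
  snp_count <- sum(variable)
  list(snp_count = snp_count,
       bp_per_snp = if (snp_count > 0) sum(comparable_cols) / snp_count
                    else NA_real_,
       columns_compared = sum(comparable_cols))
}

#' Percent identity matrix
#'
#' Pairwise percent identity (identical comparable columns / comparable
#' columns x 100) with pairwise deletion of gaps and `N`; the diagonal is
#' 100.
#'
#' @param seqs named character vector of equal-length aligned sequences
#'   (>= 2).
#' @return symmetric numeric matrix.
#' @export
percent_identity_matrix <- function(seqs) {
  m <- .aln_matrix(seqs)
  if (nrow(m) < 2L) stop("need at least two sequences", call. = FALSE)
  n <- nrow(m)
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  out <- matrix(100, n, n, dimnames = list(ids, ids))
  base <- m %in% DNA_BASES
  dim(base) <- dim(m)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- base[i, ] & base[j, ]
      pid <- if (any(ok)) 100 * mean(m[i, ok] == m[j, ok]) else NA_real_
      out[i, j] <- out[j, i] <- pid
    }
  }
  out
}

#' Per-gene divergence summary across a conspecific panel
#'
#' For each gene alignment: mean and standard deviation of K2P distance
#' over sequence pairs, plus SNP count and bp-per-SNP. The species-level
#' mean is unweighted across genes (each gene counts once). Pair mode
#' `"all_pairs"` (default) uses every pair; `"to_reference"` compares
#' every sequence to `reference` only.
#'
#' @param panels named list: gene name -> named character vector of
#'   equal-length aligned sequences.
#' @param species species label carried into the output.
#' @param mode `"all_pairs"` or `"to_reference"`.
#' @param reference sequence id used when `mode = "to_reference"`.
#' @return data frame (one row per gene) with attributes
#'   `species_mean_k2p`, `species_mean_bp_per_snp`, `species`,
#'   `gap_policy`.
#' @export
gene_panel_summary <- function(panels, species = "",
                               mode = c("all_pairs", "to_reference"),
                               reference = NULL) {
  mode <- match.arg(mode)
  rows <- lapply(names(panels), function(g) {
    seqs <- panels[[g]]
    if (length(seqs) < 2L) {
      warning(sprintf("gene '%s' has fewer than 2 sequences; skipped", g),
              call. = FALSE)
      return(NULL)
    }
    ids <- names(seqs)
    prs <- if (mode == "all_pairs") {
      utils::combn(seq_along(seqs), 2L, simplify = FALSE)
    } else {
      ref <- match(reference, ids)
      if (is.na(ref)) stop(sprintf("reference '%s' absent from gene '%s'",
                                   reference, g), call. = FALSE)
      lapply(setdiff(seq_along(seqs), ref), function(i) c(ref, i))
    }
    ds <- vapply(prs, function(p) k2p(seqs[[p[1]]], seqs[[p[2]]])$d_K2P,
                 numeric(1))
    sat <- sum(is.na(ds))
    sd_d <- if (sum(!is.na(ds)) > 1L) sd(ds, na.rm = TRUE) else NA_real_
    dens <- snp_density(seqs)
    data.frame(gene = g, n_seq = length(seqs), n_pairs = length(prs),
               mean_k2p = mean(ds, na.rm = TRUE), sd_k2p = sd_d,
               saturated_pairs = sat,
               snp_count = dens$snp_count, bp_per_snp = dens$bp_per_snp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no gene had two or more sequences", call. = FALSE)
  rownames(out) <- NULL
  attr(out, "species") <- species
  attr(out, "species_mean_k2p") <- mean(out$mean_k2p, na.rm = TRUE)
  attr(out, "species_mean_bp_per_snp") <- mean(out$bp_per_snp, na.rm = TRUE)
  attr(out, "gap_policy") <- "pairwise deletion of gap/N columns"
  out
}
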