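#' @name phylogeny
#' @title Concatenated-PCG distance phylogeny
#' @description Concatenation of the 13 protein-coding genes into a
#'   supermatrix, Kimura two-parameter distance matrices, a natively
#'   implemented Saitou-Nei neighbor-joining tree with nonparametric
#'   bootstrap support, and exports (Newick, FASTA/relaxed-PHYLIP
#'   supermatrix, partition table) for external likelihood or Bayesian
#'   tools. Trees are unrooted; an optional outgroup roots for display
#'   only.
NULL

#' Concatenate protein-coding genes into a supermatrix
#'
#' Genes are concatenated in the canonical genome order
#' `nad2, cox1, cox2, atp8, atp6, cox3, nad3, nad5, nad4, nad4L, nad6,
#' cytb, nad1`. Input is either a named list of per-gene alignments
#' (gene -> named character vector, equal lengths within a gene) or a
#' list of [mitogenome] records (genes are extracted; all records must
#' yield equal gene lengths, e.g. simulator output). Taxa missing from
#' any gene are dropped with a warning; duplicated taxon ids are an
#' error.
#'
#' @param x per-gene alignments or a list of mitogenome records.
#' @param genes gene names to use, default the 13 PCGs present in `x`.
#' @return object of class `"supermatrix"`: list with `matrix` (named
#'   character vector of concatenated rows), `taxa`, `partitions` (data
#'   frame `gene`, `start`, `end`).
#' @export
concatenate_pcgs <- function(x, genes = NULL) {
  if (length(x) && inherits(x[[1]], "mitogenome")) {
    ids <- vapply(x, `[[`, character(1), "id")
    if (anyDuplicated(ids)) stop("duplicated taxon id", call. = FALSE)
    gene_names <- if (is.null(genes)) PCG_ORDER else genes
    x <- lapply(setNames(gene_names, gene_names), function(g) {
      vapply(setNames(x, ids), function(rec) {
        if (!g %in% rec$features$name) NA_character_
        else extract_gene(rec, g)
      }, character(1))
    })
  }
  stopifnot(is.list(x), !is.null(names(x)))
  # default scope is the 13 PCGs; other features only on request
  order_known <- intersect(PCG_ORDER, names(x))
  gene_names <- if (is.null(genes)) {
    if (length(order_known)) order_known else names(x)
  } else genes
  x <- x[gene_names]
  taxa <- Reduce(union, lapply(x, names))
  if (anyDuplicated(taxa)) stop("duplicated taxon id", call. = FALSE)
  keep <- taxa
  for (g in gene_names) {
    present <- names(x[[g]])[!is.na(x[[g]])]
    keep <- intersect(keep, present)
  }
  dropped <- setdiff(taxa, keep)
  if (length(dropped)) {
    warning(sprintf("taxa missing from some gene(s) dropped: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  }
  if (!length(keep)) stop("no taxon present in every gene", call. = FALSE)
  widths <- vapply(x, function(g) {
    w <- unique(nchar(g[keep]))
    if (length(w) != 1L) stop("ragged gene alignment", call. = FALSE)
    w
  }, integer(1))
  ends <- cumsum(widths)
  partitions <- data.frame(gene = gene_names,
                           start = c(1L, head(ends, -1L) + 1L),
                           end = ends, stringsAsFactors = FALSE)
  rows <- vapply(keep, function(tx) {
    paste(vapply(x, function(g) g[[tx]], character(1)), collapse = "")
  }, character(1))
  structure(list(matrix = rows, taxa = keep, partitions = partitions),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa x %d columns, %d partitions\n",
              length(x$taxa), nchar(x$matrix[[1]]), nrow(x$partitions)))
  invisible(x)
}

#' Slice one gene back out of a supermatrix
#'
#' @param sm a `"supermatrix"`.
#' @param gene gene name present in `sm$partitions`.
#' @return named character vector, the gene's alignment.
#' @export
extract_partition <- function(sm, gene) {
  p <- sm$partitions[sm$partitions$gene == gene, ]
  if (nrow(p) != 1L) stop(sprintf("no partition '%s'", gene), call. = FALSE)
  vapply(sm$matrix, substr, character(1), p$start, p$end)
}

#' Pairwise K2P distance matrix
#'
#' @param seqs named character vector of equal-length aligned sequences,
#'   or a `"supermatrix"`.
#' @return symmetric numeric matrix of K2P distances (`NA` marks
#'   saturated pairs), zero diagonal.
#' @export
k2p_matrix <- function(seqs) {
  if (inherits(seqs, "supermatrix")) seqs <- seqs$matrix
  m <- .aln_matrix(seqs)
  n <- nrow(m)
  ids <- rownames(m)
  base <- m %in% DNA_BASES
  dim(base) <- dim(m)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- base[i, ] & base[j, ]
      va <- m[i, ok]; vb <- m[j, ok]
      diff <- va != vb
      ts <- sum(paste0(va[diff], vb[diff]) %in% .TS_PAIRS)
      P <- ts / length(va); Q <- (sum(diff) - ts) / length(va)
      w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
      D[i, j] <- D[j, i] <-
        if (w1 <= 0 || w2 <= 0) NA_real_
        else -0.5 * log(w1) - 0.25 * log(w2)
    }
  }
  D
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Native implementation of the agglomerative neighbor-joining algorithm.
#' Ties in the Q criterion are broken deterministically by the smallest
#' taxon-index pair (row-major over the active list, original taxa
#' first). Negative branch-length estimates are clamped to 0 with the
#' deficit transferred to the sister edge, so path lengths through each
#' join are preserved.
#'
#' @param D symmetric numeric matrix with zero diagonal, `n >= 3` taxa.
#' @return an unrooted `ape::phylo` tree.
#' @export
#' @examples
#' D <- matrix(c(0,3,5,6, 3,0,6,7, 5,6,0,7, 6,7,7,0), 4, 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' nj_tree(D)
nj_tree <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (any(is.na(D)) || any(!is.finite(D))) {
    stop("distance matrix contains NA/NaN (saturated pairs?)",
         call. = FALSE)
  }
  if (any(D < 0)) stop("negative distances", call. = FALSE)
  if (any(abs(D - t(D)) > 1e-12) || any(diag(D) != 0)) {
    stop("distance matrix must be symmetric with zero diagonal",
         call. = FALSE)
  }
  labs <- rownames(D)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  sub <- labs                      # newick fragment per active node
  active <- D
  while (nrow(active) > 3L) {
    k <- nrow(active)
    r <- rowSums(active)
    Qm <- (k - 2) * active - outer(r, r, "+")
    diag(Qm) <- Inf
    # smallest index pair among ties, row-major upper triangle
    best <- which(Qm == min(Qm[upper.tri(Qm)]), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    dij <- active[i, j]
    vi <- dij / 2 + (r[i] - r[j]) / (2 * (k - 2))
    vj <- dij - vi
    if (vi < 0) { vj <- dij; vi <- 0 }
    if (vj < 0) { vi <- dij; vj <- 0 }
    du <- (active[i, ] + active[j, ] - dij) / 2
    du <- du[-c(i, j)]
    newsub <- sprintf("(%s:%s,%s:%s)", sub[i], fmt(vi), sub[j], fmt(vj))
    sub <- c(sub[-c(i, j)], newsub)
    active <- rbind(cbind(active[-c(i, j), -c(i, j), drop = FALSE], du),
                    c(du, 0))
    m <- nrow(active)
    rownames(active)[m] <- colnames(active)[m] <- sprintf("u%d", m)
  }
  d12 <- active[1, 2]; d13 <- active[1, 3]; d23 <- active[2, 3]
  v1 <- (d12 + d13 - d23) / 2
  v2 <- (d12 + d23 - d13) / 2
  v3 <- (d13 + d23 - d12) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", sub[1], fmt(v1), sub[2], fmt(v2),
                 sub[3], fmt(v3))
  ape::read.tree(text = txt)
}

.rep_seeds <- function(seed, n) {
  # one master seed spawns a stable stream of per-replicate seeds, so a
  # larger replicate count extends rather than reshuffles earlier ones
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

.resample_columns <- function(rows, idx) {
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  out <- apply(m[, idx, drop = FALSE], 1L, paste, collapse = "")
  names(out) <- names(rows)
  out
}

#' Bootstrap support for the neighbor-joining tree
#'
#' Columns of the supermatrix are resampled with replacement; each
#' replicate gets a K2P distance matrix and an NJ tree; the support of
#' each internal bipartition of the point-estimate tree is the percentage
#' of successful replicates containing it. Replicates whose distance
#' matrix saturates are skipped and counted.
#'
#' @param sm a `"supermatrix"` (or named character vector of equal-length
#'   aligned sequences).
#' @param n_replicates number of bootstrap replicates (>= 1).
#' @param seed master RNG seed; replicate streams derive from it.
#' @param outgroup optional taxon id used to root the returned tree for
#'   display.
#' @return list with `tree` (point-estimate `phylo`, `node.label` holding
#'   integer percent supports), `supports`, `n_ok`, `n_skipped`,
#'   `replicates` (the replicate trees).
#' @export
bootstrap_nj <- function(sm, n_replicates = 100L, seed = 1L,
                         outgroup = NULL) {
  stopifnot(n_replicates >= 1L)
  rows <- if (inherits(sm, "supermatrix")) sm$matrix else sm
  D <- k2p_matrix(rows)
  if (any(is.na(D))) stop("point-estimate distances saturated",
                          call. = FALSE)
  point <- nj_tree(D)
  ncol_aln <- nchar(rows[[1]])
  seeds <- .rep_seeds(seed, n_replicates)
  trees <- vector("list", n_replicates)
  n_skipped <- 0L
  for (rpl in seq_len(n_replicates)) {
    set.seed(seeds[rpl])
    idx <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
    Db <- k2p_matrix(.resample_columns(rows, idx))
    if (any(is.na(Db))) { n_skipped <- n_skipped + 1L; next }
    trees[[rpl]] <- nj_tree(Db)
  }
  trees <- trees[!vapply(trees, is.null, logical(1))]
  n_ok <- length(trees)
  if (n_ok == 0L) stop("all bootstrap replicates saturated", call. = FALSE)
  class(trees) <- "multiPhylo"
  counts <- ape::prop.clades(point, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supports <- round(100 * counts / n_ok)
  point$node.label <- as.character(supports)
  point$node.label[1] <- ""         # root of the unrooted representation
  out_tree <- point
  if (!is.null(outgroup)) {
    out_tree <- ape::root(point, outgroup = outgroup, resolve.root = FALSE,
                          edgelabel = TRUE)
  }
  list(tree = out_tree, supports = supports, n_ok = n_ok,
       n_skipped = n_skipped, replicates = trees)
}

#' Bootstrap support of one bipartition
#'
#' Percentage of replicate trees in which `taxa` form one side of an
#' internal bipartition (i.e. the group is monophyletic on the unrooted
#' tree).
#'
#' @param replicates list of `phylo` trees (e.g. from [bootstrap_nj()]).
#' @param taxa character vector, one side of the split.
#' @return percent in `[0, 100]`.
#' @export
split_support <- function(replicates, taxa) {
  has_split <- vapply(replicates, function(tr) {
    is_monophyletic_unrooted(tr, taxa)
  }, logical(1))
  100 * mean(has_split)
}

#' Test unrooted monophyly of a taxon set
#'
#' `TRUE` when `taxa` vs the rest is a bipartition of the unrooted tree.
#'
#' @param tree a `phylo`.
#' @param taxa character vector of tip labels.
#' @return logical scalar.
#' @export
is_monophyletic_unrooted <- function(tree, taxa) {
  tips <- tree$tip.label
  taxa <- intersect(taxa, tips)
  if (length(taxa) <= 1L || length(taxa) >= length(tips) - 1L) return(TRUE)
  bp <- ape::prop.part(tree)
  labs <- attr(bp, "labels")
  want <- sort(match(taxa, labs))
  comp <- sort(setdiff(seq_along(labs), want))
  any(vapply(bp, function(p) identical(sort(p), want) ||
                              identical(sort(p), comp), logical(1)))
}

#' Write a tree to a Newick file
#'
#' Branch lengths and integer support labels are preserved;
#' `ape::read.tree` parses the file back to an isomorphic tree.
#'
#' @param tree a `phylo`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Export a supermatrix for external phylogenetics tools
#'
#' Writes aligned FASTA, relaxed PHYLIP and a partition TSV
#' (`gene`, `start`, `end`) so maximum-likelihood or Bayesian analyses
#' can be reproduced outside this package.
#'
#' @param sm a `"supermatrix"`.
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @return named character vector of the three paths, invisibly.
#' @export
write_supermatrix <- function(sm, dir, stem = "supermatrix") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(stem, ".fasta"))
  phy <- file.path(dir, paste0(stem, ".phy"))
  parts <- file.path(dir, paste0(stem, ".partitions.tsv"))
  write_fasta(sm$matrix, fa)
  con <- file(phy, "w")
  writeLines(sprintf("%d %d", length(sm$taxa), nchar(sm$matrix[[1]])), con)
  writeLines(sprintf("%s  %s", names(sm$matrix), unname(sm$matrix)), con)
  close(con)
  write.table(sm$partitions, parts, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fasta = fa, phylip = phy, partitions = parts))
}
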