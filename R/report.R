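#' @name report
#' @title Pipeline orchestration and summary artifacts
#' @description High-level commands that run the characterization,
#'   divergence and phylogeny stages end to end and render their summary
#'   tables (annotation-style gene table, composition, RSCU, per-gene
#'   divergence, identity matrix, tree files). Every numeric table gets a
#'   machine-readable JSON twin and every output directory exactly one
#'   JSON run manifest, so deterministic stages can be re-run from the
#'   manifest alone. A thin command-line wrapper with subcommands
#'   (`characterize`, `divergence`, `phylo`, `simulate`, `identity`)
#'   ships in `inst/scripts/mitocomp.R`.
NULL

.write_twin <- function(df, dir, stem) {
  tsv <- file.path(dir, paste0(stem, ".tsv"))
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(df, file.path(dir, paste0(stem, ".json")),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(tsv)
}

#' Write the run manifest of an output directory
#'
#' Records command, parameters, input digests (md5), package version,
#' seeds and a timestamp; deterministic stages are fully re-runnable from
#' it. Exactly one manifest is written per output directory.
#'
#' @param dir output directory.
#' @param command command name.
#' @param parameters named list of parameters (seeds included).
#' @param inputs character vector of input file paths (digested).
#' @return the manifest path, invisibly.
#' @export
run_manifest <- function(dir, command, parameters = list(),
                         inputs = character()) {
  digests <- if (length(inputs)) {
    as.list(setNames(unname(md5sum(inputs)), basename(inputs)))
  } else NULL
  manifest <- list(command = command, parameters = parameters,
                   input_md5 = digests,
                   tool = "mitocomp",
                   version = as.character(packageVersion("mitocomp")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Characterize one annotated mitogenome
#'
#' Emits the annotation-style gene table (sizes from coordinates,
#' intergenic spacing recomputed as `next.start - prev.end - 1`) and,
#' when the record carries a sequence, the composition report, per-gene
#' and pooled RSCU tables and the start/stop classification. A record
#' without PCGs, or without a sequence, yields the gene table plus a
#' warning list in the returned object.
#'
#' @param record a [mitogenome] record.
#' @param outdir output directory (created).
#' @param code_table_id NCBI translation table number.
#' @param inputs optional paths digested into the manifest.
#' @return list with `gene_table`, `pcg_extent`, `n_functional_genes`,
#'   and (sequence permitting) `composition`, `rscu`, `start_stop`;
#'   `warnings` collects skipped stages.
#' @export
characterize <- function(record, outdir, code_table_id = 5,
                         inputs = character()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  f <- record$features
  gene_table <- data.frame(
    name = f$name, category = f$category, strand = f$strand,
    start = f$start, end = f$end, size = f$size,
    intergenic = intergenic_spacing(record),
    start_codon = f$start_codon, stop_codon = f$stop_codon,
    anticodon = f$anticodon, stringsAsFactors = FALSE)
  .write_twin(gene_table, outdir, "gene_table")
  warns <- character()
  out <- list(
    gene_table = gene_table,
    pcg_extent = sum(f$size[f$category == "PCG"]),
    n_functional_genes = sum(f$category %in% c("PCG", "tRNA", "rRNA")),
    genome_length = record$length)
  if (!is.null(record$sequence)) {
    out$composition <- composition_report(record)
    .write_twin(out$composition, outdir, "composition")
    if (any(f$category == "PCG")) {
      rs <- rscu_report(record, code_table_id)
      .write_twin(rs$per_gene, outdir, "rscu_per_gene")
      .write_twin(rs$pooled, outdir, "rscu_pooled")
      out$rscu <- rs
      out$start_stop <- start_stop_table(record, code_table_id)
      .write_twin(out$start_stop, outdir, "start_stop")
    } else {
      warns <- c(warns, "no PCG features: RSCU and start/stop skipped")
    }
  } else {
    warns <- c(warns,
               "record carries no sequence: composition/RSCU skipped")
  }
  out$warnings <- warns
  for (w in warns) warning(w, call. = FALSE)
  run_manifest(outdir, "characterize",
               parameters = list(id = record$id,
                                 code_table_id = code_table_id),
               inputs = inputs)
  invisible(out)
}

#' Per-gene divergence table for a conspecific panel
#'
#' Runs [gene_panel_summary()] over per-gene alignments (a
#' `"conspecific_panel"`, a named list, or a directory of aligned
#' per-gene FASTA files) and writes the per-gene K2P / SNP-density table
#' plus its species-mean row.
#'
#' @param panel panel input (see description).
#' @param species species label.
#' @param outdir output directory, or `NULL` to skip writing.
#' @param genes restrict to these genes (default: 13 PCGs + `rrnS` +
#'   `rrnL` when present).
#' @param ... passed to [gene_panel_summary()].
#' @return the summary data frame (attributes carry species means).
#' @export
divergence_table <- function(panel, species = "", outdir = NULL,
                             genes = NULL, ...) {
  panels <- if (inherits(panel, "conspecific_panel")) {
    panel$gene_alignments
  } else if (is.character(panel) && length(panel) == 1L &&
             dir.exists(panel)) {
    files <- list.files(panel, pattern = "\\.(fa|fasta)$",
                        full.names = TRUE)
    setNames(lapply(files, read_fasta),
             file_path_sans_ext(basename(files)))
  } else panel
  if (is.null(genes)) {
    genes <- intersect(c(PCG_ORDER, "rrnS", "rrnL"), names(panels))
    if (!length(genes)) genes <- names(panels)
  }
  out <- gene_panel_summary(panels[genes], species = species, ...)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    printable <- out
    num <- vapply(printable, is.numeric, logical(1))
    printable[num] <- lapply(printable[num], round, digits = 3)
    mean_row <- printable[1, ]
    mean_row[] <- NA
    mean_row$gene <- sprintf("mean (%s)", species)
    mean_row$mean_k2p <- round(attr(out, "species_mean_k2p"), 3)
    mean_row$bp_per_snp <- round(attr(out, "species_mean_bp_per_snp"), 3)
    .write_twin(rbind(printable, mean_row), outdir, "divergence")
    run_manifest(outdir, "divergence",
                 parameters = list(species = species, genes = genes))
  }
  out
}

#' Distance phylogeny pipeline for a taxon panel
#'
#' Concatenates the protein-coding genes, computes the K2P distance
#' matrix, builds the NJ tree with bootstrap supports, and writes the
#' Newick tree, the supermatrix exports (FASTA, relaxed PHYLIP,
#' partition table) and the percent-identity matrix of the concatenated
#' sequences.
#'
#' @param x per-gene alignments, list of [mitogenome] records, or a
#'   `"conspecific_panel"`.
#' @param outdir output directory.
#' @param n_replicates bootstrap replicates.
#' @param seed master bootstrap seed.
#' @param outgroup optional taxon id for display rooting.
#' @return list with `supermatrix`, `distances`, `bootstrap` (see
#'   [bootstrap_nj()]), `identity`.
#' @export
phylo_pipeline <- function(x, outdir = NULL, n_replicates = 100L,
                           seed = 1L, outgroup = NULL) {
  if (inherits(x, "conspecific_panel")) x <- x$gene_alignments
  sm <- concatenate_pcgs(x)
  if (length(sm$taxa) < 3L) stop("need at least 3 taxa", call. = FALSE)
  D <- k2p_matrix(sm)
  bs <- bootstrap_nj(sm, n_replicates = n_replicates, seed = seed,
                     outgroup = outgroup)
  idm <- percent_identity_matrix(sm$matrix)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_newick(bs$tree, file.path(outdir, "nj_tree.nwk"))
    write_supermatrix(sm, outdir)
    write.table(data.frame(taxon = rownames(idm), round(idm, 3),
                           check.names = FALSE),
                file.path(outdir, "identity_matrix.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
    run_manifest(outdir, "phylo",
                 parameters = list(n_replicates = n_replicates,
                                   seed = seed,
                                   outgroup = outgroup,
                                   n_taxa = length(sm$taxa)))
  }
  list(supermatrix = sm, distances = D, bootstrap = bs, identity = idm)
}
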