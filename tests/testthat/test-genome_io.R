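test_that("shipped annotation fixtures reproduce the published gene inventory", {
  aeg <- fixture_record("aegypti")
  alb <- fixture_record("albopictus")
  for (rec in list(aeg, alb)) {
    expect_equal(nrow(rec$features), 38L)
    expect_equal(sum(rec$features$category %in% c("PCG", "tRNA", "rRNA")),
                 37L)
    expect_equal(table(rec$features$category)[["PCG"]], 13L)
    expect_equal(table(rec$features$category)[["tRNA"]], 22L)
    expect_equal(sum(rec$features$category == "CR"), 1L)
  }
  expect_equal(aeg$length, 16662L)
  expect_equal(alb$length, 16585L)
  expect_equal(aeg$features$size[aeg$features$name == "CR"], 1721L)
  expect_equal(alb$features$size[alb$features$name == "CR"], 1694L)
  expect_equal(sum(aeg$features$size[aeg$features$category == "PCG"]), 11191L)
  expect_equal(sum(alb$features$size[alb$features$category == "PCG"]), 11223L)
})

test_that("feature sizes honour origin wrap on circular genomes", {
  expect_equal(feature_size(16600L, 50L, 16662L), 113L)
  expect_equal(feature_size(14942L, 16662L, 16662L), 1721L)
  feats <- data.frame(name = c("CR", "wrapper"), strand = "+",
                      start = c(14942L, 16600L), end = c(16662L, 50L))
  rec <- mitogenome("x", features = feats, circular = TRUE, length = 16662L)
  expect_equal(rec$features$size[rec$features$name == "wrapper"], 113L)
  expect_error(
    mitogenome("x", features = feats, circular = FALSE, length = 16662L),
    "circular")
})

test_that("size column is cross-checked against coordinates and coordinates win", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("name\tstrand\tstart\tend\tsize",
               "geneA\t+\t10\t39\t30",
               "geneB\t+\t50\t100\t40"), tf)
  expect_warning(rec <- read_feature_table(tf), "coordinates win")
  expect_equal(rec$features$size[rec$features$name == "geneB"], 51L)
  # duplicated names are an error
  writeLines(c("name\tstrand\tstart\tend",
               "geneA\t+\t10\t39", "geneA\t+\t50\t100"), tf)
  expect_error(read_feature_table(tf), "duplicated")
  # start > end is only legal on circular records
  writeLines(c("name\tstrand\tstart\tend",
               "geneA\t+\t100\t10"), tf)
  expect_error(read_feature_table(tf, circular = FALSE), "non-circular")
})

test_that("gene extraction respects strand and circular topology", {
  rec <- mitogenome("m", sequence = "ATGCCC",
                    features = data.frame(name = "g", strand = "+",
                                          start = 1L, end = 3L))
  expect_equal(extract_gene(rec, "g"), "ATG")
  rec$features$strand <- "-"
  expect_equal(extract_gene(rec, "g"), "CAT")
  # wrap: tail then head, then orientation
  wrap <- mitogenome("m2", sequence = "AAAATTGGCC",
                     features = data.frame(name = "w", strand = "+",
                                           start = 9L, end = 2L))
  expect_equal(extract_gene(wrap, "w"), "CCAA")
  wrap$features$strand <- "-"
  expect_equal(extract_gene(wrap, "w"), "TTGG")
  expect_error(extract_gene(mitogenome("m3", sequence = "ACGT"), "nope"),
               "no feature")
})

test_that("reverse-strand extraction is the reverse complement of the flipped feature", {
  set.seed(11)
  for (i in 1:20) {
    L <- sample(50:200, 1)
    s <- random_dna(L)
    st <- sample.int(L, 1); en <- sample.int(L, 1)  # may wrap
    rec <- mitogenome("r", sequence = s,
                      features = data.frame(name = c("fwd", "rev"),
                                            strand = c("+", "-"),
                                            start = st, end = en))
    expect_equal(extract_gene(rec, "rev"),
                 revcomp(extract_gene(rec, "fwd")))
  }
})

test_that("FASTA writing round-trips and rejects degenerate input", {
  seqs <- c(s1 = "ACGTACGTACGT", s2 = paste(rep("AT", 60), collapse = ""))
  fa <- tempfile(fileext = ".fasta")
  write_fasta(seqs, fa)
  lines <- readLines(fa)
  expect_equal(sum(startsWith(lines, ">")), 2L)
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 70L))
  expect_equal(read_fasta(fa), seqs)
  expect_error(write_fasta(character(0), fa), "no sequences")
  writeLines(c(">amb", "ACGR"), fa)
  expect_error(read_fasta(fa), "outside")
})

test_that("feature tables round-trip coordinates exactly", {
  anc <- cached_ancestor()
  tf <- tempfile(fileext = ".tsv")
  write_feature_table(anc, tf)
  back <- read_feature_table(tf, sequence = anc$sequence)
  expect_identical(back$features$start, anc$features$start)
  expect_identical(back$features$end, anc$features$end)
  expect_identical(back$features$name, anc$features$name)
})

test_that("GenBank flat files parse with synonym normalization", {
  gb <- c(
    "LOCUS       TEST0001 40 bp    DNA     circular   UNA 01-JAN-2000",
    "DEFINITION  toy record.",
    "ACCESSION   TEST0001",
    "SOURCE      .",
    "  ORGANISM  Aedes toyensis",
    "FEATURES             Location/Qualifiers",
    "     source          1..40",
    "     CDS             2..13",
    "                     /gene=\"ND5\"",
    "     CDS             complement(14..25)",
    "                     /gene=\"COI\"",
    "     tRNA            26..33",
    "                     /product=\"tRNA-Ile\"",
    "     misc_feature    join(38..40,1..1)",
    "                     /note=\"control region\"",
    "ORIGIN",
    "        1 atggctaaat aaatgtttag ccattaatcg gcctaaatta",
    "//")
  tf <- tempfile(fileext = ".gb")
  writeLines(gb, tf)
  rec <- read_genbank(tf)
  expect_s3_class(rec, "mitogenome")
  expect_equal(rec$length, 40L)
  expect_true(rec$circular)
  expect_equal(rec$species, "Aedes toyensis")
  expect_setequal(rec$features$name, c("nad5", "cox1", "trnI", "CR"))
  cr <- rec$features[rec$features$name == "CR", ]
  expect_equal(c(cr$start, cr$end, cr$size), c(38L, 1L, 4L))
  expect_equal(rec$features$strand[rec$features$name == "cox1"], "-")
  # a record with no features is still valid
  writeLines(gb[-(6:15)], tf)
  expect_equal(nrow(read_genbank(tf)$features), 0L)
  # a record without ORIGIN is not
  writeLines(gb[1:15], tf)
  expect_error(read_genbank(tf), "ORIGIN")
})

test_that("simulator GenBank output round-trips to identical coordinates", {
  anc <- cached_ancestor()
  tf <- tempfile(fileext = ".gb")
  write_genbank(anc, tf)
  back <- read_genbank(tf)
  expect_equal(back$length, 16662L)
  expect_equal(nrow(back$features), 38L)
  expect_identical(back$features$start, anc$features$start)
  expect_identical(back$features$end, anc$features$end)
  expect_identical(back$sequence, anc$sequence)
})

test_that("unknown gene names pass through with a warning", {
  expect_warning(out <- normalize_gene_name("mystery7"), "unrecognized")
  expect_equal(out, "mystery7")
  expect_silent(normalize_gene_name(c("ND4L", "tRNA-Ser", "16S", "cytb")))
})

test_that("intergenic spacing is recomputed from coordinates", {
  aeg <- fixture_record("aegypti")
  sp <- intergenic_spacing(aeg)
  f <- aeg$features
  expect_equal(sp[f$name == "trnQ"], 2L)     # 70 - 67 - 1
  expect_equal(sp[f$name == "trnM"], 49L)    # 188 - 138 - 1
  expect_equal(sp[f$name == "nad2"], 0L)     # abuts trnM
  expect_equal(sp[f$name == "atp6"], -7L)    # overlaps atp8
  expect_equal(sp[f$name == "trnI"], 0L)     # circular: CR ends at L
})
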