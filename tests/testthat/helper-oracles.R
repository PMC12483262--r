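# Independent oracles and shared fixtures for the test suite.

BASES <- c("A", "C", "G", "T")

random_dna <- function(n, prob = NULL) {
  paste(sample(BASES, n, replace = TRUE, prob = prob), collapse = "")
}

# Exhaustive global-alignment score by enumerating every monotone
# alignment path; affine gap of k residues costs open + k * ext.
# Deliberately independent of the package's dynamic-programming aligner.
brute_align_score <- function(a, b, match = 1, mismatch = -1,
                              open = 5, ext = 1) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  rec <- function(i, j, last) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, s + rec(i + 1L, j + 1L, "d"))
    }
    if (i <= n) {
      best <- max(best,
                  -(ext + if (last == "u") 0 else open) +
                    rec(i + 1L, j, "u"))
    }
    if (j <= m) {
      best <- max(best,
                  -(ext + if (last == "l") 0 else open) +
                    rec(i, j + 1L, "l"))
    }
    best
  }
  rec(1L, 1L, "none")
}

# Direct RSCU evaluation from a named count vector, straight from the
# defining formula.
slow_rscu <- function(counts, code_table_id = 5) {
  code <- Biostrings::getGeneticCode(as.character(code_table_id))
  sense <- names(code)[code != "*"]
  out <- setNames(rep(NA_real_, length(sense)), sense)
  for (cod in sense) {
    fam <- sense[code[sense] == code[[cod]]]
    tot <- sum(counts[fam])
    if (tot > 0) out[[cod]] <- counts[[cod]] / (tot / length(fam))
  }
  out
}

# K80 substitution probabilities after divergence d (independent copy of
# the closed form, used to compute simulation expectations).
k80_expect <- function(d, kappa) {
  beta <- 1 / (kappa + 2); alpha <- kappa * beta
  p_ts <- 0.25 + 0.25 * exp(-4 * beta * d) -
          0.5 * exp(-2 * (alpha + beta) * d)
  p_tv <- 2 * (0.25 - 0.25 * exp(-4 * beta * d))
  c(ts = p_ts, tv = p_tv, diff = p_ts + p_tv)
}

# shared slow-to-build fixtures, built once per run
.fixture_cache <- new.env(parent = emptyenv())

cached_ancestor <- function(seed = 42, at_bias = 0.79) {
  key <- sprintf("anc_%d_%g", seed, at_bias)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <-
      make_ancestor(sim_config(seed = seed, at_bias = at_bias))
  }
  .fixture_cache[[key]]
}

cached_panel <- function(n_taxa = 6, depth = 0.004, seed = 42) {
  key <- sprintf("panel_%d_%g_%d", n_taxa, depth, seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <-
      make_conspecific_panel(n_taxa, depth, sim_config(seed = seed))
  }
  .fixture_cache[[key]]
}
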