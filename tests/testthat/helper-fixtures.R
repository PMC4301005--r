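# Shared fixtures and independent oracles. Heavy objects are built once per
# session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small synthetic genome + corrupted draft used across module tests.
small_truth <- function() {
  cached("small_truth", function() {
    generate_genome(size = 8e5, n_operons = 4, seed = 101)
  })
}

small_profile <- function() {
  cr1_profile(n_plain_gaps = 2, rrna_only = 3, placeable = 3,
              n_runs_total = 30, relocation_size = 5e4,
              relocation_sep = 6e4)
}

small_draft <- function() {
  cached("small_draft", function() {
    corrupt_to_draft(small_truth(), small_profile(), seed = 102)
  })
}

# A gap amplicon containing one complete operon with unique flanks, plus
# the flanking "gap primer" footprints, built from the master genes.
operon_amplicon <- function(its_len = 500, flank = 300, seed = 7) {
  gt <- small_truth()
  genes <- gt$genes
  op <- gt$operons[gt$operons$strand == "+", ][1, ]
  op_seq <- substr(gt$genome, op$start + 1, op$end)
  set.seed(seed)
  left <- random_dna(flank, 0.5)
  right <- random_dna(flank, 0.5)
  paste0(left, op_seq, right)
}

# Brute-force hybridization-site oracle: explicit offset loop with IUPAC
# expansion on the primer side only; template ambiguity never matches.
oracle_sites <- function(template, primer, max_mismatch = 2,
                         three_prime_run = 3) {
  scan_strand <- function(tmpl, pat, strand) {
    n <- nchar(tmpl)
    L <- nchar(pat)
    pat_sets <- IUPAC_SETS[strsplit(pat, NULL)[[1]]]
    tmpl_chars <- strsplit(tmpl, NULL)[[1]]
    out <- list()
    if (n < L) return(out)
    for (s in 0:(n - L)) {
      mm <- 0L
      for (j in seq_len(L)) {
        tc <- tmpl_chars[s + j]
        if (!(tc %in% c("A", "C", "G", "T")) || !(tc %in% pat_sets[[j]])) {
          mm <- mm + 1L
        }
      }
      if (mm > max_mismatch) next
      idx <- if (strand == "+") (L - three_prime_run + 1):L else
        1:three_prime_run
      tp_ok <- all(vapply(idx, function(j) {
        tc <- tmpl_chars[s + j]
        tc %in% c("A", "C", "G", "T") && tc %in% pat_sets[[j]]
      }, TRUE))
      if (!tp_ok) next
      out[[length(out) + 1]] <- data.frame(start = s, end = s + L,
                                           strand = strand,
                                           mismatches = mm)
    }
    out
  }
  rows <- c(scan_strand(template, primer, "+"),
            scan_strand(template, revcomp(primer), "-"))
  if (length(rows) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), ]
}

# Brute-force N50: try every contig length as the answer.
oracle_n50 <- function(lens) {
  lens <- sort(lens, decreasing = TRUE)
  total <- sum(lens)
  for (i in seq_along(lens)) {
    if (sum(lens[1:i]) >= total / 2) return(lens[i])
  }
}

expect_tbl_cols <- function(tbl, cols) {
  expect_true(all(cols %in% names(tbl)),
              info = paste("missing:", paste(setdiff(cols, names(tbl)),
                                             collapse = ", ")))
}
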