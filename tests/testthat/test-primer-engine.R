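test_that("nearest-neighbor Tm behaves physically", {
  # GC-rich duplexes melt higher than AT-rich ones of the same length
  expect_gt(melting_temp(strrep("GC", 10)), melting_temp(strrep("AT", 10)))
  # a duplex and its reverse complement share one Tm
  p <- "AGAGTTTGATCCTGGCTCAG"
  expect_equal(melting_temp(p), melting_temp(revcomp(p)), tolerance = 1e-9)
  expect_error(melting_temp("ACGTACGTX"), "non-IUPAC")
  expect_error(melting_temp("ACGT"), "too short")
})

test_that("NN Tm of the U1 walk primer agrees with the Wallace rule", {
  u1 <- "TGGGATACCACCCTGATCGT" # A+T = 9, G+C = 11
  expect_equal(wallace_tm(u1), 2 * 9 + 4 * 11)
  expect_lt(abs(melting_temp(u1) - wallace_tm(u1)), 8)
})

test_that("degenerate positions take the minimum-Tm disambiguation", {
  # resolving Y/R to the weak A/T expansion can only lower Tm
  expect_lte(melting_temp("ACGTAYGTACRTACGTA"),
             melting_temp("ACGTACGTACGTACGTA"))
})

test_that("gc_content counts strong bases fully, ambiguity fractionally", {
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("AGAGTTTGATCCTGGCTCAG"), 50) # the 16S 8F primer
  expect_equal(gc_content("AT"), 0)
  expect_equal(gc_content("SS"), 100) # S = {C,G}
  expect_equal(gc_content("AR"), 25) # R contributes 1/2
  expect_equal(gc_content("NN"), 50)
})

test_that("find_primer_sites locates exact, degenerate and strand hits", {
  set.seed(500)
  bg <- random_dna(400)
  p <- "TGGGATACCACCCTGATCGT"
  tmpl <- paste0(substr(bg, 1, 100), p, substr(bg, 101, 400))
  s <- find_primer_sites(tmpl, p)
  expect_equal(nrow(s), 1)
  expect_equal(s$start, 100L)
  expect_equal(s$mismatches, 0L)
  expect_equal(s$strand, "+")

  # 127F degenerate codes expand: Y~T, R~A, V~G
  tmpl2 <- paste0(substr(bg, 1, 100), "CTGAATGGGAGAACC",
                  substr(bg, 101, 200))
  s2 <- find_primer_sites(tmpl2, "CYGAATGGGRVAACC")
  expect_equal(s2$mismatches, 0L)

  # reverse-complement hit reported on the minus strand
  tmpl3 <- paste0(substr(bg, 1, 100), revcomp(p), substr(bg, 101, 400))
  s3 <- find_primer_sites(tmpl3, p)
  expect_equal(s3$strand, "-")

  # three scattered mismatches defeat the budget of two
  pm <- p
  substr(pm, 2, 2) <- "C"
  substr(pm, 6, 6) <- "G"
  substr(pm, 10, 10) <- "C"
  expect_equal(nrow(find_primer_sites(tmpl, pm)), 0)
})

test_that("template N never confirms hybridization", {
  p <- "TGGGATACCACCCTGATCGT"
  left <- strrep("G", 50)
  mkt <- function(copy) paste0(left, copy, strrep("C", 50))
  # N at the primer 3' terminus kills the site
  c1 <- p
  substr(c1, 20, 20) <- "N"
  expect_equal(nrow(find_primer_sites(mkt(c1), p)), 0)
  # two interior Ns consume the whole mismatch budget; a third kills it
  c2 <- p
  substr(c2, 3, 3) <- "N"
  substr(c2, 7, 7) <- "N"
  expect_equal(find_primer_sites(mkt(c2), p)$mismatches, 2L)
  c3 <- c2
  substr(c3, 11, 11) <- "N"
  expect_equal(nrow(find_primer_sites(mkt(c3), p)), 0)
})

test_that("site search equals the brute-force oracle on random cases", {
  set.seed(501)
  primers <- c("ACGTRYSWACGTACGTAC", "TTGACCTGATCGTAGCTA",
               "CYGAATGGGRVAACC")
  for (i in 1:150) {
    tmpl <- random_dna(sample(60:160, 1), gc = runif(1, 0.3, 0.7))
    # occasionally plant a mutated copy and some Ns
    p <- sample(primers, 1)
    if (i %% 2 == 0) {
      at <- sample(1:(nchar(tmpl) - nchar(p)), 1)
      copy <- chartr("RYSWV", "ATCAG", p)
      if (i %% 4 == 0) substr(copy, 3, 3) <- "T"
      substr(tmpl, at, at + nchar(copy) - 1) <- copy
    }
    if (i %% 5 == 0) substr(tmpl, 10, 11) <- "NN"
    got <- find_primer_sites(tmpl, p)
    want <- oracle_sites(tmpl, p)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got$start, want$start)
      expect_equal(got$mismatches, want$mismatches)
      expect_equal(got$strand, want$strand)
    }
  }
})

test_that("reverse-complementing the template mirrors sites", {
  set.seed(502)
  tmpl <- random_dna(300)
  p <- "TGGGATACCACCCTGATCGT"
  tmpl <- paste0(substr(tmpl, 1, 120), p, substr(tmpl, 121, 300))
  fwd <- find_primer_sites(tmpl, p)
  rc <- find_primer_sites(revcomp(tmpl), p)
  expect_equal(nrow(fwd), nrow(rc))
  expect_equal(sort(nchar(tmpl) - fwd$end), sort(rc$start))
  expect_setequal(rc$strand, chartr("+-", "-+", fwd$strand))
})

test_that("simulate_pcr pairs convergent sites into products", {
  set.seed(503)
  bg <- random_dna(1000)
  f <- "TGGGATACCACCCTGATCGT"
  r <- "GTTTGGGCTAATCCGCGTTC"
  tmpl <- bg
  substr(tmpl, 101, 120) <- f
  substr(tmpl, 881, 900) <- revcomp(r)
  amp <- simulate_pcr(tmpl, f, r)
  expect_equal(nrow(amp), 1)
  expect_equal(amp$start, 100L)
  expect_equal(amp$end, 900L)
  expect_equal(amp$length, 800L)
  expect_equal(nchar(amp$product), 800L)

  # primer order must not matter
  amp2 <- simulate_pcr(tmpl, r, f)
  expect_equal(amp$start, amp2$start)
  expect_equal(amp$end, amp2$end)

  # both primers on the same strand yield no product
  tmpl_same <- bg
  substr(tmpl_same, 101, 120) <- f
  substr(tmpl_same, 881, 900) <- r
  expect_equal(nrow(simulate_pcr(tmpl_same, f, r)), 0)

  # two forward sites give two products
  tmpl_multi <- tmpl
  substr(tmpl_multi, 301, 320) <- f
  amp3 <- simulate_pcr(tmpl_multi, f, r)
  expect_equal(nrow(amp3), 2)
  expect_equal(sort(amp3$length), c(600L, 800L))

  # oversized products are suppressed
  expect_equal(nrow(simulate_pcr(tmpl, f, r, max_product = 500)), 0)
})

test_that("amplicon lengths survive template reverse complement", {
  set.seed(504)
  tmpl <- random_dna(800)
  f <- "TGGGATACCACCCTGATCGT"
  r <- "CCGTCACACCACGAGAGTTT"
  substr(tmpl, 51, 70) <- f
  substr(tmpl, 601, 620) <- revcomp(r)
  a1 <- simulate_pcr(tmpl, f, r)
  a2 <- simulate_pcr(revcomp(tmpl), f, r)
  expect_equal(sort(a1$length), sort(a2$length))
})

test_that("design_primer is deterministic and honours constraints", {
  set.seed(505)
  tmpl <- random_dna(1000, gc = 0.5)
  d1 <- design_primer(tmpl, window = c(100, 500))
  d2 <- design_primer(tmpl, window = c(100, 500))
  expect_equal(d1$status, "ok")
  expect_identical(d1, d2)
  expect_gte(d1$tm, 55)
  expect_lte(d1$tm, 65)
  expect_gte(d1$gc, 40)
  expect_lte(d1$gc, 60)
  expect_true(nchar(d1$seq) %in% 18:25)
  # re-checking the designed oligo finds exactly its one site
  expect_equal(nrow(find_primer_sites(tmpl, d1$seq)), 1)

  dpoly <- design_primer(strrep("A", 400), window = c(50, 350))
  expect_equal(dpoly$status, "undesignable")
  expect_match(dpoly$reason, "GC")

  # duplicating the window elsewhere in scope defeats uniqueness
  dup <- paste0(tmpl, substr(tmpl, 101, 500))
  ddup <- design_primer(dup, window = c(100, 500))
  expect_equal(ddup$status, "undesignable")
  expect_match(ddup$reason, "unique")
})

test_that("purity_check flags products of distant primer pairs", {
  set.seed(506)
  genome <- random_dna(5000)
  f <- design_primer(genome, window = c(1000, 1400))$seq
  r <- design_primer(genome, window = c(2000, 2400), direction = "rev")$seq
  pairs <- tibble::tibble(name = "distant", fwd = f, rev = r)
  on_genome <- purity_check(genome, pairs)
  expect_false(attr(on_genome, "pass"))
  clean <- purity_check(substr(genome, 3000, 4800), pairs)
  expect_true(attr(clean, "pass"))
  expect_true(attr(purity_check("", pairs), "pass")) # vacuous
})

test_that("primer tables round-trip and ship the universal set", {
  up <- universal_primers()
  expect_tbl_cols(up, c("name", "sequence", "gene", "direction"))
  expect_setequal(up$name, c("8F", "1492R", "127F", "2241R",
                             "U1", "U2", "U3", "U4"))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_primer_table(up, tf)
  expect_equal(read_primer_table(tf)$sequence, up$sequence)
  gp <- cr1_gap_primers()
  expect_equal(nrow(gp), 13)
  expect_true("4-13" %in% gp$gap)
})
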