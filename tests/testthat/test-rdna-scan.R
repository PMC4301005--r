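test_that("scan_contigs finds planted gene copies with correct metrics", {
  gt <- small_truth()
  g16 <- gt$genes$seq[gt$genes$gene == "16S"]
  set.seed(600)
  bg <- random_dna(6000)
  exact <- paste0(substr(bg, 1, 2000), g16, substr(bg, 2001, 6000))
  hits <- scan_contigs(as_contigs("c", exact), gt$genes)
  h16 <- hits[hits$gene == "16S", ]
  expect_equal(nrow(h16), 1)
  expect_equal(h16$identity, 100)
  expect_equal(h16$gene_fraction, 1, tolerance = 0.01)
  expect_equal(h16$start, 2000L, tolerance = 2)
  expect_equal(h16$strand, "+")

  # 5% seeded substitutions stay above the 90% identity floor
  set.seed(601)
  mut <- rdnafinish:::mutate_seq(g16, 0.05)
  tmpl <- paste0(substr(bg, 1, 2000), mut, substr(bg, 2001, 6000))
  hm <- scan_contigs(as_contigs("c", tmpl), gt$genes)
  hm <- hm[hm$gene == "16S", ]
  expect_equal(nrow(hm), 1)
  expect_gte(hm$identity, 90)

  # reverse-complemented copy reports the minus strand
  rcc <- paste0(substr(bg, 1, 2000), revcomp(g16), substr(bg, 2001, 6000))
  hr <- scan_contigs(as_contigs("c", rcc), gt$genes)
  expect_equal(hr$strand[hr$gene == "16S"], "-")
})

test_that("seeded scan agrees with a direct whole-contig alignment", {
  gt <- small_truth()
  g5 <- gt$genes$seq[gt$genes$gene == "5S"]
  set.seed(602)
  for (i in 1:5) {
    bg <- random_dna(3000)
    at <- sample(500:2500, 1)
    copy <- rdnafinish:::mutate_seq(g5, 0.03)
    tmpl <- paste0(substr(bg, 1, at), copy,
                   substr(bg, at + 1, 3000))
    hit <- scan_contigs(as_contigs("c", tmpl),
                        tibble::tibble(gene = "5S", seq = g5),
                        min_fragment = 80)
    # independent route: full dynamic-programming local alignment
    sm <- Biostrings::nucleotideSubstitutionMatrix(2, -3, baseOnly = FALSE)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(g5), Biostrings::DNAString(tmpl),
      type = "local", substitutionMatrix = sm,
      gapOpening = 5, gapExtension = 2)
    expect_equal(nrow(hit), 1)
    expect_equal(hit$start, BiocGenerics::start(Biostrings::subject(aln)) - 1L,
                 tolerance = 3)
    expect_equal(hit$end, BiocGenerics::end(Biostrings::subject(aln)),
                 tolerance = 3)
    expect_equal(hit$identity, Biostrings::pid(aln, type = "PID1"),
                 tolerance = 1)
  }
})

test_that("mask rule combines the size and coverage thresholds", {
  gt <- small_truth()
  g16 <- gt$genes$seq[gt$genes$gene == "16S"]
  set.seed(603)
  contigs <- as_contigs(
    c("rrna_short", "rrna_long", "mixed_short"),
    c(substr(g16, 1, 1500),                       # fully rDNA, < 2 kb
      paste0(g16, g16),                           # fully rDNA, >= 2 kb
      paste0(substr(g16, 1, 450), random_dna(1050)))) # 30% rDNA
  hits <- scan_contigs(contigs, gt$genes)
  m <- mask_rrna_contigs(contigs, hits)
  rep <- m$report
  expect_true(rep$masked[rep$id == "rrna_short"])
  expect_false(rep$masked[rep$id == "rrna_long"]) # fails the size rule
  expect_false(rep$masked[rep$id == "mixed_short"]) # fails coverage rule
  expect_setequal(m$contigs$id, c("rrna_long", "mixed_short"))
})

test_that("masking never removes a contig at or above the size threshold", {
  gt <- small_truth()
  g23 <- gt$genes$seq[gt$genes$gene == "23S"]
  contigs <- as_contigs("pure_rdna", substr(g23, 1, 2000))
  hits <- scan_contigs(contigs, gt$genes)
  m <- mask_rrna_contigs(contigs, hits)
  expect_false(any(m$report$masked))
})

test_that("contig ends are annotated within the end window", {
  contigs <- as_contigs(c("a", "b"), c(strrep("A", 10000), strrep("C", 9000)))
  hits <- tibble::tibble(
    contig_id = c("a", "a"), gene = c("16S", "23S"),
    start = c(0L, 4000L), end = c(800L, 5000L),
    strand = "+", identity = 99, gene_fraction = 0.5, aligned_bp = 800L)
  ends <- annotate_contig_ends(contigs, hits)
  expect_equal(nrow(ends), 4) # two ends per contig
  a5 <- ends[ends$contig_id == "a" & ends$end == "5p", ]
  expect_true(a5$annotated)
  expect_equal(a5$genes, "16S") # the interior 23S hit touches no end
  expect_false(any(ends$annotated[ends$contig_id == "b"]))
})

test_that("operon clustering groups by span and strand", {
  mk_hit <- function(gene, s, e, strand = "+", id = "g") {
    tibble::tibble(contig_id = id, gene = gene, start = s, end = e,
                   strand = strand, identity = 99, gene_fraction = 1,
                   aligned_bp = e - s)
  }
  hits <- dplyr::bind_rows(
    mk_hit("16S", 1000L, 2500L), mk_hit("23S", 3000L, 5900L),
    mk_hit("5S", 6000L, 6116L))
  ops <- cluster_operons(hits)
  expect_equal(nrow(ops), 1)
  expect_true(ops$complete)
  expect_equal(ops$start, 1000L)
  expect_equal(ops$end, 6116L)

  far <- dplyr::bind_rows(mk_hit("16S", 1000L, 2500L),
                          mk_hit("16S", 51000L, 52500L))
  expect_equal(nrow(cluster_operons(far)), 2)

  # opposite strands never share an operon
  mixed <- dplyr::bind_rows(mk_hit("16S", 1000L, 2500L),
                            mk_hit("23S", 3000L, 5900L, strand = "-"))
  ops2 <- cluster_operons(mixed)
  expect_equal(nrow(ops2), 2)
  expect_false(any(ops2$complete))
})

test_that("operon calls have disjoint spans per strand", {
  gt <- small_truth()
  hits <- scan_contigs(as_contigs("genome", gt$genome), gt$genes)
  ops <- cluster_operons(hits)
  expect_equal(nrow(ops), nrow(gt$operons))
  expect_true(all(ops$complete))
  for (s in c("+", "-")) {
    o <- ops[ops$strand == s, ]
    o <- o[order(o$start), ]
    if (nrow(o) > 1) expect_true(all(o$start[-1] >= o$end[-nrow(o)]))
  }
})

test_that("masking the small-fixture draft removes the planted rRNA contigs", {
  dt <- small_draft()
  gt <- small_truth()
  hits <- scan_contigs(dt$contigs, gt$genes)
  m <- mask_rrna_contigs(dt$contigs, hits)
  expect_setequal(m$report$id[m$report$masked], dt$rrna_only$contig_id)
  expect_equal(nrow(m$contigs), nrow(dt$contigs) - nrow(dt$rrna_only))
})
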