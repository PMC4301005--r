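# Seeded synthetic genomes and corrupted draft assemblies with full ground
# truth, emulating the defects that rDNA repeats inflict on short-read
# bacterial assemblies.

# sample one or `n` integers uniformly from [lo, hi], robust to lo == hi
sample_range <- function(lo, hi, n = 1) {
  lo + sample.int(hi - lo + 1, n, replace = TRUE) - 1L
}

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Random DNA sequence
#'
#' @param n Length in bp.
#' @param gc GC fraction (default 0.45).
#' @return Single DNA string.
#' @export
random_dna <- function(n, gc = 0.45) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Substitute bases at `rate` outside protected positions; substitutions
# always change the base.
mutate_seq <- function(seq, rate, protected = integer(0)) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, NULL)[[1]]
  idx <- which(stats::runif(length(chars)) < rate)
  idx <- setdiff(idx, protected)
  if (length(idx) == 0) return(seq)
  bases <- c("A", "C", "G", "T")
  chars[idx] <- vapply(chars[idx], function(b) {
    sample(setdiff(bases, b), 1)
  }, "")
  paste(chars, collapse = "")
}

plant <- function(seq, oligo, at) {
  # at: 0-based start
  paste0(substr(seq, 1, at), oligo,
         substr(seq, at + nchar(oligo) + 1, nchar(seq)))
}

# Fixed disambiguations of the degenerate universal primers used for the
# mutation-free footprints (Y->T, R->A, V->G, H->A).
.fp_127f <- "CTGAATGGGAGAACC"
.fp_2241r <- "ACCGCCCCAGTAAAACT"

# Footprint layout within the master genes (0-based starts).
.gene16_len <- 1550L
.gene23_len <- 2900L
.gene5_len <- 116L
.operon_spacer <- 30L

master_genes <- function(gc, primers) {
  pget <- function(nm) primers$sequence[match(nm, primers$name)]
  g16 <- random_dna(.gene16_len, gc)
  g16 <- plant(g16, pget("8F"), 10L)
  g16 <- plant(g16, revcomp(pget("U1")), 60L)
  g16 <- plant(g16, pget("U2"), 1440L)
  g16 <- plant(g16, revcomp(pget("1492R")), 1471L)
  fp16 <- c(11:30, 61:80, 1441:1460, 1472:1490) # 1-based protected
  g23 <- random_dna(.gene23_len, gc)
  g23 <- plant(g23, .fp_127f, 120L)
  g23 <- plant(g23, revcomp(pget("U3")), 160L)
  g23 <- plant(g23, revcomp(.fp_2241r), 2224L)
  g23 <- plant(g23, pget("U4"), 2790L)
  fp23 <- c(121:135, 161:180, 2225:2241, 2791:2810)
  g5 <- random_dna(.gene5_len, gc)
  list(g16 = g16, g23 = g23, g5 = g5, fp16 = fp16, fp23 = fp23)
}

#' Generate a synthetic genome with divergent rDNA operons
#'
#' A background genome at the given GC is seeded with `n_operons` copies of
#' one master rRNA operon (16S of 1550 bp, ITS of `its_range` bp, 23S of
#' 2900 bp, a 30 bp spacer and a 5S of 116 bp). Copies carry independent
#' substitutions at `divergence` plus ITS length jitter, but the universal
#' primer footprints (8F/1492R, 127F/2241R at their canonical gene offsets,
#' and U1-U4 at the gene boundaries) are kept mutation-free, so universal
#' primers always find their sites. Operon slots are quasi-regular with one
#' double-width span left free of operons (room for large-rearrangement
#' simulation). Fully deterministic given the seed.
#'
#' @param size Genome size in bp (default 6e6).
#' @param n_operons Number of operon copies (default 12).
#' @param divergence Per-base substitution rate between copies
#'   (default 0.02).
#' @param gc Background GC fraction (default 0.45).
#' @param its_range ITS length range in bp (default `c(400, 600)`).
#' @param seed Random seed (default 42).
#' @return Object of class `genome_truth`: list with `genome` (string),
#'   `operons` (tibble of per-copy coordinates and strand), `genes`
#'   (master gene table usable as scan consensus), `size`, `gc`, `seed`.
#' @export
generate_genome <- function(size = 6e6, n_operons = 12, divergence = 0.02,
                            gc = 0.45, its_range = c(400, 600), seed = 42) {
  primers <- universal_primers()
  max_operon <- .gene16_len + its_range[2] + .gene23_len + .operon_spacer +
    .gene5_len
  slot_w <- size / (n_operons + 2)
  if (slot_w < max_operon * 3) {
    stop("genome too small to host ", n_operons, " operons with spacing",
         call. = FALSE)
  }
  with_local_seed(seed, {
    genome <- random_dna(size, gc)
    mg <- master_genes(gc, primers)
    master_its <- random_dna(its_range[2], gc)
    master_spacer <- random_dna(.operon_spacer, gc)

    centers <- (seq_len(n_operons + 1)) * slot_w
    centers <- centers[-ceiling((n_operons + 1) / 2)]
    jitter <- stats::runif(n_operons, -slot_w / 8, slot_w / 8)
    starts <- round(centers + jitter)

    operons <- purrr::map_dfr(seq_len(n_operons), function(i) {
      its_len <- sample_range(its_range[1], its_range[2])
      g16 <- mutate_seq(mg$g16, divergence, mg$fp16)
      its <- mutate_seq(substr(master_its, 1, its_len), divergence)
      g23 <- mutate_seq(mg$g23, divergence, mg$fp23)
      spacer <- mutate_seq(master_spacer, divergence)
      g5 <- mutate_seq(mg$g5, divergence)
      op_seq <- paste0(g16, its, g23, spacer, g5)
      strand <- sample(c("+", "-"), 1, prob = c(0.75, 0.25))
      s <- starts[i]
      L <- nchar(op_seq)
      tibble::tibble(
        operon = i, start = s, end = s + L, strand = strand,
        its_len = its_len,
        s16_start = s, s16_end = s + .gene16_len,
        its_start = s + .gene16_len, its_end = s + .gene16_len + its_len,
        s23_start = s + .gene16_len + its_len,
        s23_end = s + .gene16_len + its_len + .gene23_len,
        s5_start = s + L - .gene5_len, s5_end = s + L,
        seq = if (strand == "+") op_seq else revcomp(op_seq))
    })
    # coordinates above are in forward-operon layout; for '-' copies the
    # written sequence is the reverse complement, so gene sub-intervals are
    # mirrored within the operon span
    for (i in seq_len(nrow(operons))) {
      if (operons$strand[i] == "-") {
        s <- operons$start[i]
        e <- operons$end[i]
        flip <- function(a, b) c(s + (e - b), s + (e - a))
        f16 <- flip(operons$s16_start[i], operons$s16_end[i])
        fits <- flip(operons$its_start[i], operons$its_end[i])
        f23 <- flip(operons$s23_start[i], operons$s23_end[i])
        f5 <- flip(operons$s5_start[i], operons$s5_end[i])
        operons$s16_start[i] <- f16[1]; operons$s16_end[i] <- f16[2]
        operons$its_start[i] <- fits[1]; operons$its_end[i] <- fits[2]
        operons$s23_start[i] <- f23[1]; operons$s23_end[i] <- f23[2]
        operons$s5_start[i] <- f5[1]; operons$s5_end[i] <- f5[2]
      }
      genome <- paste0(substr(genome, 1, operons$start[i]),
                       operons$seq[i],
                       substr(genome, operons$end[i] + 1, size))
    }
    genes <- tibble::tibble(
      gene = c("16S", "23S", "5S"),
      seq = c(mg$g16, mg$g23, mg$g5),
      length = c(.gene16_len, .gene23_len, .gene5_len))
    structure(list(genome = genome,
                   operons = dplyr::select(operons, -"seq"),
                   genes = genes, size = size, gc = gc,
                   divergence = divergence, seed = seed),
              class = "genome_truth")
  })
}

#' Corruption profile emulating the CR1 draft assembly
#'
#' The default profile reproduces the defect load of the CR1-style
#' reference scenario: 38 contigs of which 10 are short rRNA-only contigs and 10 are
#' small placeable contigs, 198 ambiguous-base stretches of 9-769 bp, 18
#' inter-contig gaps (12 containing an operon), and one 200 kb segmental
#' relocation adjacent to an N-stretch.
#'
#' @param n_plain_gaps Gaps without rDNA content (default 6).
#' @param plain_gap_len Plain gap length range in bp.
#' @param frag_margin How far inside the operon the breaks fall, leaving
#'   rDNA fragments of this size on the flanking contig ends (bp).
#' @param rrna_only Number of rRNA-isoform contigs (default 10).
#' @param rrna_len Their length range in bp (must satisfy the mask rule).
#' @param placeable Number of small excised contigs (default 10).
#' @param placeable_len Excised segment length range in bp.
#' @param n_runs_total Total ambiguous stretches, including the excision
#'   stretches and the relocation-adjacent one (default 198).
#' @param n_run_len Pure N-run length range in bp (default `c(9, 769)`).
#' @param relocation_size Relocated block size in bp (default 2e5);
#'   `NULL` disables the rearrangement.
#' @param relocation_sep Distance between block source and destination
#'   (default 3e5).
#' @return Named list of profile parameters.
#' @export
cr1_profile <- function(n_plain_gaps = 6, plain_gap_len = c(4000, 12000),
                        frag_margin = c(120, 200), rrna_only = 10,
                        rrna_len = c(800, 1500), placeable = 10,
                        placeable_len = c(400, 600), n_runs_total = 198,
                        n_run_len = c(9, 769), relocation_size = 2e5,
                        relocation_sep = 3e5) {
  list(n_plain_gaps = n_plain_gaps, plain_gap_len = plain_gap_len,
       frag_margin = frag_margin, rrna_only = rrna_only,
       rrna_len = rrna_len, placeable = placeable,
       placeable_len = placeable_len, n_runs_total = n_runs_total,
       n_run_len = n_run_len, relocation_size = relocation_size,
       relocation_sep = relocation_sep)
}

# Allocate `n` non-overlapping intervals of the given lengths inside
# [lo, hi) avoiding `occupied` (tibble start/end), with `spacing` bp
# between features. Rejection sampling; deterministic under the caller's
# seed. Returns a tibble start/end or stops when infeasible.
allocate_intervals <- function(lens, lo, hi, occupied, spacing = 1000,
                               max_tries = 2000) {
  out <- list()
  occ <- occupied
  for (L in lens) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      s <- floor(stats::runif(1, lo, hi - L))
      e <- s + L
      clash <- nrow(occ) > 0 &&
        any(s < occ$end + spacing & e > occ$start - spacing)
      if (!clash) {
        occ <- dplyr::bind_rows(occ, tibble::tibble(start = s, end = e))
        out[[length(out) + 1]] <- tibble::tibble(start = s, end = e)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("infeasible feature packing", call. = FALSE)
  }
  dplyr::bind_rows(out)
}

#' Corrupt a synthetic genome into a draft assembly with ground truth
#'
#' Applies the documented defect operators to a [generate_genome()] truth:
#' the genome is broken inside operon margins (so contig ends carry rDNA
#' fragments) and at plain gap positions, near-operon segments are excised
#' as standalone rRNA-isoform contigs, pure N-runs are injected, small
#' unique segments are excised and replaced by N-runs of jittered length
#' (re-emitted as separate small contigs carrying 300 bp of flank overlap),
#' one segmental relocation is applied inside the largest contig adjacent
#' to an N-stretch, and every contig is emitted in a random orientation and
#' renamed in descending length order.
#'
#' @param truth `genome_truth` from [generate_genome()].
#' @param profile See [cr1_profile()].
#' @param seed Random seed (default 43).
#' @return Object of class `draft_truth`; see Details in the package
#'   vignette. Key elements: `contigs` (the draft), `backbone`, `gaps`,
#'   `n_runs`, `smalls`, `rrna_only`, `relocation`, `seed`, `profile`.
#' @export
corrupt_to_draft <- function(truth, profile = cr1_profile(), seed = 43) {
  stopifnot(inherits(truth, "genome_truth"))
  genome <- truth$genome
  size <- truth$size
  ops <- truth$operons
  with_local_seed(seed, {
    # ---- gap regions ------------------------------------------------
    d1 <- sample_range(profile$frag_margin[1], profile$frag_margin[2],
                       nrow(ops))
    d2 <- sample_range(profile$frag_margin[1], profile$frag_margin[2],
                       nrow(ops))
    op_gaps <- tibble::tibble(
      start = ops$start + d1, end = ops$end - d2,
      has_operon = TRUE, operon = ops$operon)
    # origin gap makes the circular bookkeeping linear
    g0_len <- sample_range(profile$plain_gap_len[1],
                           profile$plain_gap_len[2])
    plain <- tibble::tibble(start = 0L, end = g0_len,
                            has_operon = FALSE, operon = NA_integer_)
    # remaining plain gaps: one per distinct inter-operon span, skipping
    # the widest span (reserved for the relocation)
    span_bounds <- sort(c(g0_len, op_gaps$start, op_gaps$end, size))
    spans <- tibble::tibble(lo = span_bounds[-length(span_bounds)],
                            hi = span_bounds[-1])
    spans <- spans[spans$hi - spans$lo > 50000, ]
    spans <- spans[order(spans$hi - spans$lo, decreasing = TRUE), ]
    spans <- spans[-1, ] # widest span kept gap-free
    if (nrow(spans) < profile$n_plain_gaps - 1) {
      stop("not enough inter-operon spans for plain gaps", call. = FALSE)
    }
    pick <- spans[sample(nrow(spans), profile$n_plain_gaps - 1), ]
    for (i in seq_len(nrow(pick))) {
      gl <- sample_range(profile$plain_gap_len[1],
                         profile$plain_gap_len[2])
      gs <- floor(stats::runif(1, pick$lo[i] + 20000,
                               pick$hi[i] - 20000 - gl))
      plain <- dplyr::bind_rows(plain, tibble::tibble(
        start = gs, end = gs + gl, has_operon = FALSE,
        operon = NA_integer_))
    }
    gaps <- dplyr::arrange(dplyr::bind_rows(op_gaps, plain), .data$start)
    gaps$gap_index <- seq_len(nrow(gaps))
    gaps$content <- substring(genome, gaps$start + 1, gaps$end)

    # ---- backbone contigs (raw slices between gaps) ------------------
    n_ctg <- nrow(gaps)
    backbone <- tibble::tibble(
      index = seq_len(n_ctg),
      genome_start = gaps$end,
      genome_end = c(gaps$start[-1], size))
    backbone$raw <- substring(genome, backbone$genome_start + 1,
                              backbone$genome_end)
    backbone$length_raw <- backbone$genome_end - backbone$genome_start

    # ---- relocation inside the largest contig ------------------------
    reloc <- NULL
    reloc_idx <- which.max(backbone$length_raw)
    if (!is.null(profile$relocation_size)) {
      L <- profile$relocation_size
      sep <- profile$relocation_sep
      margin <- 25000
      clen <- backbone$length_raw[reloc_idx]
      if (clen < L + sep + 2 * margin + 10000) {
        stop("largest contig too short for the requested relocation",
             call. = FALSE)
      }
      a <- floor(stats::runif(1, margin,
                              clen - margin - sep - L - 5000))
      b <- a + L
      d <- b + sep
      s <- backbone$raw[reloc_idx]
      nl <- sample_range(max(50, profile$n_run_len[1]),
                         min(769, profile$n_run_len[2]))
      # dest N-run at [d-nl, d), block spliced in right after it
      s <- paste0(substr(s, 1, d - nl), strrep("N", nl),
                  substr(s, d + 1, clen))
      dest_run <- tibble::tibble(start = d - nl, end = d, kind = "adjacent",
                                 original = substr(backbone$raw[reloc_idx],
                                                   d - nl + 1, d))
      s <- paste0(substr(s, 1, a), substr(s, b + 1, d),
                  substr(s, a + 1, b), substr(s, d + 1, clen))
      backbone$raw[reloc_idx] <- s
      # in spliced coords: block at [d-L, d); dest run at [d-L-nl, d-L)
      reloc <- list(contig_index = reloc_idx,
                    src_start = a, src_end = b,
                    insert_at = d, block_size = L,
                    block_start = d - L, block_end = d,
                    genome_src_start = backbone$genome_start[reloc_idx] + a,
                    genome_src_end = backbone$genome_start[reloc_idx] + b)
      dest_run$start <- dest_run$start - L
      dest_run$end <- dest_run$end - L
    }

    # ---- feature allocation per contig -------------------------------
    margin <- 2000L
    occupied <- lapply(seq_len(n_ctg), function(i) {
      tibble::tibble(start = numeric(0), end = numeric(0))
    })
    n_runs <- list()
    if (!is.null(reloc)) {
      i <- reloc$contig_index
      occupied[[i]] <- tibble::tibble(
        start = c(reloc$block_start - 1000, reloc$src_start - 1000),
        end = c(reloc$block_end + 1000, reloc$src_end + 1000))
      n_runs[[length(n_runs) + 1]] <- tibble::tibble(
        contig_index = i, start = dest_run$start, end = dest_run$end,
        length = dest_run$end - dest_run$start, kind = "adjacent",
        original = dest_run$original, excised = NA_character_,
        small_id = NA_character_)
    }

    # placeable excisions (not in the relocation contig)
    cand_idx <- setdiff(seq_len(n_ctg), reloc_idx)
    exc_contigs <- sample(rep(cand_idx,
                              length.out = max(profile$placeable,
                                               length(cand_idx))),
                          profile$placeable)
    # assembler-style flank overlap copied into each emitted small contig;
    # kept short enough that excised segment + overlaps stay under 1 kb
    flank <- 180L
    smalls <- list()
    for (j in seq_len(profile$placeable)) {
      i <- exc_contigs[j]
      L <- sample_range(profile$placeable_len[1], profile$placeable_len[2])
      iv <- allocate_intervals(L, margin + flank,
                               backbone$length_raw[i] - margin - flank,
                               occupied[[i]])
      occupied[[i]] <- dplyr::bind_rows(occupied[[i]], iv)
      jlen <- round(L * stats::runif(1, 0.8, 1.2))
      sm_id <- sprintf("small_%02d", j)
      raw <- backbone$raw[i]
      n_runs[[length(n_runs) + 1]] <- tibble::tibble(
        contig_index = i, start = iv$start, end = iv$start + jlen,
        length = jlen, kind = "excision",
        original = NA_character_,
        excised = substr(raw, iv$start + 1, iv$end),
        small_id = sm_id)
      smalls[[length(smalls) + 1]] <- tibble::tibble(
        id = sm_id,
        seq = substr(raw, iv$start - flank + 1, iv$end + flank),
        host_index = i, host_start = iv$start, host_end = iv$end)
    }
    smalls <- dplyr::bind_rows(smalls)
    if (nrow(smalls) == 0) {
      smalls <- tibble::tibble(id = character(), seq = character(),
                               host_index = integer(),
                               host_start = numeric(),
                               host_end = numeric())
    }

    # pure N runs spread over contigs proportional to length
    n_pure <- profile$n_runs_total - profile$placeable -
      as.integer(!is.null(reloc))
    run_contigs <- sample(seq_len(n_ctg), n_pure, replace = TRUE,
                          prob = backbone$length_raw)
    for (i in seq_len(n_ctg)) {
      cnt <- sum(run_contigs == i)
      if (cnt == 0) next
      lens <- sample_range(profile$n_run_len[1], profile$n_run_len[2],
                           cnt)
      iv <- allocate_intervals(lens, margin,
                               backbone$length_raw[i] - margin,
                               occupied[[i]])
      occupied[[i]] <- dplyr::bind_rows(occupied[[i]], iv)
      raw <- backbone$raw[i]
      n_runs[[length(n_runs) + 1]] <- tibble::tibble(
        contig_index = i, start = iv$start, end = iv$end,
        length = iv$end - iv$start, kind = "pure",
        original = substring(raw, iv$start + 1, iv$end),
        excised = NA_character_, small_id = NA_character_)
    }
    n_runs <- dplyr::bind_rows(n_runs)
    if (nrow(n_runs) == 0) {
      n_runs <- tibble::tibble(contig_index = integer(), start = numeric(),
                               end = numeric(), length = numeric(),
                               kind = character(), original = character(),
                               excised = character(),
                               small_id = character())
    }

    # ---- apply N edits (left to right, tracking the length delta) ----
    backbone$seq <- backbone$raw
    n_runs <- dplyr::arrange(n_runs, .data$contig_index, .data$start)
    n_runs$edited_start <- NA_real_
    n_runs$edited_end <- NA_real_
    for (i in seq_len(n_ctg)) {
      rows <- which(n_runs$contig_index == i)
      if (length(rows) == 0) next
      raw <- backbone$raw[i]
      pieces <- character(0)
      cursor <- 0L # raw coordinate consumed so far
      delta <- 0L
      for (r in rows) {
        kind <- n_runs$kind[r]
        raw_start <- n_runs$start[r]
        raw_end <- if (kind == "excision") {
          # excision interval in raw coords is [start, start + exc_len)
          n_runs$start[r] + nchar(n_runs$excised[r])
        } else {
          n_runs$end[r]
        }
        pieces <- c(pieces, substr(raw, cursor + 1, raw_start),
                    strrep("N", n_runs$length[r]))
        n_runs$edited_start[r] <- raw_start + delta
        n_runs$edited_end[r] <- raw_start + delta + n_runs$length[r]
        delta <- delta + n_runs$length[r] - (raw_end - raw_start)
        cursor <- raw_end
      }
      pieces <- c(pieces, substr(raw, cursor + 1, nchar(raw)))
      backbone$seq[i] <- paste(pieces, collapse = "")
    }
    backbone$length <- nchar(backbone$seq)

    # ---- rRNA-isoform contigs (exact slices of planted gene copies) --
    rrna_proto <- tibble::tibble(id = character(), seq = character(),
                                 operon = integer(), gene = character(),
                                 genome_start = numeric(),
                                 genome_end = numeric())
    rrna_only <- purrr::map_dfr(seq_len(profile$rrna_only), function(j) {
      op <- ops[((j - 1) %% nrow(ops)) + 1, ]
      use23 <- j %% 2 == 0
      gs <- if (use23) op$s23_start else op$s16_start
      ge <- if (use23) op$s23_end else op$s16_end
      glen <- ge - gs
      L <- sample_range(profile$rrna_len[1],
                        min(profile$rrna_len[2], glen))
      s <- gs + sample.int(glen - L + 1, 1) - 1L
      tibble::tibble(id = sprintf("rrna_%02d", j),
                     seq = substr(genome, s + 1, s + L),
                     operon = op$operon,
                     gene = if (use23) "23S" else "16S",
                     genome_start = s, genome_end = s + L)
    })
    if (nrow(rrna_only) == 0) rrna_only <- rrna_proto

    # ---- emit: random orientations, rename by descending length ------
    flip_interval <- function(s, e, len) c(len - e, len - s)
    backbone$orientation <- sample(c("+", "-"), n_ctg, replace = TRUE)
    for (i in seq_len(n_ctg)) {
      if (backbone$orientation[i] == "-") {
        backbone$seq[i] <- revcomp(backbone$seq[i])
        len <- backbone$length[i]
        rows <- which(n_runs$contig_index == i)
        for (r in rows) {
          f <- flip_interval(n_runs$edited_start[r], n_runs$edited_end[r],
                             len)
          n_runs$edited_start[r] <- f[1]
          n_runs$edited_end[r] <- f[2]
        }
      }
    }
    flip_some <- function(seqs, orientation) {
      out <- seqs
      idx <- which(orientation == "-")
      if (length(idx)) out[idx] <- revcomp(seqs[idx])
      out
    }
    smalls$orientation <- sample(c("+", "-"), nrow(smalls), replace = TRUE)
    smalls$emitted_seq <- flip_some(smalls$seq, smalls$orientation)
    rrna_only$orientation <- sample(c("+", "-"), nrow(rrna_only),
                                    replace = TRUE)
    rrna_only$emitted_seq <- flip_some(rrna_only$seq, rrna_only$orientation)

    all_tbl <- dplyr::bind_rows(
      tibble::tibble(role = "backbone", key = as.character(backbone$index),
                     seq = backbone$seq),
      tibble::tibble(role = "rrna_only", key = rrna_only$id,
                     seq = rrna_only$emitted_seq),
      tibble::tibble(role = "small", key = smalls$id,
                     seq = smalls$emitted_seq))
    all_tbl$length <- nchar(all_tbl$seq)
    all_tbl <- all_tbl[order(-all_tbl$length,
                             all_tbl$role, all_tbl$key), ]
    all_tbl$id <- sprintf("contig_%02d", seq_len(nrow(all_tbl)))

    name_of <- function(role, key) {
      all_tbl$id[all_tbl$role == role & all_tbl$key == key]
    }
    backbone$contig_id <- vapply(backbone$index, function(i) {
      name_of("backbone", as.character(i))
    }, "")
    rrna_only$contig_id <- vapply(rrna_only$id, name_of, "",
                                  role = "rrna_only")
    smalls$contig_id <- vapply(smalls$id, name_of, "", role = "small")
    n_runs$contig_id <- backbone$contig_id[n_runs$contig_index]
    gaps$left_contig <- backbone$contig_id[c(n_ctg, seq_len(n_ctg - 1))]
    gaps$right_contig <- backbone$contig_id[seq_len(n_ctg)]
    if (!is.null(reloc)) {
      reloc$contig_id <- backbone$contig_id[reloc$contig_index]
      reloc$orientation <- backbone$orientation[reloc$contig_index]
    }

    contigs <- as_contigs(all_tbl$id, all_tbl$seq)

    structure(list(
      contigs = contigs,
      backbone = dplyr::select(backbone, "contig_id", "index",
                               "genome_start", "genome_end", "orientation",
                               "length"),
      gaps = dplyr::select(gaps, "gap_index", "left_contig", "right_contig",
                           "start", "end", "has_operon", "operon",
                           "content"),
      n_runs = dplyr::select(n_runs, "contig_id", "contig_index",
                             start = "edited_start", end = "edited_end",
                             "length", "kind", raw_start = "start",
                             "original", "excised", "small_id"),
      smalls = dplyr::select(smalls, "contig_id", "id", "host_index",
                             "host_start", "host_end", "orientation",
                             "seq"),
      rrna_only = dplyr::select(rrna_only, "contig_id", "id", "operon",
                                "gene", "genome_start", "genome_end",
                                "orientation"),
      relocation = reloc,
      seed = seed, profile = profile
    ), class = "draft_truth")
  })
}

#' Reconstruct the source genome from a corrupted draft and its truth
#'
#' Inverts every corruption operator: contig orientations are undone, the
#' relocation is spliced back, N-runs are restored to their original or
#' excised content, and backbone contigs are interleaved with the recorded
#' gap contents in true order. Used as the generator's self-consistency
#' invariant: the result must equal the generated genome byte for byte.
#'
#' @param draft `draft_truth` from [corrupt_to_draft()].
#' @return Single genome string.
#' @export
reconstruct_genome <- function(draft) {
  bb <- draft$backbone
  contigs <- draft$contigs
  seqs <- character(nrow(bb))
  for (row in seq_len(nrow(bb))) {
    idx <- bb$index[row]
    seq <- contigs$seq[match(bb$contig_id[row], contigs$id)]
    len <- nchar(seq)
    # 1. undo the emitted orientation
    if (bb$orientation[row] == "-") seq <- revcomp(seq)
    # 2. restore N runs (stored coords are in the emitted orientation;
    #    map back to pre-flip coordinates), right to left
    runs <- draft$n_runs[draft$n_runs$contig_index == idx, , drop = FALSE]
    if (nrow(runs) > 0) {
      if (bb$orientation[row] == "-") {
        s <- len - runs$end
        e <- len - runs$start
        runs$start <- s
        runs$end <- e
      }
      runs <- runs[order(-runs$start), ]
      for (r in seq_len(nrow(runs))) {
        fill <- if (runs$kind[r] == "excision") runs$excised[r] else
          runs$original[r]
        seq <- paste0(substr(seq, 1, runs$start[r]), fill,
                      substr(seq, runs$end[r] + 1, nchar(seq)))
      }
    }
    # 3. undo the relocation splice: lengths are back to raw here because
    #    pure runs are length-preserving and excisions avoid this contig
    rl <- draft$relocation
    if (!is.null(rl) && rl$contig_index == idx) {
      block <- substr(seq, rl$block_start + 1, rl$block_end)
      rest <- paste0(substr(seq, 1, rl$block_start),
                     substr(seq, rl$block_end + 1, nchar(seq)))
      seq <- paste0(substr(rest, 1, rl$src_start), block,
                    substr(rest, rl$src_start + 1, nchar(rest)))
    }
    seqs[idx] <- seq
  }
  gaps <- draft$gaps[order(draft$gaps$gap_index), ]
  paste0(gaps$content, seqs, collapse = "")
}
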