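# Locating ribosomal gene fragments on contigs, masking rRNA-only contigs,
# annotating contig ends and clustering gene hits into operons.

empty_hits <- function() {
  tibble::tibble(contig_id = character(), gene = character(),
                 start = integer(), end = integer(), strand = character(),
                 identity = numeric(), gene_fraction = numeric(),
                 aligned_bp = integer())
}

#' Locate rDNA gene fragments on contigs
#'
#' Seed-and-extend local search of each consensus gene against every contig
#' on both strands: exact seed k-mers from the gene are matched against the
#' contig, seed clusters define candidate regions, and each candidate is
#' refined by local pairwise alignment. Hits with identity below
#' `min_identity` or aligned length below `min_fragment` are discarded;
#' overlapping hits of the same gene on the same strand are merged keeping
#' the best identity.
#'
#' @param contigs Contig tibble.
#' @param genes Consensus gene table (see [as_gene_table()]).
#' @param min_identity Minimum percent identity (default 90).
#' @param min_fragment Minimum aligned fragment length in bp (default 100).
#' @param seed_k Seed k-mer length (default 13).
#' @param seed_step Spacing of seeds along the gene (default 10).
#' @return Hit tibble: `contig_id`, `gene`, `start`, `end` (0-based
#'   half-open on the contig), `strand`, `identity`, `gene_fraction`,
#'   `aligned_bp`.
#' @export
scan_contigs <- function(contigs, genes, min_identity = 90,
                         min_fragment = 100, seed_k = 13, seed_step = 10) {
  genes <- as_gene_table(genes)
  if (nrow(genes) == 0) stop("no consensus genes supplied", call. = FALSE)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                 baseOnly = FALSE)
  out <- purrr::map_dfr(seq_len(nrow(genes)), function(gi) {
    gene_seq <- genes$seq[gi]
    glen <- nchar(gene_seq)
    purrr::map_dfr(c("+", "-"), function(strand) {
      gseq <- if (strand == "+") gene_seq else revcomp(gene_seq)
      # one seed dictionary per gene orientation, scanned over all contigs
      starts <- seq(1, max(1, nchar(gseq) - seed_k + 1), by = seed_step)
      seeds <- substring(gseq, starts, starts + seed_k - 1)
      pure <- grepl("^[ACGT]+$", seeds)
      starts <- starts[pure]
      seeds <- seeds[pure]
      if (length(seeds) == 0) return(NULL)
      pd <- Biostrings::PDict(seeds)
      purrr::map_dfr(seq_len(nrow(contigs)), function(ci) {
        scan_one(contigs$seq[ci], contigs$id[ci], gseq, genes$gene[gi],
                 glen, strand, min_identity, min_fragment, seed_k,
                 sm, pd, starts)
      })
    })
  })
  if (nrow(out) == 0) return(empty_hits())
  merge_hits(out)
}

# One gene orientation against one contig. `pd`/`seed_starts` are the
# precomputed seed dictionary for this gene orientation.
scan_one <- function(contig_seq, contig_id, gene_seq, gene_name, glen,
                     strand, min_identity, min_fragment, seed_k, sm,
                     pd, seed_starts) {
  clen <- nchar(contig_seq)
  if (clen < min_fragment) return(NULL)
  m <- Biostrings::matchPDict(pd, Biostrings::DNAString(contig_seq))
  hit_pos <- BiocGenerics::start(BiocGenerics::unlist(m)) # 1-based contig
  hit_seed <- rep(seq_along(seed_starts), S4Vectors::elementNROWS(m))
  if (length(hit_pos) == 0) return(NULL)
  goff <- seed_starts[hit_seed] # 1-based gene offset of each seed
  # diagonal = contig position of gene base 1 implied by the seed
  diag <- hit_pos - goff
  ord <- order(diag, hit_pos)
  diag <- diag[ord]
  goff <- goff[ord]
  # cluster seeds whose implied gene origin agrees within half a gene length
  grp <- cumsum(c(1, diff(diag) > max(50, glen %/% 2)))
  regions <- lapply(split(seq_along(diag), grp), function(ix) {
    d <- diag[ix]
    go <- goff[ix]
    # clip both the contig region and the gene to the seed-supported span,
    # so fragment hits align fragment-vs-fragment, not whole-gene
    g_lo <- max(1, min(go) - 150)
    g_hi <- min(nchar(gene_seq), max(go) + seed_k + 150)
    lo <- max(1, min(d) + g_lo - 150)
    hi <- min(clen, max(d) + g_hi + 150)
    c(lo, hi, g_lo, g_hi)
  })
  # merge candidate regions overlapping on the contig
  if (length(regions) > 1) {
    regions <- regions[order(vapply(regions, `[`, 0, 1))]
    merged <- list(regions[[1]])
    for (r in regions[-1]) {
      last <- merged[[length(merged)]]
      if (r[1] <= last[2]) {
        merged[[length(merged)]] <-
          c(last[1], max(last[2], r[2]), min(last[3], r[3]),
            max(last[4], r[4]))
      } else merged[[length(merged) + 1]] <- r
    }
    regions <- merged
  }
  purrr::map_dfr(regions, function(r) {
    region_seq <- substr(contig_seq, r[1], r[2])
    gene_part <- substr(gene_seq, r[3], r[4])
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(gene_part), Biostrings::DNAString(region_seq),
      type = "local", substitutionMatrix = sm,
      gapOpening = 5, gapExtension = 2)
    alen <- Biostrings::nchar(aln)
    if (alen < min_fragment) return(NULL)
    ident <- Biostrings::pid(aln, type = "PID1")
    if (ident < min_identity) return(NULL)
    sub_start <- BiocGenerics::start(Biostrings::subject(aln))
    sub_end <- BiocGenerics::end(Biostrings::subject(aln))
    pat_w <- BiocGenerics::width(Biostrings::pattern(aln))
    tibble::tibble(
      contig_id = contig_id, gene = gene_name,
      start = r[1] - 1L + sub_start - 1L,
      end = r[1] - 1L + sub_end,
      strand = strand, identity = ident,
      gene_fraction = pat_w / glen,
      aligned_bp = as.integer(alen))
  })
}

# Merge overlapping same-gene, same-strand hits on a contig, keeping the
# best identity and the union interval.
merge_hits <- function(hits) {
  hits |>
    dplyr::group_by(.data$contig_id, .data$gene, .data$strand) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(grp = cumsum(.data$start > dplyr::lag(
      cummax(.data$end), default = -1L))) |>
    dplyr::group_by(.data$grp, .add = TRUE) |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      identity = max(.data$identity),
      gene_fraction = max(.data$gene_fraction),
      aligned_bp = max(.data$aligned_bp), .groups = "drop") |>
    dplyr::select(-"grp") |>
    dplyr::relocate("contig_id", "gene", "start", "end", "strand") |>
    dplyr::arrange(.data$contig_id, .data$start)
}

#' Mask contigs comprised of rRNA genes
#'
#' Flags contigs shorter than `max_length` whose rDNA-covered fraction is
#' at least `min_cover` and removes them from the working set; contigs at
#' or above the length threshold are never masked regardless of rDNA
#' content.
#'
#' @param contigs Contig tibble.
#' @param hits Hit tibble from [scan_contigs()] computed on these contigs.
#' @param max_length Mask length threshold in bp, exclusive (default 2000).
#' @param min_cover Minimum rDNA-covered fraction of the contig
#'   (default 0.8).
#' @return List of class `rdna_mask`: `report` (per-contig tibble with
#'   `masked`, `covered_fraction`, `genes`) and `contigs` (the reduced
#'   working set).
#' @export
mask_rrna_contigs <- function(contigs, hits, max_length = 2000,
                              min_cover = 0.8) {
  cover <- rdna_cover(contigs, hits)
  report <- contigs |>
    dplyr::select("id", "length") |>
    dplyr::left_join(cover, by = c(id = "contig_id")) |>
    dplyr::mutate(
      covered_fraction = dplyr::coalesce(.data$covered_fraction, 0),
      genes = dplyr::coalesce(.data$genes, ""),
      masked = .data$length < max_length &
        .data$covered_fraction >= min_cover)
  structure(list(
    report = report,
    contigs = contigs[!report$masked, , drop = FALSE]
  ), class = "rdna_mask")
}

rdna_cover <- function(contigs, hits) {
  if (nrow(hits) == 0) {
    return(tibble::tibble(contig_id = character(),
                          covered_fraction = numeric(), genes = character()))
  }
  hits |>
    dplyr::group_by(.data$contig_id) |>
    dplyr::summarise(
      covered_fraction = {
        ir <- IRanges::reduce(IRanges::IRanges(.data$start + 1L, .data$end))
        sum(BiocGenerics::width(ir)) /
          contigs$length[match(.data$contig_id[1], contigs$id)]
      },
      genes = paste(sort(unique(.data$gene)), collapse = ","),
      .groups = "drop")
}

#' Annotate contig ends with rDNA fragments
#'
#' An end is annotated with a gene when one of that gene's hits starts or
#' ends within `end_window` bp of the contig terminus.
#'
#' @param contigs Contig tibble.
#' @param hits Hit tibble from [scan_contigs()].
#' @param end_window Window at each terminus in bp (default 200).
#' @return Tibble with one row per contig end: `contig_id`, `end` (`"5p"`
#'   or `"3p"`), `genes` (comma-separated, `""` if none), `annotated`.
#'   Two rows per contig, so `nrow()` is the total end count.
#' @export
annotate_contig_ends <- function(contigs, hits, end_window = 200) {
  ends <- tidyr::expand_grid(contig_id = contigs$id, end = c("5p", "3p"))
  ends$genes <- ""
  for (i in seq_len(nrow(ends))) {
    len <- contigs$length[match(ends$contig_id[i], contigs$id)]
    h <- hits[hits$contig_id == ends$contig_id[i], , drop = FALSE]
    if (nrow(h) == 0) next
    near <- if (ends$end[i] == "5p") {
      h$start < end_window | h$end <= end_window
    } else {
      h$end > len - end_window | h$start >= len - end_window
    }
    ends$genes[i] <- paste(sort(unique(h$gene[near])), collapse = ",")
  }
  ends$annotated <- nzchar(ends$genes)
  ends
}

#' Cluster rDNA hits into operon calls
#'
#' Same-strand hits on one sequence are grouped greedily in positional
#' order while the running span of the group stays within `max_span`. An
#' operon is complete when it contains both a 16S and a 23S hit.
#'
#' @param hits Hit tibble (the `contig_id` column names the sequence).
#' @param max_span Maximum intra-operon span in bp (default 10000).
#' @return Tibble of operon calls: `seq_id`, `operon`, `start`, `end`,
#'   `strand`, `genes`, `n_genes`, `complete`.
#' @export
cluster_operons <- function(hits, max_span = 10000) {
  if (nrow(hits) == 0) {
    return(tibble::tibble(seq_id = character(), operon = integer(),
                          start = integer(), end = integer(),
                          strand = character(), genes = character(),
                          n_genes = integer(), complete = logical()))
  }
  greedy_groups <- function(start, end) {
    grp <- integer(length(start))
    cur_grp <- 1L
    cur_start <- start[1]
    grp[1] <- cur_grp
    for (i in seq_along(start)[-1]) {
      if (end[i] - cur_start > max_span) {
        cur_grp <- cur_grp + 1L
        cur_start <- start[i]
      }
      grp[i] <- cur_grp
    }
    grp
  }
  hits |>
    dplyr::group_by(seq_id = .data$contig_id, .data$strand) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(grp = greedy_groups(.data$start, .data$end)) |>
    dplyr::group_by(.data$grp, .add = TRUE) |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      genes = paste(sort(unique(.data$gene)), collapse = ","),
      n_genes = length(unique(.data$gene)),
      complete = all(c("16S", "23S") %in% .data$gene),
      .groups = "drop") |>
    dplyr::select(-"grp") |>
    dplyr::arrange(.data$seq_id, .data$start) |>
    dplyr::mutate(operon = dplyr::row_number(), .after = "seq_id")
}
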