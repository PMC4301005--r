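# Final acceptance check: every original draft contig must be represented
# in the finished sequence.

#' Verify draft coverage in a finished assembly
#'
#' Aligns every original draft contig (including previously masked rRNA
#' contigs) to the finished sequence by anchor chaining: exact seed matches
#' are grouped per diagonal into chains, inter-anchor segments are verified
#' by direct alignment, and coverage may be split across several chains
#' (a contig spanning a corrected rearrangement is still fully covered).
#' N positions in the draft are excluded from both identity and coverage
#' denominators. Circular finished genomes are virtually doubled so
#' origin-spanning contigs are found; placements are reported modulo the
#' genome length.
#'
#' @param contigs Original draft contig tibble.
#' @param final_assembly Finished sequence (string, contig tibble or
#'   `reference_genome`).
#' @param min_identity Minimum percent identity per contig (default 99).
#' @param min_cover Minimum covered fraction of informative (non-N) bases
#'   (default 0.99).
#' @param circular Treat the finished sequence as circular (default TRUE).
#' @param k,seed_step Anchoring parameters (defaults 21 and 100).
#' @return Object of class `coverage_report`: `per_contig` tibble
#'   (`contig_id`, `length`, `informative`, `ref_start`, `ref_end`,
#'   `strand`, `identity`, `covered_fraction`, `status`), `pass` flag and
#'   `failing` ids.
#' @export
verify_draft_coverage <- function(contigs, final_assembly,
                                  min_identity = 99, min_cover = 0.99,
                                  circular = TRUE, k = 21,
                                  seed_step = 100) {
  fin <- as_template(final_assembly)
  if (!nzchar(fin$seq[1])) stop("empty final assembly", call. = FALSE)
  glen <- nchar(fin$seq[1])
  plain_seq <- fin$seq[1]
  plain_rc <- revcomp(plain_seq)
  doubled <- NULL # built lazily for origin-spanning contigs only

  place_one <- function(ctg, search_seq, search_rc) {
    informative <- ctg$length - stringr::str_count(ctg$seq, "N")
    if (informative == 0) {
      return(tibble::tibble(contig_id = ctg$id, length = ctg$length,
                            informative = 0L, ref_start = NA_integer_,
                            ref_end = NA_integer_, strand = NA_character_,
                            identity = NA_real_, covered_fraction = 1,
                            status = "no informative bases"))
    }
    step_i <- max(25L, min(seed_step, ctg$length %/% 20L))
    anchors <- seed_anchors(ctg$seq, search_seq, k = k, step = step_i,
                            unique_in_ref = FALSE, min_len = k,
                            ref_rc = search_rc)
    if (nrow(anchors) == 0) {
      # divergent or absent: fall back to a direct local alignment for
      # small contigs so a near-miss gets an identity estimate
      ident <- NA_real_
      if (ctg$length <= 20000) {
        sm <- Biostrings::nucleotideSubstitutionMatrix(
          match = 1, mismatch = -1, baseOnly = FALSE)
        aln <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(gsub("N", "A", ctg$seq)),
          Biostrings::DNAString(search_seq), type = "local",
          substitutionMatrix = sm, gapOpening = 5, gapExtension = 2)
        ident <- Biostrings::pid(aln, type = "PID1")
      }
      return(tibble::tibble(contig_id = ctg$id, length = ctg$length,
                            informative = informative,
                            ref_start = NA_integer_, ref_end = NA_integer_,
                            strand = NA_character_, identity = ident,
                            covered_fraction = 0, status = "fail"))
    }
    chains <- chain_anchors(anchors, ctg$seq, search_seq, search_rc)
    n_pos <- which(strsplit(ctg$seq, NULL)[[1]] == "N")
    cov <- IRanges::reduce(IRanges::IRanges(chains$intervals$start + 1L,
                                            chains$intervals$end))
    cov_bases <- sum(BiocGenerics::width(cov))
    n_in_cov <- sum(n_pos %in% unlist(lapply(seq_along(cov), function(j) {
      BiocGenerics::start(cov)[j]:BiocGenerics::end(cov)[j]
    })))
    covered_fraction <- (cov_bases - n_in_cov) / informative
    identity <- 100 * chains$matched / max(1, chains$compared)
    best <- chains$best
    ref_start <- best$ref_start %% glen
    ref_end <- ref_start + (best$ref_end - best$ref_start)
    ok <- covered_fraction >= min_cover && identity >= min_identity
    tibble::tibble(contig_id = ctg$id, length = ctg$length,
                   informative = as.integer(informative),
                   ref_start = as.integer(ref_start),
                   ref_end = as.integer(ref_end), strand = best$strand,
                   identity = identity,
                   covered_fraction = covered_fraction,
                   status = if (ok) "ok" else "fail")
  }

  per_contig <- purrr::map_dfr(seq_len(nrow(contigs)), function(i) {
    row <- place_one(contigs[i, ], plain_seq, plain_rc)
    if (circular && row$status == "fail") {
      # origin-spanning contigs need the virtually doubled genome
      if (is.null(doubled)) {
        doubled <<- list(seq = paste0(plain_seq, plain_seq))
        doubled$rc <<- revcomp(doubled$seq)
      }
      row2 <- place_one(contigs[i, ], doubled$seq, doubled$rc)
      if (is.na(row$covered_fraction) ||
          row2$covered_fraction > row$covered_fraction) {
        row <- row2
      }
    }
    row
  })
  failing <- per_contig$contig_id[per_contig$status == "fail"]
  structure(list(per_contig = per_contig, pass = length(failing) == 0,
                 failing = failing),
            class = "coverage_report")
}

# Chain anchors per (strand, diagonal neighbourhood); verify inter-anchor
# segments by direct comparison. Chains are then selected greedily by
# anchored size, skipping chains that map already-covered contig regions
# (extra placements of a repeat contig must not dilute identity), and
# matched/compared counts accumulate over selected chains only.
chain_anchors <- function(anchors, ctg_seq, search_seq, search_rc) {
  anchors$offset <- ifelse(anchors$strand == "+",
                           anchors$ref_start - anchors$query_start,
                           anchors$ref_end + anchors$query_start)
  anchors <- anchors[order(anchors$strand, anchors$offset,
                           anchors$query_start), ]
  grp <- cumsum(c(1, anchors$strand[-1] != anchors$strand[-nrow(anchors)] |
                    abs(diff(anchors$offset)) > 2000))
  chains <- lapply(unique(grp), function(g) {
    a <- anchors[grp == g, , drop = FALSE]
    a <- a[order(a$query_start), ]
    cov <- IRanges::reduce(IRanges::IRanges(a$query_start + 1L, a$query_end))
    cov_w <- sum(BiocGenerics::width(cov))
    matched <- cov_w # anchored bases are exact
    compared <- cov_w
    intervals <- list(tibble::tibble(start = BiocGenerics::start(cov) - 1L,
                                     end = BiocGenerics::end(cov)))
    # verify inter-anchor segments (substitution-only differences expected)
    if (nrow(a) > 1) {
      for (j in seq_len(nrow(a) - 1)) {
        qgap <- c(a$query_end[j], a$query_start[j + 1])
        if (qgap[2] <= qgap[1] || qgap[2] - qgap[1] > 20000) next
        qseg <- substr(ctg_seq, qgap[1] + 1, qgap[2])
        if (a$strand[1] == "+") {
          rs <- a$ref_end[j]
          re <- a$ref_start[j + 1]
          if (re <= rs || re - rs != qgap[2] - qgap[1]) next
          rseg <- substr(search_seq, rs + 1, re)
        } else {
          re <- a$ref_start[j]
          rs <- a$ref_end[j + 1]
          if (re <= rs || re - rs != qgap[2] - qgap[1]) next
          rseg <- revcomp(substr(search_seq, rs + 1, re))
        }
        qb <- utf8ToInt(qseg)
        rb <- utf8ToInt(rseg)
        non_n <- qb != utf8ToInt("N")
        matched <- matched + sum(qb[non_n] == rb[non_n])
        compared <- compared + sum(non_n)
        intervals[[length(intervals) + 1]] <-
          tibble::tibble(start = qgap[1], end = qgap[2])
      }
    }
    list(summary = tibble::tibble(
      query_start = min(a$query_start), query_end = max(a$query_end),
      ref_start = min(a$ref_start), ref_end = max(a$ref_end),
      strand = a$strand[1], anchored = cov_w),
      intervals = dplyr::bind_rows(intervals),
      matched = matched, compared = compared)
  })
  ord <- order(-vapply(chains, function(ch) ch$summary$anchored, 0))
  taken <- IRanges::IRanges()
  matched <- 0
  compared <- 0
  intervals <- list()
  kept <- list()
  for (ch in chains[ord]) {
    ir <- IRanges::IRanges(ch$intervals$start + 1L, ch$intervals$end)
    novel <- sum(BiocGenerics::width(IRanges::setdiff(ir, taken)))
    if (novel < max(50, 0.1 * sum(BiocGenerics::width(ir)))) next
    taken <- IRanges::reduce(c(taken, ir))
    matched <- matched + ch$matched
    compared <- compared + ch$compared
    intervals[[length(intervals) + 1]] <- ch$intervals
    kept[[length(kept) + 1]] <- ch$summary
  }
  kept <- dplyr::bind_rows(kept)
  list(intervals = dplyr::bind_rows(intervals),
       matched = matched, compared = compared,
       best = kept[which.max(kept$anchored), ])
}
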