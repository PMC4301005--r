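# Reference-guided contig ordering/orientation via unique k-mer anchoring,
# and inter-contig gap size estimation.

# Seed-and-extend exact anchors between one query sequence and one
# reference sequence (both strands). Seeds are k-mers sampled every
# `step` bp along the query; with `unique_in_ref = TRUE` only seeds with a
# single match across the reference and its reverse complement are kept.
# Same-diagonal seed runs are merged and extended outward while bases
# match. Coordinates are 0-based half-open; `query_start`/`query_end` are
# always on the query's forward strand, as are `ref_start`/`ref_end` on the
# reference's.
seed_anchors <- function(query_seq, ref_seq, k = 21, step = 250,
                         unique_in_ref = TRUE, min_len = 2 * k,
                         seed_filter = NULL, ref_rc = NULL) {
  qlen <- nchar(query_seq)
  empty <- tibble::tibble(query_start = integer(), query_end = integer(),
                          ref_start = integer(), ref_end = integer(),
                          strand = character(), length = integer())
  if (qlen < k) return(empty)
  starts <- unique(c(seq(1, qlen - k + 1, by = step), qlen - k + 1))
  seeds <- substring(query_seq, starts, starts + k - 1)
  pure <- grepl("^[ACGT]+$", seeds)
  starts <- starts[pure]
  seeds <- seeds[pure]
  if (!is.null(seed_filter)) {
    keep <- seed_filter(seeds)
    starts <- starts[keep]
    seeds <- seeds[keep]
  }
  if (length(seeds) == 0) return(empty)
  pd <- Biostrings::PDict(seeds)
  if (is.null(ref_rc)) ref_rc <- revcomp(ref_seq)
  subjects <- list(`+` = ref_seq, `-` = ref_rc)
  m_fwd <- Biostrings::matchPDict(pd, Biostrings::DNAString(ref_seq))
  m_rev <- Biostrings::matchPDict(pd, Biostrings::DNAString(ref_rc))
  n_fwd <- S4Vectors::elementNROWS(m_fwd)
  n_rev <- S4Vectors::elementNROWS(m_rev)
  if (unique_in_ref) {
    keep <- (n_fwd + n_rev) == 1L
  } else {
    keep <- (n_fwd + n_rev) >= 1L
  }
  if (!any(keep)) return(empty)

  seed_tbl <- purrr::map_dfr(c("+", "-"), function(strand) {
    m <- if (strand == "+") m_fwd else m_rev
    idx <- which(keep & S4Vectors::elementNROWS(m) > 0)
    if (length(idx) == 0) return(NULL)
    purrr::map_dfr(idx, function(i) {
      pos <- BiocGenerics::start(m[[i]])
      tibble::tibble(qs = starts[i], rs = pos, strand = strand)
    })
  })
  if (nrow(seed_tbl) == 0) return(empty)
  seed_tbl$diag <- seed_tbl$rs - seed_tbl$qs

  rlen <- nchar(ref_seq)
  # extend one anchor per maximal exact region per (strand, diagonal):
  # walk the group's seeds in order, skipping those already absorbed by
  # the previous extension
  groups <- split(seed_tbl, paste(seed_tbl$strand, seed_tbl$diag))
  rows <- purrr::map_dfr(groups, function(g) {
    g <- g[order(g$qs), ]
    subj <- subjects[[g$strand[1]]]
    out <- list()
    cur_end <- -Inf
    for (j in seq_len(nrow(g))) {
      if (g$qs[j] + k - 1 <= cur_end) next
      ext <- extend_exact(query_seq, subj, g$qs[j], g$rs[j], k)
      cur_end <- ext$qs + ext$len - 1
      if (ext$len < min_len) next
      q0 <- ext$qs - 1L
      r0 <- ext$rs - 1L
      out[[length(out) + 1]] <- if (g$strand[1] == "+") {
        tibble::tibble(query_start = q0, query_end = q0 + ext$len,
                       ref_start = r0, ref_end = r0 + ext$len,
                       strand = "+", length = ext$len)
      } else {
        tibble::tibble(query_start = q0, query_end = q0 + ext$len,
                       ref_start = rlen - (r0 + ext$len),
                       ref_end = rlen - r0,
                       strand = "-", length = ext$len)
      }
    }
    dplyr::bind_rows(out)
  })
  if (nrow(rows) == 0) return(empty)
  dplyr::distinct(rows) |> dplyr::arrange(.data$query_start)
}

# Extend an exact match [qs, qs+len) ~ [rs, rs+len) (1-based) outward by
# doubling substring comparisons.
extend_exact <- function(q, r, qs, rs, len) {
  qlen <- nchar(q)
  rlen <- nchar(r)
  # left
  chunk <- 64L
  while (chunk >= 1L) {
    if (qs - chunk >= 1 && rs - chunk >= 1 &&
        substr(q, qs - chunk, qs - 1) == substr(r, rs - chunk, rs - 1)) {
      qs <- qs - chunk
      rs <- rs - chunk
      len <- len + chunk
      chunk <- chunk * 2L
    } else {
      chunk <- chunk %/% 2L
    }
  }
  # right
  chunk <- 64L
  qe <- qs + len - 1L
  re <- rs + len - 1L
  while (chunk >= 1L) {
    if (qe + chunk <= qlen && re + chunk <= rlen &&
        substr(q, qe + 1, qe + chunk) == substr(r, re + 1, re + chunk)) {
      qe <- qe + chunk
      re <- re + chunk
      len <- len + chunk
      chunk <- chunk * 2L
    } else {
      chunk <- chunk %/% 2L
    }
  }
  list(qs = qs, rs = rs, len = len)
}

#' Anchor contigs on a reference genome
#'
#' Maximal exact matches between each contig and the reference, seeded from
#' k-mers that occur exactly once in the reference (both strands) and once
#' in the contig set; anchors shorter than `2k` are discarded. Repeat
#' regions (such as rDNA operons) therefore anchor poorly by design.
#'
#' @param contigs Contig tibble.
#' @param reference Reference genome: `reference_genome` object, contig
#'   tibble, or DNA string (first record used).
#' @param k Seed k-mer length (default 21).
#' @param step Seed sampling interval along each contig in bp
#'   (default 250).
#' @return Anchor tibble: `contig_id`, `contig_start`, `contig_end`,
#'   `ref_start`, `ref_end`, `strand`, `length` (0-based half-open).
#' @export
anchor_contigs <- function(contigs, reference, k = 21, step = 250) {
  ref <- as_template(reference)
  if (nrow(ref) == 0 || !nzchar(ref$seq[1])) {
    stop("empty reference", call. = FALSE)
  }
  ref_seq <- ref$seq[1]
  ref_rc <- revcomp(ref_seq)

  # Seed uniqueness across the whole contig set (both strands), computed
  # in one pass over all contigs' sampled seeds.
  sample_starts <- function(len) {
    if (len < k) return(integer(0))
    unique(c(seq(1, len - k + 1, by = step), len - k + 1))
  }
  all_seeds <- unlist(lapply(seq_len(nrow(contigs)), function(i) {
    st <- sample_starts(contigs$length[i])
    substring(contigs$seq[i], st, st + k - 1)
  }))
  all_seeds <- unique(all_seeds[grepl("^[ACGT]+$", all_seeds)])
  uniq_ok <- logical(0)
  if (length(all_seeds) > 0) {
    all_seqs <- Biostrings::DNAStringSet(c(contigs$seq, revcomp(contigs$seq)))
    cnt <- Biostrings::vcountPDict(Biostrings::PDict(all_seeds), all_seqs)
    uniq_ok <- rowSums(cnt) == 1L
    names(uniq_ok) <- all_seeds
  }
  seed_filter <- function(seeds) {
    ok <- uniq_ok[seeds]
    ok[is.na(ok)] <- FALSE
    unname(ok)
  }
  purrr::map_dfr(seq_len(nrow(contigs)), function(i) {
    a <- seed_anchors(contigs$seq[i], ref_seq, k = k, step = step,
                      unique_in_ref = TRUE, seed_filter = seed_filter,
                      ref_rc = ref_rc)
    if (nrow(a) == 0) return(NULL)
    dplyr::mutate(a, contig_id = contigs$id[i], .before = 1) |>
      dplyr::rename(contig_start = "query_start", contig_end = "query_end")
  })
}

#' Order and orient contigs against a reference
#'
#' Each contig's orientation is the strand carrying the majority of its
#' anchored bases (exact ties break to `+` with a warning); its reference
#' start estimate is the median of its anchors' implied contig-5' reference
#' positions. Contigs without anchors are listed unplaced.
#'
#' @param contigs Contig tibble.
#' @param anchors Anchor tibble from [anchor_contigs()].
#' @return Object of class `scaffold_layout`: list with `placements`
#'   (tibble `contig_id`, `orientation`, `ref_start_est`, `n_anchors`,
#'   `anchored_bp`, sorted by start estimate) and `unplaced` (character).
#' @export
order_and_orient <- function(contigs, anchors) {
  placed <- intersect(contigs$id, unique(anchors$contig_id))
  placements <- purrr::map_dfr(placed, function(id) {
    a <- anchors[anchors$contig_id == id, ]
    len <- contigs$length[match(id, contigs$id)]
    by_strand <- tapply(a$length, a$strand, sum)
    plus <- if ("+" %in% names(by_strand)) by_strand[["+"]] else 0
    minus <- if ("-" %in% names(by_strand)) by_strand[["-"]] else 0
    if (plus == minus) {
      warning("contig '", id, "': anchor strands tie, orienting '+'",
              call. = FALSE)
    }
    ori <- if (minus > plus) "-" else "+"
    a <- a[a$strand == ori, ]
    est <- if (ori == "+") {
      stats::median(a$ref_start - a$contig_start)
    } else {
      stats::median(a$ref_start - (len - a$contig_end))
    }
    tibble::tibble(contig_id = id, orientation = ori,
                   ref_start_est = est, n_anchors = nrow(a),
                   anchored_bp = sum(a$length))
  })
  placements <- dplyr::arrange(placements, .data$ref_start_est)
  structure(list(
    placements = placements,
    unplaced = setdiff(contigs$id, placed)
  ), class = "scaffold_layout")
}

#' Estimate inter-contig gap sizes from a layout
#'
#' The gap between adjacent placed contigs is the reference distance
#' between their projected inward ends; negative values are permitted and
#' flagged as putative overlaps. With `circular = TRUE` a wrap-around gap
#' between the last and first placed contigs is included.
#'
#' @param layout `scaffold_layout` from [order_and_orient()].
#' @param anchors Anchor tibble.
#' @param contigs Contig tibble.
#' @param reference Reference genome (used for its length).
#' @param circular Treat the genome as circular (default `FALSE`).
#' @return Gap tibble: `gap_id`, `left_contig`, `left_end`, `right_contig`,
#'   `right_end`, `size`, `overlap`, `rdna` (classification placeholder,
#'   `"unknown"`).
#' @export
estimate_gap_sizes <- function(layout, anchors, contigs, reference,
                               circular = FALSE) {
  pl <- layout$placements
  if (nrow(pl) < 2) stop("need at least two placed contigs", call. = FALSE)
  ref <- as_template(reference)
  rlen <- nchar(ref$seq[1])

  proj <- purrr::map_dfr(seq_len(nrow(pl)), function(i) {
    id <- pl$contig_id[i]
    ori <- pl$orientation[i]
    len <- contigs$length[match(id, contigs$id)]
    a <- anchors[anchors$contig_id == id & anchors$strand == ori, ]
    if (ori == "+") {
      lead <- a[which.min(a$contig_start), ]
      trail <- a[which.max(a$contig_end), ]
      start_proj <- lead$ref_start - lead$contig_start
      end_proj <- trail$ref_end + (len - trail$contig_end)
    } else {
      lead <- a[which.max(a$contig_end), ] # contig 3' maps to ref start
      trail <- a[which.min(a$contig_start), ]
      start_proj <- lead$ref_start - (len - lead$contig_end)
      end_proj <- trail$ref_end + trail$contig_start
    }
    tibble::tibble(contig_id = id, orientation = ori,
                   ref_start_proj = start_proj, ref_end_proj = end_proj)
  })

  n <- nrow(pl)
  idx_pairs <- if (circular) {
    cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  } else {
    cbind(seq_len(n - 1), seq_len(n)[-1])
  }
  purrr::map_dfr(seq_len(nrow(idx_pairs)), function(r) {
    i <- idx_pairs[r, 1]
    j <- idx_pairs[r, 2]
    size <- proj$ref_start_proj[j] - proj$ref_end_proj[i]
    if (circular && j == 1L) size <- size + rlen
    left_end <- if (proj$orientation[i] == "+") "3p" else "5p"
    right_end <- if (proj$orientation[j] == "+") "5p" else "3p"
    tibble::tibble(
      gap_id = paste0(proj$contig_id[i], "|", proj$contig_id[j]),
      left_contig = proj$contig_id[i], left_end = left_end,
      right_contig = proj$contig_id[j], right_end = right_end,
      size = size, overlap = size < 0, rdna = "unknown")
  })
}
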