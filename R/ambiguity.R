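# Ambiguous-base (N) stretches: detection, flanking primer design, and
# placement of small contigs into stretches.

#' Find ambiguous-base stretches
#'
#' Maximal runs of `N` of at least `min_length` bases, reported in
#' coordinate order per contig.
#'
#' @param contigs Contig tibble (or single DNA string).
#' @param min_length Minimum run length reported (default 3, the shortest
#'   run assemblers emit).
#' @return Tibble: `contig_id`, `start`, `end` (0-based half-open),
#'   `length`.
#' @export
#' @examples
#' find_n_stretches("ACGTNNNNACGT")
find_n_stretches <- function(contigs, min_length = 3) {
  contigs <- as_template(contigs)
  out <- purrr::map_dfr(seq_len(nrow(contigs)), function(i) {
    m <- gregexpr("N+", contigs$seq[i])[[1]]
    if (m[1] == -1) return(NULL)
    len <- attr(m, "match.length")
    tibble::tibble(contig_id = contigs$id[i], start = as.integer(m) - 1L,
                   end = as.integer(m) - 1L + len, length = len)
  })
  if (nrow(out) == 0) {
    return(tibble::tibble(contig_id = character(), start = integer(),
                          end = integer(), length = integer()))
  }
  out[out$length >= min_length, , drop = FALSE]
}

#' Design primers flanking each N-stretch
#'
#' For every stretch, a forward primer is designed upstream on the plus
#' strand and a reverse primer downstream on the minus strand, each within
#' `search_window` bp of the stretch boundary, so that the predicted PCR
#' product reads across the stretch. Stretches whose flanks are too short,
#' ambiguous, or repetitive are reported as undesignable with the reason.
#'
#' @param contigs Contig tibble holding the stretches.
#' @param stretches Stretch tibble from [find_n_stretches()].
#' @param search_window Primer search window adjacent to each boundary in
#'   bp (default 350).
#' @param constraints See [primer_constraints()].
#' @param uniqueness_scope Contig set for the specificity check (default:
#'   `contigs`).
#' @return Tibble with one row per stretch and primer side (`side` in
#'   `fwd`/`rev`) carrying the [design_primer()] columns plus `stretch_id`.
#' @export
design_n_flanking_primers <- function(contigs, stretches,
                                      search_window = 350,
                                      constraints = primer_constraints(),
                                      uniqueness_scope = contigs) {
  purrr::map_dfr(seq_len(nrow(stretches)), function(i) {
    st <- stretches[i, ]
    sid <- sprintf("%s:%d-%d", st$contig_id, st$start, st$end)
    ctg_seq <- contigs$seq[match(st$contig_id, contigs$id)]
    len <- nchar(ctg_seq)
    fwd <- design_primer(
      contigs, window = c(trim_n(ctg_seq, st$start - search_window,
                                 st$start, "left"), st$start),
      direction = "fwd", template_id = st$contig_id,
      constraints = constraints, uniqueness_scope = uniqueness_scope,
      name = paste0(sid, "_F"))
    rev <- design_primer(
      contigs, window = c(st$end, trim_n(ctg_seq, st$end,
                                         st$end + search_window, "right")),
      direction = "rev", template_id = st$contig_id,
      constraints = constraints, uniqueness_scope = uniqueness_scope,
      name = paste0(sid, "_R"))
    dplyr::bind_cols(tibble::tibble(stretch_id = sid, side = c("fwd", "rev")),
                     dplyr::bind_rows(fwd, rev))
  })
}

# Clip a window boundary so it does not run off the sequence or across a
# neighbouring N run. Returns the adjusted boundary (0-based).
trim_n <- function(seq, from, to, side) {
  len <- nchar(seq)
  from <- max(0L, as.integer(from))
  to <- min(len, as.integer(to))
  if (to <= from) return(if (side == "left") to else from)
  chunk <- substr(seq, from + 1, to)
  if (side == "left") {
    # window ends at `to`; push `from` right past the last N in the chunk
    m <- gregexpr("N", chunk)[[1]]
    if (m[1] != -1) from <- from + max(m)
    from
  } else {
    m <- gregexpr("N", chunk)[[1]]
    if (m[1] != -1) to <- from + min(m) - 1L
    to
  }
}

#' Place small contigs into N-stretches
#'
#' A small contig is placed into a stretch when its two ends align to the
#' host sequence flanking that stretch (both orientations tried) at or
#' above `min_flank_identity`; placements replace the stretch's Ns with the
#' small contig's novel interior and re-emit the merged host contig. A
#' small contig matching two stretches equally well is reported unplaced
#' with both candidates listed.
#'
#' @param small_contigs Contig tibble of candidate small contigs.
#' @param host_contigs Contig tibble of stretch-bearing hosts.
#' @param stretches Stretch tibble from [find_n_stretches()] on the hosts.
#' @param flank_window Host flank length compared to the contig ends in bp
#'   (default 300).
#' @param min_flank_identity Minimum percent identity of each flank
#'   alignment (default 95).
#' @param length_tol Tolerated relative difference between the stretch
#'   length and the replacement length (default 0.5, i.e. +/-50%).
#' @return List of class `placement_result`: `placements` tibble,
#'   `unplaced` tibble (with reasons), and `contigs` (hosts with
#'   placements merged in, placed small contigs removed).
#' @export
place_small_contigs <- function(small_contigs, host_contigs, stretches,
                                flank_window = 300,
                                min_flank_identity = 95,
                                length_tol = 0.5) {
  placements <- list()
  unplaced <- list()
  host_seqs <- stats::setNames(host_contigs$seq, host_contigs$id)

  for (i in seq_len(nrow(small_contigs))) {
    sc <- small_contigs[i, ]
    cands <- purrr::map_dfr(seq_len(nrow(stretches)), function(j) {
      st <- stretches[j, ]
      host <- host_seqs[[st$contig_id]]
      purrr::map_dfr(c("+", "-"), function(ori) {
        sseq <- if (ori == "+") sc$seq else revcomp(sc$seq)
        sc_match <- match_flanks(sseq, host, st, flank_window)
        if (is.null(sc_match)) return(NULL)
        tibble::tibble(stretch_idx = j, orientation = ori,
                       id5 = sc_match$id5, id3 = sc_match$id3,
                       novel_start = sc_match$novel_start,
                       novel_end = sc_match$novel_end,
                       score = (sc_match$id5 + sc_match$id3) / 2)
      })
    })
    cands <- cands[cands$id5 >= min_flank_identity &
                     cands$id3 >= min_flank_identity, , drop = FALSE]
    if (nrow(cands) == 0) {
      unplaced[[length(unplaced) + 1]] <- tibble::tibble(
        small_id = sc$id, reason = "no stretch with matching flanks",
        candidates = "")
      next
    }
    # length compatibility of the replacement
    ok_len <- vapply(seq_len(nrow(cands)), function(k) {
      st <- stretches[cands$stretch_idx[k], ]
      novel_len <- cands$novel_end[k] - cands$novel_start[k]
      abs(novel_len - st$length) <= length_tol * st$length
    }, TRUE)
    cands <- cands[ok_len, , drop = FALSE]
    if (nrow(cands) == 0) {
      unplaced[[length(unplaced) + 1]] <- tibble::tibble(
        small_id = sc$id, reason = "replacement length outside tolerance",
        candidates = "")
      next
    }
    best <- max(cands$score)
    top <- cands[cands$score == best, , drop = FALSE]
    if (length(unique(top$stretch_idx)) > 1) {
      labs <- vapply(unique(top$stretch_idx), function(j) {
        st <- stretches[j, ]
        sprintf("%s:%d-%d", st$contig_id, st$start, st$end)
      }, "")
      unplaced[[length(unplaced) + 1]] <- tibble::tibble(
        small_id = sc$id, reason = "ambiguous: ties between stretches",
        candidates = paste(labs, collapse = ";"))
      next
    }
    placements[[length(placements) + 1]] <- dplyr::bind_cols(
      tibble::tibble(small_id = sc$id), top[1, ])
  }

  placements <- dplyr::bind_rows(placements)
  # resolve stretch contention: best score per stretch wins, losers unplaced
  if (nrow(placements) > 0) {
    placements <- placements |>
      dplyr::group_by(.data$stretch_idx) |>
      dplyr::arrange(dplyr::desc(.data$score), .by_group = TRUE)
    losers <- dplyr::filter(placements, dplyr::row_number() > 1) |>
      dplyr::ungroup()
    placements <- dplyr::filter(placements, dplyr::row_number() == 1) |>
      dplyr::ungroup()
    if (nrow(losers) > 0) {
      unplaced[[length(unplaced) + 1]] <- tibble::tibble(
        small_id = losers$small_id,
        reason = "stretch claimed by a better-scoring contig",
        candidates = "")
    }
  }
  unplaced <- dplyr::bind_rows(unplaced)

  # merge placements into hosts (right-to-left per host to keep coords)
  merged <- host_contigs
  if (nrow(placements) > 0) {
    placements$host_id <- stretches$contig_id[placements$stretch_idx]
    placements$stretch_start <- stretches$start[placements$stretch_idx]
    placements$stretch_end <- stretches$end[placements$stretch_idx]
    for (hid in unique(placements$host_id)) {
      ph <- placements[placements$host_id == hid, , drop = FALSE]
      ph <- ph[order(-ph$stretch_start), ]
      seq <- merged$seq[match(hid, merged$id)]
      for (k in seq_len(nrow(ph))) {
        sc_seq <- small_contigs$seq[match(ph$small_id[k], small_contigs$id)]
        if (ph$orientation[k] == "-") sc_seq <- revcomp(sc_seq)
        novel <- substr(sc_seq, ph$novel_start[k] + 1, ph$novel_end[k])
        seq <- paste0(substr(seq, 1, ph$stretch_start[k]), novel,
                      substr(seq, ph$stretch_end[k] + 1, nchar(seq)))
      }
      merged$seq[match(hid, merged$id)] <- seq
      merged$length[match(hid, merged$id)] <- nchar(seq)
    }
    placed_ids <- placements$small_id
  } else {
    placed_ids <- character(0)
  }
  working <- dplyr::bind_rows(
    merged,
    small_contigs[!small_contigs$id %in% placed_ids, , drop = FALSE])

  structure(list(
    placements = if (nrow(placements) > 0) {
      tibble::as_tibble(placements[, c("small_id", "host_id",
                                       "stretch_start", "stretch_end",
                                       "orientation", "id5", "id3",
                                       "novel_start", "novel_end",
                                       "score")])
    } else {
      tibble::tibble(small_id = character(), host_id = character(),
                     stretch_start = integer(), stretch_end = integer(),
                     orientation = character(), id5 = numeric(),
                     id3 = numeric(), novel_start = integer(),
                     novel_end = integer(), score = numeric())
    },
    unplaced = unplaced,
    contigs = working
  ), class = "placement_result")
}

# Align the two ends of a candidate small contig to the host flanks of a
# stretch with free end gaps. Returns identities and the novel interior of
# the small contig, or NULL when an end barely aligns.
match_flanks <- function(sseq, host, st, flank_window) {
  slen <- nchar(sseq)
  w <- min(flank_window, slen %/% 2)
  if (w < 20) return(NULL)
  left_host <- substr(host, max(1, st$start - flank_window + 1), st$start)
  right_host <- substr(host, st$end + 1,
                       min(nchar(host), st$end + flank_window))
  if (nchar(left_host) < 20 || nchar(right_host) < 20) return(NULL)
  # cheap prescreen: one of two 15-mers from each contig end must occur
  # verbatim in the corresponding host flank before paying for alignment
  hit15 <- function(end_seq, flank_seq) {
    grepl(substr(end_seq, 1, 15), flank_seq, fixed = TRUE) ||
      grepl(substr(end_seq, 16, 30), flank_seq, fixed = TRUE)
  }
  right_ok <- grepl(substr(sseq, slen - 14, slen), right_host,
                    fixed = TRUE) ||
    grepl(substr(sseq, slen - 29, slen - 15), right_host, fixed = TRUE)
  if (!hit15(sseq, left_host) || !right_ok) return(NULL)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = FALSE)
  a5 <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(substr(sseq, 1, w)),
    Biostrings::DNAString(left_host), type = "overlap",
    substitutionMatrix = sm, gapOpening = 2, gapExtension = 1)
  a3 <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(substr(sseq, slen - w + 1, slen)),
    Biostrings::DNAString(right_host), type = "overlap",
    substitutionMatrix = sm, gapOpening = 2, gapExtension = 1)
  cov5 <- Biostrings::nchar(a5) / w
  cov3 <- Biostrings::nchar(a3) / w
  if (cov5 < 0.5 || cov3 < 0.5) return(NULL)
  # novel interior = part of the small contig not aligned to either flank
  end5 <- BiocGenerics::end(Biostrings::pattern(a5)) # within first w bases
  start3 <- (slen - w) + BiocGenerics::start(Biostrings::pattern(a3)) - 1L
  if (start3 < end5) return(NULL)
  list(id5 = Biostrings::pid(a5, type = "PID1"),
       id3 = Biostrings::pid(a3, type = "PID1"),
       novel_start = end5, novel_end = start3)
}
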