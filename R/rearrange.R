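# Windowed draft-vs-reference placement and rearrangement calling, plus
# junction-verification primer design.

#' Place draft windows on a reference
#'
#' Tiles the draft sequence with overlapping windows and places each window
#' at its best unique-anchor-supported reference location. Windows without
#' unique anchor support (e.g. rDNA repeats, N runs) are reported unplaced.
#'
#' @param draft_seq Draft sequence (single string or contig tibble; rows
#'   are concatenated in order to one coordinate system).
#' @param reference Reference genome.
#' @param window Window size in bp (default 10000).
#' @param step Window step in bp (default 5000, i.e. 50% overlap).
#' @param k Anchor seed length (default 21).
#' @param seed_step Anchor seed sampling interval (default 500).
#' @return List of class `window_map`: `placements` tibble (`window_id`,
#'   `draft_start`, `draft_end`, `ref_start`, `ref_end`, `strand`,
#'   `anchored_bp`, `placed`), `anchors` (the underlying anchor tibble in
#'   draft coordinates), `window`, `step`.
#' @export
window_map <- function(draft_seq, reference, window = 10000, step = 5000,
                       k = 21, seed_step = 500) {
  tmpl <- as_template(draft_seq)
  draft <- paste(tmpl$seq, collapse = "")
  ref <- as_template(reference)
  if (!nzchar(ref$seq[1])) stop("empty reference", call. = FALSE)
  anchors <- seed_anchors(draft, ref$seq[1], k = k, step = seed_step,
                          unique_in_ref = TRUE)
  dlen <- nchar(draft)
  win_starts <- seq(0L, max(0L, dlen - 1L), by = step)
  win_starts <- win_starts[win_starts < dlen]
  placements <- purrr::map_dfr(seq_along(win_starts), function(i) {
    ws <- win_starts[i]
    we <- min(dlen, ws + window)
    ov <- anchors[anchors$query_start < we & anchors$query_end > ws, ,
                  drop = FALSE]
    if (nrow(ov) == 0) {
      return(tibble::tibble(window_id = i, draft_start = ws, draft_end = we,
                            ref_start = NA_integer_, ref_end = NA_integer_,
                            strand = NA_character_, anchored_bp = 0L,
                            placed = FALSE))
    }
    ov$ov_len <- pmin(ov$query_end, we) - pmax(ov$query_start, ws)
    # majority vote over anchored bases by (strand, offset-class)
    ov$offset <- ifelse(ov$strand == "+",
                        ov$ref_start - ov$query_start,
                        ov$ref_end + ov$query_start)
    ov$class <- paste(ov$strand, round(ov$offset / 1000))
    best_class <- names(which.max(tapply(ov$ov_len, ov$class, sum)))
    ovb <- ov[ov$class == best_class, , drop = FALSE]
    main <- ovb[which.max(ovb$ov_len), ]
    clip_s <- pmax(main$query_start, ws)
    clip_e <- pmin(main$query_end, we)
    if (main$strand == "+") {
      rs <- main$ref_start + (clip_s - main$query_start)
      re <- rs + (clip_e - clip_s)
    } else {
      re <- main$ref_end - (clip_s - main$query_start)
      rs <- re - (clip_e - clip_s)
    }
    tibble::tibble(window_id = i, draft_start = ws, draft_end = we,
                   ref_start = rs, ref_end = re, strand = main$strand,
                   anchored_bp = sum(ov$ov_len), placed = TRUE)
  })
  structure(list(placements = placements, anchors = anchors,
                 window = window, step = step),
            class = "window_map")
}

#' Call large rearrangements from window placements
#'
#' Breakpoints are placed between draft-adjacent placed windows whose
#' reference placement jumps by at least `min_jump` bp or flips strand;
#' runs of windows between breakpoints form segments. An interior segment
#' becomes an inversion call when its strand differs from both flanking
#' segments, and a relocation call when excising it would leave its
#' flanking segments reference-continuous (within `min_jump`). Slow
#' coordinate drift (for example from unsequenced inter-contig gaps) never
#' triggers a breakpoint because discordance is judged between adjacent
#' windows only. When two draft-adjacent segments describe the same
#' relocation from both sides, the smaller is reported (parsimony) and the
#' larger noted as its displaced counterpart. Call edges are refined to
#' anchor resolution. Calls whose breakpoints lie within `n_margin` bp of
#' a supplied N-stretch are typed `insertion-at-N`.
#'
#' @param wmap `window_map` object.
#' @param min_jump Minimum reference displacement in bp (default 50000).
#' @param n_stretches Optional stretch tibble (draft coordinates) used to
#'   annotate insertion-at-N calls.
#' @param n_margin Distance to an N-stretch that counts as adjacent
#'   (default 1000).
#' @return Tibble of calls: `call_id`, `draft_start`, `draft_end`,
#'   `block_size`, `type` (`relocation`, `inversion`, `insertion-at-N`),
#'   `ref_start`, `ref_end`, `offset`, `windows` (supporting window ids),
#'   `note`.
#' @export
call_rearrangements <- function(wmap, min_jump = 50000, n_stretches = NULL,
                                n_margin = 1000) {
  pl <- wmap$placements[wmap$placements$placed, , drop = FALSE]
  empty <- tibble::tibble(call_id = integer(), draft_start = integer(),
                          draft_end = integer(), block_size = integer(),
                          type = character(), ref_start = integer(),
                          ref_end = integer(), offset = numeric(),
                          windows = character(), note = character())
  if (nrow(pl) < 3) return(empty)
  pl$offset <- ifelse(pl$strand == "+",
                      pl$ref_start - pl$draft_start,
                      pl$ref_end + pl$draft_start)
  # breakpoints between adjacent placed windows
  n <- nrow(pl)
  jump <- pl$strand[-1] != pl$strand[-n] |
    abs(pl$offset[-1] - pl$offset[-n]) >= min_jump
  if (!any(jump)) return(empty)
  pl$segment <- cumsum(c(1, jump))
  segs <- pl |>
    dplyr::group_by(.data$segment) |>
    dplyr::summarise(
      draft_start = min(.data$draft_start),
      draft_end = max(.data$draft_end),
      strand = .data$strand[1],
      first_offset = .data$offset[1],
      last_offset = .data$offset[dplyr::n()],
      first_ref_start = .data$ref_start[1],
      first_ref_end = .data$ref_end[1],
      last_ref_start = .data$ref_start[dplyr::n()],
      last_ref_end = .data$ref_end[dplyr::n()],
      offset = stats::median(.data$offset),
      ref_start = min(.data$ref_start),
      ref_end = max(.data$ref_end),
      windows = paste(.data$window_id, collapse = ","),
      n_windows = dplyr::n(),
      .groups = "drop")
  ns <- nrow(segs)
  if (ns < 3) return(empty)
  # candidate interior segments
  is_cand <- logical(ns)
  for (i in 2:(ns - 1)) {
    left <- segs[i - 1, ]
    right <- segs[i + 1, ]
    if (segs$strand[i] != left$strand && segs$strand[i] != right$strand) {
      is_cand[i] <- TRUE # inversion
    } else if (left$strand == right$strand) {
      # excision continuity in reference coordinates
      gap_ref <- if (left$strand == "+") {
        right$first_ref_start - left$last_ref_end
      } else {
        left$last_ref_start - right$first_ref_end
      }
      if (abs(gap_ref) < min_jump) is_cand[i] <- TRUE
    }
  }
  if (!any(is_cand)) return(empty)
  runs <- segs[is_cand, , drop = FALSE]
  runs$flank_strand <- vapply(which(is_cand), function(i) {
    segs$strand[i - 1]
  }, "")
  runs$flank_offset <- vapply(which(is_cand), function(i) {
    segs$last_offset[i - 1]
  }, 0)

  # refine run edges using the underlying anchors of the same class
  an <- wmap$anchors
  an$offset <- ifelse(an$strand == "+",
                      an$ref_start - an$query_start,
                      an$ref_end + an$query_start)
  runs <- purrr::map_dfr(seq_len(nrow(runs)), function(i) {
    r <- runs[i, ]
    sel <- an$strand == r$strand &
      abs(an$offset - r$offset) < wmap$step &
      an$query_end > r$draft_start - wmap$step &
      an$query_start < r$draft_end + wmap$step
    if (any(sel)) {
      r$draft_start <- min(an$query_start[sel])
      r$draft_end <- max(an$query_end[sel])
      r$ref_start <- min(an$ref_start[sel])
      r$ref_end <- max(an$ref_end[sel])
    }
    r
  })
  runs$block_size <- runs$draft_end - runs$draft_start

  # parsimony: two draft-adjacent runs describing one relocation from both
  # sides -> keep the smaller, note the larger
  drop <- rep(FALSE, nrow(runs))
  note <- rep("", nrow(runs))
  if (nrow(runs) > 1) {
    for (i in seq_len(nrow(runs) - 1)) {
      gap_between <- runs$draft_start[i + 1] - runs$draft_end[i]
      if (gap_between <= 2 * wmap$step && runs$strand[i] == runs$strand[i + 1]) {
        big <- if (runs$block_size[i] >= runs$block_size[i + 1]) i else i + 1
        small <- if (big == i) i + 1 else i
        drop[big] <- TRUE
        note[small] <- sprintf(
          "complementary displaced segment at draft %d-%d absorbed",
          runs$draft_start[big], runs$draft_end[big])
      }
    }
  }
  runs$note <- note
  runs <- runs[!drop, , drop = FALSE]
  if (nrow(runs) == 0) return(empty)

  runs$type <- ifelse(runs$strand != runs$flank_strand, "inversion",
                      "relocation")
  if (!is.null(n_stretches) && nrow(n_stretches) > 0) {
    for (i in seq_len(nrow(runs))) {
      near <- abs(n_stretches$end - runs$draft_start[i]) <= n_margin |
        abs(n_stretches$start - runs$draft_end[i]) <= n_margin
      if (runs$type[i] == "relocation" && any(near)) {
        runs$type[i] <- "insertion-at-N"
      }
    }
  }
  tibble::tibble(call_id = seq_len(nrow(runs)),
                 draft_start = as.integer(runs$draft_start),
                 draft_end = as.integer(runs$draft_end),
                 block_size = as.integer(runs$block_size),
                 type = runs$type,
                 ref_start = as.integer(runs$ref_start),
                 ref_end = as.integer(runs$ref_end),
                 offset = runs$offset - runs$flank_offset,
                 windows = runs$windows, note = runs$note)
}

#' Design junction-verification primers for a rearrangement call
#'
#' For each hypothesized junction (the call's draft start and end), designs
#' one primer on each side within `max_offset` bp of the breakpoint so the
#' predicted product spans the junction. Search windows are clipped at N
#' stretches; when the breakpoint abuts an N run, the primer is placed
#' beyond it so the product spans stretch plus junction.
#'
#' @param call One row of the call tibble from [call_rearrangements()].
#' @param draft_seq Draft sequence (string or contig tibble, concatenated).
#' @param max_offset Maximum primer distance from the breakpoint in bp
#'   (default 1000).
#' @param constraints See [primer_constraints()].
#' @param uniqueness_scope Scope for specificity (default: the draft).
#' @return Tibble with one row per junction side pair: `junction`
#'   (`"start"`/`"end"`), the two primer results (nested columns
#'   `left_*`, `right_*`), `product_start`, `product_end`, `status`.
#' @export
design_junction_primers <- function(call, draft_seq, max_offset = 1000,
                                    constraints = primer_constraints(),
                                    uniqueness_scope = NULL) {
  tmpl <- as_template(draft_seq)
  draft <- paste(tmpl$seq, collapse = "")
  dlen <- nchar(draft)
  ctg <- as_contigs("draft", draft)
  if (is.null(uniqueness_scope)) uniqueness_scope <- ctg

  # maximal N run containing or abutting a position, or NULL
  n_run_around <- function(bp) {
    at <- function(i) i >= 1 && i <= dlen &&
      substr(draft, i, i) == "N"
    i <- if (at(bp + 1)) bp + 1 else if (at(bp)) bp else return(NULL)
    lo <- i
    while (at(lo - 1)) lo <- lo - 1
    hi <- i
    while (at(hi + 1)) hi <- hi + 1
    c(lo - 1L, hi) # 0-based half-open
  }

  one_junction <- function(bp, label) {
    fail_side <- function(nm) {
      tibble::tibble(name = nm, seq = NA_character_, tm = NA_real_,
                     gc = NA_real_, template_id = "draft",
                     start = NA_integer_, end = NA_integer_,
                     strand = NA_character_, status = "undesignable",
                     reason = "breakpoint too close to the sequence end")
    }
    run <- n_run_around(bp)
    left_edge <- if (!is.null(run) && run[1] < bp) run[1] else bp
    right_edge <- if (!is.null(run) && run[2] > bp) run[2] else bp
    left <- if (left_edge < 100) fail_side(paste0("junction_", label, "_L"))
    else design_primer(
      ctg, window = c(trim_n(draft, left_edge - max_offset, left_edge,
                             "left"), left_edge),
      direction = "fwd", constraints = constraints,
      uniqueness_scope = uniqueness_scope,
      name = paste0("junction_", label, "_L"))
    right <- if (dlen - right_edge < 100) {
      fail_side(paste0("junction_", label, "_R"))
    } else design_primer(
      ctg, window = c(right_edge, trim_n(draft, right_edge,
                                         right_edge + max_offset,
                                         "right")),
      direction = "rev", constraints = constraints,
      uniqueness_scope = uniqueness_scope,
      name = paste0("junction_", label, "_R"))
    status <- if (left$status == "ok" && right$status == "ok") "ok" else
      "undesignable"
    tibble::tibble(
      junction = label, breakpoint = bp,
      left_name = left$name, left_seq = left$seq, left_start = left$start,
      left_reason = left$reason,
      right_name = right$name, right_seq = right$seq,
      right_end = right$end, right_reason = right$reason,
      product_start = left$start, product_end = right$end,
      product_length = right$end - left$start,
      status = status)
  }
  dplyr::bind_rows(one_junction(call$draft_start, "start"),
                   one_junction(call$draft_end, "end"))
}
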