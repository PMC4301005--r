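# Gap-spanning primer design, rDNA classification of gaps, and the
# six-reaction parallel walk plan (or a traditional serial plan) per gap.

#' Design a gap-spanning primer pair
#'
#' Places a forward primer whose 5' base lies `offset_range` bp inside the
#' left contig's inward end, oriented toward the gap, and symmetrically a
#' reverse primer on the right contig, both satisfying the primer-engine
#' constraints and unique in `uniqueness_scope`.
#'
#' @param gap One row of the gap tibble from [estimate_gap_sizes()].
#' @param layout `scaffold_layout` (for contig orientations).
#' @param contigs Contig tibble.
#' @param offset_range Distance of the primer 5' base from the contig's
#'   inward end, in bp (default `c(250, 350)`).
#' @param constraints See [primer_constraints()].
#' @param uniqueness_scope Contig set for specificity (default `contigs`).
#' @return Two-row tibble (`side` = `"left"`/`"right"`) of
#'   [design_primer()] results plus `gap_id` and `genomic_seq` (the primer
#'   as it reads on the placed strand).
#' @export
design_gap_primers <- function(gap, layout, contigs,
                               offset_range = c(250, 350),
                               constraints = primer_constraints(),
                               uniqueness_scope = contigs) {
  pl <- layout$placements
  one_side <- function(contig_id, side) {
    ori <- pl$orientation[match(contig_id, pl$contig_id)]
    len <- contigs$length[match(contig_id, contigs$id)]
    # inward end: for the left contig the gap lies after its placed 3' end,
    # for the right contig before its placed 5' end
    toward_gap_right <- (side == "left") == (ori == "+")
    if (toward_gap_right) {
      window <- c(len - offset_range[2], len - offset_range[1])
      direction <- "fwd"
    } else {
      window <- c(offset_range[1], offset_range[2])
      direction <- "rev"
    }
    # Constrain the search window so every candidate's 5' base (footprint
    # start for a forward primer, footprint end for a reverse one) falls
    # inside the offset range.
    minL <- min(constraints$length)
    if (direction == "fwd") {
      des <- design_primer(contigs, window = c(window[1], window[2] + minL),
                           direction = "fwd", template_id = contig_id,
                           constraints = constraints,
                           uniqueness_scope = uniqueness_scope,
                           name = paste0(gap$gap_id, "_", side))
    } else {
      des <- design_primer(contigs, window = c(window[1] - minL, window[2]),
                           direction = "rev", template_id = contig_id,
                           constraints = constraints,
                           uniqueness_scope = uniqueness_scope,
                           name = paste0(gap$gap_id, "_", side))
    }
    des$side <- side
    des$gap_id <- gap$gap_id
    des$genomic_seq <- des$seq
    des
  }
  dplyr::bind_rows(one_side(gap$left_contig, "left"),
                   one_side(gap$right_contig, "right"))
}

#' Classify a gap amplicon by rDNA content
#'
#' Mirrors the wet-lab re-amplification of a gel-purified gap product with
#' universal rRNA primers: 16S is judged present when the 8F/1492R pair
#' yields an in-silico product of 1200-1700 bp, 23S when 127F/2241R yields
#' 1800-2400 bp. 5S (for which no universal pair exists) is assessed by a
#' direct consensus scan when a 5S consensus is supplied.
#'
#' @param amplicon Gap amplicon sequence (single string or contig tibble).
#' @param primers Universal primer table (default [universal_primers()]).
#' @param consensus_5s Optional 5S consensus sequence for the direct scan.
#' @param size_16s,size_23s Accepted product-size windows in bp.
#' @return One-row tibble: `has_16s`, `has_23s`, `has_5s`, `len_16s`,
#'   `len_23s` (supporting product lengths, NA when absent), `rdna`.
#' @export
classify_gap_rdna <- function(amplicon, primers = universal_primers(),
                              consensus_5s = NULL,
                              size_16s = c(1200, 1700),
                              size_23s = c(1800, 2400)) {
  tmpl <- as_template(amplicon)
  if (!nzchar(tmpl$seq[1])) stop("empty amplicon", call. = FALSE)
  pget <- function(nm) primers$sequence[match(nm, primers$name)]
  p16 <- simulate_pcr(tmpl, pget("8F"), pget("1492R"),
                      fwd_name = "8F", rev_name = "1492R")
  p23 <- simulate_pcr(tmpl, pget("127F"), pget("2241R"),
                      fwd_name = "127F", rev_name = "2241R")
  in_win <- function(p, win) p$length[p$length >= win[1] & p$length <= win[2]]
  l16 <- in_win(p16, size_16s)
  l23 <- in_win(p23, size_23s)
  has_5s <- NA
  if (!is.null(consensus_5s)) {
    genes <- as_gene_table(c(`5S` = consensus_5s))
    hits <- scan_contigs(tmpl, genes, min_identity = 90, min_fragment = 80)
    has_5s <- nrow(hits) > 0
  }
  has_16s <- length(l16) > 0
  has_23s <- length(l23) > 0
  tibble::tibble(
    has_16s = has_16s, has_23s = has_23s, has_5s = has_5s,
    len_16s = if (has_16s) max(l16) else NA_integer_,
    len_23s = if (has_23s) max(l23) else NA_integer_,
    rdna = if (has_16s || has_23s || isTRUE(has_5s)) "present" else "absent")
}

read_span_model <- function(read_span = c(750, 1000)) {
  list(conservative = read_span[1], optimistic = read_span[length(read_span)])
}

#' Parallel six-reaction walk plan for an rDNA gap
#'
#' For a gap amplicon containing a complete 16S-ITS-23S operon, emits the
#' six simultaneous Sanger reactions that tile the unknown flanking and
#' intragenic sequence in a single round (equivalent to three serial
#' primer-walking stages): the two gap primers reading inward from the
#' amplicon ends, U1/U2 at the 16S boundaries and U3/U4 at the 23S
#' boundaries. The 16S and 23S gene bodies themselves are treated as known
#' (they are what the universal primers anneal to), so predicted uncovered
#' intervals are reported over the flanks and the intragenic spacer only,
#' using the conservative read span. A universal primer without a site on
#' the amplicon degrades the affected segment to traditional walking,
#' which is reported.
#'
#' @param amplicon Gap amplicon sequence.
#' @param gap_fwd,gap_rev The gap primer pair (sequences 5'->3').
#' @param primers Universal primer table (default [universal_primers()]).
#' @param read_span Readable bases per Sanger reaction, conservative and
#'   optimistic (default `c(750, 1000)`).
#' @param gap_id Gap label carried through to the plan.
#' @return Object of class `walk_plan`; see [plan_traditional_walk()] for
#'   the shared structure.
#' @export
plan_rdna_walk <- function(amplicon, gap_fwd, gap_rev,
                           primers = universal_primers(),
                           read_span = c(750, 1000), gap_id = "gap") {
  tmpl <- as_template(amplicon)
  alen <- nchar(tmpl$seq[1])
  span <- read_span_model(read_span)
  cls <- classify_gap_rdna(tmpl, primers)
  if (!cls$has_16s || !cls$has_23s) {
    stop("amplicon does not contain a complete 16S+23S operon; ",
         "use plan_traditional_walk()", call. = FALSE)
  }
  pget <- function(nm) primers$sequence[match(nm, primers$name)]
  # operon orientation within the amplicon: plan on the reverse complement
  # when 16S runs right-to-left, swapping the gap primers' roles
  s8 <- find_primer_sites(tmpl, pget("8F"))
  if (!any(s8$strand == "+") && any(s8$strand == "-")) {
    flipped <- as_contigs(tmpl$id[1], revcomp(tmpl$seq[1]))
    out <- plan_rdna_walk(flipped, gap_rev, gap_fwd, primers = primers,
                          read_span = read_span, gap_id = gap_id)
    out$template_orientation <- "-"
    return(out)
  }
  # gene body intervals from the universal products
  p16 <- simulate_pcr(tmpl, pget("8F"), pget("1492R"))
  p16 <- p16[p16$length >= 1200 & p16$length <= 1700, ][1, ]
  p23 <- simulate_pcr(tmpl, pget("127F"), pget("2241R"))
  p23 <- p23[p23$length >= 1800 & p23$length <= 2400, ][1, ]

  site_of <- function(nm, strand, near) {
    s <- find_primer_sites(tmpl, pget(nm), primer_name = nm)
    s <- s[s$strand == strand, ]
    if (nrow(s) == 0) return(NULL)
    s[which.min(abs((s$start + s$end) / 2 - near)), ]
  }
  reaction <- function(id, primer_name, site, direction) {
    if (direction == "right") {
      read_start <- site$end
      read_end <- min(alen, site$end + span$conservative)
    } else {
      read_end <- site$start
      read_start <- max(0, site$start - span$conservative)
    }
    tibble::tibble(reaction = id, primer = primer_name,
                   primer_start = site$start, primer_end = site$end,
                   direction = direction,
                   read_start = read_start, read_end = read_end)
  }

  gap_f_site <- find_primer_sites(tmpl, gap_fwd, primer_name = "gap_fwd")
  gap_f_site <- gap_f_site[gap_f_site$strand == "+", ][1, ]
  gap_r_site <- find_primer_sites(tmpl, gap_rev, primer_name = "gap_rev")
  gap_r_site <- gap_r_site[gap_r_site$strand == "-", ]
  gap_r_site <- gap_r_site[which.max(gap_r_site$end), ]

  want <- list(
    list("r1", "gap_fwd", gap_f_site, "right", "left flank"),
    list("r2", "U1", site_of("U1", "-", p16$start), "left", "left flank"),
    list("r3", "U2", site_of("U2", "+", p16$end), "right", "intragenic"),
    list("r4", "U3", site_of("U3", "-", p23$start), "left", "intragenic"),
    list("r5", "U4", site_of("U4", "+", p23$end), "right", "right flank"),
    list("r6", "gap_rev", gap_r_site, "left", "right flank"))

  reactions <- list()
  degraded <- list()
  for (w in want) {
    site <- w[[3]]
    if (is.null(site) || nrow(site) == 0 || any(is.na(site$start))) {
      degraded[[length(degraded) + 1]] <- tibble::tibble(
        reaction = w[[1]], primer = w[[2]], segment = w[[5]],
        note = "no hybridization site on amplicon; walk this segment")
      next
    }
    reactions[[length(reactions) + 1]] <-
      reaction(w[[1]], w[[2]], site, w[[4]])
  }
  reactions <- dplyr::bind_rows(reactions)
  degraded <- dplyr::bind_rows(degraded)

  # Unknown sequence = amplicon minus the 16S/23S gene bodies. The
  # universal products delimit the bodies up to the canonical primer
  # offsets within each gene (8F ~10 bp into 16S, 1492R ~60 bp before its
  # end; 127F at position ~127 of 23S, 2241R ~666 bp before its end), so
  # the known intervals are extended by those margins.
  known <- IRanges::IRanges(
    start = pmax(1L, c(p16$start - 10L, p23$start - 127L) + 1L),
    end = pmin(alen, c(p16$end + 60L, p23$end + 666L)))
  covered <- IRanges::IRanges(start = reactions$read_start + 1L,
                              end = reactions$read_end)
  covered <- c(covered, IRanges::IRanges(reactions$primer_start + 1L,
                                         reactions$primer_end))
  uncovered <- IRanges::setdiff(
    IRanges::IRanges(1L, alen),
    IRanges::reduce(c(known, covered)))
  uncovered <- tibble::tibble(start = BiocGenerics::start(uncovered) - 1L,
                              end = BiocGenerics::end(uncovered),
                              length = BiocGenerics::width(uncovered))

  structure(list(
    gap_id = gap_id, strategy = "rdna-parallel",
    reactions = reactions,
    stage_equivalent = as.integer(ceiling(nrow(reactions) / 2)),
    uncovered = uncovered,
    degraded = degraded,
    template_length = alen,
    template_orientation = "+",
    read_span = span
  ), class = "walk_plan")
}

#' Traditional bidirectional primer-walking plan
#'
#' Serial Sanger walking from both gap ends: each stage's primer anneals to
#' the previous stage's read, so stages form a dependency chain. Stage
#' count is `ceiling(gap_length / (2 * conservative_span))`.
#'
#' @param gap_length Gap length in bp (> 0).
#' @param read_span Readable bases per reaction, conservative first
#'   (default `c(750, 1000)`).
#' @param gap_id Gap label.
#' @return Object of class `walk_plan`: list with `gap_id`, `strategy`,
#'   `reactions` (tibble with `stage` and `depends_on`), `stage_equivalent`,
#'   `uncovered`, `template_length`, `read_span`.
#' @export
plan_traditional_walk <- function(gap_length, read_span = c(750, 1000),
                                  gap_id = "gap") {
  if (gap_length <= 0) stop("gap length must be positive", call. = FALSE)
  span <- read_span_model(read_span)
  stages <- as.integer(ceiling(gap_length / (2 * span$conservative)))
  reactions <- purrr::map_dfr(seq_len(stages), function(s) {
    left_start <- (s - 1) * span$conservative
    right_end <- gap_length - (s - 1) * span$conservative
    tibble::tibble(
      reaction = paste0("s", s, c("_left", "_right")),
      primer = paste0("walk_", s, c("_left", "_right")),
      primer_start = NA_integer_, primer_end = NA_integer_,
      direction = c("right", "left"),
      read_start = c(left_start, max(0, right_end - span$conservative)),
      read_end = c(min(gap_length, left_start + span$conservative),
                   right_end),
      stage = s,
      depends_on = if (s == 1) c(NA_character_, NA_character_) else
        paste0("s", s - 1, c("_left", "_right")))
  })
  covered <- IRanges::reduce(IRanges::IRanges(reactions$read_start + 1L,
                                              reactions$read_end))
  uncovered <- IRanges::setdiff(IRanges::IRanges(1L, gap_length), covered)
  structure(list(
    gap_id = gap_id, strategy = "traditional",
    reactions = reactions,
    stage_equivalent = stages,
    uncovered = tibble::tibble(start = BiocGenerics::start(uncovered) - 1L,
                               end = BiocGenerics::end(uncovered),
                               length = BiocGenerics::width(uncovered)),
    degraded = tibble::tibble(),
    template_length = as.integer(gap_length),
    read_span = span
  ), class = "walk_plan")
}
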