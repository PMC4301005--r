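# Oligonucleotide model: melting temperature, GC content, IUPAC-aware
# hybridization-site search, in-silico PCR and constraint-driven design.

# Unified nearest-neighbor thermodynamic parameters (dH kcal/mol,
# dS cal/(mol K)) for Watson-Crick dinucleotide stacks, plus helix
# initiation terms per terminal base pair.
.nn_dH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
            CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
            TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2,
            CC = -8.0)
.nn_dS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
            TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
            CC = -19.9)
.init_dH <- c(G = 0.1, C = 0.1, A = 2.3, T = 2.3)
.init_dS <- c(G = -2.8, C = -2.8, A = 4.1, T = 4.1)

# Conservative (annealing-weakest) disambiguation of a degenerate primer:
# at each ambiguous position pick the weakest-stacking available base,
# preferring A, then T, then C, then G.
min_tm_disambiguate <- function(seq) {
  chars <- strsplit(seq, NULL)[[1]]
  pref <- c("A", "T", "C", "G")
  out <- vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (is.null(set)) stop("non-IUPAC character '", ch, "' in primer",
                           call. = FALSE)
    pref[pref %in% set][1]
  }, "")
  paste(out, collapse = "")
}

#' Nearest-neighbor melting temperature of a primer
#'
#' Duplex melting temperature under the unified nearest-neighbor
#' thermodynamic model with an entropy salt correction
#' (`dS + 0.368 (L-1) ln[Na+]`). Degenerate IUPAC positions are evaluated on
#' the minimum-Tm disambiguation, giving a conservative annealing estimate.
#'
#' @param seq Primer sequence 5'->3' (IUPAC codes allowed), length >= 10.
#' @param salt_mM Monovalent cation concentration in mM (default 50).
#' @param oligo_nM Oligo concentration in nM (default 500).
#' @return Melting temperature in degrees Celsius.
#' @export
#' @examples
#' melting_temp("TGGGATACCACCCTGATCGT")
melting_temp <- function(seq, salt_mM = 50, oligo_nM = 500) {
  seq <- normalise_dna(seq, "primer")
  if (nchar(seq) < 10) stop("primer too short (length >= 10 required)",
                            call. = FALSE)
  s <- if (grepl("^[ACGT]+$", seq)) seq else min_tm_disambiguate(seq)
  chars <- strsplit(s, NULL)[[1]]
  L <- length(chars)
  steps <- paste0(chars[-L], chars[-1])
  dH <- sum(.nn_dH[steps]) + .init_dH[chars[1]] + .init_dH[chars[L]]
  dS <- sum(.nn_dS[steps]) + .init_dS[chars[1]] + .init_dS[chars[L]]
  dS <- dS + 0.368 * (L - 1) * log(salt_mM / 1000)
  ct <- oligo_nM * 1e-9
  tm_k <- (dH * 1000) / (dS + 1.9872 * log(ct / 4))
  unname(tm_k - 273.15)
}

#' GC content of a primer
#'
#' Percent G+C. Unambiguous strong bases (G, C, S) count fully; other
#' ambiguity codes contribute the fraction of their expansion set that is
#' G or C (e.g. R contributes 1/2, N contributes 1/2).
#'
#' @param seq Primer sequence (IUPAC codes allowed), non-empty.
#' @return GC percentage in `[0, 100]`.
#' @export
#' @examples
#' gc_content("AGAGTTTGATCCTGGCTCAG") # 50
gc_content <- function(seq) {
  seq <- normalise_dna(seq, "primer")
  if (!nzchar(seq)) stop("empty primer", call. = FALSE)
  L <- nchar(seq)
  if (grepl("^[ACGT]+$", seq)) {
    return(100 * (L - nchar(gsub("[GC]", "", seq))) / L)
  }
  chars <- strsplit(seq, NULL)[[1]]
  frac <- vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    mean(set %in% c("G", "C"))
  }, 0)
  100 * sum(frac) / L
}

#' Wallace-rule melting temperature
#'
#' The counting rule `2(A+T) + 4(G+C)`, used as a quick cross-check of the
#' nearest-neighbor model. Ambiguity codes contribute fractionally through
#' their GC content.
#'
#' @param seq Primer sequence.
#' @return Temperature in degrees Celsius.
#' @export
wallace_tm <- function(seq) {
  seq <- normalise_dna(seq, "primer")
  L <- nchar(seq)
  gc <- gc_content(seq) / 100 * L
  2 * (L - gc) + 4 * gc
}

empty_sites <- function() {
  tibble::tibble(primer = character(), template_id = character(),
                 start = integer(), end = integer(), strand = character(),
                 mismatches = integer(), three_prime_ok = logical())
}

# Coerce the template argument to a contig tibble.
as_template <- function(template) {
  if (is.data.frame(template)) return(template)
  if (inherits(template, "reference_genome")) return(template$sequence)
  if (is.character(template)) {
    ids <- names(template)
    if (is.null(ids)) ids <- paste0("template_", seq_along(template))
    return(as_contigs(ids, normalise_dna(template, "template")))
  }
  stop("cannot interpret template", call. = FALSE)
}

#' Find hybridization sites of a primer on templates
#'
#' Reports every site, on both strands, where the primer matches the
#' template under IUPAC expansion of the *primer only* with at most
#' `max_mismatch` mismatches and an exact match over the primer's
#' 3'-terminal `three_prime_run` bases. Ambiguous template bases (including
#' N) never match. Site strand is reported so that polymerase extension
#' proceeds 5'->3' into the template: a `-` site extends leftward.
#'
#' @param template Contig tibble, single DNA string, or named character
#'   vector of sequences.
#' @param primer Primer sequence 5'->3' (IUPAC codes allowed).
#' @param max_mismatch Maximum number of mismatches (default 2).
#' @param three_prime_run Number of 3'-terminal primer bases that must match
#'   exactly (default 3).
#' @param primer_name Label used in the output (defaults to the sequence).
#' @return Tibble of sites: `primer`, `template_id`, `start`, `end`
#'   (0-based half-open on the template's forward strand), `strand`,
#'   `mismatches`, `three_prime_ok`.
#' @export
find_primer_sites <- function(template, primer, max_mismatch = 2,
                              three_prime_run = 3,
                              primer_name = NULL) {
  primer <- normalise_dna(primer, "primer")
  if (is.null(primer_name)) primer_name <- primer
  contigs <- as_template(template)
  pb_fwd <- seq_bits(primer)
  pb_rev <- seq_bits(revcomp(primer))
  L <- length(pb_fwd)

  one_strand <- function(subject, tmpl_bits, pat, pat_bits, strand, id) {
    hits <- Biostrings::matchPattern(
      Biostrings::DNAString(pat), subject,
      max.mismatch = max_mismatch,
      fixed = c(pattern = FALSE, subject = TRUE))
    if (length(hits) == 0) return(NULL)
    st <- BiocGenerics::start(hits) - 1L # to 0-based
    keep <- st >= 0 & st + L <= length(tmpl_bits)
    st <- st[keep]
    if (length(st) == 0) return(NULL)
    rows <- lapply(st, function(s) {
      chunk <- tmpl_bits[(s + 1):(s + L)]
      mm <- primer_mismatches(pat_bits, chunk)
      if (mm > max_mismatch) return(NULL)
      # 3' end of the primer: rightmost bases for '+', leftmost for '-'
      idx <- if (strand == "+") (L - three_prime_run + 1):L else
        1:three_prime_run
      tp_ok <- primer_mismatches(pat_bits[idx], chunk[idx]) == 0
      if (!tp_ok) return(NULL)
      tibble::tibble(primer = primer_name, template_id = id,
                     start = s, end = s + L, strand = strand,
                     mismatches = mm, three_prime_ok = TRUE)
    })
    dplyr::bind_rows(rows)
  }

  out <- purrr::map_dfr(seq_len(nrow(contigs)), function(i) {
    seq <- contigs$seq[i]
    subject <- Biostrings::DNAString(seq)
    tb <- template_bits(seq)
    dplyr::bind_rows(
      one_strand(subject, tb, primer, pb_fwd, "+", contigs$id[i]),
      one_strand(subject, tb, revcomp(primer), pb_rev, "-", contigs$id[i])
    )
  })
  if (nrow(out) == 0) return(empty_sites())
  dplyr::arrange(out, .data$template_id, .data$start)
}

#' In-silico PCR
#'
#' Pairs every forward-strand site of either primer with every
#' reverse-strand site of either primer on the same template, keeping pairs
#' whose predicted product is at most `max_product` bp. The two primers are
#' interchangeable: either may act as the forward primer.
#'
#' @param template Contig tibble or DNA string(s).
#' @param fwd,rev Primer sequences 5'->3'.
#' @param max_product Maximum product length in bp (default 15000).
#' @param max_mismatch,three_prime_run Site-search stringency, see
#'   [find_primer_sites()].
#' @param fwd_name,rev_name Optional primer labels.
#' @return Tibble of amplicons sorted by length: `template_id`, `start`,
#'   `end`, `length`, `fwd_primer`, `rev_primer`, `fwd_mismatches`,
#'   `rev_mismatches`, `product` (sequence).
#' @export
simulate_pcr <- function(template, fwd, rev, max_product = 15000,
                         max_mismatch = 2, three_prime_run = 3,
                         fwd_name = NULL, rev_name = NULL) {
  contigs <- as_template(template)
  fwd <- normalise_dna(fwd, "primer")
  rev <- normalise_dna(rev, "primer")
  if (is.null(fwd_name)) fwd_name <- fwd
  if (is.null(rev_name)) rev_name <- rev
  primers <- unique(tibble::tibble(name = c(fwd_name, rev_name),
                                   seq = c(fwd, rev)))
  sites <- purrr::map_dfr(seq_len(nrow(primers)), function(i) {
    find_primer_sites(contigs, primers$seq[i], max_mismatch,
                      three_prime_run, primer_name = primers$name[i])
  })
  empty <- tibble::tibble(template_id = character(), start = integer(),
                          end = integer(), length = integer(),
                          fwd_primer = character(), rev_primer = character(),
                          fwd_mismatches = integer(),
                          rev_mismatches = integer(), product = character())
  if (nrow(sites) == 0) return(empty)
  plus <- sites[sites$strand == "+", ]
  minus <- sites[sites$strand == "-", ]
  if (nrow(plus) == 0 || nrow(minus) == 0) return(empty)
  out <- purrr::map_dfr(seq_len(nrow(contigs)), function(i) {
    id <- contigs$id[i]
    p <- plus[plus$template_id == id, ]
    m <- minus[minus$template_id == id, ]
    if (nrow(p) == 0 || nrow(m) == 0) return(NULL)
    grid <- tidyr::expand_grid(fi = seq_len(nrow(p)), ri = seq_len(nrow(m)))
    grid$start <- p$start[grid$fi]
    grid$end <- m$end[grid$ri]
    grid$length <- grid$end - grid$start
    grid <- grid[grid$length > 0 & grid$length <= max_product, ]
    if (nrow(grid) == 0) return(NULL)
    tibble::tibble(
      template_id = id, start = grid$start, end = grid$end,
      length = grid$length,
      fwd_primer = p$primer[grid$fi], rev_primer = m$primer[grid$ri],
      fwd_mismatches = p$mismatches[grid$fi],
      rev_mismatches = m$mismatches[grid$ri],
      product = substr(contigs$seq[i], grid$start + 1, grid$end))
  })
  if (nrow(out) == 0) return(empty)
  dplyr::arrange(out, .data$length)
}

#' Default primer design constraints
#'
#' @param length Allowed primer lengths (bp).
#' @param tm Allowed melting-temperature range (deg C).
#' @param gc Allowed GC range (percent).
#' @return Named list of constraints.
#' @export
primer_constraints <- function(length = 18:25, tm = c(55, 65),
                               gc = c(40, 60)) {
  list(length = length, tm = tm, gc = gc)
}

#' Design a primer inside a search window
#'
#' Enumerates every substring of the window at the allowed lengths, rejects
#' candidates containing ambiguous bases or violating the Tm/GC bounds,
#' scores survivors by `-|Tm - 60|` (ties: smaller `|GC - 50|`, then
#' leftmost) and returns the best candidate that has exactly one
#' hybridization site in the uniqueness scope. Fully deterministic.
#'
#' @param template Contig tibble or single DNA string holding the window.
#' @param template_id Id of the contig carrying the window (default: first).
#' @param window Integer vector `c(start, end)`, 0-based half-open, within
#'   which the primer's footprint must lie.
#' @param direction `"fwd"` designs on the forward strand (reads rightward),
#'   `"rev"` on the reverse strand (reads leftward).
#' @param constraints See [primer_constraints()].
#' @param uniqueness_scope Contig tibble against which specificity is
#'   checked (default: the template itself). `NULL` skips the check.
#' @param name Name for the designed primer.
#' @return One-row tibble: `name`, `seq`, `tm`, `gc`, `template_id`,
#'   `start`, `end`, `strand`, `status` (`"ok"` or `"undesignable"`),
#'   `reason`.
#' @export
design_primer <- function(template, window, direction = c("fwd", "rev"),
                          template_id = NULL,
                          constraints = primer_constraints(),
                          uniqueness_scope = template, name = "primer") {
  direction <- match.arg(direction)
  contigs <- as_template(template)
  if (is.null(template_id)) template_id <- contigs$id[1]
  seq <- contigs$seq[match(template_id, contigs$id)]
  ws <- max(0L, as.integer(window[1]))
  we <- min(nchar(seq), as.integer(window[2]))
  fail <- function(reason) {
    tibble::tibble(name = name, seq = NA_character_, tm = NA_real_,
                   gc = NA_real_, template_id = template_id,
                   start = NA_integer_, end = NA_integer_,
                   strand = if (direction == "fwd") "+" else "-",
                   status = "undesignable", reason = reason)
  }
  if (we - ws < min(constraints$length)) {
    return(fail("search window shorter than minimum primer length"))
  }
  win <- substr(seq, ws + 1, we)
  n_amb <- n_tm <- n_gc <- 0L
  cand <- list()
  for (L in constraints$length) {
    n_pos <- nchar(win) - L + 1
    if (n_pos < 1) next
    starts <- seq_len(n_pos)
    subs <- substring(win, starts, starts + L - 1)
    pure <- grepl("^[ACGT]+$", subs)
    n_amb <- n_amb + sum(!pure)
    for (j in which(pure)) {
      s <- subs[j]
      gc <- gc_content(s)
      if (gc < constraints$gc[1] || gc > constraints$gc[2]) {
        n_gc <- n_gc + 1L
        next
      }
      tm <- melting_temp(s)
      if (tm < constraints$tm[1] || tm > constraints$tm[2]) {
        n_tm <- n_tm + 1L
        next
      }
      cand[[length(cand) + 1]] <- list(start = ws + starts[j] - 1L, len = L,
                                       tm = tm, gc = gc, seq = s)
    }
  }
  if (length(cand) == 0) {
    return(fail(sprintf(
      "no candidate passed constraints (ambiguous: %d, GC: %d, Tm: %d)",
      n_amb, n_gc, n_tm)))
  }
  score <- vapply(cand, function(x) -abs(x$tm - 60), 0)
  tie <- vapply(cand, function(x) abs(x$gc - 50), 0)
  pos <- vapply(cand, function(x) x$start, 0L)
  ord <- order(-score, tie, pos)
  n_unique_fail <- 0L
  scope_set <- if (!is.null(uniqueness_scope)) {
    Biostrings::DNAStringSet(as_template(uniqueness_scope)$seq)
  }
  for (k in ord) {
    x <- cand[[k]]
    oligo <- if (direction == "fwd") x$seq else revcomp(x$seq)
    if (!is.null(uniqueness_scope)) {
      # fast permissive site count (mismatch budget without the 3' rule);
      # the designed footprint itself is exact, so a count of one implies
      # exactly one strict hybridization site as well
      ns <- sum(Biostrings::vcountPattern(oligo, scope_set,
                                          max.mismatch = 2)) +
        sum(Biostrings::vcountPattern(revcomp(oligo), scope_set,
                                      max.mismatch = 2))
      if (ns != 1) {
        n_unique_fail <- n_unique_fail + 1L
        if (n_unique_fail >= 25L) break # give up: window is repetitive
        next
      }
    }
    return(tibble::tibble(
      name = name, seq = oligo, tm = x$tm, gc = x$gc,
      template_id = template_id, start = x$start, end = x$start + x$len,
      strand = if (direction == "fwd") "+" else "-",
      status = "ok", reason = NA_character_))
  }
  fail(sprintf(
    "no constraint-satisfying unique oligo (uniqueness failures: %d)",
    n_unique_fail))
}

#' Template purity check against distant primer pairs
#'
#' A candidate template (e.g. a gel-purified gap amplicon) passes when none
#' of the supplied distant-locus primer pairs yields an in-silico product on
#' it, mirroring the contamination control used for genomic-template PCR.
#'
#' @param template Contig tibble or DNA string (may be empty).
#' @param pairs Tibble with columns `fwd` and `rev` (primer sequences),
#'   optionally `name`.
#' @param ... Passed to [simulate_pcr()].
#' @return Tibble with one row per pair (`name`, `n_products`, `pass`) plus
#'   attribute `pass` (overall).
#' @export
purity_check <- function(template, pairs, ...) {
  if (!all(c("fwd", "rev") %in% names(pairs))) {
    stop("pairs must have columns 'fwd' and 'rev'", call. = FALSE)
  }
  if (is.null(pairs$name)) pairs$name <- paste0("pair_", seq_len(nrow(pairs)))
  empty_template <- (is.character(template) &&
                       all(!nzchar(template))) ||
    (is.data.frame(template) && nrow(template) == 0)
  res <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    np <- if (empty_template) 0L else
      nrow(simulate_pcr(template, pairs$fwd[i], pairs$rev[i], ...))
    tibble::tibble(name = pairs$name[i], n_products = np, pass = np == 0)
  })
  attr(res, "pass") <- all(res$pass)
  res
}

#' Universal 16S/23S primer set
#'
#' The universal and operon-walking primers used for rDNA gap testing and
#' the six-reaction parallel walk: 8F/1492R (16S), 127F/2241R (23S, with
#' degenerate IUPAC positions) and the walk primers U1-U4.
#'
#' @return Tibble with columns `name`, `sequence`, `gene`, `direction`.
#' @export
universal_primers <- function() {
  read_primer_table(system.file("extdata", "universal_primers.tsv",
                                package = "rdnafinish", mustWork = TRUE))
}

#' CR1 gap-specific primer pairs
#'
#' The published gap-amplification primer pairs for the *P. polymyxa* CR1
#' draft (one row per contig gap, forward and reverse sequence).
#'
#' @return Tibble with columns `gap`, `fwd`, `rev`.
#' @export
cr1_gap_primers <- function() {
  readr::read_tsv(system.file("extdata", "cr1_gap_primers.tsv",
                              package = "rdnafinish", mustWork = TRUE),
                  show_col_types = FALSE)
}

#' Read / write a primer table
#'
#' TSV with header columns `name`, `sequence`, `gene`, `direction`.
#'
#' @param path File path.
#' @return Tibble of primers.
#' @export
read_primer_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("name", "sequence")
  if (!all(need %in% names(out))) {
    stop("primer table must have columns 'name' and 'sequence'",
         call. = FALSE)
  }
  out$sequence <- normalise_dna(out$sequence, "primer")
  out
}

#' @rdname read_primer_table
#' @param primers Tibble of primers.
#' @export
write_primer_table <- function(primers, path) {
  readr::write_tsv(primers, path)
  invisible(path)
}
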