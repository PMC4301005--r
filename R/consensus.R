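# Consensus building for ribosomal subunit genes from near-identical copies.

# Expected biological length ranges used for sanity warnings.
.gene_length_ranges <- list(`16S` = c(1400, 1600), `23S` = c(2700, 3100),
                            `5S` = c(100, 130))

#' Build a consensus gene from same-gene copies
#'
#' Column-wise majority consensus. Equal-length inputs are treated as
#' already columnwise-comparable; copies of differing length are first
#' aligned to the longest copy by global pairwise alignment (match +1,
#' mismatch -1, gap -2 per base) and merged center-star style. Ties between
#' bases emit the IUPAC code covering the tied bases; columns whose
#' plurality symbol is a gap are dropped.
#'
#' @param copies Character vector of DNA sequences (>= 1), e.g. Sanger reads
#'   of individual operon copies.
#' @param name Gene name, conventionally one of `"16S"`, `"23S"`, `"5S"`.
#' @return One-row tibble: `gene`, `seq`, `length`.
#' @export
#' @examples
#' build_consensus(c("ACGT", "ACGT", "ACAT"), "16S")
build_consensus <- function(copies, name = "gene") {
  if (length(copies) == 0) stop("no input copies", call. = FALSE)
  copies <- vapply(copies, normalise_dna, "", USE.NAMES = FALSE)
  if (any(!nzchar(copies))) stop("empty input copy", call. = FALSE)
  mat <- if (length(unique(nchar(copies))) == 1) {
    do.call(rbind, strsplit(copies, NULL))
  } else {
    align_copies(copies)
  }
  cons <- apply(mat, 2, consensus_symbol)
  seq <- paste(cons[cons != "-"], collapse = "")
  rng <- .gene_length_ranges[[name]]
  if (!is.null(rng) && (nchar(seq) < rng[1] || nchar(seq) > rng[2])) {
    warning(sprintf("%s consensus length %d outside expected range %d-%d bp",
                    name, nchar(seq), rng[1], rng[2]), call. = FALSE)
  }
  tibble::tibble(gene = name, seq = seq, length = nchar(seq))
}

# Plurality symbol of one alignment column; base ties -> covering IUPAC
# code; '-' returned when the gap is the strict plurality.
consensus_symbol <- function(col) {
  tab <- sort(table(col), decreasing = TRUE)
  top <- max(tab)
  winners <- names(tab)[tab == top]
  if ("-" %in% winners) {
    if (length(winners) == 1) return("-")
    winners <- setdiff(winners, "-")
  }
  if (length(winners) == 1) return(winners)
  iupac_union_code(winners)
}

# Center-star alignment of copies to the longest copy using the package's
# consensus scoring (match +1, mismatch -1, gap -2 per gapped base).
align_copies <- function(copies) {
  center_i <- which.max(nchar(copies))
  center <- copies[center_i]
  others <- copies[-center_i]
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = FALSE)
  alns <- lapply(others, function(s) {
    a <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(s), Biostrings::DNAString(center),
      type = "global", substitutionMatrix = sm,
      gapOpening = 0, gapExtension = 2)
    list(pat = as.character(Biostrings::alignedPattern(a)),
         sub = as.character(Biostrings::alignedSubject(a)))
  })
  # Union insertion profile: max insertions after each center position.
  ins_profile <- integer(nchar(center) + 1) # index 1 = before first base
  per_aln <- lapply(alns, function(a) {
    sub_chars <- strsplit(a$sub, NULL)[[1]]
    # map each alignment column to a center position (0 = before first)
    cpos <- cumsum(sub_chars != "-")
    ins <- tabulate(cpos[sub_chars == "-"] + 1L,
                    nbins = nchar(center) + 1L)
    list(pat = strsplit(a$pat, NULL)[[1]], sub = sub_chars, cpos = cpos,
         ins = ins)
  })
  for (a in per_aln) ins_profile <- pmax(ins_profile, a$ins)

  expand_row <- function(chars, cpos, ins) {
    # re-pad each run of insertions after center position p to the profile
    out <- character(0)
    idx <- 1
    for (p in 0:nchar(center)) {
      block <- which(cpos == p)
      ins_here <- if (p == 0) block else block[-1]
      base_col <- if (p == 0) integer(0) else block[1]
      pad <- ins_profile[p + 1] - length(ins_here)
      out <- c(out, chars[base_col], chars[ins_here], rep("-", pad))
    }
    out
  }
  center_chars <- strsplit(center, NULL)[[1]]
  center_row <- character(0)
  for (p in 0:nchar(center)) {
    base <- if (p == 0) character(0) else center_chars[p]
    center_row <- c(center_row, base, rep("-", ins_profile[p + 1]))
  }
  rows <- c(list(center_row),
            lapply(per_aln, function(a) expand_row(a$pat, a$cpos, a$ins)))
  do.call(rbind, rows)
}

#' Coerce consensus gene input to a gene table
#'
#' Accepts a gene tibble (`gene`, `seq`), a named character vector of
#' sequences, or a FASTA path whose record ids are gene names.
#'
#' @param genes Gene input.
#' @return Tibble with columns `gene`, `seq`, `length`.
#' @export
as_gene_table <- function(genes) {
  if (is.data.frame(genes)) {
    stopifnot(all(c("gene", "seq") %in% names(genes)))
    genes$length <- nchar(genes$seq)
    return(tibble::as_tibble(genes))
  }
  if (is.character(genes) && length(genes) == 1 && file.exists(genes)) {
    ctg <- read_contigs(genes)
    return(tibble::tibble(gene = ctg$id, seq = ctg$seq, length = ctg$length))
  }
  if (is.character(genes)) {
    if (is.null(names(genes))) stop("gene sequences must be named",
                                    call. = FALSE)
    return(tibble::tibble(gene = names(genes),
                          seq = normalise_dna(unname(genes)),
                          length = nchar(genes)))
  }
  stop("cannot interpret consensus genes", call. = FALSE)
}
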