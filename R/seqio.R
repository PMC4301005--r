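# FASTA / FASTQ / GenBank ingestion and the standard assembly QC statistics.

#' Read a draft assembly from FASTA
#'
#' Reads a multi-record FASTA file into a contig table. Sequences are folded
#' to upper case, RNA `U` is folded to `T`, and any character outside the
#' IUPAC nucleotide alphabet is a fatal parse error. Record order is
#' preserved and ids (the first whitespace-delimited header token) must be
#' unique.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `seq`, `length` (bp), one row per
#'   record.
#' @export
read_contigs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0) stop("no FASTA records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(x))
  if (any(ids == "")) {
    stop("malformed FASTA header (empty id) at record ",
         which(ids == "")[1], " in ", path, call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("duplicate contig id '", dup, "' in ", path, call. = FALSE)
  }
  seqs <- as.character(x)
  if (any(nchar(seqs) == 0)) {
    stop("empty sequence for record '", ids[which(nchar(seqs) == 0)[1]],
         "' in ", path, call. = FALSE)
  }
  seqs <- vapply(seq_along(seqs), function(i) {
    tryCatch(normalise_dna(seqs[i]),
             error = function(e) stop("record '", ids[i], "': ",
                                      conditionMessage(e), call. = FALSE))
  }, "")
  as_contigs(ids, seqs)
}

#' Build a contig table from ids and sequences
#'
#' @param id Character vector of unique contig ids.
#' @param seq Character vector of upper-case IUPAC DNA sequences.
#' @return A contig tibble (`id`, `seq`, `length`).
#' @export
as_contigs <- function(id, seq) {
  stopifnot(length(id) == length(seq))
  if (anyDuplicated(id)) stop("contig ids must be unique", call. = FALSE)
  tibble::tibble(id = as.character(id), seq = as.character(seq),
                 length = nchar(seq))
}

#' Write a contig table to FASTA
#'
#' @param contigs Contig tibble (`id`, `seq`).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_contigs <- function(contigs, path) {
  x <- Biostrings::BStringSet(contigs$seq)
  names(x) <- contigs$id
  Biostrings::writeXStringSet(x, path, width = 80)
  invisible(path)
}

#' Read a reference genome from FASTA or GenBank flat file
#'
#' Format is auto-detected from the first non-blank line (`LOCUS` for
#' GenBank, `>` for FASTA). For GenBank input, `rRNA`, `tRNA` and `CDS`
#' features are returned with 0-based half-open coordinates converted from
#' the 1-based inclusive source convention; `join(...)` locations are
#' collapsed to their outer span. FASTA input yields an empty feature table.
#'
#' @param path Path to the reference file.
#' @return A list of class `reference_genome` with elements `sequence`
#'   (contig tibble) and `features` (tibble `type`, `start`, `end`,
#'   `strand`).
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- ""
  con <- file(path, "r")
  on.exit(close(con), add = TRUE)
  while (length(l <- readLines(con, 1)) && !nzchar(trimws(l))) {}
  first <- if (length(l)) l else ""
  if (startsWith(first, ">")) {
    seqs <- read_contigs(path)
    out <- list(sequence = seqs, features = empty_features())
  } else if (startsWith(first, "LOCUS")) {
    out <- parse_genbank(path)
  } else {
    stop("unknown reference format (expected FASTA or GenBank): ", path,
         call. = FALSE)
  }
  structure(out, class = "reference_genome")
}

empty_features <- function() {
  tibble::tibble(type = character(), start = integer(), end = integer(),
                 strand = character())
}

# Minimal GenBank flat-file reader: LOCUS name, selected features, ORIGIN
# sequence. Qualifier lines are ignored.
parse_genbank <- function(path) {
  lines <- readLines(path)
  locus <- lines[startsWith(lines, "LOCUS")][1]
  if (is.na(locus)) stop("GenBank file without LOCUS line: ", path,
                         call. = FALSE)
  id <- strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1]][1]

  keep_types <- c("rRNA", "tRNA", "CDS")
  feat <- list()
  in_features <- FALSE
  i <- 1
  n <- length(lines)
  while (i <= n) {
    l <- lines[i]
    if (startsWith(l, "FEATURES")) { in_features <- TRUE; i <- i + 1; next }
    if (startsWith(l, "ORIGIN")) break
    if (in_features && grepl("^ {5}\\S", l)) {
      key <- sub("^\\s+", "", substr(l, 1, 20))
      key <- strsplit(key, "\\s+")[[1]][1]
      loc <- trimws(substr(l, 22, nchar(l)))
      # location may continue on following lines
      while (i + 1 <= n && grepl("^ {21}", lines[i + 1]) &&
             !grepl("^ {21}/", lines[i + 1])) {
        loc <- paste0(loc, trimws(lines[i + 1]))
        i <- i + 1
      }
      if (key %in% keep_types) feat[[length(feat) + 1]] <- c(key, loc)
    }
    i <- i + 1
  }
  seq <- ""
  if (i <= n && startsWith(lines[i], "ORIGIN")) {
    body <- lines[(i + 1):n]
    body <- body[!startsWith(body, "//")]
    seq <- paste(gsub("[ 0-9/]", "", body), collapse = "")
    seq <- normalise_dna(seq, "ORIGIN sequence")
  }
  if (!nzchar(seq)) stop("GenBank file without sequence: ", path,
                         call. = FALSE)
  features <- if (length(feat)) {
    purrr::map_dfr(feat, function(f) {
      loc <- parse_gb_location(f[2])
      tibble::tibble(type = f[1], start = loc$start, end = loc$end,
                     strand = loc$strand)
    })
  } else {
    empty_features()
  }
  list(sequence = as_contigs(id, seq), features = features)
}

# "10..100", "complement(10..100)", "join(1..5,10..20)" -> 0-based half-open
# outer span plus strand.
parse_gb_location <- function(loc) {
  strand <- if (grepl("complement", loc)) "-" else "+"
  nums <- as.integer(unlist(regmatches(loc, gregexpr("[0-9]+", loc))))
  if (length(nums) < 2) stop("cannot parse GenBank location: ", loc,
                             call. = FALSE)
  list(start = min(nums) - 1L, end = max(nums), strand = strand)
}

#' Read per-base Phred qualities from FASTQ
#'
#' Expects Sanger Phred+33 encoding.
#'
#' @param path Path to an (uncompressed) FASTQ file.
#' @return A tibble with columns `id` and `quals` (list column of integer
#'   Phred scores, one per base).
#' @export
read_fastq_quality <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  q <- as.character(S4Vectors::mcols(x)$qualities)
  tibble::tibble(
    id = sub("\\s.*$", "", names(x)),
    quals = lapply(q, function(s) utf8ToInt(s) - 33L)
  )
}

#' N50 of an assembly
#'
#' The size of the contig at which half of the total assembly bases are
#' accounted for when that contig is combined with all longer contigs
#' (threshold met with `>=`).
#'
#' @param x Contig tibble (with a `length` column) or a numeric vector of
#'   contig lengths.
#' @return Integer N50 in bp; always the length of one of the contigs.
#' @export
#' @examples
#' n50(c(10, 8, 6, 4, 2)) # 8
n50 <- function(x) {
  lens <- if (is.data.frame(x)) x$length else x
  lens <- as.numeric(lens)
  if (length(lens) == 0) stop("empty assembly", call. = FALSE)
  if (any(lens < 0)) stop("negative contig length", call. = FALSE)
  lens <- sort(lens, decreasing = TRUE)
  cum <- cumsum(lens)
  out <- lens[which(cum >= sum(lens) / 2)[1]]
  if (out <= .Machine$integer.max) as.integer(out) else out
}

#' Fraction of bases at or above a quality threshold
#'
#' The run-level quality statistic usually reported as "Q30": the fraction
#' of all bases whose Phred score `Q = -10 log10(e)` meets the threshold.
#'
#' @param records Quality table from [read_fastq_quality()], or a list /
#'   vector of integer Phred scores.
#' @param threshold Minimum Phred score counted as high quality (default 30,
#'   i.e. a 1/1000 error chance).
#' @return Fraction in `[0, 1]`.
#' @export
q30_fraction <- function(records, threshold = 30) {
  q <- if (is.data.frame(records)) unlist(records$quals) else unlist(records)
  if (length(q) == 0) stop("no bases", call. = FALSE)
  mean(q >= threshold)
}

#' Phred score for an error probability
#'
#' @param e Error probability in (0, 1].
#' @return `-10 * log10(e)`.
#' @export
phred_from_error <- function(e) {
  stopifnot(all(e > 0), all(e <= 1))
  -10 * log10(e)
}

#' Fold coverage of a sequencing library
#'
#' @param total_read_bases Total sequenced bases (bp).
#' @param genome_size Genome size (bp), must be positive.
#' @return Fold coverage (dimensionless).
#' @export
#' @examples
#' estimate_coverage(600e6, 6e6) # 100
estimate_coverage <- function(total_read_bases, genome_size) {
  if (genome_size <= 0) stop("genome size must be positive", call. = FALSE)
  total_read_bases / genome_size
}

#' Assembly summary statistics
#'
#' @param contigs Contig tibble.
#' @param total_read_bases Optional total sequenced bases for a coverage
#'   estimate.
#' @param genome_size Genome size used for the coverage estimate; defaults
#'   to the assembly's total bases.
#' @return One-row tibble: `n_contigs`, `total_bp`, `n50`, `coverage`.
#' @export
assembly_stats <- function(contigs, total_read_bases = NULL,
                           genome_size = NULL) {
  total <- sum(contigs$length)
  cov <- NA_real_
  if (!is.null(total_read_bases)) {
    gs <- if (is.null(genome_size)) total else genome_size
    cov <- estimate_coverage(total_read_bases, gs)
  }
  tibble::tibble(n_contigs = nrow(contigs), total_bp = total,
                 n50 = n50(contigs), coverage = cov)
}

# Add 1-based inclusive companion columns to an interval table for
# human-readable TSV reports (internal coordinates stay 0-based half-open).
add_1based <- function(df, start = "start", end = "end") {
  if (start %in% names(df)) df[[paste0(start, "_1based")]] <- df[[start]] + 1L
  if (end %in% names(df)) df[[paste0(end, "_1based")]] <- df[[end]]
  df
}
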