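# End-to-end finishing workflow: masking -> end annotation -> N stretches
# and flanking primers -> small-contig placement -> scaffolding -> gap
# classification and walk plans -> rearrangement detection -> validation.

#' Configuration for the finishing pipeline
#'
#' Every tunable named by a pipeline stage, with its default. Values can be
#' overridden individually; the effective configuration is embedded in the
#' report for reproducibility.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of configuration values.
#' @export
finishing_config <- function(...) {
  cfg <- list(
    scan_min_identity = 90, scan_min_fragment = 100,
    mask_max_length = 2000, mask_min_cover = 0.8,
    end_window = 200,
    n_min_length = 3, flank_search_window = 350,
    place_flank_window = 300, place_min_identity = 95,
    anchor_k = 21, anchor_step = 250,
    circular = TRUE,
    gap_offset_range = c(250, 350),
    pcr_max_product = 15000,
    size_16s = c(1200, 1700), size_23s = c(1800, 2400),
    read_span = c(750, 1000),
    window = 10000, window_step = 5000, min_jump = 50000,
    small_max_length = 1000,
    verify_min_identity = 99, verify_min_cover = 0.99,
    design_flanking_primers = TRUE)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config option(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  cfg
}

#' Run the genome-finishing planning workflow
#'
#' Executes, in order: rRNA-contig masking, contig-end annotation,
#' N-stretch detection (optionally with flanking primer design),
#' small-contig placement, reference-guided scaffolding with gap
#' enumeration, gap primer design and rDNA gap classification with walk
#' plans, rearrangement detection with junction primers, and (when a final
#' assembly is supplied) draft-coverage validation. Stages that need a
#' reference are skipped without one.
#'
#' @param draft Draft contigs: tibble or FASTA path.
#' @param genes Consensus gene table for the rDNA scan (see
#'   [as_gene_table()]); typically 16S/23S/5S.
#' @param reference Optional finished related genome (path, tibble, or
#'   `reference_genome`).
#' @param genomic_template Optional genome sequence used as the in-silico
#'   PCR template for gap amplification (the stand-in for genomic DNA).
#'   Defaults to the reference.
#' @param final_assembly Optional finished sequence to validate against
#'   the original draft.
#' @param config See [finishing_config()].
#' @param out_dir Optional directory; when given, per-stage artifact files
#'   (TSV/BED/JSON/FASTA) and `report.json` are written.
#' @return Object of class `finishing_report` with one element per stage
#'   and `summary` (one-row tibble of the headline counts).
#' @export
run_finishing_plan <- function(draft, genes, reference = NULL,
                               genomic_template = NULL,
                               final_assembly = NULL,
                               config = finishing_config(),
                               out_dir = NULL) {
  contigs <- if (is.character(draft) && length(draft) == 1 &&
                 file.exists(draft)) read_contigs(draft) else
                   as_template(draft)
  genes <- as_gene_table(genes)
  if (is.character(reference) && length(reference) == 1) {
    reference <- read_reference(reference)
  }
  if (is.null(genomic_template)) genomic_template <- reference

  report <- list(config = config, n_input_contigs = nrow(contigs))

  # -- stage 1: rDNA scan and masking --------------------------------
  hits <- scan_contigs(contigs, genes,
                       min_identity = config$scan_min_identity,
                       min_fragment = config$scan_min_fragment)
  mask <- mask_rrna_contigs(contigs, hits,
                            max_length = config$mask_max_length,
                            min_cover = config$mask_min_cover)
  working <- mask$contigs
  report$hits <- hits
  report$mask <- mask

  # -- stage 2: end annotation ---------------------------------------
  ends <- annotate_contig_ends(working,
                               hits[hits$contig_id %in% working$id, ],
                               end_window = config$end_window)
  report$ends <- ends

  # -- stage 3: N stretches and flanking primers ---------------------
  stretches <- find_n_stretches(working, min_length = config$n_min_length)
  report$stretches <- stretches
  if (isTRUE(config$design_flanking_primers) && nrow(stretches) > 0) {
    report$flanking_primers <- design_n_flanking_primers(
      working, stretches, search_window = config$flank_search_window,
      uniqueness_scope = working)
  }

  # -- stage 4: place small contigs into stretches -------------------
  small_max <- config$small_max_length
  small <- working[working$length < small_max &
                     !grepl("N", working$seq), , drop = FALSE]
  hosts <- working[!working$id %in% small$id, , drop = FALSE]
  host_stretches <- stretches[stretches$contig_id %in% hosts$id, ,
                              drop = FALSE]
  placement <- place_small_contigs(
    small, hosts, host_stretches,
    flank_window = config$place_flank_window,
    min_flank_identity = config$place_min_identity)
  working <- placement$contigs
  report$placement <- placement

  # -- stage 5: scaffold against the reference -----------------------
  layout <- NULL
  gaps <- NULL
  anchors <- NULL
  if (!is.null(reference)) {
    anchors <- anchor_contigs(working, reference, k = config$anchor_k,
                              step = config$anchor_step)
    layout <- order_and_orient(working, anchors)
    if (nrow(layout$placements) >= 2) {
      gaps <- estimate_gap_sizes(layout, anchors, working, reference,
                                 circular = config$circular)
    }
    report$layout <- layout
    report$gaps <- gaps
  }

  # -- stage 6: gap primers, rDNA classification, walk plans ---------
  if (!is.null(gaps) && !is.null(genomic_template)) {
    gt <- as_template(genomic_template)
    primers <- universal_primers()
    g5 <- genes$seq[match("5S", genes$gene)]
    gap_rows <- list()
    plans <- list()
    for (i in seq_len(nrow(gaps))) {
      gp <- design_gap_primers(gaps[i, ], layout, working,
                               offset_range = config$gap_offset_range,
                               uniqueness_scope = working)
      row <- gaps[i, ]
      row$primers_ok <- all(gp$status == "ok")
      row$amplicon_length <- NA_integer_
      plan <- NULL
      if (row$primers_ok) {
        amp <- simulate_pcr(gt, gp$seq[1], gp$seq[2],
                            max_product = config$pcr_max_product)
        if (nrow(amp) > 0) {
          amp <- amp[1, ]
          row$amplicon_length <- amp$length
          cls <- classify_gap_rdna(amp$product, primers,
                                   consensus_5s = g5,
                                   size_16s = config$size_16s,
                                   size_23s = config$size_23s)
          row$rdna <- cls$rdna
          row$has_16s <- cls$has_16s
          row$has_23s <- cls$has_23s
          row$has_5s <- cls$has_5s
          plan <- if (cls$has_16s && cls$has_23s) {
            plan_rdna_walk(amp$product, gp$seq[1], gp$seq[2],
                           primers = primers,
                           read_span = config$read_span,
                           gap_id = row$gap_id)
          } else {
            plan_traditional_walk(max(1, amp$length),
                                  read_span = config$read_span,
                                  gap_id = row$gap_id)
          }
        }
      }
      if (is.null(plan)) {
        plan <- plan_traditional_walk(max(1, row$size),
                                      read_span = config$read_span,
                                      gap_id = row$gap_id)
      }
      gap_rows[[i]] <- row
      plans[[i]] <- plan
    }
    gaps <- dplyr::bind_rows(gap_rows)
    report$gaps <- gaps
    report$plans <- plans
  }

  # -- stage 7: rearrangements ---------------------------------------
  if (!is.null(layout) && nrow(layout$placements) >= 1) {
    pseudo <- pseudo_draft(layout, working)
    wmap <- window_map(pseudo$seq, reference, window = config$window,
                       step = config$window_step, k = config$anchor_k)
    pseudo_stretches <- find_n_stretches(pseudo$seq,
                                         min_length = config$n_min_length)
    calls <- call_rearrangements(wmap, min_jump = config$min_jump,
                                 n_stretches = pseudo_stretches)
    junctions <- if (nrow(calls) > 0) {
      purrr::map_dfr(seq_len(nrow(calls)), function(i) {
        dplyr::mutate(design_junction_primers(calls[i, ], pseudo$seq),
                      call_id = calls$call_id[i], .before = 1)
      })
    } else NULL
    report$window_map <- wmap
    report$rearrangements <- calls
    report$junction_primers <- junctions
  }

  # -- stage 8: validation -------------------------------------------
  if (!is.null(final_assembly)) {
    report$validation <- verify_draft_coverage(
      contigs, final_assembly,
      min_identity = config$verify_min_identity,
      min_cover = config$verify_min_cover,
      circular = config$circular)
  }

  report$summary <- tibble::tibble(
    n_contigs_input = nrow(contigs),
    n_masked = sum(mask$report$masked),
    n_after_masking = nrow(mask$contigs),
    n_annotated_ends = sum(ends$annotated),
    n_total_ends = nrow(ends),
    n_stretches = nrow(stretches),
    n_placed = nrow(placement$placements),
    n_after_placement = nrow(placement$contigs),
    n_gaps = if (!is.null(gaps)) nrow(gaps) else NA_integer_,
    n_rdna_gaps = if (!is.null(gaps) && "rdna" %in% names(gaps)) {
      sum(gaps$rdna == "present", na.rm = TRUE)
    } else NA_integer_,
    n_rearrangements = if (!is.null(report$rearrangements)) {
      nrow(report$rearrangements)
    } else NA_integer_,
    validation_pass = if (!is.null(report$validation)) {
      report$validation$pass
    } else NA)

  out <- structure(report, class = "finishing_report")
  if (!is.null(out_dir)) write_report_artifacts(out, out_dir)
  out
}

# Concatenate placed contigs in layout order and orientation into one
# pseudo-draft coordinate system (unplaced contigs appended at the end).
pseudo_draft <- function(layout, contigs) {
  pl <- layout$placements
  seqs <- vapply(seq_len(nrow(pl)), function(i) {
    s <- contigs$seq[match(pl$contig_id[i], contigs$id)]
    if (pl$orientation[i] == "-") revcomp(s) else s
  }, "")
  offsets <- cumsum(c(0, nchar(seqs)[-length(seqs)]))
  list(seq = paste(seqs, collapse = ""),
       offsets = tibble::tibble(contig_id = pl$contig_id,
                                offset = offsets))
}

#' Write finishing-report artifacts to a directory
#'
#' One subdirectory per stage with TSV/BED/JSON/FASTA artifacts, plus a
#' machine-readable `report.json` written last. Interval TSVs carry
#' 1-based companion columns (`*_1based`); BED and JSON stay 0-based.
#'
#' @param report `finishing_report`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, `out_dir`.
#' @export
write_report_artifacts <- function(report, out_dir) {
  mkd <- function(...) {
    d <- file.path(out_dir, ...)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    d
  }
  d <- mkd("mask")
  readr::write_tsv(add_1based(report$hits), file.path(d, "rdna_hits.tsv"))
  write_bed(report$hits, file.path(d, "rdna_hits.bed"),
            chrom = "contig_id", name = "gene", score = "identity")
  readr::write_tsv(report$mask$report, file.path(d, "mask_report.tsv"))
  jsonlite::write_json(report$mask$report, file.path(d, "mask_report.json"),
                       dataframe = "rows")
  d <- mkd("ends")
  readr::write_tsv(report$ends, file.path(d, "end_annotation.tsv"))
  d <- mkd("nstretch")
  readr::write_tsv(add_1based(report$stretches),
                   file.path(d, "n_stretches.tsv"))
  write_bed(report$stretches, file.path(d, "n_stretches.bed"),
            chrom = "contig_id")
  if (!is.null(report$flanking_primers)) {
    readr::write_tsv(report$flanking_primers,
                     file.path(d, "flanking_primers.tsv"))
  }
  d <- mkd("placement")
  readr::write_tsv(report$placement$placements,
                   file.path(d, "placements.tsv"))
  readr::write_tsv(report$placement$unplaced, file.path(d, "unplaced.tsv"))
  write_contigs(report$placement$contigs, file.path(d, "merged_contigs.fa"))
  if (!is.null(report$layout)) {
    d <- mkd("scaffold")
    readr::write_tsv(report$layout$placements, file.path(d, "layout.tsv"))
    if (!is.null(report$gaps)) {
      readr::write_tsv(report$gaps |> dplyr::select(-dplyr::any_of("content")),
                       file.path(d, "gaps.tsv"))
      jsonlite::write_json(report$gaps, file.path(d, "gaps.json"),
                           dataframe = "rows")
    }
  }
  if (!is.null(report$plans)) {
    d <- mkd("plans")
    for (p in report$plans) {
      base <- gsub("[^A-Za-z0-9_.-]", "_", p$gap_id)
      jsonlite::write_json(unclass(p), file.path(d, paste0(base, ".json")),
                           dataframe = "rows", auto_unbox = TRUE)
      readr::write_tsv(p$reactions,
                       file.path(d, paste0(base, "_bench.tsv")))
    }
  }
  if (!is.null(report$rearrangements)) {
    d <- mkd("rearrange")
    readr::write_tsv(report$window_map$placements,
                     file.path(d, "window_placements.tsv"))
    readr::write_tsv(report$rearrangements, file.path(d, "calls.tsv"))
    jsonlite::write_json(report$rearrangements, file.path(d, "calls.json"),
                         dataframe = "rows")
    if (!is.null(report$junction_primers)) {
      readr::write_tsv(report$junction_primers,
                       file.path(d, "junction_primers.tsv"))
    }
  }
  if (!is.null(report$validation)) {
    d <- mkd("validate")
    readr::write_tsv(report$validation$per_contig,
                     file.path(d, "coverage.tsv"))
  }
  jsonlite::write_json(
    list(summary = report$summary, config = report$config),
    file.path(out_dir, "report.json"), dataframe = "rows",
    auto_unbox = TRUE)
  invisible(out_dir)
}

#' Write an interval tibble as BED
#'
#' Six-column BED (chrom, start, end, name, score, strand) from any tibble
#' with 0-based half-open `start`/`end` columns.
#'
#' @param df Tibble of intervals.
#' @param path Output path.
#' @param chrom,name,score,strand Column names to draw each BED field from
#'   (missing ones produce `.`/0).
#' @return Invisibly, `path`.
#' @export
write_bed <- function(df, path, chrom = "contig_id", name = NULL,
                      score = NULL, strand = "strand") {
  get_col <- function(col, default) {
    if (!is.null(col) && col %in% names(df)) df[[col]] else
      rep(default, nrow(df))
  }
  bed <- tibble::tibble(
    chrom = get_col(chrom, "."),
    start = df$start, end = df$end,
    name = get_col(name, "."),
    score = if (!is.null(score) && score %in% names(df)) {
      round(df[[score]] * 10)
    } else rep(0, nrow(df)),
    strand = get_col(strand, "."))
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
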