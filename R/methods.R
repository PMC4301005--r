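# Tidiers, print methods and plots for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.walk_plan <- function(x, ...) {
  dplyr::mutate(x$reactions, gap_id = x$gap_id, strategy = x$strategy,
                .before = 1)
}

#' @export
glance.walk_plan <- function(x, ...) {
  tibble::tibble(gap_id = x$gap_id, strategy = x$strategy,
                 n_reactions = nrow(x$reactions),
                 stage_equivalent = x$stage_equivalent,
                 uncovered_bp = sum(x$uncovered$length),
                 n_degraded = nrow(x$degraded),
                 template_length = x$template_length)
}

#' @export
print.walk_plan <- function(x, ...) {
  cat(sprintf("<walk_plan> gap %s: %s, %d reactions (stage equivalent %d)\n",
              x$gap_id, x$strategy, nrow(x$reactions), x$stage_equivalent))
  cat(sprintf("  template %d bp, uncovered %d bp\n", x$template_length,
              sum(x$uncovered$length)))
  if (nrow(x$degraded) > 0) {
    cat(sprintf("  degraded segments: %s\n",
                paste(x$degraded$segment, collapse = ", ")))
  }
  invisible(x)
}

#' @export
autoplot.walk_plan <- function(object, ...) {
  rx <- object$reactions
  rx$y <- seq_len(nrow(rx))
  p <- ggplot2::ggplot(rx) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$read_start, xend = .data$read_end,
      y = .data$y, yend = .data$y, colour = .data$direction),
      linewidth = 2) +
    ggplot2::geom_point(ggplot2::aes(
      x = ifelse(.data$direction == "right", .data$read_start,
                 .data$read_end), y = .data$y), shape = 4, na.rm = TRUE) +
    ggplot2::scale_y_continuous(breaks = rx$y, labels = rx$primer) +
    ggplot2::labs(x = "template position (bp)", y = NULL,
                  title = sprintf("%s walk plan for %s", object$strategy,
                                  object$gap_id)) +
    ggplot2::theme_minimal()
  if (nrow(object$uncovered) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$uncovered,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = 0, ymax = nrow(rx) + 1, alpha = 0.15, fill = "red",
      inherit.aes = FALSE)
  }
  p
}

#' @export
tidy.scaffold_layout <- function(x, ...) {
  x$placements
}

#' @export
glance.scaffold_layout <- function(x, ...) {
  tibble::tibble(n_placed = nrow(x$placements),
                 n_unplaced = length(x$unplaced),
                 n_minus = sum(x$placements$orientation == "-"),
                 anchored_bp = sum(x$placements$anchored_bp))
}

#' @export
print.scaffold_layout <- function(x, ...) {
  cat(sprintf("<scaffold_layout> %d placed, %d unplaced\n",
              nrow(x$placements), length(x$unplaced)))
  print(x$placements, n = 10)
  invisible(x)
}

#' @export
autoplot.scaffold_layout <- function(object, ...) {
  pl <- object$placements
  pl$rank <- seq_len(nrow(pl))
  ggplot2::ggplot(pl, ggplot2::aes(x = .data$ref_start_est,
                                   y = .data$rank,
                                   colour = .data$orientation)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$contig_id),
                       hjust = -0.1, size = 3) +
    ggplot2::labs(x = "reference start estimate (bp)",
                  y = "layout order", title = "reference-guided layout") +
    ggplot2::theme_minimal()
}

#' @export
tidy.coverage_report <- function(x, ...) {
  x$per_contig
}

#' @export
glance.coverage_report <- function(x, ...) {
  tibble::tibble(pass = x$pass, n_contigs = nrow(x$per_contig),
                 n_failing = length(x$failing),
                 min_identity = min(x$per_contig$identity, na.rm = TRUE),
                 min_covered = min(x$per_contig$covered_fraction,
                                   na.rm = TRUE))
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("<coverage_report> %s (%d contigs, %d failing)\n",
              if (x$pass) "PASS" else "FAIL", nrow(x$per_contig),
              length(x$failing)))
  if (length(x$failing)) cat("  failing:",
                             paste(x$failing, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.finishing_report <- function(x, ...) {
  stage_counts <- tibble::tribble(
    ~stage, ~contigs,
    "input", x$summary$n_contigs_input,
    "after_masking", x$summary$n_after_masking,
    "after_placement", x$summary$n_after_placement)
  stage_counts
}

#' @export
glance.finishing_report <- function(x, ...) {
  x$summary
}

#' @export
print.finishing_report <- function(x, ...) {
  s <- x$summary
  cat("<finishing_report>\n")
  cat(sprintf("  contigs: %d -> %d (masking) -> %d (placement)\n",
              s$n_contigs_input, s$n_after_masking, s$n_after_placement))
  cat(sprintf("  ends annotated with rDNA: %d of %d\n",
              s$n_annotated_ends, s$n_total_ends))
  cat(sprintf("  ambiguous stretches: %d; small contigs placed: %d\n",
              s$n_stretches, s$n_placed))
  if (!is.na(s$n_gaps)) {
    cat(sprintf("  gaps: %d (%d rDNA-positive)\n", s$n_gaps,
                s$n_rdna_gaps))
  }
  if (!is.na(s$n_rearrangements)) {
    cat(sprintf("  rearrangement calls: %d\n", s$n_rearrangements))
  }
  if (!is.na(s$validation_pass)) {
    cat(sprintf("  draft coverage validation: %s\n",
                if (s$validation_pass) "PASS" else "FAIL"))
  }
  invisible(x)
}

#' @export
print.rdna_mask <- function(x, ...) {
  cat(sprintf("<rdna_mask> %d of %d contigs masked\n",
              sum(x$report$masked), nrow(x$report)))
  invisible(x)
}

#' @export
print.placement_result <- function(x, ...) {
  cat(sprintf("<placement_result> %d placed, %d unplaced\n",
              nrow(x$placements), nrow(x$unplaced)))
  invisible(x)
}

#' @export
print.genome_truth <- function(x, ...) {
  cat(sprintf("<genome_truth> %d bp, %d operons, divergence %.1f%%, seed %d\n",
              x$size, nrow(x$operons), 100 * x$divergence, x$seed))
  invisible(x)
}

#' @export
print.draft_truth <- function(x, ...) {
  cat(sprintf(
    "<draft_truth> %d contigs (%d backbone, %d rRNA-only, %d small)\n",
    nrow(x$contigs), nrow(x$backbone), nrow(x$rrna_only), nrow(x$smalls)))
  cat(sprintf("  %d N-runs, %d gaps, relocation: %s\n",
              nrow(x$n_runs), nrow(x$gaps),
              if (is.null(x$relocation)) "none" else
                sprintf("%d bp", x$relocation$block_size)))
  invisible(x)
}

#' N-stretch length distribution plot
#'
#' @param stretches Stretch tibble from [find_n_stretches()].
#' @return A ggplot object.
#' @export
plot_n_stretches <- function(stretches) {
  ggplot2::ggplot(stretches, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey30") +
    ggplot2::labs(x = "N-stretch length (bp)", y = "count",
                  title = "ambiguous base stretches") +
    ggplot2::theme_minimal()
}
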