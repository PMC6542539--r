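#' Design an evenly-spaced tiling amplicon panel
#'
#' Places \code{n_fragments} windows of \code{product_len} nucleotides with
#' starts spaced evenly over the coding sequence (1-based from the start
#' codon), the layout used to tile an ORF with PCR products of similar
#' size. Start positions are rounded to the nearest integer, so the design
#' is deterministic.
#'
#' @param cds_length length of the coding sequence in nt.
#' @param n_fragments number of amplicons (default 14).
#' @param product_len amplicon length in nt (default 150).
#' @return A \code{fragment_panel}: data.frame with columns
#'   \code{fragment}, \code{start}, \code{end}.
#' @examples
#' design_tiling(1644)          # 14 x 150 bp over a 1644-nt ORF
#' @export
design_tiling <- function(cds_length, n_fragments = 14, product_len = 150) {
  stopifnot(cds_length >= 1, n_fragments >= 1)
  if (product_len > cds_length)
    stop("product_len (", product_len, ") exceeds cds_length (",
         cds_length, ")")
  last <- cds_length - product_len + 1
  starts <- round(seq(1, last, length.out = n_fragments))
  panel <- data.frame(fragment = seq_len(n_fragments), start = starts,
                      end = starts + product_len - 1L)
  class(panel) <- c("fragment_panel", "data.frame")
  panel
}

#' Pick the common, unsaturated PCR cycle
#'
#' Semiquantitative RT-PCR compares band intensities taken from the same
#' amplification cycle; a saturated band is no longer proportional to
#' template. Returns the largest recorded cycle at which no fragment's
#' input intensity exceeds the saturation level.
#'
#' @param curves numeric matrix, fragments in rows, cycles in columns;
#'   column names (or \code{cycles}) give the cycle numbers.
#' @param saturation_level intensity above which a band is saturated.
#' @param cycles cycle numbers; defaults to numeric column names.
#' @return the selected cycle number.
#' @export
select_common_cycle <- function(curves, saturation_level, cycles = NULL) {
  curves <- as.matrix(curves)
  if (ncol(curves) < 1) stop("no cycles recorded")
  if (is.null(cycles)) cycles <- as.numeric(colnames(curves))
  if (length(cycles) != ncol(curves) || anyNA(cycles))
    stop("cycle numbers missing; supply 'cycles' or numeric column names")
  ok <- apply(curves <= saturation_level, 2, all)
  if (!any(ok)) stop("all cycles saturated at level ", saturation_level)
  max(cycles[ok])
}

#' Per-fragment Bound/Input enrichment ratios
#'
#' The ratio of Bound to (fragmented-)Input band intensity normalizes out
#' per-amplicon RT-PCR efficiency differences. Fragments whose input
#' intensity falls below an intensity floor amplify too poorly to be
#' interpreted; they are flagged low-confidence and excluded from peak
#' calling.
#'
#' @param signal data.frame with columns \code{fragment}, \code{bound},
#'   \code{input} (a \code{fragment_signal}, e.g. from
#'   \code{\link{simulate_frip}}).
#' @param input_floor intensity floor; default 10% of the median input
#'   intensity.
#' @return A \code{fragment_enrichment}: data.frame with \code{fragment},
#'   \code{ratio}, \code{low_confidence}.
#' @export
fragment_enrichment <- function(signal, input_floor = NULL) {
  stopifnot(all(c("fragment", "bound", "input") %in% names(signal)))
  if (any(signal$bound < 0) || any(signal$input < 0))
    stop("intensities must be nonnegative")
  if (is.null(input_floor)) input_floor <- 0.1 * stats::median(signal$input)
  out <- data.frame(fragment = signal$fragment,
                    ratio = ifelse(signal$input > 0,
                                   signal$bound / signal$input, NA_real_),
                    low_confidence = signal$input < input_floor |
                      signal$input == 0)
  attr(out, "input_floor") <- input_floor
  class(out) <- c("fragment_enrichment", "data.frame")
  out
}

#' Locate the binding-site fragment and its partial-cleavage smear
#'
#' The peak is the unflagged fragment with the highest Bound/Input ratio
#' (ties go to the smaller index). Because partial RNase cleavage leaves
#' longer fragments that still carry the binding site, fragments
#' immediately upstream of the peak can show elevated signal; the smear
#' report lists the contiguous run of fragments directly upstream of the
#' peak whose ratio is strictly above the median ratio of the non-peak
#' unflagged fragments.
#'
#' @param enrichment a \code{\link{fragment_enrichment}}.
#' @return A \code{frip_peak}: list with \code{peak} (fragment index),
#'   \code{smear} (integer vector, ascending), \code{ratios},
#'   \code{flagged}.
#' @export
peak_fragment <- function(enrichment) {
  ok <- !enrichment$low_confidence & !is.na(enrichment$ratio)
  if (!any(ok)) stop("all fragments flagged low-confidence")
  frag <- enrichment$fragment
  r <- enrichment$ratio
  cand <- which(ok)
  peak_i <- cand[order(-r[cand], frag[cand])][1]
  peak <- frag[peak_i]
  med <- stats::median(r[ok & frag != peak])
  smear <- integer()
  j <- peak - 1L
  repeat {
    i <- which(frag == j & ok)
    if (length(i) != 1 || !(r[i] > med)) break
    smear <- c(j, smear)
    j <- j - 1L
  }
  structure(list(peak = peak, smear = as.integer(smear),
                 ratios = stats::setNames(r, frag),
                 flagged = frag[enrichment$low_confidence],
                 median_nonpeak = med),
            class = "frip_peak")
}

#' @export
print.frip_peak <- function(x, ...) {
  cat("binding-site peak at fragment", x$peak)
  if (length(x$smear))
    cat("; upstream partial-cleavage smear:",
        paste(x$smear, collapse = ", "))
  if (length(x$flagged))
    cat("; low-confidence fragment(s):", paste(x$flagged, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Read a tiling-panel signal table
#'
#' TSV with columns \code{fragment}, \code{start}, \code{end},
#' \code{bound}, \code{input} (single-cycle intensities), as written by
#' \code{\link{write_frip_signal}}.
#'
#' @param file path to TSV.
#' @export
read_frip_signal <- function(file) {
  if (!file.exists(file)) stop("signal file not found: ", file)
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("fragment", "bound", "input")
  if (!all(need %in% names(df)))
    stop("signal table needs columns: ", paste(need, collapse = ", "))
  df
}

#' Write a tiling-panel signal table
#'
#' @param signal data.frame as produced by \code{\link{simulate_frip}}.
#' @param file path to write.
#' @export
write_frip_signal <- function(signal, file) {
  utils::write.table(signal, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
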