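#' Normalize raw counts to reads per million
#'
#' Each sample column is scaled by its own library size so that it sums to
#' one million, removing differences in sequencing depth between samples.
#'
#' @param x a \code{count_table}.
#' @return An \code{rpm_table}: same shape as the input, values in RPM.
#' @export
normalize_rpm <- function(x) {
  stopifnot(inherits(x, "count_table"))
  tot <- colSums(x$counts)
  if (any(tot == 0))
    stop("sample column(s) with zero total reads: ",
         paste(colnames(x$counts)[tot == 0], collapse = ", "))
  rpm <- sweep(x$counts, 2, tot, "/") * 1e6
  structure(list(rpm = rpm, samples = x$samples, genes = x$genes,
                 library_sizes = tot),
            class = "rpm_table")
}

#' @export
print.rpm_table <- function(x, ...) {
  cat("RPM table:", nrow(x$rpm), "genes x", ncol(x$rpm), "samples\n")
  invisible(x)
}

#' Input-coverage and biotype filter parameters
#'
#' Transcripts with normalized read coverage below \code{min_input_rpm} in
#' the Input sample, and (optionally) noncoding RNAs, are removed before
#' efficiency calculation. The boundary is exclusive: a gene at exactly the
#' threshold is retained.
#'
#' @param min_input_rpm minimum Input RPM (default 15).
#' @param drop_noncoding drop genes annotated noncoding (default TRUE).
#' @export
filter_params <- function(min_input_rpm = 15, drop_noncoding = TRUE) {
  stopifnot(is.numeric(min_input_rpm), min_input_rpm >= 0)
  structure(list(min_input_rpm = min_input_rpm,
                 drop_noncoding = isTRUE(drop_noncoding)),
            class = "filter_params")
}

# locate the single sample column for a (strain, protocol, role)
sample_col <- function(rpm, strain, protocol, role) {
  s <- rpm$samples
  i <- which(s$strain == strain & s$protocol == protocol & s$role == role)
  if (length(i) == 0)
    stop("no ", role, " sample for strain '", strain,
         "', protocol '", protocol, "'")
  if (length(i) > 1)
    stop("multiple ", role, " samples for strain '", strain,
         "', protocol '", protocol, "'; replicates must be split first")
  i
}

#' Retained genes after input-coverage filtering
#'
#' @param rpm an \code{rpm_table}.
#' @param strain,protocol identify the experiment whose Input sample the
#'   coverage rule is applied to.
#' @param params a \code{\link{filter_params}} object.
#' @return character vector of retained gene ids.
#' @export
filter_transcripts <- function(rpm, strain, protocol,
                               params = filter_params()) {
  stopifnot(inherits(rpm, "rpm_table"))
  i <- sample_col(rpm, strain, protocol, "Input")
  keep <- rpm$rpm[, i] >= params$min_input_rpm
  if (params$drop_noncoding) keep <- keep & rpm$genes$coding
  rownames(rpm$rpm)[keep]
}

#' Per-gene RIP efficiency
#'
#' RIP efficiency is the ratio of a gene's RPM in the Bound (co-purified)
#' sample to its RPM in the matched Input sample. Division by the Input
#' accounts for abundance and length differences between mRNAs.
#'
#' @inheritParams filter_transcripts
#' @param genes gene ids to compute over; defaults to the filtered set
#'   under \code{params}.
#' @return data.frame with columns \code{gene_id}, \code{rpm_input},
#'   \code{rpm_bound}, \code{efficiency}.
#' @export
rip_efficiency <- function(rpm, strain, protocol, genes = NULL,
                           params = filter_params()) {
  stopifnot(inherits(rpm, "rpm_table"))
  ii <- sample_col(rpm, strain, protocol, "Input")
  ib <- sample_col(rpm, strain, protocol, "Bound")
  if (is.null(genes)) genes <- filter_transcripts(rpm, strain, protocol, params)
  genes <- intersect(rownames(rpm$rpm), genes)
  inp <- rpm$rpm[genes, ii]
  bnd <- rpm$rpm[genes, ib]
  data.frame(gene_id = genes, rpm_input = unname(inp),
             rpm_bound = unname(bnd),
             efficiency = unname(bnd / inp),
             stringsAsFactors = FALSE)
}

#' Background-correct RIP efficiencies against the untagged control
#'
#' Subtracts, gene by gene, the RIP efficiency measured in the untagged
#' strain (nonspecific bead association) from the tagged strain's
#' efficiency, under the same purification protocol. By default only genes
#' that pass the coverage filter in both experiments are kept
#' (\code{mode = "intersection"}); \code{mode = "zero"} instead keeps all
#' tagged-retained genes and treats a missing untagged efficiency as 0.
#'
#' @param tagged,untagged data.frames from \code{\link{rip_efficiency}},
#'   computed under the same protocol.
#' @param mode \code{"intersection"} (default) or \code{"zero"}.
#' @return data.frame with the tagged columns plus
#'   \code{efficiency_untagged} and \code{corrected}.
#' @export
background_correct <- function(tagged, untagged,
                               mode = c("intersection", "zero")) {
  mode <- match.arg(mode)
  iu <- match(tagged$gene_id, untagged$gene_id)
  eu <- untagged$efficiency[iu]
  if (mode == "intersection") {
    keep <- !is.na(eu)
    tagged <- tagged[keep, , drop = FALSE]
    eu <- eu[keep]
  } else {
    eu[is.na(eu)] <- 0
  }
  tagged$efficiency_untagged <- eu
  tagged$corrected <- tagged$efficiency - eu
  rownames(tagged) <- NULL
  tagged
}

#' Rank genes by background-corrected RIP efficiency
#'
#' Rank 1 is the highest corrected efficiency. Ties are broken by larger
#' Bound RPM, then lexicographically by gene id, so the ordering is total
#' and reproducible.
#'
#' @param records data.frame with columns \code{gene_id}, \code{corrected}
#'   and (for tie-breaking) \code{rpm_bound}.
#' @return the records sorted by rank, with a \code{rank} column added.
#' @export
rank_genes <- function(records) {
  stopifnot(nrow(records) >= 1)
  rpm_bound <- if ("rpm_bound" %in% names(records)) records$rpm_bound else 0
  o <- order(-records$corrected, -rpm_bound, records$gene_id)
  records <- records[o, , drop = FALSE]
  records$rank <- seq_len(nrow(records))
  rownames(records) <- NULL
  records
}

#' Background-corrected RIP-seq enrichment analysis
#'
#' Runs the full per-experiment enrichment pipeline: RPM normalization,
#' input-coverage filtering in both the tagged and untagged experiment,
#' per-gene RIP efficiency, background correction by subtraction of the
#' untagged (bead-only) efficiency, and deterministic ranking.
#'
#' @param counts a \code{count_table} containing the tagged Input/Bound
#'   pair and the untagged Input/Bound pair under the same protocol.
#' @param strain tagged strain name.
#' @param protocol \code{"TAP"} or \code{"GFP"}.
#' @param untagged_strain strain label of the bead-background control
#'   (default \code{"untagged"}).
#' @param params \code{\link{filter_params}}.
#' @param mode correction domain, see \code{\link{background_correct}}.
#' @return An object of class \code{rip_enrichment}: list with
#'   \code{records} (ranked data.frame), \code{strain}, \code{protocol},
#'   \code{params}, \code{untagged} (the untagged efficiency table, used
#'   for the untagged-outlier exclusion step of target calling).
#' @examples
#' sim <- simulate_ripseq(rip_sim_params(n_genes = 500, seed = 1,
#'                                       planted = data.frame(gene = 7, fold = 20)))
#' enr <- rip_enrichment(sim$counts, strain = "tagged", protocol = "TAP")
#' head(enr$records)
#' @export
rip_enrichment <- function(counts, strain, protocol,
                           untagged_strain = "untagged",
                           params = filter_params(),
                           mode = c("intersection", "zero")) {
  rpm <- if (inherits(counts, "rpm_table")) counts else normalize_rpm(counts)
  et <- rip_efficiency(rpm, strain, protocol, params = params)
  eu <- rip_efficiency(rpm, untagged_strain, protocol, params = params)
  rec <- rank_genes(background_correct(et, eu, match.arg(mode)))
  structure(list(records = rec, strain = strain, protocol = protocol,
                 params = params, untagged = eu),
            class = "rip_enrichment")
}

#' @export
print.rip_enrichment <- function(x, ...) {
  cat("RIP enrichment:", x$strain, "(", x$protocol, ") vs untagged,",
      nrow(x$records), "retained genes\n")
  cat("top of ranking:\n")
  print(utils::head(x$records, 5), digits = 4)
  invisible(x)
}

#' @export
summary.rip_enrichment <- function(object, ...) {
  c0 <- object$records$corrected
  q <- stats::quantile(c0, c(.25, .5, .75), type = 7)
  out <- list(strain = object$strain, protocol = object$protocol,
              n = length(c0), quartiles = q, iqr = unname(q[3] - q[1]),
              whisker = unname(q[3] + 1.5 * (q[3] - q[1])))
  class(out) <- "summary.rip_enrichment"
  out
}

#' @export
print.summary.rip_enrichment <- function(x, ...) {
  cat(x$strain, "(", x$protocol, "):", x$n, "genes;",
      "median corrected", signif(x$quartiles[2], 3),
      "; Q3 + 1.5 IQR =", signif(x$whisker, 3), "\n")
  invisible(x)
}

#' Box plot of corrected RIP efficiencies
#'
#' Mirrors the usual presentation of RIP-seq enrichment: a box plot of the
#' per-gene corrected efficiencies with 1.5-IQR whiskers; genes beyond the
#' whisker are the outliers the target caller picks up. Optionally marks
#' named genes (e.g. the protein's own mRNA) with arrowheads.
#'
#' @param x a \code{rip_enrichment}.
#' @param highlight gene ids to mark.
#' @param ... passed to \code{\link[graphics]{boxplot}}.
#' @export
plot.rip_enrichment <- function(x, highlight = character(), ...) {
  graphics::boxplot(x$records$corrected, range = 1.5,
                    ylab = "corrected RIP efficiency",
                    main = paste0(x$strain, " (", x$protocol, ")"), ...)
  if (length(highlight)) {
    i <- match(highlight, x$records$gene_id)
    graphics::points(rep(1, sum(!is.na(i))), x$records$corrected[i[!is.na(i)]],
                     pch = 17, col = "red")
  }
  invisible(x)
}

#' Write enrichment records as TSV
#'
#' @param x a \code{rip_enrichment} (or its \code{records} data.frame).
#' @param file path to write.
#' @export
write_enrichment <- function(x, file) {
  rec <- if (inherits(x, "rip_enrichment")) x$records else x
  utils::write.table(rec, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
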