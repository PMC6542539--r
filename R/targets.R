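#' Call bound targets with the boxplot 1.5-IQR outlier rule
#'
#' A gene is called a target when its background-corrected RIP efficiency
#' lies above the upper boxplot whisker of the per-experiment distribution:
#' strictly greater than Q3 + k * IQR (quartile rule, the default, matching
#' 1.5-IQR whiskers) or greater than mean + k * IQR (mean-centred
#' alternative). Quartiles use linear interpolation between order
#' statistics (\code{\link[stats]{quantile}} type 7); the estimator is
#' recorded in the result because overlap counts are sensitive to it.
#'
#' @param records a \code{rip_enrichment}, or a data.frame with columns
#'   \code{gene_id} and \code{corrected}.
#' @param k IQR multiplier (default 1.5).
#' @param center_rule \code{"quartile"} (default) or \code{"mean"}.
#' @param label set label; defaults to the enrichment's strain.
#' @param exclude gene ids to remove after calling (e.g. untagged-strain
#'   outliers from \code{\link{untagged_outliers}}).
#' @return An object of class \code{target_set}: list with \code{label},
#'   \code{genes}, \code{threshold}, \code{k}, \code{center_rule},
#'   \code{quartile_type}, and the called genes' corrected values.
#' @examples
#' x <- data.frame(gene_id = sprintf("g%03d", 1:100),
#'                 corrected = c(rep(0, 96), rep(10, 4)))
#' call_targets(x)$genes
#' @export
call_targets <- function(records, k = 1.5,
                         center_rule = c("quartile", "mean"),
                         label = NULL, exclude = NULL) {
  center_rule <- match.arg(center_rule)
  stopifnot(is.numeric(k), k > 0)
  if (inherits(records, "rip_enrichment")) {
    if (is.null(label)) label <- records$strain
    records <- records$records
  }
  if (is.null(label)) label <- "targets"
  cc <- records$corrected
  if (length(cc) < 4)
    stop("need at least 4 genes to define quartiles, got ", length(cc))
  q <- stats::quantile(cc, c(.25, .75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  center <- if (center_rule == "quartile") q[2] else mean(cc)
  thr <- center + k * iqr
  member <- cc > thr
  genes <- records$gene_id[member]
  values <- cc[member]
  if (!is.null(exclude)) {
    keep <- !(genes %in% exclude)
    genes <- genes[keep]
    values <- values[keep]
  }
  o <- order(-values, genes)
  structure(list(label = label, genes = genes[o], corrected = values[o],
                 threshold = thr, k = k, center_rule = center_rule,
                 quartile_type = 7L, n_background = length(cc)),
            class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat("target set '", x$label, "': ", length(x$genes), " genes above ",
      signif(x$threshold, 4), " (", x$center_rule, " + ", x$k,
      " IQR, of ", x$n_background, " genes)\n", sep = "")
  invisible(x)
}

#' @export
length.target_set <- function(x) length(x$genes)

#' Untagged-strain outlier genes
#'
#' Genes whose uncorrected RIP efficiency in the untagged (bead-only)
#' experiment is itself a boxplot outlier; such genes bind the beads
#' rather than the tagged protein and can be excluded from called target
#' sets.
#'
#' @param untagged data.frame with columns \code{gene_id} and
#'   \code{efficiency} (e.g. the \code{untagged} element of a
#'   \code{rip_enrichment}).
#' @inheritParams call_targets
#' @return character vector of outlier gene ids.
#' @export
untagged_outliers <- function(untagged, k = 1.5,
                              center_rule = c("quartile", "mean")) {
  center_rule <- match.arg(center_rule)
  e <- untagged$efficiency
  q <- stats::quantile(e, c(.25, .75), type = 7, names = FALSE)
  center <- if (center_rule == "quartile") q[2] else mean(e)
  untagged$gene_id[e > center + k * (q[2] - q[1])]
}

as_gene_sets <- function(sets) {
  if (inherits(sets, "target_set")) sets <- list(sets)
  lst <- lapply(sets, function(s) if (inherits(s, "target_set")) s$genes else s)
  if (is.null(names(lst)) || any(!nzchar(names(lst)))) {
    labs <- vapply(seq_along(sets), function(i) {
      s <- sets[[i]]
      if (inherits(s, "target_set")) s$label else paste0("set", i)
    }, "")
    names(lst) <- labs
  }
  lst
}

#' Per-set exclusive targets
#'
#' A gene is exclusive to a set when it belongs to that set and to no
#' other.
#'
#' @param sets a list of \code{target_set} objects or character vectors
#'   of gene ids (named).
#' @return named list of character vectors.
#' @export
exclusive_targets <- function(sets) {
  lst <- as_gene_sets(sets)
  if (length(lst) < 2) stop("need at least 2 sets")
  out <- lapply(seq_along(lst), function(i)
    setdiff(lst[[i]], unlist(lst[-i], use.names = FALSE)))
  names(out) <- names(lst)
  out
}

#' Venn-region decomposition of target sets
#'
#' Assigns every gene in the union of the sets to exactly one Venn region,
#' the region of its exact membership pattern. Region names join the
#' member set labels with \code{"&"} (e.g. \code{"GluRS&HisRS"} is the
#' genes in both those sets and no other).
#'
#' @inheritParams exclusive_targets
#' @return named list of character vectors, one per non-empty membership
#'   pattern; region sizes sum to the size of the union.
#' @export
shared_targets <- function(sets) {
  lst <- as_gene_sets(sets)
  if (length(lst) < 2) stop("need at least 2 sets")
  genes <- sort(unique(unlist(lst, use.names = FALSE)))
  if (length(genes) == 0) return(structure(list(), names = character()))
  memb <- vapply(lst, function(s) genes %in% s, logical(length(genes)))
  if (length(genes) == 1) memb <- matrix(memb, nrow = 1)
  pattern <- apply(memb, 1, function(r) paste(names(lst)[r], collapse = "&"))
  split(genes, pattern)
}

#' Genes shared by a pair of sets (their two-set Venn region)
#'
#' Convenience accessor: the genes in both named sets and in no other set
#' of the collection.
#'
#' @inheritParams exclusive_targets
#' @param a,b labels of the two sets.
#' @export
pairwise_shared <- function(sets, a, b) {
  reg <- shared_targets(sets)
  key <- paste(sort(c(a, b)), collapse = "&")
  # region names preserve input set order; normalise both sides
  nm <- vapply(strsplit(names(reg), "&", fixed = TRUE),
               function(p) paste(sort(p), collapse = "&"), "")
  if (key %in% nm) reg[[which(nm == key)]] else character()
}

#' Write target sets as TSV
#'
#' One row per called gene: \code{gene_id}, set label, corrected value.
#'
#' @param sets list of \code{target_set} objects (or a single one).
#' @param file path to write.
#' @export
write_target_sets <- function(sets, file) {
  if (inherits(sets, "target_set")) sets <- list(sets)
  df <- do.call(rbind, lapply(sets, function(s)
    if (length(s$genes) == 0) NULL else
      data.frame(gene_id = s$genes, set = s$label, corrected = s$corrected,
                 stringsAsFactors = FALSE)))
  if (is.null(df))
    df <- data.frame(gene_id = character(), set = character(),
                     corrected = numeric())
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
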