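#' Assemble a RIP-seq count table
#'
#' A count table holds raw uniquely-mapped read counts for one or more
#' RIP-seq experiments, with each sample described by its role in the
#' pull-down (\code{"Input"} for the total extract, \code{"Bound"} for the
#' co-purified fraction), the strain carrying the tagged protein (or
#' \code{"untagged"} for the bead-background control), and the purification
#' protocol (\code{"TAP"} or \code{"GFP"}).
#'
#' @param counts integer matrix, genes in rows (rownames are gene ids),
#'   samples in columns.
#' @param samples data.frame with one row per column of \code{counts} and
#'   columns \code{role}, \code{strain}, \code{protocol}.
#' @param coding logical vector, one entry per gene; \code{FALSE} marks
#'   noncoding RNAs that the input-coverage filter can drop. Recycled if
#'   length 1.
#' @return An object of class \code{count_table}: a list with elements
#'   \code{counts}, \code{samples} and \code{genes}.
#' @examples
#' m <- matrix(c(10L, 20L, 5L, 40L), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' ct <- count_table(m, data.frame(role = c("Input", "Bound"),
#'                                 strain = "HisRS", protocol = "TAP"))
#' @export
count_table <- function(counts, samples, coding = TRUE) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  if (anyDuplicated(rownames(counts)))
    stop("gene ids must be unique")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  storage.mode(counts) <- "double"   # keeps >2^31 library sums safe
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("role", "strain", "protocol")
  if (!all(need %in% names(samples)))
    stop("samples needs columns role, strain, protocol")
  if (nrow(samples) != ncol(counts))
    stop("one samples row per count column required")
  if (!all(samples$role %in% c("Input", "Bound")))
    stop("role must be 'Input' or 'Bound'")
  if (is.null(rownames(samples)) || any(rownames(samples) != colnames(counts)))
    rownames(samples) <- colnames(counts)
  coding <- rep_len(as.logical(coding), nrow(counts))
  # every Bound sample must have a matching Input of the same strain/protocol
  b <- samples$role == "Bound"
  key <- paste(samples$strain, samples$protocol)
  if (!all(key[b] %in% key[!b]))
    stop("every Bound sample needs a matching Input sample (same strain and protocol)")
  structure(list(counts = counts, samples = samples,
                 genes = data.frame(gene_id = rownames(counts),
                                    coding = coding,
                                    stringsAsFactors = FALSE)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("RIP-seq count table:", nrow(x$counts), "genes x",
      ncol(x$counts), "samples\n")
  cat("samples:\n")
  print(cbind(x$samples, library_size = colSums(x$counts)))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

# column label <strain>.<protocol>.<role> used in TSV round-trips
sample_label <- function(samples)
  paste(samples$strain, samples$protocol, samples$role, sep = ".")

parse_sample_label <- function(labels) {
  parts <- strsplit(labels, ".", fixed = TRUE)
  bad <- lengths(parts) != 3
  if (any(bad))
    stop("cannot parse sample label(s) ", paste(labels[bad], collapse = ", "),
         "; expected <strain>.<protocol>.<role>")
  data.frame(strain = vapply(parts, `[`, "", 1),
             protocol = vapply(parts, `[`, "", 2),
             role = vapply(parts, `[`, "", 3),
             stringsAsFactors = FALSE)
}

#' Write a count table as TSV
#'
#' Header row is \code{gene_id} followed by sample labels of the form
#' \code{strain.protocol.role}; an optional last column \code{coding} keeps
#' the gene annotation. The format round-trips through
#' \code{\link{read_count_table}}.
#'
#' @param x a \code{count_table}.
#' @param file path to write.
#' @export
write_count_table <- function(x, file) {
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   coding = x$genes$coding, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("gene_id", sample_label(x$samples), "coding")
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a count table from TSV
#'
#' @param file TSV with header \code{gene_id}, then one column per sample
#'   labelled \code{strain.protocol.role}, optionally a trailing
#'   \code{coding} column (TRUE/FALSE).
#' @param samples optional data.frame overriding the metadata parsed from
#'   the column labels.
#' @return a \code{count_table}.
#' @export
read_count_table <- function(file, samples = NULL) {
  if (!file.exists(file)) stop("counts file not found: ", file)
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop("first column must be gene_id")
  coding <- TRUE
  if ("coding" %in% names(df)) {
    coding <- as.logical(df$coding)
    df$coding <- NULL
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  if (is.null(samples)) samples <- parse_sample_label(colnames(m))
  count_table(m, samples, coding)
}

#' Read a supplementary-style RIP-seq spreadsheet
#'
#' Reads one sheet of an xlsx laid out as raw uniquely-mapped read counts:
#' first column gene ids, remaining columns samples labelled
#' \code{strain.protocol.role} (or supply \code{samples}). Requires the
#' readxl package.
#'
#' @inheritParams read_count_table
#' @param sheet sheet index or name (default 1, the raw-count sheet).
#' @export
read_counts_xlsx <- function(file, sheet = 1, samples = NULL) {
  if (!requireNamespace("readxl", quietly = TRUE))
    stop("reading xlsx requires the readxl package")
  if (!file.exists(file)) stop("counts file not found: ", file)
  df <- as.data.frame(readxl::read_excel(file, sheet = sheet))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (is.null(samples)) samples <- parse_sample_label(colnames(m))
  count_table(m, samples)
}
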