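#' Scan a coding sequence for anticodon-mimic stem-loops
#'
#' Slides a window along the CDS, folds each window by base-pair
#' maximization, and reports positions where the query triplet (e.g. the
#' GUG anticodon of tRNA-His) sits with all three bases inside one hairpin
#' loop closed by a stem of at least \code{min_stem} contiguous pairs —
#' the configuration in which an mRNA element can mimic a tRNA anticodon
#' arm. Hits found at consecutive window starts for the same triplet
#' occurrence are merged into one, keeping the window with the longest
#' closing stem (ties go to the smallest start).
#'
#' @param cds coding sequence (DNA or RNA string); position 1 is the first
#'   base of the start codon.
#' @param triplet the 3-mer to look for (default \code{"GUG"}).
#' @param window_len folding-window size in nt (default 15).
#' @param step window step in nt (default 1).
#' @param min_stem minimum closing-stem length in base pairs (default 2).
#' @param min_loop minimum hairpin-loop size passed to the folder.
#' @return A \code{mimic_hits} data.frame: \code{window_start},
#'   \code{window_len}, \code{triplet_pos} (1-based CDS position of the
#'   triplet's first base), \code{stem_len}, \code{loop_start},
#'   \code{loop_end} (CDS coordinates), \code{dotbracket}.
#' @export
scan_mimic <- function(cds, triplet = "GUG", window_len = 15, step = 1,
                       min_stem = 2, min_loop = 3) {
  s <- as_rna(cds)
  triplet <- as_rna(triplet)
  stopifnot(nchar(triplet) == 3)
  n <- nchar(s)
  if (n < window_len)
    stop("sequence shorter (", n, ") than window_len (", window_len, ")")
  hits <- list()
  for (w0 in seq(1, n - window_len + 1, by = step)) {
    w <- substr(s, w0, w0 + window_len - 1)
    occ <- gregexpr(paste0("(?=", triplet, ")"), w, perl = TRUE)[[1]]
    if (occ[1] == -1) next
    st <- fold_window(w, min_loop)
    if (!st$n_pairs) next
    loops <- find_hairpin_loops(st)
    for (p in as.integer(occ)) {
      for (l in seq_len(nrow(loops))) {
        if (loops$loop_start[l] <= p && p + 2 <= loops$loop_end[l] &&
            loops$stem_len[l] >= min_stem) {
          hits[[length(hits) + 1L]] <-
            data.frame(window_start = w0, window_len = window_len,
                       triplet_pos = w0 + p - 1L,
                       stem_len = loops$stem_len[l],
                       loop_start = w0 + loops$loop_start[l] - 1L,
                       loop_end = w0 + loops$loop_end[l] - 1L,
                       dotbracket = st$dotbracket,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  empty <- data.frame(window_start = integer(), window_len = integer(),
                      triplet_pos = integer(), stem_len = integer(),
                      loop_start = integer(), loop_end = integer(),
                      dotbracket = character(), stringsAsFactors = FALSE)
  if (!length(hits)) {
    out <- empty
  } else {
    df <- do.call(rbind, hits)
    # merge runs of consecutive window starts reporting the same triplet
    # occurrence; keep the longest stem, tie -> smallest window start
    out <- do.call(rbind, lapply(split(df, df$triplet_pos), function(g) {
      g <- g[order(g$window_start), , drop = FALSE]
      run <- cumsum(c(1L, diff(g$window_start) > step))
      do.call(rbind, lapply(split(g, run), function(r)
        r[order(-r$stem_len, r$window_start)[1], , drop = FALSE]))
    }))
    out <- out[order(out$triplet_pos, out$window_start), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "triplet") <- triplet
  class(out) <- c("mimic_hits", "data.frame")
  out
}

#' Parse point-mutation strings
#'
#' Accepts the compact notation \code{"T1101A"}: reference base, 1-based
#' CDS position, alternative base. U and T are interchangeable.
#'
#' @param x character vector of mutation strings (or an already-parsed
#'   data.frame, returned unchanged).
#' @return data.frame with columns \code{position}, \code{ref}, \code{alt}.
#' @export
parse_mutations <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("position", "ref", "alt") %in% names(x)))
    return(x)
  }
  m <- regmatches(x, regexec("^([ACGTUacgtu])([0-9]+)([ACGTUacgtu])$", x))
  bad <- lengths(m) != 4
  if (any(bad))
    stop("cannot parse mutation(s): ", paste(x[bad], collapse = ", "),
         "; expected e.g. 'T1101A'")
  out <- data.frame(position = as.integer(vapply(m, `[`, "", 3)),
                    ref = toupper(vapply(m, `[`, "", 2)),
                    alt = toupper(vapply(m, `[`, "", 4)),
                    stringsAsFactors = FALSE)
  same <- chartr("T", "U", out$ref) == chartr("T", "U", out$alt)
  if (any(same))
    stop("ref and alt are identical in: ", paste(x[same], collapse = ", "))
  out
}

#' Apply point mutations to a sequence
#'
#' Substitutions are order-independent; each reference base is checked
#' against the sequence (with U/T equivalence) before being replaced, and
#' the output keeps the input's DNA or RNA alphabet.
#'
#' @param cds DNA or RNA string.
#' @param mutations character vector of mutation strings or a parsed
#'   data.frame (see \code{\link{parse_mutations}}).
#' @param offset value subtracted from each mutation position before
#'   applying, for mutating an excised window whose first base is CDS
#'   position \code{offset + 1} (default 0: positions are already local).
#' @return the mutated sequence, same length and alphabet as the input.
#' @export
apply_mutations <- function(cds, mutations, offset = 0) {
  mut <- parse_mutations(mutations)
  is_rna <- grepl("U", toupper(cds)) && !grepl("T", toupper(cds))
  b <- strsplit(toupper(cds), "")[[1]]
  for (r in seq_len(nrow(mut))) {
    pos <- mut$position[r] - offset
    if (pos < 1 || pos > length(b))
      stop("mutation position ", mut$position[r],
           " outside sequence (length ", length(b),
           if (offset) paste0(", offset ", offset) else "", ")")
    found <- chartr("T", "U", b[pos])
    expect <- chartr("T", "U", mut$ref[r])
    if (found != expect)
      stop("reference mismatch at position ", mut$position[r],
           ": expected ", mut$ref[r], ", found ", b[pos])
    alt <- mut$alt[r]
    b[pos] <- if (is_rna) chartr("T", "U", alt) else chartr("U", "T", alt)
  }
  paste(b, collapse = "")
}

#' Is a point mutation synonymous?
#'
#' Translates the affected codon before and after the substitution under
#' the standard genetic code; the mutation is synonymous (silent) when the
#' encoded amino acid is unchanged.
#'
#' @param cds coding sequence, length divisible by 3, position 1 = first
#'   base of the start codon.
#' @param mutation a single mutation string or one-row parsed data.frame.
#' @return TRUE/FALSE.
#' @examples
#' is_synonymous(strrep("GGT", 5), "T3A")   # GGT -> GGA, both Gly
#' @export
is_synonymous <- function(cds, mutation) {
  s <- chartr("U", "T", toupper(cds))
  if (nchar(s) %% 3 != 0)
    stop("CDS length (", nchar(s), ") is not a multiple of 3")
  mut <- parse_mutations(mutation)
  if (nrow(mut) != 1) stop("supply exactly one mutation")
  if (mut$position > nchar(s)) stop("mutation position outside CDS")
  ci <- (mut$position - 1) %/% 3          # 0-based codon index
  codon <- substr(s, 3 * ci + 1, 3 * ci + 3)
  mutated <- apply_mutations(s, mut)
  codon2 <- substr(mutated, 3 * ci + 1, 3 * ci + 3)
  translate_codon(codon) == translate_codon(codon2)
}

# standard-code lookup for one codon (DNA alphabet)
translate_codon <- function(codon) {
  if (requireNamespace("Biostrings", quietly = TRUE))
    unname(Biostrings::GENETIC_CODE[codon])
  else
    unname(GENETIC_CODE_STANDARD[codon])
}

# fallback copy of the standard genetic code (codon -> one-letter AA)
GENETIC_CODE_STANDARD <- local({
  b <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(b, b, paste0))), b, paste0)))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aa, codons)
})

#' Classify a mutation set's effect on an anticodon-mimic element
#'
#' Given a wild-type window containing the triplet-in-hairpin-loop element,
#' classifies a set of point mutations into one of three classes:
#' \describe{
#'   \item{anticodon_lost}{any mutated base falls inside the triplet — the
#'     anticodon-like sequence itself is changed. Decided from sequence
#'     alone, never from folding.}
#'   \item{stem_disrupted}{the refolded mutant either no longer presents
#'     the triplet inside a hairpin loop, or its closing stem retains less
#'     than \code{stem_retention} of the wild-type closing-stem pairs.}
#'   \item{stem_preserved}{otherwise — the element survives the mutations.}
#' }
#'
#' @param wt_window wild-type sequence window (DNA or RNA).
#' @param mutations mutation strings / parsed data.frame; positions are
#'   CDS coordinates when \code{window_start} is given, else window-local.
#'   May be empty (classifies the unmutated window).
#' @param triplet the anticodon-like 3-mer (default "GUG").
#' @param window_start CDS position of the window's first base (default 1).
#' @param min_loop,min_stem folding and element parameters, as in
#'   \code{\link{scan_mimic}}.
#' @param stem_retention fraction of wild-type closing-stem pairs that must
#'   survive, as contiguous stack around the loop, to count as preserved
#'   (default 0.5).
#' @return A \code{variant_class}: list with \code{class} and
#'   \code{diagnostics} (triplet_intact, pairs_retained, wt_stem_len,
#'   mutant structure).
#' @export
classify_variant <- function(wt_window, mutations = character(),
                             triplet = "GUG", window_start = 1,
                             min_loop = 3, min_stem = 2,
                             stem_retention = 0.5) {
  wt <- as_rna(wt_window)
  n <- nchar(wt)
  mut <- if (length(mutations) == 0 && !is.data.frame(mutations))
    data.frame(position = integer(), ref = character(), alt = character())
  else parse_mutations(mutations)
  local_pos <- mut$position - (window_start - 1)
  if (any(local_pos < 1 | local_pos > n))
    stop("mutation position(s) ",
         paste(mut$position[local_pos < 1 | local_pos > n], collapse = ", "),
         " fall outside the window [", window_start, ", ",
         window_start + n - 1, "]")

  # locate the wild-type element: the triplet occurrence inside a hairpin
  # loop with the longest closing stem
  wt_st <- fold_window(wt, min_loop)
  loops <- find_hairpin_loops(wt_st)
  occ <- as.integer(gregexpr(paste0("(?=", as_rna(triplet), ")"), wt,
                             perl = TRUE)[[1]])
  elem <- NULL
  for (l in seq_len(nrow(loops)))
    for (p in occ[occ > 0])
      if (loops$loop_start[l] <= p && p + 2 <= loops$loop_end[l] &&
          (is.null(elem) || loops$stem_len[l] > elem$stem))
        elem <- list(p = p, loop = loops[l, ], stem = loops$stem_len[l])
  if (is.null(elem))
    stop("wild-type window has no '", triplet, "' inside a hairpin loop")

  wt_stem_pairs <- cbind(elem$loop$closing_i - (seq_len(elem$stem) - 1L),
                         elem$loop$closing_j + (seq_len(elem$stem) - 1L))

  if (nrow(mut) && any(local_pos >= elem$p & local_pos <= elem$p + 2)) {
    res <- list(class = "anticodon_lost",
                diagnostics = list(triplet_intact = FALSE,
                                   pairs_retained = NA_real_,
                                   wt_stem_len = elem$stem,
                                   triplet_pos = elem$p))
    class(res) <- "variant_class"
    return(res)
  }

  mut_local <- mut
  mut_local$position <- local_pos
  mutant <- if (nrow(mut)) apply_mutations(wt, mut_local) else wt
  mu_st <- fold_window(mutant, min_loop)
  mu_loops <- find_hairpin_loops(mu_st)
  in_loop <- which(mu_loops$loop_start <= elem$p &
                     elem$p + 2 <= mu_loops$loop_end)
  if (length(in_loop) == 0) {
    retained <- 0
    intact <- FALSE
  } else {
    l <- mu_loops[in_loop[1], ]
    stack <- cbind(l$closing_i - (seq_len(l$stem_len) - 1L),
                   l$closing_j + (seq_len(l$stem_len) - 1L))
    retained <- sum(paste(wt_stem_pairs[, 1], wt_stem_pairs[, 2]) %in%
                      paste(stack[, 1], stack[, 2])) / elem$stem
    intact <- TRUE
  }
  cls <- if (!intact || retained < stem_retention) "stem_disrupted"
         else "stem_preserved"
  res <- list(class = cls,
              diagnostics = list(triplet_intact = intact,
                                 pairs_retained = retained,
                                 wt_stem_len = elem$stem,
                                 triplet_pos = elem$p,
                                 wt_dotbracket = wt_st$dotbracket,
                                 mutant_dotbracket = mu_st$dotbracket))
  class(res) <- "variant_class"
  res
}

#' @export
print.variant_class <- function(x, ...) {
  cat("variant class:", x$class, "\n")
  d <- x$diagnostics
  cat("  triplet intact:", d$triplet_intact,
      "| closing-stem pairs retained:",
      if (is.na(d$pairs_retained)) "-" else signif(d$pairs_retained, 3),
      "\n")
  invisible(x)
}

#' Read coding sequences from FASTA
#'
#' @param file FASTA path.
#' @return named character vector of uppercase sequences.
#' @export
read_cds_fasta <- function(file) {
  if (!file.exists(file)) stop("FASTA file not found: ", file)
  if (requireNamespace("Biostrings", quietly = TRUE))
    return(toupper(as.character(Biostrings::readBStringSet(file))))
  lines <- readLines(file)
  hdr <- grepl("^>", lines)
  id <- sub("^>\\s*(\\S+).*", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), "")
  stats::setNames(unname(seqs), id)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector.
#' @param file path to write.
#' @param width line width (default 60).
#' @export
write_fasta <- function(seqs, file, width = 60) {
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(file)
}
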