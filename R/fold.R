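## RNA secondary structure by base-pair maximization (Nussinov dynamic
## programme) plus an exhaustive enumeration oracle for small sequences.
## Allowed pairs are Watson-Crick plus GU wobble; hairpin loops must hold
## at least min_loop unpaired bases.

PAIRABLE <- c("AU", "UA", "GC", "CG", "GU", "UG")

as_rna <- function(seq) {
  s <- toupper(seq)
  s <- chartr("T", "U", s)
  if (!grepl("^[ACGU]*$", s))
    stop("illegal character(s) in sequence; expected A/C/G/U (or T)")
  s
}

can_pair <- function(a, b) paste0(a, b) %in% PAIRABLE

pairs_to_dotbracket <- function(n, pairs) {
  db <- rep(".", n)
  if (nrow(pairs)) {
    db[pairs[, 1]] <- "("
    db[pairs[, 2]] <- ")"
  }
  paste(db, collapse = "")
}

#' Construct (and validate) an RNA secondary structure
#'
#' @param sequence RNA string (T is transcribed to U).
#' @param pairs two-column integer matrix of base pairs, 1-based, i < j.
#' @param min_loop minimum unpaired bases in a hairpin loop (default 3).
#' @return A \code{secondary_structure}: list with \code{sequence},
#'   \code{pairs} (ordered by i), \code{dotbracket}, \code{n_pairs}.
#' @export
secondary_structure <- function(sequence, pairs, min_loop = 3) {
  sequence <- as_rna(sequence)
  n <- nchar(sequence)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs)) {
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
    i <- pairs[, 1]; j <- pairs[, 2]
    if (any(i >= j) || any(i < 1) || any(j > n))
      stop("pair indices out of range or not i < j")
    if (anyDuplicated(c(i, j)))
      stop("a base may occur in at most one pair")
    if (any(j - i < min_loop + 1))
      stop("pair violates minimum loop size ", min_loop)
    b <- strsplit(sequence, "")[[1]]
    if (!all(can_pair(b[i], b[j])))
      stop("disallowed base pair (only AU/UA/GC/CG/GU/UG)")
    # non-crossing: for every two pairs, nested or disjoint
    if (nrow(pairs) > 1) {
      for (u in seq_len(nrow(pairs) - 1)) {
        v <- (u + 1):nrow(pairs)
        crossing <- pairs[v, 1] < pairs[u, 2] & pairs[v, 2] > pairs[u, 2]
        if (any(crossing)) stop("crossing pairs (pseudoknot) not allowed")
      }
    }
  }
  structure(list(sequence = sequence, pairs = pairs,
                 dotbracket = pairs_to_dotbracket(n, pairs),
                 n_pairs = nrow(pairs), min_loop = min_loop),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(x$sequence, "\n", x$dotbracket, "  (", x$n_pairs, " pairs)\n",
      sep = "")
  invisible(x)
}

#' Fold a sequence window by base-pair maximization
#'
#' Nussinov-style dynamic programme over the allowed pairs (Watson-Crick
#' plus GU wobble) with a minimum hairpin-loop size. The traceback is
#' canonical and deterministic: at each subproblem the option "last base
#' unpaired" is preferred when it attains the optimum, otherwise the
#' smallest admissible partner is chosen — so the returned dot-bracket is
#' reproducible, not an arbitrary co-optimal structure.
#'
#' @param seq RNA (or DNA; T is transcribed) string.
#' @param min_loop minimum number of unpaired bases enclosed by a pair
#'   (default 3).
#' @return a \code{\link{secondary_structure}} with the maximum number of
#'   pairs.
#' @examples
#' fold_window("GGCACGUGGUGCC")   # 5-bp stem with a GUG loop
#' @export
fold_window <- function(seq, min_loop = 3) {
  s <- as_rna(seq)
  n <- nchar(s)
  b <- strsplit(s, "")[[1]]
  if (n == 0) stop("empty sequence")
  if (n <= min_loop + 1)
    return(secondary_structure(s, matrix(integer(), 0, 2), min_loop))
  dp <- matrix(0L, n, n)
  for (span in (min_loop + 1):(n - 1)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- dp[i, j - 1]
      for (k in i:(j - min_loop - 1)) {
        if (can_pair(b[k], b[j])) {
          v <- 1L + (if (k > i) dp[i, k - 1] else 0L) +
            (if (k + 1 <= j - 1) dp[k + 1, j - 1] else 0L)
          if (v > best) best <- v
        }
      }
      dp[i, j] <- best
    }
  }
  pairs <- matrix(integer(), 0, 2)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (j - i < min_loop + 1) next
    if (dp[i, j] == dp[i, j - 1]) {
      stack[[length(stack) + 1L]] <- c(i, j - 1L)
      next
    }
    for (k in i:(j - min_loop - 1)) {
      if (!can_pair(b[k], b[j])) next
      v <- 1L + (if (k > i) dp[i, k - 1] else 0L) +
        (if (k + 1 <= j - 1) dp[k + 1, j - 1] else 0L)
      if (v == dp[i, j]) {
        pairs <- rbind(pairs, c(k, j))
        if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
        if (k + 1 <= j - 1) stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
        break
      }
    }
  }
  secondary_structure(s, pairs, min_loop)
}

#' Enumerate all secondary structures of a short sequence
#'
#' Exhaustive, duplicate-free enumeration of every non-crossing structure
#' over the allowed pairs, used as the independent optimality oracle for
#' \code{\link{fold_window}}. Guarded to sequences of at most 22 nt; the
#' structure count grows exponentially.
#'
#' @inheritParams fold_window
#' @param as_pairs if TRUE (default) return bare two-column pair matrices
#'   (fast); otherwise full \code{secondary_structure} objects.
#' @return list of structures; always includes the open (pair-free)
#'   structure.
#' @export
enumerate_structures <- function(seq, min_loop = 3, as_pairs = TRUE) {
  s <- as_rna(seq)
  n <- nchar(s)
  if (n > 22) stop("sequence longer than 22 nt; enumeration refused")
  b <- strsplit(s, "")[[1]]
  memo <- new.env(parent = emptyenv())
  empty <- list(matrix(integer(), 0, 2))
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(empty)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- rec(i, j - 1L)                        # j unpaired
    for (k in i:(j - min_loop - 1)) {
      if (!can_pair(b[k], b[j])) next
      left <- if (k > i) rec(i, k - 1L) else empty
      right <- rec(k + 1L, j - 1L)
      for (L in left)
        for (R in right)
          out[[length(out) + 1L]] <- rbind(L, R, c(k, j))
    }
    memo[[key]] <- out
    out
  }
  res <- if (n == 0) empty else rec(1L, n)
  if (!as_pairs)
    res <- lapply(res, function(p) secondary_structure(s, p, min_loop))
  res
}

#' Hairpin loops of a structure
#'
#' A hairpin loop is a maximal unpaired run directly closed by a base pair
#' that encloses no other pair. Also reports the closing stem: the number
#' of contiguously stacked pairs ending in the closing pair.
#'
#' @param structure a \code{\link{secondary_structure}}.
#' @return data.frame with one row per loop: \code{loop_start},
#'   \code{loop_end} (the unpaired run), \code{closing_i},
#'   \code{closing_j}, \code{stem_len}.
#' @export
find_hairpin_loops <- function(structure) {
  p <- structure$pairs
  out <- data.frame(loop_start = integer(), loop_end = integer(),
                    closing_i = integer(), closing_j = integer(),
                    stem_len = integer())
  if (!nrow(p)) return(out)
  pairset <- paste(p[, 1], p[, 2])
  for (r in seq_len(nrow(p))) {
    a <- p[r, 1]; b <- p[r, 2]
    inside <- p[, 1] > a & p[, 1] < b
    if (any(inside)) next                       # encloses another pair
    stem <- 1L
    while (paste(a - stem, b + stem) %in% pairset) stem <- stem + 1L
    out <- rbind(out, data.frame(loop_start = a + 1L, loop_end = b - 1L,
                                 closing_i = a, closing_j = b,
                                 stem_len = stem))
  }
  out[order(out$loop_start), , drop = FALSE]
}
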