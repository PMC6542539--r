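#' Run the full analysis pipeline from a declarative config
#'
#' Executes, in order: enrichment (RPM normalization, filtering, RIP
#' efficiency, background correction, ranking), target calling (1.5-IQR
#' rule, optional untagged-outlier exclusion, exclusive/shared sets when
#' several experiments are given), and optionally fRIP peak mapping and
#' anticodon-mimic scanning. Every output file is declared in a JSON run
#' manifest together with the parameters used and an md5 hash, so
#' identical configs and seeds give identical manifests.
#'
#' @param config path to a YAML config file, or an equivalent named list.
#'   Sections: \code{counts} (file; or \code{simulate:} parameters),
#'   \code{experiments} (list of \code{strain}/\code{protocol}),
#'   \code{filter} (\code{min_input_rpm}, \code{drop_noncoding}),
#'   \code{targets} (\code{k}, \code{center_rule},
#'   \code{exclude_untagged}), \code{frip} (\code{signals} file,
#'   \code{input_floor}), \code{mimic} (\code{fasta}, \code{triplet},
#'   \code{window_len}, \code{min_stem}), \code{outdir}.
#' @return the manifest (invisibly also written to
#'   \code{outdir/manifest.json}).
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    yaml::read_yaml(config)
  } else config
  outdir <- cfg$outdir %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  log_stage <- function(stage, ...)
    message(sprintf("[%s] %s", stage, paste(..., collapse = " ")))

  ## --- counts ---------------------------------------------------------
  counts <- tryCatch({
    if (!is.null(cfg$counts)) {
      read_count_table(cfg$counts)
    } else if (!is.null(cfg$simulate)) {
      sp <- do.call(rip_sim_params, cfg$simulate)
      sim <- simulate_ripseq(sp)
      f <- file.path(outdir, "simulated_counts.tsv")
      write_count_table(sim$counts, f)
      written <- c(written, f)
      sim$counts
    } else stop("config needs either 'counts' (file) or 'simulate'")
  }, error = function(e) stop("stage counts: ", conditionMessage(e),
                              call. = FALSE))
  log_stage("counts", nrow(counts$counts), "genes,",
            ncol(counts$counts), "samples")

  fp <- do.call(filter_params, cfg$filter %||% list())
  tg <- cfg$targets %||% list()
  k <- tg$k %||% 1.5
  center <- tg$center_rule %||% "quartile"

  ## --- enrichment + target calling per experiment ---------------------
  exps <- cfg$experiments
  if (is.null(exps)) {
    s <- counts$samples
    tagged <- unique(s[s$strain != "untagged", c("strain", "protocol")])
    exps <- lapply(seq_len(nrow(tagged)), function(i)
      list(strain = tagged$strain[i], protocol = tagged$protocol[i]))
  }
  sets <- list()
  for (ex in exps) {
    enr <- tryCatch(
      rip_enrichment(counts, ex$strain, ex$protocol, params = fp),
      error = function(e) stop("stage enrich (", ex$strain, "): ",
                               conditionMessage(e), call. = FALSE))
    f <- file.path(outdir, paste0("enrichment_", ex$strain, "_",
                                  ex$protocol, ".tsv"))
    write_enrichment(enr, f)
    written <- c(written, f)
    excl <- if (isTRUE(tg$exclude_untagged))
      untagged_outliers(enr$untagged, k = k, center_rule = center) else NULL
    sets[[ex$strain]] <- call_targets(enr, k = k, center_rule = center,
                                      exclude = excl)
    log_stage("enrich", ex$strain, ex$protocol, ":",
              nrow(enr$records), "retained genes,",
              length(sets[[ex$strain]]$genes), "targets")
  }
  f <- file.path(outdir, "targets.tsv")
  write_target_sets(sets, f)
  written <- c(written, f)
  if (length(sets) >= 2) {
    venn <- lapply(shared_targets(sets), as.list)
    f <- file.path(outdir, "venn_regions.json")
    jsonlite::write_json(list(counts = lapply(venn, length),
                              regions = venn), f, auto_unbox = TRUE,
                         pretty = TRUE)
    written <- c(written, f)
  }

  ## --- optional fRIP --------------------------------------------------
  if (!is.null(cfg$frip)) {
    sig <- tryCatch(read_frip_signal(cfg$frip$signals),
                    error = function(e) stop("stage frip: ",
                                             conditionMessage(e),
                                             call. = FALSE))
    enrf <- fragment_enrichment(sig, input_floor = cfg$frip$input_floor)
    pk <- peak_fragment(enrf)
    f <- file.path(outdir, "frip_peak.json")
    jsonlite::write_json(list(peak = pk$peak, smear = pk$smear,
                              flagged = pk$flagged,
                              ratios = unname(pk$ratios)),
                         f, auto_unbox = TRUE, pretty = TRUE)
    written <- c(written, f)
    log_stage("frip", "peak fragment", pk$peak)
  }

  ## --- optional mimic scan --------------------------------------------
  if (!is.null(cfg$mimic)) {
    mc <- cfg$mimic
    seqs <- tryCatch(read_cds_fasta(mc$fasta),
                     error = function(e) stop("stage scan-mimic: ",
                                              conditionMessage(e),
                                              call. = FALSE))
    hits <- do.call(rbind, lapply(names(seqs), function(id) {
      h <- scan_mimic(seqs[[id]], triplet = mc$triplet %||% "GUG",
                      window_len = mc$window_len %||% 15,
                      min_stem = mc$min_stem %||% 2)
      if (nrow(h)) cbind(gene = id, h) else NULL
    }))
    f <- file.path(outdir, "mimic_hits.tsv")
    if (is.null(hits))
      hits <- data.frame(gene = character(), window_start = integer(),
                         triplet_pos = integer())
    utils::write.table(hits, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, f)
    log_stage("scan-mimic", nrow(hits), "hit(s)")
  }

  ## --- manifest -------------------------------------------------------
  manifest <- list(
    parameters = list(filter = unclass(fp), k = k, center_rule = center,
                      exclude_untagged = isTRUE(tg$exclude_untagged)),
    outputs = lapply(stats::setNames(written, basename(written)),
                     function(f) list(path = f,
                                      md5 = unname(tools::md5sum(f)))))
  f <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
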