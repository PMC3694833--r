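# Pipeline driver: wires enumerate -> simulate (optional) -> classify ->
# quantify -> diff from a single config, writing versioned outputs and a run
# manifest with parameter echo and output checksums.

#' Run the analysis pipeline from a config
#'
#' The config is a nested list (or path to a YAML file) with blocks:
#' * `locus`: either `fasta` + geometry fields (see [load_locus()]) or
#'   `synthetic: true` for the bundled synthetic locus;
#' * `layout`: fields of [read_layout()] (optional, defaults used);
#' * `limits`: `L_max`, `R_max`, `M_max` for [enumerate_joints()];
#' * `simulate`: optional; `kinds` (named list sample -> spectrum kind),
#'   `reads_per_sample`, `error_rate`, `contaminant_frac`;
#' * `classify`: `fastq` (ignored when simulating), `max_mismatch`,
#'   `contaminant` (`"synthetic"`, a FASTA path, or omitted);
#' * `quantify`: `threshold` (default 0.001);
#' * `diff`: optional; `condition_map` (named list sample -> condition),
#'   `alpha` (default 0.005);
#' * `seed`, `out_dir`, `stages` (default all applicable).
#'
#' Every parameter is echoed into `manifest.json` together with md5
#' checksums of all outputs; re-running an identical config reproduces
#' identical outputs byte for byte.
#'
#' @param config List or YAML path.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config needs an out_dir")
  if (is.null(config$seed)) stop("config needs a seed")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  log_stage <- function(...) message(sprintf("[nhejseq] %s", sprintf(...)))
  outputs <- character(0)
  manifest <- list(config = config, stages = list())
  seed <- as.integer(config$seed)

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- c(manifest$stages[[name]],
                                  list(elapsed_s = round(
                                    proc.time()[["elapsed"]] - t0, 3)))
    log_stage("stage %s done (%.1fs)", name,
              proc.time()[["elapsed"]] - t0)
    res
  }

  # locus + layout + joint space
  locus <- stage("locus", {
    lc <- config$locus
    if (isTRUE(lc$synthetic)) synthetic_locus() else load_locus(lc$fasta, lc)
  })
  lay <- do.call(read_layout, config$layout %||% list())
  lim <- config$limits %||% list()
  templates <- stage("enumerate", {
    tp <- enumerate_joints(locus, lay,
                           L_max = lim$L_max %||% 25L,
                           R_max = lim$R_max %||% 25L,
                           M_max = lim$M_max %||% 10L)
    write_joint_space(tp, tsv_path = out("joint_space.tsv"))
    outputs <- c(outputs, out("joint_space.tsv"))
    tp
  })

  stages <- config$stages %||%
    c("simulate"[!is.null(config$simulate)], "classify", "quantify",
      "diff"[!is.null(config$diff)])

  index_table <- NULL
  fastq <- config$classify$fastq
  if ("simulate" %in% stages) {
    sim <- stage("simulate", {
      sc <- config$simulate
      kinds <- sc$kinds
      index_table <- sample_index_table(default_sample_indexes(length(kinds)),
                                         names(kinds))
      spectra <- lapply(kinds, function(kd)
        make_spectrum(kd, templates, seed = seed,
                      reads_per_sample = sc$reads_per_sample %||% 50000L,
                      error_rate = sc$error_rate %||% 0.002,
                      contaminant_frac = sc$contaminant_frac %||% 0.5))
      res <- simulate_reads(spectra, templates, index_table, lay,
                            out_fastq = out("reads.fastq"), seed = seed)
      write_count_table(res$truth, out("truth_counts.tsv"))
      outputs <- c(outputs, out("reads.fastq"), out("truth_counts.tsv"))
      res
    })
    fastq <- sim$fastq
  }
  if (is.null(index_table)) {
    it <- config$classify$index_table
    if (is.null(it)) stop("classify stage needs an index_table (TSV path)")
    index_table <- sample_index_table(it)
  }

  counts <- NULL
  if ("classify" %in% stages) {
    counts <- stage("classify", {
      mm <- config$classify$max_mismatch %||% 1L
      if (mm != 1L)
        warning("max_mismatch = ", mm, " departs from the assay's standard ",
                "one-mismatch joint-assignment tolerance", call. = FALSE)
      cref <- config$classify$contaminant
      cref <- if (is.null(cref)) NULL
              else if (identical(cref, "synthetic")) synthetic_contaminant()
              else as.character(Biostrings::readDNAStringSet(cref)[[1]])
      cb <- classify_batch(fastq, templates, index_table, lay,
                           contaminant_ref = cref, max_mismatch = mm)
      write_count_table(cb, out("joint_counts.tsv"))
      jsonlite::write_json(cb$stats, out("run_stats.json"), auto_unbox = TRUE)
      outputs <- c(outputs, out("joint_counts.tsv"), out("run_stats.json"))
      s <- cb$stats
      conserved <- s$assigned + s$ambiguous + s$unmatched + s$contaminant +
        s$unassigned_index + s$truncated == s$total_reads
      if (!conserved) stop("read conservation violated")
      log_stage("read conservation check passed (%d reads)", s$total_reads)
      manifest$stages$classify$conservation <- conserved
      cb
    })
  }

  if ("quantify" %in% stages && !is.null(counts)) {
    stage("quantify", {
      fr <- joint_fractions(counts)
      categories <- categorize_joints(fr,
                                      config$quantify$threshold %||% 0.001)
      cf <- category_fractions(fr, categories)
      utils::write.table(data.frame(joint_id = rownames(fr), fr,
                                    category = categories,
                                    check.names = FALSE),
                         out("joint_fractions.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(data.frame(category = rownames(cf), cf,
                                    check.names = FALSE),
                         out("category_fractions.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, out("joint_fractions.tsv"),
                    out("category_fractions.tsv"))
      NULL
    })
  }

  if ("diff" %in% stages && !is.null(counts)) {
    stage("diff", {
      cmap <- unlist(config$diff$condition_map)
      keep <- colnames(counts$counts) %in% names(cmap)
      sub <- counts$counts[, keep, drop = FALSE]
      dres <- nhej_diff(sub, cmap, alpha = config$diff$alpha %||% 0.005,
                        major_threshold = config$quantify$threshold %||% 0.001)
      write_diff_table(dres, out("differential.tsv"))
      outputs <- c(outputs, out("differential.tsv"))
      NULL
    })
  }

  manifest$outputs <- lapply(stats::setNames(outputs, basename(outputs)),
                             function(f) list(path = f,
                                              md5 = unname(tools::md5sum(f))))
  manifest$seed <- seed
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
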