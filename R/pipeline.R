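#' Run the full isomiR pipeline on in-memory inputs
#'
#' Orchestrates alignment, isomiR annotation, counting, TMM correction,
#' noise-floor estimation and robustness filtering.
#'
#' @param hairpins Hairpin set.
#' @param annotations Mature annotations.
#' @param tags Collapsed tag table over all samples.
#' @param samples Sample sheet.
#' @param params [aligner_params()] (adaptor required for the default
#'   strategy).
#' @param strategy Alignment strategy, see [align_tags()].
#' @param filter [filter_config()].
#' @param decoys Optional decoy mature set for the noise floor; without
#'   decoys the configured \code{default_floor} applies.
#' @param default_floor Fallback noise floor in tpm.
#' @param tmm Whether to apply TMM effective-library-size correction.
#' @return A list of class \code{"isomir_pipeline"} with elements
#'   \code{aligned}, \code{annotated}, \code{counts}, \code{factors},
#'   \code{tpm}, \code{noise_floor}, \code{orphans}, \code{filters}.
#' @export
run_pipeline <- function(hairpins, annotations, tags, samples,
                         params = aligner_params(),
                         strategy = "adaptor_trimmed",
                         filter = filter_config(), decoys = NULL,
                         default_floor = 10, tmm = TRUE) {
  aligned <- align_tags(tags, hairpins, params, strategy)
  annotated <- annotate_alignments(aligned, annotations)
  counts <- build_counts(annotated, samples)
  factors <- if (tmm && ncol(counts$matrix) >= 2L) {
    tmm_factors(counts)
  } else NULL
  tpm <- tpm_matrix(counts, factors)
  eff <- if (is.null(factors)) counts$lib_size else
    stats::setNames(factors$effective_lib_size, factors$sample_id)
  floor <- if (!is.null(decoys)) {
    decoy_noise_floor(tags, decoys, annotations, eff, params, default_floor)
  } else as.integer(default_floor)
  if (filter$min_tpm < floor) filter$min_tpm <- as.numeric(floor)
  orphans <- flag_orphans(counts$features, tpm)
  filters <- apply_filters(tpm, samples, filter, orphans)
  structure(list(aligned = aligned, annotated = annotated, counts = counts,
                 factors = factors, tpm = tpm, noise_floor = floor,
                 orphans = orphans, filters = filters),
            class = "isomir_pipeline")
}

#' @export
print.isomir_pipeline <- function(x, ...) {
  st <- table(x$aligned$status[!duplicated(paste(x$aligned$sequence,
                                                 x$aligned$sample_id))])
  cat("isomir_pipeline:", ncol(x$counts$matrix), "samples,",
      nrow(x$counts$matrix), "features\n")
  cat("tag status:", paste(names(st), st, sep = "=", collapse = ", "), "\n")
  cat("noise floor:", x$noise_floor, "tpm;",
      length(x$filters$retained), "features retained\n")
  invisible(x)
}

#' Read a pipeline run configuration (YAML)
#'
#' Fields: \code{paths} (references, annotations, decoys, samples, reads
#'   directory, out), \code{aligner} (any [aligner_params()] field),
#'   \code{filter} (any [filter_config()] field), \code{strategy},
#'   \code{seed}.
#'
#' @param path YAML config file.
#' @return A validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (p in c("references", "annotations", "samples", "reads")) {
    if (is.null(cfg$paths[[p]]) || !file.exists(cfg$paths[[p]])) {
      stop("config paths$", p, " missing or does not exist")
    }
  }
  if (is.null(cfg$paths$out)) stop("config paths$out is required")
  cfg$aligner <- do.call(aligner_params, as.list(cfg$aligner))
  cfg$filter <- do.call(filter_config, as.list(cfg$filter))
  if (is.null(cfg$strategy)) cfg$strategy <- "adaptor_trimmed"
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg
}

load_run_inputs <- function(cfg) {
  hairpins <- read_hairpin_fasta(cfg$paths$references)
  annotations <- read_annotations(cfg$paths$annotations, hairpins)
  samples <- read_sample_sheet(cfg$paths$samples)
  fq <- list.files(cfg$paths$reads, pattern = "\\.(fastq|fq|fasta|fa)$",
                   full.names = TRUE)
  sids <- sub("\\.[^.]+$", "", basename(fq))
  unknown <- setdiff(sids, samples$sample_id)
  if (length(unknown)) stop("read files without sample-sheet entry: ",
                            paste(unknown, collapse = ", "))
  tags <- do.call(rbind, Map(read_tags, fq, sids))
  rownames(tags) <- NULL
  decoys <- if (!is.null(cfg$paths$decoys)) {
    read_hairpin_fasta(cfg$paths$decoys)
  } else NULL
  list(hairpins = hairpins, annotations = annotations, samples = samples,
       tags = tags, decoys = decoys)
}

#' Align-only command (file in, TSV out)
#'
#' @param cfg Config from [read_run_config()].
#' @return Path of the alignment TSV, invisibly.
#' @export
cmd_align <- function(cfg) {
  inp <- load_run_inputs(cfg)
  dir.create(cfg$paths$out, recursive = TRUE, showWarnings = FALSE)
  aligned <- align_tags(inp$tags, inp$hairpins, cfg$aligner, cfg$strategy)
  st <- table(aligned$status[!duplicated(paste(aligned$sequence,
                                               aligned$sample_id))])
  message("alignment: ", paste(names(st), st, sep = "=", collapse = ", "))
  write_alignments(aligned, file.path(cfg$paths$out, "alignments.tsv"))
}

#' Annotate + quantify command
#'
#' Runs the full pipeline and writes the isomiR/sample count table, tpm
#' matrix, TMM factors and filter report under \code{paths$out}.
#'
#' @param cfg Config from [read_run_config()].
#' @return The pipeline object, invisibly.
#' @export
cmd_annotate_quantify <- function(cfg) {
  inp <- load_run_inputs(cfg)
  dir.create(cfg$paths$out, recursive = TRUE, showWarnings = FALSE)
  pl <- run_pipeline(inp$hairpins, inp$annotations, inp$tags, inp$samples,
                     cfg$aligner, cfg$strategy, cfg$filter, inp$decoys)
  out <- cfg$paths$out
  write_alignments(pl$annotated, file.path(out, "isomirs.tsv"))
  write_isomir_table(pl$counts, file.path(out, "counts.tsv"))
  utils::write.table(data.frame(name = rownames(pl$tpm), pl$tpm,
                                check.names = FALSE),
                     file.path(out, "tpm.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(pl$factors)) {
    utils::write.table(pl$factors, file.path(out, "tmm_factors.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(pl$filters$report, file.path(out, "filter_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(pl)
}

#' Cohort analysis command
#'
#' Writes arm dominance, arm switching and ac-pre-miRNA candidate tables;
#' with a paired wild-type/mutant design, also the ablation report.
#'
#' @param cfg Config from [read_run_config()].
#' @param paired Optional \code{list(wt = <pipeline>, mut = <pipeline>)} for
#'   the paired-condition mode (mutant pre-resampled to wild-type depth).
#' @return A list of the analysis tables, invisibly.
#' @export
cmd_analyze <- function(cfg, paired = NULL) {
  inp <- load_run_inputs(cfg)
  dir.create(cfg$paths$out, recursive = TRUE, showWarnings = FALSE)
  pl <- run_pipeline(inp$hairpins, inp$annotations, inp$tags, inp$samples,
                     cfg$aligner, cfg$strategy, cfg$filter, inp$decoys)
  dom <- arm_dominance_table(pl$tpm, pl$counts$features, inp$samples,
                             pl$noise_floor)
  sw <- detect_arm_switching(dom)
  ac <- find_acpre_candidates(pl$annotated, pl$tpm, pl$counts$features,
                              inp$samples, inp$annotations, pl$noise_floor)
  out <- cfg$paths$out
  utils::write.table(dom, file.path(out, "arm_dominance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sw, file.path(out, "arm_switching.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ac, file.path(out, "acpre_candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  res <- list(dominance = dom, switching = sw, acpre = ac)
  if (!is.null(paired)) {
    cand <- unique(ac[ac$pass_overall, c("hairpin_id", "dominant_arm")])
    res$ablation <- ablation_report(paired$wt$counts, paired$mut$counts, cand)
    utils::write.table(res$ablation$candidates,
                       file.path(out, "ablation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(res)
}

#' Simulate-fixture command
#'
#' @param spec A [sim_spec()] (or path to a YAML file of its fields).
#' @param out_dir Fixture directory to create.
#' @return The cohort object, invisibly.
#' @export
cmd_simulate <- function(spec, out_dir) {
  if (is.character(spec)) {
    spec <- do.call(sim_spec, yaml::read_yaml(spec))
  }
  invisible(simulate_cohort(spec, out_dir))
}
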