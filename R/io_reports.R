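# Report writers and the high-level entry points tying the pipeline
# together. All outputs are plain tab-separated text, deterministic given
# identical inputs and seed, and round-trip through their readers.

#' Export an attractor profile as a long-format table
#'
#' One row per (stage, fixpoint, component) with the activity level; lost
#' stages appear with `fixpoint = 0` and `level = NA`.
#'
#' @param profile An `attractor_profile`.
#' @param path Output path; `NULL` returns the data frame only.
#' @return The long-format data frame, invisibly when written.
#' @export
write_attractor_table <- function(profile, path = NULL) {
  rows <- list()
  for (rec in profile$stages) {
    if (rec$lost || !nrow(rec$fixpoints)) {
      rows[[length(rows) + 1L]] <- data.frame(
        model_id = profile$model_id, stage_id = rec$stage_id,
        stage_name = rec$stage_name, fixpoint = 0L,
        component = if (rec$lost) "lost" else "no_fixpoint", level = NA_integer_,
        stringsAsFactors = FALSE)
      next
    }
    for (k in seq_len(nrow(rec$fixpoints))) {
      rows[[length(rows) + 1L]] <- data.frame(
        model_id = profile$model_id, stage_id = rec$stage_id,
        stage_name = rec$stage_name, fixpoint = k,
        component = colnames(rec$fixpoints),
        level = unname(rec$fixpoints[k, ]), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (is.null(path)) return(out)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Write the wild-type attractor table
#'
#' The eight-stage attractor table of the unperturbed model in wide form:
#' one row per stage with the full state, the marker pattern and the
#' physiological flag.
#'
#' @param path Output TSV path; `NULL` returns the data frame only.
#' @param network The (unperturbed) GC network.
#' @return The 8-row data frame, invisibly when written.
#' @export
#' @examples
#' run_attractors()
run_attractors <- function(path = NULL, network = gc_network()) {
  wt <- wild_type_profile(network)
  st <- do.call(rbind, lapply(wt$stages, function(rec) {
    s <- rec$fixpoints[1L, ]
    cbind(data.frame(stage_id = rec$stage_id, stage_name = rec$stage_name,
                     physiological = rec$physiological,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(s)),
          data.frame(markers = rec$patterns[1L], AID_active = rec$aid[1L],
                     stringsAsFactors = FALSE))
  }))
  rownames(st) <- NULL
  if (is.null(path)) return(st)
  utils::write.table(st, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(st)
}

#' Run the cohort pipeline and write its reports
#'
#' Computes the [cohort_report()] for a lesion table and writes
#' `cohort_report.tsv` plus `attractors_long.tsv` (per-model long-format
#' attractor tables) into `out_dir`.
#'
#' @param lesions Lesion table (data frame or TSV path).
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @param rules Mapping rules.
#' @param network Base network.
#' @return The cohort report data frame.
#' @export
run_cohort <- function(lesions, out_dir = NULL,
                       rules = default_mapping_table(), network = gc_network()) {
  if (is.character(lesions)) lesions <- read_lesion_table(lesions)
  report <- cohort_report(lesions, rules, network)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(report, file.path(out_dir, "cohort_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    long <- do.call(rbind, lapply(unique(lesions$patient_id), function(pid) {
      ps <- genotype_to_perturbations(lesions, rules, network, patient_id = pid)
      write_attractor_table(attractor_profile(patient_model(ps, network)))
    }))
    utils::write.table(long, file.path(out_dir, "attractors_long.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}

#' Read back a cohort report
#' @param path Path to `cohort_report.tsv`.
#' @return Data frame as written by [run_cohort()].
#' @export
read_cohort_report <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(model_id = "character"))
}

#' Run the drug screen and write the treatment report
#'
#' Simulates every regimen on every patient model and writes a long-format
#' report: one row per model x regimen x stage, plus the per-regimen
#' 'no marker' counts.
#'
#' @param lesions Lesion table (data frame or TSV path).
#' @param out_dir Output directory; `NULL` skips writing.
#' @param regimens Named list of drug-key vectors (default
#'   [default_regimens()]).
#' @param rules Mapping rules.
#' @param network Base network.
#' @return The treatment report data frame.
#' @export
run_drugs <- function(lesions, out_dir = NULL, regimens = default_regimens(),
                      rules = default_mapping_table(), network = gc_network()) {
  if (is.character(lesions)) lesions <- read_lesion_table(lesions)
  lesions <- validate_lesions(lesions)
  rows <- list()
  for (pid in unique(lesions$patient_id)) {
    ps <- genotype_to_perturbations(lesions, rules, network, patient_id = pid)
    pm <- patient_model(ps, network)
    for (reg in regimens) {
      out <- simulate_treatment(pm, reg)
      for (rec in out$profile$stages) {
        rows[[length(rows) + 1L]] <- data.frame(
          model_id = pid, regimen = regimen_label(reg),
          stage_name = rec$stage_name, pattern = stage_label(rec),
          no_marker_stage_count = out$no_marker_stage_count,
          reachable_stage_count = out$reachable_stage_count,
          stringsAsFactors = FALSE)
      }
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(report, file.path(out_dir, "treatment_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}

#' Read back a treatment report
#' @param path Path to `treatment_report.tsv`.
#' @return Data frame as written by [run_drugs()].
#' @export
read_treatment_report <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(model_id = "character"))
}
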