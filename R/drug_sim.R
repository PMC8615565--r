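# In-silico inhibitor simulation: each drug clamps its target component to 0
# on top of a patient model (drug clamps override genotype clamps on the same
# component), and response is scored by the 'no marker' surrogate.

#' The simulated inhibitors and their targets
#'
#' Four pathway inhibitors discussed for DLBCL: Ibrutinib (`btk` -> BTK),
#' Copanlisib (`pi3k` -> PI3K), Bortezomib (`nfkb` -> NFkB) and Venetoclax
#' (`bcl2` -> BCL2). Each clamps its target to 0. The drug acts on the named
#' component itself, so lesions downstream of the target escape it.
#'
#' @return Named character vector, drug key -> target component.
#' @export
drug_targets <- function() {
  c(btk = "BTK", pi3k = "PI3K", nfkb = "NFkB", bcl2 = "BCL2")
}

#' Clamps induced by a drug regimen
#'
#' @param regimen Character vector of drug keys (subset of
#'   `names(drug_targets())`); empty = no treatment.
#' @return Named integer vector of zero-clamps on the targets.
#' @export
#' @examples
#' regimen_clamps(c("nfkb", "bcl2"))
regimen_clamps <- function(regimen) {
  regimen <- as.character(regimen)
  bad <- setdiff(regimen, names(drug_targets()))
  if (length(bad))
    stop("unknown drug(s): ", paste(bad, collapse = ", "),
         "; available: ", paste(names(drug_targets()), collapse = ", "),
         call. = FALSE)
  stats::setNames(integer(length(regimen)), drug_targets()[regimen])
}

#' The seven regimen blocks evaluated by default
#'
#' No treatment, the four single agents, and the two BCL2-anchored
#' combinations (PI3Ki+BCL2i, NFKBi+BCL2i).
#'
#' @return Named list of drug-key vectors.
#' @export
default_regimens <- function() {
  list(none = character(0),
       btk = "btk", nfkb = "nfkb", pi3k = "pi3k", bcl2 = "bcl2",
       `pi3k+bcl2` = c("pi3k", "bcl2"),
       `nfkb+bcl2` = c("nfkb", "bcl2"))
}

regimen_label <- function(regimen) {
  if (!length(regimen)) "none" else paste(sort(regimen), collapse = "+")
}

#' Simulate an inhibitor regimen on a patient model
#'
#' Applies the regimen's zero-clamps on top of the patient network (drug
#' clamps override genotype clamps targeting the same component) and
#' profiles the reachable physiological stages. The treatment is scored by
#' the 'no marker' surrogate: stages whose fixpoints have BCL6, BLIMP1, MYC
#' and BCL2 all inactive — the model's proxy for loss of pro-survival
#' signaling. Stages lost to input clamps are excluded from the denominator.
#'
#' @param model A `patient_model` (or `logical_network`).
#' @param regimen Character vector of drug keys; empty = untreated.
#' @return A `treatment_outcome`: `model_id`, `regimen`, `profile`,
#'   `no_marker_stage_count`, `reachable_stage_count`, `fraction`,
#'   `active_marker_total` (active markers summed over stage fixpoints, the
#'   ranking tie-breaker).
#' @export
#' @examples
#' pm <- patient_model(c(CBM = 1), model_id = "CBM-GOF")
#' simulate_treatment(pm, c("nfkb", "bcl2"))
simulate_treatment <- function(model, regimen = character(0)) {
  net <- as_model_network(model)
  model_id <- if (inherits(model, "patient_model")) model$model_id else NA_character_
  treated <- apply_clamps(net, regimen_clamps(regimen))  # later clamps win
  tm <- if (inherits(model, "patient_model")) {
    structure(list(network = treated, base = model$base,
                   genotype_clamps = model$genotype_clamps,
                   model_id = model_id, conflicts = model$conflicts,
                   coo_label = model$coo_label), class = "patient_model")
  } else treated
  prof <- attractor_profile(tm)
  reach <- Filter(function(r) !r$lost, prof$stages)
  no_marker <- sum(vapply(reach, function(r)
    nrow(r$fixpoints) > 0L && all(r$patterns == "none"), TRUE))
  total_active <- sum(vapply(reach, function(r) {
    if (!nrow(r$fixpoints)) 0L
    else sum(r$fixpoints[, gc_marker_order, drop = FALSE] >= 1L)
  }, 0L))
  structure(list(model_id = model_id, regimen = sort(as.character(regimen)),
                 profile = prof,
                 no_marker_stage_count = no_marker,
                 reachable_stage_count = length(reach),
                 fraction = if (length(reach)) no_marker / length(reach) else NA_real_,
                 active_marker_total = total_active),
            class = "treatment_outcome")
}

#' @export
print.treatment_outcome <- function(x, ...) {
  cat("Treatment ", regimen_label(x$regimen),
      if (!is.na(x$model_id)) paste0(" on model ", x$model_id), ": ",
      x$no_marker_stage_count, "/", x$reachable_stage_count,
      " reachable stages at 'no marker'\n", sep = "")
  print(x$profile)
  invisible(x)
}

#' Rank candidate regimens for one patient model
#'
#' Regimens are ordered by descending number of 'no marker' stages, ties
#' broken by fewer active markers summed over stages, then by smaller
#' regimen, then lexicographically by label.
#'
#' @param model A `patient_model`.
#' @param regimens List of drug-key vectors (default [default_regimens()]).
#' @return Data frame in ranked order: `regimen`, `no_marker_stage_count`,
#'   `reachable_stage_count`, `active_marker_total`, `n_drugs`; the
#'   `treatment_outcome`s are attached as attribute `"outcomes"`.
#' @export
rank_regimens <- function(model, regimens = default_regimens()) {
  if (!length(regimens)) stop("need at least one candidate regimen", call. = FALSE)
  outcomes <- lapply(regimens, function(r) simulate_treatment(model, r))
  df <- data.frame(
    regimen = vapply(outcomes, function(o) regimen_label(o$regimen), ""),
    no_marker_stage_count = vapply(outcomes, `[[`, 0L, "no_marker_stage_count"),
    reachable_stage_count = vapply(outcomes, `[[`, 0L, "reachable_stage_count"),
    active_marker_total = vapply(outcomes, `[[`, 0L, "active_marker_total"),
    n_drugs = vapply(outcomes, function(o) length(o$regimen), 0L),
    stringsAsFactors = FALSE)
  o <- order(-df$no_marker_stage_count, df$active_marker_total, df$n_drugs,
             df$regimen)
  df <- df[o, ]
  rownames(df) <- NULL
  attr(df, "outcomes") <- outcomes[o]
  df
}
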