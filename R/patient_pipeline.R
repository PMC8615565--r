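# Patient-specific models: clamp the GC network with a genotype-derived
# perturbation set, profile its fixpoints across the GC stages, compare to
# wild type, and classify oncogenicity and NF-kB dependency.

#' Build a patient-specific model
#'
#' Applies a genotype's clamps to the base GC network and packages the result
#' with its provenance. Each patient formally gets a new model whose clamped
#' components escape their physiological regulation.
#'
#' @param perturbations A `perturbation_set` from
#'   [genotype_to_perturbations()], or a named integer clamp vector.
#' @param network Base network (default [gc_network()]).
#' @param model_id Optional id; defaults to the perturbation set's patient id.
#' @return A `patient_model`: list with `network` (clamped), `base`,
#'   `genotype_clamps`, `model_id`, `conflicts`, `coo_label`.
#' @export
#' @examples
#' pm <- patient_model(c(BCL2 = 1), model_id = "73")
patient_model <- function(perturbations, network = gc_network(), model_id = NULL) {
  if (inherits(perturbations, "perturbation_set")) {
    clamps <- perturbations$clamps
    conflicts <- perturbations$conflicts
    coo <- perturbations$coo_label
    if (is.null(model_id)) model_id <- perturbations$patient_id
  } else {
    clamps <- stats::setNames(as.integer(perturbations), names(perturbations))
    conflicts <- character(0)
    coo <- "unclassified"
  }
  clamped <- if (length(clamps)) apply_clamps(network, clamps) else network
  structure(list(network = clamped, base = network,
                 genotype_clamps = clamps,
                 model_id = if (is.null(model_id)) NA_character_ else as.character(model_id),
                 conflicts = conflicts, coo_label = coo),
            class = "patient_model")
}

#' @export
print.patient_model <- function(x, ...) {
  cat("Patient model ", x$model_id, "\n", sep = "")
  if (length(x$genotype_clamps))
    cat("  genotype clamps: ",
        paste0(names(x$genotype_clamps), "=", x$genotype_clamps, collapse = ", "),
        "\n", sep = "")
  else cat("  genotype clamps: none (wild-type behaviour)\n")
  for (cf in x$conflicts) cat("  conflict: ", cf, "\n", sep = "")
  invisible(x)
}

#' @export
summary.patient_model <- function(object, ...) {
  print(object)
  prof <- attractor_profile(object)
  print(prof)
  cat("NF-kB dependency class:", classify_nfkb(object), "\n")
  invisible(object)
}

as_model_network <- function(x) {
  if (inherits(x, "patient_model")) x$network
  else if (inherits(x, "logical_network")) x
  else stop("expected a 'patient_model' or 'logical_network'", call. = FALSE)
}

#' Stage-resolved attractor profile
#'
#' For each requested GC stage, either marks the stage as lost (an input
#' clamp contradicts the stage's input combination, so that environment no
#' longer exists for this model) or enumerates the fixpoints under the
#' stage's input assignment and attaches marker patterns.
#'
#' @param x A `patient_model` or `logical_network`.
#' @param stages Stage ids to profile; defaults to the five physiological
#'   stages for patient models (use `1:8` for the full table).
#' @return An `attractor_profile`: `model_id` plus one record per stage with
#'   `stage_id`, `stage_name`, `inputs`, `physiological`, `lost`,
#'   `fixpoints` (matrix) and `patterns`/`aid` per fixpoint.
#' @export
#' @examples
#' attractor_profile(patient_model(c(MYC = 1), model_id = "MYC-ect"))
attractor_profile <- function(x, stages = NULL) {
  net <- as_model_network(x)
  model_id <- if (inherits(x, "patient_model")) x$model_id else NA_character_
  if (is.null(stages)) stages <- physiological_stage_ids()
  st <- gc_stages()
  if (!all(stages %in% st$stage_id)) stop("unknown stage id(s)", call. = FALSE)

  input_comps <- net$names[net$is_input]
  input_clamps <- net$clamps[intersect(names(net$clamps), input_comps)]

  recs <- lapply(stages, function(id) {
    row <- st[st$stage_id == id, ]
    triple <- c(BCR = row$BCR, CD40 = row$CD40, IL21_4 = row$IL21_4)
    lost <- length(input_clamps) > 0L &&
      any(input_clamps != triple[names(input_clamps)])
    if (lost) {
      fp <- matrix(integer(0), 0L, length(net$names),
                   dimnames = list(NULL, net$names))
    } else {
      free_inputs <- setdiff(input_comps, names(input_clamps))
      fp <- enumerate_fixpoints(net, triple[free_inputs])
    }
    pats <- if (nrow(fp)) apply(fp, 1L, function(s) marker_pattern(s)$label)
            else character(0)
    aid <- if (nrow(fp)) unname(fp[, "AID"] >= 1L) else logical(0)
    list(stage_id = id, stage_name = row$stage_name, inputs = triple,
         physiological = row$physiological, lost = lost,
         fixpoints = fp, patterns = as.character(pats), aid = aid)
  })
  structure(list(model_id = model_id, stages = recs), class = "attractor_profile")
}

stage_label <- function(rec) {
  if (rec$lost) "lost"
  else if (!nrow(rec$fixpoints)) "no fixpoint"
  else paste(rec$patterns, collapse = " / ")
}

#' @export
print.attractor_profile <- function(x, ...) {
  cat("Attractor profile", if (!is.na(x$model_id)) paste0(" [model ", x$model_id, "]"),
      "\n", sep = "")
  for (rec in x$stages) {
    cat(sprintf("  %2d %-9s (BCR=%d CD40=%d IL21/4=%d)%s: %s%s\n",
                rec$stage_id, rec$stage_name,
                rec$inputs["BCR"], rec$inputs["CD40"], rec$inputs["IL21_4"],
                if (rec$physiological) "" else " n.phys.",
                stage_label(rec),
                if (length(rec$aid) && any(rec$aid)) " [AID]" else ""))
  }
  invisible(x)
}

#' Data-frame view of a profile
#'
#' @param x An `attractor_profile`.
#' @param ... Unused.
#' @return Data frame: `model_id`, `stage_id`, `stage_name`, `physiological`,
#'   `lost`, `pattern`.
#' @export
as.data.frame.attractor_profile <- function(x, ...) {
  data.frame(model_id = x$model_id,
             stage_id = vapply(x$stages, `[[`, 0L, "stage_id"),
             stage_name = vapply(x$stages, `[[`, "", "stage_name"),
             physiological = vapply(x$stages, `[[`, TRUE, "physiological"),
             lost = vapply(x$stages, `[[`, TRUE, "lost"),
             pattern = vapply(x$stages, stage_label, ""),
             stringsAsFactors = FALSE)
}

profile_stage <- function(profile, id) {
  for (rec in profile$stages) if (rec$stage_id == id) return(rec)
  NULL
}

#' Compare a patient profile to wild type
#'
#' A stage counts as changed when it is lost or when its marker pattern
#' (the sorted multiset of per-fixpoint pattern labels) differs from the
#' wild-type stage; full-state detail stays available in the profiles. Only
#' physiological stages present in both profiles are compared.
#'
#' @param wt_profile Wild-type profile ([wild_type_profile()]).
#' @param profile Patient profile ([attractor_profile()]).
#' @return A `wt_comparison`: `changed_stage_count`, `changed_stages`,
#'   `lost_stages` (names), and per-stage `deltas` listing aberrantly active
#'   and aberrantly inactive markers.
#' @export
#' @examples
#' wt <- wild_type_profile()
#' compare_to_wild_type(wt, attractor_profile(patient_model(c(ERK = 1))))
compare_to_wild_type <- function(wt_profile, profile) {
  ids <- intersect(
    vapply(wt_profile$stages, `[[`, 0L, "stage_id"),
    vapply(profile$stages, `[[`, 0L, "stage_id"))
  ids <- intersect(ids, physiological_stage_ids())
  if (!length(ids)) stop("profiles share no physiological stages", call. = FALSE)

  changed <- character(0); lost <- character(0); deltas <- list()
  for (id in ids) {
    w <- profile_stage(wt_profile, id)
    p <- profile_stage(profile, id)
    if (p$lost) {
      changed <- c(changed, p$stage_name)
      lost <- c(lost, p$stage_name)
      next
    }
    if (!identical(sort(w$patterns), sort(p$patterns))) {
      changed <- c(changed, p$stage_name)
      wt_act <- if (nrow(w$fixpoints)) gc_marker_order[colSums(w$fixpoints[, gc_marker_order, drop = FALSE] >= 1L) > 0L] else character(0)
      pt_act <- if (nrow(p$fixpoints)) gc_marker_order[colSums(p$fixpoints[, gc_marker_order, drop = FALSE] >= 1L) > 0L] else character(0)
      deltas[[p$stage_name]] <- list(aberrant_active = setdiff(pt_act, wt_act),
                                     aberrant_inactive = setdiff(wt_act, pt_act))
    }
  }
  structure(list(changed_stage_count = length(changed), changed_stages = changed,
                 lost_stages = lost, deltas = deltas),
            class = "wt_comparison")
}

#' @export
print.wt_comparison <- function(x, ...) {
  cat(x$changed_stage_count, "of the compared stages differ from wild type\n")
  if (length(x$lost_stages))
    cat("  lost:", paste(x$lost_stages, collapse = ", "), "\n")
  for (nm in names(x$deltas)) {
    d <- x$deltas[[nm]]
    cat("  ", nm, ": ", sep = "")
    if (length(d$aberrant_active))
      cat("aberrantly active ", paste(d$aberrant_active, collapse = "+"), " ", sep = "")
    if (length(d$aberrant_inactive))
      cat("aberrantly inactive ", paste(d$aberrant_inactive, collapse = "+"), sep = "")
    cat("\n")
  }
  invisible(x)
}

#' Oncogenicity flags of a profile
#'
#' Four independent criteria over the physiological stages:
#' `abnormal_combination` — BCL6 co-active with MYC and/or BCL2 in any
#' fixpoint (the aggressive double/triple-hit-like state);
#' `wrong_stage` — BCL6 active outside DZ, or MYC active outside Pre-GC and
#' LZ2; `pc_loss` — the PC stage is lost, has no fixpoint, or its attractor
#' lacks BLIMP1 (no germinal-center exit); `lz1_loss` — the LZ1 stage is
#' lost, has no fixpoint, or shows any active marker (no signal-free resting
#' state, i.e. escape from selection). `oncogenic` is the OR of the four.
#'
#' @param profile An `attractor_profile` covering the physiological stages.
#' @return An `oncogenicity_report` (list of the five flags).
#' @export
classify_oncogenic <- function(profile) {
  abnormal <- FALSE; wrong <- FALSE
  pc_loss <- FALSE; lz1_loss <- FALSE
  seen <- character(0)
  for (rec in profile$stages) {
    if (!rec$physiological) next
    seen <- c(seen, rec$stage_name)
    fp <- rec$fixpoints
    if (nrow(fp)) {
      bcl6 <- fp[, "BCL6"] >= 1L
      myc <- fp[, "MYC"] >= 1L
      bcl2 <- fp[, "BCL2"] >= 1L
      blimp1 <- fp[, "BLIMP1"] >= 1L
      if (any(bcl6 & (myc | bcl2))) abnormal <- TRUE
      if (rec$stage_name != "DZ" && any(bcl6)) wrong <- TRUE
      if (!rec$stage_name %in% c("Pre-GC", "LZ2") && any(myc)) wrong <- TRUE
    }
    if (rec$stage_name == "PC" &&
        (rec$lost || !nrow(fp) || !all(fp[, "BLIMP1"] >= 1L))) pc_loss <- TRUE
    if (rec$stage_name == "LZ1" &&
        (rec$lost || !nrow(fp) || any(rec$patterns != "none"))) lz1_loss <- TRUE
  }
  if (!all(c("LZ1", "PC") %in% seen))
    stop("profile must cover the physiological stages (LZ1..PC)", call. = FALSE)
  structure(list(abnormal_combination = abnormal, wrong_stage = wrong,
                 pc_loss = pc_loss, lz1_loss = lz1_loss,
                 oncogenic = abnormal || wrong || pc_loss || lz1_loss),
            class = "oncogenicity_report")
}

#' @export
print.oncogenicity_report <- function(x, ...) {
  cat("Oncogenicity:", if (x$oncogenic) "ONCOGENIC" else "not oncogenic", "\n")
  cat(sprintf("  abnormal marker combination: %s\n  marker in wrong stage: %s\n  PC loss: %s\n  LZ1 loss: %s\n",
              x$abnormal_combination, x$wrong_stage, x$pc_loss, x$lz1_loss))
  invisible(x)
}

#' The five NF-kB dependency classes
#' @return Character vector of class labels.
#' @export
nfkb_classes <- function() {
  c("unperturbed", "level1", "level2", "inactive", "independent")
}

# constitutive NFkB level of a genotype: evaluate the non-input clamps at the
# all-zero input. The NFkB ancestor chain (receptors -> BTK -> CBM/TRAF6 ->
# IKKc -> NFkB) is acyclic, so synchronous iteration stabilises; if it does
# not (non-GC networks), fall back to conditioned enumeration.
constitutive_nfkb_level <- function(base, clamps) {
  input_comps <- base$names[base$is_input]
  internal <- clamps[setdiff(names(clamps), input_comps)]
  net0 <- if (length(internal)) apply_clamps(base, internal) else base
  s <- stats::setNames(integer(length(net0$names)), net0$names)
  if (length(internal)) s[names(internal)] <- internal
  for (i in seq_len(length(net0$names) + 2L)) {
    s2 <- synchronous_step(net0, s)
    if (identical(s2, s)) return(unname(s["NFkB"]))
    s <- s2
  }
  fp <- enumerate_fixpoints(net0, stats::setNames(integer(length(input_comps)), input_comps))
  if (nrow(fp)) max(fp[, "NFkB"]) else 0L
}

#' NF-kB dependency class of a patient model
#'
#' Decision cascade: (1) `independent` when the genotype clamps MYC or BCL6
#' active — marker expression is then driven by the lesion, not by NF-kB;
#' (2) `inactive` when the genotype clamps NFkB (or IKKc, its sole regulator)
#' to 0; (3) `level2`/`level1` when the genotype's internal clamps give NFkB
#' a constitutive level 2/1 at the signal-free input (input clamps are set
#' aside for this diagnostic, so a receptor-only lesion such as CD79B does
#' not by itself create constitutive NF-kB); (4) `unperturbed` otherwise.
#' The cascade is total and deterministic: every genotype maps to exactly
#' one class.
#'
#' @param model A `patient_model`.
#' @return One of [nfkb_classes()].
#' @export
#' @examples
#' classify_nfkb(patient_model(c(CBM = 1)))  # "level1"
classify_nfkb <- function(model) {
  stopifnot(inherits(model, "patient_model"))
  cl <- model$genotype_clamps
  if (("MYC" %in% names(cl) && cl["MYC"] >= 1L) ||
      ("BCL6" %in% names(cl) && cl["BCL6"] >= 1L)) return("independent")
  if (("NFkB" %in% names(cl) && cl["NFkB"] == 0L) ||
      ("IKKc" %in% names(cl) && cl["IKKc"] == 0L)) return("inactive")
  lv <- constitutive_nfkb_level(model$base, cl)
  if (lv >= 2L) return("level2")
  if (lv == 1L) return("level1")
  "unperturbed"
}

#' Cohort-level report
#'
#' Runs the whole pipeline for every patient in a lesion table: genotype ->
#' perturbation set -> patient model -> physiological-stage profile ->
#' wild-type comparison, oncogenicity flags and NF-kB class.
#'
#' @param lesions Lesion table (data frame or path).
#' @param rules Mapping rules.
#' @param network Base network.
#' @return Data frame, one row per patient, with stable columns `model_id`,
#'   `coo_label`, the five stage patterns (`LZ1`, `PreGC`, `DZ`, `LZ2`,
#'   `PC`; `"lost"` where the stage is lost), `changed_stages`, `conflicts`,
#'   the four oncogenicity flags, `oncogenic` and `nfkb_class`.
#' @export
cohort_report <- function(lesions, rules = default_mapping_table(),
                          network = gc_network()) {
  if (is.character(lesions)) lesions <- read_lesion_table(lesions)
  lesions <- validate_lesions(lesions)
  wt <- wild_type_profile(network)
  ids <- unique(lesions$patient_id)
  rows <- lapply(ids, function(pid) {
    ps <- genotype_to_perturbations(lesions, rules, network, patient_id = pid)
    pm <- patient_model(ps, network)
    prof <- attractor_profile(pm)
    cmp <- compare_to_wild_type(wt, prof)
    onc <- classify_oncogenic(prof)
    pat <- stats::setNames(vapply(prof$stages, stage_label, ""),
                           vapply(prof$stages, `[[`, "", "stage_name"))
    data.frame(model_id = pid, coo_label = ps$coo_label,
               LZ1 = pat[["LZ1"]], PreGC = pat[["Pre-GC"]], DZ = pat[["DZ"]],
               LZ2 = pat[["LZ2"]], PC = pat[["PC"]],
               changed_stages = cmp$changed_stage_count,
               conflicts = paste(ps$conflicts, collapse = "; "),
               abnormal_combination = onc$abnormal_combination,
               wrong_stage = onc$wrong_stage, pc_loss = onc$pc_loss,
               lz1_loss = onc$lz1_loss, oncogenic = onc$oncogenic,
               nfkb_class = classify_nfkb(pm),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
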