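# Genotype handling: Oncoprint-style lesion tables, the gene -> model
# component mapping, the high-grade/non-synonymous filter, and the
# GOF/LOF interpretation that turns lesions into component clamps.

#' Closed vocabulary of alteration classes
#'
#' The Oncoprint categories accepted in lesion tables: mutation status
#' (non-synonymous vs synonymous), structural variants (`sv`) and the five
#' copy-number grades.
#'
#' @return Character vector of valid `alteration_class` values.
#' @export
lesion_classes <- function() {
  c("nonsynonymous_mutation", "synonymous_mutation", "sv",
    "cn_high_gain", "cn_low_gain", "cn_neutral", "cn_low_loss", "cn_high_loss")
}

# classes that survive the strong-effect filter
strong_classes <- function() {
  c("nonsynonymous_mutation", "sv", "cn_high_gain", "cn_high_loss")
}

#' Default gene-to-component mapping table
#'
#' Every gene-to-component assignment documented for the model: BCR-proximal
#' kinases, RAS family onto RAF, the CARD11/BCL10/MALT1 (CBM) complex, the
#' NF-kB regulators TNFAIP3 (A20) and NFKBIE (IkB-epsilon), receptor-level
#' TLR2/MYD88 onto TRAF6, STAT family onto STAT, PTEN onto PI3K, the BCL6
#' regulators MEF2B/IRF8 (activators) and CREBBP/EP300 (suppressing
#' acetyl-transferases), EZH2 onto BLIMP1, and the BCL2 family
#' (BCL2/BCL2L1/MCL1) onto BCL2.
#'
#' @return Data frame with columns `gene`, `component`,
#'   `role` (`oncogene`/`tumor_suppressor`) and
#'   `edge_sign` (`activating`/`inhibiting`).
#' @export
default_mapping_table <- function() {
  rows <- list(
    c("CD79B",   "BCR",    "oncogene",         "activating"),
    c("SYK",     "SYK",    "oncogene",         "activating"),
    c("BTK",     "BTK",    "oncogene",         "activating"),
    c("HRAS",    "RAF",    "oncogene",         "activating"),
    c("KRAS",    "RAF",    "oncogene",         "activating"),
    c("NRAS",    "RAF",    "oncogene",         "activating"),
    c("CARD11",  "CBM",    "oncogene",         "activating"),
    c("BCL10",   "CBM",    "oncogene",         "activating"),
    c("MALT1",   "CBM",    "oncogene",         "activating"),
    c("TNFAIP3", "IKKc",   "tumor_suppressor", "inhibiting"),
    c("TLR2",    "TRAF6",  "oncogene",         "activating"),
    c("MYD88",   "TRAF6",  "oncogene",         "activating"),
    c("REL",     "NFkB",   "oncogene",         "activating"),
    c("NFKBIE",  "NFkB",   "oncogene",         "inhibiting"),
    c("IRF4",    "IRF4",   "oncogene",         "activating"),
    c("STAT1",   "STAT",   "oncogene",         "activating"),
    c("STAT3",   "STAT",   "oncogene",         "activating"),
    c("STAT5",   "STAT",   "oncogene",         "activating"),
    c("STAT6",   "STAT",   "oncogene",         "activating"),
    c("PTEN",    "PI3K",   "tumor_suppressor", "inhibiting"),
    c("MEF2B",   "BCL6",   "oncogene",         "activating"),
    c("IRF8",    "BCL6",   "oncogene",         "activating"),
    c("CREBBP",  "BCL6",   "tumor_suppressor", "inhibiting"),
    c("EP300",   "BCL6",   "tumor_suppressor", "inhibiting"),
    c("EZH2",    "BLIMP1", "oncogene",         "inhibiting"),
    c("MYC",     "MYC",    "oncogene",         "activating"),
    c("BCL2",    "BCL2",   "oncogene",         "activating"),
    c("BCL2L1",  "BCL2",   "oncogene",         "activating"),
    c("MCL1",    "BCL2",   "oncogene",         "activating")
  )
  m <- do.call(rbind, rows)
  data.frame(gene = m[, 1], component = m[, 2], role = m[, 3],
             edge_sign = m[, 4], stringsAsFactors = FALSE)
}

validate_mapping <- function(rules, network = gc_network(), where = "mapping table") {
  req <- c("gene", "component", "role", "edge_sign")
  if (!is.data.frame(rules) || !all(req %in% names(rules)))
    stop(where, " must have columns gene, component, role, edge_sign",
         call. = FALSE)
  bad_line <- function(ok, what) {
    if (any(!ok))
      stop(where, ": ", what, " at line ",
           paste(which(!ok) + 1L, collapse = ", "),  # +1 for the header line
           call. = FALSE)
  }
  bad_line(rules$component %in% network$names, "unknown model component")
  bad_line(rules$role %in% c("oncogene", "tumor_suppressor"), "bad role")
  bad_line(rules$edge_sign %in% c("activating", "inhibiting"), "bad edge_sign")
  if (anyDuplicated(rules$gene))
    stop(where, ": duplicated gene(s): ",
         paste(unique(rules$gene[duplicated(rules$gene)]), collapse = ", "),
         call. = FALSE)
  rules
}

#' Read / write a gene-to-component mapping table
#'
#' Tab-separated with header `gene component role edge_sign`; validated
#' against the model with line-addressed errors.
#'
#' @param path File path.
#' @param network Network the components must belong to.
#' @return `load_mapping_table()`: the validated rules data frame.
#' @export
load_mapping_table <- function(path, network = gc_network()) {
  rules <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_mapping(rules, network, where = paste0("mapping table '", path, "'"))
}

#' @rdname load_mapping_table
#' @param rules Mapping rules data frame.
#' @export
write_mapping_table <- function(rules, path) {
  utils::write.table(rules, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_lesions <- function(lesions, where = "lesion table") {
  req <- c("patient_id", "gene", "alteration_class")
  if (!is.data.frame(lesions) || !all(req %in% names(lesions)))
    stop(where, " must have columns patient_id, gene, alteration_class",
         call. = FALSE)
  ok <- lesions$alteration_class %in% lesion_classes()
  if (any(!ok))
    stop(where, ": unknown alteration_class '",
         lesions$alteration_class[which(!ok)[1]], "' at line ",
         paste(which(!ok) + 1L, collapse = ", "), call. = FALSE)
  if (!"coo_label" %in% names(lesions))
    lesions$coo_label <- rep("unclassified", nrow(lesions))
  lesions
}

#' Read / write a per-patient lesion table
#'
#' Long-format tab-separated table with header
#' `patient_id gene alteration_class` and optional `coo_label`
#' (ABC/GCB/unclassified), one row per lesion, emulating a cBioPortal
#' Oncoprint export.
#'
#' @param path File path.
#' @return `read_lesion_table()`: validated data frame.
#' @export
read_lesion_table <- function(path) {
  lesions <- utils::read.delim(path, stringsAsFactors = FALSE,
                               colClasses = "character")
  validate_lesions(lesions, where = paste0("lesion table '", path, "'"))
}

#' @rdname read_lesion_table
#' @param lesions Lesion data frame.
#' @export
write_lesion_table <- function(lesions, path) {
  utils::write.table(lesions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep only lesions with a strong, mappable effect
#'
#' Retains non-synonymous mutations, structural variants and high-grade
#' copy-number gains/losses of genes present in the mapping table; drops
#' synonymous mutations, low-grade and neutral copy-number records, and genes
#' the model does not cover.
#'
#' @param lesions Lesion data frame (see [read_lesion_table()]).
#' @param rules Mapping rules (default [default_mapping_table()]).
#' @return The filtered lesion data frame.
#' @export
filter_lesions <- function(lesions, rules = default_mapping_table()) {
  lesions <- validate_lesions(lesions)
  keep <- lesions$alteration_class %in% strong_classes() &
    lesions$gene %in% rules$gene
  lesions[keep, , drop = FALSE]
}

#' Interpret one lesion as a component clamp
#'
#' Copy-number losses are loss of function (LOF), gains are gain of function
#' (GOF); mutations and structural variants follow the gene's role (GOF for
#' oncogenes, LOF for tumor suppressors). The direction is inverted when the
#' gene acts on its model component through an inhibiting edge (e.g. loss of
#' the IKK inhibitor A20 is a GOF of IKKc). LOF clamps the component to 0;
#' GOF clamps it to its maximal level, so GOF of a ternary component always
#' yields level 2.
#'
#' @param lesion One lesion (single-row data frame or list with `gene` and
#'   `alteration_class`).
#' @param rule The gene's mapping rule (single-row data frame or list).
#' @param network Network supplying component max levels.
#' @return List with `component`, `level` and `direction` (`"GOF"`/`"LOF"`).
#' @export
#' @examples
#' interpret_lesion(list(gene = "TNFAIP3",
#'                       alteration_class = "nonsynonymous_mutation"),
#'                  subset(default_mapping_table(), gene == "TNFAIP3"))
interpret_lesion <- function(lesion, rule, network = gc_network()) {
  cls <- as.character(lesion[["alteration_class"]])
  if (!cls %in% strong_classes())
    stop("lesion class '", cls, "' does not pass the strong-effect filter",
         call. = FALSE)
  if (is.null(rule) || !length(rule) ||
      (is.data.frame(rule) && nrow(rule) != 1L))
    stop("no mapping rule for gene '", lesion[["gene"]], "'", call. = FALSE)
  direction <- switch(cls,
    cn_high_gain = "GOF",
    cn_high_loss = "LOF",
    # mutations and structural variants: role decides
    if (identical(as.character(rule[["role"]]), "oncogene")) "GOF" else "LOF")
  if (identical(as.character(rule[["edge_sign"]]), "inhibiting"))
    direction <- if (direction == "GOF") "LOF" else "GOF"
  comp <- as.character(rule[["component"]])
  if (!comp %in% network$names)
    stop("mapping rule targets unknown component '", comp, "'", call. = FALSE)
  level <- if (direction == "GOF") unname(network$max_level[comp]) else 0L
  list(component = comp, level = level, direction = direction)
}

#' Convert one patient's genotype into a clamp set
#'
#' Filters the lesions, interprets each as a clamp via [interpret_lesion()],
#' and resolves them per component: duplicate same-direction clamps merge;
#' when one component receives both GOF and LOF, the LOF (level 0) is kept
#' and the conflict recorded.
#'
#' @param lesions Lesion rows of a single patient (or a table from which the
#'   patient is selected via `patient_id`).
#' @param rules Mapping rules.
#' @param network Target network.
#' @param patient_id Optional id used to subset `lesions` and label the
#'   result.
#' @return A `perturbation_set`: list with `patient_id`, `clamps` (named
#'   integer vector), `conflicts` (character) and `coo_label`.
#' @export
genotype_to_perturbations <- function(lesions, rules = default_mapping_table(),
                                      network = gc_network(), patient_id = NULL) {
  lesions <- validate_lesions(lesions)
  if (!is.null(patient_id)) lesions <- lesions[lesions$patient_id == patient_id, , drop = FALSE]
  pid <- if (!is.null(patient_id)) patient_id
         else if (nrow(lesions)) as.character(lesions$patient_id[1]) else NA_character_
  coo <- if (nrow(lesions)) as.character(lesions$coo_label[1]) else "unclassified"
  kept <- filter_lesions(lesions, rules)

  levels_by_comp <- list()
  for (i in seq_len(nrow(kept))) {
    rule <- rules[rules$gene == kept$gene[i], , drop = FALSE]
    cl <- interpret_lesion(kept[i, ], rule, network)
    levels_by_comp[[cl$component]] <- unique(c(levels_by_comp[[cl$component]], cl$level))
  }
  clamps <- integer(0)
  conflicts <- character(0)
  for (comp in names(levels_by_comp)) {
    lv <- levels_by_comp[[comp]]
    if (length(lv) > 1L) {
      conflicts <- c(conflicts,
                     paste0(comp, ": GOF/LOF conflict, LOF kept"))
      lv <- 0L  # loss of the protein is epistatic to activating lesions
    }
    clamps[comp] <- lv
  }
  clamps <- clamps[order(match(names(clamps), network$names))]
  structure(list(patient_id = pid, clamps = clamps, conflicts = conflicts,
                 coo_label = coo),
            class = "perturbation_set")
}

#' @export
print.perturbation_set <- function(x, ...) {
  cat("Perturbation set for patient ", x$patient_id, "\n", sep = "")
  if (length(x$clamps))
    cat("  clamps: ", paste0(names(x$clamps), "=", x$clamps, collapse = ", "), "\n", sep = "")
  else cat("  clamps: none\n")
  for (cf in x$conflicts) cat("  conflict: ", cf, "\n", sep = "")
  invisible(x)
}
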