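# Synthetic DLBCL cohorts: genotype tables with the statistical shape of
# published DLBCL data (BCL2 the most frequent lesion, 1-10 mapped lesions
# per patient, cell-of-origin-biased BCL2 alteration classes), plus the
# exact worked-example genotypes as fixtures. All frequencies are synthetic
# defaults, not estimates of the real cohort.

#' Specification of a synthetic cohort
#'
#' @param n_patients Number of patients.
#' @param gene_weights Named positive sampling weights per gene; defaults to
#'   weight 1 for every gene of the mapping table with BCL2 at 4, which makes
#'   BCL2 the most frequent lesion by construction.
#' @param lesion_range Integer bounds on mapped lesions per patient
#'   (default 1-10).
#' @param lesion_decay Geometric decay of the lesions-per-patient
#'   distribution within `lesion_range` (default 0.3; mean around 3).
#' @param coo_probs Cell-of-origin label distribution
#'   (ABC/GCB/unclassified).
#' @param noise_fraction Fraction of patients receiving one additional
#'   droppable record (synonymous/low-grade/unmapped) to exercise the lesion
#'   filter; default 0.
#' @param rules Mapping table defining the gene universe.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 164L,
                        gene_weights = NULL,
                        lesion_range = c(1L, 10L),
                        lesion_decay = 0.3,
                        coo_probs = c(ABC = 0.35, GCB = 0.50, unclassified = 0.15),
                        noise_fraction = 0,
                        rules = default_mapping_table()) {
  if (is.null(gene_weights)) {
    gene_weights <- stats::setNames(rep(1, nrow(rules)), rules$gene)
    gene_weights["BCL2"] <- 4
  }
  if (any(gene_weights <= 0)) stop("gene weights must be positive", call. = FALSE)
  bad <- setdiff(names(gene_weights), rules$gene)
  if (length(bad)) stop("weights for genes absent from the mapping table: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  lesion_range <- as.integer(lesion_range)
  if (length(lesion_range) != 2L || lesion_range[1] < 1L ||
      lesion_range[1] > lesion_range[2])
    stop("lesion_range must be c(min, max) with 1 <= min <= max", call. = FALSE)
  if (lesion_range[2] > length(gene_weights))
    stop("max lesions per patient exceeds the number of mappable genes",
         call. = FALSE)
  if (abs(sum(coo_probs) - 1) > 1e-8 || any(coo_probs < 0))
    stop("coo_probs must be a probability vector", call. = FALSE)
  if (noise_fraction < 0 || noise_fraction > 1)
    stop("noise_fraction must be in [0, 1]", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 gene_weights = gene_weights, lesion_range = lesion_range,
                 lesion_decay = lesion_decay, coo_probs = coo_probs,
                 noise_fraction = noise_fraction, rules = rules),
            class = "cohort_spec")
}

# alteration-class distribution for one gene given the COO label; BCL2 is
# amplification-biased in ABC and mutation/SV-biased in GCB
sample_class <- function(gene, coo) {
  if (gene == "BCL2") {
    switch(coo,
      ABC = sample(c("cn_high_gain", "nonsynonymous_mutation"), 1L,
                   prob = c(0.9, 0.1)),
      GCB = sample(c("nonsynonymous_mutation", "sv", "cn_high_gain"), 1L,
                   prob = c(0.65, 0.25, 0.10)),
      sample(c("nonsynonymous_mutation", "cn_high_gain", "sv"), 1L,
             prob = c(0.5, 0.3, 0.2)))
  } else {
    sample(c("nonsynonymous_mutation", "sv", "cn_high_gain", "cn_high_loss"),
           1L, prob = c(0.55, 0.10, 0.20, 0.15))
  }
}

#' Generate a synthetic lesion table
#'
#' Reproducible given the seed (byte-identical tables). Every patient
#' receives between `lesion_range[1]` and `lesion_range[2]` mapped lesions
#' in distinct genes; with `noise_fraction > 0`, some patients additionally
#' carry one record that [filter_lesions()] drops.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer RNG seed.
#' @return Lesion table data frame (`patient_id`, `gene`,
#'   `alteration_class`, `coo_label`).
#' @export
#' @examples
#' head(generate_cohort(cohort_spec(n_patients = 5), seed = 1))
generate_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  genes <- names(spec$gene_weights)
  kk <- spec$lesion_range[1]:spec$lesion_range[2]
  k_prob <- (1 - spec$lesion_decay)^(kk - kk[1])
  rows <- vector("list", spec$n_patients)
  for (i in seq_len(spec$n_patients)) {
    pid <- sprintf("P%04d", i)
    coo <- sample(names(spec$coo_probs), 1L, prob = spec$coo_probs)
    k <- if (length(kk) == 1L) kk else sample(kk, 1L, prob = k_prob)
    gs <- sample(genes, k, prob = spec$gene_weights)
    cls <- vapply(gs, sample_class, "", coo = coo)
    df <- data.frame(patient_id = pid, gene = gs, alteration_class = cls,
                     coo_label = coo, stringsAsFactors = FALSE)
    if (spec$noise_fraction > 0 && stats::runif(1) < spec$noise_fraction) {
      noise <- data.frame(
        patient_id = pid,
        gene = sample(c(genes, "TP53"), 1L),
        alteration_class = sample(c("synonymous_mutation", "cn_low_gain",
                                    "cn_neutral", "cn_low_loss"), 1L),
        coo_label = coo, stringsAsFactors = FALSE)
      if (noise$gene == "TP53")  # unmapped gene: any class gets dropped
        noise$alteration_class <- "nonsynonymous_mutation"
      df <- rbind(df, noise)
    }
    rows[[i]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Worked-example genotypes
#'
#' The nine patient genotypes discussed in detail in the study (models 131,
#' 73, 29, 47, 34, 60, 85, 27 and 92), recorded as lesion rows that map
#' through [default_mapping_table()] to the documented clamp sets.
#' Alteration classes not stated in the source narrative are recorded as
#' `sv` (both mutation and SV map identically under the role-based rule).
#'
#' @return Lesion table data frame with `patient_id` = model id.
#' @export
#' @examples
#' ftab <- fixture_patients()
#' genotype_to_perturbations(ftab, patient_id = "73")  # BCL2 = 1
fixture_patients <- function() {
  rows <- list(
    c("131", "CD79B",  "nonsynonymous_mutation"),
    c("73",  "MCL1",   "sv"),
    c("29",  "BCL2",   "sv"),
    c("29",  "STAT3",  "sv"),
    c("29",  "EZH2",   "sv"),
    c("47",  "TLR2",   "sv"),
    c("47",  "PTEN",   "sv"),
    c("34",  "CARD11", "sv"),
    c("34",  "MYC",    "cn_high_gain"),
    c("34",  "BCL2",   "cn_high_gain"),
    c("60",  "MEF2B",  "nonsynonymous_mutation"),
    c("60",  "TLR2",   "nonsynonymous_mutation"),
    c("85",  "EP300",  "sv"),
    c("85",  "BCL2",   "sv"),
    c("27",  "BCL2",   "sv"),
    c("27",  "MYC",    "sv"),
    c("27",  "EZH2",   "sv"),
    c("27",  "MEF2B",  "sv"),
    c("27",  "CREBBP", "sv"),
    c("27",  "PTEN",   "nonsynonymous_mutation"),
    c("92",  "NFKBIE", "cn_high_gain"),
    c("92",  "IRF4",   "sv")
  )
  m <- do.call(rbind, rows)
  data.frame(patient_id = m[, 1], gene = m[, 2], alteration_class = m[, 3],
             coo_label = "unclassified", stringsAsFactors = FALSE)
}
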