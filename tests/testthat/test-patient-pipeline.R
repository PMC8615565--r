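wt <- wild_type_profile()

test_that("patient models carry their clamps and empty genotypes stay wild type", {
  pm <- patient_model(c(BCL2 = 1), model_id = "73")
  fp <- enumerate_fixpoints(pm$network, c(BCR = 1, CD40 = 0, IL21_4 = 1))
  expect_true(all(fp[, "BCL2"] == 1L))
  pm0 <- patient_model(integer(0), model_id = "none")
  expect_identical(compare_to_wild_type(wt, attractor_profile(pm0))$changed_stage_count, 0L)
  expect_error(patient_model(c(NOPE = 1)), "unknown")
})

test_that("stages are lost exactly when an input clamp contradicts them", {
  pm <- patient_model(c(BCR = 1), model_id = "131")
  prof <- attractor_profile(pm)
  lost <- vapply(prof$stages, `[[`, TRUE, "lost")
  expect_identical(vapply(prof$stages, `[[`, "", "stage_name")[lost], "LZ1")
  expect_identical(sum(!lost), 4L)
  # property: over random input clamps, lost <=> clamp disagrees with stage input
  set.seed(303)
  for (i in 1:10) {
    comp <- sample(c("BCR", "CD40", "IL21_4"), 1)
    lv <- sample(0:1, 1)
    prof_i <- attractor_profile(patient_model(stats::setNames(lv, comp)))
    for (rec in prof_i$stages)
      expect_identical(rec$lost, unname(rec$inputs[comp] != lv))
  }
})

test_that("single ectopic perturbations change the published stage sets", {
  erk <- compare_to_wild_type(wt, attractor_profile(patient_model(c(ERK = 1))))
  expect_identical(erk$changed_stage_count, 1L)
  expect_identical(erk$changed_stages, "DZ")
  expect_identical(erk$deltas$DZ$aberrant_active, c("MYC", "BCL2"))
  expect_identical(erk$deltas$DZ$aberrant_inactive, "BCL6")

  myc <- compare_to_wild_type(wt, attractor_profile(patient_model(c(MYC = 1))))
  expect_identical(myc$changed_stage_count, 3L)
  expect_setequal(myc$changed_stages, c("LZ1", "DZ", "PC"))

  bcl2 <- compare_to_wild_type(wt, attractor_profile(patient_model(c(BCL2 = 1))))
  expect_identical(bcl2$changed_stage_count, 2L)
  expect_setequal(bcl2$changed_stages, c("LZ1", "DZ"))
})

test_that("comparing wild type with itself reports no change", {
  cmp <- compare_to_wild_type(wt, wt)
  expect_identical(cmp$changed_stage_count, 0L)
  expect_length(cmp$lost_stages, 0L)
})

test_that("oncogenicity flags fire on the defining situations", {
  expect_false(classify_oncogenic(wt)$oncogenic)

  r73 <- classify_oncogenic(attractor_profile(fixture_model("73")))
  expect_true(r73$lz1_loss)              # BCL2 survives without input
  expect_true(r73$abnormal_combination)  # BCL6+BCL2 in DZ
  expect_true(r73$oncogenic)

  r131 <- classify_oncogenic(attractor_profile(fixture_model("131")))
  expect_true(r131$lz1_loss)             # stage itself is lost
  expect_false(r131$abnormal_combination)

  r29 <- classify_oncogenic(attractor_profile(fixture_model("29")))
  expect_true(r29$pc_loss)               # PC attractor lacks BLIMP1
  expect_true(r29$wrong_stage)           # BCL6 in Pre-GC

  r92 <- classify_oncogenic(attractor_profile(fixture_model("92")))
  expect_false(r92$oncogenic)            # abnormal but no flagged combination
})

test_that("marker-gene clamps always perturb at least one wild-type stage", {
  rules <- default_mapping_table()
  marker_rules <- rules[rules$component %in% c("MYC", "BCL6", "BLIMP1", "BCL2"), ]
  for (i in seq_len(nrow(marker_rules))) {
    tab <- data.frame(patient_id = "X", gene = marker_rules$gene[i],
                      alteration_class = "sv", stringsAsFactors = FALSE)
    pm <- patient_model(genotype_to_perturbations(tab))
    cmp <- compare_to_wild_type(wt, attractor_profile(pm))
    expect_gt(cmp$changed_stage_count, 0L)
  }
})

test_that("the worked-example profiles match their published descriptions", {
  pats <- function(pid) {
    prof <- attractor_profile(fixture_model(pid))
    stats::setNames(vapply(prof$stages, function(r)
      if (r$lost) "lost" else paste(r$patterns, collapse = "/"), ""),
      vapply(prof$stages, `[[`, "", "stage_name"))
  }
  expect_identical(pats("73"),
    c(LZ1 = "BCL2", `Pre-GC` = "MYC+BCL2", DZ = "BCL6+BCL2",
      LZ2 = "MYC+BCL2", PC = "BLIMP1+BCL2"))
  p29 <- pats("29")
  expect_identical(unname(p29[c("Pre-GC", "DZ")]), rep("BCL6+BCL2", 2))
  expect_identical(unname(p29["LZ2"]), "MYC+BCL2")  # the only unchanged stage
  expect_false(grepl("BLIMP1", p29["PC"]))
  expect_identical(pats("47"),
    c(LZ1 = "MYC+BCL2", `Pre-GC` = "MYC+BCL2", DZ = "BLIMP1+BCL2",
      LZ2 = "MYC+BCL2", PC = "BLIMP1+BCL2"))
  p34 <- pats("34")
  expect_identical(unname(p34[c("LZ1", "DZ")]), rep("BCL6+MYC+BCL2", 2))
  expect_identical(unname(p34["PC"]), "BLIMP1+MYC+BCL2")
  expect_identical(unname(unique(pats("60"))), "BCL6")
  expect_identical(unname(unique(pats("85"))), "BCL6+BCL2")
  expect_identical(unname(unique(pats("27"))), "BCL6+MYC+BCL2")
  p92 <- pats("92")
  expect_false(any(grepl("MYC|BCL6", p92)))
  expect_identical(unname(p92[c("LZ1", "Pre-GC", "DZ")]),
                   c("none", "BCL2", "BLIMP1+BCL2"))
})

test_that("NF-kB classes follow the decision cascade", {
  expect_identical(classify_nfkb(fixture_model("131")), "unperturbed")
  expect_identical(classify_nfkb(fixture_model("73")), "unperturbed")
  expect_identical(classify_nfkb(fixture_model("29")), "unperturbed")
  expect_identical(classify_nfkb(fixture_model("47")), "level2")
  expect_identical(classify_nfkb(fixture_model("92")), "inactive")
  for (pid in c("60", "85", "27", "34"))
    expect_identical(classify_nfkb(fixture_model(pid)), "independent")
  # CBM-complex genotype without marker lesions: medium constitutive NF-kB
  expect_identical(classify_nfkb(patient_model(c(CBM = 1))), "level1")
  # direct NF-kB family amplification reaches the top level
  rel <- genotype_to_perturbations(
    data.frame(patient_id = "R", gene = "REL",
               alteration_class = "cn_high_gain", stringsAsFactors = FALSE))
  expect_identical(classify_nfkb(patient_model(rel)), "level2")
  # IKK-axis knockout counts as inactive
  expect_identical(classify_nfkb(patient_model(c(IKKc = 0))), "inactive")
})

test_that("the constitutive NF-kB diagnostic equals signal-free fixpoint enumeration", {
  set.seed(616)
  genos <- generate_cohort(cohort_spec(n_patients = 25), seed = 616)
  base <- gc_network()
  zero_inputs <- c(BCR = 0L, CD40 = 0L, IL21_4 = 0L)
  for (pid in unique(genos$patient_id)) {
    cl <- genotype_to_perturbations(genos, patient_id = pid)$clamps
    internal <- cl[setdiff(names(cl), c("BCR", "CD40", "IL21_4"))]
    net0 <- if (length(internal)) apply_clamps(base, internal) else base
    fp <- enumerate_fixpoints(net0, zero_inputs)
    by_enum <- if (nrow(fp)) max(fp[, "NFkB"]) else 0L
    expect_identical(gclogic:::constitutive_nfkb_level(base, cl), by_enum,
                     label = paste("model", pid))
  }
})

test_that("the cohort report has stable columns and a wild-type baseline", {
  tab <- rbind(fixture_patients(),
               data.frame(patient_id = "WTP", gene = "BCL2",
                          alteration_class = "cn_low_gain",
                          coo_label = "GCB", stringsAsFactors = FALSE))
  rep <- cohort_report(tab)
  expect_identical(names(rep),
    c("model_id", "coo_label", "LZ1", "PreGC", "DZ", "LZ2", "PC",
      "changed_stages", "conflicts", "abnormal_combination", "wrong_stage",
      "pc_loss", "lz1_loss", "oncogenic", "nfkb_class"))
  expect_identical(nrow(rep), 10L)
  # the patient whose only lesion is filtered out behaves as wild type
  wtrow <- rep[rep$model_id == "WTP", ]
  expect_false(wtrow$oncogenic)
  expect_identical(wtrow$nfkb_class, "unperturbed")
  expect_identical(wtrow$changed_stages, 0L)
  expect_identical(rep$LZ1[rep$model_id == "131"], "lost")
})
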