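# The germinal-center (GC) B-cell network: 19 components, three receptor
# inputs (BCR, CD40, IL21_4), Boolean signaling/marker nodes and three
# ternary nodes (IKKc, NFkB, IRF4) whose level-2 activity encodes the strong,
# CD40-driven mode of canonical NF-kB signaling. Multi-regulator rules follow
# the published logical functions; single-regulator rules are a documented
# reconstruction of the pathway wiring (see the methods vignette).

gc_model_lines <- c(
  "# Germinal-center B-cell logical model",
  "# inputs",
  "BCR : 1 : input",
  "CD40 : 1 : input",
  "IL21_4 : 1 : input",
  "# signaling",
  "SYK : 1 : 1 <- BCR",
  "BTK : 1 : 1 <- BCR",
  "PI3K : 1 : 1 <- SYK & BTK",
  "RAF : 1 : 1 <- BTK",
  "CBM : 1 : 1 <- BTK",
  "TRAF6 : 1 : 1 <- CD40",
  "STAT : 1 : 1 <- IL21_4",
  "IKKc : 2 : 1 <- CBM ; 2 <- TRAF6",
  "NFkB : 2 : 1 <- IKKc ; 2 <- IKKc:2",
  "IRF4 : 2 : 1 <- NFkB ; 2 <- NFkB:2",
  "ERK : 1 : 1 <- RAF & !STAT",
  "# marker genes",
  "MYC : 1 : 1 <- PI3K & NFkB & !BLIMP1 & !BCL6",
  "BCL6 : 1 : 1 <- IRF4 & !IRF4:2 & !(ERK | BLIMP1)",
  "BLIMP1 : 1 : 1 <- IRF4:2 & STAT & !BCL6",
  "AID : 1 : 1 <- NFkB & STAT & !BLIMP1",
  "BCL2 : 1 : 1 <- (PI3K | NFkB) & !BCL6"
)

#' The germinal-center B-cell logical network
#'
#' Builds the 19-component model of GC B-cell signaling and marker-gene
#' regulation: receptor inputs `BCR`, `CD40`, `IL21_4`; Boolean components
#' `SYK`, `BTK`, `PI3K`, `RAF`, `ERK`, `CBM`, `TRAF6`, `STAT`, `MYC`, `BCL6`,
#' `BLIMP1`, `AID`, `BCL2`; ternary components `IKKc`, `NFkB`, `IRF4`
#' (level 1 = low/transient, level 2 = high activity). The same definition
#' ships as a text file in `system.file("extdata", "gc_model.txt",
#' package = "gclogic")`.
#'
#' @return A `logical_network`.
#' @export
#' @examples
#' net <- gc_network()
#' summary(net)
gc_network <- function() {
  read_model(text = gc_model_lines)
}

# marker order used for pattern labels ("BCL6+MYC+BCL2" etc.)
gc_marker_order <- c("BCL6", "BLIMP1", "MYC", "BCL2")

#' The stage/input dictionary of the GC model
#'
#' The eight input combinations of (BCR, CD40, IL21_4), their stage ids
#' (`1 + 4*BCR + 2*CD40 + IL21_4`), stage names and physiological status.
#' Physiological stages: LZ1 (no signal), Pre-GC (BCR), DZ (BCR + IL21_4),
#' LZ2 (BCR + CD40), PC (all three). Combinations with T-cell help but no
#' antigen (BCR inactive) are non-physiological.
#'
#' @return Data frame: `stage_id`, `stage_name`, `BCR`, `CD40`, `IL21_4`,
#'   `physiological`.
#' @export
gc_stages <- function() {
  grid <- expand.grid(IL21_4 = 0:1, CD40 = 0:1, BCR = 0:1)[, c("BCR", "CD40", "IL21_4")]
  id <- 1L + 4L * grid$BCR + 2L * grid$CD40 + grid$IL21_4
  o <- order(id)
  grid <- grid[o, ]
  nm <- c("LZ1", "n.phys.2", "n.phys.3", "n.phys.4", "Pre-GC", "DZ", "LZ2", "PC")
  data.frame(stage_id = sort(id), stage_name = nm,
             BCR = grid$BCR, CD40 = grid$CD40, IL21_4 = grid$IL21_4,
             physiological = !mapply(classify_nonphysiological,
                                     grid$BCR, grid$CD40, grid$IL21_4),
             row.names = NULL, stringsAsFactors = FALSE)
}

physiological_stage_ids <- function() {
  st <- gc_stages()
  st$stage_id[st$physiological]
}

#' Is an input combination non-physiological?
#'
#' T-cell-derived signals (CD40 or IL21/4) without antigen engagement of the
#' BCR cannot occur in the germinal center, because T-cell help requires
#' prior antigen presentation by the B-cell.
#'
#' @param BCR,CD40,IL21_4 Input levels (0/1); alternatively pass a length-3
#'   vector as `BCR`.
#' @return Logical flag.
#' @export
#' @examples
#' classify_nonphysiological(0, 1, 0)  # TRUE
classify_nonphysiological <- function(BCR, CD40, IL21_4) {
  if (length(BCR) == 3L && missing(CD40)) {
    CD40 <- BCR[[2]]; IL21_4 <- BCR[[3]]; BCR <- BCR[[1]]
  }
  BCR == 0 && (CD40 == 1 || IL21_4 == 1)
}

#' Marker-gene pattern of a state
#'
#' Reads the activity (level >= 1) of the four stage markers BCL6, BLIMP1,
#' MYC and BCL2 that define GC stage identity. AID is computed alongside as
#' an auxiliary read-out (somatic-hypermutation competence) but excluded from
#' the pattern label and all pattern comparisons.
#'
#' @param state Named integer state vector over the GC components.
#' @return List with `active` (character vector of active markers in
#'   canonical order), `aid` (flag) and `label` (e.g. `"BCL6+BCL2"`,
#'   `"none"`).
#' @export
marker_pattern <- function(state) {
  missing <- setdiff(c(gc_marker_order, "AID"), names(state))
  if (length(missing))
    stop("state lacks marker component(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  act <- gc_marker_order[state[gc_marker_order] >= 1L]
  list(active = act,
       aid = unname(state["AID"] >= 1L),
       label = if (length(act)) paste(act, collapse = "+") else "none")
}

#' Wild-type attractor table of the GC model
#'
#' Computes the fixpoint for each of the eight input combinations of the
#' unperturbed model and attaches marker patterns and stage labels. The
#' wild-type model has exactly one fixpoint per input combination; any other
#' outcome aborts with an internal-consistency error.
#'
#' @param network The GC network (defaults to [gc_network()]); must be
#'   unclamped.
#' @return An `attractor_profile` over all eight stages.
#' @export
#' @examples
#' wt <- wild_type_profile()
#' wt
wild_type_profile <- function(network = gc_network()) {
  if (length(network$clamps))
    stop("wild_type_profile() expects the unperturbed network", call. = FALSE)
  prof <- attractor_profile(network, stages = 1:8)
  n_fp <- vapply(prof$stages, function(s) nrow(s$fixpoints), 0L)
  if (any(n_fp != 1L))
    stop("internal consistency failure: wild-type stage(s) without a unique fixpoint: ",
         paste(vapply(prof$stages[n_fp != 1L], `[[`, "", "stage_name"),
               collapse = ", "), call. = FALSE)
  prof$model_id <- "WT"
  prof
}
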