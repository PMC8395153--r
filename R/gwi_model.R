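# Curated male neuroendocrine-immune network and its stable-state catalogue.
#
# Nodes aggregate the HPA axis (CRH, ACTH, cortisol, glucocorticoid receptor
# in membrane-bound GR and internalized dimerized GRD form), the male HPG
# axis (GnRH, LH/FSH, testosterone), peripheral immune cells and cytokine
# groups (CK/MK aggregates: e.g. CK1 = IL-2/IFNg/TNFa/TNFb, MK6 = IL-6,
# MK2 = IL-10/IL-22), and a brain compartment (endothelial cells of the
# blood-brain barrier, microglia, pooled pro-inflammatory cytokines, IL-4,
# infiltrating T cells, IGF-1, VEGF). Stress and Toxin are external drives.
# Interactions across the blood-brain barrier are conditional: they are only
# allowed while the EndothelialCells node is -1 (a compromised barrier).
#
# The edge list is curated so that the six catalogued homeostatic regimes
# (gwi_states()) are fixed points of the update logic -- that is the
# documented acceptance test of the transcription -- with edge directions
# following the component biology (cortisol suppresses GnRH and NK activity
# and induces IL-10; IL-6 stimulates ACTH/cortisol and Th2; IL-2 expands
# CTL and Treg; Th17 and Treg wings antagonize; microglial activation is
# fed by peripheral IL-1-family signals only across a leaky barrier; ...).

gwi_node_table <- function() {
  txt <- c(
    "Stress external", "Toxin external",
    "CRH hpa", "ACTH hpa", "CORT hpa", "GR hpa", "GRD hpa",
    "GnRH hpg", "LHFSH hpg", "TEST hpg",
    "NK immune-cell", "CTL immune-cell", "Th1 immune-cell",
    "Th2 immune-cell", "Th17B immune-cell", "Th17_23 immune-cell",
    "Treg immune-cell", "DC immune-cell",
    "CK1 cytokine-group", "CK2 cytokine-group", "CK17 cytokine-group",
    "MK1 cytokine-group", "MK2 cytokine-group", "MK6 cytokine-group",
    "MK15 cytokine-group", "MK21 cytokine-group", "MK23 cytokine-group",
    "MK27 cytokine-group", "TGFb cytokine-group",
    "EndothelialCells brain", "Microglia brain", "ProInflam_b brain",
    "IL4_b brain", "Tcell_b brain", "IGF1 brain", "VEGF brain")
  parts <- strsplit(txt, " ", fixed = TRUE)
  data.frame(node = vapply(parts, `[`, "", 1L),
             role = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

gwi_edge_table <- function() {
  # "src -> tgt" activates, "src -| tgt" inhibits; "@BBB" marks an edge
  # gated on EndothelialCells == -1
  txt <- c(
    "Stress -> CRH",
    "CRH -> ACTH", "MK6 -> ACTH", "CK1 -> ACTH", "GR -| ACTH",
    "ACTH -> CORT", "MK6 -> CORT", "CK1 -> CORT",
    "GRD -> GR", "CORT -> GR",
    "GR -> GRD", "CORT -> GRD",
    "CORT -| GnRH", "Treg -| GnRH",
    "GnRH -> LHFSH",
    "LHFSH -> TEST",
    "CORT -| NK",
    "CORT -> MK2",
    "CK1 -> CTL", "MK2 -> CTL", "DC -> CTL", "CK2 -| CTL",
    "CTL -> CK1",
    "MK6 -> Th2", "MK2 -> Th2", "CK1 -| Th2", "NK -| Th2",
    "Th2 -> CK2", "Stress -> CK2",
    "MK2 -> Th17B", "Treg -| Th17B", "NK -| Th17B", "TEST -| Th17B",
    "Th17B -> Th17_23",
    "Th17B -> CK17", "Th17_23 -> CK17",
    "CK17 -> MK1",
    "Th17B -> MK6",
    "Th17B -> MK21", "ProInflam_b -| MK21 @BBB",
    "CK1 -> Treg", "CK17 -| Treg", "Stress -| Treg",
    "CK1 -> MK15", "CK2 -| MK15", "Treg -| MK15",
    "CK2 -| MK23",
    "CK2 -| MK27",
    "CK2 -| DC",
    "CK2 -> TGFb", "MK21 -| TGFb",
    "TGFb -> Th1",
    "CK2 -> EndothelialCells", "Tcell_b -> EndothelialCells",
    "Microglia -| EndothelialCells",
    "CTL -> Tcell_b", "Th2 -> Tcell_b", "Microglia -| Tcell_b",
    "Stress -> Microglia", "Toxin -> Microglia", "MK1 -> Microglia @BBB",
    "MK15 -> ProInflam_b", "IL4_b -| ProInflam_b",
    "CK2 -> IL4_b", "MK15 -> IL4_b", "Treg -| IL4_b", "Microglia -| IL4_b",
    "MK15 -> IGF1", "Tcell_b -| IGF1", "Microglia -| IGF1",
    "Microglia -> VEGF")
  gated <- grepl(" @BBB", txt, fixed = TRUE)
  txt <- sub(" @BBB", "", txt, fixed = TRUE)
  parts <- strsplit(txt, " ", fixed = TRUE)
  data.frame(
    source = vapply(parts, `[`, "", 1L),
    target = vapply(parts, `[`, "", 3L),
    mode = ifelse(vapply(parts, `[`, "", 2L) == "->", "activate", "inhibit"),
    gate_node = ifelse(gated, "EndothelialCells", NA_character_),
    gate_value = ifelse(gated, -1L, NA_integer_),
    stringsAsFactors = FALSE)
}

#' The packaged male neuroimmune network
#'
#' A curated ternary logical model of HPA-HPG-immune-brain regulation with
#' blood-brain-barrier conditional edges (active only while
#' `EndothelialCells` is -1). Its six fixed points are returned by
#' [gwi_states()].
#'
#' @return A [ternet_network] with 36 nodes.
#' @export
gwi_network <- function() {
  nd <- gwi_node_table()
  ternet_network(nd$node, gwi_edge_table(), roles = nd$role)
}

#' The six-state stable-state catalogue
#'
#' Named state vectors SS0..SS5, each a fixed point of [gwi_network()].
#' SS0 is nominal health (all zero). SS1 shows low ACTH with elevated
#' glucocorticoid receptor (GR, GRD). SS2-SS5 share elevated HPA activity
#' (cortisol, GR, GRD), depressed HPG activity (GnRH, LH/FSH, testosterone),
#' depressed NK activity and elevated MK2, and differ in which immune wing
#' dominates: SS2 a Th2/Th17 periphery with a quiescent brain, SS3 a
#' CTL/Treg periphery with brain inflammation behind an intact barrier,
#' SS4 a combined CTL + Th17 periphery, and SS5 the SS4 periphery with a
#' broken blood-brain barrier (EndothelialCells -1), activated microglia,
#' brain pro-inflammatory cytokines and VEGF.
#'
#' @return Integer matrix, 36 rows (nodes) x 6 columns (SS0..SS5).
#' @export
gwi_states <- function() {
  nodes <- gwi_node_table()$node
  m <- matrix(0L, nrow = length(nodes), ncol = 6,
              dimnames = list(nodes, paste0("SS", 0:5)))
  set_ <- function(col, vals) {
    m[names(vals), col] <<- as.integer(vals)
  }
  set_("SS1", c(ACTH = -1, GR = 1, GRD = 1))
  ill <- c(CORT = 1, GR = 1, GRD = 1, GnRH = -1, LHFSH = -1, TEST = -1,
           NK = -1, MK2 = 1)
  th17 <- c(Th17B = 1, Th17_23 = 1, CK17 = 1, MK1 = 1, MK6 = 1)
  set_("SS2", c(ill, th17, MK21 = 1, Th2 = 1, CK2 = 1,
                MK15 = -1, MK23 = -1, MK27 = -1, DC = -1, Treg = -1,
                EndothelialCells = 1, Tcell_b = 1, IL4_b = 1,
                ProInflam_b = -1, IGF1 = -1))
  set_("SS3", c(ill, CK1 = 1, CTL = 1, Treg = 1,
                EndothelialCells = 1, ProInflam_b = 1, Tcell_b = 1,
                IL4_b = -1, IGF1 = -1))
  set_("SS4", c(ill, th17, MK21 = 1, CK1 = 1, CTL = 1, MK15 = 1,
                TGFb = -1, Th1 = -1,
                EndothelialCells = 1, Tcell_b = 1, IL4_b = 1))
  set_("SS5", c(ill, th17, CK1 = 1, CTL = 1, MK15 = 1,
                EndothelialCells = -1, Microglia = 1, ProInflam_b = 1,
                VEGF = 1))
  m
}

#' Variable-to-node mapping of the blood cytokine panels
#'
#' Maps the 16/18-plex plasma analytes onto the model's cytokine-group
#' nodes (e.g. TNFa, TNFb, IFNg and IL-2 all report on CK1). TNF receptor
#' analytes present only in the 18-plex have no model node and are omitted.
#'
#' @return Named character vector: names are analyte labels, values node ids.
#' @export
blood_panel_map <- function() {
  c(TNFa = "CK1", TNFb = "CK1", IFNg = "CK1", IL2 = "CK1",
    IL4 = "CK2", IL5 = "CK2", IL13 = "CK2",
    IL17 = "CK17",
    IL1a = "MK1", IL1b = "MK1", IL8 = "MK1", IL12 = "MK1",
    IL10 = "MK2", IL6 = "MK6", IL15 = "MK15", IL23 = "MK23")
}

#' Node subsets visible to each measurement modality
#'
#' `"blood"` returns the cytokine-group nodes covered by the plasma panels;
#' `"blood+brain"` adds the brain nodes measured in the mouse frontal-cortex
#' panel (pooled pro-inflammatory cytokines and microglial activation
#' markers).
#'
#' @param modality `"blood"` or `"blood+brain"`.
#' @return Character vector of node ids.
#' @export
measured_nodes <- function(modality = c("blood", "blood+brain")) {
  modality <- match.arg(modality)
  blood <- unique(unname(blood_panel_map()))
  if (modality == "blood") blood
  else c(blood, "ProInflam_b", "Microglia")
}
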