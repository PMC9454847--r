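#' Marker and phenotype vocabularies
#'
#' `TME_MARKERS` lists the eight binary marker columns every cell record must
#' carry; `TME_PHENOTYPES` the six mutually exclusive lineage phenotypes;
#' `TME_GROUPS` the selectable cell groups (phenotypes plus the composite
#' `TCELL` = all CD3+ phenotypes, `IMMUNE` = T cells plus APCs, and `ALL`).
#'
#' @format Character vectors.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
TME_MARKERS <- c("CD3", "CD8", "FoxP3", "CD163", "PanCK", "PDL1", "GZMB", "Ki67")

#' @rdname vocabularies
#' @export
TME_PHENOTYPES <- c("TCELL_HELPER", "TCELL_CTL", "TCELL_TREG",
                    "APC", "EPITHELIAL", "OTHER")

#' @rdname vocabularies
#' @export
TME_GROUPS <- c(TME_PHENOTYPES, "TCELL", "IMMUNE", "ALL")
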