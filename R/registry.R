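# Canonical 62-feature registry.
#
# Group order: Gradient2D (12), Gradient3D (34), context-sensitive (4),
# CCS (12). Within groups: modality order flair, t1, t1c, t2; ascending cube
# size / radius / band. Gradient3D decomposes as 4 GM + 12 rMean + 12 rVar +
# 3 seqMean + 3 seqVar. This ordering is the column contract of every feature
# table and the deterministic tie-break order for mRMR.

CUBE_SIZES <- c(3L, 5L, 7L)
CS_MODALITIES <- c("flair", "t1")   # context features use Flair + T1 only

#' The canonical feature registry
#'
#' @return A data.frame with columns `name`, `group`
#'   (Gradient2D/Gradient3D/ContextSensitive/CCS) and `subset`
#'   (g2d/GM/rMean/rVar/seqMean/seqVar/cs/ccs), 62 rows in canonical order.
#' @export
feature_registry <- function() {
  rows <- list()
  add <- function(name, group, subset)
    rows[[length(rows) + 1L]] <<- data.frame(name = name, group = group,
                                             subset = subset)
  for (m in MODALITIES)
    for (pl in c("xy", "xz", "yz"))
      add(paste0("g2d_", m, "_", pl), "Gradient2D", "g2d")
  for (m in MODALITIES) add(paste0("GM_", m), "Gradient3D", "GM")
  for (m in MODALITIES)
    for (s in CUBE_SIZES) add(paste0("rMean_", m, "_", s), "Gradient3D", "rMean")
  for (m in MODALITIES)
    for (s in CUBE_SIZES) add(paste0("rVar_", m, "_", s), "Gradient3D", "rVar")
  for (s in CUBE_SIZES) add(paste0("seqMean_", s), "Gradient3D", "seqMean")
  for (s in CUBE_SIZES) add(paste0("seqVar_", s), "Gradient3D", "seqVar")
  for (m in CS_MODALITIES)
    for (r in c(10L, 20L)) add(paste0("cs_", m, "_r", r), "ContextSensitive", "cs")
  for (m in CS_MODALITIES)
    for (b in 1:6) add(paste0("ccs_", m, "_b", b), "CCS", "ccs")
  do.call(rbind, rows)
}

#' Feature names of the canonical registry
#'
#' @param group Optional group filter.
#' @return Character vector of feature names in canonical order.
#' @export
feature_names <- function(group = NULL) {
  reg <- feature_registry()
  if (!is.null(group)) reg <- reg[reg$group %in% group, ]
  reg$name
}
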