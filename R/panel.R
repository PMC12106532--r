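#' Default marker panel
#'
#' A 30-channel PBMC phenotyping panel covering the lineage, functional,
#' checkpoint and proliferation markers that appear in the subset labels of
#' the analysis (CD45, the major T/B/NK/myeloid lineage markers, chemokine
#' receptors, cytokines, checkpoint molecules and Ki67).  Intensities are on
#' a dimensionless raw counts-like scale; all transforms downstream are
#' asinh with a cofactor.
#'
#' The full antibody panel of a real acquisition is instrument-specific; this
#' panel is reconstructed from the markers named in subset phenotypes and is
#' approximate by design.
#'
#' @param markers optional character vector to restrict/extend the panel.
#' @return an object of class `marker_panel`: a list with `markers` (ordered
#'   names), `lineage_map` (named character: one of `"lineage"`,
#'   `"functional"`, `"checkpoint"`, `"proliferation"`), and
#'   `exclusive_pairs` (2-column matrix of mutually exclusive lineage marker
#'   pairs used by [flag_mixed()]).
#' @export
#' @examples
#' p <- default_marker_panel()
#' length(p$markers)
default_marker_panel <- function(markers = NULL) {
  lineage <- c("CD45", "CD3", "CD4", "CD8", "CD14", "CD15", "CD19", "CD56",
               "CD45RA", "HLADR", "TCRgd")
  functional <- c("CD25", "FoxP3", "CX3CR1", "CXCR3", "CCR4", "Tbet",
                  "GATA3", "IL17A", "IL4", "IL8", "TNFa", "IFNg", "GranzymeB")
  checkpoint <- c("CTLA4", "PD1", "TIGIT", "CD160", "CD244")
  proliferation <- "Ki67"
  all_markers <- c(lineage, functional, checkpoint, proliferation)
  if (!is.null(markers)) {
    all_markers <- unique(c(all_markers, markers))
  }
  if (anyDuplicated(all_markers)) stop("marker names must be unique")
  lmap <- c(
    setNames(rep("lineage", length(lineage)), lineage),
    setNames(rep("functional", length(functional)), functional),
    setNames(rep("checkpoint", length(checkpoint)), checkpoint),
    setNames("proliferation", proliferation)
  )
  extra <- setdiff(all_markers, names(lmap))
  if (length(extra)) lmap[extra] <- "functional"
  structure(
    list(
      markers = all_markers,
      lineage_map = lmap[all_markers],
      exclusive_pairs = rbind(
        c("CD3", "CD19"),
        c("CD3", "CD14"),
        c("CD14", "CD56")
      )
    ),
    class = "marker_panel"
  )
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("<marker_panel> ", length(x$markers), " markers\n", sep = "")
  cat(paste(x$markers, collapse = ", "), "\n")
  invisible(x)
}

# Expression level codes used in the archetype table.  Each level maps to a
# zero-inflated lognormal on the raw intensity scale: P(zero) = p0, otherwise
# lognormal with median `med` and log-sd `sdlog`.
.level_params <- data.frame(
  level = 0:4,
  p0    = c(0.92, 0.45, 0.12, 0.03, 0.01),
  med   = c(0.8, 8, 35, 140, 450),
  sdlog = c(0.90, 0.60, 0.50, 0.45, 0.40)
)

#' Default population archetypes
#'
#' Twenty cell-population archetypes: the eleven differentially abundant
#' subsets (four enriched in sepsis, seven depleted) plus nine fillers, one
#' of which is a tight doublet-like population co-expressing CD3 and CD19
#' that the mixed-cluster exclusion rule is meant to catch.  Each archetype
#' is a zero-inflated lognormal model per marker, parameterised through a
#' small set of expression levels (0 = negative ... 4 = very high) so that
#' populations are well separated after the asinh transform.
#'
#' @param panel a [default_marker_panel()] object.
#' @return list of `population_archetype` objects, each with `name`,
#'   `lineage`, `role` (one of `"enriched"`, `"depleted"`, `"filler"`,
#'   `"mixed"`), `p_zero`, `mean_raw` (lognormal median per marker),
#'   `sdlog`, and `dispersion` (scalar multiplier on `sdlog`).
#' @export
default_archetypes <- function(panel = default_marker_panel()) {
  mk <- panel$markers
  lv <- function(...) {
    spec <- c(...)
    out <- setNames(rep(0L, length(mk)), mk)
    out["CD45"] <- 3L
    out[names(spec)] <- as.integer(spec)
    out
  }
  def <- list(
    # -- enriched in sepsis -------------------------------------------------
    list("CD15+CD14+ monocyte", "myeloid", "enriched", 1,
         lv(CD14 = 3, CD15 = 3, HLADR = 3, IL8 = 2, TNFa = 2, CX3CR1 = 1)),
    list("CD45RA-IL17A+CD4+ T", "CD4 T", "enriched", 1,
         lv(CD3 = 3, CD4 = 3, IL17A = 3, CCR4 = 2, TNFa = 1)),
    list("CD45RA-CX3CR1+CTLA4+CD4+ T", "CD4 T", "enriched", 1,
         lv(CD3 = 3, CD4 = 3, CX3CR1 = 3, CTLA4 = 3, CXCR3 = 2)),
    list("Ki67+ B", "B", "enriched", 1,
         lv(CD19 = 3, HLADR = 3, Ki67 = 3)),
    # -- depleted in sepsis -------------------------------------------------
    list("FoxP3+CD25+CTLA4+ naive Treg", "CD4 T", "depleted", 1,
         lv(CD3 = 3, CD4 = 3, CD25 = 3, FoxP3 = 3, CTLA4 = 2, CD45RA = 3)),
    list("PD1+CTLA4+TIGIT+ em CD4", "CD4 T", "depleted", 1,
         lv(CD3 = 3, CD4 = 3, PD1 = 3, CTLA4 = 2, TIGIT = 3)),
    list("IL8+ naive CD8", "CD8 T", "depleted", 1,
         lv(CD3 = 3, CD8 = 3, CD45RA = 3, IL8 = 3)),
    list("IL8+ naive CD4", "CD4 T", "depleted", 1,
         lv(CD3 = 3, CD4 = 3, CD45RA = 3, IL8 = 3)),
    list("GATA3+CD56++ NK", "NK", "depleted", 1,
         lv(CD56 = 4, GATA3 = 3, GranzymeB = 2, Tbet = 1)),
    list("Temra CD4", "CD4 T", "depleted", 1,
         lv(CD3 = 3, CD4 = 3, CD45RA = 3, CX3CR1 = 2, GranzymeB = 2,
            Tbet = 2)),
    list("Tbet+CD244+ temra CD8", "CD8 T", "depleted", 1,
         lv(CD3 = 3, CD8 = 3, CD45RA = 3, Tbet = 3, CD244 = 3,
            GranzymeB = 3)),
    # -- fillers ------------------------------------------------------------
    list("Naive CD4", "CD4 T", "filler", 1,
         lv(CD3 = 3, CD4 = 3, CD45RA = 3)),
    list("Naive CD8", "CD8 T", "filler", 1,
         lv(CD3 = 3, CD8 = 3, CD45RA = 3, CXCR3 = 1)),
    list("Central memory CD4", "CD4 T", "filler", 1,
         lv(CD3 = 3, CD4 = 3, CCR4 = 1, CXCR3 = 1, TNFa = 1, IFNg = 1)),
    list("Naive B", "B", "filler", 1,
         lv(CD19 = 3, HLADR = 2, CD45RA = 2)),
    list("Classical monocyte", "myeloid", "filler", 1,
         lv(CD14 = 3, HLADR = 3, IL8 = 1)),
    list("CD56dim NK", "NK", "filler", 1,
         lv(CD56 = 2, GranzymeB = 3, Tbet = 2, CD160 = 2)),
    list("gdT", "gdT", "filler", 1,
         lv(CD3 = 3, TCRgd = 3, GranzymeB = 2, Tbet = 2, CXCR3 = 1)),
    list("Lin-HLADR+IL8+", "other", "filler", 1,
         lv(HLADR = 2, IL8 = 2)),
    # doublet-like mixed population: co-expresses CD3 and CD19; kept tight
    # (low dispersion) because a doublet is the superposition of two cells,
    # not a biological population with its own variability
    list("CD3+CD19+ doublet-like", "other", "mixed", 0.15,
         lv(CD3 = 3, CD4 = 3, CD19 = 3, HLADR = 3))
  )
  lapply(def, function(d) {
    levels <- d[[5]]
    pars <- .level_params[match(levels, .level_params$level), ]
    # a doublet is the superposition of two intact cells: its positive
    # lineage markers are present on every event, so no dropout is modelled
    if (d[[3]] == "mixed") pars$p0[levels >= 3] <- 0
    structure(
      list(
        name = d[[1]],
        lineage = d[[2]],
        role = d[[3]],
        dispersion = d[[4]],
        levels = levels,
        p_zero = setNames(pars$p0, mk),
        mean_raw = setNames(pars$med, mk),
        sdlog = setNames(pars$sdlog * d[[4]], mk)
      ),
      class = "population_archetype"
    )
  })
}

#' Expected asinh-transformed centroid of an archetype
#'
#' The expectation of the zero-inflated lognormal after `asinh(x / cofactor)`
#' is approximated by `(1 - p0) * asinh(median / cofactor)`; adequate for
#' separation checks and nearest-centroid oracles.
#'
#' @param archetype a `population_archetype`.
#' @param cofactor asinh cofactor (default 5).
#' @return named numeric vector over markers.
#' @export
archetype_centroid <- function(archetype, cofactor = 5) {
  (1 - archetype$p_zero) * asinh(archetype$mean_raw / cofactor)
}

#' @export
print.population_archetype <- function(x, ...) {
  pos <- names(x$levels)[x$levels >= 2]
  cat("<population_archetype> ", x$name, " [", x$lineage, ", ", x$role,
      "]\n  high markers: ", paste(pos, collapse = ", "), "\n", sep = "")
  invisible(x)
}
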