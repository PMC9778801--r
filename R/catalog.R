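# Parameter overrides for every catalogued curve variant, keyed by
# figure/panel/curve. The four families vary one binding or release
# constant pair at a time: fumarate on-rates (2A), fumarate off-rates
# (2B), succinate off-rates (2C), succinate on-rates (2D). The flux
# decompositions (figs 3-6) and ROS scans (fig 8) reuse these families;
# fig 9 titrates fumarate over the slow-succinate-release family.
.curve_overrides <- list(
  fig2A = list(`1` = list(k10 = 1,    k12 = 1),
               `2` = list(k10 = 1e-1, k12 = 1e-1),
               `3` = list(k10 = 1e-2, k12 = 1e-2),
               `4` = list(k10 = 1e-3, k12 = 1e-3),
               `5` = list(k10 = 1e-4, k12 = 1e-4)),
  fig2B = list(`1` = list(km10 = 50,   km12 = 50),
               `2` = list(km10 = 500,  km12 = 500),
               `3` = list(km10 = 5e3,  km12 = 5e3),
               `4` = list(km10 = 5e4,  km12 = 5e4)),
  fig2C = list(`1` = list(k14 = 10,   k16 = 10),
               `2` = list(k14 = 1,    k16 = 1),
               `3` = list(k14 = 1e-1, k16 = 1e-1),
               `4` = list(k14 = 1e-2, k16 = 1e-2),
               `5` = list(k14 = 1e-3, k16 = 1e-3)),
  fig2D = list(`1` = list(km14 = 0.04, km16 = 0.04),
               `2` = list(km14 = 40,   km16 = 40),
               `3` = list(km14 = 400,  km16 = 400),
               `4` = list(km14 = 4e3,  km16 = 4e3),
               `5` = list(km14 = 4e4,  km16 = 4e4)))

# figure/panel -> (family, curves) for the derived figures
.panel_map <- list(
  fig3 = list(family = "fig2C", panels = list(A = "1", B = "2",
                                              C = "3", D = "4")),
  fig4 = list(family = "fig2D", panels = list(A = "1", B = "2",
                                              C = "3", D = "4")),
  fig5 = list(family = "fig2A", panels = list(A = "1", B = "3",
                                              C = "4", D = "5")),
  fig6 = list(family = "fig2B", panels = list(A = "1", B = "2",
                                              C = "3", D = "4")),
  fig9 = list(family = "fig2C", panels = list(A = "1", B = "2",
                                              C = "3", D = "4")))

#' Catalog of figure-curve parameter variants
#'
#' Enumerates every captioned curve of the electrode-potential sweeps, flux
#' decompositions, ROS scans and fumarate titrations by figure, panel and
#' curve number, with the rate-constant overrides (relative to the basal
#' set) that define it and the experiment type that regenerates it.
#'
#' @return A data.frame with columns \code{figure}, \code{panel},
#'   \code{curve}, \code{label}, \code{experiment}, \code{overrides}
#'   (semicolon-separated \code{name=value} string; empty for basal).
#' @export
variant_catalog <- function() {
  rows <- list()
  add <- function(figure, panel, curve, overrides, experiment) {
    ov <- paste(names(overrides), vapply(overrides, format, ""),
                sep = "=", collapse = ";")
    label <- if (panel == "") paste0(figure, ".curve", curve)
             else paste0(figure, panel, ".curve", curve)
    rows[[length(rows) + 1L]] <<-
      data.frame(figure = figure, panel = panel, curve = curve,
                 label = label, experiment = experiment, overrides = ov,
                 stringsAsFactors = FALSE)
  }
  for (fam in c("fig2A", "fig2B", "fig2C", "fig2D")) {
    fig <- substr(fam, 1, 4); panel <- substr(fam, 5, 5)
    for (cv in names(.curve_overrides[[fam]]))
      add(fig, panel, cv, .curve_overrides[[fam]][[cv]], "sweep")
  }
  for (fg in c("fig3", "fig4", "fig5", "fig6")) {
    pm <- .panel_map[[fg]]
    for (pn in names(pm$panels))
      add(fg, pn, pm$panels[[pn]],
          .curve_overrides[[pm$family]][[pm$panels[[pn]]]], "sweep")
  }
  for (fam in c("fig2A", "fig2B", "fig2C", "fig2D")) {
    panel <- substr(fam, 5, 5)
    curves <- names(.curve_overrides[[fam]])
    if (fam == "fig2C") curves <- curves[1:4]   # Fig 8C shows curves 1-4
    for (cv in curves)
      add("fig8", panel, cv, .curve_overrides[[fam]][[cv]], "ros")
  }
  pm <- .panel_map$fig9
  for (pn in names(pm$panels))
    add("fig9", pn, pm$panels[[pn]],
        .curve_overrides[[pm$family]][[pm$panels[[pn]]]], "titrate")
  add("basal", "", "1", list(), "sweep")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the parameter set for a catalog entry
#'
#' @param label A label from [variant_catalog()], e.g. \code{"fig2C.curve4"}.
#' @param base Basal parameter set to start from.
#' @return A detailed-balance-consistent \code{sdh_params}.
#' @export
variant_parameters <- function(label, base = build_base_parameters()) {
  cat <- variant_catalog()
  hit <- cat[cat$label == label, ]
  if (nrow(hit) == 0L)
    stop("unknown variant label '", label, "'", call. = FALSE)
  ov <- .parse_overrides(hit$overrides[1L])
  make_variant(base, ov, label = label)
}

.parse_overrides <- function(s) {
  if (is.null(s) || !nzchar(s)) return(list())
  parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(p) as.numeric(p[2L])),
                  vapply(kv, `[`, "", 1L))
}
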