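#' Mouse-model classification rules
#'
#' Cell identity is read from lineage-reporter combinations, with Iba1 as
#' the master myeloid gate; phenotype markers (TMEM119, CD68, F4/80) are
#' never used for identity. Supported models and their reporter semantics:
#'
#' * `cx3cr1creer` - tdT labels the Cx3cr1 lineage (MG and BAM); in the
#'   parenchyma tdT+/Iba1+ is MG and tdT-/Iba1+ is MDM; at the brain
#'   borders (ventricle/CP, leptomeninges) tdT+/Iba1+ cells are BAM
#'   candidates, since border tdT+ cells lack the MG signature.
#' * `ms4a3` - tdT fate-maps monocyte-derived cells: tdT+/Iba1+ is MDM;
#'   tdT-/GFP+/Iba1+ is MG in the parenchyma and a BAM candidate at the
#'   borders.
#' * `sall1` - tdT labels only MG (splitCre); Iba1+/tdT- cells are MDM.
#' * `lyve1` - tdT labels leptomeningeal/perivascular BAM; Iba1+/tdT-
#'   cells are MDM.
#'
#' Iba1-negative non-reporter cells are `"other"`.
#'
#' @name mouse-models
NULL

tam_models <- c("cx3cr1creer", "ms4a3", "sall1", "lyve1")
tam_compartments <- c("parenchyma", "ventricle_cp", "leptomeninges")
tam_classes <- c("MG", "MDM", "BAM_candidate", "other")

#' Classify cells by reporter markers under a mouse-model rule
#'
#' @param cells data.frame with logical columns `tdT`, `GFP`, `Iba1` (plus
#'   any other columns, which are carried through).
#' @param model one of `"cx3cr1creer"`, `"ms4a3"`, `"sall1"`, `"lyve1"`.
#' @param compartment one of `"parenchyma"`, `"ventricle_cp"`,
#'   `"leptomeninges"`; resolves reporter-positive cells to MG vs. BAM
#'   candidate where the model requires it.
#' @return `cells` with a `class` column (one of `"MG"`, `"MDM"`,
#'   `"BAM_candidate"`, `"other"`); classification is a pure function of
#'   the marker columns.
#' @export
classify_cells <- function(cells, model,
                           compartment = c("parenchyma", "ventricle_cp",
                                           "leptomeninges")) {
  if (!model %in% tam_models)
    stop("unknown mouse model '", model, "'; supported: ",
         paste(tam_models, collapse = ", "))
  compartment <- match.arg(compartment)
  need <- c("tdT", "GFP", "Iba1")
  miss <- setdiff(need, names(cells))
  if (length(miss)) stop("cell table lacks column(s): ",
                         paste(miss, collapse = ", "))
  tdT <- as.logical(cells$tdT); GFP <- as.logical(cells$GFP)
  Iba1 <- as.logical(cells$Iba1)
  border <- compartment != "parenchyma"
  cls <- rep("other", nrow(cells))
  if (model == "cx3cr1creer") {
    cls[Iba1 & tdT] <- if (border) "BAM_candidate" else "MG"
    cls[Iba1 & !tdT] <- "MDM"
  } else if (model == "ms4a3") {
    cls[Iba1 & tdT] <- "MDM"
    cls[Iba1 & !tdT & GFP] <- if (border) "BAM_candidate" else "MG"
  } else if (model == "sall1") {
    cls[Iba1 & tdT] <- "MG"
    cls[Iba1 & !tdT] <- "MDM"
  } else { # lyve1
    cls[Iba1 & tdT] <- "BAM_candidate"
    cls[Iba1 & !tdT] <- "MDM"
  }
  cells$class <- cls
  cells
}

# Marker flags that make classify_cells() recover `class` under a model:
# the generator's inverse of the classification rule.
markers_for_class <- function(class, model, compartment) {
  border <- compartment != "parenchyma"
  tdT <- GFP <- FALSE
  Iba1 <- class != "other"
  if (model == "cx3cr1creer") {
    if (class == "MG") { if (border) stop("MG not resolvable at borders in cx3cr1creer"); tdT <- TRUE; GFP <- TRUE }
    if (class == "BAM_candidate") { if (!border) stop("BAM only at borders in cx3cr1creer"); tdT <- TRUE; GFP <- TRUE }
    if (class == "MDM") GFP <- TRUE
  } else if (model == "ms4a3") {
    if (class == "MDM") { tdT <- TRUE; GFP <- TRUE }
    if (class == "MG") { if (border) stop("MG not resolvable at borders in ms4a3"); GFP <- TRUE }
    if (class == "BAM_candidate") { if (!border) stop("BAM only at borders in ms4a3"); GFP <- TRUE }
  } else if (model == "sall1") {
    if (class == "MG") tdT <- TRUE
    if (class == "BAM_candidate") stop("BAM not labeled in sall1")
  } else { # lyve1
    if (class == "BAM_candidate") tdT <- TRUE
    if (class == "MG") stop("MG not labeled in lyve1")
  }
  c(tdT = tdT, GFP = GFP, Iba1 = Iba1)
}

#' Classify tumor contact of cells
#'
#' A cell inside a lesion or within `contact_tol_um` of a lesion border is
#' `"touching"`; a cell at >= `threshold_um` is `"non_touching"`; cells in
#' the open interval between the two are reported separately as
#' `"excluded_buffer"` rather than silently merged, since that interval is
#' assigned by neither printed rule.
#'
#' @param cells data.frame with numeric `x_px` (column) and `y_px` (row),
#'   0-based pixel coordinates.
#' @param labels integer matrix of lesion ids.
#' @param cal a [calibration()] object.
#' @param threshold_um non-touching distance (default 4 um).
#' @param contact_tol_um touching tolerance (default one pixel's linear
#'   size).
#' @return `cells` with `contact` and `dist_um` columns.
#' @export
contact_classify <- function(cells, labels, cal = calibration(),
                             threshold_um = 4, contact_tol_um = NULL) {
  if (is.null(contact_tol_um)) contact_tol_um <- cal$pixel_size_um
  stopifnot(threshold_um >= contact_tol_um)
  d <- distance_to_nearest_lesion(labels, cbind(cells$y_px, cells$x_px), cal)
  contact <- ifelse(d <= contact_tol_um, "touching",
                    ifelse(d >= threshold_um, "non_touching",
                           "excluded_buffer"))
  cells$dist_um <- d
  cells$contact <- contact
  cells
}
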