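# Marker panel registry and phenotype-label algebra.

.panel_registry <- list(
  immune_t   = c("CD4", "CD8", "FOXP3", "PD1"),
  macrophage = c("CD68", "CD163", "CD206", "PDL1"),
  myeloid    = c("CD8", "CD11b", "CD14", "CD15"),
  nkt        = c("CD8", "GranzB", "Granulysin", "CD16", "CD56")
)

#' Marker panels
#'
#' The four multiplexed-immunofluorescence panels supported out of the box:
#' immune T cells (CD4/CD8/FOXP3/PD-1), tumor-associated macrophages
#' (CD68/CD163/CD206/PD-L1), myeloid cells (CD8/CD11b/CD14/CD15) and NK/T
#' cells (CD8/GranzB/Granulysin/CD16/CD56). Any character vector of marker
#' names can be used in their place.
#'
#' @param name Panel name, one of `"immune_t"`, `"macrophage"`, `"myeloid"`,
#'   `"nkt"`.
#' @return Character vector of marker names in panel order.
#' @export
panel_markers <- function(name = "immune_t") {
  if (is.character(name) && length(name) > 1L) return(name)
  m <- .panel_registry[[name]]
  if (is.null(m)) stop("unknown panel: ", name)
  m
}

#' Parse a phenotype label into marker constraints
#'
#' A label such as `"CD8+FOXP3+"` requires CD8 and FOXP3 positivity and
#' leaves the remaining markers of the panel unconstrained; a trailing
#' `-` (e.g. `"CD4-CD8+FOXP3-"`) requires negativity.
#'
#' @param label Phenotype label string.
#' @param markers Panel marker vector.
#' @return Named integer vector over `markers`: 1 required positive,
#'   -1 required negative, 0 unconstrained.
#' @export
parse_phenotype <- function(label, markers = panel_markers()) {
  out <- stats::setNames(integer(length(markers)), markers)
  if (label %in% c("any", "all")) return(out)
  toks <- regmatches(label, gregexpr("[A-Za-z0-9]+[+-]", label))[[1L]]
  if (!length(toks) || nchar(paste(toks, collapse = "")) != nchar(label))
    stop("cannot parse phenotype label: ", label)
  for (t in toks) {
    mk <- sub("[+-]$", "", t)
    if (!mk %in% markers) stop("marker ", mk, " not in panel")
    out[mk] <- if (endsWith(t, "+")) 1L else -1L
  }
  out
}

#' Full phenotype signature of a positivity vector
#'
#' Deterministic label over the whole panel, e.g. `"CD4-CD8+FOXP3+PD1-"`;
#' signatures partition a cell map (each cell gets exactly one).
#'
#' @param pos Logical matrix (cells x markers) or vector.
#' @param markers Panel marker vector (order fixes the label).
#' @return Character vector of labels.
#' @export
phenotype_signature <- function(pos, markers = panel_markers()) {
  if (is.null(dim(pos))) pos <- matrix(pos, nrow = 1L)
  apply(pos, 1L, function(p)
    paste0(markers, ifelse(p, "+", "-"), collapse = ""))
}

#' Match cells against a phenotype label
#'
#' @param cells Cell data frame with `<marker>_pos` logical columns.
#' @param label Phenotype label (see [parse_phenotype()]).
#' @param markers Panel marker vector.
#' @return Logical vector over rows of `cells`.
#' @export
match_phenotype <- function(cells, label, markers = panel_markers()) {
  cons <- parse_phenotype(label, markers)
  keep <- rep(TRUE, nrow(cells))
  for (mk in markers[cons != 0L]) {
    col <- paste0(mk, "_pos")
    if (!col %in% names(cells)) stop("cell map lacks column ", col)
    keep <- keep & (cells[[col]] == (cons[mk] == 1L))
  }
  keep
}

#' Positivity vector implied by a phenotype label
#'
#' Unconstrained markers are taken negative (used when synthesizing cells
#' from a phenotype specification).
#' @keywords internal
phenotype_to_positivity <- function(label, markers = panel_markers()) {
  parse_phenotype(label, markers) == 1L
}
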