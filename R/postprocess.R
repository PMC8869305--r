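# Stress post-processing: von Mises fields, mid-substance volume averages,
# scenario comparisons, and VTU field export.

#' von Mises stress of a symmetric stress tensor
#'
#' \eqn{\sigma_{vM} = \sqrt{3/2\, s : s}} with `s` the stress deviator;
#' zero for hydrostatic states and invariant under rotations.
#'
#' @param sigma 3x3 symmetric stress tensor (Pa), or an
#'   `equilibrium_solution` (then the per-element field is returned).
#' @param tol asymmetry tolerance relative to the largest entry.
#' @return scalar (or per-element vector), Pa.
#' @export
#' @examples
#' von_mises(diag(c(2e6, 1e6, 0)))  # sqrt(3) MPa
von_mises <- function(sigma, tol = 1e-8) {
  if (inherits(sigma, "equilibrium_solution")) return(sigma$vm)
  sigma <- as.matrix(sigma)
  stopifnot(identical(dim(sigma), c(3L, 3L)))
  scale <- max(abs(sigma), 1e-300)
  if (max(abs(sigma - t(sigma))) > tol * scale)
    stop("asymmetric stress tensor")
  s <- sigma - diag(mean(diag(sigma)), 3)
  sqrt(1.5 * sum(s * s))
}

# Voigt layout used by the assembly: xx yy zz xy yz xz.
von_mises_voigt <- function(v) {
  v <- matrix(v, ncol = 6)
  p <- (v[, 1] + v[, 2] + v[, 3]) / 3
  sqrt(1.5 * ((v[, 1] - p)^2 + (v[, 2] - p)^2 + (v[, 3] - p)^2 +
                2 * (v[, 4]^2 + v[, 5]^2 + v[, 6]^2)))
}

#' Volume-weighted average of an element field over a set
#'
#' @param field per-element values.
#' @param elementSet integer indices of the contributing elements.
#' @param volumes per-element volumes (same indexing as `field`).
#' @param weighted volume-weighted mean (default) or plain element mean.
#' @return scalar average.
#' @export
average_over_set <- function(field, elementSet, volumes, weighted = TRUE) {
  if (!length(elementSet)) stop("empty element set")
  v <- volumes[elementSet]
  if (any(v <= 0)) stop("non-positive element volume in set")
  if (!weighted) return(mean(field[elementSet]))
  sum(field[elementSet] * v) / sum(v)
}

#' Percent change relative to a baseline
#'
#' `100 * (other - base) / base`; errors on a non-positive baseline.
#'
#' @param base baseline value (> 0).
#' @param other comparison value.
#' @return percent change.
#' @export
percent_change <- function(base, other) {
  if (any(base <= 0)) stop("percent_change needs a positive baseline")
  100 * (other - base) / base
}

#' Average mid-substance von Mises stress per ligament
#'
#' @param model the `knee_model` the solution was computed on.
#' @param sol an `equilibrium_solution`.
#' @param weighted volume-weighted (default) or plain element mean.
#' @return named numeric vector (Pa), one entry per ligament in the model.
#' @export
mid_substance_vm <- function(model, sol, weighted = TRUE) {
  vapply(model$ligs, function(lg)
    average_over_set(sol$vm, lg$mid_elems, sol$V0, weighted), numeric(1))
}

#' Export solution fields on a ligament to a VTU file
#'
#' Writes an ASCII XML UnstructuredGrid with the deformed node positions and
#' cell arrays `von_mises_Pa`, `G`, `lambda_max` (plus point displacements).
#' By default the mid-substance element band is exported; use
#' `set = "all"` for the whole ligament.
#'
#' @param model `knee_model`.
#' @param sol `equilibrium_solution`.
#' @param ligament ligament name.
#' @param path output file path.
#' @param set `"mid"` (default) or `"all"`.
#' @return the path, invisibly.
#' @export
export_contours <- function(model, sol, ligament, path, set = "mid") {
  lg <- model$ligs[[ligament]]
  if (is.null(lg)) stop("no such ligament in model: ", ligament)
  eset <- if (identical(set, "mid")) lg$mid_elems else lg$elems
  el <- model$elems[eset, , drop = FALSE]
  nset <- sort(unique(as.vector(el)))
  remap <- integer(nrow(model$nodes_ref)); remap[nset] <- seq_along(nset)
  cells <- matrix(remap[el], ncol = 4)
  write_vtu(path,
            points = sol$x[nset, , drop = FALSE],
            cells = cells,
            cell_data = list(von_mises_Pa = sol$vm[eset],
                             G = sol$G[eset],
                             lambda_max = sol$lambdaMax[eset]),
            point_data = list(displacement_m =
                                sol$x[nset, , drop = FALSE] -
                                model$nodes_mounted[nset, , drop = FALSE]),
            comment = paste("units: Pa, m;", model$axes))
  invisible(path)
}

#' Write / read a minimal ASCII VTU (XML UnstructuredGrid) file
#'
#' Tetrahedral cells only. `read_vtu` round-trips files written by
#' `write_vtu`.
#'
#' @param path file path.
#' @param points n x 3 coordinates.
#' @param cells m x 4 tetrahedral connectivity (1-based).
#' @param cell_data named list of per-cell numeric vectors.
#' @param point_data named list of per-point vectors or n x 3 matrices.
#' @param comment optional metadata string stored in the file.
#' @return `write_vtu`: the path, invisibly. `read_vtu`: list with
#'   `points`, `cells`, `cell_data`, `point_data`.
#' @export
write_vtu <- function(path, points, cells, cell_data = list(),
                      point_data = list(), comment = NULL) {
  n <- nrow(points); m <- nrow(cells)
  num <- function(x) paste(formatC(x, format = "g", digits = 17), collapse = " ")
  da <- function(name, x, ncomp = 1)
    sprintf('<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">%s</DataArray>',
            name, ncomp, num(if (is.matrix(x)) as.vector(t(x)) else x))
  lines <- c(
    '<?xml version="1.0"?>',
    if (!is.null(comment)) sprintf("<!-- %s -->", comment),
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    '<UnstructuredGrid>',
    sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m),
    "<Points>", da("Points", points, 3), "</Points>",
    "<Cells>",
    sprintf('<DataArray type="Int64" Name="connectivity" format="ascii">%s</DataArray>',
            paste(as.vector(t(cells)) - 1L, collapse = " ")),
    sprintf('<DataArray type="Int64" Name="offsets" format="ascii">%s</DataArray>',
            paste(4L * seq_len(m), collapse = " ")),
    sprintf('<DataArray type="UInt8" Name="types" format="ascii">%s</DataArray>',
            paste(rep(10L, m), collapse = " ")),
    "</Cells>",
    if (length(point_data)) c("<PointData>",
      unlist(lapply(names(point_data), function(nm)
        da(nm, point_data[[nm]], if (is.matrix(point_data[[nm]])) 3 else 1))),
      "</PointData>"),
    if (length(cell_data)) c("<CellData>",
      unlist(lapply(names(cell_data), function(nm) da(nm, cell_data[[nm]]))),
      "</CellData>"),
    "</Piece>", "</UnstructuredGrid>", "</VTKFile>")
  writeLines(unlist(lines), path)
  invisible(path)
}

#' @rdname write_vtu
#' @export
read_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  n <- as.integer(xml2::xml_attr(piece, "NumberOfPoints"))
  m <- as.integer(xml2::xml_attr(piece, "NumberOfCells"))
  getv <- function(node) as.numeric(strsplit(trimws(xml2::xml_text(node)), "\\s+")[[1]])
  pts <- matrix(getv(xml2::xml_find_first(piece, ".//Points/DataArray")),
                ncol = 3, byrow = TRUE)
  conn <- getv(xml2::xml_find_first(piece,
                 './/Cells/DataArray[@Name="connectivity"]'))
  cells <- matrix(as.integer(conn) + 1L, ncol = 4, byrow = TRUE)
  readset <- function(xpath) {
    nodes <- xml2::xml_find_all(piece, xpath)
    out <- list()
    for (nd in nodes) {
      nm <- xml2::xml_attr(nd, "Name")
      ncomp <- as.integer(xml2::xml_attr(nd, "NumberOfComponents"))
      v <- getv(nd)
      out[[nm]] <- if (!is.na(ncomp) && ncomp > 1)
        matrix(v, ncol = ncomp, byrow = TRUE) else v
    }
    out
  }
  list(points = pts, cells = cells,
       cell_data = readset(".//CellData/DataArray"),
       point_data = readset(".//PointData/DataArray"))
}
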