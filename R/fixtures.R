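# Packaged real-molecule fixtures: pyridine and 1-(1H-pyrrol-3-yl)ethanol.
#
# The NIC definition files transcribe the published natural internal
# coordinate sets for these molecules. The geometries are idealized,
# synthetic stand-ins (planar ring with standard bond lengths for pyridine;
# an assembled idealized conformer for the pyrrolyl ethanol): adequate for
# exercising B/G construction, symmetry blocking and CMA algebra, but not
# spectroscopic reference structures.

#' Load a packaged fixture molecule and its NIC set
#'
#' @param name \code{"pyridine"} (27 NICs with C2v irrep labels, synthetic
#'   idealized planar geometry) or \code{"pyrrolylethanol"} (45 NICs,
#'   synthetic idealized geometry; the five-ring combination constants are
#'   the standard Pulay ring values)
#' @return list with \code{mol} (a \code{\link{molecule}}), \code{nics}
#'   (a \code{\link{nic_set}}), \code{B}, \code{G}
#' @export
load_fixture <- function(name = c("pyridine", "pyrrolylethanol")) {
  name <- match.arg(name)
  xyz <- system.file("extdata", paste0(name, "_synthetic.xyz"),
                     package = "cmavib", mustWork = TRUE)
  nicf <- system.file("extdata", paste0(name, ".nic"),
                      package = "cmavib", mustWork = TRUE)
  mol <- read_xyz(xyz)
  nics <- read_nic_file(nicf, geometry = mol$coords)
  B <- build_b_matrix(nics, mol$coords)
  list(mol = mol, nics = nics, B = B,
       G = build_g_matrix(B, mol$masses))
}
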