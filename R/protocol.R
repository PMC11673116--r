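# File-driven protocol runner: validates a run configuration, executes a
# CMA protocol, and writes machine- and human-readable reports.

#' Build and validate a run configuration
#'
#' @param geometry path to an XYZ geometry
#' @param nic_file path to a NIC definition file
#' @param field_A,field_B paths to internal-basis Hessian files (Levels A, B)
#' @param field_C path to the Level-C Hessian (required for cma2)
#' @param protocol \code{"cma0"}, \code{"cma1"} or \code{"cma2"}
#' @param pairs off-diagonal pairs for cma1, as a two-column matrix or a
#'   string \code{"i,j;k,l"}
#' @param cutoff xi cutoff for cma2
#' @param xi_normalization \code{"diag"} or \code{"lambdaB"}
#' @param symmetry use irrep labels from the NIC file to enforce symmetry
#' @param out_dir report output directory (\code{NULL}: no files written)
#' @return validated list of class \code{"run_config"}
#' @export
run_config <- function(geometry, nic_file, field_A, field_B, field_C = NULL,
                       protocol = c("cma0", "cma1", "cma2"), pairs = NULL,
                       cutoff = Inf, xi_normalization = "diag",
                       symmetry = TRUE, out_dir = NULL) {
  protocol <- match.arg(protocol)
  for (p in c(geometry, nic_file, field_A, field_B, field_C)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  if (protocol == "cma2" && is.null(field_C)) {
    stop("cma2 requires a Level C force field (field_C)")
  }
  if (protocol == "cma1" && is.null(pairs)) {
    stop("cma1 requires hand-selected pairs")
  }
  if (is.character(pairs)) {
    pairs <- do.call(rbind, lapply(strsplit(pairs, ";")[[1]], function(p) {
      as.integer(strsplit(trimws(p), ",")[[1]])
    }))
  }
  structure(list(geometry = geometry, nic_file = nic_file,
                 field_A = field_A, field_B = field_B, field_C = field_C,
                 protocol = protocol, pairs = pairs, cutoff = cutoff,
                 xi_normalization = xi_normalization, symmetry = symmetry,
                 out_dir = out_dir),
            class = "run_config")
}

#' Execute a CMA protocol from a run configuration
#'
#' Reads all inputs, runs the requested protocol via \code{\link{cma_run}},
#' and (if \code{out_dir} is set) writes \code{report.json} with every
#' decision and matrix (15 significant digits), plus
#' \code{frequencies.csv} with reference/CMA frequencies and residuals
#' rounded to 0.01 cm^-1 for reading.
#'
#' @param config a \code{\link{run_config}}
#' @param verbose log decisions to stderr
#' @return the \code{\link{cma_run}} result, invisibly augmented with
#'   \code{report} (the report list)
#' @export
run_protocol <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  log_ <- function(...) if (verbose) message("[cmavib] ", ...)
  mol <- read_xyz(config$geometry)
  nics <- read_nic_file(config$nic_file, geometry = mol$coords)
  if (n_nics(nics) != n_vib(mol)) {
    stop(sprintf("NIC set size %d does not match vibrational DOF %d",
                 n_nics(nics), n_vib(mol)))
  }
  F_A <- read_hessian(config$field_A)
  F_B <- read_hessian(config$field_B)
  F_C <- if (!is.null(config$field_C)) read_hessian(config$field_C)
  B <- build_b_matrix(nics, mol$coords)
  rank <- check_nonredundancy(B, n_nics(nics))
  if (!rank$ok) {
    stop("NIC set is redundant or incomplete: rank ", rank$rank, " of ",
         rank$n_expected)
  }
  G <- build_g_matrix(B, mol$masses)
  irr <- if (config$symmetry) nics$irreps else NULL
  if (config$symmetry && is.null(nics$irreps)) {
    log_("no irrep labels in NIC file; symmetry not enforced")
  }
  log_("protocol ", config$protocol,
       if (config$protocol == "cma2") paste0(", cutoff ", config$cutoff),
       ", xi normalization ", config$xi_normalization)
  res <- cma_run(F_A, F_B, G, config$protocol, F_C = F_C,
                 pairs = config$pairs, cutoff = config$cutoff,
                 xi_normalization = config$xi_normalization,
                 irreps = irr, dof = n_vib(mol))
  if (nrow(res$selection)) {
    log_("selected pairs: ",
         paste(apply(res$selection, 1, paste, collapse = ","),
               collapse = "; "))
  }
  report <- list(
    protocol = config$protocol,
    cutoff = res$cutoff,
    xi_normalization = config$xi_normalization,
    eta_percent = res$eta,
    selected_pairs = res$selection,
    freq_ref = res$freq_ref,
    freq_cma = res$freq_cma,
    residuals = res$residuals,
    zpve_residual = res$zpve_residual,
    xi = if (!is.null(res$xi)) unclass(res$xi),
    F_CMA = res$F_CMA$matrix)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 15)
    utils::write.csv(
      data.frame(mode = seq_along(res$freq_ref),
                 irrep = res$irreps %||% NA,
                 freq_ref = round(res$freq_ref, 2),
                 freq_cma = round(res$freq_cma, 2),
                 residual = round(res$residuals, 2)),
      file.path(config$out_dir, "frequencies.csv"), row.names = FALSE)
    log_("reports written to ", config$out_dir)
  }
  res$report <- report
  invisible(res)
}

#' Direct GF frequencies for a geometry + NIC file + Hessian file
#'
#' The non-CMA workhorse: read the inputs, build B and G, solve GF.
#'
#' @param geometry XYZ path
#' @param nic_file NIC definition path
#' @param field internal-basis Hessian path
#' @return a \code{\link{normal_modes}}
#' @export
gf_frequencies_from_files <- function(geometry, nic_file, field) {
  mol <- read_xyz(geometry)
  nics <- read_nic_file(nic_file, geometry = mol$coords)
  B <- build_b_matrix(nics, mol$coords)
  G <- build_g_matrix(B, mol$masses)
  solve_gf(read_hessian(field), G, irreps = nics$irreps)
}
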