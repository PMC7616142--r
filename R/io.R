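# Result serialization: shape tables, solution CSV + JSON sidecar,
# branch tables.  All files are plain text; lengths are in units of the
# undeformed radius R and energies in units of C R^3.

#' Write / read a midsurface shape table
#'
#' CSV with header \code{s,r,z,psi,stretch_s,kappa_s,kappa_phi} (lengths
#' in units of R).  The round trip preserves values to full double
#' precision.
#'
#' @param shape a \code{midsurface_shape}.
#' @param path file path.
#' @return \code{write_shape} returns the path invisibly;
#'   \code{read_shape} returns a \code{midsurface_shape}.
#' @export
write_shape <- function(shape, path) {
  stopifnot(inherits(shape, "midsurface_shape"))
  d <- as.data.frame(shape)[, c("s", "r", "z", "psi", "stretch_s",
                                "kappa_s", "kappa_phi")]
  utils::write.csv(format(d, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_shape
#' @export
read_shape <- function(path) {
  d <- utils::read.csv(path)
  need <- c("s", "r", "z", "psi", "stretch_s", "kappa_s", "kappa_phi")
  if (!all(need %in% names(d)))
    stop("shape CSV must have columns: ", paste(need, collapse = ","))
  .new_midsurface(d$s, d$r, d$z, d$psi, d$stretch_s, d$kappa_s,
                  d$kappa_phi)
}

#' Write an equilibrium solution
#'
#' Writes the per-point shape and strain/energy tables as CSV and a JSON
#' sidecar with the scalar results (pole displacement, energy breakdown,
#' solver diagnostics, scenario echo and package version).  Output is
#' bit-identical across runs with identical inputs (the solver is
#' deterministic).
#'
#' @param solution a \code{shell_equilibrium}.
#' @param path output CSV path; the sidecar is written next to it with
#'   extension \code{.json}.
#' @param scenario optional \code{scenario_params} echoed into the
#'   sidecar.
#' @return invisibly, the sidecar path.
#' @export
write_solution <- function(solution, path, scenario = NULL) {
  stopifnot(inherits(solution, "shell_equilibrium"))
  sh <- as.data.frame(solution$shape)
  st <- as.data.frame(solution$strains)
  dens <- energy_density(solution$strains, model = solution$model)
  d <- data.frame(sh[, c("s", "r", "z", "psi", "stretch_s", "kappa_s",
                         "kappa_phi")],
                  st[, c("es", "ephi", "Ks", "Kphi", "eta")],
                  e_stretch = dens$stretch, e_couple = dens$couple,
                  e_bend = dens$bend, e_total = dens$total)
  utils::write.csv(format(d, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  side <- list(
    model = solution$model,
    d = solution$d,
    energy = as.list(solution$energy),
    diagnostics = solution$diagnostics,
    max_eta = max(abs(solution$strains$eta)),
    n_grid = nrow(sh),
    scenario = if (!is.null(scenario)) unclass(scenario) else NULL,
    package_version = as.character(utils::packageVersion("morphoshell")))
  sidecar <- sub("\\.csv$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(side, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(sidecar)
}

#' Write a continuation branch table
#'
#' CSV with columns \code{k,d,energy_total,max_eta,fold_flag} plus a
#' \code{segment} label, and a JSON sidecar carrying fold and jump
#' annotations.
#'
#' @param branch a \code{shell_branch}.
#' @param path output CSV path.
#' @return invisibly, the sidecar path.
#' @export
write_branch <- function(branch, path) {
  stopifnot(inherits(branch, "shell_branch"))
  utils::write.csv(as.data.frame(branch), path, row.names = FALSE)
  side <- list(model = attr(branch, "model"),
               folds = attr(branch, "folds"),
               jumps = attr(branch, "jumps"),
               truncated = attr(branch, "truncated"),
               k_eta_cap = attr(branch, "k_eta_cap"))
  sidecar <- sub("\\.csv$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(side, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(sidecar)
}
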