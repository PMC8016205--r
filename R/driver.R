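# End-to-end orchestration: reference -> (reduced space) -> partition ->
# Cholesky ERI -> MLCC -> excited states, with machine-readable reporting.

#' Run configuration
#'
#' Collects method and threshold settings; defaults follow standard
#' practice: SCF gradient 1e-8, Cholesky threshold 1e-3 (1e-4 when
#' MO-screened), ground-state residual |Omega| 1e-6, excited-state residual
#' 1e-4, occupied-Cholesky pivot threshold 1e-2, frozen core on.
#'
#' @param method one of `"ccs"`, `"cc2"`, `"ccsd"`, `"mlcc2"`, `"mlccsd"`
#' @param n_states number of excited states
#' @param scheme active-space scheme for multilevel methods: `"cnto"` or
#'   `"cholesky-pao"`
#' @param n_active_occ,n_active_virt active-space sizes (CNTO scheme);
#'   `n_active_virt = NULL` invokes the occupied/virtual ratio rule
#' @param active_atoms atom indices of the higher-level region
#'   (cholesky-pao scheme), or `NULL`
#' @param r_cc radius (Angstrom) defining the coupled cluster region around
#'   `center_atoms` for reduced-space runs, or `NULL` for full space
#' @param r_active radius defining the higher-level active region
#'   (cholesky-pao scheme)
#' @param center_atoms region centers for the radius selections
#' @param frozen_core logical
#' @param cd_tau Cholesky decomposition threshold
#' @param cd_screen MO-screen the Cholesky decomposition
#' @param scf_tol,gs_tol,es_tol SCF gradient / ground-state / excited-state
#'   thresholds
#' @param pivot_tol occupied-Cholesky pivot threshold
#' @param seed seed for the Davidson start vectors and any stochastic input
#' @return a `run_config`
#' @export
runConfig <- function(method = "cc2", n_states = 3, scheme = "cnto",
                      n_active_occ = NULL, n_active_virt = NULL,
                      active_atoms = NULL, r_cc = NULL, r_active = NULL,
                      center_atoms = 1L, frozen_core = TRUE,
                      cd_tau = NULL, cd_screen = NULL,
                      scf_tol = 1e-8, gs_tol = 1e-6, es_tol = 1e-4,
                      pivot_tol = 1e-2, seed = 1L) {
  method <- match.arg(method, c("ccs", "cc2", "ccsd", "mlcc2", "mlccsd"))
  scheme <- match.arg(scheme, c("cnto", "cholesky-pao"))
  if (is.null(cd_screen)) cd_screen <- !is.null(r_cc)
  if (is.null(cd_tau)) cd_tau <- if (cd_screen) 1e-4 else 1e-3
  structure(list(method = method, n_states = n_states, scheme = scheme,
                 n_active_occ = n_active_occ, n_active_virt = n_active_virt,
                 active_atoms = active_atoms, r_cc = r_cc,
                 r_active = r_active, center_atoms = center_atoms,
                 frozen_core = frozen_core, cd_tau = cd_tau,
                 cd_screen = cd_screen, scf_tol = scf_tol, gs_tol = gs_tol,
                 es_tol = es_tol, pivot_tol = pivot_tol,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Full MLCC workflow
#'
#' @param system a `molecular_system`
#' @param config a `run_config`
#' @param ints optional precomputed `ao_integral_set`
#' @return an `mlcc_report` list with reference, factorization, ground-state
#'   and excited-state results (energies in hartree, excitation energies
#'   additionally in eV)
#' @export
mlccRun <- function(system, config = runConfig(), ints = NULL) {
  if (is.null(ints)) ints <- computeAOIntegrals(system)
  ref <- runRHF(ints, system, gradient_tol = config$scf_tol)
  reduced <- !is.null(config$r_cc)
  if (reduced) {
    cc_atoms <- selectRegionByRadius(system, config$center_atoms,
                                     config$r_cc)
    ccref <- reduceReference(ref, ints, system, cc_atoms,
                             pivot_tol = config$pivot_tol,
                             freeze_core = config$frozen_core)
  } else {
    if (config$frozen_core) ref <- freezeCore(ref, ints, system)
    ccref <- ccReference(ref, ints)
  }
  cderi <- choleskyERI(ints, ccref$C, tau = config$cd_tau,
                       screen = config$cd_screen)
  # partition
  part <- switch(config$method,
    ccs = canonicalPartition(ccref, "none"),
    cc2 = ,
    ccsd = canonicalPartition(ccref, "all"),
    mlcc2 = ,
    mlccsd = {
      if (config$scheme == "cnto") {
        if (is.null(config$n_active_occ))
          stop("CNTO scheme requires n_active_occ")
        partitionCNTO(ccref, cderi, n_states = config$n_states,
                      n_o_a = config$n_active_occ,
                      n_v_a = config$n_active_virt, seed = config$seed)
      } else {
        atoms <- config$active_atoms
        if (is.null(atoms)) {
          if (is.null(config$r_active))
            stop("cholesky-pao scheme requires active_atoms or r_active")
          atoms <- selectRegionByRadius(system, config$center_atoms,
                                        config$r_active)
        }
        partitionLocalized(ccref, ints, atoms,
                           pivot_tol = config$pivot_tol)
      }
    })
  part <- semicanonicalize(ccref$F_ao_eff, part)
  U <- mo_rotation(ccref$C, part$C, ccref$S)
  cderi_p <- rotate_cholesky(cderi, U)
  cc <- cc_problem(part, ccref, cderi_p)
  gs <- if (config$method %in% c("ccs", "mlccsd", "ccsd"))
    mlccsdGroundState(cc, tol = config$gs_tol)
  else mlcc2GroundState(cc, tol = config$gs_tol)
  states <- if (config$n_states > 0) {
    if (config$method %in% c("ccs", "mlccsd", "ccsd"))
      mlccsdExcitedStates(cc, gs, config$n_states, tol = config$es_tol,
                          seed = config$seed)
    else mlcc2ExcitedStates(cc, gs, config$n_states, tol = config$es_tol,
                            seed = config$seed)
  } else list()
  omega <- vapply(states, function(s) s$omega, numeric(1))
  report <- list(
    package = "mlccx",
    method = config$method,
    scheme = if (config$method %in% c("mlcc2", "mlccsd")) config$scheme else
      "canonical",
    ev_per_hartree = HARTREE_TO_EV,
    n_atoms = length(system$atoms),
    n_ao = ints$n_ao,
    n_mo = cc$n,
    n_occ = cc$o, n_virt = cc$v,
    n_active_occ = length(cc$act_o), n_active_virt = length(cc$act_v),
    n_frozen_occ = if (reduced) ref$n_occ - cc$o else
      length(ref$frozen_occ),
    reduced_space = reduced,
    n_cholesky = cderi$n_J,
    cd_tau = config$cd_tau,
    cd_screening = if (config$cd_screen) "mo-screened" else "none",
    scf_energy = ref$energy,
    scf_iterations = ref$iterations,
    energy_corr = gs$energy_corr,
    energy_total = ref$energy + gs$energy_corr,
    gs_iterations = gs$iterations,
    gs_residual = tail(gs$residuals, 1),
    omega_hartree = omega,
    omega_ev = omega * HARTREE_TO_EV,
    es_residuals = vapply(states, function(s) s$residual, numeric(1)),
    thresholds = list(scf = config$scf_tol, cd = config$cd_tau,
                      gs = config$gs_tol, es = config$es_tol,
                      pivot = config$pivot_tol),
    seed = config$seed,
    converged = isTRUE(gs$converged))
  class(report) <- "mlcc_report"
  attr(report, "states") <- states
  report
}

#' @export
print.mlcc_report <- function(x, ...) {
  cat("MLCC run:", x$method, "(", x$scheme, ")\n")
  cat("  AOs:", x$n_ao, " MOs:", x$n_mo, " active occ/virt:",
      x$n_active_occ, "/", x$n_active_virt, " N_J:", x$n_cholesky, "\n")
  cat("  E(SCF)  =", format(x$scf_energy, digits = 12), "hartree\n")
  cat("  E(corr) =", format(x$energy_corr, digits = 10), "hartree\n")
  if (length(x$omega_hartree)) {
    cat("  omega [hartree]:", paste(format(x$omega_hartree, digits = 8),
                                    collapse = " "), "\n")
    cat("  omega [eV]     :", paste(format(x$omega_ev, digits = 8),
                                    collapse = " "), "\n")
  }
  invisible(x)
}

#' Write / read a machine-readable report
#'
#' @param report an `mlcc_report`
#' @param path output JSON path
#' @return `path`, invisibly (for `writeReport`); the report list (for
#'   `readReport`)
#' @export
writeReport <- function(report, path) {
  out <- unclass(report)
  attr(out, "states") <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(rep) <- "mlcc_report"
  rep
}

#' Convergence table across runs
#'
#' Tabulates excitation energies against active-space size, with deltas to
#' the run with the largest active space.
#'
#' @param reports list of `mlcc_report` objects (or JSON paths)
#' @return data frame with one row per run: active counts, omegas (hartree
#'   and eV) and deltas (eV) to the largest-active-space run
#' @export
compareRuns <- function(reports) {
  reports <- lapply(reports, function(r)
    if (is.character(r)) readReport(r) else r)
  fam <- c(ccs = "ccs", cc2 = "cc2", mlcc2 = "cc2",
           ccsd = "ccsd", mlccsd = "ccsd")
  key <- vapply(reports, function(r) paste(fam[[r$method]], r$n_ao, r$n_mo),
                character(1))
  if (length(unique(key)) > 1)
    stop("reports stem from different systems or methods: ",
         paste(unique(key), collapse = " | "))
  nst <- min(vapply(reports, function(r) length(r$omega_hartree), integer(1)))
  sizes <- vapply(reports, function(r) r$n_active_occ + r$n_active_virt,
                  numeric(1))
  ref_idx <- which.max(sizes)
  rows <- lapply(seq_along(reports), function(k) {
    r <- reports[[k]]
    om <- r$omega_hartree[seq_len(nst)]
    om_ref <- reports[[ref_idx]]$omega_hartree[seq_len(nst)]
    out <- data.frame(n_active_occ = r$n_active_occ,
                      n_active_virt = r$n_active_virt)
    for (s in seq_len(nst)) {
      out[[paste0("omega", s, "_hartree")]] <- om[s]
      out[[paste0("omega", s, "_ev")]] <- om[s] * r$ev_per_hartree
      out[[paste0("delta", s, "_ev")]] <- (om[s] - om_ref[s]) *
        r$ev_per_hartree
    }
    out
  })
  do.call(rbind, rows)
}
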