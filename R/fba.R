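# Flux balance analysis, used to audit models before vs. after
# standardization.
#
# FBA maximizes an objective flux subject to steady-state mass balance
# S v = 0 and flux bounds. Rationals are kept in the model; floats enter
# only inside the solver. The species rows of S are (metabolite,
# compartment) pairs, so transport reactions balance per compartment.

.DEFAULT_BOUND <- 1000

# direction-based default bounds
.default_bounds <- function(r) {
  switch(r$direction,
         reversible = c(-.DEFAULT_BOUND, .DEFAULT_BOUND),
         forward = c(0, .DEFAULT_BOUND),
         backward = c(-.DEFAULT_BOUND, 0))
}

# stoichiometric matrix: rows = species "(met)@(compartment)", cols = reactions
.stoich_matrix <- function(m) {
  rxn_ids <- names(m$reactions)
  species <- unique(unlist(lapply(m$reactions, function(r) {
    comp <- ifelse(is.na(r$participants$compartment), "",
                   r$participants$compartment)
    paste0(r$participants$met, "@", comp)
  })))
  S <- matrix(0, nrow = length(species), ncol = length(rxn_ids),
              dimnames = list(species, rxn_ids))
  for (r in m$reactions) {
    comp <- ifelse(is.na(r$participants$compartment), "",
                   r$participants$compartment)
    sp <- paste0(r$participants$met, "@", comp)
    S[cbind(sp, r$id)] <- S[cbind(sp, r$id)] + r$participants$coef
  }
  S
}

#' Maximize the objective flux of a model
#'
#' Solves `max c'v` subject to `S v = 0` and `lb <= v <= ub`. Bounds default
#' by direction: reversible (-1000, 1000), forward (0, 1000), backward
#' (-1000, 0); explicit entries in `m$bounds` override. The objective value
#' is deterministic; individual fluxes at a degenerate vertex need not be.
#'
#' @param m an [new_model()] object with `objective` set.
#' @param tol mass-balance verification tolerance (default `1e-6`).
#' @return an object of class `mrx_flux`: `status` (`"optimal"`,
#'   `"infeasible"`, `"unbounded"`), `objective_value` and `fluxes`.
#' @export
maximize_objective <- function(m, tol = 1e-6) {
  .check(!is.null(m$objective), "model %s has no objective reaction", m$name)
  S <- .stoich_matrix(m)
  rxn_ids <- colnames(S)
  lb <- ub <- numeric(length(rxn_ids))
  for (i in seq_along(rxn_ids)) {
    bd <- m$bounds[[rxn_ids[i]]] %||% .default_bounds(m$reactions[[rxn_ids[i]]])
    lb[i] <- bd[1]; ub[i] <- bd[2]
  }
  obj <- as.numeric(rxn_ids == m$objective)
  sol <- lp_solve(obj, S, rep(0, nrow(S)), lb, ub, maximize = TRUE)
  if (sol$status != "optimal")
    return(structure(list(status = sol$status,
                          objective_value = NA_real_,
                          fluxes = stats::setNames(rep(NA_real_, length(rxn_ids)),
                                                   rxn_ids)),
                     class = "mrx_flux"))
  v <- stats::setNames(sol$x, rxn_ids)
  resid <- max(abs(S %*% v))
  .check(resid <= tol, "mass-balance residual %.2e exceeds tolerance", resid)
  structure(list(status = "optimal", objective_value = sol$objective,
                 fluxes = v), class = "mrx_flux")
}

#' @export
print.mrx_flux <- function(x, ...) {
  cat(sprintf("<flux result> %s", x$status))
  if (identical(x$status, "optimal"))
    cat(sprintf(", objective %.6g", x$objective_value))
  cat("\n")
  invisible(x)
}

#' Relative objective change caused by standardization
#'
#' Runs FBA on a source model and its standardized (repaired) counterpart
#' and reports `(obj_std - obj_src) / obj_src`. A negative delta means the
#' repairs tightened the model - the typical signature of restored proton
#' costs in energy metabolism.
#'
#' @param source the published model.
#' @param standardized the repaired model (e.g. from [standardize_model()]).
#' @return an object of class `mrx_delta`: `delta` (`NA` with a flag when
#'   the source objective is 0), `objective_source`,
#'   `objective_standardized`, and `repairs` (ids of reactions that differ).
#' @export
standardization_delta <- function(source, standardized) {
  fs <- maximize_objective(source)
  ft <- maximize_objective(standardized)
  .check(identical(fs$status, "optimal") && identical(ft$status, "optimal"),
         "both models must be solvable (source: %s, standardized: %s)",
         fs$status, ft$status)
  changed <- names(source$reactions)[vapply(names(source$reactions), function(id) {
    r2 <- standardized$reactions[[id]]
    is.null(r2) || !isTRUE(all.equal(source$reactions[[id]]$participants,
                                     r2$participants, check.attributes = FALSE))
  }, logical(1))]
  if (fs$objective_value == 0) {
    return(structure(list(delta = NA_real_, undefined = TRUE,
                          objective_source = 0,
                          objective_standardized = ft$objective_value,
                          repairs = changed), class = "mrx_delta"))
  }
  structure(list(delta = (ft$objective_value - fs$objective_value) /
                   fs$objective_value,
                 undefined = FALSE,
                 objective_source = fs$objective_value,
                 objective_standardized = ft$objective_value,
                 repairs = changed), class = "mrx_delta")
}

#' @export
print.mrx_delta <- function(x, ...) {
  if (x$undefined) {
    cat("<standardization delta> undefined (source objective is 0)\n")
  } else {
    cat(sprintf("<standardization delta> %+.2f%% (%.6g -> %.6g), %d reaction(s) changed\n",
                100 * x$delta, x$objective_source, x$objective_standardized,
                length(x$repairs)))
  }
  invisible(x)
}
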