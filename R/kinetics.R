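## Smoothing width (uM) of the synthesis switch: the zeroth-order synthesis
## flux is r_syn * c_Null / (c_Null + .SYN_EPS), so it shuts off smoothly as
## the Null reservoir empties and the tagged Null -> U rate
## r_syn / (c_Null + .SYN_EPS) stays exactly flux-consistent with the bulk.
.SYN_EPS <- 1e-6

#' Analysis configuration for the kinetic integration
#'
#' @param t_eval analysis time in seconds (default 1e4: long enough for the
#'   native concentration to equilibrate in non-runaway regimes)
#' @param rtol,atol integrator relative/absolute tolerances
#' @param n_out number of logarithmically spaced output times; t_eval is
#'   always appended exactly
#' @return an object of class \code{AnalysisConfig}
#' @export
analysisConfig <- function(t_eval = 1e4, rtol = 1e-8, atol = 1e-10,
                           n_out = 60L) {
    stopifnot(t_eval > 0, rtol > 0, atol > 0, n_out >= 2)
    new("AnalysisConfig", t_eval = as.numeric(t_eval), rtol = rtol,
        atol = atol, n_out = as.integer(n_out))
}

#' @exportClass AnalysisConfig
setClass("AnalysisConfig",
         representation(t_eval = "numeric", rtol = "numeric",
                        atol = "numeric", n_out = "integer"))

## Compile the model into index structures consumed by the derivative and
## Jacobian functions: per-reaction rate values, up to three reactant indices
## (repeated index = squared concentration), net stoichiometry matrix.
.compileModel <- function(model) {
    SR <- model@stoichReact
    nr <- ncol(SR)
    ri <- matrix(NA_integer_, 3L, nr)
    for (r in seq_len(nr)) {
        nz <- which(SR[, r] > 0)
        ii <- rep(nz, SR[nz, r])
        ri[seq_along(ii), r] <- ii
    }
    list(k = unname(model@constants[model@reactions$constant]),
         ri = ri,
         syn = which(model@reactions$type == "synthesis"),
         null_idx = match("Null", model@species$name),
         S = model@stoichProd - model@stoichReact,
         ns = nrow(model@species), nr = nr)
}

.reactionRates <- function(cm, y) {
    v <- cm$k * y[cm$ri[1L, ]]
    m2 <- !is.na(cm$ri[2L, ])
    v[m2] <- v[m2] * y[cm$ri[2L, m2]]
    m3 <- !is.na(cm$ri[3L, ])
    v[m3] <- v[m3] * y[cm$ri[3L, m3]]
    if (length(cm$syn)) {
        cn <- y[cm$null_idx]
        v[cm$syn] <- cm$k[cm$syn] * cn / (cn + .SYN_EPS)
    }
    v
}

.derivFun <- function(cm) {
    force(cm)
    function(t, y, parms) {
        list(drop(cm$S %*% .reactionRates(cm, y)))
    }
}

.jacFun <- function(cm) {
    force(cm)
    function(t, y, parms) {
        DV <- matrix(0, cm$nr, cm$ns)
        r <- seq_len(cm$nr)
        i1 <- cm$ri[1L, ]; i2 <- cm$ri[2L, ]; i3 <- cm$ri[3L, ]
        f2 <- ifelse(is.na(i2), 1, y[i2])
        f3 <- ifelse(is.na(i3), 1, y[i3])
        DV[cbind(r, i1)] <- DV[cbind(r, i1)] + cm$k * f2 * f3
        m2 <- which(!is.na(i2))
        DV[cbind(m2, i2[m2])] <- DV[cbind(m2, i2[m2])] +
            cm$k[m2] * y[i1[m2]] * f3[m2]
        m3 <- which(!is.na(i3))
        DV[cbind(m3, i3[m3])] <- DV[cbind(m3, i3[m3])] +
            cm$k[m3] * y[i1[m3]] * f2[m3]
        if (length(cm$syn)) {
            cn <- y[cm$null_idx]
            DV[cm$syn, ] <- 0
            DV[cm$syn, cm$null_idx] <-
                cm$k[cm$syn] * .SYN_EPS / (cn + .SYN_EPS)^2
        }
        cm$S %*% DV
    }
}

#' Integrate the bulk mass-action system
#'
#' Starts from zero client protein (a full Null reservoir) and the configured
#' chaperone totals, and integrates the stiff mass-action ODEs to the
#' analysis time with \code{deSolve::lsoda}, using an analytic Jacobian
#' assembled from the mass-action structure (the rate constants span many
#' orders of magnitude, so a stiff-capable method is required).
#'
#' @param model a \linkS4class{NetworkModel}
#' @param config an \code{AnalysisConfig}
#' @param y0 optional named initial state overriding the model initials
#' @return a \linkS4class{KineticTrajectory} whose grid is logarithmically
#'   spaced and contains \code{t_eval} exactly
#' @export
propagateModel <- function(model, config = analysisConfig(), y0 = NULL) {
    stopifnot(is(model, "NetworkModel"), is(config, "AnalysisConfig"))
    cm <- .compileModel(model)
    if (is.null(y0)) {
        y0 <- initialState(model)
    } else {
        if (!identical(sort(names(y0)), sort(model@species$name)))
            stop("y0 must name every model species")
        y0 <- y0[model@species$name]
    }
    times <- unique(sort(c(0, 10^seq(log10(config@t_eval) - 6,
                                     log10(config@t_eval),
                                     length.out = config@n_out),
                           config@t_eval)))
    out <- deSolve::lsoda(y = y0, times = times, func = .derivFun(cm),
                          parms = NULL, jacfunc = .jacFun(cm),
                          jactype = "fullusr", rtol = config@rtol,
                          atol = config@atol, maxsteps = 50000)
    if (attr(out, "istate")[1] < 0)
        stop("integration failed at t = ", max(out[, 1]),
             " (istate ", attr(out, "istate")[1], ")")
    conc <- out[, -1, drop = FALSE]
    colnames(conc) <- model@species$name
    new("KineticTrajectory", times = out[, 1], conc = conc, model = model)
}

#' Extract the concentration snapshot at a time point
#'
#' @param traj a \linkS4class{KineticTrajectory}
#' @param t a time on the trajectory grid
#' @param clamp clamp tiny negative integrator output to zero (default TRUE)
#' @return a \linkS4class{ConcentrationState}
#' @export
stateAt <- function(traj, t, clamp = TRUE) {
    stopifnot(is(traj, "KineticTrajectory"))
    i <- which(abs(traj@times - t) <= 1e-9 * max(1, abs(t)))
    if (!length(i))
        stop("t = ", t, " is not on the trajectory grid")
    conc <- traj@conc[i[1], ]
    if (clamp) conc <- pmax(conc, 0)
    new("ConcentrationState", time = traj@times[i[1]], conc = conc)
}

#' Summarise client-protein pools in a concentration state
#'
#' Counts every client-containing species with its client stoichiometry
#' (aggregates of size n carry n monomers; double-occupancy GroEL complexes
#' carry two).  \code{native}, \code{unfolded} and \code{misfolded} are the
#' free conformer concentrations (complex-bound client is tracked by the
#' conformer totals); \code{aggregated_monomers} counts monomers in plain and
#' prepared aggregates; \code{insoluble_fraction} divides by the total client
#' outside the Null reservoir.
#'
#' @param state a \linkS4class{ConcentrationState}
#' @param model the \linkS4class{NetworkModel} the state belongs to
#' @return named numeric vector with native, native_total, unfolded,
#'   misfolded, aggregated_monomers, total_client and insoluble_fraction
#' @export
speciesSummary <- function(state, model) {
    stopifnot(is(state, "ConcentrationState"), is(model, "NetworkModel"))
    conc <- pmax(state@conc, 0)
    sp <- model@species
    agg <- grepl("^A[0-9]+\\*?$", sp$name)
    aggregated <- sum(sp$client_stoich[agg] * conc[sp$name[agg]])
    total <- sum(sp$client_stoich * conc[sp$name]) - conc[["Null"]]
    native_states <- intersect(c("N", "GrLd:{N}:GrS",
                                 .doubleLabel("N", "U"),
                                 .doubleLabel("N", "M")), sp$name)
    c(native = conc[["N"]],
      native_total = sum(conc[native_states]),
      unfolded = conc[["U"]],
      misfolded = conc[["M"]],
      aggregated_monomers = aggregated,
      total_client = total,
      insoluble_fraction = if (total > 0) aggregated / total else 0)
}

#' Check conservation-group drift along a trajectory
#'
#' @param traj a \linkS4class{KineticTrajectory}
#' @param model optional model (defaults to the trajectory's own)
#' @param tol relative drift threshold for flagging (default 1e-6)
#' @return data.frame with one row per conservation group: initial total,
#'   maximum absolute relative drift over the grid, and a flag
#' @export
conservationCheck <- function(traj, model = traj@model, tol = 1e-6) {
    stopifnot(is(traj, "KineticTrajectory"))
    res <- lapply(names(model@conservation), function(g) {
        w <- model@conservation[[g]]
        tot <- drop(traj@conc[, names(w), drop = FALSE] %*% w)
        t0 <- tot[1]
        drift <- if (t0 > 0) max(abs(tot - t0)) / t0 else max(abs(tot))
        data.frame(group = g, total = t0, max_rel_drift = drift,
                   flagged = drift > tol, stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
}

setMethod("show", "KineticTrajectory", function(object) {
    cat("KineticTrajectory:", length(object@times), "time points,",
        ncol(object@conc), "species, t in [",
        min(object@times), ",", max(object@times), "] s\n")
})

setMethod("show", "ConcentrationState", function(object) {
    cat("ConcentrationState at t =", object@time, "s;",
        sum(object@conc > 0), "nonzero species\n")
})
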