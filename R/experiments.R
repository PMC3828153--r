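#' Construct a sweep specification
#'
#' @param parameter one of "ribosome_activation_rate", "binding_factor",
#'   "capacity_factor"
#' @param grid numeric grid of values for the swept parameter
#' @param profiles list of \linkS4class{BiophysicalProfile} objects (or
#'   preset names)
#' @param options shared \linkS4class{ModelOptions}
#' @param overrides named rate-constant overrides applied to every run
#' @param transition "M->U" (misfolded-state correction) or "U->N" (folding)
#' @return a \linkS4class{SweepSpec}
#' @export
sweepSpec <- function(parameter, grid, profiles = list(proteinProfile()),
                      options = modelOptions(), overrides = numeric(),
                      transition = "M->U") {
    profiles <- lapply(profiles, function(p)
        if (is.character(p)) proteinProfile(p) else p)
    new("SweepSpec", parameter = parameter, grid = as.numeric(grid),
        profiles = profiles, options = options,
        overrides = as.numeric(overrides) |>
            setNames(names(overrides)), transition = transition)
}

.transitionEnds <- function(transition) {
    switch(transition,
           "M->U" = list(source = "M", target = "U"),
           "U->N" = list(source = "U", target = "N"),
           stop("unknown transition ", transition))
}

## One full pipeline run: build -> propagate -> freeze -> decompose.
.runPoint <- function(profile, options, overrides, config, transition) {
    model <- buildModel(profile, chaperoneLevels(), options, overrides)
    traj <- propagateModel(model, config)
    st <- stateAt(traj, config@t_eval)
    K <- extractRateMatrix(model, st)
    ends <- .transitionEnds(transition)
    d <- decomposeTransition(K, ends$source, ends$target, state = st)
    list(model = model, traj = traj, state = st, K = K, decomposition = d,
         summary = speciesSummary(st, model))
}

#' Run an experiment sweep
#'
#' For every (profile, grid value) pair: build the model, integrate to the
#' analysis time, freeze the tagged rate matrix, and decompose the requested
#' transition into entry channels with probabilities and bulk fluxes.  A
#' failed grid point is flagged (column \code{ok}) and the sweep continues.
#'
#' @param spec a \linkS4class{SweepSpec}
#' @param config an \code{AnalysisConfig}
#' @return data.frame, one row per channel per grid point, with the channel
#'   probability and flux, the species summary, and the free-chaperone
#'   concentrations needed by downstream fits
#' @export
runSweep <- function(spec, config = analysisConfig()) {
    stopifnot(is(spec, "SweepSpec"))
    rows <- list()
    for (profile in spec@profiles) {
        for (value in spec@grid) {
            opt <- spec@options
            slot(opt, spec@parameter) <- value
            res <- tryCatch(
                .runPoint(profile, opt, spec@overrides, config,
                          spec@transition),
                error = function(e) e)
            if (inherits(res, "error")) {
                rows[[length(rows) + 1L]] <- data.frame(
                    profile = profile@name, parameter = spec@parameter,
                    value = value, channel = NA_character_,
                    probability = NA_real_, flux = NA_real_,
                    reactive_probability = NA_real_, native = NA_real_,
                    unfolded = NA_real_, misfolded = NA_real_,
                    aggregated_monomers = NA_real_,
                    insoluble_fraction = NA_real_, free_GrLT = NA_real_,
                    ok = FALSE, error = conditionMessage(res),
                    stringsAsFactors = FALSE)
                next
            }
            d <- res$decomposition; s <- res$summary
            conc <- res$state@conc
            rows[[length(rows) + 1L]] <- data.frame(
                profile = profile@name, parameter = spec@parameter,
                value = value, channel = names(d@probabilities),
                probability = unname(d@probabilities),
                flux = unname(d@fluxes),
                reactive_probability = d@reactive_probability,
                native = s[["native"]], unfolded = s[["unfolded"]],
                misfolded = s[["misfolded"]],
                aggregated_monomers = s[["aggregated_monomers"]],
                insoluble_fraction = s[["insoluble_fraction"]],
                free_GrLT = if ("GrLT" %in% names(conc))
                    max(conc[["GrLT"]], 0) else 0,
                ok = TRUE, error = NA_character_,
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Compare a configuration with and without one chaperone system
#'
#' Runs the pipeline twice -- baseline and with the system's chaperone
#' concentrations knocked out to zero -- and reports species summaries,
#' per-channel fluxes of the misfolded-to-unfolded transition, and the
#' compensation deltas.
#'
#' @param profile a \linkS4class{BiophysicalProfile} or preset name
#' @param system system to knock out (e.g. "GroELS")
#' @param options a \linkS4class{ModelOptions}
#' @param config an \code{AnalysisConfig}
#' @param overrides named rate-constant overrides
#' @return list with \code{baseline}, \code{knockout} (each carrying
#'   summary, channel probabilities and fluxes) and \code{delta} (flux and
#'   summary differences, knockout minus baseline)
#' @export
knockoutCompare <- function(profile, system, options = modelOptions(),
                            config = analysisConfig(),
                            overrides = numeric()) {
    if (is.character(profile)) profile <- proteinProfile(profile)
    arm <- function(ko) {
        model <- buildModel(profile, chaperoneLevels(), options, overrides)
        if (ko) model <- knockoutSystem(model, system)
        traj <- propagateModel(model, config)
        st <- stateAt(traj, config@t_eval)
        K <- extractRateMatrix(model, st)
        d <- decomposeTransition(K, "M", "U", state = st)
        list(summary = speciesSummary(st, model),
             probabilities = d@probabilities, fluxes = d@fluxes)
    }
    base <- arm(FALSE); ko <- arm(TRUE)
    list(baseline = base, knockout = ko,
         delta = list(fluxes = ko$fluxes - base$fluxes,
                      summary = ko$summary - base$summary))
}

#' Classify a substrate by its GroELS capacity dependence
#'
#' A client whose native yield collapses when the GroELS capacity shrinks is
#' a class-III (chaperonin-obligate) substrate; one whose yield survives is
#' class I/II.  The decision compares the native yield at the smallest
#' capacity factor on the curve with the yield at full capacity (g = 1):
#' class III iff \code{yield(g_min) < theta * yield(1)}.
#'
#' @param yield_curve numeric vector of native concentrations named by the
#'   capacity factor values (must contain "1" and the minimum g)
#' @param theta classification threshold (default 0.5)
#' @return "III" or "I/II"
#' @export
classifySubstrate <- function(yield_curve, theta = 0.5) {
    g <- suppressWarnings(as.numeric(names(yield_curve)))
    if (anyNA(g)) stop("yield_curve must be named by capacity factors")
    if (!any(g == 1)) stop("yield_curve must contain the g = 1 endpoint")
    y1 <- yield_curve[[which(g == 1)]]
    ymin <- yield_curve[[which.min(g)]]
    if (ymin < theta * y1) "III" else "I/II"
}

#' Proportionality of GroELS-mediated folding to free GroEL
#'
#' From a U->N capacity sweep, fits the ratio of GroELS-mediated folding
#' flux to direct folding flux against the free ATP-bound GroEL
#' concentration, y = c * x through the origin.
#'
#' @param sweep result of \code{\link{runSweep}} on a "U->N" sweep
#' @return a \linkS4class{ProportionalityFit}
#' @export
groelFluxRatio <- function(sweep) {
    ok <- sweep[sweep$ok %in% TRUE, ]
    wide <- split(ok, interaction(ok$profile, ok$value, drop = TRUE))
    pts <- do.call(rbind, lapply(wide, function(g) {
        dir <- g$flux[g$channel == "direct"]
        gro <- g$flux[g$channel == "GroELS"]
        if (!length(dir) || !length(gro) || dir <= 0) return(NULL)
        data.frame(x = g$free_GrLT[1], y = gro / dir)
    }))
    if (is.null(pts) || !nrow(pts))
        stop("no sweep points with nonzero direct folding flux")
    fitProportionality(pts$x, pts$y)
}
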