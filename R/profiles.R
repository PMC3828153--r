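## Preset biophysical profiles of the four characteristic client proteins.
## Columns: k_mis (s^-1), K_mis, k_fold (s^-1), K_fold, k_ag (uM^-1 s^-1),
## c_crit (uM).
.PROFILES <- list(
    "Default"     = c(k_mis = 1,  K_mis = 100, k_fold = 0.1,  K_fold = 1e4,
                      k_ag = 0.1, c_crit = 0.1),
    "Slow Folder" = c(k_mis = 1,  K_mis = 0.1, k_fold = 0.02, K_fold = 3e5,
                      k_ag = 0.4, c_crit = 1),
    "Bad Folder"  = c(k_mis = 1,  K_mis = 200, k_fold = 0.1,  K_fold = 2e4,
                      k_ag = 1,   c_crit = 2),
    "Aggregator"  = c(k_mis = 10, K_mis = 40,  k_fold = 0.1,  K_fold = 2e4,
                      k_ag = 10,  c_crit = 0.01))

#' Create a client-protein biophysical profile
#'
#' Either name one of the four characteristic presets ("Default",
#' "Slow Folder", "Bad Folder", "Aggregator") or give all six parameters
#' explicitly.  Explicit parameters override the preset values.
#'
#' The presets span the characteristic behaviours of the proteostasis
#' network's clients: the Default protein is intermediate; the Slow Folder
#' folds two orders of magnitude more slowly into the most stable native
#' state and its misfolded state is transient (K_mis = 0.1), making it the
#' ideal chaperonin client; the Bad Folder has the most stable misfolded
#' state (K_mis = 200); the Aggregator misfolds ten times faster, aggregates
#' a hundred times faster and has the lowest critical aggregation
#' concentration.
#'
#' @param preset preset name, or NULL to use only the explicit parameters
#' @param k_mis,K_mis misfolding rate constant (s^-1) and equilibrium constant
#' @param k_fold,K_fold folding rate constant (s^-1) and equilibrium constant
#' @param k_ag aggregation rate constant (uM^-1 s^-1)
#' @param c_crit critical aggregation concentration (uM); the disaggregation
#'   rate is \code{k_ag * c_crit}
#' @return a \linkS4class{BiophysicalProfile}
#' @examples
#' proteinProfile("Default")
#' proteinProfile("Aggregator", k_ag = 5)
#' @export
proteinProfile <- function(preset = "Default", k_mis = NULL, K_mis = NULL,
                           k_fold = NULL, K_fold = NULL, k_ag = NULL,
                           c_crit = NULL) {
    if (!is.null(preset)) {
        if (!preset %in% names(.PROFILES))
            stop("unknown profile preset '", preset, "'; available: ",
                 paste(names(.PROFILES), collapse = ", "))
        p <- .PROFILES[[preset]]
        name <- preset
    } else {
        p <- setNames(rep(NA_real_, 6),
                      c("k_mis", "K_mis", "k_fold", "K_fold", "k_ag", "c_crit"))
        name <- "custom"
    }
    given <- list(k_mis = k_mis, K_mis = K_mis, k_fold = k_fold,
                  K_fold = K_fold, k_ag = k_ag, c_crit = c_crit)
    for (nm in names(given))
        if (!is.null(given[[nm]])) p[[nm]] <- as.numeric(given[[nm]])
    if (any(is.na(p)))
        stop("missing profile parameter(s): ",
             paste(names(p)[is.na(p)], collapse = ", "))
    new("BiophysicalProfile", name = name,
        k_mis = p[["k_mis"]], K_mis = p[["K_mis"]],
        k_fold = p[["k_fold"]], K_fold = p[["K_fold"]],
        k_ag = p[["k_ag"]], c_crit = p[["c_crit"]])
}

#' Names of the preset client-protein profiles
#' @return character vector of preset names
#' @export
profilePresets <- function() names(.PROFILES)

#' Derived reverse rate constants of a profile
#'
#' \code{k_unfold = k_fold / K_fold}, \code{k_unmis = k_mis / K_mis},
#' \code{k_dis = k_ag * c_crit}.
#'
#' @param profile a \linkS4class{BiophysicalProfile}
#' @return named numeric vector with k_unfold, k_unmis (s^-1) and k_dis
#'   (the per-event disaggregation rate, s^-1)
#' @export
derivedRates <- function(profile) {
    stopifnot(is(profile, "BiophysicalProfile"))
    c(k_unfold = profile@k_fold / profile@K_fold,
      k_unmis = profile@k_mis / profile@K_mis,
      k_dis = profile@k_ag * profile@c_crit)
}

#' Total chaperone concentrations
#'
#' Defaults are the standard cellular totals (uM): Ribosomes 20, Trigger
#' factor 20, DnaK 30, DnaJ 1 (dimer), GrpE 15, GroEL 42, GroES 35, Lon 0.3,
#' ClpB 1.8.
#'
#' @param ... named totals to override, e.g. \code{chaperoneLevels(GroEL = 0)}
#' @return a \linkS4class{ChaperoneLevels}
#' @export
chaperoneLevels <- function(...) {
    lv <- c(Rib = 20, TF = 20, DnaK = 30, DnaJ = 1, GrpE = 15,
            GroEL = 42, GroES = 35, Lon = 0.3, ClpB = 1.8)
    over <- list(...)
    if (length(over)) {
        bad <- setdiff(names(over), names(lv))
        if (length(bad) || is.null(names(over)) || any(names(over) == ""))
            stop("unknown chaperone(s): ", paste(bad, collapse = ", "))
        lv[names(over)] <- vapply(over, as.numeric, numeric(1))
    }
    new("ChaperoneLevels", levels = lv)
}

#' Structural model options
#'
#' @param ribosome_activation_rate synthesis control (s^-1); bulk synthesis
#'   flux is this rate times the ribosome total.  Default 1e-4.
#' @param n_max largest explicit aggregate size (default 20); the reaction
#'   growing an aggregate beyond n_max is omitted (reflecting boundary)
#' @param binding_factor binding factor lambda (default 1): GroEL on-rates
#'   multiplied, DnaK on-rates divided, by lambda
#' @param capacity_factor multiplier on total GroEL and GroES (default 1)
#' @param enabled_systems character subset of \code{c("KJE", "GroELS",
#'   "B+KJE", "TriggerFactor", "Degradation")}; all enabled by default
#' @param double_occupancy allow two-client GroEL complexes (default TRUE)
#' @param null_reservoir initial Null concentration in uM (default 1000);
#'   sized so the reservoir never empties on the shipped sweeps
#' @return a \linkS4class{ModelOptions}
#' @export
modelOptions <- function(ribosome_activation_rate = 1e-4,
                         n_max = 20L,
                         binding_factor = 1,
                         capacity_factor = 1,
                         enabled_systems = .SYSTEMS,
                         double_occupancy = TRUE,
                         null_reservoir = 1000) {
    new("ModelOptions",
        ribosome_activation_rate = as.numeric(ribosome_activation_rate),
        n_max = as.integer(n_max),
        binding_factor = as.numeric(binding_factor),
        capacity_factor = as.numeric(capacity_factor),
        enabled_systems = as.character(enabled_systems),
        double_occupancy = isTRUE(double_occupancy),
        null_reservoir = as.numeric(null_reservoir))
}

#' @describeIn chaperoneLevels accessor for the named totals
#' @param x a ChaperoneLevels object
#' @export
levelsVector <- function(x) {
    stopifnot(is(x, "ChaperoneLevels"))
    x@levels
}

setMethod("show", "BiophysicalProfile", function(object) {
    cat("BiophysicalProfile '", object@name, "'\n", sep = "")
    d <- derivedRates(object)
    cat(sprintf("  k_mis = %g /s, K_mis = %g (k_unmis = %g /s)\n",
                object@k_mis, object@K_mis, d[["k_unmis"]]))
    cat(sprintf("  k_fold = %g /s, K_fold = %g (k_unfold = %g /s)\n",
                object@k_fold, object@K_fold, d[["k_unfold"]]))
    cat(sprintf("  k_ag = %g /uM/s, c_crit = %g uM (k_dis = %g /s)\n",
                object@k_ag, object@c_crit, d[["k_dis"]]))
})

setMethod("show", "ChaperoneLevels", function(object) {
    cat("ChaperoneLevels (uM):\n")
    print(object@levels)
})

setMethod("show", "ModelOptions", function(object) {
    cat("ModelOptions:\n")
    cat(sprintf("  ribosome_activation_rate = %g /s, n_max = %d\n",
                object@ribosome_activation_rate, object@n_max))
    cat(sprintf("  binding_factor = %g, capacity_factor = %g\n",
                object@binding_factor, object@capacity_factor))
    cat("  enabled:", paste(object@enabled_systems, collapse = ", "), "\n")
    cat("  double_occupancy:", object@double_occupancy, "\n")
})
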