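#' @import methods
#' @importFrom stats rexp runif setNames
NULL

## Chaperone system identifiers used throughout the package.
.SYSTEMS <- c("KJE", "GroELS", "B+KJE", "TriggerFactor", "Degradation")

## Chaperone species carrying a total concentration (Table-2 style levels).
.CHAPERONES <- c("Rib", "TF", "DnaK", "DnaJ", "GrpE", "GroEL", "GroES",
                 "Lon", "ClpB")

#' Biophysical profile of a client protein
#'
#' Six parameters characterise the intrinsic folding behaviour of the client:
#' the misfolding rate constant \code{k_mis} (s^-1, U -> M) and equilibrium
#' constant \code{K_mis} (dimensionless), the folding rate constant
#' \code{k_fold} (s^-1, U -> N) and equilibrium constant \code{K_fold}
#' (dimensionless), the aggregation rate constant \code{k_ag} (uM^-1 s^-1) and
#' the critical aggregation concentration \code{c_crit} (uM).  Reverse rates
#' are derived: \code{k_unfold = k_fold / K_fold},
#' \code{k_unmis = k_mis / K_mis}, and the disaggregation rate
#' \code{k_dis = k_ag * c_crit}.
#'
#' @slot name profile name (informative only)
#' @slot k_mis,K_mis misfolding rate (s^-1) and equilibrium constant
#' @slot k_fold,K_fold folding rate (s^-1) and equilibrium constant
#' @slot k_ag aggregation rate constant (uM^-1 s^-1)
#' @slot c_crit critical aggregation concentration (uM)
#' @exportClass BiophysicalProfile
setClass("BiophysicalProfile",
         representation(name = "character",
                        k_mis = "numeric", K_mis = "numeric",
                        k_fold = "numeric", K_fold = "numeric",
                        k_ag = "numeric", c_crit = "numeric"))

setValidity("BiophysicalProfile", function(object) {
    vals <- c(k_mis = object@k_mis, K_mis = object@K_mis,
              k_fold = object@k_fold, K_fold = object@K_fold,
              k_ag = object@k_ag, c_crit = object@c_crit)
    if (length(vals) != 6L || any(!is.finite(vals)))
        return("all six profile parameters must be finite scalars")
    if (any(vals <= 0))
        return(paste0("profile parameters must be strictly positive: ",
                      paste(names(vals)[vals <= 0], collapse = ", ")))
    TRUE
})

#' Total chaperone concentrations
#'
#' Named totals (uM) for the chaperone machinery: ribosomes, trigger factor,
#' DnaK, DnaJ (dimer concentration), GrpE, GroEL, GroES, Lon and ClpB.
#'
#' @slot levels named numeric vector of totals in uM
#' @exportClass ChaperoneLevels
setClass("ChaperoneLevels", representation(levels = "numeric"))

setValidity("ChaperoneLevels", function(object) {
    if (!identical(names(object@levels), .CHAPERONES))
        return(paste0("levels must be named exactly: ",
                      paste(.CHAPERONES, collapse = ", ")))
    if (any(!is.finite(object@levels)) || any(object@levels < 0))
        return("chaperone totals must be finite and nonnegative")
    TRUE
})

#' Structural options of the proteostasis model
#'
#' @slot ribosome_activation_rate synthesis control (s^-1); the bulk synthesis
#'   flux is \code{ribosome_activation_rate * [Rib]} in uM/s
#' @slot n_max largest explicit aggregate size (>= 2)
#' @slot binding_factor multiplicative binding factor lambda (> 0): GroEL
#'   on-rates are multiplied, DnaK on-rates divided, by this factor
#' @slot capacity_factor multiplier (>= 0) on total GroEL and GroES
#' @slot enabled_systems subset of KJE, GroELS, B+KJE, TriggerFactor,
#'   Degradation
#' @slot double_occupancy allow a second client on the trans ring of a capped
#'   GroEL complex
#' @slot null_reservoir initial concentration (uM) of the bookkeeping Null
#'   species feeding synthesis
#' @exportClass ModelOptions
setClass("ModelOptions",
         representation(ribosome_activation_rate = "numeric",
                        n_max = "integer",
                        binding_factor = "numeric",
                        capacity_factor = "numeric",
                        enabled_systems = "character",
                        double_occupancy = "logical",
                        null_reservoir = "numeric"))

setValidity("ModelOptions", function(object) {
    if (object@n_max < 2L) return("n_max must be >= 2")
    if (!is.finite(object@binding_factor) || object@binding_factor <= 0)
        return("binding_factor must be > 0")
    if (!is.finite(object@capacity_factor) || object@capacity_factor < 0)
        return("capacity_factor must be >= 0")
    if (object@ribosome_activation_rate < 0)
        return("ribosome_activation_rate must be >= 0")
    bad <- setdiff(object@enabled_systems, .SYSTEMS)
    if (length(bad))
        return(paste0("unknown system(s): ", paste(bad, collapse = ", ")))
    if ("B+KJE" %in% object@enabled_systems &&
        !("KJE" %in% object@enabled_systems))
        return("B+KJE requires the KJE system (DnaK/DnaJ prepare aggregates)")
    if (object@null_reservoir <= 0)
        return("null_reservoir must be > 0")
    TRUE
})

#' Mass-action reaction network of the proteostasis model
#'
#' Species, elementary mass-action reactions, named rate constants and
#' conservation groups.  Reactions are stored as reactant/product
#' stoichiometry matrices (species x reactions); each reaction carries the
#' name of its rate constant so that configuration transforms (binding factor,
#' overrides) act on the constant table alone.  The synthesis reaction
#' (Null -> U) is flagged: its flux is zeroth order in client,
#' \code{r_syn * c_Null / (c_Null + eps)}, drawing on the Null reservoir.
#'
#' @slot species data.frame with columns name, role (client-state, chaperone,
#'   complex, bookkeeping), init (uM), client_stoich (number of client
#'   monomers carried)
#' @slot stoichReact,stoichProd stoichiometry matrices (species x reactions)
#' @slot reactions data.frame with columns id, constant (rate-constant name),
#'   type ("massaction" or "synthesis"), reversible_of (paired reaction id or
#'   NA for designated irreversible steps)
#' @slot constants named numeric vector of rate-constant values
#' @slot conservation named list; each element is a named numeric weight
#'   vector over species whose weighted sum is conserved
#' @slot profile,levels,options the configuration the model was built from
#' @exportClass NetworkModel
setClass("NetworkModel",
         representation(species = "data.frame",
                        stoichReact = "matrix",
                        stoichProd = "matrix",
                        reactions = "data.frame",
                        constants = "numeric",
                        conservation = "list",
                        profile = "BiophysicalProfile",
                        levels = "ChaperoneLevels",
                        options = "ModelOptions"))

setValidity("NetworkModel", function(object) {
    ns <- nrow(object@species); nr <- nrow(object@reactions)
    if (!identical(dim(object@stoichReact), c(ns, nr)) ||
        !identical(dim(object@stoichProd), c(ns, nr)))
        return("stoichiometry matrices must be species x reactions")
    if (anyDuplicated(object@species$name))
        return("species names must be unique")
    if (any(colSums(object@stoichReact) > 3))
        return("reactions must be elementary (at most termolecular)")
    if (!all(object@reactions$constant %in% names(object@constants)))
        return("every reaction must reference a declared rate constant")
    if (any(!is.finite(object@constants)) || any(object@constants < 0))
        return("rate constants must be finite and nonnegative")
    TRUE
})

#' A bulk concentration snapshot
#'
#' @slot time time point (s)
#' @slot conc named concentrations (uM); tiny negative integrator output is
#'   clamped to zero on construction
#' @exportClass ConcentrationState
setClass("ConcentrationState",
         representation(time = "numeric", conc = "numeric"))

#' Integrated trajectory of the bulk model
#'
#' @slot times output grid (s), always containing the analysis time
#' @slot conc matrix, time points x species
#' @slot model the integrated NetworkModel
#' @exportClass KineticTrajectory
setClass("KineticTrajectory",
         representation(times = "numeric", conc = "matrix",
                        model = "NetworkModel"))

#' Tagged-single-molecule rate matrix
#'
#' Generator K over client states at a frozen analysis time: entry (i, j) is
#' the rate (s^-1) of the tagged molecule jumping from state j to state i;
#' columns sum to zero.
#'
#' @slot K square generator matrix with state labels as dimnames
#' @slot states client-state table (label, system, agg_size, position,
#'   bulk_species)
#' @slot time analysis time the bulk concentrations were frozen at
#' @slot concentrations bulk concentration snapshot used for the freeze
#' @exportClass RateMatrix
setClass("RateMatrix",
         representation(K = "matrix", states = "data.frame",
                        time = "numeric", concentrations = "numeric"))

setValidity("RateMatrix", function(object) {
    K <- object@K
    if (nrow(K) != ncol(K)) return("K must be square")
    if (nrow(K) != nrow(object@states))
        return("state table must match K dimension")
    off <- K; diag(off) <- 0
    if (any(off < 0)) return("off-diagonal rates must be nonnegative")
    cs <- colSums(K)
    scale <- pmax(apply(abs(K), 2, max), .Machine$double.xmin)
    if (any(abs(cs) > 1e-9 * scale))
        return("columns of K must sum to zero")
    TRUE
})

#' Discrete-time transition matrix derived from a rate matrix
#'
#' Column-stochastic matrix T = I + tau * K with tau = 1 / (2 * k_max) by
#' default, where k_max is the largest total exit rate; the factor one half
#' guarantees diagonals >= 1/2 (aperiodicity).
#'
#' @slot T column-stochastic matrix
#' @slot tau time step (s)
#' @slot k_max largest total exit rate (s^-1)
#' @slot states client-state table carried over from the rate matrix
#' @exportClass TransitionMatrix
setClass("TransitionMatrix",
         representation(T = "matrix", tau = "numeric", k_max = "numeric",
                        states = "data.frame"))

setValidity("TransitionMatrix", function(object) {
    Tm <- object@T
    if (any(Tm < -1e-15) || any(Tm > 1 + 1e-12))
        return("entries must lie in [0, 1]")
    if (any(abs(colSums(Tm) - 1) > 1e-10))
        return("columns must sum to one")
    TRUE
})

#' Committor probabilities between two sink sets
#'
#' @slot A,B sink state labels
#' @slot q_B probability, per starting state, of reaching B before A
#' @slot q_A complement (q_A + q_B = 1)
#' @slot iterations number of matrix squarings used
#' @slot method "squaring" or "linear"
#' @exportClass CommittorResult
setClass("CommittorResult",
         representation(A = "character", B = "character",
                        q_B = "numeric", q_A = "numeric",
                        iterations = "integer", method = "character"))

setValidity("CommittorResult", function(object) {
    if (any(object@q_B < -1e-10) || any(object@q_B > 1 + 1e-10))
        return("q_B must lie in [0, 1]")
    if (max(abs(object@q_A + object@q_B - 1)) > 1e-8)
        return("q_A + q_B must equal 1")
    TRUE
})

#' Committors conditioned on visiting a mediator set
#'
#' \code{h} is the probability of reaching B before A having visited the
#' mediator set C en route (a start inside C counts as visited); \code{hbar}
#' the same not having visited C.  Conservation of probability gives
#' h + hbar = q_B elementwise.
#'
#' @slot mediator mediator state labels (the set C)
#' @slot h,hbar conditional committor vectors
#' @slot committor the unconditional CommittorResult on the same sinks
#' @exportClass ConditionalCommittorResult
setClass("ConditionalCommittorResult",
         representation(mediator = "character", h = "numeric",
                        hbar = "numeric", committor = "CommittorResult"))

setValidity("ConditionalCommittorResult", function(object) {
    if (max(abs(object@h + object@hbar - object@committor@q_B)) > 1e-8)
        return("h + hbar must equal q_B")
    TRUE
})

#' Entry-channel decomposition of a source-to-target transition
#'
#' Reactive paths (reaching the target before returning to the source) are
#' classified by the edge through which they first enter the target set.
#'
#' @slot source,target state label sets
#' @slot channels named list of entry-edge data.frames (columns from, to)
#' @slot probabilities per-channel probability, conditional on a reactive path
#' @slot fluxes per-channel bulk flux (uM/s); NA until computed against a
#'   concentration snapshot
#' @slot reactive_probability probability that the first excursion is reactive
#' @slot absorption internal absorption-probability matrix reused by the flux
#'   computation (transient states x channels)
#' @slot tau time step of the transition matrix used
#' @exportClass PathwayDecomposition
setClass("PathwayDecomposition",
         representation(source = "character", target = "character",
                        channels = "list", probabilities = "numeric",
                        fluxes = "numeric", reactive_probability = "numeric",
                        absorption = "matrix", tau = "numeric"))

setValidity("PathwayDecomposition", function(object) {
    p <- object@probabilities
    if (length(p) && (any(p < -1e-10) ||
                      abs(sum(p) - 1) > 1e-8))
        return("channel probabilities must be nonnegative and sum to 1")
    TRUE
})

#' Least-squares proportionality fit y = c * x through the origin
#'
#' @slot slope fitted coefficient c
#' @slot points data.frame of the fitted (x, y) points
#' @slot rss residual sum of squares
#' @slot r_squared 1 - RSS / sum((y - mean(y))^2)
#' @exportClass ProportionalityFit
setClass("ProportionalityFit",
         representation(slope = "numeric", points = "data.frame",
                        rss = "numeric", r_squared = "numeric"))

#' Specification of an experiment sweep
#'
#' @slot parameter one of ribosome_activation_rate, binding_factor,
#'   capacity_factor
#' @slot grid numeric grid of parameter values
#' @slot profiles list of BiophysicalProfile objects
#' @slot options ModelOptions shared by all runs
#' @slot overrides named rate-constant overrides
#' @slot transition "M->U" or "U->N"
#' @exportClass SweepSpec
setClass("SweepSpec",
         representation(parameter = "character", grid = "numeric",
                        profiles = "list", options = "ModelOptions",
                        overrides = "numeric", transition = "character"))

setValidity("SweepSpec", function(object) {
    if (!object@parameter %in% c("ribosome_activation_rate",
                                 "binding_factor", "capacity_factor"))
        return("unknown sweep parameter")
    if (!length(object@grid)) return("grid must be nonempty")
    if (object@parameter == "binding_factor" && any(object@grid <= 0))
        return("binding_factor grid must be positive")
    if (object@parameter != "binding_factor" && any(object@grid < 0))
        return("grid values must be nonnegative")
    if (!object@transition %in% c("M->U", "U->N"))
        return("transition must be 'M->U' or 'U->N'")
    TRUE
})
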