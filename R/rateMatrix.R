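## Tagged-single-molecule state space and time-frozen generator.
##
## Multi-client bulk species are split into one tagged state per client
## position: a doubly occupied GroEL complex GrLd:{X,Y}:GrS becomes a
## cis-tagged state GrLd:{X,y}:GrS and a trans-tagged state GrLd:{x,Y}:GrS
## (capital letter = tagged molecule).  Aggregates are one state per size
## (monomers indistinguishable); on any monomer-removing event the tagged
## molecule leaves with probability 1/n.

.cisLabel <- function(X, y) paste0("GrLd:{", X, ",", tolower(y), "}:GrS")
.transLabel <- function(x, Y) paste0("GrLd:{", tolower(x), ",", Y, "}:GrS")

#' Enumerate the client states of the tagged molecule
#'
#' Returns the deterministic-order state table of a single tagged client
#' molecule: free conformers, the Null (degraded/pre-synthesis) state,
#' chaperone complexes of the enabled systems, cis/trans-split
#' double-occupancy GroEL states, and plain and prepared aggregates of every
#' size up to \code{n_max}.
#'
#' @param model a \linkS4class{NetworkModel}
#' @return data.frame with columns label, system, agg_size, position
#'   ("" / "cis" / "trans"), and bulk_species (the bulk species whose
#'   concentration the state maps to)
#' @export
enumerateClientStates <- function(model) {
    stopifnot(is(model, "NetworkModel"))
    sys <- model@options@enabled_systems
    n_max <- model@options@n_max
    st <- list()
    add <- function(label, system, agg = 0L, pos = "", bulk = label)
        st[[length(st) + 1L]] <<- data.frame(label = label, system = system,
                                             agg_size = agg, position = pos,
                                             bulk_species = bulk,
                                             stringsAsFactors = FALSE)
    add("Null", "Degradation")
    add("U", "none"); add("N", "none"); add("M", "none")
    if ("TriggerFactor" %in% sys) add("TF:U", "none")
    if ("Degradation" %in% sys) {
        add("Lon:U", "Degradation")
        add("Lon:M", "Degradation")
    }
    if ("KJE" %in% sys)
        for (s in c("KT:U", "KT:M", "U:J:KT", "U:J:KD", "KD:U"))
            add(s, "KJE")
    if ("GroELS" %in% sys) {
        for (s in c("GrLT:U", "GrLT:M")) add(s, "GroELS")
        for (x in c("U", "N", "M"))
            add(paste0("GrLd:{", x, "}:GrS"), "GroELS")
        if (model@options@double_occupancy) {
            for (X in c("U", "N", "M")) for (y in c("U", "M"))
                add(.cisLabel(X, y), "GroELS", pos = "cis",
                    bulk = .doubleLabel(X, y))
            for (x in c("U", "N", "M")) for (Y in c("U", "M"))
                add(.transLabel(x, Y), "GroELS", pos = "trans",
                    bulk = .doubleLabel(x, Y))
        }
    }
    for (n in 2:n_max) add(paste0("A", n), "B+KJE", agg = n)
    if ("B+KJE" %in% sys)
        for (n in 2:n_max) add(paste0("A", n, "*"), "B+KJE", agg = n)
    out <- do.call(rbind, st)
    rownames(out) <- out$label
    out
}

#' Extract the tagged-molecule rate matrix at a frozen time
#'
#' Builds the generator K of the tagged single molecule from the bulk model
#' and a concentration snapshot: unimolecular client transitions carry their
#' rate constants; bimolecular transitions of the tagged client with a
#' partner species S carry \code{k * [S](t)} (for the tagged misfolded
#' monomer dimerising, the partner concentration is the bulk [M](t) itself);
#' monomer removal from an aggregate of size n routes the tagged molecule out
#' with probability 1/n; the synthesis rate out of Null is
#' \code{r_syn / (c_Null + eps)}.  Columns sum to zero.
#'
#' @param model a \linkS4class{NetworkModel}
#' @param state a \linkS4class{ConcentrationState} covering all model species
#' @return a \linkS4class{RateMatrix}
#' @export
extractRateMatrix <- function(model, state) {
    stopifnot(is(model, "NetworkModel"), is(state, "ConcentrationState"))
    missing <- setdiff(model@species$name, names(state@conc))
    if (length(missing))
        stop("state lacks species: ", paste(missing, collapse = ", "))
    conc <- pmax(state@conc[model@species$name], 0)
    k <- model@constants
    sys <- model@options@enabled_systems
    n_max <- model@options@n_max
    states <- enumerateClientStates(model)
    n <- nrow(states)
    K <- matrix(0, n, n, dimnames = list(states$label, states$label))
    add <- function(from, to, rate) {
        if (rate < 0) stop("negative rate for ", from, " -> ", to)
        K[to, from] <<- K[to, from] + rate
    }
    cav <- function(x) paste0("GrLd:{", x, "}:GrS")

    ## core + synthesis
    add("U", "N", k[["k_fold"]]); add("N", "U", k[["k_unfold"]])
    add("U", "M", k[["k_mis"]]); add("M", "U", k[["k_unmis"]])
    add("Null", "U", k[["r_syn"]] / (conc[["Null"]] + .SYN_EPS))
    if ("Degradation" %in% sys) {
        add("U", "Lon:U", k[["k_lon_on"]] * conc[["Lon"]])
        add("Lon:U", "U", k[["k_lon_off"]])
        add("Lon:U", "Null", k[["k_lon_cat"]])
        add("M", "Lon:M", k[["k_lon_on"]] * conc[["Lon"]])
        add("Lon:M", "M", k[["k_lon_off"]])
        add("Lon:M", "Null", k[["k_lon_cat"]])
    }
    if ("TriggerFactor" %in% sys) {
        add("U", "TF:U", k[["k_tf_on"]] * conc[["TF"]])
        add("TF:U", "U", k[["k_tf_off"]])
    }
    if ("KJE" %in% sys) {
        add("U", "KT:U", k[["k_KU_on"]] * conc[["KT"]])
        add("KT:U", "U", k[["k_KU_off"]])
        add("M", "KT:M", k[["k_KM_on"]] * conc[["KT"]])
        add("KT:M", "M", k[["k_KM_off"]])
        add("KT:M", "KT:U", k[["k_kje_unfold"]])
        add("KT:U", "U:J:KT", k[["k_j_on"]] * conc[["J2"]])
        add("U:J:KT", "KT:U", k[["k_j_off"]])
        add("U:J:KT", "U:J:KD", k[["k_hyd"]])
        add("U:J:KD", "KD:U", k[["k_j_rel"]])
        add("KD:U", "U", k[["k_exch"]] * conc[["GrpE"]])
    }
    if ("GroELS" %in% sys) {
        add("U", "GrLT:U", k[["k_GU_on"]] * conc[["GrLT"]])
        add("GrLT:U", "U", k[["k_GU_off"]])
        add("M", "GrLT:M", k[["k_GM_on"]] * conc[["GrLT"]])
        add("GrLT:M", "M", k[["k_GM_off"]])
        add("GrLT:U", cav("U"), k[["k_enc"]] * conc[["GrS"]])
        add("GrLT:M", cav("M"), k[["k_enc"]] * conc[["GrS"]])
        add(cav("U"), cav("N"), k[["k_fold"]])
        add(cav("N"), cav("U"), k[["k_unfold"]])
        add(cav("U"), cav("M"), k[["k_mis"]])
        add(cav("M"), cav("U"), k[["k_unmis"]])
        for (x in c("U", "N", "M")) add(cav(x), x, k[["k_cycle"]])
        if (model@options@double_occupancy) {
            for (X in c("U", "N", "M")) {
                ## tagged cavity client gains an untagged trans partner
                for (Y in c("U", "M"))
                    add(cav(X), .cisLabel(X, Y),
                        k[["k_trans_on"]] * conc[[Y]])
                ## tagged free U/M binds trans to an occupied complex
                for (Y in c("U", "M"))
                    add(Y, .transLabel(X, Y),
                        k[["k_trans_on"]] * conc[[cav(X)]])
            }
            for (y in c("U", "M")) {
                ## cis-tagged conformational dynamics (trans partner inert)
                add(.cisLabel("U", y), .cisLabel("N", y), k[["k_fold"]])
                add(.cisLabel("N", y), .cisLabel("U", y), k[["k_unfold"]])
                add(.cisLabel("U", y), .cisLabel("M", y), k[["k_mis"]])
                add(.cisLabel("M", y), .cisLabel("U", y), k[["k_unmis"]])
                ## untagged cis partner of a trans-tagged client converts at
                ## the same unimolecular rates
                add(.transLabel("U", y), .transLabel("N", y), k[["k_fold"]])
                add(.transLabel("N", y), .transLabel("U", y), k[["k_unfold"]])
                add(.transLabel("U", y), .transLabel("M", y), k[["k_mis"]])
                add(.transLabel("M", y), .transLabel("U", y), k[["k_unmis"]])
                ## cycle release: cis-tagged leaves free, trans-tagged
                ## becomes the encapsulated cis client
                for (X in c("U", "N", "M")) {
                    add(.cisLabel(X, y), X, k[["k_cycle"]])
                    add(.transLabel(X, y), cav(y), k[["k_cycle"]])
                }
            }
        }
    }
    ## aggregation of the tagged misfolded monomer
    aLab <- function(n) paste0("A", n)
    add("M", "A2", k[["k_ag"]] * conc[["M"]])
    if (n_max > 2) for (n in 2:(n_max - 1))
        add("M", aLab(n + 1), k[["k_ag"]] * conc[[aLab(n)]])
    for (n in 2:n_max) {
        if (n < n_max) add(aLab(n), aLab(n + 1), k[["k_ag"]] * conc[["M"]])
        if (n == 2) {
            ## dimer dissolution: both monomers end up free and misfolded
            add("A2", "M", k[["k_dis"]])
        } else {
            add(aLab(n), "M", k[["k_dis"]] / n)
            add(aLab(n), aLab(n - 1), k[["k_dis"]] * (n - 1) / n)
        }
    }
    if ("B+KJE" %in% sys) {
        sLab <- function(n) paste0("A", n, "*")
        prep <- k[["k_prep"]] * conc[["KT"]] * conc[["J2"]]
        extr <- k[["k_extract"]] * conc[["ClpB"]]
        for (n in 2:n_max) {
            add(aLab(n), sLab(n), prep)
            add(sLab(n), aLab(n), k[["k_unprep"]])
            if (n == 2) {
                ## dissolution: tagged monomer extracted unfolded with
                ## probability 1/2, otherwise returned misfolded
                add(sLab(2), "U", extr / 2)
                add(sLab(2), "M", extr / 2)
            } else {
                add(sLab(n), "U", extr / n)
                add(sLab(n), aLab(n - 1), extr * (n - 1) / n)
            }
        }
    }
    diag(K) <- 0
    diag(K) <- -colSums(K)
    new("RateMatrix", K = K, states = states, time = state@time,
        concentrations = conc)
}

#' @rdname RateMatrix-accessors
#' @aliases rateMatrix
#' @export
rateMatrix <- function(x) x@K

#' Accessors for RateMatrix and TransitionMatrix objects
#'
#' \code{rateMatrix} returns the generator, \code{clientStates} the state
#' table, \code{transitionMatrix} the column-stochastic matrix.
#'
#' @name RateMatrix-accessors
#' @param x a \linkS4class{RateMatrix} or \linkS4class{TransitionMatrix}
#' @export
clientStates <- function(x) x@states

setMethod("show", "RateMatrix", function(object) {
    cat("RateMatrix:", nrow(object@K), "client states, frozen at t =",
        object@time, "s\n")
    cat("  max exit rate:", max(-diag(object@K)), "/s\n")
})

#' Check the constant-rate-matrix assumption
#'
#' Compares the entry-channel pathway probabilities computed from rate
#' matrices frozen at \code{t_eval} and at \code{2 * t_eval}.  Reporting
#' only: the differences quantify how strongly the frozen-generator
#' approximation depends on the choice of analysis time.
#'
#' @param model a \linkS4class{NetworkModel}
#' @param config an \code{AnalysisConfig}; the comparison uses its
#'   \code{t_eval} and twice that
#' @param source,target state labels of the transition to decompose
#' @return list with per-channel probabilities at both times, the absolute
#'   differences, and their maximum
#' @export
frozenMatrixCheck <- function(model, config = analysisConfig(),
                              source = "M", target = "U") {
    cfg2 <- analysisConfig(t_eval = 2 * config@t_eval, rtol = config@rtol,
                           atol = config@atol, n_out = config@n_out)
    traj <- propagateModel(model, cfg2)
    probsAt <- function(t) {
        K <- extractRateMatrix(model, stateAt(traj, t))
        Tm <- buildTransitionMatrix(K)
        ch <- entryChannels(K@states, target)
        pathwayProbabilities(Tm, source, target, ch)@probabilities
    }
    ## the coarse log grid need not contain t_eval exactly; use the nearest
    ## stored times
    near <- function(t) traj@times[which.min(abs(traj@times - t))]
    p1 <- probsAt(near(config@t_eval))
    p2 <- probsAt(near(2 * config@t_eval))
    dif <- abs(p2 - p1)
    list(t1 = p1, t2 = p2, differences = dif, max_difference = max(dif))
}
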