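## Default rate constants for every step that is not part of the six-parameter
## client profile.  These are package defaults, chosen to place the shipped
## client profiles in their characteristic regimes (KJE-dominant correction of
## misfolded protein at low synthesis for the Default protein, GroELS-dominant
## for the Slow Folder, B+KJE growth with aggregate load), and every one of
## them can be overridden through buildModel(overrides = ...).  Units:
## unimolecular s^-1, bimolecular uM^-1 s^-1, termolecular uM^-2 s^-1.
.DEFAULT_CONSTANTS <- c(
    ## trigger factor (holder only)
    k_tf_on = 0.5, k_tf_off = 1,
    ## Lon degradation of unfolded client
    k_lon_on = 0.1, k_lon_off = 0.1, k_lon_cat = 1,
    ## KJE cycle
    k_KU_on = 0.5, k_KU_off = 2, k_KM_on = 0.5, k_KM_off = 2,
    k_kje_unfold = 1, k_j_on = 1, k_j_off = 0.1, k_hyd = 1,
    k_j_rel = 1, k_exch = 1,
    ## GroELS cycle (k_cycle = 0.1 /s: ~10 s timed GroES release)
    k_GU_on = 0.5, k_GU_off = 1, k_GM_on = 0.5, k_GM_off = 1,
    k_enc = 1, k_cycle = 0.1, k_trans_on = 0.5,
    ## B+KJE disaggregation
    k_prep = 0.1, k_unprep = 0.1, k_extract = 0.5)

## Rate constants that stay irreversible by design: hydrolysis, timed or
## catalysed release, encapsulation (cis and trans), extraction, degradation
## and synthesis.
.IRREVERSIBLE <- c("k_hyd", "k_j_rel", "k_exch", "k_enc", "k_cycle",
                   "k_trans_on", "k_extract", "k_lon_cat", "k_kje_unfold",
                   "r_syn")

## GroEL / DnaK client on-rates touched by the binding factor lambda.
.GROEL_ON <- c("k_GU_on", "k_GM_on", "k_trans_on")
.DNAK_ON <- c("k_KU_on", "k_KM_on")

.doubleLabel <- function(cis, trans) paste0("GrLd:{", cis, ",", trans, "}:GrS")

#' Build the proteostasis reaction network
#'
#' Assembles the full mass-action network for one client protein: intrinsic
#' folding/misfolding, synthesis from a Null reservoir and Lon degradation
#' back to it, nucleated aggregation up to \code{n_max}, and the KJE,
#' GroELS and B+KJE chaperone cycles (plus a trigger-factor holder state).
#' Reverse rates are derived from the profile's equilibrium constants;
#' every other constant starts from a documented package default.
#'
#' Construction order: defaults and profile-derived constants, then
#' \code{overrides}, then the binding factor and capacity factor from
#' \code{options} (via \code{\link{applyBindingFactor}} and
#' \code{\link{applyCapacityFactor}}).
#'
#' @param profile a \linkS4class{BiophysicalProfile}
#' @param levels a \linkS4class{ChaperoneLevels}
#' @param options a \linkS4class{ModelOptions}
#' @param overrides named numeric vector of rate-constant overrides; names
#'   must be declared constants (see \code{constants(model)})
#' @return a validated \linkS4class{NetworkModel}
#' @examples
#' m <- buildModel(proteinProfile("Default"), chaperoneLevels(), modelOptions())
#' m
#' @export
buildModel <- function(profile = proteinProfile("Default"),
                       levels = chaperoneLevels(),
                       options = modelOptions(),
                       overrides = numeric()) {
    validObject(profile); validObject(levels); validObject(options)
    sys <- options@enabled_systems
    lv <- levels@levels
    n_max <- options@n_max

    ## ---- constants -------------------------------------------------------
    d <- derivedRates(profile)
    constants <- c(k_fold = profile@k_fold, k_unfold = unname(d["k_unfold"]),
                   k_mis = profile@k_mis, k_unmis = unname(d["k_unmis"]),
                   k_ag = profile@k_ag, k_dis = unname(d["k_dis"]),
                   r_syn = options@ribosome_activation_rate * lv[["Rib"]],
                   .DEFAULT_CONSTANTS)
    if (length(overrides)) {
        if (is.null(names(overrides)) || any(names(overrides) == ""))
            stop("overrides must be a named numeric vector")
        bad <- setdiff(names(overrides), names(constants))
        if (length(bad))
            stop("unknown rate-constant override(s): ",
                 paste(bad, collapse = ", "))
        if (any(overrides < 0)) stop("rate constants must be nonnegative")
        constants[names(overrides)] <- overrides
    }

    ## ---- species ---------------------------------------------------------
    sp <- list()
    addSp <- function(name, role, init, client) {
        sp[[length(sp) + 1L]] <<- data.frame(name = name, role = role,
                                             init = init,
                                             client_stoich = client,
                                             stringsAsFactors = FALSE)
    }
    addSp("Null", "bookkeeping", options@null_reservoir, 1)
    addSp("U", "client-state", 0, 1)
    addSp("N", "client-state", 0, 1)
    addSp("M", "client-state", 0, 1)
    addSp("Rib", "chaperone", lv[["Rib"]], 0)
    if ("TriggerFactor" %in% sys) {
        addSp("TF", "chaperone", lv[["TF"]], 0)
        addSp("TF:U", "complex", 0, 1)
    }
    if ("Degradation" %in% sys) {
        addSp("Lon", "chaperone", lv[["Lon"]], 0)
        addSp("Lon:U", "complex", 0, 1)
        addSp("Lon:M", "complex", 0, 1)
    }
    if ("KJE" %in% sys) {
        addSp("KT", "chaperone", lv[["DnaK"]], 0)
        addSp("J2", "chaperone", lv[["DnaJ"]], 0)
        addSp("GrpE", "chaperone", lv[["GrpE"]], 0)
        for (s in c("KT:U", "KT:M", "U:J:KT", "U:J:KD", "KD:U"))
            addSp(s, "complex", 0, 1)
    }
    doubles <- character()
    if ("GroELS" %in% sys) {
        g <- options@capacity_factor
        addSp("GrLT", "chaperone", lv[["GroEL"]] * g, 0)
        addSp("GrS", "chaperone", lv[["GroES"]] * g, 0)
        addSp("GrLT:U", "complex", 0, 1)
        addSp("GrLT:M", "complex", 0, 1)
        for (x in c("U", "N", "M"))
            addSp(paste0("GrLd:{", x, "}:GrS"), "complex", 0, 1)
        if (options@double_occupancy) {
            for (x in c("U", "N", "M")) for (y in c("U", "M")) {
                doubles <- c(doubles, .doubleLabel(x, y))
                addSp(.doubleLabel(x, y), "complex", 0, 2)
            }
        }
    }
    for (n in 2:n_max) addSp(paste0("A", n), "client-state", 0, n)
    if ("B+KJE" %in% sys) {
        addSp("ClpB", "chaperone", lv[["ClpB"]], 0)
        for (n in 2:n_max) addSp(paste0("A", n, "*"), "complex", 0, n)
    }
    species <- do.call(rbind, sp)
    rownames(species) <- species$name
    idx <- setNames(seq_len(nrow(species)), species$name)

    ## ---- reactions -------------------------------------------------------
    re <- new.env()
    re$react <- list(); re$prod <- list(); re$const <- character()
    re$type <- character()
    addRx <- function(constant, reactants, products, type = "massaction") {
        re$react[[length(re$react) + 1L]] <- reactants
        re$prod[[length(re$prod) + 1L]] <- products
        re$const <- c(re$const, constant)
        re$type <- c(re$type, type)
        length(re$const)
    }
    pairs <- list()
    addPair <- function(cf, rf, cb, rb) {
        ## reversible pair: forward then backward
        i <- addRx(cf, rf[[1]], rf[[2]])
        j <- addRx(cb, rb[[1]], rb[[2]])
        pairs[[length(pairs) + 1L]] <<- c(i, j)
    }
    s1 <- function(...) {
        v <- c(...)
        setNames(as.numeric(v), names(v))
    }

    ## core conformational dynamics
    addPair("k_fold", list(s1(U = 1), s1(N = 1)),
            "k_unfold", list(s1(N = 1), s1(U = 1)))
    addPair("k_mis", list(s1(U = 1), s1(M = 1)),
            "k_unmis", list(s1(M = 1), s1(U = 1)))
    ## synthesis: zeroth order in client, draws on the Null reservoir
    addRx("r_syn", s1(Null = 1), s1(U = 1), type = "synthesis")
    if ("Degradation" %in% sys) {
        addPair("k_lon_on", list(s1(U = 1, Lon = 1), s1("Lon:U" = 1)),
                "k_lon_off", list(s1("Lon:U" = 1), s1(U = 1, Lon = 1)))
        addRx("k_lon_cat", s1("Lon:U" = 1), s1(Lon = 1, Null = 1))
        ## Lon also recognises misfolded client (the degradation +
        ## re-synthesis route out of M must not pass through U)
        addPair("k_lon_on", list(s1(M = 1, Lon = 1), s1("Lon:M" = 1)),
                "k_lon_off", list(s1("Lon:M" = 1), s1(M = 1, Lon = 1)))
        addRx("k_lon_cat", s1("Lon:M" = 1), s1(Lon = 1, Null = 1))
    }
    if ("TriggerFactor" %in% sys)
        addPair("k_tf_on", list(s1(U = 1, TF = 1), s1("TF:U" = 1)),
                "k_tf_off", list(s1("TF:U" = 1), s1(U = 1, TF = 1)))
    ## aggregation (misfolded monomers only)
    addPair("k_ag", list(s1(M = 2), s1(A2 = 1)),
            "k_dis", list(s1(A2 = 1), s1(M = 2)))
    if (n_max > 2) for (n in 2:(n_max - 1)) {
        an <- paste0("A", n); an1 <- paste0("A", n + 1)
        addPair("k_ag", list(s1(M = 1, setNames(1, an)), setNames(1, an1)),
                "k_dis", list(setNames(1, an1), s1(M = 1, setNames(1, an))))
    }
    if ("KJE" %in% sys) {
        addPair("k_KU_on", list(s1(U = 1, KT = 1), s1("KT:U" = 1)),
                "k_KU_off", list(s1("KT:U" = 1), s1(U = 1, KT = 1)))
        addPair("k_KM_on", list(s1(M = 1, KT = 1), s1("KT:M" = 1)),
                "k_KM_off", list(s1("KT:M" = 1), s1(M = 1, KT = 1)))
        addRx("k_kje_unfold", s1("KT:M" = 1), s1("KT:U" = 1))
        addPair("k_j_on", list(s1("KT:U" = 1, J2 = 1), s1("U:J:KT" = 1)),
                "k_j_off", list(s1("U:J:KT" = 1), s1("KT:U" = 1, J2 = 1)))
        addRx("k_hyd", s1("U:J:KT" = 1), s1("U:J:KD" = 1))
        addRx("k_j_rel", s1("U:J:KD" = 1), s1("KD:U" = 1, J2 = 1))
        ## GrpE-catalysed nucleotide exchange releases unfolded client
        addRx("k_exch", s1("KD:U" = 1, GrpE = 1), s1(U = 1, KT = 1, GrpE = 1))
    }
    if ("GroELS" %in% sys) {
        addPair("k_GU_on", list(s1(U = 1, GrLT = 1), s1("GrLT:U" = 1)),
                "k_GU_off", list(s1("GrLT:U" = 1), s1(U = 1, GrLT = 1)))
        addPair("k_GM_on", list(s1(M = 1, GrLT = 1), s1("GrLT:M" = 1)),
                "k_GM_off", list(s1("GrLT:M" = 1), s1(M = 1, GrLT = 1)))
        cav <- function(x) paste0("GrLd:{", x, "}:GrS")
        addRx("k_enc", s1("GrLT:U" = 1, GrS = 1), setNames(1, cav("U")))
        addRx("k_enc", s1("GrLT:M" = 1, GrS = 1), setNames(1, cav("M")))
        ## in-cavity conformational dynamics at bulk rates
        addPair("k_fold", list(setNames(1, cav("U")), setNames(1, cav("N"))),
                "k_unfold", list(setNames(1, cav("N")), setNames(1, cav("U"))))
        addPair("k_mis", list(setNames(1, cav("U")), setNames(1, cav("M"))),
                "k_unmis", list(setNames(1, cav("M")), setNames(1, cav("U"))))
        for (x in c("U", "N", "M"))
            addRx("k_cycle", setNames(1, cav(x)),
                  s1(GrLT = 1, GrS = 1, setNames(1, x)))
        if (options@double_occupancy) {
            for (x in c("U", "N", "M")) for (y in c("U", "M")) {
                dl <- .doubleLabel(x, y)
                ## trans binding of a second client (irreversible; the trans
                ## client leaves only through the cycle)
                addRx("k_trans_on", s1(setNames(1, cav(x)), setNames(1, y)),
                      setNames(1, dl))
                ## cycle release: cis client leaves, trans client becomes the
                ## new encapsulated cis client
                addRx("k_cycle", setNames(1, dl),
                      s1(setNames(1, x), setNames(1, cav(y))))
            }
            ## cis-client conformational dynamics in double complexes
            for (y in c("U", "M")) {
                addPair("k_fold", list(setNames(1, .doubleLabel("U", y)),
                                       setNames(1, .doubleLabel("N", y))),
                        "k_unfold", list(setNames(1, .doubleLabel("N", y)),
                                         setNames(1, .doubleLabel("U", y))))
                addPair("k_mis", list(setNames(1, .doubleLabel("U", y)),
                                      setNames(1, .doubleLabel("M", y))),
                        "k_unmis", list(setNames(1, .doubleLabel("M", y)),
                                        setNames(1, .doubleLabel("U", y))))
            }
        }
    }
    if ("B+KJE" %in% sys) {
        for (n in 2:n_max) {
            an <- paste0("A", n); ans <- paste0("A", n, "*")
            addPair("k_prep",
                    list(s1(setNames(1, an), KT = 1, J2 = 1), setNames(1, ans)),
                    "k_unprep",
                    list(setNames(1, ans), s1(setNames(1, an), KT = 1, J2 = 1)))
            if (n > 2) {
                addRx("k_extract", s1(setNames(1, ans), ClpB = 1),
                      s1(setNames(1, paste0("A", n - 1)), U = 1, ClpB = 1,
                         KT = 1, J2 = 1))
            } else {
                ## dissolution of the prepared dimer: one monomer extracted
                ## unfolded, the residual monomer returns misfolded
                addRx("k_extract", s1("A2*" = 1, ClpB = 1),
                      s1(M = 1, U = 1, ClpB = 1, KT = 1, J2 = 1))
            }
        }
    }

    nr <- length(re$const)
    ns <- nrow(species)
    SR <- matrix(0, ns, nr, dimnames = list(species$name, NULL))
    SP <- matrix(0, ns, nr, dimnames = list(species$name, NULL))
    for (r in seq_len(nr)) {
        rr <- re$react[[r]]; pp <- re$prod[[r]]
        SR[names(rr), r] <- rr
        SP[names(pp), r] <- pp
    }
    pairvec <- rep(NA_integer_, nr)
    for (p in pairs) { pairvec[p[1]] <- p[2]; pairvec[p[2]] <- p[1] }
    reactions <- data.frame(id = seq_len(nr), constant = re$const,
                            type = re$type, reversible_of = pairvec,
                            stringsAsFactors = FALSE)

    ## ---- conservation groups --------------------------------------------
    w <- function(members) setNames(members, NULL)
    groups <- list(client = setNames(species$client_stoich, species$name))
    groups$client <- groups$client[groups$client > 0]
    groups$Rib <- c(Rib = 1)
    if ("TriggerFactor" %in% sys) groups$TF <- c(TF = 1, "TF:U" = 1)
    if ("Degradation" %in% sys)
        groups$Lon <- c(Lon = 1, "Lon:U" = 1, "Lon:M" = 1)
    if ("KJE" %in% sys) {
        groups$DnaK <- c(KT = 1, "KT:U" = 1, "KT:M" = 1, "U:J:KT" = 1,
                         "U:J:KD" = 1, "KD:U" = 1)
        groups$DnaJ <- c(J2 = 1, "U:J:KT" = 1, "U:J:KD" = 1)
        groups$GrpE <- c(GrpE = 1)
        if ("B+KJE" %in% sys) {
            stars <- setNames(rep(1, n_max - 1), paste0("A", 2:n_max, "*"))
            groups$DnaK <- c(groups$DnaK, stars)
            groups$DnaJ <- c(groups$DnaJ, stars)
        }
    }
    if ("GroELS" %in% sys) {
        capped <- c(paste0("GrLd:{", c("U", "N", "M"), "}:GrS"), doubles)
        groups$GroEL <- setNames(rep(1, 3 + length(capped)),
                                 c("GrLT", "GrLT:U", "GrLT:M", capped))
        groups$GroES <- setNames(rep(1, 1 + length(capped)), c("GrS", capped))
    }
    if ("B+KJE" %in% sys) groups$ClpB <- c(ClpB = 1)

    model <- new("NetworkModel", species = species, stoichReact = SR,
                 stoichProd = SP, reactions = reactions,
                 constants = constants, conservation = groups,
                 profile = profile, levels = levels, options = options)
    if (options@binding_factor != 1)
        model <- applyBindingFactor(model, options@binding_factor)
    validObject(model)
    model
}

#' Scale chaperone binding preferences by a binding factor
#'
#' Multiplies every client-to-GroEL on-rate constant by \code{lambda} and
#' divides every client-to-DnaK on-rate constant by \code{lambda}; all other
#' constants are untouched, so \code{lambda} tunes the KJE/GroELS preference
#' without changing either cycle's internal kinetics.
#'
#' @param model a \linkS4class{NetworkModel}
#' @param lambda positive binding factor
#' @return the transformed model
#' @export
applyBindingFactor <- function(model, lambda) {
    stopifnot(is(model, "NetworkModel"))
    if (!is.finite(lambda) || lambda <= 0) stop("lambda must be > 0")
    k <- model@constants
    k[.GROEL_ON] <- k[.GROEL_ON] * lambda
    k[.DNAK_ON] <- k[.DNAK_ON] / lambda
    model@constants <- k
    model
}

#' Scale the GroELS capacity
#'
#' Multiplies the initial total GroEL and GroES concentrations by \code{g};
#' reactions and rate constants are unchanged.
#'
#' @param model a \linkS4class{NetworkModel}
#' @param g nonnegative capacity factor
#' @return the transformed model
#' @export
applyCapacityFactor <- function(model, g) {
    stopifnot(is(model, "NetworkModel"))
    if (!is.finite(g) || g < 0) stop("capacity factor must be >= 0")
    for (s in c("GrLT", "GrS"))
        if (s %in% model@species$name)
            model@species[s, "init"] <- model@species[s, "init"] * g
    model
}

#' Knock out one chaperone system
#'
#' Sets the initial concentrations of the system's chaperones to zero.  The
#' reaction list is unchanged: all fluxes through the system vanish
#' dynamically, and the corresponding tagged states remain in the state
#' space with zero entry rates.
#'
#' @param model a \linkS4class{NetworkModel}
#' @param system one of "KJE", "GroELS", "B+KJE", "TriggerFactor",
#'   "Degradation"
#' @return the transformed model
#' @export
knockoutSystem <- function(model, system) {
    stopifnot(is(model, "NetworkModel"))
    members <- switch(system,
                      "KJE" = c("KT", "J2", "GrpE"),
                      "GroELS" = c("GrLT", "GrS"),
                      "B+KJE" = "ClpB",
                      "TriggerFactor" = "TF",
                      "Degradation" = "Lon",
                      stop("unknown system '", system, "'"))
    if (!system %in% model@options@enabled_systems)
        stop("system '", system, "' is not enabled in this model")
    for (s in members) model@species[s, "init"] <- 0
    model
}

#' @rdname NetworkModel-accessors
#' @aliases constants
#' @param model a \linkS4class{NetworkModel}
#' @export
constants <- function(model) model@constants

#' Accessors for NetworkModel components
#'
#' \code{constants} returns the named rate-constant table, \code{speciesTable}
#' the species data.frame, \code{reactionsTable} the reaction metadata, and
#' \code{conservationGroups} the named weight vectors of the conserved totals.
#'
#' @name NetworkModel-accessors
#' @param model a \linkS4class{NetworkModel}
#' @export
speciesTable <- function(model) model@species

#' @rdname NetworkModel-accessors
#' @export
reactionsTable <- function(model) model@reactions

#' @rdname NetworkModel-accessors
#' @export
conservationGroups <- function(model) model@conservation

#' Initial concentration vector of a model
#' @param model a \linkS4class{NetworkModel}
#' @return named numeric vector (uM)
#' @export
initialState <- function(model) setNames(model@species$init,
                                         model@species$name)

setMethod("show", "NetworkModel", function(object) {
    cat("NetworkModel:", nrow(object@species), "species,",
        nrow(object@reactions), "reactions\n")
    cat("  profile:", object@profile@name,
        "| systems:", paste(object@options@enabled_systems, collapse = ", "),
        "\n")
    cat("  n_max =", object@options@n_max,
        "| double occupancy:", object@options@double_occupancy, "\n")
    cat("  conservation groups:",
        paste(names(object@conservation), collapse = ", "), "\n")
})
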