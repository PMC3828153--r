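## Canonical mapping from the system tag of an edge's source state to the
## entry-channel name of the five-way decomposition.
.CHANNEL_OF_TAG <- c(none = "direct", KJE = "KJE", GroELS = "GroELS",
                     "B+KJE" = "B+KJE", Degradation = "degradation")

#' Build the entry-edge channel classes for a target set
#'
#' Classifies every potential edge into the target by the chaperone-system
#' tag of the edge's source state: \code{direct} (free conformers),
#' \code{KJE} (release from DnaK/DnaJ complexes), \code{GroELS} (release or
#' unbinding from GroEL complexes), \code{B+KJE} (extraction from
#' aggregates) and \code{degradation} (re-entry from the Null state).  The
#' classes are exhaustive and mutually exclusive over entry edges, so no
#' tie-breaking is needed for paths that touch several systems; a path is
#' labelled by how it finally enters the target.
#'
#' @param states a client-state table (see
#'   \code{\link{enumerateClientStates}})
#' @param target character vector of target state labels
#' @return named list of data.frames with columns \code{from}, \code{to}
#' @export
entryChannels <- function(states, target) {
    stopifnot(all(target %in% states$label))
    from <- setdiff(states$label, target)
    tag <- states$system[match(from, states$label)]
    channel <- .CHANNEL_OF_TAG[tag]
    edges <- expand.grid(from = from, to = target,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    edges$channel <- rep(channel, times = length(target))
    out <- split(edges[c("from", "to")], edges$channel)
    ## keep the canonical channel order
    out[intersect(unname(.CHANNEL_OF_TAG), names(out))]
}

## Resolve a channel list into an edge -> channel lookup and verify it
## partitions the positive entering edges.
.channelLookup <- function(Tmat, source, target, channels) {
    if (is.null(names(channels)) || any(names(channels) == ""))
        stop("channels must be a named list")
    key <- function(f, t) paste(f, t, sep = " -> ")
    lut <- character()
    for (ch in names(channels)) {
        e <- channels[[ch]]
        kk <- key(e$from, e$to)
        dup <- kk[kk %in% names(lut)]
        if (length(dup))
            stop("channels overlap on edge(s): ", paste(dup, collapse = "; "))
        lut[kk] <- ch
    }
    ## every positive edge into the target from outside it must be covered
    for (t in target) {
        pos <- rownames(Tmat)[Tmat[t, ] > 0]
        pos <- setdiff(pos, c(t, target))
        miss <- setdiff(key(pos, t), names(lut))
        if (length(miss))
            stop("channels do not cover entering edge(s): ",
                 paste(miss, collapse = "; "))
    }
    lut
}

#' Entry-channel probabilities of a source-to-target transition
#'
#' Decomposes reactive transition paths (those reaching the target before
#' returning to the source) by the edge through which they first enter the
#' target.  The target is split into one absorbing copy per channel, the
#' source is made absorbing (a return ends the excursion unproductively),
#' and paths start from the source's normalised outflux distribution.
#' Channel probabilities are the absorbed masses renormalised over the
#' target copies, i.e. conditional on a reactive path.
#'
#' @param Tm a \linkS4class{TransitionMatrix}
#' @param source,target disjoint state-label sets
#' @param channels named list of entry-edge classes (see
#'   \code{\link{entryChannels}}); must partition the positive edges
#'   entering the target
#' @return a \linkS4class{PathwayDecomposition}
#' @export
pathwayProbabilities <- function(Tm, source, target, channels) {
    stopifnot(is(Tm, "TransitionMatrix"))
    if (length(intersect(source, target)))
        stop("source and target must be disjoint")
    Tmat <- Tm@T
    isrc <- .stateIndices(Tmat, source, "source")
    itgt <- .stateIndices(Tmat, target, "target")
    lut <- .channelLookup(Tmat, source, target, channels)
    chn <- names(channels)
    m <- length(chn)
    n <- ncol(Tmat)
    P <- t(Tmat)                                   # row-stochastic
    trans <- setdiff(seq_len(n), c(isrc, itgt))
    lab <- colnames(Tmat)
    ## absorption matrix: P(first target entry uses channel c | start j)
    R <- matrix(0, length(trans), m, dimnames = list(lab[trans], chn))
    for (jj in seq_along(trans)) {
        j <- trans[jj]
        for (t in itgt) {
            p <- P[j, t]
            if (p > 0)
                R[jj, lut[[paste(lab[j], lab[t], sep = " -> ")]]] <-
                    R[jj, lut[[paste(lab[j], lab[t], sep = " -> ")]]] + p
        }
    }
    Phi <- if (length(trans))
        solve(diag(length(trans)) - P[trans, trans, drop = FALSE], R)
    else R
    rownames(Phi) <- lab[trans]
    ## first hop out of the source: off-diagonal outflux, normalised
    alpha <- setNames(numeric(m), chn)
    out_total <- 0
    for (s in isrc) {
        hop <- P[s, ]; hop[s] <- 0
        out_total <- out_total + sum(hop)
        for (j in trans) if (hop[j] > 0)
            alpha <- alpha + hop[j] * Phi[lab[j], ]
        for (t in itgt) if (hop[t] > 0) {
            ch <- lut[[paste(lab[s], lab[t], sep = " -> ")]]
            alpha[ch] <- alpha[ch] + hop[t]
        }
    }
    if (out_total <= 0) stop("source has no outgoing transitions")
    alpha <- alpha / out_total
    reactive <- sum(alpha)
    if (reactive <= 0)
        stop("zero reactive probability: no path reaches the target ",
             "before returning to the source")
    new("PathwayDecomposition", source = as.character(source),
        target = as.character(target), channels = channels,
        probabilities = alpha / reactive,
        fluxes = setNames(rep(NA_real_, m), chn),
        reactive_probability = reactive, absorption = Phi, tau = Tm@tau)
}

#' Per-channel bulk flux of a decomposed transition
#'
#' Converts the entry-channel decomposition into bulk fluxes (uM/s): the
#' flux through channel c is the source concentration times the rate of
#' first hops, weighted by the probability that the excursion ends in
#' channel c before returning to the source.  For the folding (U to N)
#' decomposition the direct-channel flux reduces exactly to
#' \code{k_fold * [U](t)}.
#'
#' @param decomposition a \linkS4class{PathwayDecomposition}
#' @param K the \linkS4class{RateMatrix} the decomposition was computed from
#' @param state the \linkS4class{ConcentrationState} giving bulk
#'   concentrations of the source states
#' @return named numeric vector of per-channel fluxes (uM/s)
#' @export
pathwayFlux <- function(decomposition, K, state) {
    stopifnot(is(decomposition, "PathwayDecomposition"),
              is(K, "RateMatrix"), is(state, "ConcentrationState"))
    Km <- K@K
    lab <- colnames(Km)
    if (!all(rownames(decomposition@absorption) %in% lab))
        stop("decomposition and rate matrix use different state spaces")
    chn <- names(decomposition@channels)
    lut <- .channelLookup(buildTransitionMatrix(K)@T, decomposition@source,
                          decomposition@target, decomposition@channels)
    Phi <- decomposition@absorption
    flux <- setNames(numeric(length(chn)), chn)
    for (s in decomposition@source) {
        bulk <- K@states$bulk_species[match(s, K@states$label)]
        cs <- state@conc[[bulk]]
        if (is.null(cs)) stop("no concentration for source state ", s)
        cs <- max(cs, 0)
        for (j in lab) {
            if (j == s) next
            rate <- Km[j, s]
            if (rate <= 0) next
            if (j %in% decomposition@target) {
                ch <- lut[[paste(s, j, sep = " -> ")]]
                flux[ch] <- flux[ch] + cs * rate
            } else if (j %in% rownames(Phi)) {
                flux <- flux + cs * rate * Phi[j, ]
            }
            ## hops back into the source set are unreactive
        }
    }
    flux
}

#' Full decomposition of one transition at the analysis time
#'
#' Convenience wrapper: builds the transition matrix, the default entry
#' channels, the channel probabilities and (if a concentration state is
#' given) the channel fluxes.
#'
#' @param K a \linkS4class{RateMatrix}
#' @param source,target state labels
#' @param state optional \linkS4class{ConcentrationState} for fluxes
#' @param channels optional channel list; defaults to
#'   \code{entryChannels(clientStates(K), target)}
#' @return a \linkS4class{PathwayDecomposition} with fluxes filled in when a
#'   state was supplied
#' @export
decomposeTransition <- function(K, source, target, state = NULL,
                                channels = NULL) {
    if (is.null(channels)) channels <- entryChannels(K@states, target)
    Tm <- buildTransitionMatrix(K)
    d <- pathwayProbabilities(Tm, source, target, channels)
    if (!is.null(state)) d@fluxes <- pathwayFlux(d, K, state)
    d
}

#' Mediation probability of a state set on reactive transition paths
#'
#' The fraction of reactive A-to-B transition paths that visit the mediator
#' set C, computed from conditional committors over the first hops out of A:
#' \code{m_C = sum_j T(j,A) h(j) / sum_j T(j,A) q_B(j)}.
#'
#' @param Tm a \linkS4class{TransitionMatrix}
#' @param A,B,C pairwise disjoint state-label sets
#' @return scalar mediation probability in [0, 1]
#' @export
mediationProbability <- function(Tm, A, B, C) {
    stopifnot(is(Tm, "TransitionMatrix"))
    cc <- conditionalCommittor(Tm, A, B, C)
    Tmat <- Tm@T
    ia <- .stateIndices(Tmat, A, "sink A")
    num <- den <- 0
    for (a in ia) {
        hop <- Tmat[, a]; hop[ia] <- 0
        num <- num + sum(hop * cc@h)
        den <- den + sum(hop * cc@committor@q_B)
    }
    if (den <= 0) stop("zero reactive probability out of A")
    num / den
}

#' Entrance rates from one state into a set of states
#'
#' Direct lookup of generator entries: the rate (s^-1) of the tagged
#' molecule's first-order transition from \code{from} into each requested
#' state at the frozen analysis time.
#'
#' @param K a \linkS4class{RateMatrix}
#' @param from a single state label
#' @param to_states state labels
#' @return named numeric vector of rates
#' @export
entranceRates <- function(K, from, to_states) {
    stopifnot(is(K, "RateMatrix"))
    lab <- colnames(K@K)
    if (!from %in% lab) stop("unknown state label '", from, "'")
    bad <- setdiff(to_states, lab)
    if (length(bad))
        stop("unknown state label(s): ", paste(bad, collapse = ", "))
    setNames(K@K[to_states, from], to_states)
}

#' Least-squares proportionality fit through the origin
#'
#' Fits y = c * x with \code{c = sum(x y) / sum(x^2)}.
#'
#' @param x,y numeric vectors, or \code{x} a data.frame with columns x and y
#' @return a \linkS4class{ProportionalityFit}
#' @export
fitProportionality <- function(x, y = NULL) {
    if (is.data.frame(x)) { y <- x$y; x <- x$x }
    stopifnot(length(x) == length(y), length(x) >= 1)
    keep <- is.finite(x) & is.finite(y)
    x <- x[keep]; y <- y[keep]
    if (!length(x) || all(x == 0)) stop("need at least one point with x != 0")
    slope <- sum(x * y) / sum(x^2)
    rss <- sum((y - slope * x)^2)
    tss <- sum((y - mean(y))^2)
    r2 <- if (tss > 0) 1 - rss / tss else if (rss == 0) 1 else NA_real_
    new("ProportionalityFit", slope = slope,
        points = data.frame(x = x, y = y), rss = rss, r_squared = r2)
}

#' @rdname PathwayDecomposition-accessors
#' @aliases channelProbabilities
#' @export
channelProbabilities <- function(d) d@probabilities

#' Accessors for PathwayDecomposition objects
#' @name PathwayDecomposition-accessors
#' @param d a \linkS4class{PathwayDecomposition}
#' @export
channelFluxes <- function(d) d@fluxes

#' @rdname PathwayDecomposition-accessors
#' @export
reactiveProbability <- function(d) d@reactive_probability

setMethod("show", "PathwayDecomposition", function(object) {
    cat("PathwayDecomposition: {",
        paste(object@source, collapse = ","), "} -> {",
        paste(object@target, collapse = ","), "}\n", sep = "")
    df <- data.frame(channel = names(object@probabilities),
                     probability = unname(object@probabilities),
                     flux = unname(object@fluxes))
    print(df, row.names = FALSE)
    cat("reactive probability:", object@reactive_probability, "\n")
})

setMethod("show", "ProportionalityFit", function(object) {
    cat(sprintf("ProportionalityFit: y = %.4g x (n = %d, RSS = %.3g, R2 = %.3f)\n",
                object@slope, nrow(object@points), object@rss,
                object@r_squared))
})
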