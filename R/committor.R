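#' Convert a rate matrix to a discrete transition matrix
#'
#' Off-diagonal entries of T are \code{K * tau}; diagonals complete the
#' columns to one.  The default step \code{tau = 1 / (2 * k_max)}, with
#' \code{k_max} the largest total exit rate, keeps every diagonal at least
#' one half, so the chain is aperiodic and all entries are proper
#' probabilities.  Committors are invariant to the choice of \code{tau}
#' (see the discretisation-invariance property tests).
#'
#' @param K a \linkS4class{RateMatrix}, or a plain square generator matrix
#'   with zero column sums
#' @param tau optional explicit time step (s); must not exceed 1 / k_max
#' @return a \linkS4class{TransitionMatrix}
#' @export
buildTransitionMatrix <- function(K, tau = NULL) {
    states <- if (is(K, "RateMatrix")) K@states else
        data.frame(label = colnames(K) %||% as.character(seq_len(ncol(K))),
                   stringsAsFactors = FALSE)
    Km <- if (is(K, "RateMatrix")) K@K else K
    if (is.null(colnames(Km)))
        dimnames(Km) <- list(states$label, states$label)
    k_max <- max(-diag(Km))
    if (!is.finite(k_max) || k_max <= 0)
        stop("empty dynamics: largest exit rate is not positive")
    if (is.null(tau)) tau <- 1 / (2 * k_max)
    if (tau <= 0 || tau > 1 / k_max)
        stop("tau must lie in (0, 1 / k_max]")
    Tm <- diag(nrow(Km)) + tau * Km
    dimnames(Tm) <- dimnames(Km)
    new("TransitionMatrix", T = Tm, tau = tau, k_max = k_max,
        states = states)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname RateMatrix-accessors
#' @export
transitionMatrix <- function(x) x@T

#' @rdname RateMatrix-accessors
#' @export
tauStep <- function(x) x@tau

setMethod("show", "TransitionMatrix", function(object) {
    cat("TransitionMatrix:", nrow(object@T), "states, tau =", object@tau,
        "s (k_max =", object@k_max, "/s)\n")
})

.stateIndices <- function(Tm, labels, what) {
    i <- match(labels, colnames(Tm))
    if (anyNA(i))
        stop("unknown ", what, " state(s): ",
             paste(labels[is.na(i)], collapse = ", "))
    i
}

## Install absorbing sinks: off-diagonals of the sink columns are zeroed and
## the diagonals set to one.
.withSinks <- function(Tm, sinks) {
    Tm[, sinks] <- 0
    Tm[cbind(sinks, sinks)] <- 1
    Tm
}

## Iteratively square a sink-modified transition matrix until the probability
## remaining in non-sink states is below tol; returns the powered matrix and
## the squaring count.
.absorb <- function(Tm, sink_idx, tol = 1e-12, max_squarings = 200L) {
    nonsink <- setdiff(seq_len(ncol(Tm)), sink_idx)
    M <- Tm
    for (it in seq_len(max_squarings)) {
        M <- M %*% M
        ## re-enforce column stochasticity: the roundoff in column sums
        ## otherwise doubles with every squaring
        M <- M * rep(1 / colSums(M), each = nrow(M))
        resid <- if (length(nonsink))
            max(colSums(M[nonsink, , drop = FALSE])) else 0
        if (resid < tol) return(list(M = M, iterations = it))
    }
    trapped <- nonsink[colSums(Tm[nonsink, nonsink, drop = FALSE] > 0) > 0]
    stuck <- nonsink[colSums(M[nonsink, , drop = FALSE]) >= tol]
    stop("absorption did not converge in ", max_squarings,
         " squarings; probability trapped in: ",
         paste(colnames(Tm)[utils::head(stuck, 10)], collapse = ", "))
}

#' Committor probabilities between two sink sets
#'
#' Installs absorbing sinks at the state sets A and B and computes, for every
#' starting state, the probability \code{q_B} of reaching B before A.  The
#' reference route iteratively squares the sink-modified transition matrix
#' until the probability remaining outside the sinks is below \code{tol};
#' a direct sparse-free linear solve of the first-step equations is available
#' as \code{method = "linear"} and is used to cross-check the squaring route.
#'
#' @param Tm a \linkS4class{TransitionMatrix}
#' @param A,B disjoint, nonempty sets of state labels
#' @param method "squaring" (default) or "linear"
#' @param tol residual non-sink probability at which squaring stops
#' @param max_squarings squaring cap; exceeding it signals trap states
#' @return a \linkS4class{CommittorResult}
#' @export
committor <- function(Tm, A, B, method = c("squaring", "linear"),
                      tol = 1e-12, max_squarings = 200L) {
    stopifnot(is(Tm, "TransitionMatrix"))
    method <- match.arg(method)
    if (!length(A) || !length(B)) stop("A and B must be nonempty")
    if (length(intersect(A, B))) stop("A and B must be disjoint")
    Tmat <- Tm@T
    ia <- .stateIndices(Tmat, A, "sink A")
    ib <- .stateIndices(Tmat, B, "sink B")
    n <- ncol(Tmat)
    if (method == "squaring") {
        M <- .absorb(.withSinks(Tmat, c(ia, ib)), c(ia, ib), tol,
                     max_squarings)
        q_B <- colSums(M$M[ib, , drop = FALSE])
        q_A <- colSums(M$M[ia, , drop = FALSE])
        iters <- M$iterations
    } else {
        P <- t(.withSinks(Tmat, c(ia, ib)))        # row-stochastic
        trans <- setdiff(seq_len(n), c(ia, ib))
        q_B <- numeric(n); q_B[ib] <- 1
        if (length(trans)) {
            rhs <- rowSums(P[trans, ib, drop = FALSE])
            q_B[trans] <- solve(diag(length(trans)) -
                                P[trans, trans, drop = FALSE], rhs)
        }
        q_A <- 1 - q_B
        iters <- 0L
    }
    names(q_B) <- names(q_A) <- colnames(Tmat)
    new("CommittorResult", A = as.character(A), B = as.character(B),
        q_B = pmin(pmax(q_B, 0), 1), q_A = pmin(pmax(q_A, 0), 1),
        iterations = as.integer(iters), method = method)
}

#' Conditional committors through a mediator set
#'
#' Splits the committor \code{q_B} by whether the trajectory visits the
#' mediator set C before absorbing: \code{h} (visited) and \code{hbar} (not
#' visited), with \code{h + hbar = q_B}.  Computed on a doubled state space
#' carrying a visited-C flag that is set on entry into any member of C (a
#' trajectory starting inside C counts as having visited it); sinks at A and
#' B exist in both ensembles.
#'
#' @param Tm a \linkS4class{TransitionMatrix}
#' @param A,B,C pairwise disjoint state-label sets; C may be empty
#' @param tol,max_squarings as in \code{\link{committor}}
#' @return a \linkS4class{ConditionalCommittorResult}
#' @export
conditionalCommittor <- function(Tm, A, B, C, tol = 1e-12,
                                 max_squarings = 200L) {
    stopifnot(is(Tm, "TransitionMatrix"))
    base <- committor(Tm, A, B, tol = tol, max_squarings = max_squarings)
    Tmat <- Tm@T
    n <- ncol(Tmat)
    if (!length(C)) {
        h <- setNames(numeric(n), colnames(Tmat))
        return(new("ConditionalCommittorResult", mediator = character(),
                   h = h, hbar = base@q_B, committor = base))
    }
    ic <- .stateIndices(Tmat, C, "mediator")
    ia <- .stateIndices(Tmat, A, "sink A")
    ib <- .stateIndices(Tmat, B, "sink B")
    if (length(intersect(ic, c(ia, ib))))
        stop("mediator set C must not overlap the sinks")
    S <- .withSinks(Tmat, c(ia, ib))
    ## doubled space: block 1 = C not yet visited, block 2 = visited.
    ## Entering a C state moves probability into block 2; block 2 is closed.
    D <- matrix(0, 2 * n, 2 * n)
    notC <- setdiff(seq_len(n), ic)
    D[notC, seq_len(n)] <- S[notC, ]
    D[n + ic, seq_len(n)] <- S[ic, ]
    D[n + seq_len(n), n + seq_len(n)] <- S
    sink_idx <- c(ia, ib, n + ia, n + ib)
    M <- .absorb(D, sink_idx, tol, max_squarings)$M
    start <- seq_len(n)
    start[ic] <- n + ic                     # starting inside C counts as visited
    h <- colSums(M[n + ib, , drop = FALSE])[start]
    hbar <- colSums(M[ib, , drop = FALSE])[start]
    names(h) <- names(hbar) <- colnames(Tmat)
    new("ConditionalCommittorResult", mediator = as.character(C),
        h = pmin(pmax(h, 0), 1), hbar = pmin(pmax(hbar, 0), 1),
        committor = base)
}

#' Stationary weights of a rate matrix
#'
#' Solves K w = 0 with w normalised to sum one.  States outside the single
#' recurrent class get weight zero; if the solution is not a probability
#' vector (multiple recurrent classes) an error reports the reducibility.
#'
#' @param K a \linkS4class{RateMatrix} or plain generator matrix
#' @return named nonnegative probability vector
#' @export
stationaryWeights <- function(K) {
    Km <- if (is(K, "RateMatrix")) K@K else K
    n <- ncol(Km)
    A <- Km
    A[n, ] <- 1
    b <- c(rep(0, n - 1), 1)
    w <- tryCatch(solve(A, b), error = function(e)
        stop("stationary weights: generator appears reducible (",
             conditionMessage(e), ")"))
    if (any(w < -1e-8 * max(abs(w))))
        stop("stationary weights: negative components; ",
             "multiple recurrent classes?")
    w <- pmax(w, 0)
    w <- w / sum(w)
    resid <- max(abs(Km %*% w))
    if (resid > 1e-8 * max(abs(Km)))
        warning("stationary weights residual ", signif(resid, 3))
    setNames(w, colnames(Km))
}

setMethod("show", "CommittorResult", function(object) {
    cat("CommittorResult: q_B = P(reach {",
        paste(object@B, collapse = ","), "} before {",
        paste(object@A, collapse = ","), "})\n", sep = "")
    cat("  method:", object@method,
        if (object@method == "squaring")
            paste0("(", object@iterations, " squarings)"), "\n")
})

setMethod("show", "ConditionalCommittorResult", function(object) {
    cat("ConditionalCommittorResult: mediator {",
        paste(object@mediator, collapse = ","), "}\n", sep = "")
})
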