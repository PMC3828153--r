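#' Sample first-passage paths of the tagged molecule
#'
#' Exact continuous-time jump-chain sampling on the frozen generator: from
#' state j the next state is drawn proportionally to the off-diagonal rates
#' K(., j) and the holding time is exponential with the total exit rate.
#' Paths start with one hop drawn from the source's normalised outflux
#' distribution and end on first entry into any sink state (include the
#' source among the sinks to realise reactive-path conditioning).  Each path
#' is seeded independently from \code{seed} and its index, so any single
#' path can be reproduced in isolation.
#'
#' @param K a \linkS4class{RateMatrix} or plain generator matrix
#' @param source a single source state label
#' @param sinks character vector of absorbing state labels
#' @param n number of paths
#' @param seed integer seed
#' @param max_steps truncation cap per path (default 1e6); truncated paths
#'   are flagged, not dropped
#' @param record_times record exponential holding times (default TRUE)
#' @param mediators optional named list of state-label sets; each path
#'   records which sets it visited
#' @return list with elements \code{paths} (list of per-path records with
#'   states, holding times, terminal, entry edge, visited flags, truncated)
#'   and \code{labels}
#' @export
sampleFirstPassagePaths <- function(K, source, sinks, n, seed = 1L,
                                    max_steps = 1e6, record_times = TRUE,
                                    mediators = list()) {
    Km <- if (is(K, "RateMatrix")) K@K else K
    lab <- colnames(Km)
    stopifnot(n >= 1, length(source) == 1)
    is_ <- match(source, lab)
    isnk <- match(sinks, lab)
    if (anyNA(c(is_, isnk))) stop("unknown source or sink label")
    ns <- ncol(Km)
    ## per-state jump distributions
    exit <- -diag(Km)
    Pjump <- Km; diag(Pjump) <- 0
    cum <- vector("list", ns)
    targets <- vector("list", ns)
    for (j in seq_len(ns)) {
        w <- Pjump[, j]
        nz <- which(w > 0)
        targets[[j]] <- nz
        cum[[j]] <- cumsum(w[nz]) / sum(w[nz])
    }
    if (!length(targets[[is_]]))
        stop("source has no outgoing transitions")
    med_idx <- lapply(mediators, function(s) match(s, lab))
    sink_set <- logical(ns); sink_set[isnk] <- TRUE
    paths <- vector("list", n)
    for (p in seq_len(n)) {
        set.seed((seed * 1000003L + p) %% .Machine$integer.max)
        states <- integer(64); times <- numeric(64)
        cur <- is_
        len <- 0L
        truncated <- TRUE
        repeat {
            if (len >= max_steps) break
            if (record_times && exit[cur] > 0)
                tm <- rexp(1, exit[cur]) else tm <- 0
            nxt <- targets[[cur]][findInterval(runif(1), cum[[cur]],
                                              left.open = TRUE) + 1L]
            len <- len + 1L
            if (len > length(states)) {
                states <- c(states, integer(length(states)))
                times <- c(times, numeric(length(times)))
            }
            states[len] <- nxt; times[len] <- tm
            cur <- nxt
            if (sink_set[cur]) { truncated <- FALSE; break }
        }
        seqs <- states[seq_len(len)]
        visited <- vapply(med_idx, function(ii) any(seqs %in% ii), logical(1))
        paths[[p]] <- list(states = seqs,
                           holding_times = if (record_times)
                               times[seq_len(len)] else numeric(),
                           start = source,
                           terminal = if (!truncated) lab[cur] else NA_character_,
                           entry_from = if (!truncated && len >= 2)
                               lab[seqs[len - 1L]] else if (!truncated)
                               source else NA_character_,
                           visited = visited,
                           truncated = truncated,
                           seed = seed, index = p)
    }
    list(paths = paths, labels = lab, source = source, sinks = sinks)
}

#' Estimate an entry-channel decomposition from sampled paths
#'
#' Counts reactive paths (terminating in the target set) per entry channel
#' and reports binomial fractions with standard errors.  Paths terminating
#' at the source (returns) and truncated paths are counted separately.
#'
#' @param samples result of \code{\link{sampleFirstPassagePaths}}
#' @param channels named list of entry-edge data.frames (columns from, to)
#' @param target target state labels (defaults to all sinks except the
#'   source)
#' @return list with \code{fractions}, \code{se}, \code{counts},
#'   \code{n_reactive}, \code{n_return}, \code{n_truncated}
#' @export
estimateDecomposition <- function(samples, channels, target = NULL) {
    if (is.null(target)) target <- setdiff(samples$sinks, samples$source)
    key <- function(f, t) paste(f, t, sep = " -> ")
    lut <- character()
    for (ch in names(channels)) {
        e <- channels[[ch]]
        lut[key(e$from, e$to)] <- ch
    }
    counts <- setNames(numeric(length(channels)), names(channels))
    n_return <- 0L; n_trunc <- 0L
    for (p in samples$paths) {
        if (p$truncated) { n_trunc <- n_trunc + 1L; next }
        if (!p$terminal %in% target) { n_return <- n_return + 1L; next }
        ch <- lut[[key(p$entry_from, p$terminal)]]
        if (is.null(ch)) stop("no channel for entry edge ",
                              key(p$entry_from, p$terminal))
        counts[ch] <- counts[ch] + 1
    }
    nr <- sum(counts)
    if (nr == 0) stop("no reactive paths sampled")
    frac <- counts / nr
    list(fractions = frac,
         se = sqrt(pmax(frac * (1 - frac), 0) / nr),
         counts = counts, n_reactive = nr, n_return = n_return,
         n_truncated = n_trunc)
}

#' Monte-Carlo committor estimate from sampled paths
#'
#' @param samples result of \code{\link{sampleFirstPassagePaths}}
#' @param B target sink labels
#' @return list with the estimated probability of absorbing in B and its
#'   standard error
#' @export
estimateCommittor <- function(samples, B) {
    term <- vapply(samples$paths, function(p)
        if (p$truncated) NA_character_ else p$terminal, character(1))
    ok <- !is.na(term)
    nr <- sum(ok)
    if (!nr) stop("no absorbed paths")
    p <- mean(term[ok] %in% B)
    list(estimate = p, se = sqrt(p * (1 - p) / nr), n = nr)
}
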