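## Independent oracles and shared fixtures for the committor/mediation tests.
## Everything here is written from first principles (plain linear algebra and
## step-by-step probability propagation) so it never shares code paths with
## the package's squaring engine.

## Random generator matrix: nonnegative off-diagonals, zero column sums,
## irreducible with high probability (dense positive rates).
randomGenerator <- function(n, seed, scale = 1) {
    set.seed(seed)
    K <- matrix(runif(n * n, 0.05, 1) * scale, n, n)
    diag(K) <- 0
    diag(K) <- -colSums(K)
    dimnames(K) <- list(paste0("s", seq_len(n)), paste0("s", seq_len(n)))
    K
}

## Committor oracle: solve the first-step equations of the embedded jump
## chain of K directly (independent of any time discretisation).
oracleCommittor <- function(K, A, B) {
    lab <- colnames(K)
    n <- ncol(K)
    ia <- match(A, lab); ib <- match(B, lab)
    exit <- -diag(K)
    P <- t(K); diag(P) <- 0
    P <- P / ifelse(exit > 0, exit, 1)      # row-stochastic jump chain
    q <- numeric(n); q[ib] <- 1
    trans <- setdiff(seq_len(n), c(ia, ib))
    if (length(trans)) {
        q[trans] <- solve(diag(length(trans)) - P[trans, trans, drop = FALSE],
                          rowSums(P[trans, ib, drop = FALSE]))
    }
    setNames(q, lab)
}

## Conditional-committor oracle: step-by-step propagation of (state,
## visited-C) probability mass on the discrete chain T until the unabsorbed
## mass is below tol.  The geometric decay of the unabsorbed mass bounds the
## truncation error by tol.
oracleConditional <- function(Tm, A, B, C, tol = 1e-13, max_steps = 1e6) {
    lab <- colnames(Tm)
    n <- ncol(Tm)
    ia <- match(A, lab); ib <- match(B, lab); ic <- match(C, lab)
    S <- Tm
    S[, c(ia, ib)] <- 0
    S[cbind(c(ia, ib), c(ia, ib))] <- 1
    h <- hbar <- numeric(n)
    for (s in seq_len(n)) {
        ## mass vectors over (state, flag)
        p0 <- numeric(n); p1 <- numeric(n)
        if (s %in% ic) p1[s] <- 1 else p0[s] <- 1
        absorbed_b0 <- absorbed_b1 <- 0
        for (step in seq_len(max_steps)) {
            q0 <- drop(S %*% p0)
            q1 <- drop(S %*% p1)
            ## entering C flips the flag
            q1[ic] <- q1[ic] + q0[ic]
            q0[ic] <- 0
            ## harvest sink mass and clear it so it is counted once
            absorbed_b0 <- absorbed_b0 + sum(q0[ib])
            absorbed_b1 <- absorbed_b1 + sum(q1[ib])
            q0[c(ia, ib)] <- 0
            q1[c(ia, ib)] <- 0
            p0 <- q0; p1 <- q1
            if (sum(p0) + sum(p1) < tol) break
        }
        h[s] <- absorbed_b1
        hbar[s] <- absorbed_b0
    }
    list(h = setNames(h, lab), hbar = setNames(hbar, lab))
}

## Expected number of visits to each transient state of the discrete chain
## T with absorbing set `sinks`, starting from `start`: fundamental matrix
## N = (I - Q)^-1 of the jump chain.
oracleVisits <- function(K, start, sinks) {
    lab <- colnames(K)
    exit <- -diag(K)
    P <- t(K); diag(P) <- 0
    P <- P / ifelse(exit > 0, exit, 1)
    trans <- setdiff(seq_len(ncol(K)), match(sinks, lab))
    N <- solve(diag(length(trans)) - P[trans, trans, drop = FALSE])
    setNames(N[match(start, lab[trans]), ], lab[trans])
}

## Shared expensive fixtures, computed once per test file.
.fixture_env <- new.env()

defaultRun <- function() {
    if (is.null(.fixture_env$default)) {
        model <- buildModel(proteinProfile("Default"), chaperoneLevels(),
                            modelOptions())
        cfg <- analysisConfig()
        traj <- propagateModel(model, cfg)
        st <- stateAt(traj, cfg@t_eval)
        K <- extractRateMatrix(model, st)
        .fixture_env$default <- list(model = model, cfg = cfg, traj = traj,
                                     state = st, K = K,
                                     Tm = buildTransitionMatrix(K))
    }
    .fixture_env$default
}

## The canonical mediation toy: M -> U direct and M -> X -> U with return.
mediationToy <- function() {
    K <- matrix(0, 3, 3, dimnames = list(c("M", "X", "U"), c("M", "X", "U")))
    K["U", "M"] <- 1; K["X", "M"] <- 1
    K["U", "X"] <- 1; K["M", "X"] <- 1
    diag(K) <- -colSums(K)
    K
}
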