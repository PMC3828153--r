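test_that("transition matrix construction follows tau = 1/(2 k_max)", {
    K <- matrix(c(-2, 2, 1, -1), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
    Tm <- buildTransitionMatrix(K)
    expect_equal(Tm@k_max, 2)
    expect_equal(Tm@tau, 0.25)
    expect_equal(unname(Tm@T), matrix(c(0.5, 0.5, 0.25, 0.75), 2, 2))
    ## an absorbing state keeps diagonal one
    K2 <- matrix(c(-1, 1, 0, 0), 2, 2,
                 dimnames = list(c("a", "b"), c("a", "b")))
    Tm2 <- buildTransitionMatrix(K2)
    expect_equal(Tm2@T["b", "b"], 1)
    ## the half factor keeps all diagonals at least 1/2
    for (seed in 1:5) {
        Tr <- buildTransitionMatrix(randomGenerator(7, seed))
        expect_gte(min(diag(Tr@T)), 0.5)
    }
})

test_that("committors reproduce closed forms on branch and chain toys", {
    ## A <- i -> B with rates 3 and 1: q_B(i) = 1/4
    K <- matrix(0, 3, 3, dimnames = list(c("A", "i", "B"), c("A", "i", "B")))
    K["A", "i"] <- 3; K["B", "i"] <- 1
    diag(K) <- -colSums(K)
    q <- committor(buildTransitionMatrix(K), "A", "B")
    expect_equal(q@q_B[["i"]], 0.25, tolerance = 1e-12)
    expect_equal(q@q_B[["A"]], 0)
    expect_equal(q@q_B[["B"]], 1)
    ## birth-death chain A - 1 - 2 - B, all rates equal: linear profile
    Kc <- matrix(0, 4, 4, dimnames = list(c("A", "s1", "s2", "B"),
                                          c("A", "s1", "s2", "B")))
    Kc["A", "s1"] <- 1; Kc["s2", "s1"] <- 1
    Kc["s1", "s2"] <- 1; Kc["B", "s2"] <- 1
    Kc["s1", "A"] <- 1; Kc["s2", "B"] <- 1
    diag(Kc) <- 0; diag(Kc) <- -colSums(Kc)
    qc <- committor(buildTransitionMatrix(Kc), "A", "B")
    expect_equal(unname(qc@q_B), c(0, 1/3, 2/3, 1), tolerance = 1e-10)
})

test_that("squaring and linear routes agree with the jump-chain oracle on
           random generators", {
    for (seed in 1:10) {
        n <- sample(4:12, 1)
        K <- randomGenerator(n, seed)
        Tm <- buildTransitionMatrix(K)
        A <- "s1"; B <- c("s2", if (n > 6) "s3")
        qs <- committor(Tm, A, B, method = "squaring")
        ql <- committor(Tm, A, B, method = "linear")
        qo <- oracleCommittor(K, A, B)
        expect_lt(max(abs(qs@q_B - ql@q_B)), 1e-8)
        expect_lt(max(abs(qs@q_B - qo)), 1e-8)
        expect_lt(max(abs(qs@q_A + qs@q_B - 1)), 1e-10)
    }
})

test_that("conditional committors satisfy forced mediation and the empty
           mediator limits", {
    ## every x -> B path passes through C
    K <- matrix(0, 4, 4, dimnames = list(c("x", "A", "B", "C"),
                                         c("x", "A", "B", "C")))
    K["A", "x"] <- 1; K["C", "x"] <- 1
    K["x", "C"] <- 1; K["B", "C"] <- 1
    diag(K) <- -colSums(K)
    Tm <- buildTransitionMatrix(K)
    cc <- conditionalCommittor(Tm, "A", "B", "C")
    expect_equal(cc@h[["x"]], cc@committor@q_B[["x"]], tolerance = 1e-10)
    expect_equal(cc@hbar[["x"]], 0, tolerance = 1e-12)
    ## empty mediator: nothing is ever visited
    cc0 <- conditionalCommittor(Tm, "A", "B", character())
    expect_equal(unname(cc0@h), rep(0, 4))
    expect_equal(cc0@hbar, cc0@committor@q_B)
})

test_that("conditional committors match step-by-step propagation with a
           direct bypass edge", {
    K <- matrix(0, 4, 4, dimnames = list(c("x", "A", "B", "C"),
                                         c("x", "A", "B", "C")))
    K["A", "x"] <- 1; K["C", "x"] <- 1; K["B", "x"] <- 1
    K["x", "C"] <- 1; K["B", "C"] <- 1
    diag(K) <- -colSums(K)
    Tm <- buildTransitionMatrix(K)
    cc <- conditionalCommittor(Tm, "A", "B", "C")
    or <- oracleConditional(Tm@T, "A", "B", "C")
    expect_lt(max(abs(cc@h - or$h)), 1e-8)
    expect_lt(max(abs(cc@hbar - or$hbar)), 1e-8)
    expect_lt(max(abs(cc@h + cc@hbar - cc@committor@q_B)), 1e-10)
})

test_that("conditional committors match the oracle on random generators", {
    for (seed in 11:16) {
        n <- sample(5:10, 1)
        K <- randomGenerator(n, seed)
        Tm <- buildTransitionMatrix(K)
        cc <- conditionalCommittor(Tm, "s1", "s2", c("s3", "s4"))
        or <- oracleConditional(Tm@T, "s1", "s2", c("s3", "s4"))
        expect_lt(max(abs(cc@h - or$h)), 1e-8)
        expect_lt(max(abs(cc@hbar - or$hbar)), 1e-8)
    }
})

test_that("enlarging the target sink never decreases q_B", {
    for (seed in 21:25) {
        K <- randomGenerator(9, seed)
        Tm <- buildTransitionMatrix(K)
        q1 <- committor(Tm, "s1", "s2")@q_B
        q2 <- committor(Tm, "s1", c("s2", "s5"))@q_B
        expect_true(all(q2 >= q1 - 1e-10))
    }
})

test_that("committors are invariant to tau refinement", {
    for (seed in 31:33) {
        K <- randomGenerator(8, seed)
        Tm <- buildTransitionMatrix(K)
        Tm2 <- buildTransitionMatrix(K, tau = Tm@tau / 2)
        q1 <- committor(Tm, "s1", "s2")@q_B
        q2 <- committor(Tm2, "s1", "s2")@q_B
        expect_lt(max(abs(q1 - q2)), 1e-6)
    }
})

test_that("stationary weights solve K w = 0", {
    K <- matrix(c(-2, 2, 1, -1), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
    w <- stationaryWeights(K)
    expect_equal(unname(w), c(1/3, 2/3), tolerance = 1e-12)
    for (seed in 41:45) {
        Kr <- randomGenerator(10, seed)
        wr <- stationaryWeights(Kr)
        expect_equal(sum(wr), 1, tolerance = 1e-12)
        expect_true(all(wr >= 0))
        expect_lt(max(abs(Kr %*% wr)), 1e-10 * max(abs(Kr)))
    }
})

test_that("degenerate inputs are rejected", {
    K <- matrix(c(-1, 1, 0.5, -0.5), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
    Tm <- buildTransitionMatrix(K)
    expect_error(committor(Tm, "a", "a"), "disjoint")
    expect_error(committor(Tm, character(), "a"), "nonempty")
    expect_error(committor(Tm, "a", "zz"), "unknown")
    expect_error(conditionalCommittor(Tm, "a", "b", "a"), "overlap")
    expect_error(buildTransitionMatrix(matrix(0, 2, 2)), "empty dynamics")
})
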