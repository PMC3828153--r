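test_that("absorption fractions match the closed form on the branch toy", {
    K <- matrix(0, 3, 3, dimnames = list(c("A", "i", "B"), c("A", "i", "B")))
    K["A", "i"] <- 3; K["B", "i"] <- 1
    diag(K) <- -colSums(K)
    n <- 1e4
    s <- sampleFirstPassagePaths(K, "i", c("A", "B"), n = n, seed = 7,
                                 record_times = FALSE)
    est <- estimateCommittor(s, "B")
    se <- sqrt(0.25 * 0.75 / n)
    expect_lt(abs(est$estimate - 0.25), 3 * se)
    expect_equal(est$n, n)
})

test_that("path sampling is reproducible under a fixed seed", {
    K <- mediationToy()
    s1 <- sampleFirstPassagePaths(K, "M", c("M", "U"), n = 50, seed = 11)
    s2 <- sampleFirstPassagePaths(K, "M", c("M", "U"), n = 50, seed = 11)
    expect_identical(lapply(s1$paths, `[[`, "states"),
                     lapply(s2$paths, `[[`, "states"))
    s3 <- sampleFirstPassagePaths(K, "M", c("M", "U"), n = 50, seed = 12)
    expect_false(identical(lapply(s1$paths, `[[`, "states"),
                           lapply(s3$paths, `[[`, "states")))
    ## holding times are exponential draws tied to the same stream
    expect_true(all(vapply(s1$paths, function(p)
        all(p$holding_times >= 0), logical(1))))
})

test_that("decomposition estimates count entry edges", {
    fake <- list(paths = list(
        list(terminal = "U", entry_from = "M", truncated = FALSE),
        list(terminal = "U", entry_from = "M", truncated = FALSE),
        list(terminal = "U", entry_from = "M", truncated = FALSE),
        list(terminal = "U", entry_from = "X", truncated = FALSE)),
        labels = c("M", "X", "U"), source = "M", sinks = c("M", "U"))
    est <- estimateDecomposition(fake,
        list(direct = data.frame(from = "M", to = "U"),
             viaX = data.frame(from = "X", to = "U")))
    expect_equal(unname(est$fractions), c(0.75, 0.25))
    expect_equal(est$n_reactive, 4)
    ## all paths in one channel: fraction one, zero standard error
    fake1 <- fake; fake1$paths <- fake$paths[1:3]
    est1 <- estimateDecomposition(fake1,
        list(direct = data.frame(from = "M", to = "U"),
             viaX = data.frame(from = "X", to = "U")))
    expect_equal(est1$fractions[["direct"]], 1)
    expect_equal(est1$se[["direct"]], 0)
})

test_that("sampled channel fractions agree with the matrix decomposition on
           the toy", {
    K <- mediationToy()
    Tm <- buildTransitionMatrix(K)
    channels <- list(direct = data.frame(from = "M", to = "U"),
                     viaX = data.frame(from = "X", to = "U"))
    d <- pathwayProbabilities(Tm, "M", "U", channels)
    s <- sampleFirstPassagePaths(K, "M", c("M", "U"), n = 1e4, seed = 3,
                                 record_times = FALSE)
    est <- estimateDecomposition(s, channels)
    for (ch in names(channels)) {
        se <- max(est$se[[ch]], 1e-3)
        expect_lt(abs(est$fractions[[ch]] - d@probabilities[[ch]]), 3.5 * se)
    }
    ## reactive fraction among sampled paths matches 3/4
    n_tot <- est$n_reactive + est$n_return
    expect_lt(abs(est$n_reactive / n_tot - 0.75),
              3.5 * sqrt(0.75 * 0.25 / n_tot))
})

test_that("mean visit counts match the fundamental matrix on a chain", {
    K <- matrix(0, 4, 4, dimnames = list(c("A", "s1", "s2", "B"),
                                         c("A", "s1", "s2", "B")))
    K["A", "s1"] <- 1; K["s2", "s1"] <- 1
    K["s1", "s2"] <- 1; K["B", "s2"] <- 1
    diag(K) <- -colSums(K)
    n <- 4000
    s <- sampleFirstPassagePaths(K, "s1", c("A", "B"), n = n, seed = 5,
                                 record_times = FALSE)
    visits <- sapply(c("s1", "s2"), function(st) {
        i <- match(st, s$labels)
        mean(vapply(s$paths, function(p)
            sum(p$states == i) + (st == "s1"), numeric(1)))
    })
    expected <- oracleVisits(K, "s1", c("A", "B"))
    for (st in c("s1", "s2")) {
        se <- stats::sd(vapply(s$paths, function(p)
            sum(p$states == match(st, s$labels)), numeric(1))) / sqrt(n)
        expect_lt(abs(visits[[st]] - expected[[st]]), 3.5 * max(se, 1e-3))
    }
})

test_that("visited-mediator flags are recorded per path", {
    K <- matrix(0, 4, 4, dimnames = list(c("x", "A", "B", "C"),
                                         c("x", "A", "B", "C")))
    K["A", "x"] <- 1; K["C", "x"] <- 1
    K["x", "C"] <- 1; K["B", "C"] <- 1
    diag(K) <- -colSums(K)
    s <- sampleFirstPassagePaths(K, "x", c("A", "B"), n = 500, seed = 9,
                                 mediators = list(viaC = "C"),
                                 record_times = FALSE)
    reactive <- Filter(function(p) identical(p$terminal, "B"), s$paths)
    expect_gt(length(reactive), 0)
    ## every x -> B path must pass through C
    expect_true(all(vapply(reactive, function(p) p$visited[["viaC"]],
                           logical(1))))
})
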