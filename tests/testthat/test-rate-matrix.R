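smallModel <- function(double = FALSE, systems = c("KJE", "GroELS", "B+KJE",
                                                   "TriggerFactor",
                                                   "Degradation")) {
    buildModel(proteinProfile("Default"), chaperoneLevels(),
               modelOptions(n_max = 3, double_occupancy = double,
                            enabled_systems = systems))
}

test_that("client-state enumeration is exhaustive and deterministic", {
    m <- smallModel(double = FALSE)
    st <- enumerateClientStates(m)
    expected <- c("Null", "U", "N", "M", "TF:U", "Lon:U", "Lon:M",
                  "KT:U", "KT:M", "U:J:KT", "U:J:KD", "KD:U",
                  "GrLT:U", "GrLT:M",
                  "GrLd:{U}:GrS", "GrLd:{N}:GrS", "GrLd:{M}:GrS",
                  "A2", "A3", "A2*", "A3*")
    expect_setequal(st$label, expected)
    expect_equal(nrow(st), 21L)
    expect_false(anyDuplicated(st$label) > 0)
    expect_identical(st$label, enumerateClientStates(m)$label)
})

test_that("double occupancy adds six cis-tagged and six trans-tagged states", {
    st0 <- enumerateClientStates(smallModel(FALSE))
    st1 <- enumerateClientStates(smallModel(TRUE))
    added <- setdiff(st1$label, st0$label)
    expect_length(added, 12L)
    expect_setequal(added, c(
        "GrLd:{U,u}:GrS", "GrLd:{U,m}:GrS", "GrLd:{N,u}:GrS",
        "GrLd:{N,m}:GrS", "GrLd:{M,u}:GrS", "GrLd:{M,m}:GrS",
        "GrLd:{u,U}:GrS", "GrLd:{u,M}:GrS", "GrLd:{n,U}:GrS",
        "GrLd:{n,M}:GrS", "GrLd:{m,U}:GrS", "GrLd:{m,M}:GrS"))
    ## every multi-client bulk species maps to exactly two tagged states
    doubles <- st1[st1$position != "", ]
    expect_true(all(table(doubles$bulk_species) == 2))
})

test_that("knockout removes no states, only rates", {
    m <- smallModel()
    ko <- knockoutSystem(m, "GroELS")
    expect_identical(enumerateClientStates(ko)$label,
                     enumerateClientStates(m)$label)
    traj <- propagateModel(ko, analysisConfig(t_eval = 100))
    K <- extractRateMatrix(ko, stateAt(traj, 100))
    ## all binding rates into GroEL complexes vanish with the chaperone
    expect_equal(K@K["GrLT:U", "U"], 0)
    expect_equal(K@K["GrLT:M", "M"], 0)
})

test_that("frozen bimolecular rates are pseudo-first-order in the partner", {
    m <- defaultRun()$model
    st <- defaultRun()$state
    K <- defaultRun()$K
    kc <- constants(m)
    expect_equal(K@K["KT:M", "M"], kc[["k_KM_on"]] * st@conc[["KT"]])
    expect_equal(K@K["GrLT:U", "U"], kc[["k_GU_on"]] * st@conc[["GrLT"]])
    expect_equal(K@K["TF:U", "U"], kc[["k_tf_on"]] * st@conc[["TF"]])
    ## tagged dimerisation is linearised with the bulk [M]
    expect_equal(K@K["A2", "M"], kc[["k_ag"]] * st@conc[["M"]])
    ## doubling a partner concentration doubles the frozen rate
    st2 <- st
    st2@conc[["KT"]] <- 2 * st@conc[["KT"]]
    K2 <- extractRateMatrix(m, st2)
    expect_equal(K2@K["KT:M", "M"], 2 * K@K["KT:M", "M"])
    expect_equal(K2@K["KT:U", "U"], 2 * K@K["KT:U", "U"])
})

test_that("monomer removal from aggregates follows the 1/n rule", {
    run <- defaultRun()
    K <- run$K@K
    kc <- constants(run$model)
    extr <- kc[["k_extract"]] * run$state@conc[["ClpB"]]
    ## tagged monomer leaves a prepared trimer with probability 1/3
    expect_equal(K["U", "A3*"], extr / 3)
    expect_equal(K["A2", "A3*"], extr * 2 / 3)
    ## prepared dimer dissolution: extracted unfolded or returned misfolded
    expect_equal(K["U", "A2*"], extr / 2)
    expect_equal(K["M", "A2*"], extr / 2)
    ## passive shrinkage of a plain aggregate
    expect_equal(K["M", "A3"], kc[["k_dis"]] / 3)
    expect_equal(K["A2", "A3"], kc[["k_dis"]] * 2 / 3)
    expect_equal(K["M", "A2"], kc[["k_dis"]])
})

test_that("columns of the frozen generator sum to zero", {
    K <- defaultRun()$K@K
    expect_lt(max(abs(colSums(K))), 1e-12 * max(abs(K)))
    off <- K; diag(off) <- 0
    expect_true(all(off >= 0))
})

test_that("a hand-built two-state generator is reproduced", {
    K <- matrix(c(-2, 2, 1, -1), 2, 2,
                dimnames = list(c("U", "N"), c("U", "N")))
    Tm <- buildTransitionMatrix(K)
    expect_equal(colSums(K), c(U = 0, N = 0))
    expect_equal(Tm@k_max, 2)
})

test_that("rate matrices round-trip through the sparse-triplet writer", {
    run <- defaultRun()
    tp <- tempfile(fileext = ".csv"); sp <- tempfile(fileext = ".csv")
    writeRateMatrix(run$K, tp, sp)
    K2 <- readRateMatrix(tp, sp)
    expect_identical(colnames(K2@K), colnames(run$K@K))
    expect_equal(K2@K, run$K@K, tolerance = 1e-12)
    unlink(c(tp, sp))
})
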