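## A closed toy: synthesis off, misfolding and aggregation switched off by
## overrides, so only U <-> N is active; start from pure unfolded protein.
twoStateModel <- function(k_fold = 1, k_unfold = 0.01, c0 = 10) {
    m <- buildModel(proteinProfile("Default"), chaperoneLevels(),
                    modelOptions(ribosome_activation_rate = 0),
                    overrides = c(k_fold = k_fold, k_unfold = k_unfold,
                                  k_mis = 0, k_ag = 0, k_lon_on = 0,
                                  k_tf_on = 0, k_KU_on = 0, k_GU_on = 0))
    y0 <- initialState(m)
    y0[["U"]] <- c0
    list(model = m, y0 = y0)
}

test_that("closed two-state system relaxes to the analytic equilibrium", {
    tw <- twoStateModel()
    traj <- propagateModel(tw$model, analysisConfig(t_eval = 1e3), y0 = tw$y0)
    st <- stateAt(traj, 1e3)
    native_fraction <- st@conc[["N"]] / (st@conc[["N"]] + st@conc[["U"]])
    ## K / (1 + K) with K = k_fold / k_unfold = 100
    expect_equal(native_fraction, 100 / 101, tolerance = 1e-8)
    expect_equal(st@conc[["M"]], 0)
})

test_that("with no client and synthesis disabled, zero is a fixed point", {
    m <- buildModel(options = modelOptions(ribosome_activation_rate = 0))
    traj <- propagateModel(m, analysisConfig(t_eval = 100))
    cl <- conservationGroups(m)$client
    client_species <- setdiff(names(cl), "Null")
    expect_true(all(abs(traj@conc[, client_species]) < 1e-12))
})

test_that("three-state equilibrium holds with chaperones knocked out and
           aggregation disabled", {
    m <- buildModel(proteinProfile("Default"), chaperoneLevels(),
                    modelOptions(ribosome_activation_rate = 0),
                    overrides = c(k_ag = 0))
    for (s in c("KJE", "GroELS", "B+KJE", "TriggerFactor", "Degradation"))
        m <- knockoutSystem(m, s)
    y0 <- initialState(m)
    y0[["U"]] <- 5
    traj <- propagateModel(m, analysisConfig(t_eval = 1e7), y0 = y0)
    st <- stateAt(traj, 1e7)
    ## N : U = K_fold, M : U = K_mis
    expect_equal(st@conc[["N"]] / st@conc[["U"]], 1e4, tolerance = 1e-4)
    expect_equal(st@conc[["M"]] / st@conc[["U"]], 100, tolerance = 1e-4)
})

test_that("conservation groups hold along the default trajectory", {
    run <- defaultRun()
    chk <- conservationCheck(run$traj)
    expect_true(all(!chk$flagged))
    expect_true(all(chk$max_rel_drift < 1e-6))
    ## the output grid contains the analysis time exactly
    expect_true(any(run$traj@times == run$cfg@t_eval))
})

test_that("a corrupted state flags exactly its conservation group", {
    run <- defaultRun()
    traj <- run$traj
    traj@conc[nrow(traj@conc), "KT"] <-
        traj@conc[nrow(traj@conc), "KT"] + 1
    chk <- conservationCheck(traj, run$model)
    expect_true(chk$flagged[chk$group == "DnaK"])
    expect_false(chk$flagged[chk$group == "GroEL"])
})

test_that("halving integrator tolerances leaves t_eval concentrations
           unchanged to 1e-4 relative", {
    m <- defaultRun()$model
    c1 <- stateAt(propagateModel(m, analysisConfig()), 1e4)@conc
    c2 <- stateAt(propagateModel(m, analysisConfig(rtol = 5e-9,
                                                   atol = 5e-11)), 1e4)@conc
    big <- c1 > 1e-10
    expect_lt(max(abs(c1[big] - c2[big]) / c1[big]), 1e-4)
})

test_that("species summary counts client stoichiometry", {
    run <- defaultRun()
    st <- run$state
    conc <- st@conc * 0
    conc[["A3"]] <- 2; conc[["A2"]] <- 1
    fake <- new("ConcentrationState", time = 0, conc = conc)
    s <- speciesSummary(fake, run$model)
    expect_equal(s[["aggregated_monomers"]], 8)
    expect_equal(s[["insoluble_fraction"]], 1)
    ## complexed native counts toward the conformer total, not free native
    conc2 <- st@conc * 0
    conc2[["N"]] <- 1; conc2[["GrLd:{N}:GrS"]] <- 1
    s2 <- speciesSummary(new("ConcentrationState", time = 0, conc = conc2),
                         run$model)
    expect_equal(s2[["native"]], 1)
    expect_equal(s2[["native_total"]], 2)
    expect_equal(s2[["insoluble_fraction"]], 0)
})

test_that("client mass balances synthesis against degradation", {
    run <- defaultRun()
    ## the client group (including the Null reservoir) is exactly conserved
    cl <- conservationGroups(run$model)$client
    tot <- drop(run$traj@conc[, names(cl)] %*% cl)
    expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-9)
})
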