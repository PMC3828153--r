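mkModel <- function(...) buildModel(proteinProfile("Default"),
                                    chaperoneLevels(), modelOptions(...))

test_that("derived reverse rates appear as reaction constants", {
    m <- mkModel()
    k <- constants(m)
    expect_equal(k[["k_unfold"]], 0.1 / 1e4)
    expect_equal(k[["k_unmis"]], 0.01)
    expect_equal(k[["k_dis"]], 0.01)
    ## synthesis flux is the ribosome activation rate times the Rib total
    expect_equal(k[["r_syn"]], 1e-4 * 20)
})

test_that("disabling a system removes its species and reactions", {
    m <- buildModel(options = modelOptions(
        enabled_systems = c("KJE", "GroELS", "TriggerFactor", "Degradation")))
    expect_false(any(grepl("\\*$", speciesTable(m)$name)))
    expect_false(any(reactionsTable(m)$constant %in%
                     c("k_prep", "k_unprep", "k_extract")))
    expect_false("ClpB" %in% speciesTable(m)$name)
    ## core species always present
    expect_true(all(c("U", "N", "M", "Null", "A2", "A20") %in%
                    speciesTable(m)$name))
})

test_that("conservation-group initial totals equal the configured levels", {
    m <- mkModel()
    g <- conservationGroups(m)
    y0 <- initialState(m)
    tot <- vapply(g, function(w) sum(w * y0[names(w)]), numeric(1))
    expect_equal(tot[["DnaK"]], 30)
    expect_equal(tot[["DnaJ"]], 1)
    expect_equal(tot[["GroEL"]], 42)
    expect_equal(tot[["GroES"]], 35)
    expect_equal(tot[["Lon"]], 0.3)
    expect_equal(tot[["ClpB"]], 1.8)
    expect_equal(tot[["client"]], m@options@null_reservoir)
})

test_that("binding factor scales GroEL up and DnaK down, multiplicatively", {
    m <- mkModel()
    m2 <- applyBindingFactor(m, 2)
    expect_equal(constants(m2)[["k_GU_on"]], constants(m)[["k_GU_on"]] * 2)
    expect_equal(constants(m2)[["k_trans_on"]],
                 constants(m)[["k_trans_on"]] * 2)
    expect_equal(constants(m2)[["k_KU_on"]], constants(m)[["k_KU_on"]] / 2)
    expect_equal(constants(m2)[["k_KM_on"]], constants(m)[["k_KM_on"]] / 2)
    ## untouched constants
    expect_equal(constants(m2)[["k_fold"]], constants(m)[["k_fold"]])
    expect_equal(constants(m2)[["k_cycle"]], constants(m)[["k_cycle"]])
    ## identity and composition
    expect_equal(constants(applyBindingFactor(m, 1)), constants(m))
    twice <- applyBindingFactor(applyBindingFactor(m, 0.1), 0.1)
    once <- applyBindingFactor(m, 0.01)
    expect_equal(constants(twice), constants(once))
    expect_error(applyBindingFactor(m, 0), "lambda")
})

test_that("capacity factor scales only the GroEL/GroES initials", {
    m <- mkModel()
    m2 <- applyCapacityFactor(m, 0.5)
    y0 <- initialState(m2)
    expect_equal(y0[["GrLT"]], 21)
    expect_equal(y0[["GrS"]], 17.5)
    expect_equal(y0[["KT"]], 30)
    expect_equal(constants(m2), constants(m))
    y0z <- initialState(applyCapacityFactor(m, 0))
    expect_equal(y0z[["GrLT"]], 0)
    expect_equal(y0z[["GrS"]], 0)
    expect_error(applyCapacityFactor(m, -1), ">= 0")
    ## g = 0 coincides with a GroELS knockout at the initial-condition level
    expect_equal(initialState(applyCapacityFactor(m, 0)),
                 initialState(knockoutSystem(m, "GroELS")))
})

test_that("knockouts zero initials, keep reactions, and are idempotent", {
    m <- mkModel()
    ko <- knockoutSystem(m, "KJE")
    y0 <- initialState(ko)
    expect_equal(unname(y0[c("KT", "J2", "GrpE")]), c(0, 0, 0))
    expect_equal(y0[["GrLT"]], 42)
    expect_identical(reactionsTable(ko), reactionsTable(m))
    expect_equal(initialState(knockoutSystem(ko, "KJE")), y0)
    expect_error(knockoutSystem(m, "Hsp104"), "unknown system")
    m_noB <- buildModel(options = modelOptions(
        enabled_systems = c("KJE", "GroELS", "TriggerFactor", "Degradation")))
    expect_error(knockoutSystem(m_noB, "B+KJE"), "not enabled")
})

test_that("overrides must name declared constants", {
    expect_error(buildModel(overrides = c(k_zap = 1)), "unknown rate-constant")
    m <- buildModel(overrides = c(k_cycle = 0.05, k_ag = 0))
    expect_equal(constants(m)[["k_cycle"]], 0.05)
    expect_equal(constants(m)[["k_ag"]], 0)
})

test_that("model construction is deterministic", {
    m1 <- mkModel(); m2 <- mkModel()
    expect_identical(speciesTable(m1), speciesTable(m2))
    expect_identical(reactionsTable(m1), reactionsTable(m2))
    expect_identical(m1@stoichReact, m2@stoichReact)
    expect_identical(constants(m1), constants(m2))
})

test_that("every binding step is paired with an unbinding step unless
           designated irreversible", {
    m <- mkModel()
    rx <- reactionsTable(m)
    nreact <- colSums(m@stoichReact)
    bimol <- which(nreact >= 2)
    unpaired <- bimol[is.na(rx$reversible_of[bimol])]
    designated <- c("k_enc", "k_exch", "k_trans_on", "k_extract")
    expect_true(all(rx$constant[unpaired] %in% designated))
    ## and the designated irreversibles really have no reverse
    expect_true(all(is.na(rx$reversible_of[rx$constant %in% designated])))
})
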