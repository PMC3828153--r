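## Plain-text interfaces: JSON/YAML model configuration, TSV/CSV writers for
## species tables, sparse rate matrices, committors and decompositions, with
## JSON metadata sidecars.

.readConfigFile <- function(path) {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
    else if (ext == "json") jsonlite::fromJSON(path, simplifyVector = TRUE)
    else stop("config must be .json, .yml or .yaml")
}

#' Read a model configuration file
#'
#' Accepted blocks: \code{profile} (preset and/or the six biophysical
#' parameters), \code{levels} (chaperone totals), \code{options} (model
#' options) and \code{overrides} (named rate constants).  Unknown blocks or
#' keys are rejected.
#'
#' @param path JSON or YAML file
#' @return list with validated \code{profile}, \code{levels},
#'   \code{options}, \code{overrides}
#' @export
readModelConfig <- function(path) {
    cfg <- .readConfigFile(path)
    bad <- setdiff(names(cfg), c("profile", "levels", "options", "overrides"))
    if (length(bad))
        stop("unknown config block(s): ", paste(bad, collapse = ", "))
    prof_keys <- c("preset", "k_mis", "K_mis", "k_fold", "K_fold",
                   "k_ag", "c_crit")
    pc <- cfg$profile %||% list()
    bad <- setdiff(names(pc), prof_keys)
    if (length(bad))
        stop("unknown profile key(s): ", paste(bad, collapse = ", "))
    profile <- do.call(proteinProfile,
                       c(list(preset = pc$preset %||% "Default"),
                         pc[setdiff(names(pc), "preset")]))
    lc <- cfg$levels %||% list()
    levels <- do.call(chaperoneLevels, lc)
    opt_keys <- c("ribosome_activation_rate", "n_max", "binding_factor",
                  "capacity_factor", "enabled_systems", "double_occupancy",
                  "null_reservoir")
    oc <- cfg$options %||% list()
    bad <- setdiff(names(oc), opt_keys)
    if (length(bad))
        stop("unknown option key(s): ", paste(bad, collapse = ", "))
    options <- do.call(modelOptions, oc)
    overrides <- unlist(cfg$overrides %||% list())
    list(profile = profile, levels = levels, options = options,
         overrides = if (length(overrides)) overrides else numeric())
}

#' Build a model directly from a configuration file
#' @param path JSON or YAML configuration
#' @return a \linkS4class{NetworkModel}
#' @export
buildModelFromConfig <- function(path) {
    cfg <- readModelConfig(path)
    buildModel(cfg$profile, cfg$levels, cfg$options, cfg$overrides)
}

#' Write the species and reaction listing of a model
#'
#' @param model a \linkS4class{NetworkModel}
#' @param species_path,reactions_path TSV output paths (NULL to skip either)
#' @return invisibly, the two paths
#' @export
writeModelTables <- function(model, species_path = NULL,
                             reactions_path = NULL) {
    if (!is.null(species_path))
        utils::write.table(model@species, species_path, sep = "\t",
                           quote = FALSE, row.names = FALSE)
    if (!is.null(reactions_path)) {
        SR <- model@stoichReact; SP <- model@stoichProd
        fmt <- function(S, r) {
            nz <- which(S[, r] > 0)
            paste(ifelse(S[nz, r] > 1, paste0(S[nz, r], " "), ""),
                  rownames(S)[nz], sep = "", collapse = " + ")
        }
        df <- data.frame(
            id = model@reactions$id,
            reactants = vapply(model@reactions$id, function(r) fmt(SR, r), ""),
            products = vapply(model@reactions$id, function(r) fmt(SP, r), ""),
            constant = model@reactions$constant,
            value = unname(model@constants[model@reactions$constant]),
            type = model@reactions$type)
        utils::write.table(df, reactions_path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(c(species_path, reactions_path))
}

#' Write a rate matrix as sparse triplets plus a state table
#'
#' @param K a \linkS4class{RateMatrix}
#' @param triplet_path CSV of (from_state, to_state, rate), off-diagonal
#'   nonzeros only
#' @param states_path CSV state table (id, label, system, agg_size,
#'   position)
#' @return invisibly, the paths
#' @export
writeRateMatrix <- function(K, triplet_path, states_path) {
    stopifnot(is(K, "RateMatrix"))
    Km <- K@K; diag(Km) <- 0
    nz <- which(Km > 0, arr.ind = TRUE)
    df <- data.frame(from_state = colnames(Km)[nz[, 2]],
                     to_state = rownames(Km)[nz[, 1]],
                     rate = Km[nz])
    df <- df[order(match(df$from_state, colnames(Km)),
                   match(df$to_state, rownames(Km))), ]
    utils::write.csv(df, triplet_path, row.names = FALSE)
    st <- K@states
    st$id <- seq_len(nrow(st))
    utils::write.csv(st[c("id", "label", "system", "agg_size", "position")],
                     states_path, row.names = FALSE)
    invisible(c(triplet_path, states_path))
}

#' Read a rate matrix written by \code{\link{writeRateMatrix}}
#'
#' Reconstructs the generator (diagonal restored as negative column sums).
#' The state table loses the bulk-species mapping, so the result supports
#' committor analysis but not flux computation.
#'
#' @param triplet_path,states_path the two CSV files
#' @param time analysis time to record (default NA)
#' @return a \linkS4class{RateMatrix}
#' @export
readRateMatrix <- function(triplet_path, states_path, time = NA_real_) {
    st <- utils::read.csv(states_path, stringsAsFactors = FALSE)
    tr <- utils::read.csv(triplet_path, stringsAsFactors = FALSE)
    n <- nrow(st)
    K <- matrix(0, n, n, dimnames = list(st$label, st$label))
    K[cbind(match(tr$to_state, st$label), match(tr$from_state, st$label))] <-
        tr$rate
    diag(K) <- -colSums(K)
    st$bulk_species <- st$label
    rownames(st) <- st$label
    new("RateMatrix", K = K, states = st[c("label", "system", "agg_size",
                                           "position", "bulk_species")],
        time = time, concentrations = numeric())
}

#' Write a trajectory in long format
#'
#' @param traj a \linkS4class{KineticTrajectory}
#' @param path CSV path; columns time, species, concentration
#' @return invisibly, the path
#' @export
writeTrajectory <- function(traj, path) {
    stopifnot(is(traj, "KineticTrajectory"))
    df <- data.frame(
        time = rep(traj@times, times = ncol(traj@conc)),
        species = rep(colnames(traj@conc), each = length(traj@times)),
        concentration = as.vector(traj@conc))
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' Write committor vectors keyed by state label
#'
#' @param x a \linkS4class{CommittorResult} or
#'   \linkS4class{ConditionalCommittorResult}
#' @param path CSV path
#' @param meta_path optional JSON sidecar with sinks, mediators, method and
#'   iteration count
#' @return invisibly, the path
#' @export
writeCommittor <- function(x, path, meta_path = NULL) {
    if (is(x, "ConditionalCommittorResult")) {
        df <- data.frame(state = names(x@h), q_B = x@committor@q_B,
                         h = x@h, hbar = x@hbar)
        meta <- list(A = x@committor@A, B = x@committor@B, C = x@mediator,
                     method = x@committor@method,
                     iterations = x@committor@iterations)
    } else {
        df <- data.frame(state = names(x@q_B), q_B = x@q_B, q_A = x@q_A)
        meta <- list(A = x@A, B = x@B, method = x@method,
                     iterations = x@iterations)
    }
    utils::write.csv(df, path, row.names = FALSE)
    if (!is.null(meta_path))
        jsonlite::write_json(meta, meta_path, auto_unbox = TRUE)
    invisible(path)
}

#' Write a pathway decomposition (and optionally a sweep table)
#'
#' @param d a \linkS4class{PathwayDecomposition} or a \code{runSweep} table
#' @param path CSV path
#' @return invisibly, the path
#' @export
writeDecomposition <- function(d, path) {
    if (is(d, "PathwayDecomposition"))
        d <- data.frame(channel = names(d@probabilities),
                        probability = unname(d@probabilities),
                        flux = unname(d@fluxes))
    utils::write.csv(d, path, row.names = FALSE)
    invisible(path)
}
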