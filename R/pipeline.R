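# End-to-end orchestration: simulate -> features -> encoding -> readout ->
# priming analyses, with CSV/JSON serialization, manifests, and validation.
# CSV dialect: comma-separated, UTF-8, header row, '.' decimal. JSON numbers
# are written at 17 significant digits so model weights round-trip exactly.

#' Run configuration for the pipeline
#'
#' @param generator a `kp_config`.
#' @param reg a `kp_regspec`.
#' @param stages stages to execute, in dependency order.
#' @param outdir output directory.
#' @param n_epochs feature epochs.
#' @param n_perm permutations for null controls.
#' @param seed global seed (overrides the generator seed).
#' @return list of class `kp_run_config`.
#' @export
run_config <- function(generator = kp_config(), reg = kp_regspec(),
                       stages = c("simulate", "features", "encoding",
                                  "readout", "priming"),
                       outdir = tempfile("kinprime_run_"),
                       n_epochs = 4, n_perm = 200, seed = NULL) {
  allowed <- c("simulate", "features", "encoding", "readout", "priming")
  bad <- setdiff(stages, allowed)
  if (length(bad))
    stop_kp("unknown stage(s): ", paste(bad, collapse = ", "),
            class = "kp_config_error")
  if (!is.null(seed)) generator$seed <- as.integer(seed)
  structure(list(generator = generator, reg = reg, stages = stages,
                 outdir = outdir, n_epochs = n_epochs, n_perm = n_perm),
            class = "kp_run_config")
}

write_json17 <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 17, null = "null")
}

# CSV writer with %.17g numeric formatting so doubles round-trip exactly
# (write.csv's default 15 significant digits breaks checksum-based rerun
# caching).
write_csv17 <- function(df, path) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Serialize a prime set to long-format CSV
#'
#' Columns: prime_id, intention, time_s, variable, value.
#' @param primes a `kp_primes`.
#' @param path output CSV path.
#' @export
write_primes_csv <- function(primes, path) {
  rows <- lapply(seq_along(primes$trajectories), function(i) {
    tr <- primes$trajectories[[i]]
    n <- nrow(tr$channels)
    data.frame(prime_id = tr$prime_id,
               intention = as.character(primes$intention[i]),
               time_s = rep((seq_len(n) - 1) / tr$sample_rate, times = 16),
               variable = rep(colnames(tr$channels), each = n),
               value = as.vector(tr$channels),
               stringsAsFactors = FALSE)
  })
  write_csv17(do.call(rbind, rows), path)
}

#' Read a long-format prime CSV back into a `kp_primes` object
#'
#' @param path CSV written by [write_primes_csv()].
#' @param sample_rate Hz.
#' @return a `kp_primes` (without ground truth).
#' @export
read_primes_csv <- function(path, sample_rate = 100) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(d$prime_id)
  trajs <- lapply(ids, function(id) {
    sub <- d[d$prime_id == id, ]
    n <- sum(sub$variable == "W_V")
    ch <- vapply(kp_variables(), function(v) sub$value[sub$variable == v],
                 numeric(n))
    new_trajectory(ch, sample_rate, id)
  })
  intent <- vapply(ids, function(id) d$intention[d$prime_id == id][1], character(1))
  structure(list(trajectories = trajs, prime_id = ids,
                 intention = factor(intent, levels = intention_levels()),
                 ground_truth = NULL, config = NULL),
            class = "kp_primes")
}

#' Write / read a feature matrix as CSV plus JSON sidecar
#'
#' The sidecar holds the canonical label order and any standardization
#' parameters, so held-out data can be transformed consistently.
#'
#' @param features a `kp_features`.
#' @param path CSV path (sidecar gets `.json` appended).
#' @export
write_feature_matrix <- function(features, path) {
  df <- data.frame(prime_id = rownames(features$values), features$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_csv17(df, path)
  write_json17(list(labels = features$labels, zscored = features$zscored,
                    center = as.list(features$center %||% NULL),
                    scale = as.list(features$scale %||% NULL)),
               paste0(path, ".json"))
}

#' @rdname write_feature_matrix
#' @return `read_feature_matrix`: the `kp_features` object.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$prime_id
  structure(list(values = vals, labels = as.data.frame(meta$labels),
                 zscored = isTRUE(meta$zscored),
                 center = if (length(meta$center)) unlist(meta$center) else NULL,
                 scale = if (length(meta$scale)) unlist(meta$scale) else NULL),
            class = "kp_features")
}

#' Serialize / deserialize a fitted encoding or readout model as JSON
#'
#' @param model a `kp_model`.
#' @param path JSON path.
#' @export
write_model_json <- function(model, path) {
  write_json17(list(
    kind = model$kind, perceiver_id = model$perceiver_id %||% NULL,
    weights = as.list(model$weights), bias = model$bias,
    alpha = model$alpha, lambda_min = model$lambda_min,
    center = as.list(model$center), scale = as.list(model$scale),
    positive_class = model$positive_class,
    performance = model$performance, cv_performance = model$cv_performance,
    degenerate = isTRUE(model$degenerate)), path)
}

#' @rdname write_model_json
#' @return `read_model_json`: the `kp_model`.
#' @export
read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    kind = j$kind, perceiver_id = j$perceiver_id,
    weights = unlist(j$weights), bias = j$bias, alpha = j$alpha,
    lambda_min = j$lambda_min %||% NA_real_,
    center = unlist(j$center), scale = unlist(j$scale),
    positive_class = j$positive_class, performance = j$performance,
    cv_performance = j$cv_performance, degenerate = isTRUE(j$degenerate)
  ), class = "kp_model")
}

#' Validate a trial table against a schema
#'
#' Schemas: "choice" (perceiver_id, prime_id, repetition, choice, optional
#' confidence/rt_ms) and "priming" (participant_id, prime_id,
#' prime_intention, probe, congruency, rt_ms, accuracy). Choice and
#' congruency values are case-folded; violations are reported with row
#' numbers; the choice schema enforces (perceiver, prime, repetition)
#' uniqueness and the priming schema checks prime-probe/congruency
#' consistency.
#'
#' @param table data.frame or CSV path.
#' @param schema "choice" or "priming".
#' @return the normalized table (invisibly on error-free validation).
#' @export
validate_trial_table <- function(table, schema = c("choice", "priming")) {
  schema <- match.arg(schema)
  if (is.character(table)) table <- utils::read.csv(table, stringsAsFactors = FALSE)
  problems <- character(0)
  req <- if (schema == "choice") {
    c("perceiver_id", "prime_id", "repetition", "choice")
  } else {
    c("participant_id", "prime_id", "prime_intention", "probe", "congruency",
      "rt_ms", "accuracy")
  }
  miss <- setdiff(req, names(table))
  if (length(miss))
    stop_kp("missing column(s): ", paste(miss, collapse = ", "),
            class = "kp_schema_error")
  if (schema == "choice") {
    table$choice <- tolower(table$choice)
    bad <- which(!table$choice %in% c("pour", "drink"))
    if (length(bad))
      problems <- c(problems, paste0("invalid choice at rows: ",
                                     paste(utils::head(bad, 10), collapse = ", ")))
    key <- paste(table$perceiver_id, table$prime_id, table$repetition)
    dup <- which(duplicated(key))
    if (length(dup))
      problems <- c(problems,
                    paste0("duplicated (perceiver, prime, repetition) at rows: ",
                           paste(utils::head(dup, 10), collapse = ", ")))
  } else {
    table$congruency <- tolower(table$congruency)
    bad <- which(!table$congruency %in% c("congruent", "incongruent"))
    if (length(bad))
      problems <- c(problems, paste0("invalid congruency at rows: ",
                                     paste(utils::head(bad, 10), collapse = ", ")))
    map <- c(pour = "pouring", drink = "drinking")
    expect_cong <- map[table$prime_intention] == table$probe
    mismatch <- which((table$congruency == "congruent") != expect_cong)
    if (length(mismatch))
      problems <- c(problems, paste0("congruency inconsistent with prime/probe at rows: ",
                                     paste(utils::head(mismatch, 10), collapse = ", ")))
    if (any(table$rt_ms <= 0, na.rm = TRUE))
      problems <- c(problems, "non-positive rt_ms present")
  }
  if (length(problems))
    stop_kp(paste(problems, collapse = "; "), class = "kp_validation_error")
  table
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in dependency order against `outdir`,
#' writing CSV/JSON artifacts and a manifest with config hash, seeds, and
#' per-artifact MD5 checksums. Identical config + seed yields identical
#' checksums for deterministic stages. A stage whose inputs are neither on
#' disk nor produced by an enabled earlier stage raises a dependency error.
#'
#' @param config a `kp_run_config`.
#' @return the manifest (list), invisibly written to `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "kp_run_config"))
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out, f)
  need <- function(file, stage, producer) {
    if (!producer %in% config$stages && !file.exists(pth(file)))
      stop_kp("stage '", stage, "' requires missing artifact '", file,
              "' (produced by stage '", producer, "')",
              class = "kp_dependency_error")
  }
  gen <- config$generator
  artifacts <- character(0)
  primes <- perceivers <- fm <- enc <- NULL
  readout_models <- NULL
  disc <- prim <- NULL

  if ("simulate" %in% config$stages) {
    primes <- generate_primes(gen)
    perceivers <- generate_perceivers(gen, primes$ground_truth$encoding_direction)
    disc <- simulate_discrimination(primes, perceivers, gen)
    prim <- simulate_priming_session(primes, perceivers, gen)
    write_primes_csv(primes, pth("primes.csv"))
    write_csv17(disc, pth("discrimination_trials.csv"))
    write_csv17(prim, pth("priming_trials.csv"))
    write_json17(list(encoding_direction = as.list(primes$ground_truth$encoding_direction),
                      gains = as.list(perceivers$gains),
                      intention = as.list(primes$ground_truth$intention)),
                 pth("ground_truth.json"))
    artifacts <- c(artifacts, "primes.csv", "discrimination_trials.csv",
                   "priming_trials.csv", "ground_truth.json")
  }

  if ("features" %in% config$stages) {
    need("primes.csv", "features", "simulate")
    if (is.null(primes)) primes <- read_primes_csv(pth("primes.csv"), gen$sample_rate)
    fm <- zscore_features(build_feature_matrix(primes, n_epochs = config$n_epochs))
    write_feature_matrix(fm, pth("features.csv"))
    artifacts <- c(artifacts, "features.csv", "features.csv.json")
  }

  if ("encoding" %in% config$stages) {
    need("features.csv", "encoding", "features")
    need("primes.csv", "encoding", "simulate")
    if (is.null(fm)) fm <- read_feature_matrix(pth("features.csv"))
    if (is.null(primes)) primes <- read_primes_csv(pth("primes.csv"), gen$sample_rate)
    enc <- fit_encoding(fm, primes$intention, config$reg)
    write_model_json(enc, pth("encoding_model.json"))
    ste <- single_trial_encoding(enc, fm, as.character(primes$intention))
    utils::write.csv(ste, pth("encoding_indices.csv"), row.names = FALSE)
    artifacts <- c(artifacts, "encoding_model.json", "encoding_indices.csv")
  }

  if ("readout" %in% config$stages) {
    need("features.csv", "readout", "features")
    need("discrimination_trials.csv", "readout", "simulate")
    if (is.null(fm)) fm <- read_feature_matrix(pth("features.csv"))
    if (is.null(disc)) disc <- utils::read.csv(pth("discrimination_trials.csv"),
                                               stringsAsFactors = FALSE)
    disc <- validate_trial_table(disc, "choice")
    intent <- tapply(disc$intention, disc$prime_id, function(v) v[1])
    readout_models <- lapply(split(disc, disc$perceiver_id), fit_readout, features = fm)
    dir.create(pth("readout_models"), showWarnings = FALSE)
    idx_rows <- list()
    for (p in names(readout_models)) {
      write_model_json(readout_models[[p]],
                       pth(file.path("readout_models", paste0(p, ".json"))))
      idx_rows[[p]] <- single_trial_readout(readout_models[[p]], fm,
                                            intent[rownames(fm$values)])
    }
    utils::write.csv(do.call(rbind, idx_rows), pth("readout_indices.csv"),
                     row.names = FALSE)
    artifacts <- c(artifacts, "readout_indices.csv")
  }

  if ("priming" %in% config$stages) {
    need("priming_trials.csv", "priming", "simulate")
    need("readout_indices.csv", "priming", "readout")
    if (is.null(prim)) prim <- utils::read.csv(pth("priming_trials.csv"),
                                               stringsAsFactors = FALSE)
    prim <- validate_trial_table(prim, "priming")
    ri <- utils::read.csv(pth("readout_indices.csv"), stringsAsFactors = FALSE)
    key <- paste(ri$perceiver_id, ri$prime_id)
    prim$readout_index <- ri$value[match(paste(prim$participant_id, prim$prime_id), key)]
    excl <- apply_exclusions(prim)
    cim <- congruency_information_model(excl$trials, "readout_index", "rt")
    ms <- median_split_priming(excl$trials, "readout_index")
    report <- list(
      exclusions = excl$report,
      interaction = cim$lrt_interaction,
      slopes = as.data.frame(cim$slopes),
      median_split = ms$effects,
      median_split_difference = ms$difference[c("statistic", "df", "p_value", "p_holm")]
    )
    write_json17(report, pth("priming_report.json"))
    writeLines(c(
      "kinematic priming analysis",
      sprintf("trials retained: %d / %d", excl$report$n_retained, excl$report$n_input),
      sprintf("congruency x readout LRT: chi2 = %.3f, df = %d, p = %.4g",
              cim$lrt_interaction$statistic, cim$lrt_interaction$df,
              cim$lrt_interaction$p_value),
      sprintf("slope on readout (congruent):   %.3f ms/log-odds (SE %.3f)",
              cim$slopes["congruent", "estimate"], cim$slopes["congruent", "se"]),
      sprintf("slope on readout (incongruent): %.3f ms/log-odds (SE %.3f)",
              cim$slopes["incongruent", "estimate"], cim$slopes["incongruent", "se"]),
      sprintf("priming effect low readout:  %.1f ms (p_holm = %.4g)",
              ms$effects$estimate[1], ms$effects$p_holm[1]),
      sprintf("priming effect high readout: %.1f ms (p_holm = %.4g)",
              ms$effects$estimate[2], ms$effects$p_holm[2])
    ), pth("priming_report.txt"))
    artifacts <- c(artifacts, "priming_report.json", "priming_report.txt")
  }

  cfg_path <- pth("run_config.json")
  write_json17(list(seed = gen$seed, stages = config$stages,
                    n_epochs = config$n_epochs, alpha = config$reg$alpha,
                    generator = unclass(gen)), cfg_path)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = gen$seed,
    version = as.character(utils::packageVersion("kinprime")),
    timestamp = format(Sys.time(), tz = "UTC"),
    checksums = as.list(tools::md5sum(vapply(artifacts, pth, character(1))))
  )
  names(manifest$checksums) <- artifacts
  write_json17(manifest, pth("manifest.json"))
  invisible(manifest)
}
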