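# Tabular sample-set format, run configuration, and the end-to-end pipeline
# (generate -> estimate -> diagnose -> compare -> report).
#
# On disk a sample set is a directory holding one delimited file per
# (window, replica) with columns
#   sample_index  dudl  u_at_state_0 ... u_at_state_{K-1}
# plus a manifest (YAML) carrying the schedule, beta, leg label and every
# derived seed. Values are written with 17 significant digits so the
# write/read round trip is exact for doubles. The column semantics follow
# the usual dHdl / u_nk conventions, so adapters for engine-native formats
# only need to populate the same columns.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a sample set to a directory
#'
#' @param samples a `sample_set`
#' @param path directory to create/populate
#' @return `path`, invisibly
#' @export
write_sampleset <- function(samples, path) {
  stopifnot(inherits(samples, "sample_set"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory ", path, call. = FALSE)
  K <- samples$n_states
  man <- list(
    format = "alchemr-sampleset-1",
    n_states = K,
    n_replicas = samples$n_replicas,
    beta = fmt_num(samples$beta),
    leg_label = samples$leg_label,
    schedule = list(lambdas = vapply(samples$schedule$lambdas, fmt_num, ""),
                    scheme = samples$schedule$scheme),
    manifest = rapply(samples$manifest, function(x) {
      if (is.numeric(x)) vapply(as.numeric(x), fmt_num, "") else x
    }, how = "replace"))
  yaml::write_yaml(man, file.path(path, "manifest.yaml"))
  for (k in seq_len(K)) {
    for (r in seq_len(samples$n_replicas)) {
      rep <- samples$windows[[k]][[r]]
      u <- rep$u_cross
      if (is.null(u)) stop("sample set has no cross-evaluations to write",
                           call. = FALSE)
      tab <- cbind(rep$times, rep$dudl, u)
      con <- file.path(path, sprintf("window-%02d_replica-%d.tsv", k - 1, r))
      header <- c("sample_index", "dudl",
                  sprintf("u_at_state_%d", seq_len(K) - 1))
      lines <- c(paste(header, collapse = "\t"),
                 apply(tab, 1, function(row) {
                   paste(c(sprintf("%d", as.integer(row[1])), fmt_num(row[-1])),
                         collapse = "\t")
                 }))
      writeLines(lines, con)
    }
  }
  invisible(path)
}

#' Read a sample set from a directory
#'
#' Validates the manifest and the per-file schema (column count must match
#' the manifest's state count K); malformed rows are reported with their line
#' number.
#'
#' @param path directory written by [write_sampleset()]
#' @return a `sample_set`
#' @export
read_sampleset <- function(path) {
  mpath <- file.path(path, "manifest.yaml")
  if (!file.exists(mpath)) {
    stop("no manifest.yaml in ", path,
         "; a sample-set directory must carry its manifest", call. = FALSE)
  }
  man <- yaml::read_yaml(mpath)
  if (!identical(man$format, "alchemr-sampleset-1")) {
    stop("unrecognised sample-set format in manifest", call. = FALSE)
  }
  K <- man$n_states
  R <- man$n_replicas
  lambdas <- as.numeric(man$schedule$lambdas)
  schedule <- build_lambda_schedule(K, scheme = man$schedule$scheme,
                                    lambdas = lambdas)
  windows <- vector("list", K)
  for (k in seq_len(K)) {
    reps <- vector("list", R)
    for (r in seq_len(R)) {
      f <- file.path(path, sprintf("window-%02d_replica-%d.tsv", k - 1, r))
      if (!file.exists(f)) stop("missing sample file ", f, call. = FALSE)
      lines <- readLines(f)
      if (length(lines) < 2) stop("truncated sample file ", f, call. = FALSE)
      fields <- strsplit(trimws(lines[-1]), "[ \t]+")
      nc <- lengths(fields)
      bad <- which(nc != K + 2)
      if (length(bad)) {
        stop(sprintf("malformed row at line %d of %s (expected %d columns, got %d)",
                     bad[1] + 1, f, K + 2, nc[bad[1]]), call. = FALSE)
      }
      vals <- matrix(as.numeric(unlist(fields)), ncol = K + 2, byrow = TRUE)
      if (any(!is.finite(vals))) {
        stop("non-numeric value in ", f, call. = FALSE)
      }
      reps[[r]] <- list(dudl = vals[, 2],
                        u_cross = vals[, -(1:2), drop = FALSE],
                        times = as.integer(vals[, 1]))
    }
    windows[[k]] <- reps
  }
  manifest <- rapply(man$manifest, function(x) {
    y <- suppressWarnings(as.numeric(x))
    if (!anyNA(y)) y else x
  }, how = "replace")
  new_sample_set(windows, schedule, beta = as.numeric(man$beta),
                 leg_label = man$leg_label, n_replicas = R,
                 manifest = manifest)
}

#' Read a run configuration
#'
#' A YAML document with the schedule, per-leg generator settings, estimator
#' list, bootstrap controls, thresholds and the master seed; see
#' `system.file("extdata", "example-config.yaml", package = "alchemr")`.
#'
#' @param path YAML file
#' @return a validated config list
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  defaults <- list(
    n_states = 13, scheme = "one_step", n_samples = 1000, n_replicas = 5,
    autocorr_rho = 0, estimators = c("TI", "MBAR"), n_boot = 5000,
    overlap_threshold = 0.03, significance_z = 1,
    distribution_min_replicas = 48, master_seed = 1)
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  if (is.null(cfg$transformations) || !length(cfg$transformations)) {
    stop("config must define at least one transformation", call. = FALSE)
  }
  for (tr in cfg$transformations) {
    if (is.null(tr$name) || is.null(tr$solvent) || is.null(tr$complex)) {
      stop("each transformation needs name, solvent and complex leg settings",
           call. = FALSE)
    }
  }
  cfg
}

leg_system <- function(leg_cfg, n_states) {
  gaussian_chain_system(n_states,
                        kf = as.numeric(leg_cfg$kf %||% c(1, 4)),
                        mu = as.numeric(leg_cfg$mu %||% c(0, 1)),
                        offset = as.numeric(leg_cfg$offset %||% c(0, 0)))
}

#' Run the full analysis pipeline
#'
#' For every transformation in the config: generates the solvent and complex
#' Gaussian-chain legs from the master seed, estimates both legs with
#' ensemble TI and ensemble MBAR, composes the thermodynamic cycle, tests the
#' TI-FEP difference at the configured z, builds replica-averaged overlap
#' matrices with threshold verdicts, gradient profiles, and the
#' ensemble-vs-analytic error comparison. Across transformations the
#' predicted ddGs are compared with the reference values (the closed-form
#' chain ddGs unless the config supplies `reference_ddg`). A distribution
#' report is emitted per transformation when the replica count reaches the
#' configured minimum.
#'
#' Every random stage derives its seed from the master seed, so a rerun with
#' the same config reproduces the summary digest exactly.
#'
#' @param config a config list (see [read_run_config()])
#' @param out_dir optional directory for the delimited result tables
#' @return a report bundle (list) with per-transformation results, the
#'   cross-transformation `comparison_report`, and a deterministic digest
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- validate_run_config(config)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed (master seed %d): %s",
                   stage, cfg$master_seed, conditionMessage(e)), call. = FALSE)
    })
  }
  results <- list()
  pred_ti <- pred_fep <- ref <- numeric(0)
  for (ti in seq_along(cfg$transformations)) {
    tr <- cfg$transformations[[ti]]
    seed_tr <- (cfg$master_seed * 131 + ti * 7) %% 2147483647
    legs <- list()
    for (leg in c("solvent", "complex")) {
      sys <- leg_system(tr[[leg]], cfg$n_states)
      spec <- generator_spec(sys, n_samples = cfg$n_samples,
                             n_replicas = cfg$n_replicas,
                             seed = seed_tr + (leg == "complex"),
                             autocorr_rho = cfg$autocorr_rho,
                             leg_label = leg)
      samples <- run_stage(paste0("generate/", leg),
                           sample_gaussian_chain(spec))
      est <- list()
      if ("TI" %in% cfg$estimators) {
        est$TI <- run_stage(paste0("estimate-ti/", leg),
                            ties_estimate(samples, cfg$n_boot, seed_tr + 11))
      }
      if ("MBAR" %in% cfg$estimators) {
        est$MBAR <- run_stage(paste0("estimate-mbar/", leg),
                              mbar_ensemble_estimate(samples, cfg$n_boot,
                                                     seed_tr + 13))
      }
      ov <- run_stage(paste0("diagnose/", leg), sample_overlap(samples))
      legs[[leg]] <- list(
        samples_analytic = gaussian_chain_analytic(sys),
        estimates = est,
        overlap = ov,
        overlap_verdict = overlap_check(ov, cfg$overlap_threshold),
        profile = gradient_profile(samples),
        error_comparison = if (cfg$n_replicas >= 2) {
          error_comparison(samples, cfg$n_boot, seed_tr + 17)
        },
        distribution = if (cfg$n_replicas >= cfg$distribution_min_replicas) {
          distribution_stats(est[[1]]$replica_values, cfg$n_boot,
                             seed_tr + 19)
        })
    }
    cyc <- list()
    for (nm in names(legs$solvent$estimates)) {
      cyc[[nm]] <- thermo_cycle(legs$complex$estimates[[nm]],
                                legs$solvent$estimates[[nm]])
    }
    sig <- if (all(c("TI", "MBAR") %in% names(cyc))) {
      significance_test(cyc$TI$ddg, cyc$TI$sem, cyc$MBAR$ddg, cyc$MBAR$sem,
                        z = cfg$significance_z)
    }
    K <- cfg$n_states
    analytic_ddg <- (legs$complex$samples_analytic[K] -
                       legs$solvent$samples_analytic[K])
    reference <- as.numeric(tr$reference_ddg %||% analytic_ddg)
    if ("TI" %in% names(cyc)) pred_ti <- c(pred_ti, cyc$TI$ddg)
    if ("MBAR" %in% names(cyc)) pred_fep <- c(pred_fep, cyc$MBAR$ddg)
    ref <- c(ref, reference)
    results[[tr$name]] <- list(legs = legs, cycles = cyc, significance = sig,
                               reference_ddg = reference,
                               analytic_ddg = analytic_ddg)
  }
  comparison <- NULL
  if (length(pred_ti) >= 3) {
    comparison <- run_stage("compare",
      list(TI = comparison_report(pred_ti, ref,
                                  names(results), cfg$n_boot,
                                  (cfg$master_seed * 977) %% 2147483647),
           MBAR = if (length(pred_fep)) {
             comparison_report(pred_fep, ref, names(results), cfg$n_boot,
                               (cfg$master_seed * 983) %% 2147483647)
           }))
  }
  bundle <- list(config = cfg, transformations = results,
                 comparison = comparison)
  bundle$digest <- pipeline_digest(bundle)
  if (!is.null(out_dir)) write_pipeline_tables(bundle, out_dir)
  bundle
}

# deterministic digest of the bundle's numeric content
pipeline_digest <- function(bundle) {
  nums <- unlist(lapply(bundle$transformations, function(tr) {
    c(vapply(tr$cycles, function(cy) c(cy$ddg, cy$sem), numeric(2)),
      tr$reference_ddg)
  }))
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(sprintf("%.12e", nums), tf)
  unname(tools::md5sum(tf))
}

# delimited result tables: one row per estimator x leg x transformation,
# plus overlap matrices and the comparison report
write_pipeline_tables <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (nm in names(bundle$transformations)) {
    tr <- bundle$transformations[[nm]]
    for (leg in names(tr$legs)) {
      for (est in names(tr$legs[[leg]]$estimates)) {
        e <- tr$legs[[leg]]$estimates[[est]]
        rows[[length(rows) + 1]] <- data.frame(
          transformation = nm, leg = leg, estimator = est,
          delta_g = e$delta_g, sem = e$sem,
          overlap_pass = tr$legs[[leg]]$overlap_verdict$pass,
          min_offdiag = tr$legs[[leg]]$overlap_verdict$min_offdiag)
      }
      O <- tr$legs[[leg]]$overlap$values
      utils::write.table(
        data.frame(window = seq_len(nrow(O)) - 1, O),
        file.path(out_dir, sprintf("overlap_%s_%s.tsv", nm, leg)),
        sep = "\t", row.names = FALSE, quote = FALSE)
    }
    for (est in names(tr$cycles)) {
      cy <- tr$cycles[[est]]
      rows[[length(rows) + 1]] <- data.frame(
        transformation = nm, leg = "cycle", estimator = est,
        delta_g = cy$ddg, sem = cy$sem, overlap_pass = NA,
        min_offdiag = NA)
    }
  }
  utils::write.table(do.call(rbind, rows),
                     file.path(out_dir, "results.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(bundle$comparison)) {
    for (est in names(bundle$comparison)) {
      cr <- bundle$comparison[[est]]
      if (is.null(cr)) next
      tab <- data.frame(
        property = c("MUE", "MSE", "RMSD", "Pearson's", "Spearman's",
                     "Kendall's", "slope", "intercept"),
        value = vapply(c("mue", "mse", "rmsd", "pearson", "spearman",
                         "kendall_tau", "slope", "intercept"),
                       function(p) format_ci(cr[[p]]$value, cr[[p]]$ci),
                       ""))
      utils::write.table(tab,
                         file.path(out_dir, sprintf("comparison_%s.tsv", est)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  writeLines(bundle$digest, file.path(out_dir, "digest.txt"))
  invisible(out_dir)
}
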