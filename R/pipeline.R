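# End-to-end orchestration and file formats. Sessions travel as a small
# CSV dialect: a commented header block carrying metadata, then one row per
# (limb, sample) with integer sample indices so timestamps are
# reconstructed exactly from the declared rate.

#' Write a session to CSV
#'
#' Dialect: comment lines `# id:`, `# age_group:`, `# connected_side:`,
#' `# rate_hz:`, then columns `session_id, limb, sample_index, x_mm, y_mm,
#' z_mm` with limbs LW/RW/LA/RA. Coordinates are written with full
#' precision so a write/read round trip is exact.
#'
#' @param session A `mobile_session`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session_csv <- function(session, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# id: %s", session$id),
               sprintf("# age_group: %s", session$age_group),
               sprintf("# connected_side: %s", session$connected_side),
               sprintf("# rate_hz: %.10g", session$rate_hz),
               "session_id,limb,sample_index,x_mm,y_mm,z_mm"), con)
  for (marker in LIMB_MARKERS) {
    p <- session$limbs[[marker]]
    writeLines(sprintf("%s,%s,%d,%.17g,%.17g,%.17g", session$id, marker,
                       seq_len(nrow(p)) - 1L, p$x, p$y, p$z), con)
  }
  invisible(path)
}

#' Read a session from CSV
#'
#' Inverse of [write_session_csv()]; validates the dialect, requires all
#' four limbs with equal sample counts and rebuilds timestamps from the
#' sample index and declared rate.
#'
#' @param path Input file path.
#' @return A `mobile_session`.
#' @export
read_session_csv <- function(path) {
  lines <- readLines(path, n = 50)
  header <- grep("^# ", lines, value = TRUE)
  get_field <- function(key) {
    m <- grep(sprintf("^# %s:", key), header, value = TRUE)
    if (!length(m))
      mk_error(sprintf("missing '# %s:' header line", key),
               "mobilekin_parse_error")
    trimws(sub(sprintf("^# %s:", key), "", m[1]))
  }
  id <- get_field("id")
  age_group <- get_field("age_group")
  connected_side <- get_field("connected_side")
  rate_hz <- as.numeric(get_field("rate_hz"))
  if (!is.finite(rate_hz) || rate_hz <= 0)
    mk_error("invalid rate_hz header", "mobilekin_parse_error")
  d <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("session_id", "limb", "sample_index", "x_mm", "y_mm", "z_mm")
  if (!identical(names(d), need))
    mk_error(sprintf("expected columns %s", paste(need, collapse = ", ")),
             "mobilekin_parse_error")
  bad <- setdiff(unique(d$limb), LIMB_MARKERS)
  if (length(bad))
    mk_error(sprintf("unknown limb label(s): %s",
                     paste(bad, collapse = ", ")), "mobilekin_parse_error")
  missing <- setdiff(LIMB_MARKERS, unique(d$limb))
  if (length(missing))
    mk_error(sprintf("missing limb(s): %s",
                     paste(missing, collapse = ", ")),
             "mobilekin_parse_error")
  limbs <- lapply(setNames(LIMB_MARKERS, LIMB_MARKERS), function(marker) {
    sub <- d[d$limb == marker, ]
    sub <- sub[order(sub$sample_index), ]
    if (!identical(as.integer(sub$sample_index),
                   seq_len(nrow(sub)) - 1L))
      mk_error(sprintf("limb %s: sample indices not contiguous from 0",
                       marker), "mobilekin_parse_error")
    position_series(sub$sample_index / rate_hz, sub$x_mm, sub$y_mm,
                    sub$z_mm, rate_hz = rate_hz)
  })
  counts <- vapply(limbs, nrow, integer(1))
  if (length(unique(counts)) != 1)
    mk_error("limbs have differing sample counts", "mobilekin_parse_error")
  total <- counts[[1]] / rate_hz
  structure(list(id = id, age_group = age_group,
                 connected_side = connected_side, rate_hz = rate_hz,
                 phases = c(baseline = 120, play = total - 120),
                 limbs = limbs, cluster_id = NA_integer_, seed = NA),
            class = "mobile_session")
}

#' Full-run configuration
#'
#' Collects every tunable of the pipeline with defaults matching the study
#' conventions: tau = 30 s, 60 Hz capture, k = 4 clusters at 1 Hz,
#' oscillator parameters gamma = -0.25, alpha = 1, epsilon = 1,
#' Omega0 = 2.2, a = 0.13, kappa = 0.007, dt = 0.01, coupling 0/2, and a
#' 0.01 significance threshold.
#'
#' @param cohort A [cohort_spec()].
#' @param archetypes List of four [archetype_spec()].
#' @param tau Displacement-rate half-window (s).
#' @param k Number of clusters.
#' @param restarts,cluster_seed K-means restarts and seed.
#' @param params [dyn_params()] shared by generator and simulations.
#' @param alpha Significance threshold.
#' @param fit_omega Logical: also grid-fit the cluster-mean omega0
#'   (slower).
#' @param omega_grid Candidate mean omega0 values for the fit.
#' @param fit_n Ensemble size per fit candidate.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = cohort_spec(),
                       archetypes = default_archetypes(), tau = 30, k = 4,
                       restarts = 10, cluster_seed = 1,
                       params = dyn_params(), alpha = 0.01,
                       fit_omega = FALSE,
                       omega_grid = seq(0.55, 3.05, by = 0.25),
                       fit_n = 20) {
  structure(list(cohort = cohort, archetypes = archetypes, tau = tau,
                 k = k, restarts = restarts, cluster_seed = cluster_seed,
                 params = params, alpha = alpha, fit_omega = fit_omega,
                 omega_grid = omega_grid, fit_n = fit_n),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Synthesise a cohort, preprocess every session, cluster the learning
#' curves, label the clusters, run the cluster-wise mixed ANOVA with Tukey
#' post-hocs, count learners by the 1.5x criterion and (optionally) fit the
#' cluster-mean natural frequencies. All intermediate artifacts are written
#' to `out_dir`; reruns with the same config are byte-identical.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return The summary list, invisibly (also written as `summary.json`).
#' @export
run_full <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(config$cohort, config$archetypes,
                            config$params)
  write.csv(cohort$manifest, file.path(out_dir, "manifest.csv"),
            row.names = FALSE)

  total_s <- sum(config$cohort$phase_durations)
  t_grid <- 0:(total_s - 1)
  curves <- lapply(cohort$sessions, session_curves, tau = config$tau)
  names(curves) <- cohort$manifest$session_id

  tidy <- do.call(rbind, lapply(names(curves), function(id) {
    do.call(rbind, lapply(LIMB_ROLES, function(role) {
      r1 <- downsample_1hz(curves[[id]][[role]]$rate, t_grid)
      q1 <- downsample_1hz(curves[[id]][[role]]$ratio, t_grid)
      data.frame(session_id = id, limb_role = role, t_s = r1$t,
                 rate_mm_s = r1$rate, ratio = q1$ratio)
    }))
  }))
  write.csv(tidy, file.path(out_dir, "curves_1hz.csv"), row.names = FALSE)

  blocks <- do.call(rbind, lapply(names(curves), function(id) {
    do.call(rbind, lapply(LIMB_ROLES, function(role) {
      br <- block_means(curves[[id]][[role]]$rate)
      bq <- block_means(curves[[id]][[role]]$ratio)
      data.frame(session_id = id, limb_role = role, block = br$block,
                 mean_rate = br$mean, mean_ratio = bq$mean)
    }))
  }))
  write.csv(blocks, file.path(out_dir, "block_summary.csv"),
            row.names = FALSE)

  F <- build_features(curves, t_grid)
  model <- kmeans_timeseries(F, k = config$k, restarts = config$restarts,
                             seed = config$cluster_seed)
  labels <- label_clusters(model, t_grid)
  assignments <- data.frame(session_id = attr(F, "subjects"),
                            cluster_id = model$assignment,
                            semantic_label = labels[model$assignment])
  write.csv(assignments, file.path(out_dir, "assignments.csv"),
            row.names = FALSE)

  cona <- blocks[blocks$limb_role == "ConA", ]
  cl_of <- setNames(assignments$cluster_id, assignments$session_id)
  anova_cluster <- NULL
  if (length(unique(cl_of)) >= 2) {
    lt <- long_table(cona$session_id, cl_of[cona$session_id], cona$block,
                     cona$mean_rate)
    anova_cluster <- mixed_anova(lt)
    write.csv(anova_cluster$table, file.path(out_dir, "anova_cluster.csv"),
              row.names = FALSE)
    ph <- tukey_hsd(lt$value, lt$within,
                    error_ms = anova_cluster$errors$within$ms,
                    error_df = anova_cluster$errors$within$df,
                    alpha = config$alpha)
    write.csv(ph, file.path(out_dir, "tukey_phases.csv"),
              row.names = FALSE)
  }

  learners <- vapply(split(cona, cona$session_id), function(b)
    learner_flag(data.frame(block = b$block, mean = b$mean_ratio)),
    logical(1))

  fitted_omega <- NULL
  if (isTRUE(config$fit_omega)) {
    fitted_omega <- lapply(sort(unique(model$assignment)), function(i) {
      members <- which(model$assignment == i)
      Tn <- length(t_grid)
      target <- data.frame(
        t = t_grid,
        ratio = colMeans(unclass(F)[members, seq_len(Tn), drop = FALSE]))
      fit_omega0(target, config$params, config$omega_grid,
                 n = config$fit_n, seed = config$cluster_seed)$omega0
    })
    names(fitted_omega) <- paste0("cluster", sort(unique(model$assignment)))
  }

  summary <- list(
    n_subjects = nrow(cohort$manifest),
    cluster_sizes = as.list(setNames(tabulate(model$assignment, config$k),
                                     paste0("cluster", seq_len(config$k)))),
    cluster_labels = as.list(setNames(labels,
                                      paste0("cluster",
                                             seq_len(config$k)))),
    kmeans = list(k = config$k, seed = config$cluster_seed,
                  restarts = config$restarts, D = model$D,
                  iterations = model$n_iter),
    learner_count = sum(learners),
    learner_fraction = mean(learners),
    anova_cluster = if (!is.null(anova_cluster))
      lapply(split(anova_cluster$table, anova_cluster$table$effect),
             function(r) list(F = r$F, df1 = r$df,
                              p = r$p, partial_eta_sq = r$partial_eta_sq)),
    fitted_omega0 = fitted_omega,
    master_seed = config$cohort$seed)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 12, pretty = TRUE)
  invisible(summary)
}

#' Compact ANOVA report line
#'
#' Formats one effect the conventional way:
#' `F(df1, df2) = ..., p = ..., eta_p^2 = ...`.
#'
#' @param fit A [mixed_anova()] result.
#' @param effect `"between"`, `"within"` or `"interaction"`.
#' @return Character scalar.
#' @export
format_anova <- function(fit, effect = "within") {
  r <- fit$table[fit$table$effect == effect, ]
  df2 <- if (effect == "between") fit$errors$between$df
         else fit$errors$within$df
  sprintf("F(%d, %d) = %.2f, p %s, eta_p^2 = %.3f, 95%% CI = [%.3f, %.3f]",
          r$df, df2, r$F,
          if (r$p < 0.001) "< 0.001" else sprintf("= %.3f", r$p),
          r$partial_eta_sq, r$eta_ci_lo, r$eta_ci_hi)
}
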