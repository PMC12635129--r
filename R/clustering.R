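# K-means time-series clustering of multivariate learning curves: each
# infant is a (4 limb roles x T seconds) matrix of baseline ratios at 1 Hz,
# flattened to one vector; Euclidean distance, Lloyd iterations from a
# random initial assignment, best of several restarts by the objective D.

#' Per-role kinematic curves for one session
#'
#' Runs the kinematics chain (speed, displacement rate, baseline ratio) on
#' each limb of a session and returns the results keyed by limb role.
#'
#' @param session A `mobile_session`.
#' @param tau Half-window for the displacement rate (s, default 30).
#' @return Named list (ConA, UncA, IpsiL, ContL), each element a list with
#'   `rate` (a `rate_series`) and `ratio` (a `ratio_series`).
#' @export
session_curves <- function(session, tau = 30) {
  roles <- relabel_limbs(session$connected_side)
  baseline <- c(0, session$phases[["baseline"]])
  out <- setNames(vector("list", 4), LIMB_ROLES)
  for (marker in names(roles)) {
    v <- instantaneous_speed(session$limbs[[marker]])
    r <- displacement_rate(v, tau = tau)
    out[[roles[[marker]]]] <- list(rate = r,
                                   ratio = baseline_ratio(r, baseline))
  }
  out
}

#' Build the clustering feature matrix
#'
#' Down-samples each session's four baseline-ratio curves to 1 Hz and stacks
#' them (limb-role order ConA, UncA, IpsiL, ContL) into one row per subject.
#' No further scaling is applied: the baseline ratio is already normalised.
#' Sessions with a missing limb or incomplete coverage are excluded with a
#' logged reason.
#'
#' @param curves Named list: session id -> output of [session_curves()].
#' @param t_grid Integer-second grid (default `0:719`).
#' @param series Which curve to cluster on: the baseline-normalised
#'   `"ratio"` (default) or the raw displacement `"rate"` (the
#'   supplementary variant; note raw rates are not scale-normalised across
#'   infants).
#' @return A `feature_matrix`: numeric matrix (subjects x 4*length(t_grid))
#'   with attributes `subjects`, `roles`, `t_grid` and `excluded` (named
#'   character vector of exclusion reasons).
#' @export
build_features <- function(curves, t_grid = 0:719,
                           series = c("ratio", "rate")) {
  series <- match.arg(series)
  rows <- list()
  excluded <- character(0)
  for (id in names(curves)) {
    cs <- curves[[id]]
    if (!all(LIMB_ROLES %in% names(cs)) ||
        any(vapply(cs[LIMB_ROLES], is.null, logical(1)))) {
      excluded[id] <- "missing limb role"
      next
    }
    vecs <- lapply(LIMB_ROLES, function(role) {
      s <- cs[[role]][[series]]
      if (min(s$t) > min(t_grid) + 1 || max(s$t) < max(t_grid) - 1)
        return(NULL)
      downsample_1hz(s, t_grid)[[series]]
    })
    if (any(vapply(vecs, is.null, logical(1)))) {
      excluded[id] <- "incomplete coverage"
      next
    }
    rows[[id]] <- unlist(vecs)
  }
  if (!length(rows))
    mk_error("no usable sessions", "mobilekin_insufficient_data")
  F <- do.call(rbind, rows)
  structure(F, subjects = names(rows), roles = LIMB_ROLES, t_grid = t_grid,
            excluded = excluded, class = c("feature_matrix", "matrix"))
}

#' K-means clustering of multivariate time series
#'
#' Minimises \eqn{D = \sum_{i,j,t} \delta_{i,j} (x_{j,t} - v_{i,t})^2} by
#' Lloyd iterations: subjects start in random clusters, centres are member
#' means, and each subject moves to its nearest centre (Euclidean distance
#' over the concatenated limb-by-time vector) until assignments stop
#' changing. The best of `restarts` runs by final D is returned. An empty
#' cluster is reseeded at the subject farthest from its own centre. Fully
#' deterministic given `seed`.
#'
#' @param F A `feature_matrix` (or plain numeric matrix, one row per
#'   subject).
#' @param k Number of clusters (default 4).
#' @param restarts Independent random initialisations (default 10).
#' @param max_iter Iteration cap per restart (default 300).
#' @param seed Integer seed.
#' @return A `cluster_model` list: `k`, `centres` (k x T matrix),
#'   `assignment` (integer vector), `D`, `n_iter`, `seed`, `restarts`,
#'   `D_trace` (objective per iteration of the winning restart).
#' @export
kmeans_timeseries <- function(F, k = 4, restarts = 10, max_iter = 300,
                              seed = 1) {
  F <- unclass(F)
  n <- nrow(F)
  if (k < 1 || n < k)
    mk_error(sprintf("need n >= k >= 1 (n = %d, k = %d)", n, k),
             "mobilekin_invalid_k")
  best <- NULL
  for (r in seq_len(restarts)) {
    run <- with_seed(derive_seed(seed, r),
                     lloyd_once(F, k, max_iter))
    if (is.null(best) || run$D < best$D - 1e-12) best <- run
  }
  empty <- sum(tabulate(best$assignment, k) == 0)
  if (empty > 0)
    warning(sprintf(paste("degenerate clustering: %d empty cluster(s);",
                          "ties were broken toward the lowest index"),
                    empty))
  structure(c(best, list(k = k, seed = seed, restarts = restarts,
                         subjects = attr(F, "subjects"))),
            class = "cluster_model")
}

# One Lloyd run from a random assignment; returns assignment, centres, D.
lloyd_once <- function(F, k, max_iter) {
  n <- nrow(F)
  assign <- sample.int(k, n, replace = TRUE)
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    centres <- centre_means(F, assign, k)
    d2 <- dist2_to_centres(F, centres)
    # repair empty clusters: reseed at the subject farthest from its centre
    for (i in which(tabulate(assign, k) == 0)) {
      own <- d2[cbind(seq_len(n), assign)]
      far <- which.max(own)
      centres[i, ] <- F[far, ]
      d2 <- dist2_to_centres(F, centres)
      assign[far] <- i
    }
    new_assign <- max.col(-d2, ties.method = "first")
    D <- sum(d2[cbind(seq_len(n), new_assign)])
    if (length(trace) && D > trace[length(trace)] + 1e-9 * max(1, D))
      mk_error("objective increased across Lloyd iterations",
               "mobilekin_internal")
    trace <- c(trace, D)
    if (all(new_assign == assign) && iter > 1) break
    assign <- new_assign
  }
  centres <- centre_means(F, assign, k)
  d2 <- dist2_to_centres(F, centres)
  D <- sum(d2[cbind(seq_len(n), assign)])
  list(assignment = assign, centres = centres, D = D, n_iter = iter,
       D_trace = trace)
}

centre_means <- function(F, assign, k) {
  centres <- matrix(NA_real_, k, ncol(F))
  for (i in seq_len(k)) {
    m <- assign == i
    if (any(m)) centres[i, ] <- colMeans(F[m, , drop = FALSE])
  }
  # never leave NA rows: park empty centres far away until repaired
  centres[is.na(centres)] <- Inf
  centres
}

dist2_to_centres <- function(F, centres) {
  # ||x - v||^2 = ||x||^2 - 2 x.v + ||v||^2, guarded against Inf centres
  d2 <- matrix(0, nrow(F), nrow(centres))
  for (i in seq_len(nrow(centres))) {
    if (!all(is.finite(centres[i, ]))) { d2[, i] <- Inf; next }
    diff <- sweep(F, 2, centres[i, ])
    d2[, i] <- rowSums(diff * diff)
  }
  d2
}

#' Recompute the clustering objective from its parts
#'
#' @param model A `cluster_model`.
#' @param F The feature matrix the model was fitted on.
#' @return Scalar D, the sum of squared distances of each subject to its
#'   assigned centre.
#' @export
cluster_objective <- function(model, F) {
  F <- unclass(F)
  sum(vapply(seq_len(nrow(F)), function(j)
    sum((F[j, ] - model$centres[model$assignment[j], ])^2), numeric(1)))
}

#' Semantic labels for fitted clusters
#'
#' Names each cluster after its centre's behaviour: `no_increase` when the
#' connected-arm play-phase mean ratio stays below `arm_threshold`;
#' `arm_more_increase` when a centre has the largest final-block
#' connected-arm ratio of all centres and it exceeds `more_threshold`;
#' `all_limb_increase` when both leg play-phase means exceed
#' `arm_threshold`; otherwise `arm_increase`. On rule collision the priority
#' is arm_more > all_limb > arm > none.
#'
#' @param model A `cluster_model` fitted on a four-role feature matrix.
#' @param t_grid The 1 Hz grid used to build the features (default `0:719`).
#' @param arm_threshold Ratio above which a limb counts as increased
#'   (default 1.5, the conventional learning criterion).
#' @param more_threshold Final-block connected-arm ratio for the
#'   strong-increase label (default 2.5).
#' @return Character vector of labels, one per cluster.
#' @export
label_clusters <- function(model, t_grid = 0:719, arm_threshold = 1.5,
                           more_threshold = 2.5) {
  Tn <- length(t_grid)
  stopifnot(ncol(model$centres) == 4 * Tn)
  play <- t_grid >= 120
  p5 <- t_grid >= 600 & t_grid < 720
  role_block <- function(centre, role_idx, sel)
    mean(centre[(role_idx - 1) * Tn + which(sel)])
  cona_play <- apply(model$centres, 1, role_block, 1, play)
  cona_p5 <- apply(model$centres, 1, role_block, 1, p5)
  legs_play <- pmin(apply(model$centres, 1, role_block, 3, play),
                    apply(model$centres, 1, role_block, 4, play))
  labels <- character(model$k)
  for (i in seq_len(model$k)) {
    labels[i] <- if (cona_p5[i] == max(cona_p5) &&
                     cona_p5[i] > more_threshold) "arm_more_increase"
    else if (legs_play[i] > arm_threshold) "all_limb_increase"
    else if (cona_play[i] >= arm_threshold) "arm_increase"
    else "no_increase"
  }
  labels
}

#' Rand index between two partitions
#'
#' Fraction of subject pairs on which two labelings agree (same/different
#' cluster), used to score ground-truth recovery.
#'
#' @param a,b Integer or factor label vectors of equal length.
#' @return Scalar in \[0, 1\].
#' @export
rand_index <- function(a, b) {
  n <- length(a)
  stopifnot(length(b) == n)
  same_a <- outer(a, a, "==")[lower.tri(diag(n))]
  same_b <- outer(b, b, "==")[lower.tri(diag(n))]
  mean(same_a == same_b)
}
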