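#' Construct a reference table object
#'
#' Low-level constructor binding a summary-statistic matrix to model labels
#' and parameter values; [build_reference_table()] is the usual entry point.
#'
#' @param stats Numeric matrix, rows = simulations, columns named summary
#'   statistics (no missing entries).
#' @param labels Data frame with at least `category` and `submodel` columns
#'   (plus `inner`/`outer`, derived from `category` when absent).
#' @param params Numeric matrix of per-row parameter values (may be NULL).
#' @param meta List of provenance fields (seed, counts, mutation mode).
#' @return Object of class `abc_reftable`.
#' @export
new_reference_table <- function(stats, labels, params = NULL, meta = list()) {
  stats <- as.matrix(stats)
  if (anyNA(stats)) stop("reference table statistics contain missing values",
                         call. = FALSE)
  if (nrow(stats) != nrow(labels)) stop("stats/labels row mismatch")
  if (!"inner" %in% names(labels))
    labels$inner <- vapply(strsplit(labels$category, ".", fixed = TRUE),
                           `[[`, "", 1)
  if (!"outer" %in% names(labels))
    labels$outer <- vapply(strsplit(labels$category, ".", fixed = TRUE),
                           `[[`, "", 2)
  structure(list(stats = stats, labels = labels, params = params,
                 meta = meta), class = "abc_reftable")
}

#' @method print abc_reftable
#' @export
print.abc_reftable <- function(x, ...) {
  cat("abc_reftable:", nrow(x$stats), "simulations,",
      length(unique(x$labels$category)), "categories,",
      ncol(x$stats), "statistics\n")
  print(table(x$labels$category))
  invisible(x)
}

#' Build a reference table of simulated summary vectors
#'
#' For every listed model (scenario category x heterogeneity sub-model),
#' draws `n_per_model` parameter combinations from the priors, simulates a
#' multi-locus dataset for each and records its summary vector, model labels
#' and parameter values. Category labels pool the four sub-models for model
#' choice. A simulated dataset with zero polymorphic loci (possible in theta
#' mode under extreme draws) is redrawn; if such failures exceed 1% of the
#' requested simulations the run errors with a log of failed draws.
#'
#' @param models Data frame with `category` and `submodel` columns, e.g.
#'   [enumerate_models()] or a subset.
#' @param n_per_model Simulations per listed model.
#' @param locus_specs Locus specs shared by all simulations (see
#'   [make_locus_specs()]); in fixed-SNP mode must carry `s_obs`.
#' @param n_seq Haploid sequence counts for P1, P2, P3.
#' @param mode `"theta"` or `"fixed_snp"` mutation conditioning.
#' @param priors An [default_priors()] object.
#' @param rng_seed Optional integer seed for the whole build.
#' @return An `abc_reftable`.
#' @export
build_reference_table <- function(models, n_per_model, locus_specs,
                                  n_seq = c(20, 26, 16),
                                  mode = c("theta", "fixed_snp"),
                                  priors = default_priors(),
                                  rng_seed = NULL) {
  mode <- match.arg(mode)
  if (n_per_model < 1) stop("n_per_model must be >= 1", call. = FALSE)
  models <- as.data.frame(models)
  ntot <- nrow(models) * n_per_model
  with_seed(rng_seed, {
    stats <- matrix(NA_real_, ntot, length(summary_stat_names()),
                    dimnames = list(NULL, summary_stat_names()))
    params <- matrix(NA_real_, ntot, length(param_names()),
                     dimnames = list(NULL, param_names()))
    labels <- data.frame(category = character(ntot), submodel = character(ntot),
                         stringsAsFactors = FALSE)
    max_fail <- max(10, ceiling(0.01 * ntot))
    failed <- list()
    r <- 0L
    for (m in seq_len(nrow(models))) {
      for (j in seq_len(n_per_model)) {
        r <- r + 1L
        repeat {
          draw <- sample_parameters(models$category[m], models$submodel[m],
                                    priors)
          sim <- simulate_dataset_stats(draw, locus_specs, n_seq, mode,
                                        priors$mu)
          if (nrow(sim$stats) > 0) break
          failed[[length(failed) + 1]] <- unlist(draw[param_names()])
          if (length(failed) > max_fail)
            stop("more than 1% of simulated datasets were fully monomorphic; ",
                 length(failed), " failed draws logged", call. = FALSE)
        }
        stats[r, ] <- dataset_summary(sim$stats)
        params[r, ] <- unlist(draw[param_names()])
        labels$category[r] <- models$category[m]
        labels$submodel[r] <- models$submodel[m]
      }
    }
    meta <- list(seed = rng_seed, n_per_model = n_per_model, mode = mode,
                 n_loci = nrow(locus_specs), n_seq = n_seq,
                 n_failed = length(failed), failed_draws = failed)
    new_reference_table(stats, labels, params, meta)
  })
}

.rf_seed <- function(rng_seed, k) {
  if (is.null(rng_seed)) sample.int(.Machine$integer.max, 1) else rng_seed + k
}

#' Random-forest model choice with OOB-calibrated posterior probability
#'
#' Trains a classification random forest on the reference table's summary
#' statistics against grouped model labels, predicts the observed vector(s)
#' by majority vote, and estimates the posterior probability of the winning
#' group with a secondary regression forest fitted to the out-of-bag
#' correctness of the classifier (the abcrf approach). The out-of-bag
#' classification error of the forest is always reported.
#'
#' @param table An `abc_reftable`.
#' @param observed Named summary vector, or a matrix of such rows.
#' @param grouping `"category"`, `"inner"`, `"outer"`, or a vector of group
#'   labels of length `nrow(table$stats)`.
#' @param num_trees Trees per forest.
#' @param rng_seed Optional integer seed (forest training is seeded from it).
#' @return Object of class `model_posterior`: winning label(s), posterior
#'   probability, per-label vote fractions and the OOB error.
#' @export
classify <- function(table, observed, grouping = "category",
                     num_trees = 500, rng_seed = NULL) {
  stopifnot(inherits(table, "abc_reftable"))
  y <- if (length(grouping) == 1 && grouping %in% names(table$labels))
    table$labels[[grouping]]
  else if (length(grouping) == nrow(table$stats)) as.character(grouping)
  else stop("grouping must name a label column or give one label per row",
            call. = FALSE)
  y <- factor(y)
  if (nlevels(y) < 2)
    stop("degenerate reference table: fewer than 2 groups", call. = FALSE)
  obs <- .as_obs_matrix(observed, colnames(table$stats))
  df <- as.data.frame(table$stats)
  df$.group <- y
  rf <- ranger::ranger(dependent.variable.name = ".group", data = df,
                       num.trees = num_trees, seed = .rf_seed(rng_seed, 1),
                       respect.unordered.factors = TRUE,
                       num.threads = 1, verbose = FALSE)
  oob <- rf$predictions
  oob_error <- mean(oob != y, na.rm = TRUE)
  pr <- predict(rf, data = as.data.frame(obs), predict.all = TRUE,
                num.threads = 1)$predictions
  if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1)
  votes <- t(apply(pr, 1, function(v)
    tabulate(v, nbins = nlevels(y)) / length(v)))
  colnames(votes) <- levels(y)
  winner <- levels(y)[max.col(votes, ties.method = "first")]
  # regression forest on OOB correctness -> P(allocation correct | stats)
  correct <- as.numeric(as.character(oob) == as.character(y))
  dfr <- as.data.frame(table$stats)
  dfr$.correct <- ifelse(is.na(correct), 0, correct)
  rfr <- ranger::ranger(dependent.variable.name = ".correct", data = dfr,
                        num.trees = num_trees, seed = .rf_seed(rng_seed, 2),
                        num.threads = 1, verbose = FALSE)
  post <- predict(rfr, data = as.data.frame(obs),
                  num.threads = 1)$predictions
  post <- pmin(1, pmax(0, post))
  structure(list(winner = winner, posterior = post, votes = votes,
                 oob_error = oob_error, groups = levels(y),
                 num_trees = num_trees),
            class = "model_posterior")
}

.as_obs_matrix <- function(observed, stat_names) {
  if (is.null(dim(observed))) {
    if (!is.null(names(observed))) observed <- observed[stat_names]
    observed <- matrix(observed, nrow = 1,
                       dimnames = list(NULL, stat_names))
  } else {
    observed <- as.matrix(observed)
    if (!is.null(colnames(observed))) observed <- observed[, stat_names,
                                                           drop = FALSE]
    colnames(observed) <- stat_names
  }
  if (anyNA(observed)) stop("observed summary vector has missing entries",
                            call. = FALSE)
  observed
}

#' @method print model_posterior
#' @export
print.model_posterior <- function(x, ...) {
  cat("RF model choice over", length(x$groups), "groups (",
      x$num_trees, "trees ), OOB error", round(x$oob_error, 4), "\n")
  for (i in seq_along(x$winner))
    cat(sprintf("  obs %d: winner %s (posterior %.3f; votes %s)\n", i,
                x$winner[i], x$posterior[i],
                paste(sprintf("%s=%.2f", x$groups, x$votes[i, ]),
                      collapse = " ")))
  invisible(x)
}

#' Hierarchical two-question model choice
#'
#' Answers the two gene-flow questions independently on pooled labels:
#' (1) is migration between P1 and P2 ongoing (secondary contact `SC`) or
#' confined to the early post-split epoch (ancestral migration `AM`,
#' i.e. current isolation)? -- a binary classification pooling over the P3
#' configurations and sub-models; (2) which pattern of gene flow with P3 --
#' a four-way classification pooling over the P1-P2 pattern and sub-models.
#'
#' @param table An `abc_reftable` covering all 8 scenario categories.
#' @param observed Named summary vector or matrix of rows.
#' @inheritParams classify
#' @return List with `question1` and `question2` (`model_posterior`s) and
#'   `category` (the combined winning category per observation).
#' @export
hierarchical_inference <- function(table, observed, num_trees = 500,
                                   rng_seed = NULL) {
  stopifnot(inherits(table, "abc_reftable"))
  cats <- unique(table$labels$category)
  want <- enumerate_models()$category
  if (!all(unique(want) %in% cats))
    stop("reference table must cover all 8 scenario categories; missing: ",
         paste(setdiff(unique(want), cats), collapse = ", "), call. = FALSE)
  q1 <- classify(table, observed, grouping = "inner", num_trees = num_trees,
                 rng_seed = rng_seed)
  q2 <- classify(table, observed, grouping = "outer", num_trees = num_trees,
                 rng_seed = if (is.null(rng_seed)) NULL else rng_seed + 100)
  list(question1 = q1, question2 = q2,
       category = paste(q1$winner, q2$winner, sep = "."))
}

#' Random-forest parameter estimation
#'
#' Fits one regression forest per parameter (response = parameter value,
#' predictors = summary statistics) on the reference table, optionally
#' restricted to the winning scenario category (its four sub-models pooled),
#' and predicts the observed vector. Central 90% intervals come from
#' quantile regression over the trees. With `normalize = TRUE` sizes are
#' reported relative to the estimated current P1 size (N_P1 = 1 exactly)
#' and times in coalescent units of 4 N_P1 generations.
#'
#' @param table An `abc_reftable` with parameter values.
#' @param observed Named summary vector (one observation).
#' @param category Optional category string to restrict the table to.
#' @param parameters Parameters to estimate (default: all that vary).
#' @param normalize Report relative to the estimated N_P1.
#' @param num_trees Trees per forest.
#' @param rng_seed Optional integer seed.
#' @param level Central interval mass (default 0.90).
#' @return Data frame of class `parameter_estimates` with columns
#'   `parameter`, `estimate`, `lower`, `upper`; attribute `normalized`.
#' @export
estimate_parameters <- function(table, observed, category = NULL,
                                parameters = NULL, normalize = FALSE,
                                num_trees = 500, rng_seed = NULL,
                                level = 0.90) {
  stopifnot(inherits(table, "abc_reftable"))
  if (is.null(table$params)) stop("reference table has no parameter values")
  keep <- if (is.null(category)) seq_len(nrow(table$stats))
          else which(table$labels$category == category)
  if (length(keep) == 0)
    stop("no reference-table rows for category ", category, call. = FALSE)
  stats <- table$stats[keep, , drop = FALSE]
  params <- table$params[keep, , drop = FALSE]
  if (is.null(parameters)) {
    varying <- apply(params, 2, function(x) {
      x <- x[!is.na(x)]
      length(x) > 0 && diff(range(x)) > 0
    })
    constant <- apply(params, 2, function(x) {
      x <- x[!is.na(x)]
      length(x) > 0 && diff(range(x)) == 0
    })
    parameters <- colnames(params)[varying | constant]
  }
  obs <- .as_obs_matrix(observed, colnames(stats))
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  out <- data.frame(parameter = parameters, estimate = NA_real_,
                    lower = NA_real_, upper = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(parameters)) {
    y <- params[, parameters[i]]
    ok <- !is.na(y)
    if (!any(ok)) next
    if (diff(range(y[ok])) == 0) {
      out$estimate[i] <- out$lower[i] <- out$upper[i] <- y[ok][1]
      next
    }
    df <- as.data.frame(stats[ok, , drop = FALSE])
    df$.param <- y[ok]
    rf <- ranger::ranger(dependent.variable.name = ".param", data = df,
                         num.trees = num_trees, quantreg = TRUE,
                         seed = .rf_seed(rng_seed, i), num.threads = 1, verbose = FALSE)
    est <- predict(rf, data = as.data.frame(obs),
                   num.threads = 1)$predictions
    qq <- predict(rf, data = as.data.frame(obs), type = "quantiles",
                  quantiles = qs, num.threads = 1)$predictions
    out$estimate[i] <- est[1]
    out$lower[i] <- min(qq[1, 1], est[1])
    out$upper[i] <- max(qq[1, 2], est[1])
  }
  if (normalize) {
    nref <- out$estimate[out$parameter == "N_P1"]
    if (length(nref) != 1 || is.na(nref) || nref <= 0)
      stop("normalization requires an estimate of N_P1", call. = FALSE)
    sizes <- grepl("^N_", out$parameter)
    times <- grepl("^T_", out$parameter)
    for (cl in c("estimate", "lower", "upper")) {
      out[[cl]][sizes] <- out[[cl]][sizes] / nref
      out[[cl]][times] <- out[[cl]][times] / (4 * nref)
    }
    out[out$parameter == "N_P1", c("estimate", "lower", "upper")] <-
      c(1, 1, 1)
  }
  attr(out, "normalized") <- normalize
  attr(out, "category") <- category
  class(out) <- c("parameter_estimates", "data.frame")
  out
}

#' Posterior predictive check
#'
#' Simulates `n_rep` datasets at the point estimates under the winning
#' model and reports, for every summary statistic, the two-sided tail
#' probability of the observed value within the replicate distribution.
#'
#' @param estimates A non-normalized [estimate_parameters()] result (or a
#'   named vector of parameter values in natural units).
#' @param category,submodel Winning scenario category and sub-model used to
#'   simulate the replicates.
#' @param observed Named summary vector of the observed data.
#' @param locus_specs Locus specs for the replicate datasets.
#' @param n_seq Haploid sequence counts.
#' @param n_rep Number of replicate datasets.
#' @param mode,mu Mutation conditioning and rate.
#' @param rng_seed Optional integer seed.
#' @return Data frame with `statistic`, `observed`, `tail_prob`.
#' @export
posterior_predictive_check <- function(estimates, category,
                                       submodel = "NeHom.MHom", observed,
                                       locus_specs, n_seq = c(20, 26, 16),
                                       n_rep = 100,
                                       mode = c("theta", "fixed_snp"),
                                       mu = 3e-9, rng_seed = NULL) {
  mode <- match.arg(mode)
  if (inherits(estimates, "parameter_estimates")) {
    if (isTRUE(attr(estimates, "normalized")))
      stop("posterior predictive check needs estimates in natural units",
           call. = FALSE)
    est <- setNames(estimates$estimate, estimates$parameter)
  } else est <- estimates
  draw <- .draw_from_values(est, category, submodel)
  obs <- .as_obs_matrix(observed, summary_stat_names())
  with_seed(rng_seed, {
    reps <- matrix(NA_real_, n_rep, length(summary_stat_names()),
                   dimnames = list(NULL, summary_stat_names()))
    for (r in seq_len(n_rep)) {
      sim <- simulate_dataset_stats(draw, locus_specs, n_seq, mode, mu)
      if (nrow(sim$stats) == 0) next
      reps[r, ] <- dataset_summary(sim$stats)
    }
    reps <- reps[stats::complete.cases(reps), , drop = FALSE]
    if (nrow(reps) == 0) stop("all replicate datasets were monomorphic")
    p <- vapply(seq_len(ncol(reps)), function(j) {
      lo <- mean(reps[, j] <= obs[1, j])
      hi <- mean(reps[, j] >= obs[1, j])
      min(1, 2 * min(lo, hi))
    }, 1)
    data.frame(statistic = summary_stat_names(), observed = obs[1, ],
               tail_prob = p, row.names = NULL)
  })
}

## assemble a param_draw from named values, filling unmentioned fields
.draw_from_values <- function(values, category, submodel) {
  d <- list(N_P1 = 1e4, N_P2 = 1e4, N_P3 = 1e4, N_anc12 = 1e4,
            N_anc123 = 1e4, N_found_P1 = 1e4, N_found_P2 = 1e4,
            N_found_P3 = 1e4, T_change_P1 = 0, T_change_P2 = 0,
            T_change_P3 = 0, T_split12 = 1e5, T_split123 = 2e5,
            T_trans12 = 5e4, M12 = 0, M13 = 0, M23 = 0,
            shape1_Ne = NA_real_, shape2_Ne = NA_real_,
            shape1_M = NA_real_, shape2_M = NA_real_)
  for (nm in intersect(names(values), names(d)))
    if (!is.na(values[[nm]])) d[[nm]] <- unname(values[[nm]])
  # honour the model's constraints
  d$T_split12 <- min(d$T_split12, d$T_split123)
  d$T_trans12 <- min(d$T_trans12, d$T_split12)
  d$T_change_P1 <- min(d$T_change_P1, d$T_split12)
  d$T_change_P2 <- min(d$T_change_P2, d$T_split12)
  d$T_change_P3 <- min(d$T_change_P3, d$T_split123)
  cat_ <- .split_category(category)
  if (!cat_$outer %in% c("GF13", "GF1323")) d$M13 <- 0
  if (!cat_$outer %in% c("GF23", "GF1323")) d$M23 <- 0
  sub_ <- .split_submodel(submodel)
  if (!sub_$ne_hetero) { d$shape1_Ne <- NA_real_; d$shape2_Ne <- NA_real_ }
  else if (is.na(d$shape1_Ne)) { d$shape1_Ne <- 2; d$shape2_Ne <- 2 }
  if (!sub_$nm_hetero) { d$shape1_M <- NA_real_; d$shape2_M <- NA_real_ }
  else if (is.na(d$shape1_M)) { d$shape1_M <- 1; d$shape2_M <- 1 }
  d$category <- category
  d$submodel <- submodel
  class(d) <- "param_draw"
  d
}
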