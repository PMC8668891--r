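#' Locus-spec presets emulating the study dataset shape
#'
#' The default preset reproduces the shape of the observed RAD dataset:
#' 2,740 polymorphic biallelic loci, lengths in \[343, 908\] bp, and
#' 20/26/16 allele sequences for P1/P2/P3 (10/13/8 diploid males). The
#' `"fixed_snp"` preset uses the alternative length range \[339, 894\]
#' quoted for the fixed-SNP conditioning. Lengths are drawn uniformly within
#' the bounds by default; a truncated-geometric option is provided to match
#' the observed mean length (463.12 bp) inside the same range.
#'
#' @param name `"default"` or `"fixed_snp"`.
#' @param n_loci,length_range,n_seq,mean_length Override preset fields.
#' @param length_dist `"uniform"` or `"truncgeom"`.
#' @param snp_profile Optional integer vector of observed per-locus SNP
#'   counts to resample from (clipped to \[1, 91\]).
#' @return List of class `locus_preset`.
#' @export
locus_preset <- function(name = c("default", "fixed_snp"), n_loci = 2740,
                         length_range = NULL, n_seq = c(20, 26, 16),
                         length_dist = c("uniform", "truncgeom"),
                         mean_length = 463.12, snp_profile = NULL) {
  name <- match.arg(name)
  length_dist <- match.arg(length_dist)
  if (is.null(length_range))
    length_range <- if (name == "fixed_snp") c(339, 894) else c(343, 908)
  if (length_range[1] > length_range[2] || length_range[1] < 1)
    stop("invalid length bounds", call. = FALSE)
  if (!is.null(snp_profile)) {
    snp_profile <- pmin(pmax(as.integer(snp_profile), 1L), 91L)
  }
  structure(list(name = name, n_loci = as.integer(n_loci),
                 length_range = as.integer(length_range),
                 n_seq = as.integer(n_seq), length_dist = length_dist,
                 mean_length = mean_length, snp_profile = snp_profile),
            class = "locus_preset")
}

#' Draw locus specs from a preset
#'
#' @param preset A [locus_preset()].
#' @param rng_seed Optional integer seed.
#' @return Data frame with columns `length` and, when the preset carries an
#'   SNP profile, `s_obs`.
#' @export
make_locus_specs <- function(preset = locus_preset(), rng_seed = NULL) {
  stopifnot(inherits(preset, "locus_preset"))
  with_seed(rng_seed, {
    lo <- preset$length_range[1]; hi <- preset$length_range[2]
    len <- if (preset$length_dist == "uniform") {
      sample(lo:hi, preset$n_loci, replace = TRUE)
    } else {
      # truncated geometric over [lo, hi] with rate chosen so the mean
      # matches the preset's mean length
      vals <- lo:hi
      f <- function(r) sum(vals * exp(-r * (vals - lo))) /
        sum(exp(-r * (vals - lo))) - preset$mean_length
      r <- stats::uniroot(f, c(1e-8, 1))$root
      sample(vals, preset$n_loci, replace = TRUE,
             prob = exp(-r * (vals - lo)))
    }
    specs <- data.frame(length = len)
    if (!is.null(preset$snp_profile))
      specs$s_obs <- pmin(sample(preset$snp_profile, preset$n_loci,
                                 replace = TRUE), specs$length)
    specs
  })
}

#' Generate a pseudo-observed dataset with known ground truth
#'
#' Simulates one dataset under a chosen scenario category and heterogeneity
#' sub-model, writes it in the package's FASTA and VCF dialects plus a
#' plain-text ground-truth sidecar, and returns the in-memory dataset. The
#' sidecar records everything needed to regenerate the dataset
#' byte-identically (category, sub-model, full parameter draw, seed,
#' preset). The generated dataset is already clean: it passes
#' [filter_loci()] unchanged.
#'
#' @param category,submodel Generating model.
#' @param preset A [locus_preset()].
#' @param priors Priors to draw parameters from (ignored when `draw` given).
#' @param draw Optional explicit `param_draw`.
#' @param mode `"theta"` (default: SNP counts arise from the coalescent) or
#'   `"fixed_snp"`.
#' @param dir Output directory (created if needed); `NULL` skips writing.
#' @param rng_seed Integer seed (required for regeneration).
#' @param species Species labels.
#' @return List with `dataset` (`locus_dataset`), `truth` (ground-truth
#'   record) and `paths`.
#' @export
generate_pseudo_observed <- function(category, submodel = "NeHom.MHom",
                                     preset = locus_preset(),
                                     priors = default_priors(), draw = NULL,
                                     mode = c("theta", "fixed_snp"),
                                     dir = NULL, rng_seed = 1,
                                     species = c("P1", "P2", "P3")) {
  mode <- match.arg(mode)
  with_seed(rng_seed, {
    # fix the simulation seed before any optional draws so that regeneration
    # from an explicit draw consumes the stream identically
    sim_seed <- sample.int(2^31 - 1, 1)
    specs <- make_locus_specs(preset)
    if (is.null(draw)) draw <- sample_parameters(category, submodel, priors)
    dataset <- simulate_dataset(draw, specs, preset$n_seq, mode, priors$mu,
                                rng_seed = sim_seed, species = species)
    truth <- list(category = category, submodel = submodel,
                  draw = draw, rng_seed = rng_seed, preset = preset,
                  mode = mode, mu = priors$mu,
                  n_loci_out = n_loci(dataset))
    paths <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      paths <- list(fasta = file.path(dir, "pod.fasta"),
                    vcf = file.path(dir, "pod.vcf"),
                    loci = file.path(dir, "pod_loci.tsv"),
                    truth = file.path(dir, "pod_truth.txt"))
      write_loci_fasta(dataset, paths$fasta)
      write_loci_vcf(dataset, paths$vcf)
      write_locus_table(dataset, paths$loci)
      write_truth_record(truth, paths$truth)
    }
    list(dataset = dataset, truth = truth, paths = paths)
  })
}

#' Write / read a ground-truth sidecar (plain-text key-value)
#'
#' @param truth Ground-truth record from [generate_pseudo_observed()].
#' @param path File path.
#' @export
write_truth_record <- function(truth, path) {
  d <- truth$draw
  pv <- unlist(d[param_names()])
  lines <- c(paste("category =", truth$category),
             paste("submodel =", truth$submodel),
             paste("mode =", truth$mode),
             paste("mu =", format(truth$mu, digits = 17)),
             paste("rng_seed =", truth$rng_seed),
             paste("preset_name =", truth$preset$name),
             paste("n_loci =", truth$preset$n_loci),
             paste("length_range =",
                   paste(truth$preset$length_range, collapse = ", ")),
             paste("n_seq =", paste(truth$preset$n_seq, collapse = ", ")),
             paste("length_dist =", truth$preset$length_dist),
             paste0(names(pv), " = ", format(pv, digits = 17)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_truth_record
#' @export
read_truth_record <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  getv <- function(k) vals[match(k, keys)]
  to_num <- function(v) ifelse(v %in% c("NA", "NaN"), NA_real_,
                               suppressWarnings(as.numeric(v)))
  num <- function(k) to_num(trimws(strsplit(getv(k), ",")[[1]]))
  d <- lapply(param_names(), function(p) to_num(getv(p)))
  names(d) <- param_names()
  d$category <- getv("category")
  d$submodel <- getv("submodel")
  class(d) <- "param_draw"
  preset <- locus_preset(getv("preset_name"),
                         n_loci = as.integer(getv("n_loci")),
                         length_range = num("length_range"),
                         n_seq = as.integer(num("n_seq")),
                         length_dist = getv("length_dist"))
  list(category = getv("category"), submodel = getv("submodel"), draw = d,
       rng_seed = as.integer(getv("rng_seed")), preset = preset,
       mode = getv("mode"), mu = as.numeric(getv("mu")))
}

#' Regenerate a pseudo-observed dataset from its ground-truth record
#' @param truth Record from [read_truth_record()] or
#'   [generate_pseudo_observed()].
#' @return The regenerated `locus_dataset`.
#' @export
regenerate_pseudo_observed <- function(truth) {
  generate_pseudo_observed(truth$category, truth$submodel, truth$preset,
                           draw = truth$draw, mode = truth$mode,
                           dir = NULL, rng_seed = truth$rng_seed)$dataset
}

#' Model-choice and parameter recovery experiment
#'
#' For each requested scenario category, draws `n_pods` pseudo-observed
#' summary vectors from the priors (sub-models sampled uniformly unless
#' `pod_submodel` is fixed), classifies them with the two hierarchical
#' questions against a reference table, and (optionally) estimates
#' parameters for PODs of selected categories. Returns the confusion matrix
#' of combined categories, per-question accuracies, the mean posterior
#' assigned to the true group, and true-versus-estimated correlations.
#'
#' @param table An `abc_reftable` covering the categories of interest.
#' @param categories Generating categories for the PODs.
#' @param n_pods PODs per category.
#' @param locus_specs Locus specs for the PODs.
#' @param n_seq Haploid sequence counts.
#' @param priors Priors for the POD draws.
#' @param mode Mutation conditioning for the PODs.
#' @param pod_submodel Fixed sub-model for PODs, or `NULL` to sample one of
#'   the four uniformly per POD.
#' @param estimate Character vector of parameters to recover (Spearman
#'   correlation across PODs, per category); `NULL` skips estimation.
#' @param num_trees Trees per forest.
#' @param rng_seed Optional integer seed.
#' @return List with `confusion`, `accuracy_q1`, `accuracy_q2`,
#'   `mean_posterior_true`, `truth` (per-POD data frame) and
#'   `param_recovery`.
#' @export
recovery_experiment <- function(table, categories, n_pods, locus_specs,
                                n_seq = c(20, 26, 16),
                                priors = default_priors(),
                                mode = c("theta", "fixed_snp"),
                                pod_submodel = NULL, estimate = NULL,
                                num_trees = 500, rng_seed = NULL) {
  mode <- match.arg(mode)
  if (length(categories) == 0 || n_pods < 1)
    stop("design is empty", call. = FALSE)
  submods <- enumerate_models()
  submods <- unique(submods$submodel)
  with_seed(rng_seed, {
    npod_tot <- length(categories) * n_pods
    pods <- matrix(NA_real_, npod_tot, length(summary_stat_names()),
                   dimnames = list(NULL, summary_stat_names()))
    truth <- data.frame(category = rep(categories, each = n_pods),
                        submodel = NA_character_,
                        stringsAsFactors = FALSE)
    truth[param_names()] <- NA_real_
    r <- 0L
    for (cat_ in categories) {
      for (j in seq_len(n_pods)) {
        r <- r + 1L
        sub_ <- if (is.null(pod_submodel)) sample(submods, 1) else pod_submodel
        repeat {
          draw <- sample_parameters(cat_, sub_, priors)
          sim <- simulate_dataset_stats(draw, locus_specs, n_seq, mode,
                                        priors$mu)
          if (nrow(sim$stats) > 0) break
        }
        pods[r, ] <- dataset_summary(sim$stats)
        truth$submodel[r] <- sub_
        truth[r, param_names()] <- unlist(draw[param_names()])
      }
    }
    rf_seed <- sample.int(2^30, 1)
    q1 <- classify(table, pods, grouping = "inner", num_trees = num_trees,
                   rng_seed = rf_seed)
    q2 <- classify(table, pods, grouping = "outer", num_trees = num_trees,
                   rng_seed = rf_seed + 1)
    true_inner <- vapply(strsplit(truth$category, ".", fixed = TRUE),
                         `[[`, "", 1)
    true_outer <- vapply(strsplit(truth$category, ".", fixed = TRUE),
                         `[[`, "", 2)
    pred_cat <- paste(q1$winner, q2$winner, sep = ".")
    confusion <- base::table(true = truth$category, predicted = pred_cat)
    mean_post_true <-
      mean(c(q1$votes[cbind(seq_len(npod_tot),
                            match(true_inner, q1$groups))],
             q2$votes[cbind(seq_len(npod_tot),
                            match(true_outer, q2$groups))]))
    param_recovery <- NULL
    if (!is.null(estimate)) {
      param_recovery <- do.call(rbind, lapply(unique(truth$category),
                                              function(cat_) {
        idx <- which(truth$category == cat_)
        if (!cat_ %in% table$labels$category) return(NULL)
        ests <- .batch_estimate(table, pods[idx, , drop = FALSE], cat_,
                                estimate, num_trees, rf_seed + 10)
        do.call(rbind, lapply(estimate, function(p) {
          data.frame(category = cat_, parameter = p,
                     spearman = suppressWarnings(
                       cor(truth[[p]][idx], ests[, p], method = "spearman")),
                     stringsAsFactors = FALSE)
        }))
      }))
    }
    list(confusion = confusion,
         accuracy_q1 = mean(q1$winner == true_inner),
         accuracy_q2 = mean(q2$winner == true_outer),
         mean_posterior_true = mean_post_true,
         question1 = q1, question2 = q2,
         truth = truth, pods = pods, param_recovery = param_recovery)
  })
}

## one regression forest per parameter, predictions for many observations
.batch_estimate <- function(table, obs, category, parameters, num_trees,
                            rng_seed) {
  keep <- which(table$labels$category == category)
  stats <- table$stats[keep, , drop = FALSE]
  params <- table$params[keep, , drop = FALSE]
  out <- matrix(NA_real_, nrow(obs), length(parameters),
                dimnames = list(NULL, parameters))
  for (i in seq_along(parameters)) {
    y <- params[, parameters[i]]
    ok <- !is.na(y)
    df <- as.data.frame(stats[ok, , drop = FALSE])
    df$.param <- y[ok]
    rf <- ranger::ranger(dependent.variable.name = ".param", data = df,
                         num.trees = num_trees, seed = rng_seed + i,
                         num.threads = 1, verbose = FALSE)
    out[, i] <- predict(rf, data = as.data.frame(obs),
                        num.threads = 1)$predictions
  }
  out
}
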