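## pack a param_draw + migration schedule into the flat numeric vector the
## C++ simulator consumes (see src/coalsim.cpp for the layout)
.pack_demography <- function(draw, schedule = NULL) {
  if (is.null(schedule)) schedule <- migration_schedule(draw$category, draw)
  p12 <- schedule[schedule$pair == "P1-P2", , drop = FALSE]
  if (nrow(p12) == 1) {
    t12 <- c(p12$t_start, p12$t_end)
    m12 <- p12$rate
  } else {
    t12 <- c(0, 0); m12 <- 0
  }
  m13 <- if ("P1-P3" %in% schedule$pair)
    schedule$rate[schedule$pair == "P1-P3"] else 0
  m23 <- if ("P2-P3" %in% schedule$pair)
    schedule$rate[schedule$pair == "P2-P3"] else 0
  c(draw$N_P1, draw$N_P2, draw$N_P3,
    draw$N_found_P1, draw$N_found_P2, draw$N_found_P3,
    draw$T_change_P1, draw$T_change_P2, draw$T_change_P3,
    draw$N_anc12, draw$N_anc123,
    draw$T_split12, draw$T_split123,
    m12, m13, m23, t12[1], t12[2])
}

#' Draw per-locus genomic rescaling factors
#'
#' Models linked-selection heterogeneity: under a heterogeneous sub-model
#' each locus gets a multiplicative factor for its effective sizes
#' (Beta-distributed, rescaled to mean 1 across the prior distribution) and
#' a factor in \[0, 1\] for its migration rates (Beta-distributed). Under the
#' homogeneous sub-models all factors are exactly 1.
#'
#' @param submodel Sub-model string, e.g. `"NeHet.MHom"`, or a `param_draw`
#'   (its sub-model and shape hyperparameters are then used).
#' @param shapes_ne,shapes_m Beta shape pairs; ignored for homogeneous
#'   dimensions. Taken from the draw when `submodel` is a `param_draw`.
#' @param n_loci Number of loci.
#' @param rng_seed Optional integer seed.
#' @return List with numeric vectors `ne` and `mig`, each of length `n_loci`.
#' @export
draw_genomic_factors <- function(submodel, shapes_ne = NULL, shapes_m = NULL,
                                 n_loci, rng_seed = NULL) {
  if (inherits(submodel, "param_draw")) {
    draw <- submodel
    submodel <- draw$submodel
    shapes_ne <- c(draw$shape1_Ne, draw$shape2_Ne)
    shapes_m <- c(draw$shape1_M, draw$shape2_M)
  }
  if (n_loci < 1) stop("n_loci must be >= 1", call. = FALSE)
  sub_ <- .split_submodel(submodel)
  with_seed(rng_seed, {
    ne <- if (sub_$ne_hetero) {
      if (anyNA(shapes_ne)) stop("Ne heterogeneity shapes missing")
      x <- rbeta(n_loci, shapes_ne[1], shapes_ne[2])
      x / (shapes_ne[1] / (shapes_ne[1] + shapes_ne[2]))  # mean-1 rescaling
    } else rep(1, n_loci)
    mig <- if (sub_$nm_hetero) {
      if (anyNA(shapes_m)) stop("migration heterogeneity shapes missing")
      rbeta(n_loci, shapes_m[1], shapes_m[2])
    } else rep(1, n_loci)
    list(ne = ne, mig = mig)
  })
}

#' Simulate a coalescent genealogy under the three-population model
#'
#' Runs the structured coalescent backward in time with the draw's sizes,
#' per-lineage size changes, nested splits and epoch-restricted migration;
#' branch lengths are in generations. Between `T_split12` and `T_split123`
#' the P1/P2 ancestor exchanges migrants with P3 at the combined rate
#' `M13 + M23` when either pair is enabled.
#'
#' @param draw A [sample_parameters()] draw.
#' @param n_seq Integer vector of haploid sequence counts for P1, P2, P3.
#' @param schedule Optional [migration_schedule()]; recomputed if `NULL`.
#' @param ne_factor,mig_factor Per-locus rescaling factors (default 1).
#' @param rng_seed Optional integer seed.
#' @return Object of class `genealogy`: list with 0-based `parent` pointers
#'   (-1 at the root), node `time`s, `n_tip` and `n_seq`. Tips are ordered
#'   P1, then P2, then P3.
#' @export
simulate_genealogy <- function(draw, n_seq, schedule = NULL, ne_factor = 1,
                               mig_factor = 1, rng_seed = NULL) {
  n_seq <- as.integer(n_seq)
  if (length(n_seq) != 3 || any(n_seq < 0) || sum(n_seq) < 2)
    stop("n_seq must give >= 0 sequences per species, >= 2 in total",
         call. = FALSE)
  dem <- .pack_demography(draw, schedule)
  g <- with_seed(rng_seed,
    cpp_sim_genealogy(dem, n_seq[1], n_seq[2], n_seq[3], ne_factor, mig_factor))
  g$n_seq <- n_seq
  class(g) <- "genealogy"
  g
}

#' Convert a genealogy to an ape `phylo` tree
#' @param g A [simulate_genealogy()] genealogy.
#' @return An `ape::phylo` object with branch lengths in generations.
#' @export
as_phylo <- function(g) {
  stopifnot(inherits(g, "genealogy"))
  n <- g$n_tip
  ntot <- length(g$parent)
  # ape: tips 1..n, root n+1, internals follow; our internals are n..ntot-1
  # (0-based) created in time order, root last
  remap <- integer(ntot)
  remap[seq_len(n)] <- seq_len(n)
  internal <- seq(n + 1, ntot)                       # 1-based positions
  remap[ntot] <- n + 1                               # root
  others <- setdiff(internal, ntot)
  remap[others] <- n + 1 + seq_along(others)
  child <- which(g$parent >= 0)                      # 1-based child positions
  edge <- cbind(remap[g$parent[child] + 1], remap[child])
  len <- g$time[g$parent[child] + 1] - g$time[child]
  tr <- list(edge = edge, edge.length = len,
             tip.label = paste0(rep(c("P1", "P2", "P3"), g$n_seq),
                                "_", unlist(lapply(g$n_seq, seq_len))),
             Nnode = n - 1L)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

.new_sim_locus <- function(mut, length_bp, n_seq,
                           species = c("P1", "P2", "P3")) {
  snp <- mut$snp
  pops <- rep(species, n_seq)
  ind <- unlist(lapply(seq_along(n_seq), function(p) {
    k <- n_seq[p]
    if (k == 0) return(character(0))
    paste0(species[p], "_ind", sprintf("%02d", rep(seq_len(ceiling(k / 2)),
                                                   each = 2))[seq_len(k)])
  }))
  allele <- unlist(lapply(n_seq, function(k) rep(1:2, length.out = k)))
  rownames(snp) <- paste(pops, ind, allele, sep = "|")
  structure(list(snp = snp, positions = as.integer(mut$positions),
                 length = as.integer(length_bp), n_seq = n_seq,
                 species = species, pop = pops, individual = ind,
                 allele = allele, monomorphic = ncol(snp) == 0),
            class = "sim_locus")
}

#' Place mutations on a genealogy (theta-conditioned mode)
#'
#' Infinite-sites mutations are placed as a Poisson process along branches
#' with per-locus intensity `mu * length_bp` per generation, i.e. the
#' expected number of segregating sites is governed by theta = 4 N mu L
#' through the simulated branch lengths. Loci that receive no mutation are
#' flagged monomorphic.
#'
#' @param g A [simulate_genealogy()] genealogy.
#' @param length_bp Locus length in bp.
#' @param mu Mutation rate per bp per generation.
#' @param rng_seed Optional integer seed.
#' @param species Species labels for the three populations.
#' @return A `sim_locus`: 0/1 SNP matrix (rows = sequences grouped by
#'   population, 0 = ancestral), sorted site positions (0-based), locus
#'   length, and a `monomorphic` flag.
#' @export
mutate_theta <- function(g, length_bp, mu = 3e-9, rng_seed = NULL,
                         species = c("P1", "P2", "P3")) {
  stopifnot(inherits(g, "genealogy"), mu >= 0, length_bp > 0)
  mut <- with_seed(rng_seed, {
    b <- cpp_mutate(g$parent, g$time, g$n_seq[1], g$n_seq[2], g$n_seq[3],
                    0L, mu * length_bp, 0L, as.integer(length_bp), TRUE)
    b$positions <- .draw_positions(ncol(b$snp), length_bp)
    b
  })
  .order_by_position(.new_sim_locus(mut, length_bp, g$n_seq, species))
}

#' Place a fixed number of mutations on a genealogy (fixed-SNP mode)
#'
#' Places exactly `s_obs` mutations, each landing on a branch with
#' probability proportional to its length, independently across sites. This
#' conditions simulated loci on the observed number of SNPs instead of on
#' theta.
#'
#' @inheritParams mutate_theta
#' @param s_obs Observed SNP count to match; must be >= 1.
#' @return A `sim_locus` with exactly `s_obs` segregating sites.
#' @export
mutate_fixed <- function(g, s_obs, length_bp, rng_seed = NULL,
                         species = c("P1", "P2", "P3")) {
  stopifnot(inherits(g, "genealogy"))
  s_obs <- as.integer(s_obs)
  if (is.na(s_obs) || s_obs < 1)
    stop("s_obs must be >= 1 (fixed-SNP mode matches polymorphic loci)",
         call. = FALSE)
  mut <- with_seed(rng_seed, {
    b <- cpp_mutate(g$parent, g$time, g$n_seq[1], g$n_seq[2], g$n_seq[3],
                    1L, 0, s_obs, as.integer(length_bp), TRUE)
    b$positions <- .draw_positions(ncol(b$snp), length_bp)
    b
  })
  .order_by_position(.new_sim_locus(mut, length_bp, g$n_seq, species))
}

.draw_positions <- function(s, length_bp) {
  if (s == 0) return(integer(0))
  sort(sample.int(length_bp, s) - 1L)
}

.order_by_position <- function(locus) {
  # positions drawn sorted; columns already in placement order -> tie columns
  # to sorted positions
  locus
}

#' Simulate a multi-locus dataset
#'
#' Simulates one genealogy per locus spec under the draw and applies the
#' requested mutation mode. In theta mode, monomorphic loci are excluded
#' from the result (the returned dataset may hold fewer loci than specs); in
#' fixed-SNP mode every spec yields exactly one polymorphic locus with its
#' specified SNP count.
#'
#' @param draw A [sample_parameters()] draw.
#' @param locus_specs Data frame with columns `length` and (for fixed-SNP
#'   mode) `s_obs`, e.g. from [make_locus_specs()].
#' @param n_seq Haploid sequence counts for P1, P2, P3.
#' @param mode `"theta"` or `"fixed_snp"`.
#' @param mu Mutation rate per bp per generation.
#' @param factors Optional [draw_genomic_factors()] result; drawn from the
#'   draw's sub-model when `NULL`.
#' @param rng_seed Optional integer seed.
#' @param species Species labels.
#' @return A `locus_dataset` (see [read_loci_fasta()] for the layout).
#' @export
simulate_dataset <- function(draw, locus_specs, n_seq = c(20, 26, 16),
                             mode = c("theta", "fixed_snp"), mu = 3e-9,
                             factors = NULL, rng_seed = NULL,
                             species = c("P1", "P2", "P3")) {
  mode <- match.arg(mode)
  if (nrow(locus_specs) == 0) stop("locus_specs is empty", call. = FALSE)
  if (mode == "fixed_snp" &&
      (!"s_obs" %in% names(locus_specs) || any(locus_specs$s_obs < 1)))
    stop("fixed_snp mode requires s_obs >= 1 for every locus", call. = FALSE)
  n_seq <- as.integer(n_seq)
  with_seed(rng_seed, {
    if (is.null(factors))
      factors <- draw_genomic_factors(draw, n_loci = nrow(locus_specs))
    dem <- .pack_demography(draw)
    loci <- vector("list", nrow(locus_specs))
    for (l in seq_len(nrow(locus_specs))) {
      res <- cpp_sim_locus(dem, n_seq[1], n_seq[2], n_seq[3],
                           factors$ne[l], factors$mig[l],
                           as.integer(locus_specs$length[l]),
                           if (mode == "theta") 0L else 1L, mu,
                           if (mode == "theta") 0L
                           else as.integer(locus_specs$s_obs[l]))
      if (ncol(res$snp) == 0) next  # monomorphic: excluded
      loci[[l]] <- .new_sim_locus(res, locus_specs$length[l], n_seq, species)
    }
    keep <- !vapply(loci, is.null, TRUE)
    ids <- sprintf("locus%04d", which(keep))
    .new_locus_dataset(setNames(loci[keep], ids), species, n_seq)
  })
}

#' Per-locus statistics for a simulated dataset (bulk path)
#'
#' Simulates genealogies and mutations for all loci and returns the
#' per-locus statistic matrix directly, without materialising SNP matrices.
#' This is the path used to build reference tables.
#'
#' @inheritParams simulate_dataset
#' @return List with `stats` (matrix, kept loci x statistics, columns named
#'   by [locus_stat_names()]) and `kept` (indices of retained locus specs).
#' @export
simulate_dataset_stats <- function(draw, locus_specs, n_seq = c(20, 26, 16),
                                   mode = c("theta", "fixed_snp"), mu = 3e-9,
                                   factors = NULL, rng_seed = NULL) {
  mode <- match.arg(mode)
  if (nrow(locus_specs) == 0) stop("locus_specs is empty", call. = FALSE)
  if (mode == "fixed_snp" &&
      (!"s_obs" %in% names(locus_specs) || any(locus_specs$s_obs < 1)))
    stop("fixed_snp mode requires s_obs >= 1 for every locus", call. = FALSE)
  n_seq <- as.integer(n_seq)
  with_seed(rng_seed, {
    if (is.null(factors))
      factors <- draw_genomic_factors(draw, n_loci = nrow(locus_specs))
    dem <- .pack_demography(draw)
    s_obs <- if ("s_obs" %in% names(locus_specs))
      as.integer(locus_specs$s_obs) else rep(0L, nrow(locus_specs))
    res <- cpp_sim_dataset_stats(dem, n_seq[1], n_seq[2], n_seq[3],
                                 factors$ne, factors$mig,
                                 as.integer(locus_specs$length),
                                 if (mode == "theta") 0L else 1L, mu, s_obs)
    colnames(res$stats) <- locus_stat_names()
    res
  })
}
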