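#' Canonical per-locus statistic names
#'
#' Fixed ordering shared by per-locus tables, summary vectors and reference
#' tables: per-species nucleotide diversity, Watterson's theta and Tajima's
#' D; per-pair gross divergence, net divergence and FST (pairs P1P2, P1P3,
#' P2P3); per-pair site-pattern counts (shared polymorphisms `ss`, fixed
#' differences `sf`, polymorphisms exclusive to the first / second member
#' `sxA`/`sxB`); and the ABBA-BABA numerator, denominator and per-locus D.
#'
#' @return Character vector of length 33.
#' @export
locus_stat_names <- function() {
  sp <- c("P1", "P2", "P3")
  pr <- c("P1P2", "P1P3", "P2P3")
  c(paste0("pi_", sp), paste0("thetaW_", sp), paste0("tajD_", sp),
    paste0("dxy_", pr), paste0("da_", pr), paste0("fst_", pr),
    as.vector(t(outer(pr, c("ss", "sf", "sxA", "sxB"),
                      function(p, s) paste0(s, "_", p)))),
    "dstat_num", "dstat_den", "dstat")
}

#' Names of the dataset-level summary vector
#' @return Character vector: mean and (population) SD of every per-locus
#'   statistic, then the dataset-level ABBA-BABA `dstat_total`.
#' @export
summary_stat_names <- function() {
  nm <- locus_stat_names()
  c(paste0("mean_", nm), paste0("sd_", nm), "dstat_total")
}

.check_matrix <- function(mat, min_seq = 1) {
  if (!is.matrix(mat)) mat <- matrix(mat, nrow = 1)
  if (nrow(mat) < min_seq)
    stop("statistic undefined: needs at least ", min_seq, " sequences",
         call. = FALSE)
  mat
}

#' Nucleotide diversity of one population
#'
#' Average pairwise difference count across all sequence pairs, per site.
#'
#' @param mat 0/1 SNP matrix (rows = sequences, columns = segregating sites);
#'   invariant sites are implicit in `L`.
#' @param L Locus length in bp.
#' @return Per-site nucleotide diversity.
#' @export
pi_stat <- function(mat, L) {
  mat <- .check_matrix(mat, 2)
  stopifnot(L > 0)
  n <- nrow(mat)
  c_ <- colSums(mat)
  sum(c_ * (n - c_)) / (n * (n - 1) / 2) / L
}

#' Watterson's theta
#'
#' `S / (a_n * L)` with `a_n` the (n-1)-th harmonic number.
#'
#' @param S Number of segregating sites in the population.
#' @param n Number of sequences.
#' @param L Locus length in bp.
#' @export
theta_w <- function(S, n, L) {
  if (n < 2) stop("statistic undefined: n must be >= 2", call. = FALSE)
  stopifnot(L > 0, S >= 0)
  S / (sum(1 / seq_len(n - 1)) * L)
}

#' Tajima's D
#'
#' The 1989 statistic `(pi_total - S/a_n) / sqrt(e1*S + e2*S*(S-1))`, with
#' `pi_total` the total (count-unit, not per-site) average pairwise
#' difference. Undefined (NA) for `S = 0` or a non-positive variance term;
#' such loci are excluded from dataset means.
#'
#' @param pi_total Average pairwise difference count (sum over sites).
#' @param S Number of segregating sites.
#' @param n Number of sequences.
#' @export
tajima_d <- function(pi_total, S, n) {
  if (n < 2) stop("statistic undefined: n must be >= 2", call. = FALSE)
  if (S < 1) return(NA_real_)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  v <- e1 * S + e2 * S * (S - 1)
  if (v <= 0) return(NA_real_)
  (pi_total - S / a1) / sqrt(v)
}

#' Gross and net divergence between two populations
#'
#' `d_xy` is the mean pairwise difference count across all between-population
#' sequence pairs per site; `d_a = d_xy - (pi_x + pi_y)/2` (may be negative).
#'
#' @param mat_x,mat_y 0/1 SNP matrices over the same columns.
#' @param L Locus length in bp.
#' @return Named numeric vector `c(dxy, da)`.
#' @export
divergence <- function(mat_x, mat_y, L) {
  mat_x <- .check_matrix(mat_x); mat_y <- .check_matrix(mat_y)
  stopifnot(ncol(mat_x) == ncol(mat_y), L > 0)
  nx <- nrow(mat_x); ny <- nrow(mat_y)
  cx <- colSums(mat_x); cy <- colSums(mat_y)
  dxy <- sum(cx * (ny - cy) + (nx - cx) * cy) / (nx * ny) / L
  pix <- if (nx >= 2) pi_stat(mat_x, L) else NA_real_
  piy <- if (ny >= 2) pi_stat(mat_y, L) else NA_real_
  c(dxy = dxy, da = dxy - (pix + piy) / 2)
}

#' FST between two populations
#'
#' Default estimator is `1 - pi_within / pi_total` with `pi_within` the
#' unweighted mean of the two within-population diversities and `pi_total`
#' the diversity of the pooled sample. The alternative `"hudson"` form uses
#' `1 - pi_within / d_xy`. Missing (NA) when the pooled pair is monomorphic.
#'
#' @inheritParams divergence
#' @param estimator `"pi_ratio"` (default) or `"hudson"`.
#' @export
fst <- function(mat_x, mat_y, L, estimator = c("pi_ratio", "hudson")) {
  estimator <- match.arg(estimator)
  mat_x <- .check_matrix(mat_x, 2); mat_y <- .check_matrix(mat_y, 2)
  pw <- (pi_stat(mat_x, L) + pi_stat(mat_y, L)) / 2
  if (estimator == "pi_ratio") {
    pt <- pi_stat(rbind(mat_x, mat_y), L)
    if (pt <= 0) return(NA_real_)
    1 - pw / pt
  } else {
    dxy <- divergence(mat_x, mat_y, L)[["dxy"]]
    if (dxy <= 0) return(NA_real_)
    1 - pw / dxy
  }
}

#' ABBA-BABA (Patterson's) D from derived-allele frequencies
#'
#' `D = sum((1-p1) p2 p3 - p1 (1-p2) p3) / sum((1-p1) p2 p3 + p1 (1-p2) p3)`
#' over polarized sites; missing when the denominator is zero. The package
#' fixes the population ordering (P1, P2, P3) = (helenor-like,
#' achilles-like, deidamia-like).
#'
#' @param p1,p2,p3 Per-site derived-allele frequencies.
#' @return List with `D`, `num` and `den` sums.
#' @export
abba_baba_d <- function(p1, p2, p3) {
  stopifnot(length(p1) == length(p2), length(p2) == length(p3))
  if (length(p1) == 0) return(list(D = NA_real_, num = 0, den = 0))
  num <- sum((1 - p1) * p2 * p3 - p1 * (1 - p2) * p3)
  den <- sum((1 - p1) * p2 * p3 + p1 * (1 - p2) * p3)
  list(D = if (den > 0) num / den else NA_real_, num = num, den = den)
}

#' Site-pattern counts for a pair of populations
#'
#' Classifies every site of the pooled pair into exactly one category:
#' shared polymorphism, fixed difference, polymorphism exclusive to x or to
#' y, or non-informative (monomorphic in the pooled pair).
#'
#' @inheritParams divergence
#' @return Named integer vector `c(ss, sf, sx_x, sx_y)`.
#' @export
site_pattern_counts <- function(mat_x, mat_y) {
  mat_x <- .check_matrix(mat_x, 2); mat_y <- .check_matrix(mat_y, 2)
  stopifnot(ncol(mat_x) == ncol(mat_y))
  nx <- nrow(mat_x); ny <- nrow(mat_y)
  cx <- colSums(mat_x); cy <- colSums(mat_y)
  polx <- cx > 0 & cx < nx
  poly <- cy > 0 & cy < ny
  fixd <- (cx == 0 & cy == ny) | (cx == nx & cy == 0)
  c(ss = sum(polx & poly),
    sf = sum(fixd),
    sx_x = sum(polx & !poly),
    sx_y = sum(!polx & poly))
}

#' All per-locus statistics for one locus
#'
#' Computes the full 33-entry statistic vector (see [locus_stat_names()])
#' from a 0/1 SNP matrix whose rows are grouped by population.
#'
#' @param snp 0/1 SNP matrix, rows ordered P1 then P2 then P3, or a
#'   `sim_locus`.
#' @param n_seq Sequence counts per population (ignored for a `sim_locus`).
#' @param L Locus length in bp (ignored for a `sim_locus`).
#' @return Named numeric vector of length 33 (NA where undefined).
#' @export
locus_stats <- function(snp, n_seq = NULL, L = NULL) {
  if (inherits(snp, "sim_locus")) {
    n_seq <- snp$n_seq; L <- snp$length; snp <- snp$snp
  }
  stopifnot(is.matrix(snp), length(n_seq) == 3, sum(n_seq) == nrow(snp))
  st <- cpp_locus_stats(snp, n_seq[1], n_seq[2], n_seq[3], as.integer(L))
  setNames(st, locus_stat_names())
}

#' Per-locus statistic table for a dataset
#'
#' @param dataset A `locus_dataset`.
#' @return Data frame, one row per locus, columns [locus_stat_names()],
#'   with the locus identifiers as row names.
#' @export
dataset_stats <- function(dataset) {
  stopifnot(inherits(dataset, "locus_dataset"))
  rows <- t(vapply(dataset$loci, function(lc)
    locus_stats(lc$snp, lc$n_seq, lc$length), numeric(33)))
  colnames(rows) <- locus_stat_names()
  as.data.frame(rows)
}

#' Dataset-level summary vector
#'
#' Mean and standard deviation across loci of every per-locus statistic,
#' skipping missing values per statistic (a statistic missing at every locus
#' is recorded as 0 for both mean and SD), plus the dataset-level ABBA-BABA
#' D computed as the ratio of summed numerators to summed denominators.
#' The SD is the population form (divide by the number of loci); a single
#' locus therefore has SD 0.
#'
#' @param per_locus Per-locus statistic matrix or data frame with columns
#'   [locus_stat_names()], or a `locus_dataset`.
#' @return Named numeric vector of length 67 (see [summary_stat_names()]).
#' @export
dataset_summary <- function(per_locus) {
  if (inherits(per_locus, "locus_dataset")) per_locus <- dataset_stats(per_locus)
  per_locus <- as.matrix(per_locus)
  if (nrow(per_locus) == 0) stop("no loci to summarise", call. = FALSE)
  stopifnot(ncol(per_locus) == 33)
  mu <- apply(per_locus, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) 0 else mean(x)
  })
  sdev <- apply(per_locus, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) 0 else sqrt(mean((x - mean(x))^2))
  })
  den <- sum(per_locus[, "dstat_den"], na.rm = TRUE)
  num <- sum(per_locus[, "dstat_num"], na.rm = TRUE)
  setNames(c(mu, sdev, if (den > 0) num / den else 0), summary_stat_names())
}

#' Write / read per-locus statistics and summary vectors as TSV
#'
#' Both the observed and the simulated pipelines share these formats: a
#' per-locus table (one row per locus, canonical column names) and a
#' single-row summary record.
#'
#' @param x Data frame (per-locus table) or named vector (summary).
#' @param path File path.
#' @export
write_stats_table <- function(x, path) {
  if (is.null(dim(x))) x <- as.data.frame(as.list(x), check.names = FALSE)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stats_table
#' @export
read_stats_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
}
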