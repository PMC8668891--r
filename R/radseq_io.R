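## A locus_dataset holds phased multi-locus data: per-locus 0/1 SNP matrices
## (rows = allele sequences grouped by species, named "species|ind|allele"),
## the full sample sheet, and per-locus lengths. Loci are unanchored units
## with 0-based internal SNP positions.

.new_locus_dataset <- function(loci, species, n_seq) {
  structure(list(loci = loci, species = species, n_seq = as.integer(n_seq)),
            class = "locus_dataset")
}

#' @method print locus_dataset
#' @export
print.locus_dataset <- function(x, ...) {
  ns <- vapply(x$loci, function(l) ncol(l$snp), 1L)
  cat("locus_dataset:", length(x$loci), "loci,", sum(ns), "SNPs,",
      "species", paste(x$species, collapse = "/"),
      paste0("(", paste(x$n_seq, collapse = "/"), " sequences)\n"))
  invisible(x)
}

#' Number of loci in a dataset
#' @param dataset A `locus_dataset`.
#' @export
n_loci <- function(dataset) length(dataset$loci)

.seq_header <- function(locus, locus_id, delim = "|") {
  paste(locus$pop, locus$individual, locus_id, locus$allele, sep = delim)
}

#' Write a multi-locus dataset as phased FASTA
#'
#' One record per allele sequence per individual per locus, with headers
#' `>species|individual|locus|allele` (configurable delimiter). Ancestral
#' alleles are written as `ancestral_base`, derived alleles as
#' `derived_base`; non-SNP positions carry the ancestral base.
#'
#' @param dataset A `locus_dataset` (e.g. from [simulate_dataset()]).
#' @param path Output file.
#' @param delim Header field delimiter.
#' @param ancestral_base,derived_base Bases used at polarized sites.
#' @export
write_loci_fasta <- function(dataset, path, delim = "|",
                             ancestral_base = "A", derived_base = "G") {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(dataset$loci)) {
    lc <- dataset$loci[[id]]
    base <- rep(ancestral_base, lc$length)
    heads <- paste0(">", .seq_header(lc, id, delim))
    for (i in seq_len(nrow(lc$snp))) {
      s <- base
      s[lc$positions[lc$snp[i, ] == 1] + 1] <- derived_base
      writeLines(c(heads[i], paste(s, collapse = "")), con)
    }
  }
  invisible(path)
}

#' Read a phased multi-locus FASTA into a `locus_dataset`
#'
#' Records are grouped by locus from the header convention
#' `species|individual|locus|allele`; within-locus sequence lengths are
#' checked. Sites with missing or ambiguous bases (`N`) are dropped at that
#' locus for all samples; sites with more than two alleles are excluded from
#' the SNP matrix but counted so that [filter_loci()] can drop the locus.
#' Polarization of the 0/1 encoding is `"major"` (pooled major allele
#' ancestral, ties broken alphabetically) or `"ancestral_base"` (the given
#' base is ancestral wherever present) -- the latter makes round trips with
#' [write_loci_fasta()] exact.
#'
#' @param path FASTA file.
#' @param delim Header field delimiter.
#' @param polarize `"major"` or `"ancestral_base"`.
#' @param ancestral_base Base treated as ancestral under
#'   `polarize = "ancestral_base"`.
#' @return A `locus_dataset`. Loci carry an attribute-free
#'   `multiallelic_sites` count used by [filter_loci()].
#' @export
read_loci_fasta <- function(path, delim = "|",
                            polarize = c("major", "ancestral_base"),
                            ancestral_base = "A") {
  polarize <- match.arg(polarize)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  heads <- names(seqs)
  parts <- strsplit(heads, delim, fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 4
  if (any(bad))
    stop("malformed FASTA header (expected species", delim, "individual",
         delim, "locus", delim, "allele): ", heads[bad][1], call. = FALSE)
  meta <- data.frame(species = vapply(parts, `[[`, "", 1),
                     individual = vapply(parts, `[[`, "", 2),
                     locus = vapply(parts, `[[`, "", 3),
                     allele = vapply(parts, `[[`, "", 4),
                     stringsAsFactors = FALSE)
  species <- unique(meta$species)
  loci <- list()
  for (id in unique(meta$locus)) {
    idx <- which(meta$locus == id)
    chars <- strsplit(as.character(seqs[idx]), "")
    w <- unique(lengths(chars))
    if (length(w) != 1)
      stop("length mismatch within locus ", id, call. = FALSE)
    chr <- do.call(rbind, chars)
    m <- meta[idx, ]
    ord <- order(match(m$species, species), m$individual, m$allele)
    chr <- chr[ord, , drop = FALSE]
    m <- m[ord, ]
    has_n <- apply(chr, 2, function(col) any(col %in% c("N", "n", "-", "?")))
    chr <- chr[, !has_n, drop = FALSE]
    nall <- apply(chr, 2, function(col) length(unique(col)))
    multi <- sum(nall > 2)
    keep <- which(nall == 2)
    snp <- matrix(0L, nrow(chr), length(keep))
    pos <- integer(length(keep))
    allpos <- which(!has_n)
    for (j in seq_along(keep)) {
      col <- chr[, keep[j]]
      tab <- sort(table(col), decreasing = TRUE)
      anc <- if (polarize == "ancestral_base" &&
                 ancestral_base %in% names(tab)) ancestral_base
             else names(tab)[order(-tab, names(tab))][1]
      snp[, j] <- as.integer(col != anc)
      pos[j] <- allpos[keep[j]] - 1L
    }
    rownames(snp) <- paste(m$species, m$individual, m$allele, sep = "|")
    nsq <- as.integer(table(factor(m$species, levels = species)))
    loci[[id]] <- list(snp = snp, positions = pos, length = w,
                       n_seq = nsq, species = species, pop = m$species,
                       individual = m$individual, allele = m$allele,
                       multiallelic_sites = multi)
  }
  n_seq <- loci[[1]]$n_seq
  .new_locus_dataset(loci, species, n_seq)
}

#' Write a multi-locus dataset as VCF
#'
#' Simple VCF v4.2 dialect: one contig per locus (its length in the contig
#' header and as `LLEN` in INFO), `REF` = ancestral base, `ALT` = derived
#' base, phased genotypes with the two alleles of each diploid individual.
#'
#' @inheritParams write_loci_fasta
#' @export
write_loci_vcf <- function(dataset, path, ancestral_base = "A",
                           derived_base = "G") {
  con <- file(path, "w")
  on.exit(close(con))
  inds <- unique(unlist(lapply(dataset$loci, function(l) l$individual)))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=abctrio",
               '##INFO=<ID=LLEN,Number=1,Type=Integer,Description="Locus length in bp">',
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               vapply(names(dataset$loci), function(id)
                 sprintf("##contig=<ID=%s,length=%d>", id,
                         dataset$loci[[id]]$length), "")), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", inds), collapse = "\t"), con)
  for (id in names(dataset$loci)) {
    lc <- dataset$loci[[id]]
    if (ncol(lc$snp) == 0) next
    for (j in seq_along(lc$positions)) {
      gt <- vapply(inds, function(ind) {
        rows <- which(lc$individual == ind)
        if (length(rows) == 0) return("./.")
        paste(lc$snp[rows, j], collapse = "|")
      }, "")
      writeLines(paste(c(id, lc$positions[j] + 1, paste0(id, "_", j),
                         ancestral_base, derived_base, ".", "PASS",
                         paste0("LLEN=", lc$length), "GT", gt),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a multi-sample VCF into a `locus_dataset`
#'
#' Loci are identified by the `CHROM` field. Phased genotypes are split into
#' two allele rows per individual; unphased heterozygotes get a random phase
#' under the current RNG stream (allele-frequency statistics are
#' phase-invariant, so this only affects serialization). Sites with more
#' than one ALT allele are excluded from the SNP matrix but counted for
#' [filter_loci()]. The REF allele is taken as ancestral.
#'
#' @param path VCF file (v4.x, parsed with vcfR).
#' @param sample_species Named character vector mapping sample names to
#'   species labels; every sample in the file must be present.
#' @param rng_seed Optional seed for random phasing.
#' @return A `locus_dataset`.
#' @export
read_loci_vcf <- function(path, sample_species, rng_seed = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  if (!all(samples %in% names(sample_species)))
    stop("samples missing from sample_species map: ",
         paste(setdiff(samples, names(sample_species)), collapse = ", "),
         call. = FALSE)
  info <- fix[, "INFO"]
  llen <- suppressWarnings(as.integer(sub("^.*LLEN=([0-9]+).*$", "\\1", info)))
  species <- unique(unname(sample_species[samples]))
  with_seed(rng_seed, {
    loci <- list()
    for (id in unique(fix[, "CHROM"])) {
      rows <- which(fix[, "CHROM"] == id)
      multi <- grepl(",", fix[rows, "ALT"], fixed = TRUE)
      keep <- rows[!multi]
      a1 <- a2 <- matrix(0L, length(samples), length(keep))
      for (j in seq_along(keep)) {
        g <- gt[keep[j], ]
        al <- strsplit(g, "[|/]")
        phased <- grepl("|", g, fixed = TRUE)
        for (i in seq_along(al)) {
          x <- suppressWarnings(as.integer(al[[i]]))
          if (length(x) != 2 || anyNA(x)) x <- c(0L, 0L)
          if (!phased[i] && x[1] != x[2] && runif(1) < 0.5) x <- rev(x)
          a1[i, j] <- x[1]; a2[i, j] <- x[2]
        }
      }
      snp <- matrix(0L, 2 * length(samples), length(keep))
      snp[seq(1, 2 * length(samples), by = 2), ] <- a1
      snp[seq(2, 2 * length(samples), by = 2), ] <- a2
      pop <- rep(unname(sample_species[samples]), each = 2)
      ind <- rep(samples, each = 2)
      allele <- rep(1:2, length(samples))
      ord <- order(match(pop, species), ind, allele)
      snp <- snp[ord, , drop = FALSE]
      pop <- pop[ord]; ind <- ind[ord]; allele <- allele[ord]
      rownames(snp) <- paste(pop, ind, allele, sep = "|")
      pos <- as.integer(fix[keep, "POS"]) - 1L
      len <- llen[rows[1]]
      if (is.na(len)) len <- max(as.integer(fix[rows, "POS"]))
      nsq <- as.integer(table(factor(pop, levels = species)))
      loci[[id]] <- list(snp = snp, positions = pos, length = len,
                         n_seq = nsq, species = species, pop = pop,
                         individual = ind, allele = allele,
                         multiallelic_sites = sum(multi))
    }
    .new_locus_dataset(loci, species, loci[[1]]$n_seq)
  })
}

#' Filter loci to the analysis set
#'
#' Retains loci that are (i) present in every sample of the dataset,
#' (ii) polymorphic in the pooled three-species alignment and
#' (iii) composed only of biallelic SNPs. Idempotent; the numbers of loci
#' dropped per rule are recorded in the `"drop_log"` attribute.
#'
#' @param dataset A `locus_dataset`.
#' @return The filtered `locus_dataset`.
#' @export
filter_loci <- function(dataset) {
  stopifnot(inherits(dataset, "locus_dataset"))
  all_inds <- sort(unique(unlist(lapply(dataset$loci,
                                        function(l) unique(l$individual)))))
  missing_sample <- vapply(dataset$loci, function(l)
    !setequal(unique(l$individual), all_inds), TRUE)
  multiallelic <- vapply(dataset$loci, function(l) {
    m <- l$multiallelic_sites
    !is.null(m) && m > 0
  }, TRUE)
  monomorphic <- vapply(dataset$loci, function(l) ncol(l$snp) == 0, TRUE)
  drop <- missing_sample | multiallelic | monomorphic
  out <- .new_locus_dataset(dataset$loci[!drop], dataset$species,
                            dataset$n_seq)
  attr(out, "drop_log") <- data.frame(
    rule = c("missing_sample", "multiallelic", "monomorphic"),
    n_dropped = c(sum(missing_sample), sum(multiallelic & !missing_sample),
                  sum(monomorphic & !missing_sample & !multiallelic)))
  out
}

#' Write / read the per-locus table (locus ID, length, SNP count, samples)
#'
#' @param dataset A `locus_dataset`.
#' @param path File path.
#' @export
write_locus_table <- function(dataset, path) {
  tab <- data.frame(locus = names(dataset$loci),
                    length = vapply(dataset$loci, function(l) l$length, 1L),
                    n_snp = vapply(dataset$loci, function(l) ncol(l$snp), 1L))
  for (i in seq_along(dataset$species))
    tab[[paste0("n_seq_", dataset$species[i])]] <- dataset$n_seq[i]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_locus_table
#' @export
read_locus_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
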