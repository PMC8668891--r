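#' @useDynLib abctrio, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rbeta sd quantile rpois setNames cor
NULL

.INNER <- c("AM", "SC")                      # ancestral migration / secondary contact
.OUTER <- c("SI", "GF13", "GF23", "GF1323")  # P3 gene-flow configuration

## run code while temporarily seeding R's RNG; seed = NULL leaves the
## current stream untouched so callers can manage a single stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Enumerate the compared demographic models
#'
#' The model space crosses eight scenario categories -- two temporal patterns
#' of gene flow between the sister species P1 and P2 (`AM`, ancestral
#' migration followed by current isolation; `SC`, secondary contact with
#' ongoing migration) times four configurations of gene flow with the third
#' species P3 (`SI`, none; `GF13`, with P1 only; `GF23`, with P2 only;
#' `GF1323`, with both) -- with four genomic-heterogeneity sub-models
#' (homogeneous or heterogeneous effective size and migration rate along the
#' genome).
#'
#' @return A data frame with 32 rows and columns `inner`, `outer`,
#'   `ne_hetero`, `nm_hetero`, `category` (e.g. `"AM.SI"`), `submodel`
#'   (e.g. `"NeHom.MHet"`) and `model` (category x submodel), in a stable
#'   order.
#' @export
#' @examples
#' m <- enumerate_models()
#' nrow(m)             # 32
#' length(unique(m$category))  # 8
enumerate_models <- function() {
  grid <- expand.grid(nm_hetero = c(FALSE, TRUE), ne_hetero = c(FALSE, TRUE),
                      outer = .OUTER, inner = .INNER,
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("inner", "outer", "ne_hetero", "nm_hetero")]
  grid$category <- paste(grid$inner, grid$outer, sep = ".")
  grid$submodel <- paste0(ifelse(grid$ne_hetero, "NeHet", "NeHom"), ".",
                          ifelse(grid$nm_hetero, "MHet", "MHom"))
  grid$model <- paste(grid$category, grid$submodel, sep = "/")
  rownames(grid) <- NULL
  grid
}

.split_category <- function(category) {
  parts <- strsplit(category, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !(parts[1] %in% .INNER) || !(parts[2] %in% .OUTER))
    stop("unknown scenario category: ", category,
         " (expected e.g. \"AM.SI\", \"SC.GF1323\")", call. = FALSE)
  list(inner = parts[1], outer = parts[2])
}

.split_submodel <- function(submodel) {
  parts <- strsplit(submodel, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !(parts[1] %in% c("NeHom", "NeHet")) ||
      !(parts[2] %in% c("MHom", "MHet")))
    stop("unknown heterogeneity sub-model: ", submodel, call. = FALSE)
  list(ne_hetero = parts[1] == "NeHet", nm_hetero = parts[2] == "MHet")
}

#' Prior configuration for the generalist three-population model
#'
#' Defaults are the study priors: diploid sizes uniform on \[0, 1e6\]
#' (with a floor of `min_size` enforced by resampling, since the coalescent
#' degenerates at N = 0), outer split time uniform on \[0, 8e6\] generations,
#' scaled migration rates 4Nm uniform on \[0, 50\], migration transition
#' times drawn as a Beta(5, 1) fraction of the P1/P2 split under ancestral
#' migration and Beta(1, 5) under secondary contact, and a mutation rate of
#' 3e-9 per bp per generation. Heterogeneity hyperpriors (Beta shape
#' parameters for per-locus factors) are uniform on `shape_range`.
#'
#' @param ne_range,tsplit_outer_range,mig_range Uniform prior bounds.
#' @param beta_ancestral,beta_secondary Beta shape pairs for the P1-P2
#'   migration transition time.
#' @param shape_range Uniform bounds of the heterogeneity Beta shapes.
#' @param mu Mutation rate per bp per generation.
#' @param min_size Smallest admissible diploid size (resampling floor).
#' @return An object of class `abc_priors`.
#' @export
default_priors <- function(ne_range = c(0, 1e6),
                           tsplit_outer_range = c(0, 8e6),
                           mig_range = c(0, 50),
                           beta_ancestral = c(5, 1),
                           beta_secondary = c(1, 5),
                           shape_range = c(0, 20),
                           mu = 3e-9,
                           min_size = 10) {
  p <- list(ne_range = as.numeric(ne_range),
            tsplit_outer_range = as.numeric(tsplit_outer_range),
            mig_range = as.numeric(mig_range),
            beta_ancestral = as.numeric(beta_ancestral),
            beta_secondary = as.numeric(beta_secondary),
            shape_range = as.numeric(shape_range),
            mu = as.numeric(mu),
            min_size = as.numeric(min_size))
  class(p) <- "abc_priors"
  validate_priors(p)
  p
}

validate_priors <- function(p) {
  rng <- function(x, nm) {
    if (length(x) != 2 || anyNA(x) || x[1] > x[2] || x[1] < 0)
      stop("invalid prior bounds for ", nm, call. = FALSE)
  }
  rng(p$ne_range, "ne_range")
  rng(p$tsplit_outer_range, "tsplit_outer_range")
  rng(p$mig_range, "mig_range")
  rng(p$shape_range, "shape_range")
  if (any(p$beta_ancestral <= 0) || any(p$beta_secondary <= 0))
    stop("Beta shape parameters must be positive", call. = FALSE)
  if (p$mu <= 0) stop("mu must be positive", call. = FALSE)
  invisible(p)
}

## uniform size draw with the degeneracy floor
.draw_size <- function(n, range, min_size) {
  x <- runif(n, range[1], range[2])
  if (range[2] >= min_size) {
    bad <- x < min_size
    while (any(bad)) {
      x[bad] <- runif(sum(bad), range[1], range[2])
      bad <- x < min_size
    }
  }
  pmax(x, min_size)
}

#' Sample one parameter draw from the priors
#'
#' Draws a complete parameterization of the generalist model for the given
#' scenario category and heterogeneity sub-model: current and founding sizes
#' with per-lineage size-change times, nested split times
#' (`T_split12 ~ U(0, T_split123)`), migration rates with
#' category-forbidden pairs set to exactly zero, the P1-P2 migration
#' transition time as a Beta-distributed fraction of `T_split12`, and
#' heterogeneity Beta shapes (NA under homogeneous sub-models).
#'
#' @param category Scenario category string, e.g. `"AM.SI"`.
#' @param submodel Sub-model string, e.g. `"NeHet.MHom"`.
#' @param priors An [default_priors()] object.
#' @param rng_seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A named list of class `param_draw`.
#' @export
sample_parameters <- function(category, submodel = "NeHom.MHom",
                              priors = default_priors(), rng_seed = NULL) {
  validate_priors(priors)
  cat_ <- .split_category(category)
  sub_ <- .split_submodel(submodel)
  with_seed(rng_seed, {
    sz <- .draw_size(5, priors$ne_range, priors$min_size)
    fz <- .draw_size(3, priors$ne_range, priors$min_size)
    T123 <- runif(1, priors$tsplit_outer_range[1], priors$tsplit_outer_range[2])
    T12 <- runif(1, 0, T123)
    shapes <- if (cat_$inner == "AM") priors$beta_ancestral else priors$beta_secondary
    Ttr <- T12 * rbeta(1, shapes[1], shapes[2])
    M12 <- runif(1, priors$mig_range[1], priors$mig_range[2])
    M13 <- if (cat_$outer %in% c("GF13", "GF1323"))
      runif(1, priors$mig_range[1], priors$mig_range[2]) else 0
    M23 <- if (cat_$outer %in% c("GF23", "GF1323"))
      runif(1, priors$mig_range[1], priors$mig_range[2]) else 0
    draw_shapes <- function(on) {
      if (!on) return(c(NA_real_, NA_real_))
      s <- runif(2, priors$shape_range[1], priors$shape_range[2])
      while (max(s) < 0.1)
        s <- runif(2, priors$shape_range[1], priors$shape_range[2])
      s
    }
    she <- draw_shapes(sub_$ne_hetero)
    shm <- draw_shapes(sub_$nm_hetero)
    d <- list(N_P1 = sz[1], N_P2 = sz[2], N_P3 = sz[3],
              N_anc12 = sz[4], N_anc123 = sz[5],
              N_found_P1 = fz[1], N_found_P2 = fz[2], N_found_P3 = fz[3],
              T_change_P1 = runif(1, 0, T12),
              T_change_P2 = runif(1, 0, T12),
              T_change_P3 = runif(1, 0, T123),
              T_split12 = T12, T_split123 = T123, T_trans12 = Ttr,
              M12 = M12, M13 = M13, M23 = M23,
              shape1_Ne = she[1], shape2_Ne = she[2],
              shape1_M = shm[1], shape2_M = shm[2],
              category = category, submodel = submodel)
    class(d) <- "param_draw"
    d
  })
}

#' Names of the numeric fields of a parameter draw
#' @return Character vector of the 21 numeric parameter names.
#' @export
param_names <- function() {
  c("N_P1", "N_P2", "N_P3", "N_anc12", "N_anc123",
    "N_found_P1", "N_found_P2", "N_found_P3",
    "T_change_P1", "T_change_P2", "T_change_P3",
    "T_split12", "T_split123", "T_trans12",
    "M12", "M13", "M23",
    "shape1_Ne", "shape2_Ne", "shape1_M", "shape2_M")
}

#' @method print param_draw
#' @export
print.param_draw <- function(x, ...) {
  cat("Parameter draw [", x$category, "/", x$submodel, "]\n", sep = "")
  v <- unlist(x[param_names()])
  print(signif(v, 4))
  invisible(x)
}

#' Epoch-restricted migration schedule implied by a draw
#'
#' Translates a scenario category and a parameter draw into per-pair
#' migration entries with their active time interval (generations before
#' present, half-open with the boundary belonging to the older epoch).
#' Under ancestral migration the P1-P2 pair is active on
#' \[`T_trans12`, `T_split12`\] with no present-day flow; under secondary
#' contact it is active on \[0, `T_trans12`\]. Pairs involving P3 are active
#' over the whole coexistence period \[0, `T_split123`\] when the category
#' enables them, and are absent otherwise.
#'
#' @param category Scenario category string; must match `draw$category`.
#' @param draw A [sample_parameters()] draw.
#' @return Data frame with columns `pair`, `rate` (4Nm units), `t_start`,
#'   `t_end`.
#' @export
migration_schedule <- function(category, draw) {
  if (!inherits(draw, "param_draw")) stop("draw must be a param_draw")
  if (!identical(draw$category, category))
    stop("category/draw mismatch: draw was sampled for ", draw$category,
         call. = FALSE)
  cat_ <- .split_category(category)
  if (cat_$inner == "AM") {
    sched <- data.frame(pair = "P1-P2", rate = draw$M12,
                        t_start = draw$T_trans12, t_end = draw$T_split12,
                        stringsAsFactors = FALSE)
  } else {
    sched <- data.frame(pair = "P1-P2", rate = draw$M12,
                        t_start = 0, t_end = draw$T_trans12,
                        stringsAsFactors = FALSE)
  }
  if (cat_$outer %in% c("GF13", "GF1323"))
    sched <- rbind(sched, data.frame(pair = "P1-P3", rate = draw$M13,
                                     t_start = 0, t_end = draw$T_split123))
  if (cat_$outer %in% c("GF23", "GF1323"))
    sched <- rbind(sched, data.frame(pair = "P2-P3", rate = draw$M23,
                                     t_start = 0, t_end = draw$T_split123))
  rownames(sched) <- NULL
  sched
}

#' Read / write a plain-text key-value run configuration
#'
#' The configuration holds the prior bounds, species labels, per-species
#' haploid sequence counts and the run seed, one `key = value` pair per line
#' (`#` comments allowed; vector values comma-separated). Defaults equal the
#' study priors and the study sampling design.
#'
#' @param path File path.
#' @param config Named list as returned by `read_run_config()`.
#' @return `read_run_config()` returns a list with elements `priors`
#'   (class `abc_priors`), `species` (3 labels), `n_seq` (3 integers) and
#'   `seed`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1], call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- trimws(vapply(kv, `[[`, "", 2))
  getv <- function(key, default) {
    if (!key %in% keys) return(default)
    v <- strsplit(vals[match(key, keys)], ",", fixed = TRUE)[[1]]
    suppressWarnings(num <- as.numeric(trimws(v)))
    if (anyNA(num)) trimws(v) else num
  }
  priors <- default_priors(
    ne_range = getv("ne_range", c(0, 1e6)),
    tsplit_outer_range = getv("tsplit_outer_range", c(0, 8e6)),
    mig_range = getv("mig_range", c(0, 50)),
    beta_ancestral = getv("beta_ancestral", c(5, 1)),
    beta_secondary = getv("beta_secondary", c(1, 5)),
    shape_range = getv("shape_range", c(0, 20)),
    mu = getv("mu", 3e-9),
    min_size = getv("min_size", 10))
  list(priors = priors,
       species = as.character(getv("species", c("P1", "P2", "P3"))),
       n_seq = as.integer(getv("n_seq", c(20, 26, 16))),
       seed = as.integer(getv("seed", 1)[1]))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  p <- config$priors
  fmt <- function(x) paste(format(x, scientific = FALSE, trim = TRUE),
                           collapse = ", ")
  lines <- c(
    "# abctrio run configuration",
    paste("ne_range =", fmt(p$ne_range)),
    paste("tsplit_outer_range =", fmt(p$tsplit_outer_range)),
    paste("mig_range =", fmt(p$mig_range)),
    paste("beta_ancestral =", fmt(p$beta_ancestral)),
    paste("beta_secondary =", fmt(p$beta_secondary)),
    paste("shape_range =", fmt(p$shape_range)),
    paste("mu =", format(p$mu)),
    paste("min_size =", fmt(p$min_size)),
    paste("species =", paste(config$species, collapse = ", ")),
    paste("n_seq =", paste(config$n_seq, collapse = ", ")),
    paste("seed =", config$seed))
  writeLines(lines, path)
  invisible(path)
}
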