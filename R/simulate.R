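#' Configuration for the RNA-seq count simulator
#'
#' Builds the configuration object consumed by [simulate_counts()]. Defaults
#' reproduce the design of the house fly head RNA-seq compendium the package
#' is built around: 9 Y^M and 15 III^M male head libraries drawn from three
#' experimental batches, negative-binomial counts with gene-wise log-normal
#' mean abundances, multiplicative batch effects, planted genotype
#' log2 fold-changes, and co-expression modules driven by shared latent
#' factors.
#'
#' @param n_genes Number of genes (transcripts) to simulate.
#' @param n_ym,n_iiim Number of Y^M and III^M samples.
#' @param n_batches Number of experimental batches; samples are assigned to
#'   batches in round-robin order so every batch contains both genotypes.
#' @param module_spec List of planted co-expression modules, each a list with
#'   elements `size` (gene count) and `latent_correlation` (target pairwise
#'   Pearson correlation, in `[0, 1]`). Modules occupy consecutive gene
#'   indices starting at gene 1.
#' @param de_spec Data frame with columns `gene` (integer index) and
#'   `log2fc` (planted log2 fold-change, III^M minus Y^M orientation).
#' @param nb_dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); must be positive.
#' @param library_size_range Length-2 numeric, bounds of the uniform
#'   distribution of target library sizes (total counts per sample).
#' @param batch_sd Standard deviation (log2 scale) of per-gene multiplicative
#'   batch shifts; batch 1 is the reference.
#' @param abundance_sdlog Standard deviation of the log-normal distribution
#'   of relative gene abundances.
#' @param seed Integer seed; all randomness in [simulate_counts()] flows
#'   from it.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_ym = 9,
                       n_iiim = 15,
                       n_batches = 3,
                       module_spec = list(),
                       de_spec = NULL,
                       nb_dispersion = 0.2,
                       library_size_range = c(1e6, 3e6),
                       batch_sd = 0.5,
                       abundance_sdlog = 1.5,
                       seed = 1L) {
  if (n_ym < 2 || n_iiim < 2) {
    abort("Need at least 2 samples per genotype.")
  }
  if (nb_dispersion <= 0) abort("`nb_dispersion` must be positive.")
  if (length(library_size_range) != 2L || any(library_size_range <= 0)) {
    abort("`library_size_range` must be two positive numbers.")
  }
  sizes <- vapply(module_spec, function(m) as.numeric(m$size), numeric(1))
  cors <- vapply(module_spec, function(m) as.numeric(m$latent_correlation), numeric(1))
  if (sum(sizes) > n_genes) {
    abort("Planted module sizes exceed `n_genes`.")
  }
  if (length(cors) && any(cors < 0 | cors > 1)) {
    abort("`latent_correlation` must lie in [0, 1].")
  }
  if (!is.null(de_spec)) {
    de_spec <- tibble::as_tibble(de_spec)
    stopifnot(all(c("gene", "log2fc") %in% names(de_spec)))
    if (any(de_spec$gene < 1 | de_spec$gene > n_genes)) {
      abort("`de_spec$gene` indices out of range.")
    }
  }
  structure(
    list(
      n_genes = as.integer(n_genes), n_ym = as.integer(n_ym),
      n_iiim = as.integer(n_iiim), n_batches = as.integer(n_batches),
      module_spec = module_spec, de_spec = de_spec,
      nb_dispersion = nb_dispersion,
      library_size_range = library_size_range,
      batch_sd = batch_sd, abundance_sdlog = abundance_sdlog,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate an RNA-seq count matrix with planted structure
#'
#' Generates negative-binomial counts for a two-genotype (Y^M vs III^M) head
#' RNA-seq design. Gene means are log-normal relative abundances scaled to a
#' per-sample target library size; planted differentially expressed genes
#' have their III^M mean multiplied by `2^log2fc`; batch shifts act
#' multiplicatively per gene; each planted module shares a per-sample latent
#' Gaussian factor added on the log2-mean scale, with loading chosen so the
#' realized pairwise correlation approximates the requested
#' `latent_correlation`.
#'
#' @param config A [sim_config()] object.
#'
#' @return A list of class `sim_counts` with elements
#' \describe{
#'   \item{counts}{integer matrix, genes x samples}
#'   \item{metadata}{tibble with columns `sample`, `genotype`, `batch`,
#'     `strain`, `temperature`}
#'   \item{truth}{list recording planted module membership (integer per gene,
#'     0 = background), planted `log2fc` per gene, and target library sizes}
#' }
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 100, seed = 42))
#' dim(sim$counts)
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_genes <- config$n_genes
  n_samples <- config$n_ym + config$n_iiim
  genes <- gene_ids(n_genes)
  samples <- sprintf("sample_%02d", seq_len(n_samples))
  genotype <- c(rep("YM", config$n_ym), rep("IIIM", config$n_iiim))
  batch <- paste0("batch_", rep_len(seq_len(config$n_batches), n_samples))
  strain <- ifelse(genotype == "YM",
    rep_len(c("IsoCS", "CSaY"), n_samples),
    rep_len(c("CS", "CSrab"), n_samples)
  )
  metadata <- tibble::tibble(
    sample = samples, genotype = genotype, batch = batch,
    strain = strain, temperature = rep_len(c(18, 29), n_samples)
  )

  # relative abundances, normalized to proportions
  w <- rlnorm(n_genes, meanlog = 0, sdlog = config$abundance_sdlog)
  p <- w / sum(w)

  # per-gene multiplicative batch shifts (log2 scale), batch 1 = reference
  shift <- matrix(0, n_genes, config$n_batches)
  if (config$n_batches > 1) {
    shift[, -1] <- rnorm(n_genes * (config$n_batches - 1), sd = config$batch_sd)
  }

  # planted fold-changes, IIIM - YM orientation
  lfc <- numeric(n_genes)
  if (!is.null(config$de_spec)) lfc[config$de_spec$gene] <- config$de_spec$log2fc

  # module structure: one latent factor per module on the log2-mean scale.
  # With per-gene residual log-variation ~ sigma0^2, a loading of
  # sigma0 * sqrt(rho / (1 - rho)) yields pairwise correlation ~ rho.
  module <- integer(n_genes)
  # per-gene residual variation on the log2 scale for an NB gene with
  # dispersion ~0.2 is about sqrt(0.2)/ln(2) ~ 0.65; used to calibrate the
  # latent loading so realized pairwise correlation tracks the request
  sigma0 <- 0.65
  latent_effect <- matrix(0, n_genes, n_samples)
  at <- 1L
  for (m in seq_along(config$module_spec)) {
    spec <- config$module_spec[[m]]
    idx <- seq.int(at, length.out = spec$size)
    module[idx] <- m
    at <- at + spec$size
    rho <- spec$latent_correlation
    loading <- if (rho >= 1) 10 else sigma0 * sqrt(rho / (1 - rho))
    z <- rnorm(n_samples)
    latent_effect[idx, ] <- matrix(loading * z, spec$size, n_samples, byrow = TRUE)
  }

  lib <- runif(n_samples, config$library_size_range[1], config$library_size_range[2])
  batch_idx <- as.integer(sub("batch_", "", batch))
  is_iiim <- as.numeric(genotype == "IIIM")

  log2mu <- outer(log2(p), log2(lib), "+") +
    shift[, batch_idx, drop = FALSE] +
    outer(lfc, is_iiim) +
    latent_effect
  mu <- 2^log2mu
  counts <- matrix(
    rnbinom(n_genes * n_samples, mu = mu, size = 1 / config$nb_dispersion),
    n_genes, n_samples, dimnames = list(genes, samples)
  )

  structure(
    list(
      counts = counts,
      metadata = metadata,
      truth = list(
        module = setNames(module, genes),
        log2fc = setNames(lfc, genes),
        library_size = setNames(lib, samples)
      )
    ),
    class = "sim_counts"
  )
}

#' Simulate per-site allele read depths for allele-specific expression
#'
#' Emulates diagnostic-SNP read-depth tables from heterozygous III^M males
#' (carrying one III^M and one standard III chromosome allele) and homozygous
#' Y^M males (two standard III alleles). For each site and III^M group, the
#' III^M-allele depth is Binomial(site total, bias); Y^M groups carry only
#' III-allele reads. The default group design mirrors 4 III^M and 4 Y^M
#' strain-by-experimental-batch combinations.
#'
#' @param n_sites Number of diagnostic sites.
#' @param bias Numeric vector (recycled to `n_sites`) giving, per site, the
#'   expected fraction of III^M-male reads carrying the III^M allele; 1
#'   plants complete III^M bias (candidate monoallelic expression).
#' @param seed Integer seed.
#' @param n_iiim_groups,n_ym_groups Group counts; anything other than 4 + 4
#'   requires `allow_any_groups = TRUE`.
#' @param allow_any_groups Override the 4 + 4 group-design check.
#' @param mean_depth Mean total read depth per site and group (Poisson).
#' @param library_size_range Bounds for per-group total mapped reads.
#'
#' @return A list of class `sim_ase` with `depths` (tibble with columns
#'   `scaffold`, `pos`, `allele`, `group`, `genotype`, `depth`,
#'   `library_size`) and `truth` (tibble of per-site planted bias).
#' @export
simulate_allele_depths <- function(n_sites,
                                   bias = 0.5,
                                   seed = 1L,
                                   n_iiim_groups = 4L,
                                   n_ym_groups = 4L,
                                   allow_any_groups = FALSE,
                                   mean_depth = 50,
                                   library_size_range = c(8e6, 1.2e7)) {
  if (n_iiim_groups + n_ym_groups != 8L && !allow_any_groups) {
    abort("Group design is not 4 III^M + 4 Y^M; set `allow_any_groups = TRUE` to override.")
  }
  bias <- rep_len(bias, n_sites)
  if (any(bias < 0 | bias > 1)) abort("`bias` fractions must lie in [0, 1].")
  if (any(library_size_range <= 0)) abort("Library sizes must be positive.")
  set.seed(seed)

  groups <- c(
    sprintf("IIIM_g%d", seq_len(n_iiim_groups)),
    sprintf("YM_g%d", seq_len(n_ym_groups))
  )
  genotype <- rep(c("IIIM", "YM"), c(n_iiim_groups, n_ym_groups))
  lib <- round(runif(length(groups), library_size_range[1], library_size_range[2]))
  pos <- 1000L * seq_len(n_sites)

  rows <- vector("list", n_sites * length(groups))
  k <- 1L
  for (s in seq_len(n_sites)) {
    for (g in seq_along(groups)) {
      total <- stats::rpois(1, mean_depth)
      if (genotype[g] == "IIIM") {
        d_iiim <- rbinom(1, total, bias[s])
        rows[[k]] <- tibble::tibble(
          scaffold = "scaffold_1", pos = pos[s],
          allele = c("IIIM", "III"), group = groups[g], genotype = "IIIM",
          depth = c(d_iiim, total - d_iiim), library_size = lib[g]
        )
      } else {
        rows[[k]] <- tibble::tibble(
          scaffold = "scaffold_1", pos = pos[s],
          allele = "III", group = groups[g], genotype = "YM",
          depth = total, library_size = lib[g]
        )
      }
      k <- k + 1L
    }
  }
  structure(
    list(
      depths = dplyr::bind_rows(rows),
      truth = tibble::tibble(scaffold = "scaffold_1", pos = pos, bias = bias)
    ),
    class = "sim_ase"
  )
}

#' Simulate mating trials: censored latencies and competitive outcomes
#'
#' Single-choice copulation latencies are exponential with group-specific
#' hazards, observed on a 10-minute grid (times rounded up to the next
#' observation), and right-censored at `censor_minutes` (default 240 min, a
#' 4-hour assay). Competitive-trial winners are drawn from a logistic model
#' on the genotype contrast. Defaults plant the effect sizes estimated in
#' house fly single-choice assays: a genotype hazard ratio of 2.92
#' (III^M vs Y^M) and strongly reduced mating hazard at 29 degrees C.
#'
#' @param n_trials Number of latency records (split evenly over the 2x2
#'   genotype-by-temperature design) and competitive trials.
#' @param baseline_rate Y^M hazard at 22 degrees C, events per minute.
#' @param hr_genotype Hazard ratio of III^M relative to Y^M.
#' @param hr_temperature Hazard ratio of 29 relative to 22 degrees C.
#' @param hr_interaction Multiplicative interaction hazard ratio.
#' @param win_logodds Log-odds that the III^M male wins a competitive trial.
#' @param censor_minutes Right-censoring bound in minutes.
#' @param n_batches Number of experimental batches (labels only).
#' @param seed Integer seed.
#'
#' @return A list of class `sim_trials` with `latency` (tibble: `trial`,
#'   `genotype`, `temperature`, `batch`, `strain`, `latency`, `censored`),
#'   `competitive` (tibble: `trial`, `blue_genotype`, `temperature`, `batch`,
#'   `winner`), and `truth` (planted parameters).
#' @export
simulate_mating_trials <- function(n_trials,
                                   baseline_rate = 0.0014,
                                   hr_genotype = 2.92,
                                   hr_temperature = 0.2,
                                   hr_interaction = 1,
                                   win_logodds = 1,
                                   censor_minutes = 240,
                                   n_batches = 5L,
                                   seed = 1L) {
  if (n_trials < 1) abort("`n_trials` must be at least 1 (empty table).")
  if (any(c(baseline_rate, hr_genotype, hr_temperature, hr_interaction) <= 0)) {
    abort("Hazard rates and ratios must be positive.")
  }
  if (censor_minutes < 0) abort("`censor_minutes` must be non-negative.")
  set.seed(seed)

  genotype <- rep_len(c("YM", "IIIM"), n_trials)
  temperature <- rep(rep_len(c(22, 29), ceiling(n_trials / 2)), each = 2)[seq_len(n_trials)]
  batch <- paste0("batch_", rep_len(seq_len(n_batches), n_trials))
  strain <- ifelse(genotype == "YM",
    rep_len(c("IsoCS", "CSaY"), n_trials), rep_len(c("CS", "CSrab"), n_trials)
  )
  rate <- baseline_rate *
    ifelse(genotype == "IIIM", hr_genotype, 1) *
    ifelse(temperature == 29, hr_temperature, 1) *
    ifelse(genotype == "IIIM" & temperature == 29, hr_interaction, 1)
  t_raw <- rexp(n_trials, rate)
  grid <- ceiling(t_raw / 10) * 10
  censored <- grid > censor_minutes
  latency <- ifelse(censored, censor_minutes, grid)

  blue_genotype <- rep_len(c("YM", "IIIM"), n_trials)
  comp_temp <- rep(rep_len(c(18, 29), ceiling(n_trials / 2)), each = 2)[seq_len(n_trials)]
  p_iiim <- stats::plogis(win_logodds)
  winner <- ifelse(runif(n_trials) < p_iiim, "IIIM", "YM")

  structure(
    list(
      latency = tibble::tibble(
        trial = seq_len(n_trials), genotype = genotype,
        temperature = temperature, batch = batch, strain = strain,
        latency = latency, censored = censored
      ),
      competitive = tibble::tibble(
        trial = seq_len(n_trials), blue_genotype = blue_genotype,
        temperature = comp_temp, batch = batch, winner = winner
      ),
      truth = list(
        baseline_rate = baseline_rate, hr_genotype = hr_genotype,
        hr_temperature = hr_temperature, hr_interaction = hr_interaction,
        win_logodds = win_logodds, censor_minutes = censor_minutes
      )
    ),
    class = "sim_trials"
  )
}

#' Write and read planted ground truth
#'
#' Serializes the ground-truth component of a simulation object to JSON so
#' recovery tests can compare estimates with the planted values. Tibbles are
#' stored column-wise; named numeric vectors keep their names.
#'
#' @param truth A ground-truth list (the `truth` element of a simulation).
#' @param path File path.
#' @return `read_ground_truth()` returns the list; `write_ground_truth()`
#'   returns `path` invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  # named atomic vectors become JSON objects (names preserved)
  truth <- lapply(truth, function(x) {
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x
  })
  jsonlite::write_json(truth, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
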