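#' Simulate an expression matrix with known ground-truth scaling factors
#'
#' Emulates the data model the scaling methods assume: a large "core" of
#' genes expressed in a mutually consistent pattern across samples, a set
#' of sample-specific genes concentrated in a few samples, and a continuum
#' of variable genes. Every value is then distorted by per-sample true
#' factors, so that factor-recovery error of any method can be measured
#' exactly.
#'
#' Gene classes:
#' * **core** genes: value `B_g * phi_k * 2^e`, `e ~ Normal(0, sigma)` in
#'   log2 units -- a shared base profile `B_g` (log-normal, log2 mean
#'   `base_meanlog2`, sd `base_sdlog2`) under multiplicative noise.
#' * **specific** genes: a constant baseline in every sample plus one owner
#'   sample whose (pre-distortion) value is `specific_ratio` times the sum
#'   of all other samples, so each passes the Jongeneel specificity test
#'   after correct normalization. Owner samples are drawn with Zipf(1)
#'   weights: a few samples carry most specific-gene mass, which is what
#'   breaks total-count scaling.
#' * **noise** (variable) genes: own base level times the sample factor
#'   times `2^(s_g * e)` with a per-gene dispersion `s_g` drawn log-uniform
#'   on `noise_sd_range` -- the heterogeneous gene-level variability of
#'   real transcriptomes, spanning from nearly core-like to effectively
#'   independent profiles. A fraction `dropout` of their cells is zeroed.
#'
#' @param n_samples Number of samples (default 16).
#' @param n_core,n_specific,n_noise Gene counts per class.
#' @param true_factors Optional positive vector of per-sample distortion
#'   factors; drawn as `2^r`, `r` uniform on `[-0.5, 0.5)`, when omitted.
#' @param sigma Core-gene multiplicative noise sd in log2 units
#'   (default 0.05).
#' @param base_meanlog2,base_sdlog2 Parameters of the log-normal base
#'   expression (defaults 4 and 2: values span several orders of magnitude).
#' @param specific_meanlog2 Base-level log2 mean for specific genes.
#' @param specific_ratio Owner-sample excess over the summed baseline
#'   (default 3; must be > 1 for specificity).
#' @param noise_sd_range Range of per-gene log2 dispersions for variable
#'   genes (default `c(0.1, 2)`).
#' @param dropout Probability that a variable-gene cell is zeroed
#'   (default 0.1).
#' @param seed Integer seed; the whole matrix is reproducible under it.
#' @return A list with `data` (the distorted expression tibble) and `truth`
#'   (list: `true_factors` factor tibble, `adjusted_factors` its product-1
#'   form, `core`, `specific` (tibble `gene`, `sample`), `noise` gene ids,
#'   and `base` core profile).
#' @export
simulate_expression <- function(n_samples = 16L, n_core = 2000L,
                                n_specific = 200L, n_noise = 500L,
                                true_factors = NULL, sigma = 0.05,
                                base_meanlog2 = 4, base_sdlog2 = 2,
                                specific_meanlog2 = 4, specific_ratio = 3,
                                noise_sd_range = c(0.1, 2), dropout = 0.1,
                                seed = 1L) {
  if (n_samples < 2L) abort("at least 2 samples.")
  if (n_core + n_specific + n_noise < 2L) abort("at least 2 genes.")
  if (sigma < 0) abort("`sigma` must be non-negative.")
  if (specific_ratio <= 1) abort("`specific_ratio` must exceed 1.")
  samples <- sprintf("s%02d", seq_len(n_samples))

  built <- withr::with_seed(seed, {
    phi <- if (is.null(true_factors)) 2^runif(n_samples, -0.5, 0.5) else {
      if (length(true_factors) != n_samples || any(true_factors <= 0)) {
        abort("`true_factors` must be one positive value per sample.")
      }
      as.double(true_factors)
    }

    core_ids <- sprintf("core%04d", seq_len(n_core))
    spec_ids <- sprintf("spec%04d", seq_len(n_specific))
    noise_ids <- sprintf("var%04d", seq_len(n_noise))

    blocks <- list()
    base <- double()
    if (n_core > 0) {
      base <- 2^rnorm(n_core, base_meanlog2, base_sdlog2)
      eps <- matrix(rnorm(n_core * n_samples, 0, sigma), n_core, n_samples)
      blocks$core <- (base %o% phi) * 2^eps
      rownames(blocks$core) <- core_ids
    }
    spec_owner <- character()
    if (n_specific > 0) {
      # Zipf-weighted owner samples: few samples get most specific genes
      zipf <- (1 / seq_len(n_samples)) / sum(1 / seq_len(n_samples))
      owner <- sample.int(n_samples, n_specific, replace = TRUE, prob = zipf)
      baseline <- 2^rnorm(n_specific, specific_meanlog2, base_sdlog2)
      sm <- matrix(rep(baseline, n_samples), n_specific, n_samples)
      peak <- specific_ratio * baseline * (n_samples - 1)
      sm[cbind(seq_len(n_specific), owner)] <- peak
      blocks$spec <- sweep(sm, 2L, phi, `*`)
      rownames(blocks$spec) <- spec_ids
      spec_owner <- samples[owner]
    }
    if (n_noise > 0) {
      nbase <- 2^rnorm(n_noise, base_meanlog2, base_sdlog2)
      sds <- exp(runif(n_noise, log(noise_sd_range[1L]), log(noise_sd_range[2L])))
      eps <- matrix(rnorm(n_noise * n_samples), n_noise, n_samples) * sds
      nm <- (nbase %o% phi) * 2^eps
      if (dropout > 0) {
        nm[matrix(runif(n_noise * n_samples) < dropout, n_noise, n_samples)] <- 0
      }
      blocks$noise <- nm
      rownames(blocks$noise) <- noise_ids
    }
    m <- do.call(rbind, blocks)
    colnames(m) <- samples
    list(m = m, phi = phi, base = base, core_ids = core_ids,
         spec_ids = spec_ids, noise_ids = noise_ids, spec_owner = spec_owner)
  })

  data <- dplyr::bind_cols(
    tibble(gene = rownames(built$m)),
    as_tibble(as.data.frame(built$m))
  )
  truth_factors <- scaling_factors(setNames(built$phi, samples))
  list(
    data = check_expression(data),
    truth = list(
      true_factors = truth_factors,
      adjusted_factors = adjust_factors(truth_factors),
      core = built$core_ids,
      specific = tibble(gene = built$spec_ids, sample = built$spec_owner),
      noise = built$noise_ids,
      base = setNames(built$base, built$core_ids),
      sigma = sigma, seed = seed
    )
  )
}

#' Distort an expression matrix by per-sample factors
#'
#' Multiplies every value of sample `k` by `factors[k]`; the exact inverse
#' of normalizing by the reciprocal factors. Rank-based constructs
#' (trimmed sets, ubiquitous genes, the similarity network) are invariant
#' under this operation.
#'
#' @param data An expression tibble.
#' @param factors A factor tibble or named numeric vector over the samples.
#' @return The distorted expression tibble.
#' @export
distort_expression <- function(data, factors) {
  data <- check_expression(data)
  apply_factors(data, factors)
}
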