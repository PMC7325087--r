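## Simulation data-generating processes.
##
## All generators are pure functions of their arguments: the RNG state is
## saved and restored, so calling a generator never disturbs the caller's
## random stream and a fixed seed always yields a bit-identical dataset.

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

check_n <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 1) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  as.integer(n)
}

#' Linear-logit data-generating process
#'
#' One continuous predictor and a binary outcome generated as
#' `Y = 1\{3 X1 + eps > 0\}` with `X1 ~ N(0, 1)` and `eps ~ Logistic(0, 1)`,
#' i.e. exactly a logistic regression model with slope 3 on the latent scale.
#' The logistic noise is drawn by inverse-CDF transform of a uniform draw so
#' the stream is reproducible across platforms.
#'
#' @param n Number of samples.
#' @param seed Integer seed; fixed seed implies an identical dataset.
#' @param noise If `FALSE`, the noise term is dropped so labels become the
#'   deterministic indicator `1\{3 X1 > 0\}` (testing switch, on by default).
#' @return A [labeled_dataset] with a single predictor `X1`.
#' @export
#'
#' @examples
#' d <- gen_linear_dgp(500, seed = 1)
#' mean(d$y)
gen_linear_dgp <- function(n, seed = 1L, noise = TRUE) {
  n <- check_n(n)
  with_local_seed(seed, {
    x <- rnorm(n)
    eps <- if (noise) qlogis(runif(n)) else 0
    labeled_dataset(matrix(x, ncol = 1L), as.integer(3 * x + eps > 0),
                    names = "X1")
  })
}

#' Interval-membership (nonlinear) data-generating process
#'
#' `Y = 1\{X1 + 0.25 eps in (-6, -2.5) U (0, 1.5)\}` with
#' `X1 ~ U(-10, 10)` and `eps ~ N(0, 1)`. The positive class occupies two
#' disjoint intervals of total length 5 on a support of length 20, so the
#' marginal positive rate is about 25% and no monotone single-index model
#' can separate the classes.
#'
#' @inheritParams gen_linear_dgp
#' @return A [labeled_dataset] with a single predictor `X1`.
#' @export
gen_nonlinear_dgp <- function(n, seed = 1L, noise = TRUE) {
  n <- check_n(n)
  with_local_seed(seed, {
    x <- runif(n, -10, 10)
    eps <- if (noise) rnorm(n) else 0
    z <- x + 0.25 * eps
    y <- (z > -6 & z < -2.5) | (z > 0 & z < 1.5)
    labeled_dataset(matrix(x, ncol = 1L), as.integer(y), names = "X1")
  })
}

#' Four-predictor interaction data-generating process
#'
#' `Y = 1\{sigma(X1 + X2 + X3 + beta * X3 * X4) > 0.5\}` with
#' `X1..X3 ~ N(0, 1)` and `X4` drawn uniformly from `\{-0.5, 0.5\}`.
#' Because `sigma(z) > 0.5` exactly when `z > 0`, the label equals the
#' deterministic indicator `1\{X1 + X2 + X3 + X4 + beta * X3 * X4 > 0\}`
#' given the predictors: this DGP has no noise term, only an interaction of
#' tunable strength `beta` between the final two predictors.
#'
#' @param n Number of samples.
#' @param beta Interaction strength (finite real).
#' @param seed Integer seed.
#' @return A [labeled_dataset] with predictors `X1..X4`.
#' @export
gen_interaction_dgp <- function(n, beta = 0, seed = 1L) {
  n <- check_n(n)
  stopifnot(is.finite(beta))
  with_local_seed(seed, {
    X <- cbind(X1 = rnorm(n), X2 = rnorm(n), X3 = rnorm(n),
               X4 = sample(c(-0.5, 0.5), n, replace = TRUE))
    y <- as.integer(rowSums(X) + beta * X[, "X3"] * X[, "X4"] > 0)
    labeled_dataset(X, y)
  })
}

#' Two-locus pure-epistasis genotype data-generating process
#'
#' Synthetic stand-in for a genome-wide two-locus interaction study. Two
#' causal biallelic loci are coded as minor-allele counts `\{0, 1, 2\}`
#' (Hardy-Weinberg draws) and the trait follows an XOR penetrance on carrier
#' status: `y = 1` iff exactly one causal locus carries at least one minor
#' allele, with the label flipped with probability `heritability_noise`.
#' The causal minor-allele frequency defaults to `1 - sqrt(1/2)` so that the
#' carrier frequency is exactly 1/2, which makes each causal locus exactly
#' marginally independent of the trait -- the canonical pure-epistasis model
#' in which a main-effects-only logistic regression performs at chance while
#' a model aware of the interaction can approach the noise ceiling.
#' `n_noise_loci` additional independent non-causal loci are appended.
#'
#' The two causal loci are always the first two columns (`snp1`, `snp2`).
#'
#' @param n Number of samples.
#' @param n_noise_loci Number of non-causal loci to append (default 18).
#' @param heritability_noise Label-flip probability in `[0, 0.5]`.
#' @param maf Minor-allele frequency of every locus (default `1 - sqrt(1/2)`).
#' @param seed Integer seed.
#' @return A [labeled_dataset] with `2 + n_noise_loci` genotype predictors.
#' @export
gen_epistasis_dgp <- function(n, n_noise_loci = 18L, heritability_noise = 0.1,
                              maf = 1 - sqrt(0.5), seed = 1L) {
  n <- check_n(n)
  if (length(heritability_noise) != 1L || is.na(heritability_noise) ||
      heritability_noise < 0 || heritability_noise > 0.5) {
    stop("`heritability_noise` must lie in [0, 0.5]", call. = FALSE)
  }
  n_noise_loci <- as.integer(n_noise_loci)
  stopifnot(n_noise_loci >= 0L, maf > 0, maf < 1)
  with_local_seed(seed, {
    g1 <- rbinom(n, 2L, maf)
    g2 <- rbinom(n, 2L, maf)
    y <- as.integer(xor(g1 >= 1L, g2 >= 1L))
    if (heritability_noise > 0) {
      flip <- rbinom(n, 1L, heritability_noise) == 1L
      y[flip] <- 1L - y[flip]
    }
    G <- cbind(g1, g2)
    if (n_noise_loci > 0L) {
      G <- cbind(G, matrix(rbinom(n * n_noise_loci, 2L, maf), nrow = n))
    }
    labeled_dataset(G, y, names = paste0("snp", seq_len(ncol(G))))
  })
}

#' Generate a dataset from a DGP configuration
#'
#' Dispatcher over the four generators, driven by a configuration list as
#' used in JSON run configs: fields `dgp_id` (one of `"linear"`,
#' `"nonlinear_interval"`, `"interaction4"`, `"epistasis"`), `n`, `seed`,
#' and, where relevant, `beta`, `n_noise_loci`, `heritability_noise`.
#'
#' @param config Named list (or JSON-parsed equivalent).
#' @return A [labeled_dataset].
#' @export
simulate_dgp <- function(config) {
  stopifnot(is.list(config), !is.null(config$dgp_id), !is.null(config$n))
  seed <- if (is.null(config$seed)) 1L else config$seed
  switch(match.arg(config$dgp_id,
                   c("linear", "nonlinear_interval", "interaction4",
                     "epistasis")),
    linear = gen_linear_dgp(config$n, seed = seed),
    nonlinear_interval = gen_nonlinear_dgp(config$n, seed = seed),
    interaction4 = gen_interaction_dgp(
      config$n, beta = if (is.null(config$beta)) 0 else config$beta,
      seed = seed),
    epistasis = gen_epistasis_dgp(
      config$n,
      n_noise_loci = if (is.null(config$n_noise_loci)) 18L
                     else config$n_noise_loci,
      heritability_noise = if (is.null(config$heritability_noise)) 0.1
                           else config$heritability_noise,
      seed = seed)
  )
}
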