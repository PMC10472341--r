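#' Simulation configuration
#'
#' Builds and validates the configuration object that drives the synthetic
#' survey generator. Areas are the cross-classification region x sex x
#' age group (2 sexes, 5 age bands: 15-34, 35-54, 55-64, 65-74, >=75), so the
#' number of areas is \code{D = n_regions * 10}.
#'
#' The generative model for the true area prevalences is a multinomial logit
#' with reference category "never smoker": for categories k = 1 (smoker) and
#' k = 2 (ex-smoker),
#' \deqn{\eta_{dk} = x_{dk}'\beta_k + u_{dk}, \quad u_{dk} \sim N(0, \phi_k)}
#' and \eqn{p_{dk} = \exp(\eta_{dk}) / (1 + \exp(\eta_{d1}) + \exp(\eta_{d2}))},
#' \eqn{p_{d3} = 1 - p_{d1} - p_{d2}}. Covariates are an intercept plus
#' \code{n_covariates} standardized continuous area-level variables drawn
#' independently per category.
#'
#' @param n_regions Number of regions; areas = \code{n_regions * 10}.
#' @param beta1,beta2 Regression coefficient vectors for the smoker and
#'   ex-smoker logits. Length is \code{1 + n_covariates}.
#' @param phi Length-2 nonnegative vector of random-effect variances
#'   \eqn{(\phi_1, \phi_2)} on the logit scale.
#' @param n_covariates Number of standardized continuous covariates per
#'   category (in addition to the intercept).
#' @param national_sample_per_area,regional_sample_per_area Planned sample
#'   size per area for the two emulated surveys; a scalar or a length-D
#'   vector. Zero entries are legal and yield areas with no respondents.
#' @param weight_dispersion Nonnegative log-scale standard deviation of the
#'   multiplicative lognormal weight noise (unit mean); 0 gives exact
#'   equal-allocation weights \code{population_size / n_d}.
#' @param pop_meanlog,pop_sdlog Lognormal parameters for area population
#'   sizes.
#' @param seed Integer seed; identical configurations reproduce byte-identical
#'   synthetic data.
#'
#' @return A list of class \code{"sim_config"}.
#' @seealso [generate_area_frame()], [generate_survey()], [default_sim_config()]
#' @export
sim_config <- function(n_regions = 18,
                       beta1 = c(-0.9, 0.35, -0.2),
                       beta2 = c(-0.75, 0.15, 0.25),
                       phi = c(0.1, 0.1),
                       n_covariates = 2,
                       national_sample_per_area = 130,
                       regional_sample_per_area = 780,
                       weight_dispersion = 0.3,
                       pop_meanlog = log(5e4),
                       pop_sdlog = 0.3,
                       seed = 1L) {
  cfg <- list(
    n_regions = as.integer(n_regions),
    beta1 = as.numeric(beta1),
    beta2 = as.numeric(beta2),
    phi = as.numeric(phi),
    n_covariates = as.integer(n_covariates),
    national_sample_per_area = as.numeric(national_sample_per_area),
    regional_sample_per_area = as.numeric(regional_sample_per_area),
    weight_dispersion = as.numeric(weight_dispersion),
    pop_meanlog = as.numeric(pop_meanlog),
    pop_sdlog = as.numeric(pop_sdlog),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_regions < 1) stop("n_regions must be >= 1")
  if (length(cfg$phi) != 2 || any(!is.finite(cfg$phi)) || any(cfg$phi < 0)) {
    stop("phi must be two finite nonnegative random-effect variances")
  }
  r <- 1L + cfg$n_covariates
  if (length(cfg$beta1) != r || length(cfg$beta2) != r) {
    stop("beta1 and beta2 must have length 1 + n_covariates (intercept first)")
  }
  D <- n_areas(cfg)
  for (nm in c("national_sample_per_area", "regional_sample_per_area")) {
    n_d <- cfg[[nm]]
    if (!length(n_d) %in% c(1L, D) || any(n_d < 0) || any(n_d != floor(n_d))) {
      stop(nm, " must be a nonnegative integer scalar or length-D vector")
    }
  }
  if (all(rep(cfg$national_sample_per_area, length.out = D) == 0) &&
      all(rep(cfg$regional_sample_per_area, length.out = D) == 0)) {
    stop("at least one area must have a positive sample size")
  }
  if (cfg$weight_dispersion < 0) stop("weight_dispersion must be >= 0")
  invisible(cfg)
}

#' Number of areas implied by a configuration
#' @param cfg A \code{sim_config}.
#' @return Integer, \code{n_regions * 2 * 5}.
#' @export
n_areas <- function(cfg) cfg$n_regions * 2L * 5L

#' Default paired-survey scenario
#'
#' The default geometry mirrors a national health survey spread over
#' 18 regions x 2 sexes x 5 age groups = 180 areas with roughly 130
#' respondents per area, validated against a regional survey six times
#' larger per area (the reported regional-to-national sample ratio is 5.9).
#' One area of the national survey is deliberately given zero sample, so
#' the pipeline always exercises the synthetic (fixed-effects-only)
#' prediction path that replaces an undefined direct estimate.
#'
#' @param seed Integer seed.
#' @return A \code{sim_config}.
#' @export
default_sim_config <- function(seed = 1L) {
  cfg <- sim_config(seed = as.integer(seed))
  D <- n_areas(cfg)
  nat <- rep(130, D)
  nat[D] <- 0  # zero-sample cell: oldest age band, one region
  cfg$national_sample_per_area <- nat
  validate_sim_config(cfg)
  cfg
}

#' Read / write a simulation configuration
#'
#' Configurations are stored as YAML so runs are reproducible from a plain
#' text file.
#'
#' @param path File path.
#' @return \code{read_sim_config} returns a \code{sim_config};
#'   \code{write_sim_config} returns \code{path} invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(sim_config, raw[setdiff(names(raw), "national_zero_areas")])
  if (!is.null(raw$national_zero_areas)) {
    D <- n_areas(cfg)
    nat <- rep(cfg$national_sample_per_area, length.out = D)
    nat[as.integer(raw$national_zero_areas)] <- 0
    cfg$national_sample_per_area <- nat
    validate_sim_config(cfg)
  }
  cfg
}

#' @rdname read_sim_config
#' @param cfg A \code{sim_config}.
#' @export
write_sim_config <- function(cfg, path) {
  validate_sim_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
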