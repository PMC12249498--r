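#' Generate a synthetic saturation-binding dataset
#'
#' Draws total and nonspecific bound values at the given free-ligand
#' concentrations from a one-site model: specific binding is
#' \eqn{B(L) = B_{max} L / (K_d + L)} plus Gaussian noise, nonspecific
#' binding is linear in L plus the same noise, and total = specific +
#' nonspecific. With \code{noise_sd = 0} the curve is exact, so a downstream
#' one-site fit must recover the generating parameters.
#'
#' @param bmax Generating maximal binding capacity (fmol/mg protein), > 0.
#' @param kd Generating dissociation constant (nM), > 0.
#' @param concentrations Free ligand concentrations (nM), all > 0. Default:
#'   12 log-spaced points over the assay design span 0.09--4.95 nM.
#' @param noise_sd Gaussian measurement noise SD (fmol/mg protein).
#' @param replicates Replicates per concentration (the assays run in
#'   duplicate).
#' @param ns_slope Nonspecific binding per nM of ligand (fmol/mg/nM).
#' @param seed Integer seed.
#' @return Object of class \code{"saturation_dataset"}: data.frame with
#'   columns \code{conc_nM}, \code{replicate}, \code{total},
#'   \code{nonspecific}; the generating parameters are kept in attributes.
#' @examples
#' d <- generate_saturation_dataset(100, 1, noise_sd = 0, seed = 1)
#' @export
generate_saturation_dataset <- function(bmax, kd,
                                        concentrations =
                                          exp(seq(log(0.09), log(4.95),
                                                  length.out = 12)),
                                        noise_sd = 0, replicates = 2,
                                        ns_slope = 0.02 * bmax, seed = 1) {
  if (!is.numeric(bmax) || bmax <= 0) stop("'bmax' must be > 0")
  if (!is.numeric(kd) || kd <= 0) stop("'kd' must be > 0")
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (replicates < 1) stop("'replicates' must be >= 1")
  set.seed(as.integer(seed))
  L <- rep(concentrations, each = replicates)
  rep_id <- rep(seq_len(replicates), times = length(concentrations))
  spec <- bmax * L / (kd + L) + stats::rnorm(length(L), 0, noise_sd)
  ns <- ns_slope * L + stats::rnorm(length(L), 0, noise_sd)
  d <- data.frame(conc_nM = L, replicate = rep_id, total = spec + ns,
                  nonspecific = ns)
  attr(d, "generating") <- list(bmax = bmax, kd = kd, ns_slope = ns_slope,
                                noise_sd = noise_sd)
  class(d) <- c("saturation_dataset", "data.frame")
  d
}

#' Generate a synthetic densitometry dataset
#'
#' Constructs western-blot band optical densities (target and beta-actin,
#' each with a local background) such that the background-subtracted,
#' actin-normalized ratio has the stated group mean. Noise perturbs the
#' target band multiplicatively (log-normal with the given CV).
#'
#' @param true_ratio Named numeric vector: mean normalized expression per
#'   group.
#' @param n Samples per group (recycled).
#' @param noise Coefficient of variation of the normalized ratio (0 = exact).
#' @param actin_od Mean beta-actin band OD (arbitrary units).
#' @param background Local background OD applied to both bands.
#' @param seed Integer seed.
#' @return data.frame with columns \code{sample}, \code{group},
#'   \code{target_od}, \code{target_bg}, \code{actin_od}, \code{actin_bg}.
#' @export
generate_densitometry_dataset <- function(true_ratio, n = 6, noise = 0.1,
                                          actin_od = 100, background = 10,
                                          seed = 1) {
  if (any(n < 1)) stop("'n' must be >= 1")
  if (is.null(names(true_ratio)))
    names(true_ratio) <- paste0("g", seq_along(true_ratio))
  n <- rep_len(as.integer(n), length(true_ratio))
  set.seed(as.integer(seed))
  rows <- lapply(seq_along(true_ratio), function(g) {
    ratio <- true_ratio[[g]] * if (noise > 0)
      stats::rlnorm(n[g], -0.5 * log1p(noise^2), sqrt(log1p(noise^2)))
      else rep(1, n[g])
    data.frame(sample = sprintf("%s_%02d", names(true_ratio)[g],
                                seq_len(n[g])),
               group = names(true_ratio)[g],
               target_od = ratio * actin_od + background,
               target_bg = background,
               actin_od = actin_od + background,
               actin_bg = background,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
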