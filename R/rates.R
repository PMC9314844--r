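#' Demographic rates of the nine-state life cycle
#'
#' Container for the annual demographic rates driving the pre-breeding-census
#' projection: survival over the first two years of life (`phi0`, applied to
#' both the fledgling-to-yearling and yearling-to-age-2 transitions) and from
#' age 2 onwards (`phi2`); age-specific recruitment probabilities `rho3` to
#' `rho6` (conditional on survival; recruitment at age 7 is forced, so no rate
#' is stored for it); breeding probabilities of former breeders (`psi_b`) and
#' former skippers (`psi_s`); and per-capita fledgling production of
#' first-time (`pi_f`) and experienced (`pi_e`) breeders (half the per-nest
#' fledgling number, since a nest is attended by two adults).
#'
#' Interval-indexed rates (`phi0`, `phi2`, `rho*`, `psi_*`) have one value per
#' year-to-year interval (`n_years - 1`); productivity rates (`pi_f`, `pi_e`)
#' have one value per year. Scalars are recycled.
#'
#' @param phi0,phi2 survival probabilities.
#' @param rho3,rho4,rho5,rho6 recruitment probabilities at ages 3--6.
#' @param psi_b,psi_s breeding probabilities of former breeders/skippers.
#' @param pi_f,pi_e per-capita fledgling rates (non-negative).
#' @param n_years length of the study horizon (>= 2).
#'
#' @return An object of class `demographic_rates`: a list of rate vectors plus
#'   `n_years`.
#' @export
#' @examples
#' r <- demographic_rates(phi0 = 0.65, phi2 = 0.81, rho3 = 0.13, rho4 = 0.41,
#'                        rho5 = 0.53, rho6 = 0.67, psi_b = 0.90, psi_s = 0.69,
#'                        pi_f = 0.16, pi_e = 0.36, n_years = 28)
#' r
demographic_rates <- function(phi0, phi2, rho3, rho4, rho5, rho6,
                              psi_b, psi_s, pi_f, pi_e, n_years) {
  if (!is.numeric(n_years) || length(n_years) != 1L || n_years < 2) {
    bp_stop("'n_years' must be a single integer >= 2")
  }
  n_years <- as.integer(n_years)
  ni <- n_years - 1L
  out <- list(
    phi0 = recycle_to(phi0, ni, "phi0"),
    phi2 = recycle_to(phi2, ni, "phi2"),
    rho3 = recycle_to(rho3, ni, "rho3"),
    rho4 = recycle_to(rho4, ni, "rho4"),
    rho5 = recycle_to(rho5, ni, "rho5"),
    rho6 = recycle_to(rho6, ni, "rho6"),
    psi_b = recycle_to(psi_b, ni, "psi_b"),
    psi_s = recycle_to(psi_s, ni, "psi_s"),
    pi_f = recycle_to(pi_f, n_years, "pi_f"),
    pi_e = recycle_to(pi_e, n_years, "pi_e"),
    n_years = n_years
  )
  for (nm in c("phi0", "phi2", "rho3", "rho4", "rho5", "rho6", "psi_b", "psi_s")) {
    check_prob(out[[nm]], nm)
  }
  check_nonneg(out$pi_f, "pi_f")
  check_nonneg(out$pi_e, "pi_e")
  structure(out, class = "demographic_rates")
}

#' @export
print.demographic_rates <- function(x, ...) {
  cat(sprintf("Demographic rates over %d years (%d intervals)\n",
              x$n_years, x$n_years - 1L))
  for (nm in c("phi0", "phi2", "rho3", "rho4", "rho5", "rho6",
               "psi_b", "psi_s", "pi_f", "pi_e")) {
    v <- x[[nm]]
    if (length(unique(round(v, 10))) == 1L) {
      cat(sprintf("  %-5s = %.3f (constant)\n", nm, v[1]))
    } else {
      cat(sprintf("  %-5s : mean %.3f, range [%.3f, %.3f]\n",
                  nm, mean(v), min(v), max(v)))
    }
  }
  invisible(x)
}

# Extract the rates of interval t (transition year t -> t+1), as scalars.
rates_at <- function(rates, t) {
  stopifnot(t >= 1, t <= rates$n_years - 1L)
  list(
    phi0 = rates$phi0[t], phi2 = rates$phi2[t],
    rho = c(rates$rho3[t], rates$rho4[t], rates$rho5[t], rates$rho6[t]),
    psi_b = rates$psi_b[t], psi_s = rates$psi_s[t],
    pi_f = rates$pi_f[t], pi_e = rates$pi_e[t]
  )
}

#' Observation model for the three data streams
#'
#' Resighting probabilities and count observation error: yearlings and older
#' pre-breeders have their own (possibly year-varying) resighting
#' probabilities, while breeders and skippers share one constant resighting
#' probability; annual breeder counts carry log-normal error with
#' time-independent standard deviation `sigma_obs`.
#'
#' Resightings can occur from the second study year onwards (individuals are
#' marked as chicks and first available at age 1), so `p_y` and `p_p` have one
#' value per year from year 2 to `n_years`.
#'
#' @param p_y yearling resighting probability (scalar or length `n_years - 1`).
#' @param p_p resighting probability of pre-breeders aged 2+ (scalar or length
#'   `n_years - 1`).
#' @param p_r constant resighting probability of breeders and skippers.
#' @param sigma_obs standard deviation of the log-scale count error (> 0, or 0
#'   for error-free counts in simulation).
#' @param n_years study horizon.
#'
#' @return An object of class `observation_model`.
#' @export
observation_model <- function(p_y, p_p, p_r, sigma_obs, n_years) {
  n_years <- as.integer(n_years)
  if (n_years < 2) bp_stop("'n_years' must be >= 2")
  out <- list(
    p_y = recycle_to(p_y, n_years - 1L, "p_y"),
    p_p = recycle_to(p_p, n_years - 1L, "p_p"),
    p_r = as.numeric(p_r),
    sigma_obs = as.numeric(sigma_obs),
    n_years = n_years
  )
  check_prob(out$p_y, "p_y")
  check_prob(out$p_p, "p_p")
  check_prob(out$p_r, "p_r")
  if (length(out$p_r) != 1L || length(out$sigma_obs) != 1L) {
    bp_stop("'p_r' and 'sigma_obs' must be scalars")
  }
  check_nonneg(out$sigma_obs, "sigma_obs")
  structure(out, class = "observation_model")
}

#' @export
print.observation_model <- function(x, ...) {
  cat(sprintf(
    "Observation model (%d years): p_y mean %.3f, p_p mean %.3f, p_r %.3f, sigma_obs %.3f\n",
    x$n_years, mean(x$p_y), mean(x$p_p), x$p_r, x$sigma_obs))
  invisible(x)
}
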