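# Core stochastic projection of the nine-state pre-breeding-census life cycle.

#' Expectation matrix of the life cycle
#'
#' The 9 x 9 matrix `A_t` such that `E[N(t+1)] = A_t N(t) + I(t+1) e_F`, where
#' `e_F` is the indicator of the first-time-breeder class. Survival over the
#' first two years of life uses `phi0` (both the fledgling-to-yearling and the
#' yearling-to-age-2 transitions); all older classes survive with `phi2`.
#' Recruitment happens at ages 3--7, with the age-7 rate fixed to 1.
#'
#' @param rates a [demographic_rates] object.
#' @param t interval index (transition from year `t` to `t + 1`).
#' @return A 9 x 9 numeric matrix with rows/columns in class order.
#' @export
expectation_matrix <- function(rates, t = 1L) {
  r <- rates_at(rates, t)
  A <- matrix(0, 9L, 9L, dimnames = list(CLASSES, CLASSES))
  A["Y", "F"] <- r$pi_f * r$phi0
  A["Y", "E"] <- r$pi_e * r$phi0
  A["P2", "Y"] <- r$phi0
  A["P3", "P2"] <- r$phi2 * (1 - r$rho[1])
  A["P4", "P3"] <- r$phi2 * (1 - r$rho[2])
  A["P5", "P4"] <- r$phi2 * (1 - r$rho[3])
  A["P6", "P5"] <- r$phi2 * (1 - r$rho[4])
  A["F", "P2"] <- r$phi2 * r$rho[1]
  A["F", "P3"] <- r$phi2 * r$rho[2]
  A["F", "P4"] <- r$phi2 * r$rho[3]
  A["F", "P5"] <- r$phi2 * r$rho[4]
  A["F", "P6"] <- r$phi2            # recruitment at age 7 is forced
  A["E", "F"] <- A["E", "E"] <- r$phi2 * r$psi_b
  A["E", "S"] <- r$phi2 * r$psi_s
  A["S", "F"] <- A["S", "E"] <- r$phi2 * (1 - r$psi_b)
  A["S", "S"] <- r$phi2 * (1 - r$psi_s)
  A
}

#' Expected one-year projection
#'
#' Deterministic expectation of the stochastic transition: the class vector at
#' `t + 1` expected from the state at `t`, the demographic rates of interval
#' `t` and the immigrant pulse entering at `t + 1` (clamped at zero; the raw,
#' possibly negative immigrant value is kept only for inference).
#'
#' @param rates a [demographic_rates] object.
#' @param state_t length-9 class vector (or single-year [population_state]).
#' @param I_next immigrants entering the first-time-breeder class at `t + 1`.
#' @param t interval index.
#' @return Named numeric vector of expected class sizes at `t + 1`.
#' @export
#' @examples
#' r <- demographic_rates(0.65, 0.81, 0.13, 0.41, 0.53, 0.67, 0.90, 0.69,
#'                        0.16, 0.36, n_years = 2)
#' project_expectation(r, c(359, 233, 164, 79, 30, 8, 366, 1371, 188), 230)
project_expectation <- function(rates, state_t, I_next = 0, t = 1L) {
  state_t <- as.numeric(state_t)
  if (length(state_t) != 9L) bp_stop("'state_t' must have 9 classes")
  check_nonneg(state_t, "state_t")
  A <- expectation_matrix(rates, t)
  out <- drop(A %*% state_t)
  out["F"] <- out["F"] + max(I_next, 0)
  out
}

#' Simulate one stochastic transition
#'
#' Draws the class vector at `t + 1` with full demographic stochasticity:
#' new yearlings are Poisson around the expected locally produced and
#' surviving fledglings, and every survival / recruitment / breeding
#' transition is a (nested) binomial draw from its source class, so no
#' destination count can exceed its source. Immigrants enter as
#' `round(max(I_next, 0))` first-time breeders.
#'
#' @inheritParams project_expectation
#' @param nsim number of independent replicate draws.
#' @return If `nsim = 1`, a named integer vector; otherwise a 9 x `nsim`
#'   integer matrix.
#' @export
simulate_transition <- function(rates, state_t, I_next = 0, t = 1L, nsim = 1L) {
  state_t <- as.numeric(state_t)
  if (length(state_t) != 9L) bp_stop("'state_t' must have 9 classes")
  check_nonneg(state_t, "state_t")
  if (any(abs(state_t - round(state_t)) > 1e-8)) {
    bp_stop("'state_t' must contain integer counts")
  }
  st <- as.integer(round(state_t))
  r <- rates_at(rates, t)
  pulse <- as.integer(round(max(I_next, 0)))

  ynew <- rpois(nsim, (st[7] * r$pi_f + st[8] * r$pi_e) * r$phi0)
  sy <- rbinom(nsim, st[1], r$phi0)
  sp2 <- rbinom(nsim, st[2], r$phi2)
  sp3 <- rbinom(nsim, st[3], r$phi2)
  sp4 <- rbinom(nsim, st[4], r$phi2)
  sp5 <- rbinom(nsim, st[5], r$phi2)
  sp6 <- rbinom(nsim, st[6], r$phi2)
  rec2 <- rbinom(nsim, sp2, r$rho[1])
  rec3 <- rbinom(nsim, sp3, r$rho[2])
  rec4 <- rbinom(nsim, sp4, r$rho[3])
  rec5 <- rbinom(nsim, sp5, r$rho[4])
  sf <- rbinom(nsim, st[7], r$phi2)
  fb <- rbinom(nsim, sf, r$psi_b)
  se <- rbinom(nsim, st[8], r$phi2)
  eb <- rbinom(nsim, se, r$psi_b)
  ss <- rbinom(nsim, st[9], r$phi2)
  sb <- rbinom(nsim, ss, r$psi_s)

  out <- rbind(
    Y = ynew,
    P2 = sy,
    P3 = sp2 - rec2,
    P4 = sp3 - rec3,
    P5 = sp4 - rec4,
    P6 = sp5 - rec5,
    F = rec2 + rec3 + rec4 + rec5 + sp6 + pulse,
    E = fb + eb + sb,
    S = (sf - fb) + (se - eb) + (ss - sb)
  )
  if (nsim == 1L) out[, 1L] else out
}

#' Simulate a full population trajectory at the individual level
#'
#' Runs the stochastic life cycle forward for `n_years` years, tracking every
#' individual so that capture-resighting histories can be generated from true
#' latent paths. Aggregating the individual class codes reproduces the class
#' counts exactly; locally produced fledglings are Poisson draws thinned by
#' first-year survival (equivalent to the Poisson yearling model of
#' [simulate_transition]), and immigrants enter as first-time breeders.
#'
#' @param rates a [demographic_rates] object (defines `n_years`).
#' @param I_series immigrant numbers entering in years `2 .. n_years`
#'   (length `n_years - 1`; negative values are clamped to zero and rounded
#'   for the realized pulse).
#' @param initial_state length-9 class vector for year 1.
#' @param seed optional RNG seed (fixed seed gives an identical trajectory).
#' @param dd_psi_b optional density-dependence coefficient: before each
#'   interval, `psi_b[t]` is shifted on the logit scale by
#'   `dd_psi_b * (B[t] - B[1]) / (0.1 B[1])` using the realized breeder total
#'   `B[t]`; the realized `psi_b` series is returned in `$rates`.
#' @return An object of class `trajectory`: a list with
#'   \describe{
#'     \item{states}{[population_state] matrix, 9 x n_years;}
#'     \item{class_mat}{individuals x years integer matrix of class indices
#'       (0 = not yet present or dead, 1..9 = class);}
#'     \item{entry_year, origin}{per-individual entry year and origin
#'       (`initial`, `born`, `immigrant`);}
#'     \item{born_year}{year of birth for `born` individuals (NA otherwise);
#'       chicks exist at age 0 (not a census class) and appear as yearlings
#'       the following year if they survive;}
#'     \item{branches}{per-interval transition aggregates (survivors,
#'       recruits, breeding decisions) used by the state-process likelihood;}
#'     \item{I_pulse}{realized immigrant pulses.}
#'   }
#' @export
simulate_trajectory <- function(rates, I_series, initial_state, seed = NULL,
                                dd_psi_b = 0) {
  T <- rates$n_years
  if (T < 2) bp_stop("'n_years' must be >= 2")
  I_series <- recycle_to(I_series, T - 1L, "I_series")
  st0 <- as.numeric(initial_state)
  if (length(st0) != 9L || any(st0 < 0)) bp_stop("invalid initial state")
  st0 <- as.integer(round(st0))
  if (!is.null(seed)) set.seed(seed)
  B_ref <- sum(st0[7:8])

  n0 <- sum(st0)
  # generous pre-allocation; grown if needed
  cap <- n0 + as.integer(sum(pmax(I_series, 0))) + 64L
  class_mat <- matrix(0L, nrow = cap, ncol = T)
  entry_year <- integer(cap)
  origin <- character(cap)
  born_year <- rep(NA_integer_, cap)
  n_ind <- 0L

  add_individuals <- function(k, year, cls, orig, born = NA_integer_) {
    if (k == 0L) return(integer(0))
    while (n_ind + k > nrow(class_mat)) {
      class_mat <<- rbind(class_mat,
                          matrix(0L, nrow = max(1024L, k), ncol = T))
      entry_year <<- c(entry_year, integer(max(1024L, k)))
      origin <<- c(origin, character(max(1024L, k)))
      born_year <<- c(born_year, rep(NA_integer_, max(1024L, k)))
    }
    idx <- n_ind + seq_len(k)
    n_ind <<- n_ind + k
    if (!is.na(cls) && cls > 0L && year <= T) class_mat[idx, year] <<- cls
    entry_year[idx] <<- year
    origin[idx] <<- orig
    born_year[idx] <<- born
    idx
  }

  for (k in seq_len(9L)) add_individuals(st0[k], 1L, k, "initial")

  pulse <- as.integer(round(pmax(I_series, 0)))
  branches <- vector("list", T - 1L)
  chick_ids <- vector("list", T)  # fledglings born in year t (age 0)

  for (t in seq_len(T - 1L)) {
    cls <- class_mat[seq_len(n_ind), t]
    if (dd_psi_b != 0 && B_ref > 0) {
      B_t <- sum(cls == 7L) + sum(cls == 8L)
      z <- (B_t - B_ref) / (0.1 * B_ref)
      rates$psi_b[t] <- plogis(qlogis(rates$psi_b[t]) + dd_psi_b * z)
    }
    r <- rates_at(rates, t)

    # locally produced fledglings at t (age 0, censused only if they reach 1)
    NF <- sum(cls == 7L); NE <- sum(cls == 8L)
    nfl <- rpois(1L, NF * r$pi_f + NE * r$pi_e)
    ids_chicks <- add_individuals(nfl, t, 0L, "born", born = t)
    chick_ids[[t]] <- ids_chicks
    surv_chick <- if (nfl > 0) rbinom(nfl, 1L, r$phi0) == 1L else logical(0)
    if (nfl > 0) class_mat[ids_chicks[surv_chick], t + 1L] <- 1L

    alive <- which(cls > 0L)
    acl <- cls[alive]
    p_surv <- ifelse(acl == 1L, r$phi0, r$phi2)
    survived <- rbinom(length(alive), 1L, p_surv) == 1L
    sv <- alive[survived]
    scl <- acl[survived]

    newcls <- integer(length(sv))
    newcls[scl == 1L] <- 2L                      # Y -> P2
    for (i in 2:5) {                             # P2..P5: recruit or age
      sel <- scl == i
      if (any(sel)) {
        rec <- rbinom(sum(sel), 1L, r$rho[i - 1L]) == 1L
        newcls[sel] <- ifelse(rec, 7L, i + 1L)
      }
    }
    newcls[scl == 6L] <- 7L                      # P6 -> F (forced)
    sel <- scl %in% c(7L, 8L)                    # F,E -> E or S
    if (any(sel)) {
      br <- rbinom(sum(sel), 1L, r$psi_b) == 1L
      newcls[sel] <- ifelse(br, 8L, 9L)
    }
    sel <- scl == 9L                             # S -> E or S
    if (any(sel)) {
      br <- rbinom(sum(sel), 1L, r$psi_s) == 1L
      newcls[sel] <- ifelse(br, 8L, 9L)
    }
    class_mat[sv, t + 1L] <- newcls

    add_individuals(pulse[t], t + 1L, 7L, "immigrant")

    branches[[t]] <- c(
      ynew = sum(surv_chick),
      sy = sum(scl == 1L),
      sp2 = sum(scl == 2L), sp3 = sum(scl == 3L), sp4 = sum(scl == 4L),
      sp5 = sum(scl == 5L), sp6 = sum(scl == 6L),
      rec2 = sum(scl == 2L & newcls == 7L), rec3 = sum(scl == 3L & newcls == 7L),
      rec4 = sum(scl == 4L & newcls == 7L), rec5 = sum(scl == 5L & newcls == 7L),
      sf = sum(scl == 7L), fb = sum(scl == 7L & newcls == 8L),
      se = sum(scl == 8L), eb = sum(scl == 8L & newcls == 8L),
      ss = sum(scl == 9L), sb = sum(scl == 9L & newcls == 8L)
    )
  }

  class_mat <- class_mat[seq_len(n_ind), , drop = FALSE]
  states <- vapply(seq_len(T), function(t) {
    tabulate(class_mat[, t], nbins = 9L)
  }, integer(9L))
  rownames(states) <- CLASSES

  structure(list(
    states = population_state(states),
    class_mat = class_mat,
    entry_year = entry_year[seq_len(n_ind)],
    origin = origin[seq_len(n_ind)],
    born_year = born_year[seq_len(n_ind)],
    chick_ids = chick_ids,
    branches = branches,
    I_pulse = pulse,
    I_series = I_series,
    rates = rates
  ), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  B <- breeders(x$states)
  cat(sprintf("Simulated trajectory: %d years, %d individuals\n",
              ncol(x$states), nrow(x$class_mat)))
  cat(sprintf("Breeders: %d .. %d (mean %.0f); realized growth %.4f/yr\n",
              min(B), max(B), mean(B),
              exp(mean(diff(log(B))))))
  invisible(x)
}
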