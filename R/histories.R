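# Capture-resighting histories: representation, validation, pooling.

#' Capture-resighting histories
#'
#' Per-individual annual observation codes over the study window. Individuals
#' are marked as chicks (age 0) in their ringing year; resightings can occur
#' from the following year onwards and report the true breeding status
#' without error: `0` not seen, `1` pre-breeder (yearling or older), `2`
#' breeder, `3` skipper. Birds ringed before the study window (`ring_year < 1`)
#' are supported: their likelihood is conditioned on the first resighting
#' inside the window.
#'
#' @param obs integer matrix (individuals x years) of observation codes; cells
#'   for years up to and including the ringing year must be `NA` or `-1`.
#' @param ring_year integer vector of ringing years (1-based study years;
#'   values < 1 denote pre-window ringing).
#' @param id optional individual identifiers.
#' @param validate enforce the life-cycle invariants (no breeder/skipper code
#'   before age 3, no pre-breeder code after recruitment, ...). The data
#'   loader always validates; disable only to evaluate the likelihood of
#'   structurally impossible histories, for which [forward_loglik] returns
#'   `-Inf` rather than raising an error.
#'
#' @return An object of class `capture_histories`: list with `obs` (codes,
#'   `-1` before first availability), `ring_year`, `id`, `n_years`.
#' @export
capture_histories <- function(obs, ring_year, id = NULL, validate = TRUE) {
  obs <- as.matrix(obs)
  storage.mode(obs) <- "integer"
  obs[is.na(obs)] <- -1L
  n <- nrow(obs)
  T <- ncol(obs)
  if (length(ring_year) != n) bp_stop("'ring_year' must match nrow(obs)")
  ring_year <- as.integer(ring_year)
  if (is.null(id)) id <- seq_len(n)

  x <- structure(list(obs = obs, ring_year = ring_year, id = id, n_years = T),
                 class = "capture_histories")
  if (validate) validate_histories(x)
  x
}

# Enforce the structural invariants of the life cycle on observed codes.
validate_histories <- function(x) {
  obs <- x$obs
  T <- x$n_years
  for (i in seq_len(nrow(obs))) {
    r <- x$ring_year[i]
    if (r >= T) {
      if (any(obs[i, ] >= 0L)) {
        bp_stop(sprintf("history %s: resighting without any post-ringing year", x$id[i]),
                class = "bp_history_error")
      }
      next
    }
    pre <- seq_len(min(max(r, 0L), T))
    if (length(pre) && any(obs[i, pre] > 0L)) {
      bp_stop(sprintf("history %s: resighting at or before ringing", x$id[i]),
              class = "bp_history_error")
    }
    yrs <- (max(r, 0L) + 1L):T
    codes <- obs[i, yrs]
    ages <- yrs - r
    if (any(codes %in% c(2L, 3L) & ages < 3L)) {
      bp_stop(sprintf(
        "history %s: breeder/skipper code before age 3 (recruitment starts at age 3)",
        x$id[i]), class = "bp_history_error")
    }
    rec <- which(codes %in% c(2L, 3L))
    if (length(rec) && any(codes[rec[1L]:length(codes)] == 1L)) {
      bp_stop(sprintf("history %s: pre-breeder code after recruitment", x$id[i]),
              class = "bp_history_error")
    }
    if (any(codes == 1L & ages > 6L)) {
      bp_stop(sprintf("history %s: pre-breeder code after age 6", x$id[i]),
              class = "bp_history_error")
    }
  }
  invisible(x)
}

#' @export
print.capture_histories <- function(x, ...) {
  n <- nrow(x$obs)
  seen <- sum(rowSums(x$obs > 0L) > 0L)
  cat(sprintf("Capture histories: %d individuals over %d years (%d ever resighted)\n",
              n, x$n_years, seen))
  invisible(x)
}

# Pool identical (ring_year, codes) histories with multiplicity weights.
# The likelihood is unchanged; the forward pass runs once per unique history.
pool_histories <- function(x) {
  key <- paste(x$ring_year, apply(x$obs, 1L, paste, collapse = ","))
  first <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[first])))
  list(obs = x$obs[first, , drop = FALSE],
       ring_year = x$ring_year[first],
       weight = as.numeric(w),
       n_total = nrow(x$obs))
}

# Long-form data.frame <-> capture_histories (CSV schema of io module).
histories_to_long <- function(x) {
  n <- nrow(x$obs)
  out <- do.call(rbind, lapply(seq_len(n), function(i) {
    yrs <- which(x$obs[i, ] >= 0L)
    data.frame(id = x$id[i], ring_year = x$ring_year[i],
               year = yrs, code = x$obs[i, yrs])
  }))
  rownames(out) <- NULL
  out
}

histories_from_long <- function(df, n_years) {
  need <- c("id", "ring_year", "year", "code")
  if (!all(need %in% names(df))) {
    bp_stop(sprintf("history table must have columns %s",
                    paste(need, collapse = ", ")))
  }
  if (any(df$code < 0L | df$code > 3L)) {
    bp_stop("illegal status code (must be 0..3)", class = "bp_history_error")
  }
  ids <- unique(df$id)
  obs <- matrix(-1L, nrow = length(ids), ncol = n_years)
  ring <- integer(length(ids))
  for (k in seq_along(ids)) {
    rows <- df[df$id == ids[k], , drop = FALSE]
    ring[k] <- rows$ring_year[1L]
    obs[k, rows$year] <- as.integer(rows$code)
    yrs <- (max(ring[k], 0L) + 1L):n_years
    if (ring[k] < n_years) obs[k, yrs[obs[k, yrs] < 0L]] <- 0L
  }
  capture_histories(obs, ring, ids)
}
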