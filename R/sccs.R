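#' Partition observation time into self-controlled case series intervals
#'
#' Cuts each person's observation period at every exposure-era boundary,
#' season (calendar-quarter) boundary, age-band birthday and co-drug era
#' boundary, producing intervals of constant covariate value that exactly
#' partition the observation time. Events are assigned to the unique
#' containing interval. Day 0 corresponds to 1 January of `ref_year`;
#' quarters are the 91/91/92/91-day blocks of a 365-day year (leap days
#' are ignored at claims-day granularity).
#'
#' @param observation_periods Tibble `person_id`, `start_day`, `end_day`.
#' @param eras Exposure eras (`person_id`, `era_start_day`, `era_end_day`),
#'   built with the 90-day gap rule.
#' @param events Outcome occurrences (`person_id`, `day`); every event must
#'   lie inside its person's observation period.
#' @param persons Optional `persons` table with `year_of_birth`; when
#'   supplied (with `age_band_years`), age bands become a time-varying
#'   covariate.
#' @param age_band_years Width of age bands in years (default 5); `NULL`
#'   disables the age covariate.
#' @param seasons Cut at calendar quarters (default `TRUE`).
#' @param co_drug_eras Optional named list of era tibbles, one per
#'   co-medication; each becomes a logical `co_<name>` covariate.
#' @param ref_year Calendar year of day 0.
#' @return Tibble of intervals: `person_id`, `start_day`, `end_day`,
#'   `length_days`, `exposed`, `season`, `age_band`, `co_*` flags,
#'   `n_events`.
#' @export
build_sccs_intervals <- function(observation_periods, eras, events,
                                 persons = NULL, age_band_years = 5,
                                 seasons = TRUE, co_drug_eras = NULL,
                                 ref_year = 2010) {
  obs <- tibble::as_tibble(observation_periods)
  ev_chk <- dplyr::left_join(events, obs, by = "person_id")
  bad <- is.na(ev_chk$start_day) | ev_chk$day < ev_chk$start_day |
    ev_chk$day > ev_chk$end_day
  if (any(bad)) {
    abort("event(s) outside the person's observation period.",
          class = "safetysignal_data_error")
  }

  era_list <- split(eras, eras$person_id)
  co_lists <- purrr::map(co_drug_eras, ~ split(.x, .x$person_id))
  ev_list <- split(events$day, events$person_id)
  yob <- NULL
  if (!is.null(persons) && !is.null(age_band_years)) {
    yob <- stats::setNames(persons$year_of_birth, persons$person_id)
  }
  qdays <- c(0L, 91L, 182L, 273L)

  per_person <- function(pid, s0, e0) {
    key <- as.character(pid)
    er <- era_list[[key]]
    cuts <- c(s0, e0 + 1L)
    if (!is.null(er)) {
      cuts <- c(cuts, er$era_start_day, er$era_end_day + 1L)
    }
    if (seasons) {
      yr <- 0:(e0 %/% 365L + 1L)
      sb <- as.vector(outer(365L * yr, qdays, `+`))
      cuts <- c(cuts, sb[sb > s0 & sb <= e0])
    }
    if (!is.null(yob)) {
      age0 <- ref_year - yob[[key]]
      bands <- seq(age_band_years * ((age0 %/% age_band_years) + 1L),
                   age0 + e0 %/% 365L + age_band_years + 1L,
                   by = age_band_years)
      bd <- as.integer(ceiling((bands - age0) * 365.25))
      cuts <- c(cuts, bd[bd > s0 & bd <= e0])
    }
    for (cl in co_lists) {
      ce <- cl[[key]]
      if (!is.null(ce)) {
        cuts <- c(cuts, ce$era_start_day, ce$era_end_day + 1L)
      }
    }
    cuts <- sort(unique(pmax(pmin(cuts, e0 + 1L), s0)))
    start <- cuts[-length(cuts)]
    end <- cuts[-1] - 1L
    keep <- end >= start
    start <- start[keep]; end <- end[keep]

    in_eras <- function(d, e) {
      if (is.null(e)) return(rep(FALSE, length(d)))
      vapply(d, function(x) any(x >= e$era_start_day &
                                  x <= e$era_end_day), logical(1))
    }
    out <- tibble::tibble(
      person_id = pid, start_day = start, end_day = end,
      length_days = end - start + 1L,
      exposed = in_eras(start, er),
      season = (start %% 365L) %/% 91L %% 4L + 1L
    )
    out$age_band <- if (!is.null(yob)) {
      age <- (ref_year - yob[[key]]) + start / 365.25
      as.integer(age %/% age_band_years) * age_band_years
    } else {
      0L
    }
    for (nm in names(co_lists)) {
      out[[paste0("co_", nm)]] <- in_eras(start, co_lists[[nm]][[key]])
    }
    evd <- ev_list[[key]]
    out$n_events <- if (is.null(evd)) {
      0L
    } else {
      as.integer(tabulate(findInterval(evd, cuts), nbins = length(start)))
    }
    out
  }

  purrr::pmap_dfr(
    list(obs$person_id, obs$start_day, obs$end_day), per_person
  )
}

#' Fit the self-controlled case series model
#'
#' Conditional Poisson regression on the interval table: for each case
#' (person with at least one event), the event counts over that person's
#' intervals are multinomial with probabilities proportional to
#' `length_days * exp(x beta)`, conditioning on the person's event total --
#' which cancels every time-invariant per-person effect, including
#' unmeasured frailty. The exposure coefficient is never penalized;
#' nuisance covariates (age band, season, co-drugs) are L1-regularized with
#' the penalty chosen by seeded k-fold cross-validation over cases
#' (out-of-fold conditional log-likelihood), followed by an unpenalized
#' refit on the selected support from which the reported standard error is
#' taken.
#'
#' @param intervals Output of [build_sccs_intervals()].
#' @param regularize_covariates Penalize nuisance covariates (default
#'   `TRUE`; ignored when there are none).
#' @param cv_folds Cross-validation folds (default 10, capped at the
#'   number of cases).
#' @param seed Seed for the fold split.
#' @param n_lambda Penalty-grid size.
#' @return Object of class `sccs_fit`: `log_irr`, `se`, `irr`, `ci95_low`,
#'   `ci95_high`, `p`, `n_cases`, `n_events_exposed`,
#'   `n_events_unexposed`, `selected_penalty`, `coefficients`,
#'   `estimable`.
#' @export
fit_sccs <- function(intervals, regularize_covariates = TRUE,
                     cv_folds = 10, seed = 1, n_lambda = 10) {
  d <- intervals |>
    dplyr::filter(.data$length_days > 0) |>
    dplyr::group_by(.data$person_id) |>
    dplyr::filter(sum(.data$n_events) > 0L) |>
    dplyr::ungroup()
  if (!nrow(d)) {
    abort("no cases (persons with >= 1 event).",
          class = "safetysignal_estimation_error")
  }
  n_ev_exp <- sum(d$n_events[d$exposed])
  n_ev_unexp <- sum(d$n_events[!d$exposed])
  n_cases <- dplyr::n_distinct(d$person_id)
  res_na <- structure(
    list(log_irr = NA_real_, se = NA_real_, irr = NA_real_,
         ci95_low = NA_real_, ci95_high = NA_real_, p = NA_real_,
         n_cases = n_cases, n_events_exposed = n_ev_exp,
         n_events_unexposed = n_ev_unexp, selected_penalty = NA_real_,
         coefficients = tibble::tibble(term = character(),
                                       estimate = double()),
         estimable = FALSE),
    class = "sccs_fit"
  )
  if (sum(d$length_days[d$exposed]) == 0 ||
      sum(d$length_days[!d$exposed]) == 0) {
    warn("no exposed (or no unexposed) time among cases; IRR inestimable.")
    return(res_na)
  }

  # design: exposure first, then nuisance dummies (first level dropped)
  nuis <- NULL
  mk_dummies <- function(v, prefix) {
    lev <- sort(unique(v))
    if (length(lev) < 2L) return(NULL)
    m <- vapply(lev[-1], function(l) as.numeric(v == l),
                numeric(length(v)))
    colnames(m) <- paste0(prefix, lev[-1])
    m
  }
  nuis <- cbind(nuis, mk_dummies(d$season, "season_"))
  nuis <- cbind(nuis, mk_dummies(d$age_band, "age_"))
  for (nm in grep("^co_", names(d), value = TRUE)) {
    v <- as.numeric(d[[nm]])
    if (length(unique(v)) > 1L) {
      m <- matrix(v, ncol = 1, dimnames = list(NULL, nm))
      nuis <- cbind(nuis, m)
    }
  }
  X <- cbind(exposed = as.numeric(d$exposed), nuis)
  pidx <- match(d$person_id, unique(d$person_id))
  y <- d$n_events
  off <- log(d$length_days)
  pen_idx <- if (ncol(X) > 1L) 2:ncol(X) else integer()

  lambda <- 0
  if (regularize_covariates && length(pen_idx)) {
    set.seed(seed)
    ids <- unique(pidx)
    k <- min(cv_folds, length(ids))
    foldid <- sample(rep(seq_len(k), length.out = length(ids)))[pidx]
    b0 <- sccs_newton(X[, 1, drop = FALSE], y, off, pidx)$beta
    g <- sccs_grad(c(b0, rep(0, length(pen_idx))), X, y, off, pidx)
    lmax <- max(abs(g[pen_idx]), 1e-8)
    grid <- exp(seq(log(lmax), log(lmax * 1e-3), length.out = n_lambda))
    cvll <- vapply(grid, function(lam) {
      sum(vapply(seq_len(k), function(f) {
        tr <- foldid != f
        fit <- sccs_fista(X[tr, , drop = FALSE], y[tr], off[tr],
                          pidx[tr], lam, pen_idx)
        sccs_loglik(fit, X[!tr, , drop = FALSE], y[!tr], off[!tr],
                    pidx[!tr])
      }, numeric(1)))
    }, numeric(1))
    lambda <- grid[which.max(cvll)]
    bpen <- sccs_fista(X, y, off, pidx, lambda, pen_idx)
    active <- c(1L, pen_idx[abs(bpen[pen_idx]) > 1e-8])
  } else {
    active <- seq_len(ncol(X))
  }

  fit <- sccs_newton(X[, active, drop = FALSE], y, off, pidx)
  if (!fit$converged || !is.finite(fit$beta[1]) ||
      abs(fit$beta[1]) > 20) {
    warn("SCCS fit did not converge; IRR inestimable.")
    return(res_na)
  }
  beta <- unname(fit$beta[1])
  se <- unname(sqrt(fit$vcov[1, 1]))
  out <- res_na
  out$log_irr <- beta
  out$se <- se
  out$irr <- exp(beta)
  out$ci95_low <- exp(beta - Z95 * se)
  out$ci95_high <- exp(beta + Z95 * se)
  out$p <- 2 * pnorm(-abs(beta / se))
  out$selected_penalty <- lambda
  out$coefficients <- tibble::tibble(
    term = colnames(X)[active], estimate = fit$beta
  )
  out$estimable <- TRUE
  out
}

#' @export
print.sccs_fit <- function(x, ...) {
  if (!x$estimable) {
    cat("<sccs_fit>  inestimable (", x$n_cases, "cases )\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<sccs_fit>  IRR = %.3f [%.3f, %.3f]  p = %.3g  (%d cases)\n",
    x$irr, x$ci95_low, x$ci95_high, x$p, x$n_cases))
  invisible(x)
}

#' @rdname fit_sccs
#' @param x An `sccs_fit`.
#' @param ... Unused.
#' @method tidy sccs_fit
#' @export
tidy.sccs_fit <- function(x, ...) x$coefficients

#' @rdname fit_sccs
#' @method glance sccs_fit
#' @export
glance.sccs_fit <- function(x, ...) {
  tibble::tibble(
    log_irr = x$log_irr, se = x$se, irr = x$irr,
    ci95_low = x$ci95_low, ci95_high = x$ci95_high, p = x$p,
    n_cases = x$n_cases, n_events_exposed = x$n_events_exposed,
    n_events_unexposed = x$n_events_unexposed,
    selected_penalty = x$selected_penalty, estimable = x$estimable
  )
}

# ---- conditional Poisson internals -------------------------------------
# log-likelihood (up to the multinomial constant) of the within-person
# multinomial model, for interval design X, counts y, offset log-length,
# person index pidx

sccs_parts <- function(beta, X, y, off, pidx) {
  pid <- match(pidx, sort(unique(pidx))) # contiguous 1..P
  eta <- drop(X %*% beta) + off
  mm <- ave(eta, pid, FUN = max) # per-element person max (stable LSE)
  w <- exp(eta - mm)
  denom <- as.vector(rowsum(w, pid)) # row i = person i
  first <- !duplicated(pid)
  mxp <- numeric(max(pid))
  mxp[pid[first]] <- mm[first]
  list(eta = eta, w = w / denom[pid], lden = log(denom) + mxp, pid = pid)
}

sccs_loglik <- function(beta, X, y, off, pidx) {
  p <- sccs_parts(beta, X, y, off, pidx)
  Np <- as.vector(rowsum(y, p$pid))
  sum(y * p$eta) - sum(Np * p$lden)
}

sccs_grad <- function(beta, X, y, off, pidx) {
  p <- sccs_parts(beta, X, y, off, pidx)
  Np <- as.vector(rowsum(y, p$pid))
  drop(crossprod(X, y) - crossprod(X, Np[p$pid] * p$w))
}

sccs_info <- function(beta, X, y, off, pidx) {
  p <- sccs_parts(beta, X, y, off, pidx)
  Np <- as.vector(rowsum(y, p$pid))
  A <- crossprod(X, X * (Np[p$pid] * p$w))
  G <- rowsum(X * p$w, p$pid)
  A - crossprod(G, G * Np)
}

sccs_newton <- function(X, y, off, pidx, tol = 1e-10, max_iter = 50) {
  beta <- rep(0, ncol(X))
  ll <- sccs_loglik(beta, X, y, off, pidx)
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    g <- sccs_grad(beta, X, y, off, pidx)
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    I <- sccs_info(beta, X, y, off, pidx)
    step <- tryCatch(solve(I + diag(1e-10, ncol(X)), g),
                     error = function(e) g * 0.01)
    h <- 1
    repeat {
      cand <- beta + h * step
      llc <- sccs_loglik(cand, X, y, off, pidx)
      if (llc >= ll - 1e-12 || h < 1e-8) break
      h <- h / 2
    }
    if (abs(llc - ll) < 1e-13 && max(abs(g)) < 1e-6) {
      beta <- cand; converged <- TRUE; break
    }
    beta <- cand; ll <- llc
  }
  I <- sccs_info(beta, X, y, off, pidx)
  vcov <- tryCatch(solve(I), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  list(beta = beta, vcov = vcov, loglik = ll, converged = converged)
}

# FISTA on the L1-penalized negative conditional log-likelihood;
# coordinates in pen_idx are soft-thresholded, the rest are free
sccs_fista <- function(X, y, off, pidx, lambda, pen_idx,
                       max_iter = 500, tol = 1e-7) {
  k <- ncol(X)
  beta <- rep(0, k)
  zt <- beta
  t_acc <- 1
  L <- max(1, sum(y)) # Lipschitz guess, adapted by backtracking
  f <- function(b) -sccs_loglik(b, X, y, off, pidx)
  gr <- function(b) -sccs_grad(b, X, y, off, pidx)
  fz <- f(zt)
  for (i in seq_len(max_iter)) {
    g <- gr(zt)
    repeat {
      cand <- zt - g / L
      cand[pen_idx] <- soft_threshold(cand[pen_idx], lambda / L)
      fc <- f(cand)
      qc <- fz + sum(g * (cand - zt)) + L / 2 * sum((cand - zt)^2)
      if (fc <= qc + 1e-12 || L > 1e12) break
      L <- L * 2
    }
    t_new <- (1 + sqrt(1 + 4 * t_acc^2)) / 2
    znew <- cand + (t_acc - 1) / t_new * (cand - beta)
    if (max(abs(cand - beta)) < tol) { beta <- cand; break }
    beta <- cand
    zt <- znew
    t_acc <- t_new
    fz <- f(zt)
  }
  beta
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
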