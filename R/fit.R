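# Maximum-likelihood estimation of the latent-class conditional logit from
# observed choices. The likelihood of one woman's choice is a mixture over
# classes: P(y_i) = sum_c pi_ic * softmax_c(V_i)[y_i], with pi from the
# membership multinomial logit. Estimation maximises the marginal
# log-likelihood directly with BFGS from several perturbed starts, and
# reports standard errors from the inverse numerical Hessian. Used both to
# refit simulated choices (parameter recovery) and to ingest externally
# estimated coefficients.

pack_params <- function(gamma, betas) c(gamma, unlist(betas))

unpack_params <- function(theta, p_m, p_u, n_classes) {
  gamma <- theta[seq_len(p_m)]
  betas <- vector("list", n_classes)
  off <- p_m
  for (c_i in seq_len(n_classes)) {
    betas[[c_i]] <- theta[off + seq_len(p_u)]
    off <- off + p_u
  }
  list(gamma = gamma, betas = betas)
}

# Marginal log-likelihood of the 2+-class model.
# Z: n x p_m membership design; X: (sum alts) x p_u alternative design;
# chooser: alt-row -> woman index; chosen: logical per alt row.
lc_loglik <- function(theta, Z, X, chooser, chosen, n_classes) {
  pr <- unpack_params(theta, ncol(Z), ncol(X), n_classes)
  n <- nrow(Z)
  lp_m <- cbind(0, Z %*% matrix(pr$gamma, ncol = n_classes - 1))
  lp_m <- lp_m - apply(lp_m, 1, max)
  pi_m <- exp(lp_m)
  pi_m <- pi_m / rowSums(pi_m)
  lik <- numeric(n)
  for (c_i in seq_len(n_classes)) {
    v <- drop(X %*% pr$betas[[c_i]])
    ev <- exp(v - max(v))
    denom <- rowsum(ev, chooser)[, 1]
    p_chosen <- ev[chosen] / denom[chooser[chosen]]
    lik <- lik + pi_m[, c_i] * p_chosen
  }
  sum(log(pmax(lik, 1e-300)))
}

#' Fit a latent-class conditional logit to observed choices
#'
#' @param data Long tibble with one row per woman-alternative: a `woman_id`
#'   column, a logical `chosen` column marking the selected alternative,
#'   the alternative-level utility covariates and the woman-level
#'   membership covariates (constant within `woman_id`).
#' @param membership_vars Names of woman-level covariates for the
#'   class-membership logit (an intercept is always added).
#' @param utility_vars Names of alternative-level covariates for the
#'   class-conditional utility.
#' @param n_classes Number of latent classes (default 2).
#' @param n_starts Number of perturbed BFGS starts; the best likelihood
#'   wins.
#' @param maxit BFGS iteration cap per start.
#' @return An `lc_logit_fit`: coefficient and standard-error vectors for
#'   the membership and per-class utility models (classes ordered by
#'   increasingly negative distance sensitivity of the first utility
#'   covariate), the log-likelihood and convergence info. Has [tidy()] and
#'   [glance()] methods.
#' @export
fit_latent_class_logit <- function(data, membership_vars, utility_vars,
                                   n_classes = 2, n_starts = 3, maxit = 500) {
  data <- as_tibble(data)
  stop_if_missing_cols(data, c("woman_id", "chosen", membership_vars, utility_vars),
                       "choice data")
  data <- arrange(data, .data$woman_id)
  chooser <- as.integer(factor(data$woman_id))
  chosen <- as.logical(data$chosen)
  if (!all(tapply(chosen, chooser, sum) == 1)) {
    abort("each woman_id must have exactly one chosen alternative")
  }
  first_row <- !duplicated(chooser)
  Z <- cbind(intercept = 1, as.matrix(data[first_row, membership_vars, drop = FALSE]))
  X <- as.matrix(data[, utility_vars, drop = FALSE])
  p_m <- ncol(Z) * (n_classes - 1)
  p_u <- ncol(X)

  negll <- function(theta) -lc_loglik(theta, Z, X, chooser, chosen, n_classes)
  # neutral start: zero membership, class utilities split on the first
  # covariate so the classes can separate
  base_beta <- rep(0, p_u)
  starts <- lapply(seq_len(n_starts), function(s) {
    betas <- lapply(seq_len(n_classes), function(c_i) {
      b <- base_beta
      b[1] <- -0.05 * c_i
      b
    })
    th <- pack_params(rep(0, p_m), betas)
    if (s > 1) th <- th + rnorm(length(th), 0, 0.15)
    th
  })
  fits <- lapply(starts, function(th) {
    tryCatch(optim(th, negll, method = "BFGS", control = list(maxit = maxit)),
             error = function(e) list(value = Inf, convergence = 1L))
  })
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  if (!is.finite(best$value)) abort("latent-class fit failed from every start")
  hess <- optimHess(best$par, negll)
  se <- tryCatch(sqrt(diag(solve(hess))), error = function(e) rep(NA_real_, length(best$par)))

  pr <- unpack_params(best$par, ncol(Z), ncol(X), n_classes)
  se_pr <- unpack_params(se, ncol(Z), ncol(X), n_classes)
  # canonical class order: most negative first utility coefficient first
  ord <- order(vapply(pr$betas, `[[`, 0, 1))
  if (n_classes == 2 && !identical(ord, 1:2)) {
    pr$betas <- pr$betas[ord]
    se_pr$betas <- se_pr$betas[ord]
    pr$gamma <- -pr$gamma # swapping 2 classes flips the membership logit
  }
  name_beta <- function(b) setNames(b, utility_vars)
  structure(list(
    membership = list(coef = setNames(pr$gamma, colnames(Z)),
                      se = setNames(se_pr$gamma, colnames(Z))),
    utility = lapply(seq_len(n_classes), function(c_i) {
      list(coef = name_beta(pr$betas[[c_i]]), se = name_beta(se_pr$betas[[c_i]]))
    }),
    logLik = -best$value,
    n_obs = nrow(Z),
    n_classes = n_classes,
    convergence = best$convergence
  ), class = "lc_logit_fit")
}

#' @export
print.lc_logit_fit <- function(x, ...) {
  cat(sprintf("<lc_logit_fit> %d classes, %d choosers, logLik = %.2f\n",
              x$n_classes, x$n_obs, x$logLik))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a latent-class logit fit
#'
#' @param x An `lc_logit_fit`.
#' @param ... Unused.
#' @return Tibble with `component` (`membership` or `utility_class<c>`),
#'   `term`, `estimate`, `std.error`.
#' @method tidy lc_logit_fit
#' @export
tidy.lc_logit_fit <- function(x, ...) {
  rows <- list(tibble(component = "membership",
                      term = names(x$membership$coef),
                      estimate = unname(x$membership$coef),
                      std.error = unname(x$membership$se)))
  for (c_i in seq_len(x$n_classes)) {
    blk <- x$utility[[c_i]]
    rows[[c_i + 1]] <- tibble(component = sprintf("utility_class%d", c_i),
                              term = names(blk$coef),
                              estimate = unname(blk$coef),
                              std.error = unname(blk$se))
  }
  bind_rows(rows)
}

#' Glance at a latent-class logit fit
#'
#' @inheritParams tidy.lc_logit_fit
#' @return One-row tibble with `logLik`, `AIC`, `nobs`, `n_classes`,
#'   `converged`.
#' @method glance lc_logit_fit
#' @export
glance.lc_logit_fit <- function(x, ...) {
  k <- length(x$membership$coef) + sum(lengths(lapply(x$utility, `[[`, "coef")))
  tibble(logLik = x$logLik, AIC = 2 * k - 2 * x$logLik, nobs = x$n_obs,
         n_classes = x$n_classes, converged = x$convergence == 0)
}
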